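# Compact FCS 3.1 I/O: list-mode, single-precision float, little-endian.

#' Write an event matrix to an FCS 3.1 file
#'
#' Writes list-mode single-precision float data ($DATATYPE F, $MODE L,
#' $BYTEORD 1,2,3,4). Channel names go to $PnN and marker short names to
#' $PnS. Only the channel data are written; truth sidecar labels never
#' enter the file.
#'
#' @param events a `cyto_events` object or a numeric matrix with channel
#'   column names.
#' @param path output file path.
#' @param panel optional panel data.frame supplying marker names.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, panel = NULL) {
  if (inherits(events, "cyto_events")) {
    panel <- panel %||% events$panel
    exprs <- events$exprs
  } else exprs <- events
  stopifnot(is.matrix(exprs), !is.null(colnames(exprs)))
  n_par <- ncol(exprs)
  n_tot <- nrow(exprs)
  markers <- colnames(exprs)
  if (!is.null(panel)) {
    i <- match(colnames(exprs), panel$channel)
    markers[!is.na(i)] <- panel$marker[i[!is.na(i)]]
  }

  delim <- "/"
  # $BEGINDATA/$ENDDATA are zero-padded to fixed width so the TEXT segment
  # length does not depend on their values (avoids offset circularity).
  make_kv <- function(bd, ed) {
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%010d", bd),
            "$ENDDATA", sprintf("%010d", ed),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0",
            "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
    for (j in seq_len(n_par)) {
      kv <- c(kv, sprintf("$P%dN", j), colnames(exprs)[j],
              sprintf("$P%dS", j), markers[j],
              sprintf("$P%dB", j), "32",
              sprintf("$P%dE", j), "0,0",
              sprintf("$P%dR", j),
              as.character(max(1, ceiling(max(exprs[, j], 0)))))
    }
    paste0(delim, paste0(kv, delim, collapse = ""))
  }
  header_len <- 58L
  text_len <- nchar(make_kv(0, 0), type = "bytes")
  text_begin <- header_len
  text_end <- text_begin + text_len - 1L
  data_begin <- if (n_tot > 0) text_end + 1L else 0L
  data_end <- if (n_tot > 0) data_begin + 4L * n_par * n_tot - 1L else 0L
  text <- make_kv(data_begin, data_end)
  stopifnot(nchar(text, type = "bytes") == text_len)

  off <- function(x) {
    s <- if (x > 99999999) "0" else as.character(x)
    sprintf("%8s", s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(paste0(off(text_begin), off(text_end), off(data_begin),
                   off(data_end), off(0), off(0)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n_tot > 0)
    writeBin(as.numeric(t(exprs)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file written in list-mode float format
#'
#' Parses the HEADER and TEXT segments, validates the required keywords
#' and reads the DATA segment into an events-by-channels matrix.
#'
#' @param path FCS file path.
#' @return a `cyto_events` object (panel reconstructed from $PnN/$PnS;
#'   roles are not stored in FCS and come back as `"unknown"`).
#' @export
read_fcs <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58)
    cp_stop("FCS parse error at offset 0: file too short for an FCS header")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 10, useBytes = TRUE)
  if (substr(magic, 1, 6) != "FCS3.1" && substr(magic, 1, 6) != "FCS3.0")
    cp_stop("FCS parse error at offset 0: missing FCS3.x magic")
  offs <- suppressWarnings(as.integer(vapply(1:6, function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  if (anyNA(offs[1:2]))
    cp_stop("FCS parse error at offset 10: unreadable TEXT segment offsets")
  seek(con, offs[1])
  text <- readChar(con, offs[2] - offs[1] + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, toupper(keys))
  need <- function(k) {
    if (!k %in% names(kw))
      cp_stop("FCS parse error: missing required keyword %s", k)
    kw[[k]]
  }
  if (need("$DATATYPE") != "F")
    cp_stop("FCS parse error: unsupported $DATATYPE '%s' (only F)",
            kw[["$DATATYPE"]])
  if (need("$MODE") != "L")
    cp_stop("FCS parse error: unsupported $MODE '%s' (only L)", kw[["$MODE"]])
  byteord <- need("$BYTEORD")
  endian <- if (byteord == "1,2,3,4") "little" else
    if (byteord == "4,3,2,1") "big" else
      cp_stop("FCS parse error: unsupported $BYTEORD '%s'", byteord)
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  ch <- vapply(seq_len(n_par), function(j) need(sprintf("$P%dN", j)), "")
  mk <- vapply(seq_len(n_par), function(j) {
    k <- sprintf("$P%dS", j)
    if (k %in% names(kw)) kw[[k]] else ch[j]
  }, "")
  if (n_tot > 0) {
    data_begin <- as.integer(need("$BEGINDATA"))
    if (data_begin == 0) data_begin <- offs[3]
    seek(con, data_begin)
    vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4,
                    endian = endian)
    if (length(vals) < n_par * n_tot)
      cp_stop("FCS parse error: DATA segment truncated at offset %d",
              data_begin + 4 * length(vals))
    exprs <- matrix(vals, ncol = n_par, byrow = TRUE,
                    dimnames = list(NULL, ch))
  } else {
    exprs <- matrix(numeric(0), 0, n_par, dimnames = list(NULL, ch))
  }
  panel <- data.frame(channel = ch, marker = mk, role = "unknown")
  panel$role[ch == "Time"] <- "time"
  new_cyto_events(exprs, panel)
}
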