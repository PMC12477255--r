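# Hierarchical threshold gating: config-driven gate tree over arcsinh
# intensities, rooted at the CD45+CD66- mononuclear gate.

#' Default hierarchical gate configuration
#'
#' Encodes the standard mononuclear immunophenotyping strategy with a
#' CD45+CD66- root and 13 reported populations: CD4 T, CD8 T, activated
#' (HLA-DR+Ki67+) CD8 T, CD3+CD4-CD8- T, B cells, IgM+ B cells, CD56+CD16-
#' and CD16+ NK cells, pDC, mDC and classical / intermediate /
#' non-classical monocytes. Cutoffs are on the arcsinh(x/5) scale and
#' default to the midpoint between the synthetic negative and positive
#' modes; every cutoff is config-overridable.
#'
#' @param cutoff default threshold on the arcsinh(x/5) scale.
#' @return list of gate node specs for [build_gate_tree()].
#' @export
default_gate_config <- function(cutoff = 2.25) {
  g <- function(marker, op) list(marker = marker, op = op, cutoff = cutoff)
  node <- function(name, parent, rule, reported = TRUE)
    list(name = name, parent = parent, rule = rule, reported = reported)
  list(
    node("mononuclear", NULL, list(g("CD45", ">"), g("CD66", "<")),
         reported = FALSE),
    node("CD4T", "mononuclear",
         list(g("CD3", ">"), g("CD4", ">"), g("CD8", "<"))),
    node("CD8T", "mononuclear",
         list(g("CD3", ">"), g("CD8", ">"), g("CD4", "<"))),
    node("CD8Tact", "CD8T", list(g("HLADR", ">"), g("Ki67", ">"))),
    node("DNT", "mononuclear",
         list(g("CD3", ">"), g("CD4", "<"), g("CD8", "<"))),
    node("B", "mononuclear", list(g("CD3", "<"), g("CD20", ">"))),
    node("BIgM", "B", list(g("IgM", ">"))),
    node("NK56", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD56", ">"), g("CD16", "<"))),
    node("NK16", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD56", "<"), g("CD16", ">"),
              g("CD14", "<"), g("HLADR", "<"))),
    node("pDC", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD14", "<"), g("CD123", ">"),
              g("HLADR", ">"))),
    node("mDC", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD14", "<"), g("CD16", "<"),
              g("CD123", "<"), g("CD11c", ">"), g("HLADR", ">"))),
    node("cMC", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD14", ">"), g("CD16", "<"))),
    node("intMC", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD14", ">"), g("CD16", ">"),
              g("CD11b", ">"), g("HLADR", ">"))),
    node("ncMC", "mononuclear",
         list(g("CD3", "<"), g("CD20", "<"), g("CD14", "<"), g("CD16", ">"),
              g("CD11b", ">"), g("HLADR", ">")))
  )
}

#' Build a gate tree from a node configuration
#'
#' Validates the node list (unique names, acyclic parent links, known
#' panel markers, valid operators) and orders nodes topologically.
#'
#' @param config list of node specs (see [default_gate_config()]).
#' @param panel panel data.frame mapping markers to channels.
#' @return object of class `gate_tree`.
#' @export
build_gate_tree <- function(config = default_gate_config(),
                            panel = default_panel()) {
  names_ <- vapply(config, `[[`, "", "name")
  if (anyDuplicated(names_))
    cp_stop("configuration error: duplicate gate names: %s",
            paste(unique(names_[duplicated(names_)]), collapse = ", "))
  for (nd in config) {
    if (!is.null(nd$parent) && !nd$parent %in% names_)
      cp_stop("configuration error: node '%s' has unknown parent '%s'",
              nd$name, nd$parent)
    if (!is.null(nd$parent) && nd$parent == nd$name)
      cp_stop("configuration error: node '%s' is its own parent", nd$name)
    for (rl in nd$rule) {
      if (!rl$op %in% c(">", "<"))
        cp_stop("configuration error: invalid operator '%s' in node '%s'",
                rl$op, nd$name)
      marker_to_channel(panel, rl$marker)
    }
  }
  # topological order; failure to place every node means a cycle
  placed <- character(0)
  order_ <- integer(0)
  remaining <- seq_along(config)
  while (length(remaining)) {
    ready <- remaining[vapply(config[remaining], function(nd)
      is.null(nd$parent) || nd$parent %in% placed, TRUE)]
    if (!length(ready))
      cp_stop("configuration error: cycle in gate tree involving: %s",
              paste(names_[remaining], collapse = ", "))
    placed <- c(placed, names_[ready])
    order_ <- c(order_, ready)
    remaining <- setdiff(remaining, ready)
  }
  nodes <- config[order_]
  names(nodes) <- names_[order_]
  reported <- names(nodes)[vapply(nodes, function(nd)
    isTRUE(nd$reported), TRUE)]
  structure(list(nodes = nodes, panel = panel, reported = reported,
                 root = names(nodes)[vapply(nodes, function(nd)
                   is.null(nd$parent), TRUE)][1]),
            class = "gate_tree")
}

#' @export
print.gate_tree <- function(x, ...) {
  cat(sprintf("gate_tree: %d nodes, root '%s', %d reported populations\n",
              length(x$nodes), x$root, length(x$reported)))
  invisible(x)
}

# Reported parent of a reported node ("" for direct children of the root).
#' @noRd
reported_parent <- function(tree, name) {
  p <- tree$nodes[[name]]$parent
  while (!is.null(p) && !p %in% tree$reported)
    p <- tree$nodes[[p]]$parent
  p %||% ""
}

#' Apply a gate tree to events
#'
#' Transforms the gated channels to the arcsinh(x/cofactor) scale and
#' evaluates nodes top-down: an event belongs to a node iff it satisfies
#' the node's rule and its parent's membership. Events failing the
#' mononuclear root are excluded from all denominators; mononuclear events
#' matching no reported leaf remain "other". The per-event label is the
#' deepest reported node an event belongs to.
#'
#' @param events `cyto_events` or matrix.
#' @param tree a `gate_tree`.
#' @param cofactor arcsinh cofactor (default 5).
#' @return list of class `gate_result`: `membership` (events x nodes
#'   logical matrix), `counts` (named counts for reported populations),
#'   `mononuclear_total`, `labels` (deepest reported population per event;
#'   `"other"` for unannotated mononuclear events, NA for non-mononuclear).
#' @export
apply_gates <- function(events, tree, cofactor = 5) {
  stopifnot(inherits(tree, "gate_tree"))
  exprs <- get_exprs(events)
  n <- nrow(exprs)
  memb <- matrix(FALSE, n, length(tree$nodes),
                 dimnames = list(NULL, names(tree$nodes)))
  for (nm in names(tree$nodes)) {
    nd <- tree$nodes[[nm]]
    m <- if (is.null(nd$parent)) rep(TRUE, n) else memb[, nd$parent]
    for (rl in nd$rule) {
      ch <- marker_to_channel(tree$panel, rl$marker)
      if (!ch %in% colnames(exprs))
        cp_stop("missing channel '%s' (marker %s) in events", ch, rl$marker)
      z <- arcsinh_transform(exprs[, ch], cofactor)
      m <- m & (if (rl$op == ">") z > rl$cutoff else z < rl$cutoff)
    }
    memb[, nm] <- m
  }
  labels <- rep(NA_character_, n)
  labels[memb[, tree$root]] <- "other"
  for (nm in tree$reported)        # topological order: children overwrite
    labels[memb[, nm]] <- nm
  counts <- colSums(memb[, tree$reported, drop = FALSE])
  structure(list(membership = memb, counts = counts,
                 mononuclear_total = sum(memb[, tree$root]),
                 labels = labels, tree = tree),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate_result: %d mononuclear events, %d reported populations\n",
              x$mononuclear_total, length(x$counts)))
  invisible(x)
}
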