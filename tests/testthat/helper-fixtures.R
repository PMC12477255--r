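# Shared fixtures: small truth objects and simulated batches, cached per
# test run so expensive simulations happen once.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

tiny_truth <- function() fixture("tiny_truth", function()
  make_truth(default_config(n_animals = 2, n_events = 2000), seed = 1))

# no drift, no vaccination effects: clean parameter-recovery setting
flat_truth <- function() fixture("flat_truth", function()
  make_truth(default_config(n_animals = 2, n_events = 2000,
                            drift_range = 1, effect_scale = 0), seed = 3))

first_code <- function(truth) {
  sch <- barcode_scheme("s1", truth$config$barcode$n, truth$config$barcode$k)
  sch$codes[1, ]
}

# a pooled 6-sample batch with beads + doublets, plus its scheme
small_batch <- function() fixture("small_batch", function() {
  tr <- tiny_truth()
  grid <- expand.grid(a = tr$animals$animal_id, s = tr$config$stims,
                      stringsAsFactors = FALSE)
  keys <- paste(grid$a, "PBMC", grid$s, sep = "_")
  sch <- barcode_scheme(keys)
  metas <- lapply(seq_len(nrow(grid)), function(i)
    sample_meta(grid$a[i], "PBMC", grid$s[i], sch$codes[keys[i], ]))
  ev <- simulate_batch(tr, metas, n_events = 2000, bead_fraction = 0.05,
                       doublet_fraction = 0.02)
  list(truth = tr, events = ev, scheme = sch, keys = keys, metas = metas)
})

# gated sample list for feature tests: 2 animals x 2 tissues x 3 stims
gated_fixture <- function() fixture("gated", function() {
  tr <- flat_truth()
  tree <- build_gate_tree()
  grid <- expand.grid(a = tr$animals$animal_id, t = tr$config$tissues,
                      s = tr$config$stims, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    m <- sample_meta(grid$a[i], grid$t[i], grid$s[i],
                     barcode_code = first_code(tr))
    ev <- simulate_sample(tr, m, n_events = 4000, bead_fraction = 0)
    list(meta = list(animal_id = grid$a[i],
                     group = tr$animals$group[match(grid$a[i],
                                                    tr$animals$animal_id)],
                     tissue = grid$t[i], stim = grid$s[i]),
         gate = apply_gates(ev, tree), events = ev)
  })
  names(out) <- paste(grid$a, grid$t, grid$s, sep = "_")
  out
})

# truth fraction a gate node should recover: own component plus nested
# children components
gated_truth_fraction <- function(truth, animal, tissue, pop) {
  kids <- names(truth$pop_parent)[truth$pop_parent == pop]
  f <- truth$animal_freqs[animal, tissue, ]
  unname(f[pop] + sum(f[kids]))
}
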