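# Small shared fixtures. Simulated cohorts are cached per (config label,
# seed) within a test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  sim_config(n_donors = 20, n_cell_types = 4, n_proteins = 5,
             n_conditions = 5, cells_per_sample = 60, ...)
}

# a scaled cohort preserving the 86-donor / 16-condition / 9-type / 15-protein
# design but with fewer cells per sample (min_events scaled to match)
scaled_config <- function(...) {
  sim_config(cells_per_sample = 250, ...)
}

scaled_min_events <- 5

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_cohort <- function(seed = 1) {
  cached(paste0("tiny_", seed), simulate_cohort(tiny_config(), seed = seed))
}

tiny_features <- function(seed = 1) {
  cached(paste0("tinyfeat_", seed), {
    co <- tiny_cohort(seed)
    med <- compute_sample_medians(co, min_events = 5)
    fm <- derive_features(med)
    list(cohort = co, features = fm, responsive = threshold_features(fm))
  })
}

scaled_features <- function(seed = 1, ...) {
  cached(paste0("scaledfeat_", seed, "_", paste(c(...), collapse = "_")), {
    simulate_features(scaled_config(...), seed = seed,
                      min_events = scaled_min_events)
  })
}

# two planted correlation blocks (sizes 5 and 6), no cross-correlation:
# features are latent + small noise, a textbook module structure
block_matrix <- function(n_donors = 60, sizes = c(5, 6), noise = 0.3,
                         seed = 42) {
  set.seed(seed)
  X <- do.call(cbind, lapply(seq_along(sizes), function(b) {
    z <- rnorm(n_donors)
    sapply(seq_len(sizes[b]), function(i) z + rnorm(n_donors, 0, noise))
  }))
  colnames(X) <- unlist(lapply(seq_along(sizes), function(b)
    paste0("B", b, "_", seq_len(sizes[b]))))
  X
}

as_features <- function(X, donors = sprintf("d%02d", seq_len(nrow(X)))) {
  rownames(X) <- donors
  meta <- data.frame(feature = colnames(X),
                     protein = sub("_.*$", "", colnames(X)),
                     cell_type = "ct", condition = "stim",
                     stringsAsFactors = FALSE)
  structure(list(values = X, meta = meta, donors = donors),
            class = "stimmod_features")
}
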