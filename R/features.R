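#' Arcsinh intensity transform
#'
#' The standard cytometry variance-stabilising transform,
#' `arcsinh(x / cofactor)` with cofactor 5.
#'
#' @param x raw intensities (finite numeric).
#' @param cofactor positive scalar divisor.
#' @return transformed values, same shape as `x`.
#' @export
transform_intensity <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0)
    stop("'cofactor' must be a positive scalar", call. = FALSE)
  asinh(x / cofactor)
}

#' Per-sample signaling medians
#'
#' Computes the median arcsinh-transformed intensity of every protein in
#' every gated cell type of every (donor, condition) sample. Cell types
#' represented by fewer than `min_events` cells in a sample yield missing
#' medians (an unstable median is worse than an absent one); cell types
#' absent from a sample are likewise missing, never zero.
#'
#' @param events a `data.table`/data.frame with columns `donor`, `condition`,
#'   `cell_type` and one raw-intensity column per protein (as produced by
#'   [simulate_cohort()] or [read_event_tables()]), or a `stimmod_cohort`.
#' @param proteins character vector of protein column names; defaults to all
#'   columns beyond the three label columns.
#' @param cofactor arcsinh cofactor.
#' @param min_events minimum cells per (sample, cell type) for a usable median.
#' @return a `data.table` of class `stimmod_medians` with columns `donor`,
#'   `condition`, `cell_type`, `protein`, `median`, `n_events`, covering the
#'   full grid of observed samples x configured cell types x proteins.
#' @export
compute_sample_medians <- function(events, proteins = NULL, cofactor = 5,
                                   min_events = 20) {
  cell_types <- NULL
  if (inherits(events, "stimmod_cohort")) {
    if (is.null(proteins)) proteins <- events$config$proteins
    cell_types <- events$config$cell_types
    events <- events$events
  }
  events <- data.table::as.data.table(events)
  label_cols <- c("donor", "condition", "cell_type")
  miss <- setdiff(label_cols, names(events))
  if (length(miss))
    stop("event table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(proteins)) proteins <- setdiff(names(events), label_cols)
  unknown <- setdiff(proteins, names(events))
  if (length(unknown))
    stop("unknown protein columns: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cell_types)) cell_types <- sort(unique(events$cell_type))

  tr <- events[, c(label_cols, proteins), with = FALSE]
  for (p in proteins)
    data.table::set(tr, j = p, value = transform_intensity(tr[[p]], cofactor))

  donor <- condition <- cell_type <- n_events <- NULL # R CMD check NSE
  # two passes so data.table's grouped-median fast path applies
  med <- tr[, lapply(.SD, median), by = c(label_cols), .SDcols = proteins]
  cnt <- tr[, list(n_events = .N), by = c(label_cols)]
  med <- med[cnt, on = label_cols]

  # expand to the full (sample x cell type) grid so absent types are missing
  samples <- unique(med[, c("donor", "condition")])
  full <- samples[, list(cell_type = cell_types), by = c("donor", "condition")]
  med <- med[full, on = label_cols]
  med[is.na(n_events), n_events := 0L]

  long <- data.table::melt(med, id.vars = c(label_cols, "n_events"),
                           variable.name = "protein", value.name = "median",
                           variable.factor = FALSE)
  long[n_events < min_events, median := NA_real_]
  data.table::setcolorder(long, c("donor", "condition", "cell_type",
                                  "protein", "median", "n_events"))
  data.table::setattr(long, "class",
                      c("stimmod_medians", class(long)))
  long
}

#' Derive the donors x immune-features matrix
#'
#' An immune feature is the median arcsinh-transformed intensity of one
#' protein in one cell type under one condition, minus the matched
#' unstimulated median. The unstimulated condition is kept in the feature
#' enumeration (its deltas are identically zero), so the pre-threshold
#' feature count equals `conditions x cell_types x proteins` — 2,160 at the
#' default 16 x 9 x 15 design. A feature is missing for a donor when either
#' operand median is missing.
#'
#' @param medians a `stimmod_medians` table from [compute_sample_medians()].
#' @param unstim_condition condition id of the unstimulated reference.
#' @return an object of class `stimmod_features`: list with `values`
#'   (donors x features numeric matrix), `meta` (data.frame: `feature`,
#'   `protein`, `cell_type`, `condition`) and `donors`.
#' @export
derive_features <- function(medians, unstim_condition = "unstim") {
  stopifnot(inherits(medians, "stimmod_medians") || is.data.frame(medians))
  dt <- data.table::as.data.table(medians)
  donor <- condition <- NULL
  if (!unstim_condition %in% dt$condition)
    stop("unstimulated condition '", unstim_condition, "' not present",
         call. = FALSE)
  no_ref <- setdiff(unique(dt$donor), unique(dt[condition == unstim_condition]$donor))
  if (length(no_ref))
    stop("donors missing the unstimulated sample: ",
         paste(no_ref, collapse = ", "), call. = FALSE)

  ref <- dt[condition == unstim_condition,
            c("donor", "cell_type", "protein", "median")]
  data.table::setnames(ref, "median", "ref_median")
  dt <- ref[dt, on = c("donor", "cell_type", "protein")]
  dt[, delta := median - ref_median]

  dt[, feature := feature_id(protein, cell_type, condition)]
  donors <- unique(dt$donor)
  meta <- unique(dt[, c("feature", "protein", "cell_type", "condition")])
  data.table::setorder(meta, condition, cell_type, protein)

  wide <- data.table::dcast(dt, donor ~ feature, value.var = "delta")
  values <- as.matrix(wide, rownames = "donor")
  values <- values[donors, meta$feature, drop = FALSE]

  structure(list(values = values, meta = as.data.frame(meta), donors = donors),
            class = "stimmod_features")
}

#' Responsiveness threshold on immune features
#'
#' Keeps features whose cohort mean (over donors with non-missing values) is
#' at least `min_mean`; 0.2 on the arcsinh scale is the conventional cut
#' separating genuine stimulation responses from noise around baseline. The
#' boundary is inclusive. By default the signed mean is used, so strongly
#' negative-responding features are dropped too; set `use_abs = TRUE` to
#' threshold on the absolute mean instead.
#'
#' @param fm a `stimmod_features` object.
#' @param min_mean responsiveness threshold on the mean feature value.
#' @param use_abs threshold `|mean|` rather than the signed mean.
#' @return a `stimmod_features` object restricted to retained features, with
#'   attribute `dropped` (count) and `feature_means` (named vector).
#' @export
threshold_features <- function(fm, min_mean = 0.2, use_abs = FALSE) {
  stopifnot(inherits(fm, "stimmod_features"))
  if (ncol(fm$values) == 0L) stop("feature matrix is empty", call. = FALSE)
  mu <- colMeans(fm$values, na.rm = TRUE)
  crit <- if (use_abs) abs(mu) else mu
  keep <- !is.na(crit) & crit >= min_mean
  out <- structure(list(values = fm$values[, keep, drop = FALSE],
                        meta = fm$meta[keep, , drop = FALSE],
                        donors = fm$donors),
                   class = "stimmod_features")
  attr(out, "dropped") <- sum(!keep)
  attr(out, "feature_means") <- mu
  out
}

#' @export
print.stimmod_features <- function(x, ...) {
  cat(sprintf("Immune feature matrix: %d donors x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  proteins: %d, cell types: %d, conditions: %d; %.1f%% missing\n",
              length(unique(x$meta$protein)), length(unique(x$meta$cell_type)),
              length(unique(x$meta$condition)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Run simulation and feature derivation in one call
#'
#' Convenience wrapper: simulate a cohort, compute sample medians, derive
#' and threshold features.
#'
#' @inheritParams simulate_cohort
#' @param min_mean,min_events see [threshold_features()] and
#'   [compute_sample_medians()].
#' @return list with `cohort`, `features` (pre-threshold) and `responsive`
#'   (post-threshold `stimmod_features`).
#' @export
simulate_features <- function(config = sim_config(), seed = 1L,
                              min_mean = 0.2, min_events = 20) {
  cohort <- simulate_cohort(config, seed = seed)
  med <- compute_sample_medians(cohort, cofactor = config$cofactor,
                                min_events = min_events)
  fm <- derive_features(med, unstim_condition = config$unstim)
  list(cohort = cohort, features = fm,
       responsive = threshold_features(fm, min_mean = min_mean))
}
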