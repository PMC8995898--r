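#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. When both samples
#' have at most `exact_max` observations the two-sided p-value is computed
#' by exhaustive enumeration of all group splits of the observed pooled
#' values (so ties are handled exactly); otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' The statistic reported is the Mann-Whitney U for the first sample.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the enumeration path.
#' @return list of class `stimmod_test`: `statistic` (U), `p_value`,
#'   `method`, `medians` (per group), `n` (per group).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(test_result(U, 1, "wilcoxon (degenerate)", x, y))
  }

  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate every assignment of the pooled midranks to group 1
    splits <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_null - mu) >= abs(U - mu) - 1e-12)
    return(test_result(U, p, "wilcoxon (exact enumeration)", x, y))
  }

  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(U, p, "wilcoxon (normal approximation)", x, y)
}

test_result <- function(stat, p, method, x, y, adjusted_p = NA_real_) {
  structure(list(statistic = stat, p_value = p, adjusted_p = adjusted_p,
                 method = method,
                 medians = c(stats::median(x), stats::median(y)),
                 means = c(mean(x), mean(y)),
                 n = c(length(x), length(y))),
            class = "stimmod_test")
}

#' @export
print.stimmod_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(" (adjusted %.4g)", x$adjusted_p))
  cat(sprintf("\n  group medians: %.4g vs %.4g (n = %d, %d)\n",
              x$medians[1], x$medians[2], x$n[1], x$n[2]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference of the two empirical CDFs;
#' the p-value uses the asymptotic Kolmogorov distribution at effective
#' sample size `n1 * n2 / (n1 + n2)`, appropriate for the cohort-scale group
#' sizes this package targets.
#'
#' @param x,y numeric samples.
#' @return a `stimmod_test` list (`statistic` is D).
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pooled)
  Fy <- stats::ecdf(y)(pooled)
  D <- max(abs(Fx - Fy))
  ne <- n1 * n2 / (n1 + n2)
  t <- sqrt(ne) * D
  if (t < 1e-12) {
    p <- 1
  } else {
    k <- seq_len(100)
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  }
  test_result(D, p, "kolmogorov-smirnov (asymptotic)", x, y)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: `p * m / rank`, enforced monotone by a
#' running minimum from the largest p downwards, capped at 1. Missing
#' p-values are passed through as missing and do not count toward `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pv)
  out <- rep(NA_real_, length(p))
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(pv[o] * m / (m - seq_len(m) + 1)))[ro]
    out[ok] <- adj
  }
  out
}

#' Sex-stratified correlation matrices in a fixed feature order
#'
#' Computes the feature correlation matrix separately within each group of
#' donors (typically the two sexes), with every matrix laid out in the same
#' feature order — by convention the dendrogram order of the full-cohort
#' clustering — so stratified adjacency maps are directly comparable.
#'
#' @param fm a `stimmod_features` object.
#' @param metadata data.frame with `donor_id` and a grouping column.
#' @param full_order character vector giving the fixed feature order
#'   (defaults to the columns of `fm`).
#' @param group_col name of the grouping column in `metadata`.
#' @param min_group minimum donors per group.
#' @return object of class `stimmod_stratcorr`: named list of
#'   `stimmod_corr` objects (one per group) plus `feature_order`.
#' @export
stratified_correlations <- function(fm, metadata, full_order = NULL,
                                    group_col = "sex", min_group = 3) {
  stopifnot(inherits(fm, "stimmod_features"))
  if (!group_col %in% names(metadata))
    stop("metadata lacks column '", group_col, "'", call. = FALSE)
  if (is.null(full_order)) full_order <- colnames(fm$values)
  groups <- split(metadata$donor_id, metadata[[group_col]])
  small <- names(groups)[lengths(groups) < min_group]
  if (length(small))
    stop("group(s) below the size floor of ", min_group, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  per_group <- lapply(groups, function(ids) {
    sub <- fm$values[rownames(fm$values) %in% ids, full_order, drop = FALSE]
    correlation_matrix(sub)
  })
  structure(c(per_group, list(feature_order = full_order)),
            class = "stimmod_stratcorr")
}

#' Compare stratified correlation distributions globally and per module
#'
#' The global test compares all upper-triangle correlation values between
#' the two groups with the Wilcoxon rank-sum test; per-module tests compare
#' within-module pairs, with `"unassigned"` features forming one extra
#' family member, and Benjamini-Hochberg adjustment across that family.
#' Correlation pairs are treated as exchangeable observations; they are in
#' truth dependent (pairs share donors and features), so the p-values are
#' descriptive summaries of a difference in correlation structure, not
#' calibrated tests — see the package vignette.
#'
#' @param stratified a `stimmod_stratcorr` with exactly two groups.
#' @param assignment a `stimmod_modules` object.
#' @return list with `global` (a `stimmod_test`) and `per_module`
#'   (data.frame: `module`, `n_pairs`, medians per group, `statistic`, `p`,
#'   `adjusted_p`, `direction`).
#' @seealso [bootstrap_correlation_difference()] for a donor-level
#'   resampling alternative whose p-values respect the dependence among
#'   correlation pairs.
#' @export
compare_correlation_distributions <- function(stratified, assignment) {
  stopifnot(inherits(stratified, "stimmod_stratcorr"),
            inherits(assignment, "stimmod_modules"))
  gnames <- setdiff(names(stratified), "feature_order")
  if (length(gnames) != 2L)
    stop("exactly two groups required, found: ", paste(gnames, collapse = ", "),
         call. = FALSE)
  R1 <- stratified[[gnames[1]]]$R
  R2 <- stratified[[gnames[2]]]$R
  ut <- upper.tri(R1)
  global <- wilcoxon_rank_sum(R1[ut][!is.na(R1[ut])], R2[ut][!is.na(R2[ut])])

  fam <- c(assignment$modules,
           list(unassigned = names(assignment$module_of)[
             assignment$module_of == "unassigned"]))
  rows <- lapply(names(fam), function(m) {
    feats <- intersect(fam[[m]], rownames(R1))
    if (length(feats) < 2L)
      return(data.frame(module = m, n_pairs = 0L, median_1 = NA, median_2 = NA,
                        statistic = NA, p = NA, direction = NA,
                        stringsAsFactors = FALSE))
    s1 <- R1[feats, feats][upper.tri(diag(length(feats)))]
    s2 <- R2[feats, feats][upper.tri(diag(length(feats)))]
    s1 <- s1[!is.na(s1)]; s2 <- s2[!is.na(s2)]
    if (!length(s1) || !length(s2))
      return(data.frame(module = m, n_pairs = 0L, median_1 = NA, median_2 = NA,
                        statistic = NA, p = NA, direction = NA,
                        stringsAsFactors = FALSE))
    tt <- wilcoxon_rank_sum(s1, s2)
    data.frame(module = m, n_pairs = length(s1),
               median_1 = tt$medians[1], median_2 = tt$medians[2],
               statistic = tt$statistic, p = tt$p_value,
               direction = ifelse(tt$medians[1] > tt$medians[2],
                                  gnames[1], gnames[2]),
               stringsAsFactors = FALSE)
  })
  per_module <- do.call(rbind, rows)
  names(per_module)[names(per_module) == "median_1"] <- paste0("median_", gnames[1])
  names(per_module)[names(per_module) == "median_2"] <- paste0("median_", gnames[2])
  per_module$adjusted_p <- benjamini_hochberg(per_module$p)
  list(global = global, per_module = per_module, groups = gnames)
}

#' Donor-bootstrap test of group differences in module coordination
#'
#' A resampling alternative to [compare_correlation_distributions()] that
#' respects the dependence structure of correlation estimates. The
#' statistic per module is the difference in mean within-module correlation
#' between the two groups; donors are resampled with replacement *within*
#' each group, the statistic recomputed per replicate, and a two-sided
#' p-value obtained by inverting the percentile interval (twice the
#' fraction of bootstrap statistics on the far side of zero). Since donors
#' — not correlation pairs — are the resampled units, the bootstrap
#' distribution carries the pairs' dependence.
#'
#' @param fm a `stimmod_features` object.
#' @param metadata donor metadata with `donor_id` and the grouping column.
#' @param assignment a `stimmod_modules` object.
#' @param group_col grouping column name.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame: `module`, observed group means, `delta`, `p`,
#'   `adjusted_p` (BH over modules + unassigned), `direction`.
#' @export
bootstrap_correlation_difference <- function(fm, metadata, assignment,
                                             group_col = "sex",
                                             n_boot = 200, seed = 1L) {
  stopifnot(inherits(fm, "stimmod_features"),
            inherits(assignment, "stimmod_modules"))
  groups <- split(metadata$donor_id, metadata[[group_col]])
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  gnames <- names(groups)
  fam <- c(assignment$modules,
           list(unassigned = names(assignment$module_of)[
             assignment$module_of == "unassigned"]))
  fam <- fam[lengths(fam) >= 2L]
  X <- fm$values

  mean_within <- function(rows, feats) {
    suppressWarnings(R <- stats::cor(X[rows, feats, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    mean(R[upper.tri(R)], na.rm = TRUE)
  }
  rows_of <- lapply(groups, function(ids) which(fm$donors %in% ids))
  obs <- vapply(fam, function(feats)
    c(mean_within(rows_of[[1]], feats), mean_within(rows_of[[2]], feats)),
    numeric(2))

  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(fam),
                 dimnames = list(NULL, names(fam)))
  for (b in seq_len(n_boot)) {
    r1 <- sample(rows_of[[1]], replace = TRUE)
    r2 <- sample(rows_of[[2]], replace = TRUE)
    boot[b, ] <- vapply(fam, function(feats)
      mean_within(r1, feats) - mean_within(r2, feats), numeric(1))
  }
  delta <- obs[1, ] - obs[2, ]
  p <- vapply(seq_along(fam), function(j) {
    bb <- boot[, j]
    min(1, 2 * min(mean(bb <= 0), mean(bb >= 0)) + 1 / n_boot)
  }, numeric(1))
  out <- data.frame(module = names(fam), mean_1 = obs[1, ], mean_2 = obs[2, ],
                    delta = delta, p = p,
                    direction = ifelse(delta > 0, gnames[1], gnames[2]),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", gnames[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", gnames[2])
  out$adjusted_p <- benjamini_hochberg(out$p)
  out
}

#' Compare module-score distributions between two donor groups
#'
#' Per-module two-sample Kolmogorov-Smirnov test on the score
#' distributions, Benjamini-Hochberg adjusted across the module family
#' (modules plus the unassigned pseudo-module — 12 tests at the canonical
#' 11-module structure). Direction is reported from group means.
#'
#' @param scores a `stimmod_scores` object.
#' @param metadata data.frame with `donor_id` and a grouping column.
#' @param group_col grouping column name.
#' @param min_group minimum donors per group.
#' @return data.frame: `module`, group means, `D`, `p`, `adjusted_p`,
#'   `direction`.
#' @export
compare_module_scores <- function(scores, metadata, group_col = "sex",
                                  min_group = 5) {
  stopifnot(inherits(scores, "stimmod_scores"))
  groups <- split(metadata$donor_id, metadata[[group_col]])
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(lengths(groups) < min_group))
    stop("each group needs at least ", min_group, " donors", call. = FALSE)
  gnames <- names(groups)
  S <- scores$scores
  rows <- lapply(colnames(S), function(m) {
    s1 <- S[rownames(S) %in% groups[[1]], m]
    s2 <- S[rownames(S) %in% groups[[2]], m]
    s1 <- s1[!is.na(s1)]; s2 <- s2[!is.na(s2)]
    tt <- ks_two_sample(s1, s2)
    data.frame(module = m, mean_1 = mean(s1), mean_2 = mean(s2),
               D = tt$statistic, p = tt$p_value,
               direction = ifelse(mean(s1) > mean(s2), gnames[1], gnames[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", gnames[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", gnames[2])
  out$adjusted_p <- benjamini_hochberg(out$p)
  out
}
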