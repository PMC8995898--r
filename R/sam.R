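#' SAM moderated difference statistic
#'
#' For each feature, `d = (mean(group1) - mean(group2)) / (s + s0)` where
#' `s` is the pooled standard error of the mean difference and `s0` a small
#' positive "fudge" constant that damps features whose tiny variance would
#' otherwise inflate `d`.
#'
#' @param X donors x features numeric matrix (missing values tolerated).
#' @param labels two-level factor/character over donors; the first level is
#'   the minuend of the difference.
#' @param s0 fudge constant (>= 0).
#' @return list with `d`, `s` (per-feature pooled SE), `diff` (mean
#'   difference) — all named by feature.
#' @export
sam_statistic <- function(X, labels, s0 = 0) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels", call. = FALSE)
  g1 <- labels == levels(labels)[1]
  n1 <- colSums(!is.na(X[g1, , drop = FALSE]))
  n2 <- colSums(!is.na(X[!g1, , drop = FALSE]))
  if (any(n1 < 2) || any(n2 < 2))
    stop("each class needs at least 2 non-missing donors per feature", call. = FALSE)
  m1 <- colMeans(X[g1, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(X[!g1, , drop = FALSE], na.rm = TRUE)
  ss1 <- colSums(sweep(X[g1, , drop = FALSE], 2L, m1)^2, na.rm = TRUE)
  ss2 <- colSums(sweep(X[!g1, , drop = FALSE], 2L, m2)^2, na.rm = TRUE)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (s0 == 0 && any(s == 0))
    stop("zero-variance feature with s0 = 0 gives an infinite statistic; use s0 > 0",
         call. = FALSE)
  list(d = (m1 - m2) / (s + s0), s = s, diff = m1 - m2)
}

#' Choose the SAM fudge constant s0
#'
#' Scans s0 candidates over the percentile grid (0, 5, ..., 100%) of the
#' per-feature pooled standard errors and picks the one minimizing the
#' coefficient of variation of the spread of `d` (median absolute
#' deviation) across windows of features grouped by their `s` quantile —
#' i.e. the s0 that makes the scale of `d` as independent of `s` as
#' possible.
#'
#' @inheritParams sam_statistic
#' @param n_windows number of s-quantile windows (reduced automatically for
#'   small feature sets).
#' @return scalar s0.
#' @export
choose_s0 <- function(X, labels, n_windows = 100) {
  base <- sam_statistic(X, labels, s0 = max(stats::median(
    sam_stat_s(X, labels)), .Machine$double.eps))
  s <- base$s
  p <- ncol(as.matrix(X))
  n_windows <- max(2L, min(n_windows, floor(p / 2)))
  if (p < 4 || length(unique(s)) < 2) {
    warning("degenerate standard-error distribution; falling back to median(s)")
    return(stats::median(s))
  }
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows, labels = FALSE)
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  cv <- vapply(cand, function(s0) {
    d <- sam_statistic(X, labels, s0 = s0)$d
    v <- vapply(split(d, win), function(dd) stats::mad(dd), numeric(1))
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cv))) {
    warning("degenerate spread across windows; falling back to median(s)")
    return(stats::median(s))
  }
  cand[which.min(cv)]
}

sam_stat_s <- function(X, labels) sam_statistic(X, labels, s0 = 1)$s

#' SAM permutation analysis with false discovery rate
#'
#' Unpaired two-class Significance Analysis: the moderated statistic `d` is
#' computed on the observed labels and on label permutations; for any
#' threshold `t`, the estimated FDR is the average over permutations of the
#' number of null `|d|` values exceeding `t`, divided by the observed count
#' exceeding `t` (the original SAM convention; `fp_summary = "median"`
#' switches to the median count, which is more robust to outlying
#' permutations but degenerates to an FDR of exactly zero at extreme
#' thresholds in about half of null datasets). Each feature's q-value is
#' the smallest such FDR over thresholds that call it. Permutations are
#' exhaustive when the total number of label assignments is at most
#' `exhaustive_max`, otherwise `n_perm` random permutations are drawn.
#'
#' @inheritParams sam_statistic
#' @param n_perm number of random permutations.
#' @param s0 fudge constant; `NULL` selects it with [choose_s0()].
#' @param fdr FDR level defining the significant sets (default 1%).
#' @param seed integer seed for the permutation draw.
#' @param exhaustive_max enumeration limit on `choose(n, n1)`.
#' @param fp_summary how the per-threshold false-positive count is
#'   summarized across permutations: `"mean"` (default) or `"median"`.
#' @return object of class `sam_fit`: `d`, `s0`, `q_value`,
#'   `significant_up` / `significant_down` (feature names at `fdr`; "up"
#'   means higher in the first label level), `n_perm`, `fdr`.
#' @export
sam_permutation_fdr <- function(X, labels, n_perm = 1000, s0 = NULL,
                                fdr = 0.01, seed = 1L,
                                exhaustive_max = 10000,
                                fp_summary = c("mean", "median")) {
  fp_summary <- match.arg(fp_summary)
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels", call. = FALSE)
  n <- length(labels)
  n1 <- sum(labels == levels(labels)[1])
  if (n1 == 0L || n1 == n) stop("a class is empty", call. = FALSE)
  # drop features so sparsely observed that some label permutation could
  # leave a class with fewer than 2 usable donors
  n_missing <- colSums(is.na(X))
  droppable <- n_missing > min(n1, n - n1) - 2
  if (any(droppable)) {
    message("excluding ", sum(droppable),
            " feature(s) with too many missing donors for permutation analysis")
    X <- X[, !droppable, drop = FALSE]
    if (!ncol(X)) stop("no features with sufficient non-missing donors",
                       call. = FALSE)
  }
  if (is.null(s0)) s0 <- choose_s0(X, labels)
  obs <- sam_statistic(X, labels, s0 = s0)
  d <- obs$d

  set.seed(as.integer(seed))
  total <- choose(n, n1)
  if (total <= exhaustive_max) {
    idx <- utils::combn(n, n1)
    perms <- ncol(idx)
    perm_sets <- lapply(seq_len(perms), function(j) idx[, j])
  } else {
    perms <- n_perm
    perm_sets <- lapply(seq_len(perms), function(j) sample.int(n, n1))
  }
  null_abs <- matrix(NA_real_, nrow = perms, ncol = ncol(X))
  lv <- levels(labels)
  for (j in seq_len(perms)) {
    lab <- rep(lv[2], n)
    lab[perm_sets[[j]]] <- lv[1]
    null_abs[j, ] <- abs(sam_statistic(X, factor(lab, levels = lv), s0 = s0)$d)
  }

  ad <- abs(d)
  ord <- order(ad, decreasing = TRUE)
  thresholds <- ad[ord]
  obs_counts <- seq_along(thresholds)
  # per-threshold count of null |d| values at or above t, per permutation
  summarize <- if (fp_summary == "mean") mean else stats::median
  fp <- vapply(thresholds, function(t)
    summarize(rowSums(null_abs >= t)), numeric(1))
  fdr_at <- pmin(1, fp / obs_counts)
  # q of the k-th ranked feature: min FDR over thresholds at or below its |d|
  q_sorted <- rev(cummin(rev(fdr_at)))
  q <- numeric(length(d))
  q[ord] <- q_sorted
  names(q) <- names(d)

  up <- names(d)[q < fdr & d > 0]
  down <- names(d)[q < fdr & d < 0]
  structure(list(d = d, s0 = s0, q_value = q, significant_up = up,
                 significant_down = down, n_perm = perms, fdr = fdr,
                 exhaustive = total <= exhaustive_max,
                 fp_summary = fp_summary, levels = lv),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM two-class analysis (%s permutations, s0 = %.4g)\n",
              if (x$exhaustive) paste0(x$n_perm, " exhaustive") else x$n_perm,
              x$s0))
  cat(sprintf("  at FDR < %g%%: %d higher in '%s', %d higher in '%s'\n",
              100 * x$fdr, length(x$significant_up), x$levels[1],
              length(x$significant_down), x$levels[2]))
  invisible(x)
}

#' Report significant features grouped by signaling protein
#'
#' Partitions the SAM calls at a chosen FDR into the direction each is
#' higher in, grouped by protein — the level at which differential immune
#' features typically organize.
#'
#' @param result a `sam_fit` object.
#' @param feature_meta the `meta` data.frame of a `stimmod_features` object.
#' @param fdr FDR level (defaults to the one stored in the fit).
#' @return list with data.frames `up` and `down` (`feature`, `protein`,
#'   `cell_type`, `condition`, `d`, `q_value`) and tables `up_by_protein`,
#'   `down_by_protein`.
#' @export
significant_features <- function(result, feature_meta, fdr = NULL) {
  stopifnot(inherits(result, "sam_fit"))
  if (is.null(fdr)) fdr <- result$fdr
  pick <- function(dirn) {
    feats <- names(result$d)[result$q_value < fdr &
                               (if (dirn == "up") result$d > 0 else result$d < 0)]
    meta <- feature_meta[match(feats, feature_meta$feature), , drop = FALSE]
    df <- cbind(meta, d = result$d[feats], q_value = result$q_value[feats])
    rownames(df) <- NULL
    df[order(-abs(df$d)), , drop = FALSE]
  }
  up <- pick("up"); down <- pick("down")
  list(up = up, down = down,
       up_by_protein = sort(table(up$protein), decreasing = TRUE),
       down_by_protein = sort(table(down$protein), decreasing = TRUE))
}

#' Cross-group agreement of feature medians
#'
#' Pearson correlation of per-feature medians computed separately in the
#' two groups — a descriptive check that the two groups' overall response
#' landscapes agree even when individual features differ.
#'
#' @param X donors x features matrix.
#' @param labels two-level grouping.
#' @return scalar Pearson R.
#' @export
median_agreement <- function(X, labels) {
  labels <- as.factor(labels)
  g1 <- labels == levels(labels)[1]
  m1 <- apply(X[g1, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  m2 <- apply(X[!g1, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  stats::cor(m1, m2, use = "complete.obs")
}
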