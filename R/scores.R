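#' Normalize immune features across donors
#'
#' Per-feature z-score across donors (the default), or min-max scaling to
#' \[0, 1\]. Normalization parameters are returned so they can be re-applied
#' to new donors (e.g. scoring test donors with training-set parameters).
#' Zero-variance features cannot be normalized and are excluded with a
#' warning.
#'
#' @param fm a `stimmod_features` object or donors x features matrix.
#' @param method `"zscore"` or `"minmax"`.
#' @param params optional parameter list from a previous call, re-applied
#'   as-is.
#' @return list of class `stimmod_znorm`: `z` (donors x features),
#'   `params` (data.frame `feature`, `center`, `scale`), `method`.
#' @export
normalize_features <- function(fm, method = c("zscore", "minmax"),
                               params = NULL) {
  method <- match.arg(method)
  X <- if (inherits(fm, "stimmod_features")) fm$values else as.matrix(fm)
  if (is.null(params)) {
    if (method == "zscore") {
      center <- colMeans(X, na.rm = TRUE)
      scale <- apply(X, 2L, stats::sd, na.rm = TRUE)
    } else {
      center <- apply(X, 2L, min, na.rm = TRUE)
      scale <- apply(X, 2L, max, na.rm = TRUE) - center
    }
    params <- data.frame(feature = colnames(X), center = center, scale = scale,
                         stringsAsFactors = FALSE, row.names = NULL)
  } else {
    params <- if (inherits(params, "stimmod_znorm")) params$params else params
    idx <- match(colnames(X), params$feature)
    if (anyNA(idx)) stop("params missing some features", call. = FALSE)
    params <- params[idx, ]
    method <- attr(params, "method") %||% method
  }
  bad <- !is.finite(params$scale) | params$scale == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance feature(s) excluded from normalization")
    X <- X[, !bad, drop = FALSE]
    params <- params[!bad, ]
  }
  z <- sweep(sweep(X, 2L, params$center, "-"), 2L, params$scale, "/")
  structure(list(z = z, params = params, method = method),
            class = "stimmod_znorm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-donor module scores
#'
#' The score of donor d in module m is the mean of the normalized values of
#' the module's member features, ignoring missing members; a donor missing
#' every member gets a missing score. Features outside all modules are
#' scored together as the pseudo-module `"unassigned"`.
#'
#' @param zfm a `stimmod_znorm` object from [normalize_features()].
#' @param assignment a `stimmod_modules` object (or a named feature ->
#'   module vector).
#' @return object of class `stimmod_scores`: list with `scores` (donors x
#'   modules matrix; last column `"unassigned"` when present) and `members`.
#' @export
compute_module_scores <- function(zfm, assignment) {
  stopifnot(inherits(zfm, "stimmod_znorm"))
  module_of <- if (inherits(assignment, "stimmod_modules"))
    assignment$module_of else assignment
  declared <- if (inherits(assignment, "stimmod_modules"))
    names(assignment$modules) else setdiff(unique(module_of), "unassigned")
  feats <- intersect(names(module_of), colnames(zfm$z))
  groups <- split(feats, factor(module_of[feats],
                                levels = union(declared, unique(module_of))))
  mods <- setdiff(declared, "unassigned")
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))), mods)]
  if (any(module_of == "unassigned")) mods <- c(mods, "unassigned")
  empty <- mods[lengths(groups[mods]) == 0L]
  if (length(empty))
    stop("module(s) with no surviving member features: ",
         paste(empty, collapse = ", "), call. = FALSE)
  scores <- vapply(mods, function(m)
    rowMeans(zfm$z[, groups[[m]], drop = FALSE], na.rm = TRUE),
    numeric(nrow(zfm$z)))
  scores[is.nan(scores)] <- NA_real_
  dimnames(scores) <- list(rownames(zfm$z), mods)
  structure(list(scores = scores, members = groups[mods]),
            class = "stimmod_scores")
}

#' Correlation between two modules' score vectors
#'
#' Pearson correlation of per-donor scores of two modules, optionally within
#' a donor subset (e.g. one sex). Used to ask whether a donor's strength in
#' one coordinated program predicts their strength in another.
#'
#' @param scores a `stimmod_scores` object.
#' @param module_a,module_b module ids (columns of the score matrix).
#' @param donor_subset optional character vector of donor ids.
#' @return scalar Pearson R (NA with a warning if undefined).
#' @export
correlate_module_scores <- function(scores, module_a, module_b,
                                    donor_subset = NULL) {
  stopifnot(inherits(scores, "stimmod_scores"))
  S <- scores$scores
  miss <- setdiff(c(module_a, module_b), colnames(S))
  if (length(miss)) stop("unknown module(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.null(donor_subset)) S <- S[rownames(S) %in% donor_subset, , drop = FALSE]
  x <- S[, module_a]; y <- S[, module_b]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 donors with both scores", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("undefined correlation: a score vector is constant")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}
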