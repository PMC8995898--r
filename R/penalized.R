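#' Proximal operator of the sparse-group penalty
#'
#' For one coefficient block: elementwise soft-threshold at `l1`, then group
#' soft-threshold — scale by `max(0, 1 - l2 / ||.||_2)`. With `l1 = 0` this
#' is the group-lasso prox; with `l2 = 0` the lasso prox.
#'
#' @param v numeric block.
#' @param l1 elementwise threshold (`t * lambda * alpha`).
#' @param l2 group threshold (`t * lambda * (1 - alpha) * sqrt(p_g)`).
#' @return shrunk block, same length as `v`.
#' @export
prox_sparse_group <- function(v, l1, l2) {
  u <- sign(v) * pmax(abs(v) - l1, 0)
  if (l2 > 0) {
    nrm <- sqrt(sum(u^2))
    if (nrm <= l2) return(rep(0, length(v)))
    u <- u * (1 - l2 / nrm)
  }
  u
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

penalty_value <- function(beta, spec) {
  if (spec$penalty == "ridge") return(spec$lambda * sum(beta^2) / 2)
  l1 <- spec$lambda * spec$alpha * sum(abs(beta))
  l2 <- 0
  if (spec$alpha < 1) {
    gl <- split(beta, spec$groups)
    l2 <- spec$lambda * (1 - spec$alpha) *
      sum(vapply(gl, function(b) sqrt(length(b)) * sqrt(sum(b^2)), numeric(1)))
  }
  l1 + l2
}

apply_prox <- function(beta, t, spec) {
  if (spec$penalty == "ridge") return(beta / (1 + t * spec$lambda))
  if (spec$alpha == 1 || is.null(spec$groups))
    return(soft_threshold(beta, t * spec$lambda * spec$alpha))
  idx <- split(seq_along(beta), spec$groups)
  out <- beta
  for (g in idx) {
    out[g] <- prox_sparse_group(beta[g], t * spec$lambda * spec$alpha,
                                t * spec$lambda * (1 - spec$alpha) * sqrt(length(g)))
  }
  out
}

# mean logistic deviance/2: log(1 + exp(eta)) - y * eta, in stable form
logistic_loss <- function(eta, y) {
  mean(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
}

#' Penalty specification for penalized logistic models
#'
#' @param penalty one of `"ridge"`, `"lasso"`, `"grouplasso"`, `"sgl"`.
#' @param lambda overall penalty strength (>= 0).
#' @param alpha l1 mixing fraction in \[0, 1\] (forced to 1 for lasso, 0 for
#'   ridge/grouplasso).
#' @param groups feature -> group id vector (required for grouped
#'   penalties); unassigned features should be given singleton group ids.
#' @return list of class `stimmod_penalty`.
#' @export
penalty_spec <- function(penalty = c("ridge", "lasso", "grouplasso", "sgl"),
                         lambda = 0.1, alpha = NULL, groups = NULL) {
  penalty <- match.arg(penalty)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  alpha <- switch(penalty,
                  ridge = 0, lasso = 1, grouplasso = 0,
                  sgl = if (is.null(alpha)) 0.95 else alpha)
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (penalty %in% c("grouplasso", "sgl") && is.null(groups))
    stop("'groups' is required for ", penalty, call. = FALSE)
  structure(list(penalty = penalty, lambda = lambda, alpha = alpha,
                 groups = groups),
            class = "stimmod_penalty")
}

#' Fit a penalized logistic classifier by proximal gradient descent
#'
#' Minimizes mean logistic deviance plus the penalty of `spec`:
#' `lambda * (alpha * ||b||_1 + (1 - alpha) * sum_g sqrt(p_g) ||b_g||_2)`
#' for the lasso / group-lasso / sparse-group-lasso family, or
#' `lambda * ||b||_2^2 / 2` for ridge. The intercept is never penalized.
#' Columns are standardized on the training data (means 0, sd 1) and
#' coefficients reported on both scales. Steps use backtracking line
#' search, so the objective decreases monotonically; non-convergence within
#' `max_iter` is flagged on the returned object rather than silently
#' ignored.
#'
#' @param X n x p numeric matrix.
#' @param y binary response (0/1, logical, or two-level factor; the second
#'   level is the positive class).
#' @param spec a [penalty_spec()].
#' @param standardize standardize columns on the training data.
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap.
#' @param init optional warm-start coefficient vector (standardized scale).
#' @return object of class `penlogit`: `intercept`, `beta` (original
#'   scale), `beta_std`, `spec`, `converged`, `n_iter`, `objective`,
#'   `center`/`scale`, `levels`.
#' @export
fit_penalized_logistic <- function(X, y, spec, standardize = TRUE,
                                   tol = 1e-9, max_iter = 5000, init = NULL) {
  stopifnot(inherits(spec, "stimmod_penalty"))
  X <- as.matrix(X)
  yl <- NULL
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    if (nlevels(y) != 2L) stop("y must be binary", call. = FALSE)
    yl <- levels(y)
    y <- as.numeric(y == yl[2])
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
    yl <- c("0", "1")
  }
  n <- nrow(X); p <- ncol(X)
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd) * sqrt((n - 1) / n)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, p); scl <- rep(1, p)
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

  beta <- if (is.null(init)) rep(0, p) else init
  b0 <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  eta <- drop(b0 + Xs %*% beta)
  f <- logistic_loss(eta, y)
  obj <- f + penalty_value(beta, spec)
  t_step <- 1
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- stats::plogis(eta)
    g_beta <- drop(crossprod(Xs, mu - y)) / n
    g_b0 <- mean(mu - y)
    # backtracking on the smooth part
    repeat {
      beta_new <- apply_prox(beta - t_step * g_beta, t_step, spec)
      b0_new <- b0 - t_step * g_b0
      d_beta <- beta_new - beta; d_b0 <- b0_new - b0
      eta_new <- drop(b0_new + Xs %*% beta_new)
      f_new <- logistic_loss(eta_new, y)
      quad <- f + sum(g_beta * d_beta) + g_b0 * d_b0 +
        (sum(d_beta^2) + d_b0^2) / (2 * t_step)
      if (f_new <= quad + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    obj_new <- f_new + penalty_value(beta_new, spec)
    if (obj_new > obj + 1e-10) {
      # should not happen under backtracking; bail out conservatively
      break
    }
    delta <- obj - obj_new
    beta <- beta_new; b0 <- b0_new; eta <- eta_new; f <- f_new; obj <- obj_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    t_step <- min(t_step * 2, 1e4) # allow the step to grow back
  }

  beta_orig <- beta / scl
  intercept <- b0 - sum(beta_orig * center)
  structure(list(intercept = intercept, beta = stats::setNames(beta_orig, colnames(X)),
                 beta_std = stats::setNames(beta, colnames(X)),
                 intercept_std = b0, spec = spec, converged = converged,
                 n_iter = it, objective = obj, center = center, scale = scl,
                 levels = yl, n = n),
            class = "penlogit")
}

#' @export
print.penlogit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("Penalized logistic fit (%s, lambda = %.4g, alpha = %.2g)\n",
              x$spec$penalty, x$spec$lambda, x$spec$alpha))
  cat(sprintf("  %d of %d nonzero coefficients; %sconverged in %d iterations\n",
              nz, length(x$beta), if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' @export
coef.penlogit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.penlogit <- function(object, newdata,
                             type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  eta <- drop(object$intercept + as.matrix(newdata) %*% object$beta)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = object$levels[1 + as.integer(stats::plogis(eta) > 0.5)])
}

#' KKT residual of a penalized logistic fit
#'
#' Sup-norm of the minimal-norm subgradient of the penalized objective at
#' the fitted coefficients (on the standardized scale the solver works on).
#' Zero at an exact optimum; used as the convergence certificate in tests.
#'
#' @param fit a `penlogit` object.
#' @param X,y the training data the fit was computed on.
#' @return scalar residual.
#' @export
kkt_residual <- function(fit, X, y) {
  spec <- fit$spec
  Xs <- sweep(sweep(as.matrix(X), 2L, fit$center), 2L, fit$scale, "/")
  if (is.factor(y) || is.character(y))
    y <- as.numeric(as.factor(y)) - 1
  n <- nrow(Xs)
  mu <- stats::plogis(drop(fit$intercept_std + Xs %*% fit$beta_std))
  g <- drop(crossprod(Xs, mu - y)) / n
  b <- fit$beta_std
  lam <- spec$lambda; al <- spec$alpha
  res <- abs(mean(mu - y)) # intercept stationarity
  if (spec$penalty == "ridge") return(max(res, max(abs(g + lam * b))))
  groups <- spec$groups %||% seq_along(b)
  for (gset in split(seq_along(b), groups)) {
    w <- if (al < 1) sqrt(length(gset)) else 0
    gg <- g[gset]; bb <- b[gset]
    if (any(bb != 0)) {
      grp <- lam * (1 - al) * w * bb / sqrt(sum(bb^2))
      nz <- bb != 0
      # nonzero coords: full stationarity; zero coords: |g_i| <= lam*alpha
      res <- max(res,
                 max(abs(gg[nz] + lam * al * sign(bb[nz]) + grp[nz])),
                 if (any(!nz)) max(pmax(abs(gg[!nz]) - lam * al, 0)) else 0)
    } else {
      # zero block: ||soft(g, lam*alpha)||_2 must not exceed the group threshold
      shr <- pmax(abs(gg) - lam * al, 0)
      res <- max(res, max(0, sqrt(sum(shr^2)) - lam * (1 - al) * w))
    }
  }
  res
}

#' Random train/test split of donors
#'
#' Seed-reproducible random split (50 training / the rest test at the
#' canonical 86-donor design). If the training set misses a class the split
#' is redrawn with a warning.
#'
#' @param metadata data.frame with `donor_id` and the class column.
#' @param n_train training-set size.
#' @param seed integer seed.
#' @param class_col class column name.
#' @param stratify draw the split stratified by class.
#' @return list with `train` and `test` donor-id vectors.
#' @export
split_train_test <- function(metadata, n_train = 50, seed = 1L,
                             class_col = "sex", stratify = FALSE) {
  n <- nrow(metadata)
  if (n_train >= n) stop("'n_train' must be smaller than the cohort", call. = FALSE)
  set.seed(as.integer(seed))
  draw <- function() {
    if (stratify) {
      idx <- unlist(lapply(split(seq_len(n), metadata[[class_col]]), function(i)
        sample(i, round(length(i) * n_train / n))))
      if (length(idx) != n_train)
        idx <- c(idx, sample(setdiff(seq_len(n), idx), n_train - length(idx)))
      idx
    } else sample.int(n, n_train)
  }
  idx <- draw()
  tries <- 0L
  while (length(unique(metadata[[class_col]][idx])) < 2L && tries < 100L) {
    warning("training set lacked a class; redrawing the split")
    idx <- draw(); tries <- tries + 1L
  }
  list(train = metadata$donor_id[idx], test = metadata$donor_id[-idx])
}

lambda_max_for <- function(X, y, spec) {
  n <- nrow(X)
  r <- y - mean(y)
  g <- abs(drop(crossprod(X, r))) / n
  groups <- spec$groups %||% seq_len(ncol(X))
  idx <- split(seq_len(ncol(X)), groups)
  gmax <- max(vapply(idx, function(i) sqrt(sum(g[i]^2)) / sqrt(length(i)),
                     numeric(1)))
  switch(spec$penalty,
         ridge = max(g),
         lasso = max(g),
         grouplasso = gmax,
         sgl = max(max(g) / max(spec$alpha, 0.01),
                   gmax / max(1 - spec$alpha, 0.01)))
}

#' Cross-validated tuning of the penalty strength
#'
#' k-fold cross-validation, repeated over independent fold assignments,
#' scoring each (lambda, alpha) grid point by mean held-out binomial
#' deviance. Ties are broken toward the larger lambda (the sparser /
#' more-regularized model). The lambda grid defaults to 50 points
#' log-spaced over four decades down from the smallest lambda that zeroes
#' every coefficient. Folds that end up missing a class are redrawn with a
#' warning. Fits along the lambda path are warm-started.
#'
#' @param X,y as in [fit_penalized_logistic()].
#' @param penalty penalty family.
#' @param groups feature -> group vector for grouped penalties.
#' @param alpha_grid alpha values to scan (scalar for most families).
#' @param lambda_grid optional explicit lambda grid.
#' @param n_lambda,lambda_decades automatic grid size and span.
#' @param k folds; `repeats` independent fold assignments.
#' @param seed integer seed.
#' @param tol,max_iter solver settings for the per-fold fits.
#' @return list of class `stimmod_cv`: `best_lambda`, `best_alpha`,
#'   `cv_table` (grid with mean deviance), `fit` (final fit on all data at
#'   the selected point).
#' @export
cross_validate_lambda <- function(X, y, penalty = "ridge", groups = NULL,
                                  alpha_grid = NULL, lambda_grid = NULL,
                                  n_lambda = 50, lambda_decades = 4,
                                  k = 10, repeats = 3, seed = 1L,
                                  tol = 1e-8, max_iter = 2000) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y); ybin <- as.numeric(y == levels(y)[2])
  } else ybin <- as.numeric(y)
  n <- nrow(X)
  if (k > n) stop("'k' cannot exceed the number of donors", call. = FALSE)
  if (is.null(alpha_grid))
    alpha_grid <- switch(penalty, ridge = 0, lasso = 1, grouplasso = 0,
                         sgl = 0.95)
  set.seed(as.integer(seed))
  spec0 <- penalty_spec(penalty, lambda = 1, alpha = alpha_grid[1],
                        groups = groups)
  if (is.null(lambda_grid)) {
    Xsc <- scale(X)
    Xsc[!is.finite(Xsc)] <- 0 # constant columns carry no signal
    lmax <- lambda_max_for(Xsc, ybin, spec0) * 1.05
    lambda_grid <- exp(seq(log(lmax), log(lmax) - lambda_decades * log(10),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid)
  dev_sum <- rep(0, nrow(grid)); dev_n <- rep(0, nrow(grid))

  for (rep_i in seq_len(repeats)) {
    folds <- sample(rep(seq_len(k), length.out = n))
    tries <- 0L
    while (any(vapply(seq_len(k), function(f)
      length(unique(ybin[folds != f])) < 2L, logical(1))) && tries < 50L) {
      warning("a fold's training data lacked a class; redrawing folds")
      folds <- sample(rep(seq_len(k), length.out = n)); tries <- tries + 1L
    }
    for (f in seq_len(k)) {
      tr <- folds != f
      for (a in alpha_grid) {
        warm <- NULL
        for (li in seq_along(lambda_grid)) {
          spec <- penalty_spec(penalty, lambda = lambda_grid[li], alpha = a,
                               groups = groups)
          fit <- fit_penalized_logistic(X[tr, , drop = FALSE], ybin[tr], spec,
                                        tol = tol, max_iter = max_iter,
                                        init = warm)
          warm <- fit$beta_std
          pr <- predict(fit, X[!tr, , drop = FALSE], type = "response")
          pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
          dev <- -2 * mean(ybin[!tr] * log(pr) + (1 - ybin[!tr]) * log(1 - pr))
          gi <- which(grid$lambda == lambda_grid[li] & grid$alpha == a)
          dev_sum[gi] <- dev_sum[gi] + dev
          dev_n[gi] <- dev_n[gi] + 1
        }
      }
    }
  }
  grid$mean_deviance <- dev_sum / dev_n
  best_dev <- min(grid$mean_deviance)
  cand <- grid[grid$mean_deviance <= best_dev + 1e-12, ]
  best <- cand[which.max(cand$lambda), ] # tie -> larger lambda

  final_spec <- penalty_spec(penalty, lambda = best$lambda, alpha = best$alpha,
                             groups = groups)
  fit <- fit_penalized_logistic(X, if (is.factor(y)) y else ybin, final_spec,
                                tol = tol, max_iter = max_iter * 2)
  structure(list(best_lambda = best$lambda, best_alpha = best$alpha,
                 cv_table = grid, fit = fit, k = k, repeats = repeats),
            class = "stimmod_cv")
}

#' Evaluate a classifier on held-out donors
#'
#' Accuracy at probability threshold 0.5, the full ROC curve over all score
#' thresholds, and AUC computed by the rank (Mann-Whitney) statistic, which
#' equals trapezoidal integration of the ROC with midrank tie handling.
#'
#' @param fit a `penlogit` fit (or any object with a `predict` method
#'   returning probabilities) — alternatively pass `scores` directly.
#' @param X_test,y_test held-out data.
#' @param scores optional pre-computed scores overriding `fit`.
#' @return list: `accuracy`, `auc`, `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`), `n_test`.
#' @export
evaluate_model <- function(fit = NULL, X_test = NULL, y_test, scores = NULL) {
  if (is.null(scores)) scores <- predict(fit, X_test, type = "response")
  if (is.factor(y_test) || is.character(y_test)) {
    y_test <- as.factor(y_test)
    ybin <- as.numeric(y_test == levels(y_test)[2])
  } else ybin <- as.numeric(y_test)
  acc <- mean((scores > 0.5) == (ybin == 1))
  n1 <- sum(ybin == 1); n0 <- sum(ybin == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class test set: AUC undefined")
    auc <- NA_real_
  } else {
    r <- rank(scores)
    auc <- (sum(r[ybin == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(threshold = th,
                    fpr = vapply(th, function(t) mean(scores[ybin == 0] >= t),
                                 numeric(1)),
                    tpr = vapply(th, function(t) mean(scores[ybin == 1] >= t),
                                 numeric(1)))
  list(accuracy = acc, auc = auc, roc = roc, n_test = length(ybin))
}

#' Lasso classifier on module scores
#'
#' Trains a lasso logistic model of donor class on the module-score matrix
#' (scores computed with training-donor normalization parameters, applied
#' unchanged to test donors) and evaluates on the held-out donors.
#'
#' @param fm a `stimmod_features` object (post-threshold).
#' @param assignment a `stimmod_modules` object.
#' @param metadata donor metadata with `donor_id` and the class column.
#' @param split a [split_train_test()] result (or `NULL` to draw one).
#' @param seed seed used for the split (when drawn here) and CV folds.
#' @param class_col class column name.
#' @param ... passed to [cross_validate_lambda()].
#' @return list: `fit`, `cv`, `evaluation`, `selected_modules`, `split`.
#' @export
fit_module_score_model <- function(fm, assignment, metadata, split = NULL,
                                   seed = 1L, class_col = "sex", ...) {
  if (is.null(split)) split <- split_train_test(metadata, seed = seed,
                                                class_col = class_col)
  tr_fm <- subset_features(fm, split$train)
  te_fm <- subset_features(fm, split$test)
  z_tr <- normalize_features(tr_fm)
  z_te <- normalize_features(te_fm, params = z_tr)
  s_tr <- compute_module_scores(z_tr, assignment)
  s_te <- compute_module_scores(z_te, assignment)
  y_tr <- metadata[[class_col]][match(rownames(s_tr$scores), metadata$donor_id)]
  y_te <- metadata[[class_col]][match(rownames(s_te$scores), metadata$donor_id)]
  cv <- cross_validate_lambda(s_tr$scores, factor(y_tr), penalty = "lasso",
                              seed = seed, ...)
  ev <- evaluate_model(cv$fit, s_te$scores, factor(y_te))
  list(fit = cv$fit, cv = cv, evaluation = ev,
       selected_modules = names(cv$fit$beta)[cv$fit$beta != 0],
       split = split)
}

subset_features <- function(fm, donor_ids) {
  keep <- fm$donors %in% donor_ids
  structure(list(values = fm$values[keep, , drop = FALSE], meta = fm$meta,
                 donors = fm$donors[keep]),
            class = "stimmod_features")
}
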