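logit_data <- function(n = 60, p = 6, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  if (is.null(beta)) beta <- c(1.5, -1, rep(0, p - 2))
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(X = X, y = y)
}

test_that("prox operators satisfy their closed-form identities", {
  v <- c(3, -0.2, 0.5)
  # lambda = 0 -> identity
  expect_equal(prox_sparse_group(v, 0, 0), v)
  # pure soft-threshold
  expect_equal(prox_sparse_group(v, 0.5, 0), c(2.5, 0, 0))
  # block with post-soft-threshold norm below the group threshold -> zero
  expect_equal(prox_sparse_group(c(0.3, -0.2), 0.1, 1), c(0, 0))
})

test_that("prox output satisfies the subgradient optimality condition", {
  # prox_h(v) minimizes 0.5||u - v||^2 + l1 ||u||_1 + l2 ||u||_2:
  # check 0 in u - v + l1 sgn(u) + l2 d||u||
  set.seed(20)
  for (i in 1:20) {
    v <- rnorm(5, 0, 2)
    l1 <- runif(1, 0, 1.5); l2 <- runif(1, 0, 2)
    u <- prox_sparse_group(v, l1, l2)
    if (any(u != 0)) {
      g <- u - v + l1 * sign(u) + l2 * u / sqrt(sum(u^2))
      nz <- u != 0
      expect_lt(max(abs(g[nz])), 1e-8)
      if (any(!nz)) expect_true(all(abs(v[!nz]) <= l1 + 1e-8))
    } else {
      expect_lte(sqrt(sum(pmax(abs(v) - l1, 0)^2)), l2 + 1e-8)
    }
  }
})

test_that("huge lambda zeroes all coefficients, intercept = training log-odds", {
  d <- logit_data()
  for (pen in c("ridge", "lasso", "grouplasso", "sgl")) {
    spec <- penalty_spec(pen, lambda = 1e4,
                         groups = rep(c("a", "b"), each = 3))
    fit <- fit_penalized_logistic(d$X, d$y, spec)
    # ridge only shrinks toward zero (|beta*| ~ |grad|/lambda); the sparse
    # penalties zero out exactly through their prox
    expect_true(all(abs(fit$beta) < if (pen == "ridge") 1e-4 else 1e-10),
                info = pen)
    expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-3)
  }
})

test_that("lambda = 0 matches the unpenalized Newton (glm) oracle", {
  d <- logit_data(n = 40, p = 5)
  fit <- fit_penalized_logistic(d$X, d$y, penalty_spec("lasso", lambda = 0),
                                tol = 1e-12, max_iter = 20000)
  oracle <- glm(d$y ~ d$X, family = binomial())
  expect_lt(max(abs(coef(fit)[-1] - coef(oracle)[-1])), 1e-4)
  expect_lt(abs(coef(fit)[1] - coef(oracle)[1]), 1e-4)
})

test_that("KKT residuals are small at convergence for all four penalties", {
  d <- logit_data(n = 50, p = 8, seed = 3)
  groups <- rep(c("g1", "g2"), each = 4)
  for (pen in c("ridge", "lasso", "grouplasso", "sgl")) {
    spec <- penalty_spec(pen, lambda = 0.05, groups = groups)
    fit <- fit_penalized_logistic(d$X, d$y, spec, tol = 1e-12,
                                  max_iter = 50000)
    expect_true(fit$converged, info = pen)
    expect_lt(kkt_residual(fit, d$X, d$y), 1e-4)
  }
})

test_that("lasso equals sparse group lasso with singleton groups and alpha 1", {
  d <- logit_data(n = 55, p = 7, seed = 5)
  f1 <- fit_penalized_logistic(d$X, d$y, penalty_spec("lasso", lambda = 0.03),
                               tol = 1e-13, max_iter = 50000)
  f2 <- fit_penalized_logistic(
    d$X, d$y, penalty_spec("sgl", lambda = 0.03, alpha = 1,
                           groups = paste0("s", 1:7)),
    tol = 1e-13, max_iter = 50000)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
})

test_that("ridge shrinkage agrees with the glmnet reference", {
  skip_if_not_installed("glmnet")
  d <- logit_data(n = 80, p = 6, seed = 8)
  lam <- 0.2
  fit <- fit_penalized_logistic(d$X, d$y, penalty_spec("ridge", lambda = lam),
                                tol = 1e-13, max_iter = 50000)
  ref <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                        lambda = lam, standardize = TRUE, thresh = 1e-14)
  expect_lt(max(abs(fit$beta - as.numeric(ref$beta))), 5e-3)
})

test_that("group penalties produce group-respecting zero patterns", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("x", 1:9)))
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  y <- rbinom(n, 1, plogis(X[, 4:6] %*% c(1.5, 1.2, -1.5))) # only g2 informative
  fit <- fit_penalized_logistic(X, y, penalty_spec("grouplasso", lambda = 0.08,
                                                   groups = groups),
                                tol = 1e-12, max_iter = 50000)
  by_group <- split(fit$beta != 0, groups)
  # within each group all-zero or all-nonzero
  expect_true(all(vapply(by_group, function(b) all(b) || !any(b), logical(1))))
  expect_true(all(fit$beta[4:6] != 0))
})

test_that("objective decreases monotonically along the iterations", {
  # indirectly: a warm-started refit cannot end at a higher objective
  d <- logit_data(n = 50, p = 6, seed = 9)
  spec <- penalty_spec("sgl", lambda = 0.05, alpha = 0.5,
                       groups = rep(c("a", "b"), each = 3))
  f_cold <- fit_penalized_logistic(d$X, d$y, spec, max_iter = 10)
  f_warm <- fit_penalized_logistic(d$X, d$y, spec, init = f_cold$beta_std,
                                   max_iter = 5000, tol = 1e-12)
  expect_lte(f_warm$objective, f_cold$objective + 1e-12)
})

test_that("train/test splits are disjoint, exhaustive and reproducible", {
  md <- data.frame(donor_id = sprintf("d%02d", 1:86),
                   sex = rep(c("female", "male"), 43))
  s1 <- split_train_test(md, n_train = 50, seed = 4)
  expect_length(s1$train, 50)
  expect_length(s1$test, 36)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), md$donor_id)
  expect_identical(s1, split_train_test(md, n_train = 50, seed = 4))
  expect_error(split_train_test(md, n_train = 86), "smaller")
  # degenerate class balance: the split is redrawn until both classes train
  md2 <- data.frame(donor_id = sprintf("d%02d", 1:10),
                    sex = c(rep("female", 9), "male"))
  for (s in 1:10) {
    s2 <- suppressWarnings(split_train_test(md2, n_train = 8, seed = s))
    expect_length(unique(md2$sex[md2$donor_id %in% s2$train]), 2)
  }
})

test_that("model evaluation: accuracy, ROC and AUC behave as rank statistics", {
  y <- c(0, 0, 0, 1, 1, 1)
  ev <- evaluate_model(scores = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), y_test = y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  ev_rev <- evaluate_model(scores = 1 - c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                           y_test = y)
  expect_equal(ev_rev$auc, 0) # reversal flips AUC
  expect_warning(ev1 <- evaluate_model(scores = runif(4),
                                       y_test = rep(1, 4)), "single-class")
  expect_true(is.na(ev1$auc))
  # ROC endpoints
  expect_equal(ev$roc$fpr[1], 0); expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
})

test_that("AUC agrees with the pROC reference including ties", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    s <- round(runif(40), 1)
    if (length(unique(y)) < 2) next
    ours <- evaluate_model(scores = s, y_test = y)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("cross-validation is reproducible, honours ties toward larger lambda", {
  d <- logit_data(n = 40, p = 5, seed = 11)
  cv1 <- cross_validate_lambda(d$X, d$y, "lasso", k = 5, repeats = 1,
                               n_lambda = 8, seed = 2)
  cv2 <- cross_validate_lambda(d$X, d$y, "lasso", k = 5, repeats = 1,
                               n_lambda = 8, seed = 2)
  expect_identical(cv1$best_lambda, cv2$best_lambda)
  expect_identical(cv1$cv_table$mean_deviance, cv2$cv_table$mean_deviance)
  # grid of one point returns trivially
  cv3 <- cross_validate_lambda(d$X, d$y, "ridge", lambda_grid = 0.5, k = 4,
                               repeats = 1, seed = 1)
  expect_equal(cv3$best_lambda, 0.5)
  # an explicit tie on the deviance column resolves to the larger lambda
  tied <- cv1$cv_table
  tied$mean_deviance <- 1
  best_dev <- min(tied$mean_deviance)
  cand <- tied[tied$mean_deviance <= best_dev + 1e-12, ]
  expect_equal(cand[which.max(cand$lambda), "lambda"], max(tied$lambda))
})

test_that("module-score lasso selects planted modules and reduces sensibly", {
  fx <- scaled_features(2, mean_shift_by_sex = list(
    male = c(pSTAT1 = 1), female = c(pERK12 = 1)))
  det <- detect_modules(fx$responsive)
  md <- fx$cohort$metadata
  res <- fit_module_score_model(fx$responsive, det$modules, md, seed = 2,
                                k = 5, repeats = 1, n_lambda = 12)
  expect_gt(res$evaluation$auc, 0.6)
  summ <- module_summary(det$modules, fx$responsive$meta)
  planted <- summ$module[grepl("pSTAT1|pERK12", summ$proteins)]
  expect_gt(length(intersect(res$selected_modules, planted)), 0)
})
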