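test_that("wilcoxon exact enumeration matches hand-counted splits", {
  # x = (1,2), y = (3,4): U = 0; of the C(4,2) = 6 splits, |U - 2| >= 2 for
  # U in {0, 4} -> two-sided p = 2/6
  t1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(t1$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(t1$statistic, 0)
  # identical samples -> p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # all tied -> p = 1 with warning
  expect_warning(t2 <- wilcoxon_rank_sum(rep(2, 3), rep(2, 4)), "tied")
  expect_equal(t2$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("wilcoxon exact path agrees with the reference implementation", {
  set.seed(4)
  for (i in 1:10) {
    x <- runif(6, 0, 30); y <- runif(8, 0, 30) # continuous: both paths exact
    ours <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon large-sample path agrees with the tie-corrected normal approximation", {
  set.seed(9)
  x <- round(rnorm(40), 1); y <- round(rnorm(45, 0.4), 1) # ties likely
  ours <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # strong planted shift -> tiny p
  expect_lt(wilcoxon_rank_sum(rnorm(60), rnorm(60, 3))$p_value, 1e-6)
})

test_that("wilcoxon is invariant to swapping the two groups", {
  set.seed(2)
  x <- rnorm(15); y <- rnorm(12, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(y, x)$p_value, tolerance = 1e-12)
})

test_that("KS statistic matches hand ECDF computation", {
  t1 <- ks_two_sample(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  expect_equal(t1$statistic, 0.25, tolerance = 1e-12)
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(1:4, 11:14)$statistic, 1) # disjoint supports
})

test_that("KS asymptotic p agrees with the reference implementation", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(35); y <- rnorm(42, 0.3)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("Benjamini-Hochberg matches the step-up formula and the reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(25)^2
  expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"),
               tolerance = 1e-12)
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA passthrough
  out <- benjamini_hochberg(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
})

test_that("stratified correlations share the fixed feature order and group floor", {
  fx <- tiny_features(1)
  md <- fx$cohort$metadata
  ord <- rev(colnames(fx$responsive$values))
  st <- stratified_correlations(fx$responsive, md, full_order = ord)
  expect_equal(rownames(st$female$R), ord)
  expect_equal(rownames(st$male$R), ord)
  md_bad <- md; md_bad$sex[md_bad$sex == "male"][-1] <- "female"
  expect_error(stratified_correlations(fx$responsive, md_bad), "size floor")
  # identical donor sets in both groups -> identical matrices
  md_same <- rbind(transform(md, sex = "g1"), transform(md, sex = "g2"))
  st2 <- stratified_correlations(fx$responsive, md_same)
  expect_equal(st2$g1$R, st2$g2$R)
})

test_that("a perfect one-sided coordination block is detected in the right direction", {
  set.seed(31)
  n <- 30
  z <- rnorm(n)
  # females: near-perfect block; males: independent noise
  Xf <- sapply(1:6, function(i) z + rnorm(n, 0, 0.05))
  Xm <- matrix(rnorm(n * 6), n)
  colnames(Xf) <- colnames(Xm) <- paste0("f", 1:6)
  X <- rbind(Xf, Xm)
  fm <- as_features(X)
  md <- data.frame(donor_id = fm$donors,
                   sex = rep(c("female", "male"), each = n))
  asg <- structure(list(module_of = setNames(rep("M1", 6), colnames(X)),
                        modules = list(M1 = colnames(X))),
                   class = "stimmod_modules")
  st <- stratified_correlations(fm, md)
  res <- compare_correlation_distributions(st, asg)
  row <- res$per_module[res$per_module$module == "M1", ]
  expect_lt(row$p, 0.05)
  expect_equal(row$direction, "female")
  expect_gt(row$median_female, row$median_male)
})

test_that("sex-asymmetric loadings raise female within-module correlation", {
  fx <- scaled_features(3, loading_by_sex = c(female = 1.5, male = 0.5))
  det <- detect_modules(fx$responsive)
  md <- fx$cohort$metadata
  st <- stratified_correlations(fx$responsive, md,
                                full_order = det$hclust$labels[det$hclust$order])
  res <- compare_correlation_distributions(st, det$modules)
  pm <- res$per_module[res$per_module$module != "unassigned", ]
  expect_true(all(pm$direction == "female"))
  expect_lt(res$global$p_value, 1e-6)
})

test_that("module-score comparisons find planted mean shifts with direction", {
  fx <- scaled_features(2, mean_shift_by_sex = list(
    male = c(pSTAT1 = 1), female = c(pERK12 = 1)))
  det <- detect_modules(fx$responsive)
  z <- normalize_features(fx$responsive)
  sc <- compute_module_scores(z, det$modules)
  md <- fx$cohort$metadata
  res <- compare_module_scores(sc, md)
  summ <- module_summary(det$modules, fx$responsive$meta)
  m_stat1 <- summ$module[grep("pSTAT1", summ$proteins)]
  m_erk <- summ$module[grep("pERK12", summ$proteins)]
  hit <- res[res$adjusted_p < 0.05, ]
  expect_true(m_stat1 %in% hit$module)
  expect_true(m_erk %in% hit$module)
  expect_equal(hit$direction[hit$module == m_stat1], "male")
  expect_equal(hit$direction[hit$module == m_erk], "female")
  # constant scores in both groups -> D = 0, p = 1
  sc0 <- sc; sc0$scores[] <- 0
  res0 <- compare_module_scores(sc0, md)
  expect_true(all(res0$D == 0))
  expect_true(all(res0$p == 1))
})

test_that("donor bootstrap agrees in direction and stays quiet under the null", {
  fx <- scaled_features(3, loading_by_sex = c(female = 1.5, male = 0.5))
  det <- detect_modules(fx$responsive)
  bs <- bootstrap_correlation_difference(fx$responsive, fx$cohort$metadata,
                                         det$modules, n_boot = 100, seed = 1)
  pm <- bs[bs$module != "unassigned", ]
  expect_true(all(pm$direction == "female"))
  expect_gt(sum(pm$adjusted_p < 0.05), length(pm$module) / 2)
  # null cohort: mostly quiet
  fx0 <- scaled_features(4)
  det0 <- detect_modules(fx0$responsive)
  bs0 <- bootstrap_correlation_difference(fx0$responsive, fx0$cohort$metadata,
                                          det0$modules, n_boot = 100, seed = 1)
  expect_lte(sum(bs0$adjusted_p < 0.05, na.rm = TRUE), 1)
})
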