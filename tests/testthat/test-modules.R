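test_that("correlation matrix matches direct Pearson computation", {
  X <- cbind(x = c(1, 2, 3), y = c(6, 4, 5))
  cm <- correlation_matrix(X, min_pairs = 3)
  expect_equal(cm$R["x", "y"], -0.5, tolerance = 1e-12)
  expect_equal(diag(cm$R), c(x = 1, y = 1))
  # duplicated and negated columns
  X2 <- cbind(a = rnorm(10), b = 0)
  X2[, "b"] <- X2[, "a"]
  X2 <- cbind(X2, c = -X2[, "a"])
  cm2 <- correlation_matrix(X2)
  expect_equal(cm2$R["a", "b"], 1)
  expect_equal(cm2$R["a", "c"], -1)
  expect_true(isSymmetric(cm2$R))
})

test_that("zero-variance and under-supported pairs are set missing", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  expect_warning(cm <- correlation_matrix(X), "zero-variance")
  expect_true(all(is.na(cm$R["b", ])))
  X2 <- cbind(a = c(1, 2, NA, NA, 3), b = c(2, 1, 5, 6, NA))
  cm2 <- correlation_matrix(X2, min_pairs = 3)
  expect_true(is.na(cm2$R["a", "b"])) # only 2 complete pairs
  expect_equal(cm2$n_pairs["a", "b"], 2)
})

test_that("clustering separates planted blocks at the top split", {
  X <- block_matrix(sizes = c(5, 6))
  cm <- correlation_matrix(X)
  hc <- cluster_features(cm)
  top2 <- cutree(hc, k = 2)
  expect_equal(length(unique(top2[grep("^B1_", names(top2))])), 1L)
  expect_equal(length(unique(top2[grep("^B2_", names(top2))])), 1L)
})

test_that("clustering is invariant to feature input order", {
  X <- block_matrix(sizes = c(4, 5), seed = 7)
  cm1 <- correlation_matrix(X)
  perm <- sample(ncol(X))
  cm2 <- correlation_matrix(X[, perm])
  hc1 <- cluster_features(cm1); hc2 <- cluster_features(cm2)
  # same topology: identical cophenetic distances between any two features
  d1 <- as.matrix(cophenetic(hc1)); d2 <- as.matrix(cophenetic(hc2))
  expect_equal(d1[colnames(X), colnames(X)], d2[colnames(X), colnames(X)],
               tolerance = 1e-12)
})

test_that("adjacency binning is strict at the cutoff with a +1 diagonal", {
  R <- matrix(c(1, 0.7, -0.6, 0.3,
                0.7, 1, 0.5, -0.5,
                -0.6, 0.5, 1, 0,
                0.3, -0.5, 0, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  cm <- structure(list(R = R, n_pairs = matrix(99, 4, 4), features = letters[1:4]),
                  class = "stimmod_corr")
  A <- bin_adjacency(cm, cutoff = 0.5)$A
  expect_equal(A["a", "b"], 1L)   # 0.7
  expect_equal(A["a", "c"], -1L)  # -0.6
  expect_equal(A["a", "d"], 0L)   # 0.3
  expect_equal(A["b", "c"], 0L)   # exactly 0.5 -> strict
  expect_equal(A["b", "d"], 0L)   # exactly -0.5 -> strict
  expect_equal(unname(diag(A)), rep(1L, 4))
  expect_error(bin_adjacency(cm, cutoff = 1.5), "cutoff")
  # sign consistency with R wherever nonzero
  nz <- A != 0
  expect_true(all(sign(A[nz]) == sign(R[nz])))
})

test_that("module extraction recovers planted blocks exactly", {
  X <- block_matrix(sizes = c(5, 6), noise = 0.2)
  det <- detect_modules(as_features(X))
  mods <- det$modules
  expect_length(mods$modules, 2L)
  got <- lapply(mods$modules, sort)
  want <- list(sort(grep("^B1_", colnames(X), value = TRUE)),
               sort(grep("^B2_", colnames(X), value = TRUE)))
  expect_true(setequal(got, want))
  expect_error(extract_modules(det$hclust, det$adjacency, min_size = 1),
               "min_size")
})

test_that("independent features yield no modules in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    det <- detect_modules(as_features(X))
    length(det$modules$modules)
  }, numeric(1))
  expect_gte(sum(hits == 0), 19)
})

test_that("module extraction is invariant to feature order", {
  fx <- scaled_features(1)
  det1 <- detect_modules(fx$responsive)
  perm_fm <- fx$responsive
  set.seed(3)
  perm <- sample(ncol(perm_fm$values))
  perm_fm$values <- perm_fm$values[, perm]
  perm_fm$meta <- perm_fm$meta[perm, ]
  det2 <- detect_modules(perm_fm)
  # same partition up to module relabeling
  feats <- colnames(fx$responsive$values)
  expect_equal(adjusted_rand_index(det1$modules$module_of[feats],
                                   det2$modules$module_of[feats]), 1)
})

test_that("module summary flags the dominant attribute by concentration", {
  meta <- data.frame(
    feature = paste0("f", 1:6),
    protein = rep("pSTAT1", 6),
    cell_type = c("A", "B", "C", "D", "A", "B"),
    condition = c("s1", "s1", "s2", "s2", "s3", "s3"),
    stringsAsFactors = FALSE)
  asg <- structure(list(module_of = setNames(rep("M1", 6), meta$feature),
                        modules = list(M1 = meta$feature)),
                   class = "stimmod_modules")
  summ <- module_summary(asg, meta)
  expect_equal(summ$dominant_attribute, "protein")
  expect_equal(summ$n_features, 6L)
  # one feature per attribute value in every attribute -> tie -> none
  meta2 <- data.frame(feature = paste0("g", 1:3),
                      protein = c("p1", "p2", "p3"),
                      cell_type = c("A", "B", "C"),
                      condition = c("s1", "s2", "s3"),
                      stringsAsFactors = FALSE)
  asg2 <- structure(list(module_of = setNames(rep("M1", 3), meta2$feature),
                         modules = list(M1 = meta2$feature)),
                    class = "stimmod_modules")
  expect_equal(module_summary(asg2, meta2)$dominant_attribute, "none")
})

test_that("recovered modules on simulated cohorts are protein-dominated", {
  fx <- scaled_features(1)
  det <- detect_modules(fx$responsive)
  summ <- module_summary(det$modules, fx$responsive$meta)
  expect_true(all(summ$dominant_attribute == "protein"))
})

test_that("within-module correlation summaries match hand computation", {
  R <- matrix(0.2, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- 1
  cm <- structure(list(R = R, features = paste0("f", 1:4)),
                  class = "stimmod_corr")
  dimnames(cm$R) <- list(cm$features, cm$features)
  asg <- structure(list(module_of = setNames(c("M1", "M1", "unassigned",
                                               "unassigned"), cm$features),
                        modules = list(M1 = c("f1", "f2"))),
                   class = "stimmod_modules")
  w <- within_module_correlation(cm, asg)
  expect_equal(unname(w$per_module["M1"]), 1)
  expect_equal(w$overall_mean, mean(R[upper.tri(R)]))
  # planted cohorts: coherence far above background
  fx <- scaled_features(1)
  det <- detect_modules(fx$responsive)
  w2 <- within_module_correlation(det$corr, det$modules)
  expect_gt(w2$within_mean, w2$overall_mean)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:5) {
    a <- sample(letters[1:4], 30, replace = TRUE)
    b <- sample(letters[1:3], 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
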