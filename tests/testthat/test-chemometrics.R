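test_that("autoscaling centres, scales, and inverts exactly", {
  set.seed(1)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 12, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  xs <- autoscale(x)
  expect_true(all(abs(colMeans(xs)) < 1e-10))
  expect_equal(unname(apply(xs, 2, sd)), rep(1, 5))
  expect_equal(unscale(xs), x, ignore_attr = TRUE)
  # already-scaled input is unchanged up to tolerance
  expect_equal(unclass(autoscale(unclass(xs))), unclass(xs),
               ignore_attr = TRUE, tolerance = 1e-10)
  x[, 3] <- 7
  expect_error(autoscale(x), "constant column.*v3")
})

test_that("PCA explains a rank-1 matrix with one component and reconstructs", {
  set.seed(2)
  r1 <- outer(rnorm(10), rnorm(4)) # rank 1
  p <- pca_fit(r1, n_components = 1, cv_folds = 0, scale = FALSE)
  expect_equal(p$r2x[1], 1.0, tolerance = 1e-10)
  x <- matrix(rnorm(80), 16, 5)
  p2 <- pca_fit(x, n_components = 5, cv_folds = 0, scale = TRUE)
  expect_equal(crossprod(p2$loadings), diag(5), ignore_attr = TRUE,
               tolerance = 1e-10) # orthonormal loadings
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(recon, unclass(autoscale(x)), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(p2$r2x_cum) >= 0))
  expect_error(pca_fit(x, n_components = 20), "exceeds")
})

test_that("control and model separate along the first principal component", {
  co <- generate_cohort(control_model_specs(), seed = 5)
  x <- as.matrix(co[, cohort_index_names()])
  p <- pca_fit(x, n_components = 2, cv_folds = 7)
  t1 <- p$scores[, 1]
  ctrl <- t1[co$group == "control"]; modl <- t1[co$group == "model"]
  # silhouette > 0 along component 1: groups are linearly separated
  expect_true(max(ctrl) < min(modl) || max(modl) < min(ctrl))
  expect_gt(p$q2, 0)
})

test_that("PLS-DA scores are orthogonal and R2Y non-decreasing", {
  co <- generate_cohort(qsbss_reference_groups(n = 8), seed = 9)
  x <- as.matrix(co[, cohort_index_names()])
  m <- plsda(x, co$group, n_components = 3, cv_folds = 7)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_true(all(diff(m$r2y_cum) >= -1e-12))
  expect_lte(m$r2y_cum[3], 1 + 1e-12)
  expect_lte(m$q2, m$r2y_cum[3])
})

test_that("PLS-DA degenerates correctly: no signal vs noiseless limit", {
  set.seed(4)
  x <- matrix(rnorm(200), 20, 10)
  g <- rep(c("a", "b"), each = 10)
  m0 <- plsda(x, g, n_components = 2, cv_folds = 7)
  expect_lte(m0$q2, 0.2) # noise labels: no real predictive ability
  # class-determined X: R2Y -> 1 (unscaled so the noise floor stays tiny)
  xs <- cbind(ifelse(g == "a", 1, -1) + rnorm(20, sd = 1e-3),
              matrix(rnorm(100, sd = 1e-3), 20, 5))
  m1 <- plsda(xs, g, n_components = 2, cv_folds = 0, scale = FALSE)
  expect_gt(m1$r2y_cum[2], 0.999)
  expect_error(plsda(x[1:3, ], c("a", "a", "b")), "at least 2 members")
})

test_that("a planted 3-SD shift on half the variables gives strong Q2", {
  wins <- 0L
  for (s in 1:40) {
    set.seed(s)
    x <- matrix(rnorm(16 * 10), 16, 10)
    x[9:16, 1:5] <- x[9:16, 1:5] + 3
    g <- rep(c("a", "b"), each = 8)
    m <- plsda(x, g, n_components = 2, cv_folds = 7)
    if (m$q2 > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 38) # >= 95% of replicates
})

test_that("VIP satisfies its normalization and flags planted signal", {
  co <- generate_cohort(control_model_specs(), seed = 13)
  x <- as.matrix(co[, cohort_index_names()])
  m <- plsda(x, co$group, n_components = 2, cv_folds = 0)
  v <- vip(m)
  expect_equal(sum(v^2), ncol(x), tolerance = 1e-8)
  # symmetric informativeness -> all VIP equal 1
  xsym <- cbind(c(rep(0, 8), rep(1, 8)), c(rep(0, 8), rep(1, 8)))
  xsym <- xsym + matrix(rnorm(32, sd = 1e-6), 16, 2)
  vsym <- vip(plsda(xsym, rep(c("a", "b"), each = 8), 1, cv_folds = 0))
  expect_equal(unname(vsym), c(1, 1), tolerance = 1e-3)
  # one informative variable among noise dominates with VIP > 1
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    xn <- matrix(rnorm(16 * 8), 16, 8,
                 dimnames = list(NULL, paste0("v", 1:8)))
    xn[9:16, 1] <- xn[9:16, 1] + 4
    vv <- vip(plsda(xn, rep(c("a", "b"), each = 8), 2, cv_folds = 0))
    if (names(which.max(vv)) == "v1" && vv["v1"] > 1) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("VIP agrees with the independent mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  co <- generate_cohort(control_model_specs(), seed = 11)
  x <- as.matrix(co[, cohort_index_names()])
  m <- plsda(x, co$group, n_components = 2, cv_folds = 0)
  mo <- mixOmics::plsda(x, co$group, ncomp = 2, scale = TRUE)
  expect_equal(unname(vip(m)), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-8)
  expect_equal(abs(cor(m$scores[, 1], mo$variates$X[, 1])), 1,
               tolerance = 1e-8)
})

test_that("permutation validation is seeded and separates signal from noise", {
  co <- generate_cohort(control_model_specs(), seed = 21)
  x <- as.matrix(co[, cohort_index_names()])
  m <- plsda(x, co$group, n_components = 2, cv_folds = 7)
  pv1 <- permutation_validate(x, co$group, m, n_perm = 30, seed = 42)
  pv2 <- permutation_validate(x, co$group, m, n_perm = 30, seed = 42)
  expect_identical(pv1, pv2)
  expect_true(pv1$valid)
  expect_lt(pv1$q2_intercept, 0)
  # pure noise: the real model is no better than its permutations
  set.seed(8)
  xn <- matrix(rnorm(16 * 10), 16, 10)
  gn <- rep(c("a", "b"), each = 8)
  mn <- plsda(xn, gn, n_components = 2, cv_folds = 7)
  pvn <- permutation_validate(xn, gn, mn, n_perm = 50, seed = 1)
  expect_false(pvn$valid)
})

test_that("group centroid distances rank treatments by proximity to normal", {
  scores <- rbind(c(1.69, -0.4), c(1.69, -0.4),
                  c(-4.36, -0.61), c(-4.36, -0.61),
                  c(1.69, -0.4), c(1.69, -0.4))
  g <- c("control", "control", "model", "model", "tx", "tx")
  r <- group_distance_ranking(scores, g, "control")
  expect_equal(r$group, c("tx", "model"))
  expect_equal(r$distance[1], 0)
  expect_equal(r$distance[2], sqrt((1.69 + 4.36)^2 + (-0.4 + 0.61)^2),
               tolerance = 1e-12) # ~6.054
  # three planted offsets rank by magnitude
  sc <- rbind(matrix(0, 2, 2), matrix(1, 2, 2), matrix(3, 2, 2), matrix(2, 2, 2))
  gg <- rep(c("ref", "g1", "g3", "g2"), each = 2)
  expect_equal(group_distance_ranking(sc, gg, "ref")$group, c("g1", "g2", "g3"))
  expect_error(group_distance_ranking(scores, g, "missing"), "absent")
})

test_that("summary ANOVA: equal means give F = 0; two groups give F = t^2", {
  m <- matrix(5, 3, 2); s <- matrix(1, 3, 2); ns <- c(6, 7, 8)
  res <- summary_anova(m, s, ns, control = NULL, model_group = NULL)
  expect_equal(res$anova$F, c(0, 0))
  expect_equal(res$anova$p, c(1, 1))
  # two-group identity, equal n and sd so pooled and Welch coincide
  m2 <- matrix(c(5, 7), 2, 1); s2 <- matrix(c(1.2, 1.2), 2, 1)
  rownames(m2) <- rownames(s2) <- c("control", "model")
  r2 <- summary_anova(m2, s2, c(8, 8))
  tstat <- r2$pairwise$t[1]
  expect_equal(r2$anova$F, tstat^2, tolerance = 1e-10)
})

test_that("summary ANOVA agrees with aov on raw cohorts (round trip)", {
  co <- generate_cohort(qsbss_reference_groups(n = 7), seed = 17)
  x <- co$WBV1
  by_g <- split(x, co$group)
  means <- matrix(vapply(by_g, mean, numeric(1)), ncol = 1,
                  dimnames = list(names(by_g), "WBV1"))
  sds <- matrix(vapply(by_g, sd, numeric(1)), ncol = 1,
                dimnames = list(names(by_g), "WBV1"))
  res <- summary_anova(means, sds, lengths(by_g),
                       control = NULL, model_group = NULL)
  ref <- summary(stats::aov(x ~ co$group))[[1]]
  expect_equal(res$anova$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$anova$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("printed-table FIB contrast is significant at the 1% level", {
  gs <- qsbss_reference_groups(n = 8, groups = c("control", "model"))
  means <- rbind(control = gs$control$means, model = gs$model$means)
  sds <- rbind(control = gs$control$sds, model = gs$model$sds)
  colnames(means) <- colnames(sds) <- cohort_index_names()
  res <- summary_anova(means, sds, c(8, 8))
  fib <- res$pairwise[res$pairwise$index == "FIB" &
                      res$pairwise$reference == "control", ]
  expect_true(fib$sig01)
})
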