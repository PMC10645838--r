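# small labelled gaussian dataset with a mean shift on the first block of
# variables; shift = 0 gives pure noise
make_classes <- function(n_per = 6, p = 8, shift = 4, sd = 1, seed = 1) {
  set.seed(seed)
  mu <- c(rep(shift, 4), rep(0, p - 4))
  x <- rbind(
    matrix(stats::rnorm(n_per * p, 0, sd), n_per, p),
    matrix(stats::rnorm(n_per * p, 0, sd), n_per, p) +
      matrix(mu, n_per, p, byrow = TRUE)
  )
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

test_that("Pareto scaling divides centered columns by the root of their sd", {
  x <- cbind(a = c(0, 4, 8, 4), b = c(1, 2, 3, 4))
  sc <- pareto_scale(x)
  expect_equal(sc[, "a"], (x[, "a"] - 4) / sqrt(stats::sd(x[, "a"])),
               ignore_attr = TRUE)
  # the scaled column's variance equals the raw column's sd
  set.seed(3)
  m <- matrix(stats::rnorm(60, sd = rep(c(1, 4, 9), each = 20)), 20, 3)
  scm <- pareto_scale(m)
  expect_equal(apply(scm, 2, stats::var), apply(m, 2, stats::sd),
               ignore_attr = TRUE)
  expect_warning(sc2 <- pareto_scale(cbind(k = rep(5, 4), b = 1:4)),
                 "zero-variance")
  expect_equal(colnames(sc2), "b")
  expect_error(pareto_scale(matrix(1, 4, 2)), "zero variance")
})

test_that("PCA explains variance like a direct eigen-decomposition", {
  set.seed(5)
  # rank-1 matrix: one component carries everything
  u <- stats::rnorm(10)
  v <- stats::rnorm(4)
  r1 <- fit_pca(outer(u, v), n_components = 1)
  expect_equal(r1$r2x, 1.0)
  # random matrix: component shares match the eigenvalues of the
  # (uncentered) covariance, computed independently
  x <- matrix(stats::rnorm(80), 16, 5)
  pc <- fit_pca(x, n_components = 5)
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)$values
  expect_equal(pc$r2x, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(pc$r2x_cum) >= 0))
  # orthonormal loadings; duplicated samples share scores
  expect_equal(crossprod(pc$loadings), diag(5), ignore_attr = TRUE)
  xd <- rbind(x, x[1, ])
  pcd <- fit_pca(xd, 2)
  expect_equal(pcd$scores[1, ], pcd$scores[nrow(xd), ])
  expect_error(fit_pca(outer(u, v), n_components = 2), "rank")
})

test_that("OPLS-DA separates planted two-cluster data and is label-symmetric", {
  d <- make_classes(shift = 4, seed = 7)
  xs <- pareto_scale(d$x)
  m <- fit_oplsda(xs, d$labels, seed = 1)
  expect_gt(m$q2, 0.9)
  expect_lte(m$q2, m$r2y + 1e-8)
  # swapping the class names flips the score sign, |Q2| unchanged
  swapped <- ifelse(d$labels == "a", "b", "a")
  m2 <- fit_oplsda(xs, swapped, seed = 1)
  expect_equal(m2$t, -m$t, tolerance = 1e-8)
  expect_equal(abs(m2$q2), abs(m$q2), tolerance = 1e-8)
  expect_error(fit_oplsda(xs, rep("a", nrow(xs))), "two classes")
})

test_that("orthogonal filtering never weakens the training-set correlation", {
  for (seed in 1:5) {
    d <- make_classes(shift = 1.5, sd = 2, seed = seed)
    xs <- pareto_scale(d$x)
    y <- ifelse(d$labels == "b", 1, -1)
    m <- fit_oplsda(xs, d$labels, n_orth = 1)
    w_pls <- drop(crossprod(xs, y - mean(y)))
    t_pls <- drop(xs %*% (w_pls / sqrt(sum(w_pls^2))))
    expect_gte(abs(stats::cor(m$t, y)), abs(stats::cor(t_pls, y)) - 1e-8)
  }
})

test_that("labels independent of the data give no predictive ability", {
  q2s <- vapply(1:10, function(seed) {
    d <- make_classes(shift = 0, seed = 100 + seed)
    fit_oplsda(pareto_scale(d$x), d$labels, seed = 1)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("permutation p-values are seeded, reproducible and calibrated", {
  d <- make_classes(shift = 4, seed = 7)
  xs <- pareto_scale(d$x)
  m <- fit_oplsda(xs, d$labels, seed = 1)
  p1 <- permutation_test(m, xs, d$labels, n_perm = 100, seed = 5)
  p2 <- permutation_test(m, xs, d$labels, n_perm = 100, seed = 5)
  expect_identical(p1, p2)  # bit-exact under a fixed seed
  expect_lte(p1$perm_p, 0.02)
  expect_gte(p1$perm_p, 1 / 101)  # smallest attainable at 100 permutations
  # identical data in both classes: no signal to lose, p near 1
  xnull <- rbind(xs[1:6, ], xs[1:6, ])
  mnull <- fit_oplsda(xnull, d$labels, seed = 1)
  pnull <- permutation_test(mnull, xnull, d$labels, n_perm = 50, seed = 5)
  expect_gte(pnull$perm_p, 0.5)
  expect_error(permutation_test(m, xs, d$labels, n_perm = 0), "n_perm")
})

test_that("CV-ANOVA tracks signal strength alongside the permutation test", {
  strong <- make_classes(shift = 4, seed = 21)
  weak <- make_classes(shift = 0.3, seed = 21)
  ms <- fit_oplsda(pareto_scale(strong$x), strong$labels, seed = 1)
  mw <- fit_oplsda(pareto_scale(weak$x), weak$labels, seed = 1)
  ps <- cv_anova(ms)
  pw <- cv_anova(mw)
  expect_lt(ps, 0.001)
  expect_lt(ps, pw)
  # same ordering as the permutation test
  perm_s <- permutation_test(ms, pareto_scale(strong$x), strong$labels,
                             n_perm = 50, seed = 2)$perm_p
  perm_w <- permutation_test(mw, pareto_scale(weak$x), weak$labels,
                             n_perm = 50, seed = 2)$perm_p
  expect_lte(perm_s, perm_w)
})

test_that("S-plot band selection honours its thresholds", {
  d <- make_classes(shift = 4, seed = 7)
  xs <- pareto_scale(d$x)
  m <- fit_oplsda(xs, d$labels, seed = 1)
  all_bands <- select_discriminant_bands(m, cov_thresh = 0, corr_thresh = 0)
  expect_equal(sort(all_bands$variable), sort(colnames(xs)))
  none <- select_discriminant_bands(m, cov_thresh = Inf, corr_thresh = 0)
  expect_equal(nrow(none), 0)
  hits <- select_discriminant_bands(m, cov_thresh = 0, corr_thresh = 0.9)
  expect_true(all(hits$variable %in% paste0("V", 1:4)))
  expect_true(all(hits$enriched_in == "b"))
})

test_that("Rf calibration maps the anchors exactly and is monotone", {
  expect_equal(rf_to_dp(0.57)[[1]], 1L)
  expect_equal(rf_to_dp(0.51)[[1]], 2L)
  expect_equal(rf_to_dp(0.40)[[1]], 3L)
  expect_equal(rf_to_dp(0.09)[[1]], 11L)
  grid <- seq(0.095, 0.95, by = 0.005)
  dps <- as.integer(rf_to_dp(grid))
  expect_true(all(diff(dps) <= 0))  # larger Rf never means larger DP
  low <- rf_to_dp(0.05)
  expect_true(is.na(low[[1]]))
  expect_equal(attr(low, "label"), ">11 (application point)")
  expect_error(rf_to_dp(0), "within")
  expect_error(rf_to_dp(1.2), "within")
})
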