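test_that("glucose normalization divides by the summed glucose percentage", {
  r <- normalize_to_glucose(c(t_fruf = 30, b21_fruf = 37, b26_fruf = 5,
                              di_fruf = 10, t_glcp = 9, i_glcp = 9))
  expect_equal(unname(round(r[c("t_fruf", "b21_fruf", "b26_fruf",
                                "di_fruf")], 2)),
               c(1.67, 2.06, 0.28, 0.56))
  expect_equal(r[["glcp"]], 1.0)
  # scale invariance
  r2 <- normalize_to_glucose(c(t_fruf = 60, b21_fruf = 74, b26_fruf = 10,
                               di_fruf = 20, t_glcp = 18, i_glcp = 18))
  expect_equal(unclass(r), unclass(r2), ignore_attr = TRUE)
  expect_error(normalize_to_glucose(c(t_fruf = 100)), "F-series")
})

test_that("core DP is the one-decimal sum of the five ratios", {
  expect_equal(core_dp(c(t_fruf = 1.8, b21_fruf = 2.2, b26_fruf = 0.3,
                         di_fruf = 0.6, glcp = 1.0)), 5.9)
  expect_equal(core_dp(c(t_fruf = 2.3, b21_fruf = 2.8, b26_fruf = 0.3,
                         di_fruf = 0.8, glcp = 1.0)), 7.2)
  expect_equal(core_dp(c(t_fruf = 0, b21_fruf = 0, b26_fruf = 0,
                         di_fruf = 0, glcp = 1.0)), 1.0)
})

test_that("molecule assignment applies the zero / below-one / half-up rule", {
  a <- assign_molecules(c(t_fruf = 1.8, b21_fruf = 2.2, b26_fruf = 0.3,
                          di_fruf = 0.6, glcp = 1.0))
  expect_equal(as.vector(a), c(2L, 2L, 1L, 1L, 1L))
  expect_equal(attr(a, "total_dp"), 7)
  b <- assign_molecules(c(t_fruf = 2.3, b21_fruf = 2.8, b26_fruf = 0.3,
                          di_fruf = 0.8, glcp = 1.0))
  expect_equal(as.vector(b), c(2L, 3L, 1L, 1L, 1L))
  expect_equal(attr(b, "total_dp"), 8)
  z <- assign_molecules(c(t_fruf = 0, b21_fruf = 0, b26_fruf = 0,
                          di_fruf = 0, glcp = 1.0))
  expect_equal(attr(z, "total_dp"), 1)
  # half-up, not banker's rounding
  expect_equal(as.vector(assign_molecules(c(x = 2.5))), 3L)
  expect_error(assign_molecules(c(x = -0.1)), "negative")
})

test_that("molecule assignment is non-decreasing in each ratio", {
  set.seed(11)
  for (i in 1:200) {
    v <- stats::runif(1, 0, 5)
    w <- v + stats::runif(1, 0, 5)
    expect_lte(assign_molecules(c(x = v))[["x"]],
               assign_molecules(c(x = w))[["x"]])
  }
})

test_that("summaries report both standard-deviation conventions", {
  tab <- amica_bulb_ratios()
  assigned <- tab
  for (i in seq_len(nrow(tab))) {
    assigned[i, -1] <- as.list(assign_molecules(unlist(tab[i, -1])))
  }
  s <- summarize_linkage(tab, assigned)
  cd <- s$ratios[s$ratios$class == "core_dp", ]
  expect_equal(round_half_up(cd$mean, 1), 6.1)
  expect_equal(round(cd$sd_sample, 2), 0.53)     # n-1 convention
  dpr <- s$assigned[s$assigned$class == "dp", ]
  expect_equal(round_half_up(dpr$mean, 1), 7.2)
  expect_equal(round(dpr$sd_population, 2), 0.37)  # n convention
  # a constant class has zero spread under both conventions
  glc <- s$ratios[s$ratios$class == "glcp", ]
  expect_equal(glc$sd_sample, 0)
  expect_equal(glc$sd_population, 0)
  expect_error(summarize_linkage(tab[1, ], assigned[1, ]), "two samples")
})

test_that("count scaling multiplies non-glucose classes and re-rounds", {
  counts <- c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1, di_fruf = 1, glcp = 1)
  got <- scale_counts(counts, hpaec_dp = 20, mean_dp = 7.2)
  expect_equal(round(got$scale_factor, 2), 2.78)
  expect_equal(unname(got$counts), c(6L, 6L, 3L, 3L, 1L))
  same <- scale_counts(counts, hpaec_dp = 7, mean_dp = 7)
  expect_equal(same$scale_factor, 1)
  expect_equal(same$counts, stats::setNames(as.integer(counts), names(counts)))
  expect_warning(scale_counts(counts, hpaec_dp = 5, mean_dp = 7), "clamped")
})

test_that("branching frequency is the 2->1 to branch-point ratio", {
  expect_equal(round_half_up(branching_frequency(
    c(b21_fruf = 2.2, di_fruf = 0.6)), 1), 3.7)
  expect_equal(branching_frequency(c(b21_fruf = 0.4, di_fruf = 0.4)), 1.0)
  expect_identical(branching_frequency(c(b21_fruf = 2, di_fruf = 0)), Inf)
})

test_that("neo fraction is the internal share of glucose", {
  expect_equal(neo_fraction(c(t_glcp = 4, i_glcp = 4, t_fruf = 92)), 0.5)
  expect_equal(neo_fraction(c(t_glcp = 5, i_glcp = 0, t_fruf = 95)), 0.0)
  expect_equal(neo_fraction(c(t_glcp = 2, i_glcp = 6, t_fruf = 92)), 0.75)
  expect_error(neo_fraction(c(t_fruf = 100)), "glucose")
})

test_that("proposed structures pair a graminan core with its agavin counterpart", {
  props <- propose_structures(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
                                di_fruf = 1), hpaec_dp = 20)
  expect_equal(dp(props$graminan_core), 7)
  expect_equal(classify_topology(props$graminan_core), "graminan")
  # internal glucose carries one extra terminal fructose on its C6
  expect_equal(dp(props$agavin_core), 8)
  expect_equal(classify_topology(props$agavin_core), "agavin")
  expect_equal(dp(props$graminan_extended), 20)
  expect_equal(dp(props$agavin_extended), 20)
  for (s in props[c("graminan_core", "agavin_core",
                    "graminan_extended", "agavin_extended")]) {
    expect_equal(sum(census(s)), dp(s))
  }
  expect_equal(nrow(props$report), 4)
})

test_that("the full inference pipeline reproduces the worked example", {
  inf <- infer_linkage_table(amica_bulb_ratios(), hpaec_dp = 20)
  expect_equal(round_half_up(inf$mean_core_dp, 1), 6.1)
  expect_equal(round_half_up(inf$mean_assigned_dp, 1), 7.2)
  expect_equal(round(inf$scale_factor, 2), 2.78)
  expect_equal(round_half_up(inf$branching_frequency, 1), 3.7)
  expect_equal(unname(inf$scaled_counts), c(6L, 6L, 3L, 3L, 1L))
})
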