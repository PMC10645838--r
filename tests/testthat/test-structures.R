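test_that("census assigns each residue its linkage class from substitutions", {
  expect_equal(census(h_sucrose()),
               as_census(c(t_fruf = 1, t_glcp = 1)),
               ignore_attr = TRUE)
  expect_equal(census(h_nystose()),
               as_census(c(t_glcp = 1, b21_fruf = 2, t_fruf = 1)),
               ignore_attr = TRUE)
  cen7 <- census(h_dp7_graminan())
  expect_equal(cen7,
               as_census(c(t_glcp = 1, b21_fruf = 2, b26_fruf = 1,
                           di_fruf = 1, t_fruf = 2)),
               ignore_attr = TRUE)
  expect_equal(sum(cen7), dp(h_dp7_graminan()))
})

test_that("dp counts residues", {
  expect_equal(dp(h_sucrose()), 2)
  kestose <- h_structure(c(G = "glucose", Fs = "fructose", Fa = "fructose"),
                         list(c("G", "Fs", "C2"), c("Fa", "Fs", "C1")))
  expect_equal(dp(kestose), 3)
  expect_equal(dp(h_dp7_graminan()), 7)
})

test_that("malformed structures are rejected with the offending residue named", {
  # two glucoses
  expect_error(
    h_structure(c(G = "glucose", G2 = "glucose", F1 = "fructose"),
                list(c("G", "F1", "C2"), c("F1", "G2", "C6"))),
    "at most one glucose")
  # fructose cannot land on a glucose C1
  expect_error(
    h_structure(c(G = "glucose", F1 = "fructose"),
                list(c("F1", "G", "C1"))),
    "C6")
  # double donation through one anomeric carbon
  expect_error(
    h_structure(c(G = "glucose", F1 = "fructose", F2 = "fructose",
                  F3 = "fructose"),
                list(c("G", "F1", "C2"), c("F1", "F2", "C1"),
                     c("F1", "F3", "C6"))),
    "donates")
  # position occupied twice
  expect_error(
    h_structure(c(Fa = "fructose", Fb = "fructose", Fc = "fructose"),
                list(c("Fb", "Fa", "C1"), c("Fc", "Fa", "C1"))),
    "occupied")
  # disconnected forest
  expect_error(
    h_structure(c(Fa = "fructose", Fb = "fructose",
                  Fc = "fructose", Fd = "fructose"),
                list(c("Fb", "Fa", "C1"))),
    "tree|connected")
})

test_that("topology classification follows the glucose position and branching", {
  inulin <- h_nystose()
  expect_equal(classify_topology(inulin), "inulin")
  levan <- h_structure(c(G = "glucose", Fs = "fructose", Fa = "fructose",
                         Fb = "fructose"),
                       list(c("G", "Fs", "C2"), c("Fa", "Fs", "C6"),
                            c("Fb", "Fa", "C6")))
  expect_equal(classify_topology(levan), "levan")
  expect_equal(classify_topology(h_dp7_graminan()), "graminan")
  neo <- h_structure(c(G = "glucose", Fs = "fructose", Fn = "fructose"),
                     list(c("G", "Fs", "C2"), c("Fn", "G", "C6")))
  expect_equal(classify_topology(neo), "inulin-neo-series")
  fser <- h_structure(c(Fa = "fructose", Fb = "fructose"),
                      list(c("Fb", "Fa", "C1")))
  expect_equal(classify_topology(fser), "F-series")
})

test_that("assemble_core reproduces the target census for both glucose modes", {
  expect_equal(census(assemble_core(c(t_fruf = 1, t_glcp = 1))),
               as_census(c(t_fruf = 1, t_glcp = 1)), ignore_attr = TRUE)
  gram <- assemble_core(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
                          di_fruf = 1, t_glcp = 1))
  expect_equal(census(gram), census(h_dp7_graminan()))
  expect_equal(classify_topology(gram), "graminan")
  agav_counts <- c(t_fruf = 3, b21_fruf = 3, b26_fruf = 1, di_fruf = 1,
                   i_glcp = 1)
  agav <- assemble_core(agav_counts)
  expect_equal(census(agav), as_census(agav_counts), ignore_attr = TRUE)
  expect_equal(classify_topology(agav), "agavin")
})

test_that("assemble_core round-trips random realizable censuses (both modes)", {
  set.seed(41)
  for (i in 1:60) {
    internal <- i %% 2 == 0
    cn <- random_census(internal)
    built <- assemble_core(cn)
    expect_equal(unname(census(built)), unname(as_census(cn)))
    expect_equal(nrow(built$edges), nrow(built$residues) - 1L)
    if (cn[["di_fruf"]] > 0 && internal) {
      expect_equal(classify_topology(built), "agavin")
    }
  }
})

test_that("unrealizable censuses raise infeasibility errors naming the condition", {
  # levan residues with no branch residue to carry them
  expect_error(assemble_core(c(t_fruf = 1, b26_fruf = 2, t_glcp = 1)),
               "no 1,6-di branch")
  # extra terminals beyond the open arms
  expect_error(assemble_core(c(t_fruf = 3, b21_fruf = 2, di_fruf = 1,
                               b26_fruf = 1, t_glcp = 1)),
               "terminal fructose")
  # an internal glucose consumes one extra acceptor position: the same
  # fructose counts that build a DP-7 graminan cannot build a DP-7 agavin
  expect_error(assemble_core(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
                               di_fruf = 1, i_glcp = 1)),
               "terminal fructose")
  expect_error(assemble_core(c(t_fruf = 2, b21_fruf = 3, b26_fruf = 1,
                               di_fruf = 1, i_glcp = 1)),
               "terminal fructose")
})

test_that("backbone extension inserts 2->1 units and conserves everything else", {
  core <- assemble_core(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
                          di_fruf = 1, t_glcp = 1))
  ext <- extend_to_target_dp(core, 20, mode = "backbone")
  expect_equal(dp(ext), 20)
  cen <- census(ext)
  expect_equal(cen[["b21_fruf"]], 15)
  expect_equal(cen[["t_fruf"]], 2)
  expect_equal(cen[["di_fruf"]], 1)
  expect_equal(classify_topology(ext), "graminan")
  # identity at the current DP
  expect_identical(extend_to_target_dp(core, dp(core)), core)
  expect_error(extend_to_target_dp(core, 5), "smaller")
})

test_that("proportional extension scales counts, rounds, and stays realizable", {
  core <- assemble_core(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
                          di_fruf = 1, t_glcp = 1))
  ext <- extend_to_target_dp(core, 20, mode = "proportional")
  # factor 20/7 on (2, 2, 1, 1) rounds half-up to (6, 6, 3, 3); DP 1+18 = 19,
  # with terminals reconciled to the branch count (4 = 3 + 1) and the excess
  # carried as backbone units
  cen <- census(ext)
  expect_equal(dp(ext), 19)
  expect_equal(cen[["di_fruf"]], 3)
  expect_equal(cen[["b26_fruf"]], 3)
  expect_equal(cen[["t_fruf"]], 4)
  expect_equal(cen[["b21_fruf"]], 8)
  expect_equal(cen[["t_glcp"]], 1)
  expect_silent(validate_fructan(ext))
})

test_that("structures serialize to fructan-1 JSON and back", {
  s <- h_dp7_graminan()
  js <- structure_to_json(s)
  s2 <- structure_from_json(js)
  expect_equal(census(s2), census(s))
  expect_equal(dp(s2), dp(s))
  expect_equal(s2$root, s$root)
  tmp <- withr::local_tempfile(fileext = ".json")
  structure_to_json(s, tmp)
  expect_equal(census(structure_from_json(tmp)), census(s))
  expect_error(structure_from_json('{"schema": "other"}'), "fructan-1")
})
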