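means <- param_means(default_parameters())

test_that("hazard ratios modify annual probabilities through the rate scale", {
  expect_identical(apply_hazard_ratio(0.0294, 1), 0.0294)
  expect_equal(apply_hazard_ratio(0.0294, 0.65), 0.01920964465621933,
               tolerance = 1e-12)
  expect_identical(apply_hazard_ratio(0, 0.65), 0)
  expect_identical(apply_hazard_ratio(0.0294, 0.65, "multiply"), 0.0294 * 0.65)
  expect_error(apply_hazard_ratio(1, 0.65), "certain event")
  expect_error(apply_hazard_ratio(0.5, -1), "positive")
})

test_that("transition matrices carry the published first-cycle structure", {
  M <- build_transition_matrix(means, "chemo", cycle = 1)
  expect_equal(M["DFS", ],
    c(DFS = 1 - 0.0053 - 0.0294 - 0.0785 - 0.0020, CHF = 0.0053,
      REC_Y1 = 0.0294, REC_LATER = 0, MET_Y1 = 0.0785, MET_LATER = 0,
      DEATH = 0.0020))
  Mt <- build_transition_matrix(means, "trastuzumab", cycle = 1)
  expect_equal(Mt["DFS", "CHF"], 0.0053 * 3.97)   # = 0.021041
  expect_equal(Mt["DFS", "REC_Y1"], 1 - (1 - 0.0294)^0.65)
  # CHF residual returns to DFS
  expect_equal(M["CHF", "DFS"], 1 - 0.0294 - 0.0785 - 0.15)
  # no CHF entry after the treatment year
  expect_identical(build_transition_matrix(means, "chemo", cycle = 2)["DFS", "CHF"], 0)
  # death absorbing
  expect_identical(M["DEATH", ], c(DFS = 0, CHF = 0, REC_Y1 = 0, REC_LATER = 0,
                                   MET_Y1 = 0, MET_LATER = 0, DEATH = 1))
})

test_that("efficacy expiry makes the arms' DFS rows coincide", {
  M12t <- build_transition_matrix(means, "trastuzumab", cycle = 12,
                                  efficacy_years = 11)
  M12c <- build_transition_matrix(means, "chemo", cycle = 12)
  expect_identical(M12t, M12c)
  M11t <- build_transition_matrix(means, "trastuzumab", cycle = 11)
  expect_false(identical(M11t["DFS", ], M12c["DFS", ]))
})

test_that("matrices are row-stochastic for random valid parameter tables", {
  for (seed in 1:25) {
    v <- param_means(random_parameter_table(seed))
    for (arm in c("trastuzumab", "chemo")) for (cyc in c(1, 2, 12)) {
      M <- build_transition_matrix(v, arm, cyc)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
    }
  }
})

test_that("infeasible exit probabilities raise an error naming the state", {
  v <- means
  v["tp_dfs_met"] <- 0.999
  expect_error(build_transition_matrix(v, "chemo", 1), "DFS exit")
  v <- means
  v["tp_chf_death"] <- 0.95
  expect_error(build_transition_matrix(v, "chemo", 1), "CHF exit")
})

test_that("cohort traces conserve mass with monotone death and degenerate limits", {
  for (arm in c("trastuzumab", "chemo")) {
    tr <- run_cohort(means, arm)
    expect_identical(nrow(tr), 49L)
    expect_equal(unname(rowSums(tr)), rep(1, 49), tolerance = 1e-10)
    expect_true(all(diff(tr[, "DEATH"]) >= -1e-14))
    expect_true(all(tr >= 0 & tr <= 1))
  }
  # all transition probabilities zero: the cohort never leaves DFS
  v0 <- means
  v0[startsWith(names(v0), "tp_")] <- 0
  tr0 <- run_cohort(v0, "chemo")
  expect_identical(unique(tr0[, "DFS"]), 1)
  # certain first-cycle death is absorbing
  v1 <- means
  v1[c("tp_dfs_chf", "tp_dfs_rec", "tp_dfs_met")] <- 0
  v1["tp_dfs_death"] <- 1
  tr1 <- run_cohort(v1, "chemo")
  expect_identical(unique(tr1[, "DEATH"]), 1)
})

test_that("first two cycles match the hand-iterated occupancy", {
  tr <- run_cohort(means, "chemo")
  s1 <- 0.0053 + 0.0294 + 0.0785 + 0.0020   # DFS exits, cycle 1 (with CHF)
  s2 <- 0.0294 + 0.0785 + 0.0020            # cycle 2: CHF entry closed
  expect_equal(tr[1, "DFS"], 1 - s1, tolerance = 1e-12)
  # cycle 2: survivors of the DFS exits plus the CHF residual returning
  expect_equal(tr[2, "DFS"],
               (1 - s1) * (1 - s2) + 0.0053 * (1 - 0.0294 - 0.0785 - 0.15),
               tolerance = 1e-12)
  expect_equal(tr[2, "REC_LATER"],
               tr[1, "REC_Y1"] * (1 - 0.0785 - 0.295), tolerance = 1e-12)
})

test_that("null treatment effect makes the two arms identical", {
  v <- param_means(null_effect_table())
  expect_equal(unclass(run_cohort(v, "trastuzumab")),
               unclass(run_cohort(v, "chemo")),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("engine matches a brute-force matrix-power oracle on a 3-state collapse", {
  # disable CHF and local recurrence: DFS -> metastasis -> death only,
  # equivalent to a 3-state chain (DFS, pooled-sick, death)
  v <- means
  v[c("tp_dfs_chf", "tp_dfs_rec", "tp_chf_rec", "tp_chf_met", "tp_chf_death",
      "tp_rec_met", "tp_rec_death")] <- 0
  p_sick <- v[["tp_dfs_met"]]; p_die <- v[["tp_dfs_death"]]; q <- v[["tp_met_death"]]
  A <- matrix(c(1 - p_sick - p_die, p_sick, p_die,
                0, 1 - q, q,
                0, 0, 1), 3, 3, byrow = TRUE)
  tr <- run_cohort(v, "chemo")
  Apow <- diag(3)
  for (t in 1:49) {
    Apow <- Apow %*% A
    expected <- as.numeric(c(1, 0, 0) %*% Apow)
    expect_equal(tr[t, "DFS"], expected[1], tolerance = 1e-12)
    expect_equal(tr[t, "MET_Y1"] + tr[t, "MET_LATER"], expected[2], tolerance = 1e-12)
    expect_equal(tr[t, "DEATH"], expected[3], tolerance = 1e-12)
  }
})
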