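seg_from_runs <- function(run_labels, run_len = 10, n_maps = 4, fs = 200) {
  segmentation_from_labels(list(rep(run_labels, each = run_len)),
                           fs = fs, n_maps = n_maps,
                           map_labels = LETTERS[seq_len(n_maps)])
}

test_that("observed transitions match hand counts", {
  obs <- observed_transitions(seg_from_runs(c(1, 2, 1, 2, 1)))
  expect_equal(unname(obs["A_to_B"]), 50)
  expect_equal(unname(obs["B_to_A"]), 50)
  expect_equal(sum(obs), 100)
  expect_equal(sum(obs[!names(obs) %in% c("A_to_B", "B_to_A")]), 0)

  # 20-run cycle in one epoch: 19 transitions, 5 of each of A>B, B>C, C>D
  cyc <- observed_transitions(seg_from_runs(rep(c(1, 2, 3, 4), 5)))
  expect_equal(unname(cyc[c("A_to_B", "B_to_C", "C_to_D")]),
               rep(100 * 5 / 19, 3))
  expect_equal(unname(cyc["D_to_A"]), 100 * 4 / 19)
  expect_error(observed_transitions(seg_from_runs(1)), "fewer than two runs")
})

test_that("transitions are counted within epochs only", {
  two_ep <- segmentation_from_labels(
    list(rep(c(1L, 2L), each = 10), rep(c(3L, 4L), each = 10)),
    fs = 200, n_maps = 4, map_labels = LETTERS[1:4])
  obs <- observed_transitions(two_ep)
  expect_equal(unname(obs["B_to_C"]), 0)  # the epoch boundary is not a transition
  expect_equal(unname(obs["A_to_B"]), 50)
  expect_equal(unname(obs["C_to_D"]), 50)
})

test_that("expected transitions follow the occurrence product rule", {
  eq <- expected_transitions(rep(0.25, 4))
  expect_equal(unname(eq), rep(100 / 12, 12))

  p <- c(0.4, 0.3, 0.2, 0.1)
  e <- expected_transitions(p, LETTERS[1:4])
  # hand arithmetic: sum over ordered distinct pairs = 1 - sum(p^2) = 0.7
  expect_equal(unname(e["A_to_B"]), 100 * 0.12 / 0.7, tolerance = 1e-12)
  expect_equal(sum(e), 100)
  # enumeration cross-check of the whole vector
  idx <- expand.grid(j = 1:4, i = 1:4)[, 2:1]
  idx <- idx[idx$i != idx$j, ]
  idx <- idx[order(idx$i, idx$j), ]
  expect_equal(unname(e), 100 * p[idx$i] * p[idx$j] / 0.7, tolerance = 1e-12)

  z <- expected_transitions(c(0.5, 0.5, 0, 0), LETTERS[1:4])
  expect_equal(sum(z), 100)
  expect_true(all(z[grepl("C|D", names(z))] == 0))

  rc <- expected_transitions(p, LETTERS[1:4], rule = "row-conditional")
  expect_equal(sum(rc), 100)
  expect_false(isTRUE(all.equal(unname(rc), unname(e))))
})

test_that("chi-square distance matches hand arithmetic and is asymmetric", {
  expect_equal(chi_square_distance(1:12, 1:12), 0)
  obs <- c(10, 0, rep(8, 10))
  exp <- c(5, 5, rep(8, 10))
  expect_equal(chi_square_distance(obs, exp), 10)
  expect_false(chi_square_distance(obs, exp) ==
               chi_square_distance(exp, obs))
  expect_error(chi_square_distance(1:3, rep(0, 3)), "all expected")
})

test_that("observed percentages track the planted transition structure", {
  tw <- matrix(c(0, 3, 1, 1,
                 1, 0, 3, 1,
                 1, 1, 0, 3,
                 3, 1, 1, 0), 4, 4, byrow = TRUE)
  cfg <- subject_sim_config(duration_s = 200, transition_weights = tw)
  sim <- simulate_subject(cfg, seed = 17)
  seg <- segmentation_from_labels(labels_to_epochs(sim$states, 200),
                                  fs = 200, n_maps = 4,
                                  map_labels = LETTERS[1:4])
  obs <- observed_transitions(seg)
  # long-run pair frequencies: stationary dist of the embedded run chain
  # times the row-normalized transition probabilities
  p <- tw / rowSums(tw)
  pi <- Re(eigen(t(p))$vectors[, 1]); pi <- pi / sum(pi)
  theo <- sweep(p, 1, pi, "*")
  theo_vec <- 100 * c(t(theo))[c(t(diag(4) == 0))]
  expect_equal(unname(obs), theo_vec, tolerance = 0.15)
})

test_that("transition profile is internally consistent", {
  seg <- seg_from_runs(c(1, 2, 3, 1, 4, 2, 1, 3))
  pr <- transition_profile(seg)
  expect_equal(sum(pr$observed), 100)
  expect_equal(sum(pr$expected), 100)
  expect_equal(pr$chi2, chi_square_distance(pr$observed, pr$expected))
})

test_that("permutation test returns p = 1 when observed equals expected", {
  set.seed(5)
  exp <- matrix(rep(100 / 12, 12 * 10), 10, 12)
  res <- syntax_permutation_test(exp, exp, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_warning(syntax_permutation_test(exp, exp, n_perm = 50, seed = 1),
                 "100 permutations")
  expect_error(syntax_permutation_test(exp[1, , drop = FALSE],
                                       exp[1, , drop = FALSE], 200),
               "two subjects")
})

test_that("permutation test is deterministic given the seed and detects syntax", {
  set.seed(6)
  pr <- simulate_null_profiles(30, attractor = "A")
  a <- syntax_permutation_test(pr$observed, pr$expected, n_perm = 500,
                               seed = 3)
  b <- syntax_permutation_test(pr$observed, pr$expected, n_perm = 500,
                               seed = 3)
  expect_identical(a$p_value, b$p_value)
  expect_lt(a$p_value, 0.01)
})
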