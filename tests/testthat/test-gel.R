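test_that("ladder interpolation is log-linear in migration distance", {
  lane <- tibble::tibble(
    distance_mm = c(10, 15, 20), intensity = c(1, 1, 1)
  )
  ladder <- tibble::tibble(
    distance_mm = c(10, 20), length_nt = c(23130, 2027)
  )
  len <- lane_fragment_length(lane, ladder)
  expect_equal(len, sqrt(23130 * 2027), tolerance = 1e-6) # ~6847 nt
  out_of_range <- tibble::tibble(
    distance_mm = c(30, 35), intensity = c(1, 2)
  )
  expect_error(lane_fragment_length(out_of_range, ladder), "ladder range")
})

test_that("raw-fragment lanes return the number-average length", {
  lane <- tibble::tibble(fragment_length = rep(50000, 100))
  expect_equal(lane_fragment_length(lane), 50000)
  expect_error(
    lane_fragment_length(tibble::tibble(fragment_length = c(1, -5))),
    "positive"
  )
})

test_that("cpds_per_kb implements the Poisson break-density formula", {
  expect_equal(cpds_per_kb(2000, 10000), 0.4)
  expect_equal(cpds_per_kb(5000, 5000), 0)
  expect_warning(out <- cpds_per_kb(10000, 2000), "clamped")
  expect_equal(out, 0)
})

test_that("percent repaired is relative to the 0 h density", {
  expect_equal(percent_repaired(1, 1), 0)
  expect_equal(percent_repaired(0, 1), 100)
  expect_equal(percent_repaired(0.08, 1), 92)
  expect_error(percent_repaired(0.5, 0), "phi_0")
  expect_warning(percent_repaired(1.2, 1), "negative")
})

test_that("simulated Poisson cleavage recovers the true density", {
  lanes <- simulate_gel_lanes(
    c("0" = 0.5), molecule_length = 50000, n_molecules = 5000, seed = 1
  )
  t4 <- lanes[lanes$treatment == "t4", ]
  mock <- lanes[lanes$treatment == "mock", ]
  # renewal theory: number-average length = 1/(phi/1000 + 1/L)
  expect_equal(
    lane_fragment_length(t4), 1 / (0.5 / 1000 + 1 / 50000),
    tolerance = 0.05
  )
  est <- cpds_per_kb(lane_fragment_length(t4), lane_fragment_length(mock))
  expect_equal(est, 0.5, tolerance = 0.05)
  # monotonicity: doubling density shortens fragments
  lanes2 <- simulate_gel_lanes(c("0" = 1.0),
    molecule_length = 50000,
    n_molecules = 5000, seed = 1
  )
  expect_lt(
    lane_fragment_length(lanes2[lanes2$treatment == "t4", ]),
    lane_fragment_length(t4)
  )
  # zero density leaves molecules intact
  lanes0 <- simulate_gel_lanes(c("0" = 0), n_molecules = 50, seed = 1)
  expect_true(all(
    lanes0$fragment_length[lanes0$treatment == "t4"] == 50000
  ))
})

test_that("gel summary reproduces a known repair time course", {
  lanes <- simulate_gel_lanes(
    c("0" = 1, "30" = 0.5, "60" = 0.1),
    n_molecules = 5000, seed = 2
  )
  summ <- gel_repair_summary(lanes)
  expect_equal(summ$pct_repaired[summ$timepoint == 0], 0)
  expect_equal(summ$pct_repaired[summ$timepoint == 30], 50, tolerance = 0.1)
  expect_equal(summ$pct_repaired[summ$timepoint == 60], 90, tolerance = 0.05)
  expect_equal(
    summ$fraction_remaining, 1 - summ$pct_repaired / 100,
    tolerance = 1e-12
  )
})

test_that("Holm-Sidak adjustment is monotone, conservative and exact at m=1", {
  expect_equal(holm_sidak(0.03), 0.03)
  p <- c(0.01, 0.2, 0.04, 0.8)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
  # closed form for the smallest: 1 - (1 - p_min)^m
  expect_equal(min(adj), 1 - (1 - 0.01)^4)
})

test_that("replicate_test handles identical and degenerate groups", {
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 3), value = rep(c(5, 5), each = 3)
  )
  res <- replicate_test(d)
  expect_equal(res$p.adj, 1)
  d2 <- tibble::tibble(
    group = rep(c("a", "b"), each = 3),
    value = c(1, 2, 3, 1.1, 2.1, 3.1)
  )
  res2 <- replicate_test(d2)
  expect_equal(res2$p.value, res2$p.adj) # single comparison
  expect_error(
    replicate_test(tibble::tibble(group = c("a", "b"), value = 1:2)),
    "2 replicates"
  )
})

test_that("unpaired t-test type-I error is nominal under the null", {
  set.seed(42)
  n_rep <- 1000
  rej <- vapply(seq_len(n_rep), function(i) {
    d <- tibble::tibble(
      group = rep(c("a", "b"), each = 3), value = stats::rnorm(6)
    )
    replicate_test(d)$p.adj < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.08)
})
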