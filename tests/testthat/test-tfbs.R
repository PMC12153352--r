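test_that("telomere exclusion removes sites within 1 kb of either end", {
  lens <- c(chrI = 20000L)
  sites <- tibble::tibble(
    tf = "reb1", chrom = "chrI",
    midpoint = c(900L, 1001L, 10000L, 19100L, 19000L),
    strand = "+", occupancy = 50
  )
  out <- load_tfbs(sites, lens)
  expect_setequal(out$midpoint, c(1001L, 10000L, 19000L))
  expect_error(
    load_tfbs(dplyr::mutate(sites, chrom = "chrZ"), lens), "chrZ"
  )
})

test_that("per-TF midpoint offsets are applied exactly once", {
  lens <- c(chrI = 20000L)
  sites <- tibble::tibble(
    tf = c("a", "a", "b"), chrom = "chrI",
    midpoint = c(5000L, 6000L, 7000L), strand = "+", occupancy = 1
  )
  out <- load_tfbs(sites, lens,
    offsets = tibble::tibble(tf = "a", offset = 1L)
  )
  expect_equal(out$midpoint, c(5001L, 6001L, 7000L))
})

test_that("core and flank windows partition the +/-100 bp span", {
  fx <- shared_fixture()
  sites <- load_tfbs(fx$ann$tfbs, fx$genome)
  trt <- fx$sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, 0.4)
  st <- tf_core_flank(fx$t0, trt, sites, nz)
  span <- tibble::tibble(
    chrom = sites$chrom, lo = sites$midpoint - 100L,
    hi = sites$midpoint + 100L, strand = NA_character_
  )
  total <- sum(cpdrepair:::range_sums(fx$t0, span))
  core <- tibble::tibble(
    chrom = sites$chrom, lo = sites$midpoint - 4L,
    hi = sites$midpoint + 4L, strand = NA_character_
  )
  n0_flank <- total - sum(cpdrepair:::range_sums(fx$t0, core))
  expect_equal(st$n0_core + n0_flank, total)
})

test_that("TFs below the core count threshold are flagged excluded", {
  g <- toy_genome(chrI = strrep("CT", 5000))
  tr0 <- zero_track(g)
  sel <- tr0$pos >= 4996 & tr0$pos <= 5004 & tr0$strand == "+"
  tr0$count[sel] <- 11L # 99 core counts over 9 positions
  tr0 <- new_lesion_track(tr0)
  trt <- tr0
  sites <- tibble::tibble(
    tf = "x", chrom = "chrI", midpoint = 5000L, strand = "+", occupancy = 50
  )
  nz <- structure(
    list(f_gel = 0.4, n0_total = 1000, nt_total = 1000, timepoint = 30),
    class = "cpd_normalizer"
  )
  st <- tf_core_flank(tr0, trt, sites, nz)
  expect_equal(st$n0_core, 99)
  expect_true(st$excluded)
  tr0$count[sel][1] <- 12L # one more core count crosses the threshold
  st2 <- tf_core_flank(new_lesion_track(tr0), new_lesion_track(tr0), sites, nz)
  expect_false(st2$excluded)
})

test_that("no-occlusion simulation gives near-zero core-flank delta", {
  fx <- shared_fixture()
  # model in shared fixture occludes tfA sites; rerun without blocking
  model <- repair_rate_model(tfbs_block = 1)
  sim <- simulate_repair(fx$t0, model, fx$ann, 30, "rad14+PR", seed = 61)
  trt <- sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, sim$true_fraction_remaining[["30"]])
  sites <- load_tfbs(fx$ann$tfbs, fx$genome)
  st <- tf_core_flank(fx$t0, trt, sites, nz)
  se <- st$f_core * sqrt(1 / st$nt_core + 1 / st$n0_core)
  expect_lt(abs(st$delta), 4 * se)
})

test_that("occupancy-dependent blocking elevates the core fraction", {
  fx <- shared_fixture()
  trt <- fx$sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, fx$sim$true_fraction_remaining[["30"]])
  sites <- load_tfbs(fx$ann$tfbs, fx$genome)
  st <- tf_scatter(fx$t0, trt, sites, nz, min_core_cpds = 10)
  expect_gt(st$delta[1], 0)
})

test_that("site profiles mask offsets below the count threshold", {
  fx <- shared_fixture()
  trt <- fx$sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, 0.4)
  sites <- load_tfbs(fx$ann$tfbs, fx$genome)
  pr <- tf_site_profile(fx$t0, trt, sites, nz, half_window = 100)
  expect_equal(nrow(pr), 201)
  expect_true(all(is.na(pr$fraction[pr$masked])))
  expect_true(all(pr$masked[pr$n0 < 10 | pr$nt < 10]))
  expect_true(all(!pr$masked[pr$n0 >= 10 & pr$nt >= 10]))
})

test_that("occupancy split is strict at the threshold", {
  sites <- tibble::tibble(
    tf = "reb1", chrom = "chrI", midpoint = 1:4 * 1000L, strand = "+",
    occupancy = c(9.9, 10, 50, NA)
  )
  out <- occupancy_split(sites)
  expect_equal(nrow(out), 3)
  expect_equal(out$cohort, c("control", "bound", "bound"))
})
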