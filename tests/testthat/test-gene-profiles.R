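test_that("TS/NTS assignment follows the template-strand convention", {
  expect_equal(assign_ts_nts("+", "-"), "TS")
  expect_equal(assign_ts_nts("+", "+"), "NTS")
  expect_equal(assign_ts_nts("-", "+"), "TS")
  expect_equal(assign_ts_nts("-", "-"), "NTS")
})

test_that("bin layout matches the fixed widths on both gene orientations", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrI", tss = 1001L, tes = 1600L, strand = "+"
  )
  b <- gene_bins(genes)
  coding <- b[b$region == "coding", ]
  expect_equal(coding$lo, seq(1001L, 1501L, by = 100L))
  expect_equal(coding$hi, seq(1100L, 1600L, by = 100L))
  up <- b[b$region == "upstream", ]
  expect_equal(up$lo, c(500L, 667L, 834L))
  expect_equal(up$hi, c(666L, 833L, 1000L))
  expect_true(all(up$hi - up$lo + 1 == 167))
  down <- b[b$region == "downstream", ]
  expect_equal(down$lo, c(1601L, 1768L, 1935L))

  # minus-strand gene: same layout mirrored around its own TSS/TES
  gm <- tibble::tibble(
    gene_id = "g2", chrom = "chrI", tss = 1600L, tes = 1001L, strand = "-"
  )
  bm <- gene_bins(gm)
  cm <- bm[bm$region == "coding", ]
  expect_equal(cm$hi[1], 1600L) # bin 1 abuts the TSS
  expect_equal(cm$lo[6], 1001L)
  um <- bm[bm$region == "upstream", ]
  expect_equal(um$lo, c(1935L, 1768L, 1601L))
  expect_equal(um$hi, c(2101L, 1934L, 1767L))
})

test_that("rounding splits a non-divisible span with remainder in last bin", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrI", tss = 1L, tes = 601L, strand = "+"
  )
  coding <- gene_bins(genes, flank_bins = 0)
  expect_equal(sum(coding$hi - coding$lo + 1), 601)
  expect_equal(coding$hi[6], 601L)
  short <- tibble::tibble(
    gene_id = "g2", chrom = "chrI", tss = 10L, tes = 13L, strand = "+"
  )
  expect_message(out <- gene_bins(short), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("binned fractions aggregate to the gene-set-wide fraction", {
  fx <- shared_fixture()
  trt <- fx$sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, 0.4)
  bp <- bin_genes(fx$t0, trt, fx$ann$genes, nz)
  expect_equal(nrow(bp), 24) # 12 bins x 2 frames
  # count-weighted aggregate over all bins == fraction from summed counts
  agg <- normalized_fraction(nz, sum(bp$n0), sum(bp$nt))
  expect_equal(
    sum(bp$fraction * bp$n0) / sum(bp$n0), agg,
    tolerance = 1e-12
  )
})

test_that("TS occlusion elevates the TS fraction in all coding bins", {
  fx <- shared_fixture()
  trt <- fx$sim$tracks[["30"]]
  nz <- gel_anchor(fx$t0, trt, fx$sim$true_fraction_remaining[["30"]])
  bp <- bin_genes(fx$t0, trt, fx$ann$genes, nz)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(bp)[, c("bin", "region", "frame", "fraction")],
    names_from = "frame", values_from = "fraction"
  )
  coding <- wide[wide$region == "coding", ]
  expect_true(all(coding$TS > coding$NTS))
  la <- log2_asymmetry(bp)
  expect_true(all(la$log2_ts_nts[la$region == "coding"] > 0))
  pt <- paired_bin_test(bp)
  expect_lt(pt$p.value, 0.05)
  expect_gt(pt$estimate, 0)
})

test_that("log2 asymmetry and the paired test behave at the null and edges", {
  sym <- fake_binned_profile(ts = rep(0.4, 6), nts = rep(0.4, 6))
  la <- log2_asymmetry(sym)
  expect_true(all(la$log2_ts_nts == 0))
  expect_equal(paired_bin_test(sym)$p.value, 1)

  doubled <- fake_binned_profile(ts = rep(0.4, 6), nts = rep(0.2, 6))
  expect_true(all(log2_asymmetry(doubled)$log2_ts_nts == 1))
  pt <- paired_bin_test(doubled) # zero-variance nonzero difference
  expect_true(pt$degenerate)
  expect_lt(pt$p.value, 1e-12)

  zero <- fake_binned_profile(ts = c(0, rep(0.4, 5)), nts = rep(0.4, 6))
  expect_true(is.na(log2_asymmetry(zero)$log2_ts_nts[1]))
})

test_that("transcription cohorts use the stated thresholds", {
  genes <- tibble::tibble(rate = c(20, 0.5, 5, NA))
  out <- stratify_by_transcription(genes)
  expect_equal(as.character(out$cohort), c("high", "low", "intermediate"))
  expect_equal(nrow(out), 3) # missing rate dropped
})

test_that("TSS metaprofile emits one row per offset per strand frame", {
  fx <- shared_fixture()
  nz <- gel_anchor(fx$t0, fx$t0, 0.4)
  mp <- tss_metaprofile(fx$t0, fx$t0, fx$ann$genes, nz)
  expect_equal(nrow(mp), 1141 * 2) # window -500..640
  expect_equal(sort(unique(mp$offset)), -500:640)
  # uniform retention: flat at F_gel wherever defined
  expect_true(all(abs(mp$fraction[!is.na(mp$fraction)] - 0.4) < 1e-12))
})

test_that("gene matrix rows are sorted stably by descending rate", {
  fx <- shared_fixture()
  nz <- gel_anchor(fx$t0, fx$t0, 0.4)
  gm <- gene_cluster_matrix(fx$t0, fx$t0, fx$ann$genes, nz,
    window = c(-50, 50)
  )
  rates <- gm |>
    dplyr::distinct(gene_id, rate)
  expect_true(all(diff(rates$rate) <= 0))
  # ties keep input order (stable sort)
  tied <- fx$ann$genes$gene_id[fx$ann$genes$rate == 20]
  expect_equal(
    as.character(rates$gene_id[rates$rate == 20]), tied
  )
  # two genes with identical per-offset counts give identical rows
  wide <- gm |>
    dplyr::select("gene_id", "offset", "fraction") |>
    tidyr::pivot_wider(names_from = "offset", values_from = "fraction")
  expect_equal(nrow(wide), nrow(fx$ann$genes))
})
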