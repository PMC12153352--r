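test_that("unique filter drops every copy of cross-isolate recurrences", {
  rec <- tibble::tibble(
    isolate = c("i3", "i7", "i1"),
    chrom = "chrI", pos = c(100L, 100L, 200L),
    ref = c("C", "C", "T"), alt = c("T", "T", "A")
  )
  out <- unique_filter(rec)
  expect_equal(out$pos, 200L)
  one <- unique_filter(rec, keep = "one")
  expect_equal(sort(one$pos), c(100L, 200L))
  # same site in the same isolate twice is not a cross-isolate recurrence
  same <- tibble::tibble(
    isolate = "i1", chrom = "chrI", pos = c(5L, 5L),
    ref = "C", alt = "T"
  )
  expect_equal(nrow(unique_filter(same)), 2)
})

test_that("purine-reference records fold into the pyrimidine frame once", {
  g <- toy_genome(chrI = "TTGAT")
  rec <- tibble::tibble(
    isolate = "i1", chrom = "chrI", pos = 3L, ref = "G", alt = "A"
  )
  cls <- classify_mutations(rec, g)
  expect_equal(cls$class, "C>T")
  expect_equal(cls$context, "TCA") # revcomp of plus-strand TGA
  expect_equal(cls$pyr_strand, "-")
  expect_true(cls$dipy) # TC is a dipyrimidine on the minus strand
})

test_that("spectrum conserves the record count over 96 channels", {
  fx <- shared_fixture()
  muts <- simulate_passaging_mutations(fx$genome, fx$ann,
    n_isolates = 5, mean_per_isolate = 60, seed = 70
  )
  sp <- trinuc_spectrum(muts, fx$genome)
  expect_equal(nrow(sp), 96)
  expect_equal(sum(sp$count), nrow(muts))
  # class weights concentrated on C>T show up as the modal class
  by_class <- sp |>
    dplyr::group_by(class) |>
    dplyr::summarise(n = sum(count))
  expect_equal(by_class$class[which.max(by_class$n)], "C>T")
})

test_that("invalid mutation records are skipped or rejected", {
  g <- toy_genome(chrI = "TTGAT")
  expect_message(
    out <- classify_mutations(tibble::tibble(
      isolate = "i", chrom = "chrI", pos = c(3L, 3L), ref = c("G", "GG"),
      alt = c("A", "A")
    ), g),
    "non-SNV"
  )
  expect_equal(nrow(out), 1)
  expect_message(
    end <- classify_mutations(tibble::tibble(
      isolate = "i", chrom = "chrI", pos = 1L, ref = "T", alt = "A"
    ), g),
    "chromosome ends"
  )
  expect_equal(nrow(end), 0)
  expect_error(
    classify_mutations(tibble::tibble(
      isolate = "i", chrom = "chrI", pos = 3L, ref = "C", alt = "T"
    ), g),
    "mismatch"
  )
})

test_that("constructed context imbalance normalizes to asymmetry exactly 1", {
  # One plus-strand gene; TCA occurs 4x on the sense (NTS) strand and 12x on
  # the template (TS) strand (as TGA in plus coordinates). One C>T mutation
  # at every occurrence: m ratio 3, but A = 1 after context normalization.
  spacer <- "GGTT" # no TCA/TGA across junctions
  seqs <- paste0(
    strrep(paste0("TCA", spacer), 4),
    strrep(paste0("TGA", spacer), 12)
  )
  g <- toy_genome(chrI = paste0("CC", seqs, strrep("G", 1200)))
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrI", tss = 3L,
    tes = 2L + nchar(seqs), strand = "+"
  )
  # mutations: C>T at the middle C of every TCA (plus) and TGA (minus frame)
  pos_tca <- 2L + seq(0L, by = 7L, length.out = 4) + 2L
  pos_tga <- 2L + 4L * 7L + seq(0L, by = 7L, length.out = 12) + 2L
  rec <- tibble::tibble(
    isolate = sprintf("i%02d", seq_len(16)),
    chrom = "chrI",
    pos = c(pos_tca, pos_tga),
    ref = c(rep("C", 4), rep("G", 12)),
    alt = c(rep("T", 4), rep("A", 12))
  )
  asym <- transcriptional_asymmetry(rec, genes, g)
  ch <- asym[asym$class == "C>T" & asym$context == "TCA", ]
  expect_equal(ch$m_ts, 12)
  expect_equal(ch$m_nts, 4)
  expect_equal(ch$k_ts, 12)
  expect_equal(ch$k_nts, 4)
  expect_identical(ch$ratio, 1)
  expect_true(ch$flagged) # 16 < 30 mutations
})

test_that("infinite-ratio sentinel and flags behave at the edges", {
  g <- toy_genome(chrI = paste0("CCTCACC", strrep("G", 1200)))
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrI", tss = 2L, tes = 7L, strand = "-"
  )
  # gene on minus strand: template is plus strand, so a plus-frame C>T at
  # pos 4 is a TS mutation; no NTS mutations anywhere
  rec <- tibble::tibble(
    isolate = "i1", chrom = "chrI", pos = 4L, ref = "C", alt = "T"
  )
  asym <- transcriptional_asymmetry(rec, genes, g)
  ch <- asym[asym$class == "C>T" & asym$context == "TCA", ]
  expect_identical(ch$ratio, Inf)
})

test_that("class exclusion removes exactly the specified channels", {
  fx <- shared_fixture()
  muts <- simulate_passaging_mutations(fx$genome, fx$ann,
    n_isolates = 10, mean_per_isolate = 100,
    class_weights = c("C>T" = 0.7, "T>A@NTA" = 0.3), seed = 71
  )
  cls <- classify_mutations(muts, fx$genome)
  n_nta <- sum(cls$class == "T>A" & grepl("^[ACGT]TA$", cls$context))
  kept <- exclude_class(muts, "T>A@NTA", fx$genome)
  expect_equal(nrow(kept), nrow(muts) - n_nta)
  k2 <- classify_mutations(kept, fx$genome)
  expect_false(any(k2$class == "T>A" & grepl("TA$", k2$context)))
  # share of T>A@NTA tracks the configured 30% weight
  expect_equal(n_nta / nrow(muts), 0.3, tolerance = 0.15)
  # empty spec is the identity; malformed specs error
  expect_identical(exclude_class(muts, NULL, fx$genome), muts)
  expect_error(exclude_class(muts, "Q>T", fx$genome), "malformed")
})

test_that("gene-body distribution recovers the configured strand fold", {
  g <- make_genome(72, 1, 150000, 0.38)
  ann <- make_annotations(g,
    n_genes = 40, gene_length = 1500,
    gene_spacing = 2700, seed = 73
  )
  for (fold in c(1, 4)) {
    muts <- simulate_passaging_mutations(g, ann,
      n_isolates = 20, mean_per_isolate = 120, ts_fold = fold,
      seed = 74 + fold
    )
    dist <- gene_body_distribution(unique_filter(muts), ann$genes, g)
    est <- mutation_strand_fold(dist)
    expect_equal(est, fold, tolerance = 0.3)
  }
})

test_that("intergenic mutations land only in flank bins or nowhere", {
  g <- toy_genome(chrI = paste0(strrep("A", 2000), "TC", strrep("A", 2000)))
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrI", tss = 100L, tes = 699L, strand = "+"
  )
  rec <- tibble::tibble(
    isolate = "i1", chrom = "chrI", pos = 2001L, ref = "T", alt = "A"
  )
  dist <- gene_body_distribution(rec, genes, g)
  expect_equal(sum(dist$count[dist$region == "coding"]), 0)
  expect_equal(sum(dist$count), 0) # far from flanks too
})

test_that("recurrent duplication is removed at the configured rate", {
  fx <- shared_fixture()
  muts <- simulate_passaging_mutations(fx$genome, fx$ann,
    n_isolates = 20, mean_per_isolate = 90,
    recurrent_fraction = 0.1, seed = 75
  )
  kept <- unique_filter(muts)
  removed <- 1 - nrow(kept) / nrow(muts)
  expect_equal(removed, 0.1, tolerance = 0.02)
})

test_that("canavanine frequency and fold induction follow the plate math", {
  expect_equal(canr_frequency(25, 1, 50, 1e4), 5e-5)
  expect_equal(fold_induction(5e-5, 1e-6), 50)
  expect_equal(fold_induction(2e-6, 2e-6), 1)
  expect_error(canr_frequency(10, 1, 0, 1e4), "colonies_sc")
})
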