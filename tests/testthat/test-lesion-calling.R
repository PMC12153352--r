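test_that("lesion calling follows the upstream-dinucleotide convention", {
  # Plus-strand read with 5' end at p = 5 over GGAAGG: upstream plus bases
  # AA at (3,4) -> minus-strand lesion, dinucleotide TT, retained.
  g <- toy_genome(chrI = "GGAAGG")
  r <- tibble::tibble(
    chrom = "chrI", start = 4L, end = 6L, strand = "+"
  )
  call <- call_lesions(r, g)
  expect_equal(call$strand, "-")
  expect_equal(call$pos, 3L)
  expect_equal(call$dinuc, "TT")
  expect_equal(call$status, "retained")

  # Minus-strand read with 5' end at q = 2 over GGTTGG: downstream plus
  # bases TT at (3,4) -> plus-strand lesion, retained.
  g2 <- toy_genome(chrI = "GGTTGG")
  r2 <- tibble::tibble(
    chrom = "chrI", start = 0L, end = 2L, strand = "-"
  )
  call2 <- call_lesions(r2, g2)
  expect_equal(call2$strand, "+")
  expect_equal(call2$pos, 3L)
  expect_equal(call2$dinuc, "TT")
  expect_equal(call2$status, "retained")

  # Upstream AT on the minus strand is not a dipyrimidine -> filtered.
  g3 <- toy_genome(chrI = "GCATGC")
  r3 <- tibble::tibble(
    chrom = "chrI", start = 4L, end = 6L, strand = "+"
  )
  expect_equal(call_lesions(r3, g3)$status, "non_dipyrimidine")
})

test_that("reads with off-end or ambiguous upstream windows are tallied", {
  g <- toy_genome(chrI = "GGNAGG")
  r <- tibble::tibble(
    chrom = "chrI",
    start = c(4L, 0L), end = c(6L, 2L), strand = c("+", "+")
  )
  call <- call_lesions(r, g)
  expect_equal(call$status, c("ambiguous_base", "off_end"))
})

test_that("build_lesion_track zero-fills, aggregates and conserves N", {
  g <- toy_genome(chrI = paste0("GGAAGG", strrep("T", 1000)))
  none <- build_lesion_track(
    tibble::tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0)
    ), g
  )
  expect_equal(track_total(none), 0)
  expect_equal(nrow(none), nrow(dipyrimidine_sites(g)))

  r <- tibble::tibble(
    chrom = "chrI", start = rep(4L, 3), end = rep(6L, 3), strand = "+"
  )
  tr <- build_lesion_track(r, g)
  expect_equal(tr$count[tr$pos == 3 & tr$strand == "-"], 3L)
  expect_equal(track_total(tr), 3)
  comp <- dinucleotide_composition(tr)
  expect_equal(sum(comp$count), 3)
  expect_equal(comp$count[comp$dinuc == "TT"], 3)
})

test_that("reads on unknown chromosomes are an error naming the chromosome", {
  g <- toy_genome(chrI = strrep("ACGT", 300))
  r <- tibble::tibble(chrom = "chrX", start = 10L, end = 20L, strand = "+")
  expect_error(build_lesion_track(r, g), "chrX")
})

test_that("mirror symmetry: reverse-complementing genome and reads swaps strands", {
  fx <- shared_fixture()
  g <- fx$genome
  len <- chrom_lengths(g)[[1]]
  reads <- lesions_to_reads(fx$sim$tracks[["60"]], g, 0, seed = 7)
  tr <- build_lesion_track(reads, g)

  gm <- toy_genome(chrI = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g[[1]]))
  ))
  mirrored <- tibble::tibble(
    chrom = reads$chrom,
    start = len - reads$end,
    end = len - reads$start,
    strand = ifelse(reads$strand == "+", "-", "+")
  )
  trm <- build_lesion_track(mirrored, gm)
  # site at (pos, s) maps to (len - pos, opposite strand)
  a <- tr[tr$count > 0, ]
  m <- match(
    paste(len - a$pos, ifelse(a$strand == "+", "-", "+")),
    paste(trm$pos, trm$strand)
  )
  expect_false(anyNA(m))
  expect_identical(trm$count[m], a$count)
  expect_equal(track_total(trm), track_total(tr))
})
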