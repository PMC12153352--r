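MUT_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Remove mutations recurrent across isolates
#'
#' A substitution observed in two or more independent isolates is almost
#' certainly ancestral or pre-existing rather than induced during passaging,
#' so by default every copy of a cross-isolate recurrent (chrom, pos, ref,
#' alt) is removed. `keep = "one"` instead retains a single representative.
#'
#' @param records Mutation tibble with `isolate`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param keep `"none"` (drop all copies, default) or `"one"`.
#' @return Filtered tibble.
#' @export
unique_filter <- function(records, keep = c("none", "one")) {
  keep <- match.arg(keep)
  assert_cols(records, c("isolate", "chrom", "pos", "ref", "alt"), "`records`")
  records |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::filter(
      if (keep == "none") {
        dplyr::n_distinct(.data$isolate) == 1
      } else {
        dplyr::row_number() == 1 | dplyr::n_distinct(.data$isolate) == 1
      }
    ) |>
    dplyr::ungroup()
}

#' Classify substitutions into the pyrimidine frame
#'
#' Every single-base substitution is expressed with a pyrimidine (C or T)
#' reference: purine-reference records are reverse-complemented exactly
#' once, so a plus-strand G>A in 5'-TGA-3' becomes C>T in context TCA on the
#' minus strand. `pyr_strand` records which genomic strand carries the
#' pyrimidine. Records whose reference does not match the genome are an
#' error; non-SNV records and records without both flanking bases are
#' skipped with a message.
#'
#' @param records Mutation tibble (`isolate`, `chrom`, `pos`, `ref`, `alt`).
#' @param genome Genome the records were called against.
#' @return The SNV records with `class`, `context` (pyrimidine-frame
#'   trinucleotide), `pyr_strand` and `dipy` (pyrimidine neighbour flag)
#'   appended.
#' @export
classify_mutations <- function(records, genome) {
  assert_cols(records, c("chrom", "pos", "ref", "alt"), "`records`")
  unknown <- setdiff(unique(records$chrom), names(genome))
  if (length(unknown)) {
    rlang::abort(sprintf(
      "mutation(s) on unknown chromosome(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  snv <- records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T") & records$ref != records$alt
  if (any(!snv)) {
    rlang::inform(sprintf("%d non-SNV record(s) skipped", sum(!snv)))
    records <- records[snv, ]
  }
  lens <- chrom_lengths(genome)
  interior <- records$pos > 1L & records$pos < lens[records$chrom]
  if (any(!interior)) {
    rlang::inform(sprintf(
      "%d record(s) at chromosome ends skipped (no flanking context)",
      sum(!interior)
    ))
    records <- records[interior, ]
  }
  obs <- genome_substr(genome, records$chrom, records$pos, records$pos)
  bad <- obs != records$ref
  if (any(bad)) {
    rlang::abort(paste0(
      "reference allele mismatch at: ",
      paste(utils::head(sprintf(
        "%s:%d (%s!=%s)", records$chrom[bad], records$pos[bad],
        records$ref[bad], obs[bad]
      ), 5), collapse = ", ")
    ))
  }
  ctx_plus <- genome_substr(
    genome, records$chrom, records$pos - 1L, records$pos + 1L
  )
  pyr <- records$ref %in% PYRIMIDINES
  records$pyr_strand <- ifelse(pyr, "+", "-")
  records$class <- ifelse(pyr,
    paste0(records$ref, ">", records$alt),
    paste0(comp_bases(records$ref), ">", comp_bases(records$alt))
  )
  records$context <- ifelse(pyr, ctx_plus, revcomp(ctx_plus))
  b1 <- substr(records$context, 1, 1)
  b3 <- substr(records$context, 3, 3)
  records$dipy <- b1 %in% PYRIMIDINES | b3 %in% PYRIMIDINES
  records
}

# All 96 pyrimidine-frame channels, zero-filled.
spectrum_channels <- function() {
  tidyr::expand_grid(
    class = MUT_CLASSES, b1 = c("A", "C", "G", "T"), b3 = c("A", "C", "G", "T")
  ) |>
    dplyr::mutate(
      context = paste0(.data$b1, substr(.data$class, 1, 1), .data$b3),
      dipy = .data$b1 %in% PYRIMIDINES | .data$b3 %in% PYRIMIDINES
    ) |>
    dplyr::select("class", "context", "dipy")
}

#' Strand-resolved trinucleotide mutation spectrum
#'
#' Counts substitutions by the 6 pyrimidine-standardized classes x 16
#' trinucleotide contexts; the matrix total equals the number of
#' contributing records. The dipyrimidine flag marks channels whose
#' reference pyrimidine has a pyrimidine neighbour (the CPD-capable
#' contexts).
#'
#' @inheritParams classify_mutations
#' @return A `spectrum_matrix` tibble with all 96 channels: `class`,
#'   `context`, `dipy`, `count`.
#' @export
trinuc_spectrum <- function(records, genome) {
  cls <- classify_mutations(records, genome)
  counts <- cls |>
    dplyr::count(.data$class, .data$context, name = "count")
  out <- spectrum_channels() |>
    dplyr::left_join(counts, by = c("class", "context")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  structure(out,
    n_records = nrow(cls),
    class = c("spectrum_matrix", class(out))
  )
}

#' Strand-resolved mutation counts along gene bodies
#'
#' Assigns each gene-associated mutation to the transcribed strand (TS) if
#' its pyrimidine-frame reference lies on the template strand (the
#' lesion-on-template convention), NTS otherwise, and bins it with the same
#' layout as the repair profiles (equal coding bins plus fixed-width
#' flanks). Mutations in overlapping genes are counted once per gene.
#'
#' @inheritParams classify_mutations
#' @param genes Gene annotation tibble.
#' @inheritParams gene_bins
#' @return Tibble `bin`, `region`, `frame`, `count`.
#' @export
gene_body_distribution <- function(records, genes, genome,
                                   n_bins = 6, flank_bins = 3,
                                   flank_width = 167) {
  cls <- classify_mutations(records, genome)
  bins <- gene_bins(genes, n_bins, flank_bins, flank_width)
  counts <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    sel <- cls$chrom == b$chrom & cls$pos >= b$lo & cls$pos <= b$hi
    fr <- assign_ts_nts(b$strand, cls$pyr_strand[sel])
    tibble::tibble(
      bin = b$bin, region = b$region,
      frame = c("TS", "NTS"),
      count = c(sum(fr == "TS"), sum(fr == "NTS"))
    )
  })
  counts |>
    dplyr::group_by(.data$bin, .data$region, .data$frame) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Aggregate TS:NTS mutation fold of a gene-body distribution
#'
#' @param dist Output of [gene_body_distribution()].
#' @param region Region to aggregate over (default coding bins).
#' @return Scalar TS/NTS count ratio.
#' @export
mutation_strand_fold <- function(dist, region = "coding") {
  d <- dist[dist$region %in% region, ]
  sum(d$count[d$frame == "TS"]) / sum(d$count[d$frame == "NTS"])
}

# Trinucleotide occurrence counts per strand across gene bodies.
# Returns tibble(context, k_ts, k_nts) over all 64 plus-frame trinucs.
genebody_context_counts <- function(genes, genome) {
  tri_counts <- function(seqs) {
    tris <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < 3) {
        return(character(0))
      }
      substring(s, 1:(n - 2), 3:n)
    }), use.names = FALSE)
    table(tris[!grepl("[^ACGT]", tris)])
  }
  per_strand <- list(
    "+" = genes[genes$strand == "+", ], "-" = genes[genes$strand == "-", ]
  )
  get_counts <- function(g) {
    if (nrow(g) == 0) {
      return(table(character(0)))
    }
    tri_counts(genome_substr(
      genome, g$chrom, pmin(g$tss, g$tes), pmax(g$tss, g$tes)
    ))
  }
  plus_genes <- get_counts(per_strand[["+"]]) # sense = plus strand
  minus_genes <- get_counts(per_strand[["-"]]) # sense = minus strand
  lookup <- function(tab, ctx) {
    out <- as.numeric(tab[ctx])
    out[is.na(out)] <- 0
    out
  }
  ctx <- unique(spectrum_channels()$context)
  rc <- revcomp(ctx)
  tibble::tibble(
    context = ctx,
    # Template of a plus gene is the minus strand: occurrences of ctx there
    # appear as revcomp(ctx) on the plus-strand sequence; and vice versa.
    k_ts = lookup(plus_genes, rc) + lookup(minus_genes, ctx),
    k_nts = lookup(plus_genes, ctx) + lookup(minus_genes, rc)
  )
}

#' Trinucleotide-normalized transcriptional asymmetry of mutations
#'
#' For each mutation class x context channel, the TS and NTS gene-body
#' mutation counts are normalized by the number of times that context occurs
#' on each strand across gene bodies, giving
#' `A = (m_TS / k_TS) / (m_NTS / k_NTS)`. Channels with fewer than
#' `min_count` total mutations are reported but flagged; `m_NTS = 0` with
#' `m_TS > 0` yields an `Inf` sentinel.
#'
#' @inheritParams gene_body_distribution
#' @param min_count Flag threshold on `m_TS + m_NTS`.
#' @return Tibble per channel: `class`, `context`, `dipy`, `m_ts`, `m_nts`,
#'   `k_ts`, `k_nts`, `ratio`, `flagged`.
#' @export
transcriptional_asymmetry <- function(records, genes, genome,
                                      min_count = 30) {
  cls <- classify_mutations(records, genome)
  body <- genes |>
    dplyr::mutate(
      lo = pmin(.data$tss, .data$tes), hi = pmax(.data$tss, .data$tes)
    )
  m <- purrr::map_dfr(seq_len(nrow(body)), function(i) {
    g <- body[i, ]
    sel <- cls$chrom == g$chrom & cls$pos >= g$lo & cls$pos <= g$hi
    if (!any(sel)) {
      return(NULL)
    }
    d <- cls[sel, ]
    d$frame <- assign_ts_nts(g$strand, d$pyr_strand)
    d[, c("class", "context", "frame")]
  }) |>
    dplyr::count(.data$class, .data$context, .data$frame) |>
    tidyr::pivot_wider(
      names_from = "frame", values_from = "n", values_fill = 0L
    )
  for (col in c("TS", "NTS")) {
    if (!col %in% names(m)) m[[col]] <- 0L
  }
  k <- genebody_context_counts(genes, genome)
  spectrum_channels() |>
    dplyr::left_join(m, by = c("class", "context")) |>
    dplyr::mutate(
      m_ts = dplyr::coalesce(.data$TS, 0L),
      m_nts = dplyr::coalesce(.data$NTS, 0L)
    ) |>
    dplyr::select(-dplyr::any_of(c("TS", "NTS"))) |>
    dplyr::left_join(k, by = "context") |>
    dplyr::mutate(
      ratio = dplyr::case_when(
        m_ts + m_nts == 0 ~ NA_real_,
        m_nts == 0 ~ Inf,
        k_ts == 0 | k_nts == 0 ~ NA_real_,
        TRUE ~ (m_ts / k_ts) / (m_nts / k_nts)
      ),
      flagged = (.data$m_ts + .data$m_nts) < min_count
    )
}

# Parse class specs like "T>A@NTA" or "C>T" (N = wildcard base).
parse_class_spec <- function(spec) {
  m <- regmatches(
    spec, regexec("^([CT]>[ACGT])(@([ACGTN]{3}))?$", spec)
  )[[1]]
  if (length(m) == 0 || m[1] == "") {
    rlang::abort(sprintf("malformed class spec '%s'", spec))
  }
  list(class = m[2], context = if (m[4] == "") NULL else m[4])
}

#' Exclude a mutation class (optionally context-restricted)
#'
#' Removes records matching a pyrimidine-frame class spec such as
#' `"T>A@NTA"` (T>A substitutions in any NTA context, the signature of
#' atypical thymine-adenine photoproducts) or `"C>T"` (all C>T). `N` in a
#' context is a wildcard. An empty spec is the identity.
#'
#' @inheritParams classify_mutations
#' @param class_spec Character vector of specs (or `NULL`).
#' @return Records with matching mutations removed.
#' @export
exclude_class <- function(records, class_spec, genome) {
  if (is.null(class_spec) || length(class_spec) == 0 ||
    all(class_spec == "")) {
    return(records)
  }
  cls <- classify_mutations(records, genome)
  drop <- rep(FALSE, nrow(cls))
  for (spec in class_spec) {
    p <- parse_class_spec(spec)
    hit <- cls$class == p$class
    if (!is.null(p$context)) {
      pat <- paste0("^", gsub("N", "[ACGT]", p$context), "$")
      hit <- hit & grepl(pat, cls$context)
    }
    drop <- drop | hit
  }
  cls[!drop, setdiff(names(cls), c(
    "class", "context", "pyr_strand", "dipy"
  ))]
}

#' Canavanine-resistance mutation frequency and fold induction
#'
#' The forward-mutation frequency at the CAN1 reporter is the density of
#' canavanine-resistant colonies relative to total viable cells:
#' `(colonies_can * dilution_can) / (colonies_sc * dilution_sc)`, where each
#' dilution is the fold-dilution of the plated aliquot (selective plates are
#' typically plated near-undiluted, nonselective plates at ~1e4).
#'
#' @param colonies_can,colonies_sc Colony counts on selective (SC-Arg+Can)
#'   and nonselective (SC) plates.
#' @param dilution_can,dilution_sc Fold-dilutions of the plated aliquots.
#' @return Mutation frequency (mutants per viable cell).
#' @export
canr_frequency <- function(colonies_can, dilution_can,
                           colonies_sc, dilution_sc) {
  if (any(colonies_sc <= 0)) {
    rlang::abort("`colonies_sc` must be positive")
  }
  (colonies_can * dilution_can) / (colonies_sc * dilution_sc)
}

#' @rdname canr_frequency
#' @param freq_uv,freq_control Mutation frequencies with and without UV.
#' @return `fold_induction()`: the ratio `freq_uv / freq_control`.
#' @export
fold_induction <- function(freq_uv, freq_control) {
  freq_uv / freq_control
}
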