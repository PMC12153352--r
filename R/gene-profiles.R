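#' Transcribed- vs non-transcribed-strand assignment
#'
#' The transcribed strand (TS) of a gene is the template strand, i.e. the
#' strand opposite the annotated mRNA-sense strand; the non-transcribed
#' strand (NTS) is the sense strand itself. Flanks inherit the gene's frame.
#'
#' @param gene_strand Gene (mRNA-sense) strand, `"+"` or `"-"` (vectorized).
#' @param lesion_strand Genomic strand of the lesion/mutation.
#' @return Character vector, `"TS"` or `"NTS"`.
#' @export
assign_ts_nts <- function(gene_strand, lesion_strand) {
  ifelse(lesion_strand == gene_strand, "NTS", "TS")
}

# Genomic strand carrying a given frame for a gene strand.
frame_strand <- function(gene_strand, frame) {
  ifelse(
    frame == "NTS", gene_strand,
    ifelse(gene_strand == "+", "-", "+")
  )
}

#' Bin layout for a gene set
#'
#' Divides each coding span (TSS..TES) into `n_bins` equal bins oriented
#' TSS -> TES (bin boundaries are rounded cumulative edges; remainder bases
#' fall in the last bin), and adds `flank_bins` contiguous fixed-width bins
#' immediately upstream of the TSS and downstream of the TES. Profile bins
#' are numbered 1..(2*flank_bins + n_bins) from the far upstream flank to the
#' far downstream flank. Genes shorter than `n_bins` bp are excluded with a
#' message.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `tes`, `strand`.
#' @param n_bins Number of equal coding bins.
#' @param flank_bins,flank_width Number and width (bp) of flank bins.
#' @return Tibble with one row per gene x bin: `gene_id`, `bin`, `region`
#'   (upstream/coding/downstream), `chrom`, `lo`, `hi`, `strand`.
#' @export
gene_bins <- function(genes, n_bins = 6, flank_bins = 3, flank_width = 167) {
  assert_cols(genes, c("chrom", "tss", "tes", "strand"), "`genes`")
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  }
  short <- abs(genes$tes - genes$tss) + 1 < n_bins
  if (any(short)) {
    rlang::inform(sprintf(
      "%d gene(s) shorter than %d bp excluded from binning", sum(short),
      n_bins
    ))
    genes <- genes[!short, ]
  }
  fw <- flank_width
  if (nrow(genes) == 0) {
    return(tibble::tibble(
      gene_id = character(0), chrom = character(0), strand = character(0),
      bin = integer(0), region = character(0), lo = integer(0),
      hi = integer(0)
    ))
  }
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- abs(g$tes - g$tss) + 1L
    edges <- round(seq_len(n_bins) * len / n_bins)
    edges[n_bins] <- len
    e0 <- c(0L, edges[-n_bins])
    dir <- if (g$strand == "+") 1L else -1L
    coding <- tibble::tibble(
      bin = flank_bins + seq_len(n_bins), region = "coding",
      lo = pmin(g$tss + dir * e0, g$tss + dir * (edges - 1L)),
      hi = pmax(g$tss + dir * e0, g$tss + dir * (edges - 1L))
    )
    up <- tibble::tibble(
      bin = seq_len(flank_bins), region = "upstream",
      lo = pmin(
        g$tss - dir * (fw * (flank_bins - seq_len(flank_bins) + 1L)),
        g$tss - dir * (fw * (flank_bins - seq_len(flank_bins)) + 1L)
      ),
      hi = pmax(
        g$tss - dir * (fw * (flank_bins - seq_len(flank_bins) + 1L)),
        g$tss - dir * (fw * (flank_bins - seq_len(flank_bins)) + 1L)
      )
    )
    down <- tibble::tibble(
      bin = flank_bins + n_bins + seq_len(flank_bins), region = "downstream",
      lo = pmin(
        g$tes + dir * (fw * (seq_len(flank_bins) - 1L) + 1L),
        g$tes + dir * (fw * seq_len(flank_bins))
      ),
      hi = pmax(
        g$tes + dir * (fw * (seq_len(flank_bins) - 1L) + 1L),
        g$tes + dir * (fw * seq_len(flank_bins))
      )
    )
    dplyr::bind_rows(up, coding, down) |>
      dplyr::mutate(
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        .before = 1
      )
  }) |>
    dplyr::arrange(.data$gene_id, .data$bin)
}

#' Gel-anchored TS/NTS repair fractions in gene-body bins and flanks
#'
#' For each profile bin, counts at both timepoints are summed across all
#' genes separately for the TS and NTS (aggregation before division), then
#' converted to a normalized fraction of CPDs remaining with the gel anchor.
#'
#' @param track_0,track_t Lesion tracks at time 0 and the repair timepoint.
#' @param genes Gene annotation tibble (see [gene_bins()]).
#' @param normalizer A [gel_anchor()] object.
#' @inheritParams gene_bins
#' @return A `binned_profile` tibble: `bin`, `region`, `frame` (TS/NTS),
#'   `n0`, `nt`, `fraction`.
#' @export
bin_genes <- function(track_0, track_t, genes, normalizer,
                      n_bins = 6, flank_bins = 3, flank_width = 167) {
  bins <- gene_bins(genes, n_bins, flank_bins, flank_width)
  both <- tidyr::expand_grid(frame = c("TS", "NTS"), bins) |>
    dplyr::mutate(strand = frame_strand(.data$strand, .data$frame))
  both$n0 <- range_sums(track_0, both)
  both$nt <- range_sums(track_t, both)
  out <- both |>
    dplyr::group_by(.data$bin, .data$region, .data$frame) |>
    dplyr::summarise(
      n0 = sum(.data$n0), nt = sum(.data$nt), .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = normalized_fraction(normalizer, .data$n0, .data$nt)
    ) |>
    dplyr::arrange(.data$bin, dplyr::desc(.data$frame))
  structure(out,
    n_genes = length(unique(bins$gene_id)),
    class = c("binned_profile", class(out))
  )
}

#' Per-bin log2 strand asymmetry of unrepaired CPDs
#'
#' `log2(f_TS / f_NTS)` per bin; positive values mean more unrepaired damage
#' on (slower repair of) the transcribed strand. Bins where either strand
#' fraction is zero or undefined are reported as missing.
#'
#' @param profile A `binned_profile` from [bin_genes()].
#' @return Tibble with `bin`, `region`, `log2_ts_nts`.
#' @export
log2_asymmetry <- function(profile) {
  profile |>
    tibble::as_tibble() |>
    dplyr::select("bin", "region", "frame", "fraction") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "fraction") |>
    dplyr::mutate(log2_ts_nts = ifelse(
      is.na(.data$TS) | is.na(.data$NTS) | .data$TS <= 0 | .data$NTS <= 0,
      NA_real_, log2(.data$TS / .data$NTS)
    )) |>
    dplyr::select("bin", "region", "log2_ts_nts")
}

#' Paired t-test over the coding-bin strand difference
#'
#' Two-sided paired t-test of the TS vs NTS fraction remaining across the
#' coding bins (the gene-body repair asymmetry test). With all differences
#' zero the p-value is 1; a constant nonzero difference (zero variance) is
#' degenerate and reported as below machine epsilon with a flag.
#'
#' @param profile A `binned_profile` from [bin_genes()].
#' @return One-row tibble: `estimate` (mean TS - NTS), `statistic`, `df`,
#'   `p.value`, `degenerate`.
#' @export
paired_bin_test <- function(profile) {
  wide <- profile |>
    tibble::as_tibble() |>
    dplyr::filter(.data$region == "coding") |>
    dplyr::select("bin", "frame", "fraction") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "fraction")
  d <- wide$TS - wide$NTS
  if (all(d == 0)) {
    return(tibble::tibble(
      estimate = 0, statistic = 0, df = length(d) - 1, p.value = 1,
      degenerate = TRUE
    ))
  }
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      estimate = mean(d), statistic = sign(mean(d)) * Inf,
      df = length(d) - 1, p.value = .Machine$double.eps, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(wide$TS, wide$NTS, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p.value = tt$p.value, degenerate = FALSE
  )
}

#' TSS-aligned single-nucleotide repair metaprofile
#'
#' For each offset relative to the TSS (minus-strand genes mirrored so that
#' positive offsets run into the gene), counts are summed across genes per
#' strand frame (TS/NTS) and converted to normalized fractions remaining.
#' Offsets running past a chromosome end simply contribute no counts for
#' that gene.
#'
#' @inheritParams bin_genes
#' @param window Integer c(upstream, downstream) offsets, e.g. c(-500, 640).
#' @return A `meta_profile` tibble: `offset`, `frame`, `n0`, `nt`,
#'   `fraction`.
#' @export
tss_metaprofile <- function(track_0, track_t, genes, normalizer,
                            window = c(-500, 640)) {
  assert_cols(genes, c("chrom", "tss", "strand"), "`genes`")
  offsets <- seq.int(window[1], window[2])
  grid <- tidyr::expand_grid(
    genes[, c("chrom", "tss", "strand")], offset = offsets,
    frame = c("TS", "NTS")
  ) |>
    dplyr::mutate(
      pos = ifelse(.data$strand == "+", .data$tss + .data$offset,
        .data$tss - .data$offset
      ),
      gstrand = frame_strand(.data$strand, .data$frame)
    )
  lut0 <- track_0[, c("chrom", "pos", "strand", "count")]
  lutt <- track_t[, c("chrom", "pos", "strand", "count")]
  grid <- grid |>
    dplyr::left_join(lut0,
      by = c("chrom", "pos", gstrand = "strand")
    ) |>
    dplyr::rename(n0 = "count") |>
    dplyr::left_join(lutt,
      by = c("chrom", "pos", gstrand = "strand")
    ) |>
    dplyr::rename(nt = "count")
  out <- grid |>
    dplyr::group_by(.data$offset, .data$frame) |>
    dplyr::summarise(
      n0 = sum(.data$n0, na.rm = TRUE), nt = sum(.data$nt, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = normalized_fraction(normalizer, .data$n0, .data$nt)
    )
  structure(out,
    n_genes = nrow(genes),
    class = c("meta_profile", class(out))
  )
}

#' Per-gene repair matrix around the TSS, sorted by transcription rate
#'
#' One row per gene (sorted stably by descending transcription rate), one
#' column per TSS-relative offset, holding the normalized fraction of CPDs
#' remaining with both strands pooled (or a single strand frame). Suitable
#' for writing as TSV input to heatmap tools.
#'
#' @inheritParams tss_metaprofile
#' @param frame `"both"` (pool strands), `"TS"` or `"NTS"`.
#' @return Long tibble: `gene_id`, `rate`, `offset`, `n0`, `nt`, `fraction`,
#'   with `gene_id` an ordered factor (descending rate).
#' @export
gene_cluster_matrix <- function(track_0, track_t, genes, normalizer,
                                window = c(-500, 640), frame = "both") {
  assert_cols(genes, c("chrom", "tss", "strand", "rate"), "`genes`")
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  }
  genes <- genes[order(-genes$rate), ] # stable: order() preserves ties
  offsets <- seq.int(window[1], window[2])
  grid <- tidyr::expand_grid(
    genes[, c("gene_id", "chrom", "tss", "strand", "rate")],
    offset = offsets
  ) |>
    dplyr::mutate(
      pos = ifelse(.data$strand == "+", .data$tss + .data$offset,
        .data$tss - .data$offset
      )
    )
  pool <- function(track) {
    tr <- track[, c("chrom", "pos", "strand", "count")]
    if (frame == "both") {
      tr |>
        dplyr::group_by(.data$chrom, .data$pos) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop")
    } else {
      tibble::tibble(
        chrom = tr$chrom, pos = tr$pos, gstrand = tr$strand,
        count = tr$count
      )
    }
  }
  if (frame == "both") {
    grid <- grid |>
      dplyr::left_join(pool(track_0), by = c("chrom", "pos")) |>
      dplyr::rename(n0 = "count") |>
      dplyr::left_join(pool(track_t), by = c("chrom", "pos")) |>
      dplyr::rename(nt = "count")
  } else {
    grid$gstrand <- frame_strand(grid$strand, frame)
    grid <- grid |>
      dplyr::left_join(pool(track_0), by = c("chrom", "pos", "gstrand")) |>
      dplyr::rename(n0 = "count") |>
      dplyr::left_join(pool(track_t), by = c("chrom", "pos", "gstrand")) |>
      dplyr::rename(nt = "count")
  }
  grid |>
    dplyr::mutate(
      n0 = dplyr::coalesce(.data$n0, 0L), nt = dplyr::coalesce(.data$nt, 0L),
      fraction = normalized_fraction(normalizer, .data$n0, .data$nt),
      gene_id = factor(.data$gene_id, levels = unique(genes$gene_id))
    ) |>
    dplyr::select(
      "gene_id", "rate", "offset", "n0", "nt", "fraction"
    )
}
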