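#' Load transcription-factor binding sites with telomere filtering
#'
#' Applies optional per-TF midpoint offsets (small shifts that center the
#' conserved motif positions, configured per TF and applied exactly once)
#' and removes every site within `telomere_exclusion_bp` of either end of
#' its chromosome.
#'
#' @param tfbs Tibble with `tf`, `chrom`, `midpoint` (1-based), `strand` and
#'   optionally `occupancy`.
#' @param genome Genome (or named integer vector of chromosome lengths).
#' @param telomere_exclusion_bp Sites with distance to the nearest
#'   chromosome end `<=` this value are excluded.
#' @param offsets Optional tibble with `tf`, `offset` (bp added to the
#'   midpoints of that TF; unlisted TFs default to 0).
#' @return Filtered tibble with `dist_to_end` appended.
#' @export
load_tfbs <- function(tfbs, genome, telomere_exclusion_bp = 1000,
                      offsets = NULL) {
  assert_cols(tfbs, c("tf", "chrom", "midpoint", "strand"), "`tfbs`")
  lens <- if (is.character(genome)) chrom_lengths(genome) else genome
  unknown <- setdiff(unique(tfbs$chrom), names(lens))
  if (length(unknown)) {
    rlang::abort(sprintf(
      "TFBS on unknown chromosome(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  if (!is.null(offsets)) {
    assert_cols(offsets, c("tf", "offset"), "`offsets`")
    tfbs <- tfbs |>
      dplyr::left_join(offsets, by = "tf") |>
      dplyr::mutate(
        midpoint = .data$midpoint + dplyr::coalesce(.data$offset, 0L)
      ) |>
      dplyr::select(-"offset")
  }
  tfbs |>
    dplyr::mutate(
      dist_to_end = pmin(
        .data$midpoint, lens[.data$chrom] - .data$midpoint + 1L
      )
    ) |>
    dplyr::filter(.data$dist_to_end > telomere_exclusion_bp)
}

#' Core-vs-flank repair statistic for one transcription factor
#'
#' Sums counts over both strands across all sites of the TF in the core
#' window (motif midpoint +/- `core_halfwidth`) and the flanking window
#' (+/- `flank_halfwidth`, excluding the core), computes gel-anchored
#' fractions remaining by aggregation-then-ratio, and reports
#' `delta = f_core - f_flank` (positive = repair inhibited in the bound
#' core). TFs with fewer than `min_core_cpds` core counts at either
#' timepoint are flagged `excluded`.
#'
#' @param track_0,track_t Lesion tracks.
#' @param sites TFBS tibble for one TF (see [load_tfbs()]).
#' @param normalizer A [gel_anchor()] object.
#' @param core_halfwidth,flank_halfwidth Window half-widths (bp).
#' @param min_core_cpds Minimum core counts required at both timepoints.
#' @return One-row tibble: `tf`, `n_sites`, `n0_core`, `nt_core`, `f_core`,
#'   `f_flank`, `delta`, `excluded`.
#' @export
tf_core_flank <- function(track_0, track_t, sites, normalizer,
                          core_halfwidth = 4, flank_halfwidth = 100,
                          min_core_cpds = 100) {
  core <- tibble::tibble(
    chrom = sites$chrom, lo = sites$midpoint - core_halfwidth,
    hi = sites$midpoint + core_halfwidth, strand = NA_character_
  )
  flank <- dplyr::bind_rows(
    tibble::tibble(
      chrom = sites$chrom, lo = sites$midpoint - flank_halfwidth,
      hi = sites$midpoint - core_halfwidth - 1L, strand = NA_character_
    ),
    tibble::tibble(
      chrom = sites$chrom, lo = sites$midpoint + core_halfwidth + 1L,
      hi = sites$midpoint + flank_halfwidth, strand = NA_character_
    )
  )
  n0_core <- sum(range_sums(track_0, core))
  nt_core <- sum(range_sums(track_t, core))
  n0_flank <- sum(range_sums(track_0, flank))
  nt_flank <- sum(range_sums(track_t, flank))
  f_core <- normalized_fraction(normalizer, n0_core, nt_core)
  f_flank <- normalized_fraction(normalizer, n0_flank, nt_flank)
  tibble::tibble(
    tf = sites$tf[1] %||% NA_character_,
    n_sites = nrow(sites),
    n0_core = n0_core, nt_core = nt_core,
    f_core = f_core, f_flank = f_flank,
    delta = f_core - f_flank,
    excluded = n0_core < min_core_cpds | nt_core < min_core_cpds
  )
}

#' Core-vs-flank scatter table across all TFs
#'
#' Maps [tf_core_flank()] over the TFs present in `sites` and returns one
#' row per TF, ordered by TF name so reruns on identical inputs are
#' byte-identical.
#'
#' @inheritParams tf_core_flank
#' @return A `tf_scatter` tibble, one row per TF.
#' @export
tf_scatter <- function(track_0, track_t, sites, normalizer,
                       core_halfwidth = 4, flank_halfwidth = 100,
                       min_core_cpds = 100) {
  out <- sites |>
    dplyr::group_by(.data$tf) |>
    dplyr::group_map(~ tf_core_flank(
      track_0, track_t, dplyr::mutate(.x, tf = .y$tf), normalizer,
      core_halfwidth, flank_halfwidth, min_core_cpds
    )) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$tf)
  structure(
    out,
    genome_fraction = normalizer$f_gel,
    class = c("tf_scatter", class(out))
  )
}

#' Per-position repair profile around TFBS midpoints
#'
#' Offsets are oriented by motif strand (minus-strand motifs mirrored);
#' counts from both genomic strands are pooled at each position and
#' aggregated across sites, then converted to gel-anchored fractions.
#' Offsets with fewer than `min_cpds` counts at either timepoint are masked
#' (fraction set to `NA`).
#'
#' @inheritParams tf_core_flank
#' @param half_window Profile half-width in bp.
#' @param min_cpds Mask threshold on the aggregated counts.
#' @return A `tfbs_profile` tibble: `offset`, `n0`, `nt`, `fraction`,
#'   `masked`.
#' @export
tf_site_profile <- function(track_0, track_t, sites, normalizer,
                            half_window = 500, min_cpds = 10) {
  offsets <- seq.int(-half_window, half_window)
  grid <- tidyr::expand_grid(
    sites[, c("chrom", "midpoint", "strand")], offset = offsets
  ) |>
    dplyr::mutate(pos = ifelse(.data$strand == "+",
      .data$midpoint + .data$offset, .data$midpoint - .data$offset
    ))
  pool <- function(track) {
    track |>
      tibble::as_tibble() |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  grid <- grid |>
    dplyr::left_join(pool(track_0), by = c("chrom", "pos")) |>
    dplyr::rename(n0 = "count") |>
    dplyr::left_join(pool(track_t), by = c("chrom", "pos")) |>
    dplyr::rename(nt = "count")
  out <- grid |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      n0 = sum(.data$n0, na.rm = TRUE), nt = sum(.data$nt, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      masked = .data$n0 < min_cpds | .data$nt < min_cpds,
      fraction = ifelse(.data$masked, NA_real_,
        normalized_fraction(normalizer, .data$n0, .data$nt)
      )
    )
  structure(out,
    n_sites = nrow(sites),
    class = c("tfbs_profile", class(out))
  )
}

#' Split binding sites into bound vs low-occupancy control sets
#'
#' Sites with occupancy strictly below `threshold` are low-occupancy
#' controls (unbound motif matches); the rest are bound. Sites missing an
#' occupancy value are dropped from the split.
#'
#' @param sites TFBS tibble with an `occupancy` column.
#' @param threshold Strict upper bound for the control set.
#' @return `sites` with an added `cohort` column (`"bound"` / `"control"`).
#' @export
occupancy_split <- function(sites, threshold = 10) {
  assert_cols(sites, "occupancy", "`sites`")
  sites |>
    dplyr::filter(!is.na(.data$occupancy)) |>
    dplyr::mutate(cohort = ifelse(
      .data$occupancy < threshold, "control", "bound"
    ))
}
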