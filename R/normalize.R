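#' Anchor CPD-seq repair fractions to the gel-measured bulk fraction
#'
#' CPD-seq read counts are relative (library depth differs between
#' timepoints), so the per-site ratio of depth-normalized counts,
#' `r_i = (n_i(t)/N_t) / (n_i(0)/N_0)`, has genome-wide mean 1 by
#' construction and carries no absolute repair scale. The alkaline gel assay
#' supplies that scale: the genome-wide fraction of CPDs remaining
#' `F_gel(t)`. The normalized fraction remaining at any site or region is
#' `f = F_gel(t) * r`, so the genome-wide normalized fraction equals
#' `F_gel(t)` exactly.
#'
#' @param track_0 Lesion track at time 0.
#' @param track_t Lesion track at the repair timepoint.
#' @param f_gel Gel-measured genome-wide fraction of CPDs remaining at the
#'   same timepoint (in `[0, 1]`).
#' @return A `cpd_normalizer` with the anchoring factor and library totals.
#' @export
gel_anchor <- function(track_0, track_t, f_gel) {
  n0 <- track_total(track_0)
  nt <- track_total(track_t)
  if (n0 <= 0 || nt <= 0) {
    rlang::abort("both tracks must contain retained reads (N > 0)")
  }
  if (f_gel < 0 || f_gel > 1) {
    rlang::abort("`f_gel` must be in [0, 1]")
  }
  structure(
    list(
      f_gel = f_gel, n0_total = n0, nt_total = nt,
      timepoint = (attr(track_t, "meta") %||% list())$timepoint
    ),
    class = "cpd_normalizer"
  )
}

#' @export
print.cpd_normalizer <- function(x, ...) {
  cat(sprintf(
    "<cpd_normalizer> F_gel = %.4g (N0 = %s, Nt = %s)\n",
    x$f_gel, format(x$n0_total, big.mark = ","),
    format(x$nt_total, big.mark = ",")
  ))
  invisible(x)
}

#' Normalized fraction of CPDs remaining for aggregated counts
#'
#' Regions aggregate counts before dividing (sum of counts at t over sum at
#' 0, depth-normalized, times the gel anchor), which is robust to zero-count
#' sites. Sites or regions with `n0 = 0` are undefined and return `NA`.
#'
#' @param normalizer A [gel_anchor()] object.
#' @param n0,nt Summed counts at time 0 and time t (vectorized).
#' @return Normalized fraction(s) remaining.
#' @export
normalized_fraction <- function(normalizer, n0, nt) {
  stopifnot(inherits(normalizer, "cpd_normalizer"))
  out <- normalizer$f_gel * (nt / normalizer$nt_total) /
    (n0 / normalizer$n0_total)
  out[n0 == 0] <- NA_real_
  out
}

#' Per-site normalized repair fractions
#'
#' @inheritParams gel_anchor
#' @param normalizer A [gel_anchor()] object for the same track pair.
#' @return Tibble of sites with `n0 > 0`: `chrom`, `pos`, `strand`, `n0`,
#'   `nt`, `fraction`.
#' @export
site_fractions <- function(track_0, track_t, normalizer) {
  stopifnot(nrow(track_0) == nrow(track_t))
  out <- tibble::tibble(
    chrom = track_0$chrom, pos = track_0$pos, strand = track_0$strand,
    n0 = track_0$count, nt = track_t$count
  ) |>
    dplyr::filter(.data$n0 > 0)
  out$fraction <- normalized_fraction(normalizer, out$n0, out$nt)
  out
}

#' Normalized fraction remaining over arbitrary regions
#'
#' @inheritParams site_fractions
#' @param regions Tibble with `chrom`, `lo`, `hi` and optional `strand`
#'   (`NA` or absent pools both strands).
#' @return `regions` with `n0`, `nt` and `fraction` columns appended.
#' @export
region_fractions <- function(track_0, track_t, regions, normalizer) {
  if (!"strand" %in% names(regions)) regions$strand <- NA_character_
  regions$n0 <- range_sums(track_0, regions)
  regions$nt <- range_sums(track_t, regions)
  regions$fraction <- normalized_fraction(normalizer, regions$n0, regions$nt)
  regions
}
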