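#' Lesion-count tracks
#'
#' A lesion track is a tibble with one row per genomic dipyrimidine on each
#' strand (`chrom`, `pos`, `strand`, `dinuc`, `count`), zero-filled so that
#' undamaged sites are explicit. `pos` is the 1-based plus-strand coordinate
#' of the 5'-most base of the 2-bp span. Metadata (library id, timepoint,
#' strain, total retained reads) is carried in attributes.
#'
#' @param sites Tibble of dipyrimidine sites with a `count` column.
#' @param meta Named list of metadata (library, timepoint, strain, ...).
#' @return A `lesion_track` tibble.
#' @export
new_lesion_track <- function(sites, meta = list()) {
  assert_cols(sites, c("chrom", "pos", "strand", "dinuc", "count"), "track")
  if (any(sites$count < 0)) {
    rlang::abort("lesion counts must be non-negative")
  }
  structure(
    tibble::as_tibble(sites),
    meta = meta,
    n_reads = sum(sites$count),
    class = c("lesion_track", class(tibble::tibble()))
  )
}

#' Total lesion (retained read) count of a track
#' @param track A lesion track tibble.
#' @return Numeric total of `count`.
#' @export
track_total <- function(track) sum(track$count)

#' @export
print.lesion_track <- function(x, ...) {
  meta <- attr(x, "meta") %||% list()
  cat(sprintf(
    "<lesion_track> %d dipyrimidine sites, N = %s%s\n",
    nrow(x), format(track_total(x), big.mark = ","),
    if (length(meta)) {
      paste0(" (", paste(names(meta), unlist(meta),
        sep = "=", collapse = ", "
      ), ")")
    } else ""
  ))
  NextMethod()
}

#' Simulate UV damage induction
#'
#' Draws independent Poisson lesion counts at every dipyrimidine site, with
#' mean `dose_scale` times a dinucleotide-specific propensity. CPDs form only
#' at dipyrimidines, so all other positions are structurally zero. The
#' propensity defaults are free parameters of the simulator: TT sites are
#' made the most photoreactive and CC the least, in line with the usual
#' ordering of CPD yields.
#'
#' @param genome A genome (named character vector).
#' @param dose_scale Expected lesions per unit propensity (dose surrogate).
#' @param dinuc_propensity Named non-negative weights for TT/TC/CT/CC.
#' @param seed Integer seed.
#' @return A `lesion_track` at time 0.
#' @export
simulate_damage <- function(genome, dose_scale,
                            dinuc_propensity = c(
                              TT = 1, TC = 0.6, CT = 0.5, CC = 0.25
                            ),
                            seed = 1) {
  if (dose_scale < 0) rlang::abort("`dose_scale` must be >= 0")
  if (any(dinuc_propensity < 0)) {
    rlang::abort("`dinuc_propensity` must be non-negative")
  }
  miss <- setdiff(DIPYRIMIDINES, names(dinuc_propensity))
  if (length(miss)) {
    rlang::abort(paste0(
      "`dinuc_propensity` missing: ", paste(miss, collapse = ", ")
    ))
  }
  sites <- dipyrimidine_sites(genome)
  lam <- dose_scale * unname(dinuc_propensity[sites$dinuc])
  sites$count <- withr::with_seed(as.integer(seed), {
    stats::rpois(nrow(sites), lam)
  })
  new_lesion_track(sites, meta = list(timepoint = 0, library = "sim_t0"))
}
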