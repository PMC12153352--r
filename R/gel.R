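#' Simulate alkaline-gel lanes by Poisson cleavage
#'
#' T4 endonuclease V cleaves DNA at every CPD, so under random (Poisson)
#' damage a molecule of length L with lesion density phi (CPDs per kb)
#' receives a Poisson(phi * L / 1000) number of cuts at uniform positions,
#' and its fragments follow renewal-process statistics. Mock-treated lanes
#' are uncleaved. Fragment lengths are reported per lane, emulating what a
#' densitometry trace summarizes.
#'
#' @param true_density Tibble with `timepoint` and `density` (CPDs/kb), or a
#'   named numeric vector of densities by timepoint.
#' @param molecule_length Single-stranded molecule length (nt).
#' @param n_molecules Molecules per lane.
#' @param seed Integer seed.
#' @return Tibble of lanes: `lane`, `treatment` (`"t4"` / `"mock"`),
#'   `timepoint`, `fragment_length`.
#' @export
simulate_gel_lanes <- function(true_density, molecule_length = 50000,
                               n_molecules = 10000, seed = 1) {
  if (!is.data.frame(true_density)) {
    true_density <- tibble::tibble(
      timepoint = as.numeric(names(true_density)),
      density = as.numeric(true_density)
    )
  }
  assert_cols(true_density, c("timepoint", "density"), "`true_density`")
  if (any(true_density$density < 0)) {
    rlang::abort("`density` must be >= 0")
  }
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(nrow(true_density)), function(i) {
      tp <- true_density$timepoint[i]
      phi <- true_density$density[i]
      n_breaks <- stats::rpois(n_molecules, phi * molecule_length / 1000)
      frags <- unlist(lapply(which(n_breaks > 0), function(m) {
        cuts <- sort(stats::runif(n_breaks[m], 0, molecule_length))
        diff(c(0, cuts, molecule_length))
      }), use.names = FALSE)
      frags <- frags[frags > 0] # coincident cuts leave degenerate fragments
      frags <- c(frags, rep(molecule_length, sum(n_breaks == 0)))
      dplyr::bind_rows(
        tibble::tibble(
          lane = sprintf("t4_%g", tp), treatment = "t4", timepoint = tp,
          fragment_length = frags
        ),
        tibble::tibble(
          lane = sprintf("mock_%g", tp), treatment = "mock", timepoint = tp,
          fragment_length = rep(molecule_length, n_molecules)
        )
      )
    })
  })
}

#' Representative fragment length of a gel lane
#'
#' For simulated lanes carrying raw fragment lengths, returns the
#' number-average length (total nucleotides over total fragments), the
#' quantity whose reciprocal estimates breaks per nucleotide under Poisson
#' cleavage. For densitometry lanes, finds the migration distance at the
#' lane's median cumulative intensity and converts it to a length by
#' log-linear interpolation of the ladder calibration; migration outside the
#' ladder range is an error (no extrapolation).
#'
#' @param lane Tibble for one lane: either a `fragment_length` column, or
#'   `distance_mm` + `intensity` columns.
#' @param ladder Tibble with `distance_mm` and `length_nt` (>= 2 rows);
#'   required for densitometry lanes.
#' @return Length in nt (scalar).
#' @export
lane_fragment_length <- function(lane, ladder = NULL) {
  if ("fragment_length" %in% names(lane)) {
    if (any(lane$fragment_length <= 0)) {
      rlang::abort("fragment lengths must be positive")
    }
    return(mean(lane$fragment_length))
  }
  assert_cols(lane, c("distance_mm", "intensity"), "densitometry `lane`")
  if (is.null(ladder) || nrow(ladder) < 2) {
    rlang::abort("a `ladder` with at least 2 points is required")
  }
  o <- order(lane$distance_mm)
  d <- lane$distance_mm[o]
  w <- lane$intensity[o]
  cum <- cumsum(w) / sum(w)
  med <- d[which(cum >= 0.5)[1]]
  lo <- order(ladder$distance_mm)
  ld <- ladder$distance_mm[lo]
  ll <- log(ladder$length_nt[lo])
  if (med < min(ld) || med > max(ld)) {
    rlang::abort("median migration lies outside the ladder range")
  }
  exp(stats::approx(ld, ll, xout = med)$y)
}

#' Estimate CPDs per kb from T4-endoV and mock fragment lengths
#'
#' Under Poisson (random) cleavage the expected breaks per nucleotide equal
#' the reciprocal of the number-average fragment length, so the lesion
#' density is `phi = 1000 * (1/length_t4 - 1/length_mock)` CPDs per kb. The
#' mock term removes background fragmentation. Negative differences clamp to
#' zero with a warning.
#'
#' @param length_t4,length_mock Number-average fragment lengths (nt).
#' @return Lesion density phi in CPDs per kb.
#' @export
cpds_per_kb <- function(length_t4, length_mock) {
  if (any(length_t4 <= 0) || any(length_mock <= 0)) {
    rlang::abort("fragment lengths must be positive")
  }
  phi <- 1000 * (1 / length_t4 - 1 / length_mock)
  if (any(phi < 0)) {
    rlang::warn("T4 lane fragments longer than mock; density clamped to 0")
    phi <- pmax(phi, 0)
  }
  phi
}

#' Percent of CPDs repaired relative to the 0 h timepoint
#'
#' @param phi_t,phi_0 Lesion densities (CPDs/kb) at time t and time 0.
#' @return `100 * (1 - phi_t / phi_0)`. Negative values (apparent damage
#'   gain) are reported as-is with a warning.
#' @export
percent_repaired <- function(phi_t, phi_0) {
  if (any(phi_0 <= 0)) {
    rlang::abort("`phi_0` must be > 0 (no damage induced at time 0)")
  }
  r <- 100 * (1 - phi_t / phi_0)
  if (any(r < 0)) {
    rlang::warn("negative percent repaired (phi_t > phi_0); reported as-is")
  }
  r
}

#' Summarize gel lanes into a repair time course
#'
#' Computes, per timepoint, the T4/mock fragment lengths, the lesion density
#' phi, the percent repaired relative to the earliest (0) timepoint, and the
#' genome-wide fraction of CPDs remaining `F_gel = 1 - R/100` (clamped to
#' `[0, 1]`) used to anchor CPD-seq normalization.
#'
#' @param lanes Tibble as produced by [simulate_gel_lanes()] or read from a
#'   lane TSV (`lane`, `treatment`, `timepoint`, then `fragment_length` or
#'   `distance_mm`/`intensity` rows).
#' @param ladder Optional ladder calibration for densitometry lanes.
#' @return A `repair_summary` tibble: `timepoint`, `length_t4`,
#'   `length_mock`, `phi`, `pct_repaired`, `fraction_remaining`.
#' @export
gel_repair_summary <- function(lanes, ladder = NULL) {
  assert_cols(lanes, c("treatment", "timepoint"), "`lanes`")
  by_tp <- lanes |>
    dplyr::group_by(.data$timepoint, .data$treatment) |>
    dplyr::group_modify(~ tibble::tibble(
      len = lane_fragment_length(.x, ladder)
    )) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      names_from = "treatment", values_from = "len", names_prefix = "length_"
    )
  assert_cols(by_tp, c("length_t4", "length_mock"), "gel summary")
  out <- by_tp |>
    dplyr::arrange(.data$timepoint) |>
    dplyr::mutate(phi = cpds_per_kb(.data$length_t4, .data$length_mock))
  phi0 <- out$phi[out$timepoint == min(out$timepoint)][1]
  out <- out |>
    dplyr::mutate(
      pct_repaired = percent_repaired(.data$phi, phi0),
      fraction_remaining = pmin(pmax(1 - .data$pct_repaired / 100, 0), 1)
    )
  class(out) <- c("repair_summary", class(out))
  out
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorts raw p-values ascending and sets
#' `adj_i = max_(j <= i) 1 - (1 - p_j)^(m - j + 1)`, clipped to `[0, 1]`;
#' adjusted values are monotone in rank and never below the raw p.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)), 1)
  adj[order(o)]
}

#' Pairwise unpaired t-tests with Holm-Sidak correction
#'
#' Compares every pair of replicate groups (e.g. percent-repaired values per
#' strain/timepoint) with an unpaired two-sample t-test (pooled variance) and
#' adjusts the family of p-values with [holm_sidak()]. Degenerate pairs with
#' zero variance in both groups and equal means get p = 1.
#'
#' @param data Data frame of replicate measurements.
#' @param value,group Column names (strings) of the measurement and group.
#' @return Tibble with `group1`, `group2`, `estimate` (mean difference),
#'   `p.value` (raw) and `p.adj`.
#' @export
replicate_test <- function(data, value = "value", group = "group") {
  assert_cols(data, c(value, group), "`data`")
  g <- split(data[[value]], data[[group]])
  if (any(lengths(g) < 2)) {
    rlang::abort("each group needs at least 2 replicates")
  }
  pairs <- utils::combn(names(g), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    x <- g[[pr[1]]]
    y <- g[[pr[2]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    }
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      estimate = mean(x) - mean(y), p.value = p
    )
  })
  res$p.adj <- holm_sidak(res$p.value)
  res
}
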