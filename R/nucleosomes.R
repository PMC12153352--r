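#' Keep strongly positioned nucleosomes
#'
#' Filters a dyad table to nucleosomes with positioning score strictly
#' greater than `min_score` (the strongly-positioned subset used for
#' dyad-aligned repair analysis).
#'
#' @param dyads Tibble with `chrom`, `pos`, `score`.
#' @param min_score Strict lower bound on the score.
#' @return Filtered tibble; empty result is an error.
#' @export
filter_dyads <- function(dyads, min_score = 5) {
  assert_cols(dyads, c("chrom", "pos", "score"), "`dyads`")
  out <- dyads[dyads$score > min_score, ]
  if (nrow(out) == 0) {
    rlang::abort("no dyads pass the score filter")
  }
  out
}

#' Dyad-aligned repair profile per strand
#'
#' For every offset relative to the nucleosome dyad (position 0), counts are
#' summed over all dyads per genomic strand and converted either to a
#' gel-anchored fraction of CPDs remaining (`mode = "fraction"`) or reported
#' as raw sums (`mode = "count"`, for accessibility data such as DNase-seq
#' cleavage, which needs no 0-min reference). Offsets are measured in
#' plus-strand coordinates relative to the dyad; the 5'->3' re-orientation
#' of the minus strand is a separate step ([align_strands()]). Dyads whose
#' window runs off a chromosome simply contribute nothing at those offsets.
#'
#' @param track_0 Lesion (or cleavage) track at time 0.
#' @param track_t Track at the repair timepoint (ignored in count mode).
#' @param dyads Dyad tibble, already filtered (see [filter_dyads()]).
#' @param normalizer A [gel_anchor()] object (fraction mode only).
#' @param mode `"fraction"` or `"count"`.
#' @param half_window Half-window in bp (profile covers -half..+half).
#' @return A `dyad_profile` tibble: `offset`, `strand`, `n0`, `nt`, `value`;
#'   attributes record mode, alignment state and dyad count.
#' @export
dyad_profile <- function(track_0, track_t = NULL, dyads, normalizer = NULL,
                         mode = c("fraction", "count"), half_window = 90) {
  mode <- match.arg(mode)
  if (mode == "fraction" &&
    (is.null(track_t) || is.null(normalizer))) {
    rlang::abort("fraction mode needs `track_t` and `normalizer`")
  }
  offsets <- seq.int(-half_window, half_window)
  grid <- tidyr::expand_grid(
    dyads[, c("chrom", "pos")], offset = offsets,
    gstrand = c("+", "-")
  ) |>
    dplyr::mutate(gpos = .data$pos + .data$offset)
  join_counts <- function(grid, track, col) {
    lut <- tibble::tibble(
      chrom = track$chrom, gpos = track$pos, gstrand = track$strand,
      count = track$count
    )
    grid |>
      dplyr::left_join(lut, by = c("chrom", "gpos", "gstrand")) |>
      dplyr::mutate(!!col := dplyr::coalesce(.data$count, 0L)) |>
      dplyr::select(-"count")
  }
  grid <- join_counts(grid, track_0, "n0")
  grid <- if (is.null(track_t)) {
    dplyr::mutate(grid, nt = NA_integer_)
  } else {
    join_counts(grid, track_t, "nt")
  }
  out <- grid |>
    dplyr::group_by(offset = .data$offset, strand = .data$gstrand) |>
    dplyr::summarise(
      n0 = sum(.data$n0), nt = sum(.data$nt), .groups = "drop"
    )
  out$value <- if (mode == "fraction") {
    normalized_fraction(normalizer, out$n0, out$nt)
  } else {
    as.numeric(out$n0)
  }
  structure(out,
    mode = mode, alignment = "genomic", n_dyads = nrow(dyads),
    half_window = half_window,
    class = c("dyad_profile", class(out))
  )
}

#' Orient both strands of a dyad profile 5' to 3'
#'
#' Re-indexes the minus strand by `offset -> -offset` so both strands read
#' 5'->3' left to right; the plus strand is unchanged. Applying the
#' operation twice restores the original profile.
#'
#' @param profile A `dyad_profile`.
#' @return The profile with alignment state toggled.
#' @export
align_strands <- function(profile) {
  at <- attributes(profile)
  out <- profile |>
    tibble::as_tibble() |>
    dplyr::mutate(offset = ifelse(
      .data$strand == "-", -.data$offset, .data$offset
    )) |>
    dplyr::arrange(.data$strand, .data$offset)
  structure(out,
    mode = at$mode,
    alignment = if (identical(at$alignment, "aligned")) {
      "genomic"
    } else {
      "aligned"
    },
    n_dyads = at$n_dyads, half_window = at$half_window,
    class = c("dyad_profile", class(out))
  )
}

#' Combine the two 5'->3'-aligned strands of a dyad profile
#'
#' Per-offset unweighted mean of the two aligned strand values (counts are
#' summed for reference).
#'
#' @param profile An aligned `dyad_profile` (see [align_strands()]).
#' @return A combined `dyad_profile` with `strand = "combined"`.
#' @export
combine_strands <- function(profile) {
  at <- attributes(profile)
  if (!identical(at$alignment, "aligned")) {
    rlang::abort("combine_strands() needs a 5'->3'-aligned profile")
  }
  out <- profile |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      n0 = sum(.data$n0), nt = sum(.data$nt),
      value = mean(.data$value), .groups = "drop"
    ) |>
    dplyr::mutate(strand = "combined", .after = "offset")
  structure(out,
    mode = at$mode, alignment = "combined", n_dyads = at$n_dyads,
    half_window = at$half_window,
    class = c("dyad_profile", class(out))
  )
}

#' Fit the rotational-setting periodicity of a dyad profile
#'
#' Least-squares fit of `value ~ a + c1*offset + c2*offset^2 +
#' b*cos(2*pi*(offset - phase)/period)` over the nucleosome core
#' (|offset| <= `core_halfwidth`); the quadratic terms absorb the smooth
#' translational trend so the cosine captures the helical periodicity. The
#' phase convention is the offset (bp, wrapped to one period around 0) of
#' the fitted cosine maximum.
#'
#' Offsets within `label_halfwidth` bp of the fitted minima of fraction
#' remaining are labelled `minor_out` (the outward-facing minor groove is
#' repaired fastest, so it holds the least residual damage); offsets near
#' the maxima are `minor_in`; the rest `intermediate`. For a count-mode
#' accessibility profile the assignment inverts: cleavage maxima are
#' minor-out. If the fitted amplitude is not distinguishable from zero
#' (|b| < 2 standard errors) the labels are withheld and the phase flagged
#' unreliable.
#'
#' @param profile A combined (or single-strand) `dyad_profile`.
#' @param period Helical period in bp.
#' @param core_halfwidth Core particle half-width (bp).
#' @param label_halfwidth Labelling tolerance around extrema (bp).
#' @param detrend Include the quadratic trend terms (default TRUE).
#' @return A `rotational_fit` list: `phase` (cosine maximum, bp),
#'   `phase_minimum`, `amplitude`, `amplitude_se`, `reliable`, `period`,
#'   `mode`, `labels` tibble and the underlying `lm` fit.
#' @export
rotational_settings <- function(profile, period = 10.3, core_halfwidth = 73,
                                label_halfwidth = 2, detrend = TRUE) {
  mode <- attr(profile, "mode") %||% "fraction"
  d <- profile |>
    tibble::as_tibble() |>
    dplyr::filter(
      abs(.data$offset) <= core_halfwidth, !is.na(.data$value)
    )
  w <- 2 * pi / period
  X <- data.frame(
    value = d$value, o = d$offset,
    c1 = cos(w * d$offset), s1 = sin(w * d$offset)
  )
  fml <- if (detrend) {
    value ~ o + I(o^2) + c1 + s1
  } else {
    value ~ c1 + s1
  }
  fit <- stats::lm(fml, data = X)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  b1 <- cf[["c1"]]
  b2 <- cf[["s1"]]
  amp <- sqrt(b1^2 + b2^2)
  amp_se <- if (amp > 0) {
    sqrt(
      (b1^2 * V["c1", "c1"] + 2 * b1 * b2 * V["c1", "s1"] +
        b2^2 * V["s1", "s1"]) / amp^2
    )
  } else {
    sqrt(max(V["c1", "c1"], V["s1", "s1"]))
  }
  reliable <- amp >= 2 * amp_se
  phase <- wrap_phase(atan2(b2, b1) / w, period)
  phase_min <- wrap_phase(phase + period / 2, period)

  labels <- d |>
    dplyr::select("offset", "value") |>
    dplyr::mutate(label = if (!reliable) {
      NA_character_
    } else {
      dist_max <- circular_dist(.data$offset, phase, period)
      dist_min <- circular_dist(.data$offset, phase_min, period)
      # Profile maxima hold the most signal: residual damage (fraction mode,
      # minor-in) or cleavage (count mode, minor-out).
      at_max <- dist_max <= label_halfwidth
      at_min <- dist_min <= label_halfwidth
      if (mode == "count") {
        dplyr::case_when(
          at_max ~ "minor_out", at_min ~ "minor_in",
          TRUE ~ "intermediate"
        )
      } else {
        dplyr::case_when(
          at_max ~ "minor_in", at_min ~ "minor_out",
          TRUE ~ "intermediate"
        )
      }
    })

  structure(
    list(
      phase = phase, phase_minimum = phase_min, amplitude = amp,
      amplitude_se = amp_se, reliable = reliable, period = period,
      mode = mode, labels = labels, fit = fit
    ),
    class = "rotational_fit"
  )
}

#' @export
print.rotational_fit <- function(x, ...) {
  cat(sprintf(
    "<rotational_fit> period %.1f bp; phase (max) %.2f bp; amplitude %.4g (se %.2g)%s\n",
    x$period, x$phase, x$amplitude, x$amplitude_se,
    if (x$reliable) "" else " [unreliable]"
  ))
  invisible(x)
}

#' 5' vs 3' asymmetry of an aligned dyad profile
#'
#' Mean value over offsets `+window[1]..+window[2]` minus the mean over the
#' mirrored negative offsets. For a fraction-remaining profile a positive
#' index means more residual damage on (slower repair of) the 3' side of the
#' nucleosomal DNA. The standard error propagates the per-offset binomial
#' counting error of the two timepoints.
#'
#' @param profile An aligned or combined `dyad_profile`.
#' @param window Offset range c(near, far) on the 3' side, default 10..50.
#' @return One-row tibble: `index`, `se`, `z`.
#' @export
asymmetry_index <- function(profile, window = c(10, 50)) {
  d <- tibble::as_tibble(profile)
  if (identical(attr(profile, "alignment"), "genomic")) {
    rlang::abort("asymmetry_index() needs an aligned or combined profile")
  }
  pick <- function(sgn) {
    d[d$offset %in% (sgn * seq.int(window[1], window[2])), ]
  }
  up <- pick(1)
  down <- pick(-1)
  var_of <- function(x) {
    v <- x$value^2 * (1 / pmax(x$nt, 1) + 1 / pmax(x$n0, 1))
    sum(v, na.rm = TRUE) / nrow(x)^2
  }
  index <- mean(up$value, na.rm = TRUE) - mean(down$value, na.rm = TRUE)
  se <- sqrt(var_of(up) + var_of(down))
  tibble::tibble(index = index, se = se, z = index / se)
}
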