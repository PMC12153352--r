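#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rotational-setting fit
#'
#' @param x A `rotational_fit` from [rotational_settings()].
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted quantity (phase, amplitude);
#'   `glance()` returns a one-row model summary.
#' @exportS3Method generics::tidy
tidy.rotational_fit <- function(x, ...) {
  tibble::tibble(
    term = c("phase_max", "phase_min", "amplitude"),
    estimate = c(x$phase, x$phase_minimum, x$amplitude),
    std.error = c(NA_real_, NA_real_, x$amplitude_se)
  )
}

#' @rdname tidy.rotational_fit
#' @exportS3Method generics::glance
glance.rotational_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    period = x$period, phase = x$phase, amplitude = x$amplitude,
    amplitude_se = x$amplitude_se, reliable = x$reliable,
    r.squared = s$r.squared, nobs = length(s$residuals)
  )
}
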