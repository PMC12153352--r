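#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for result objects
#'
#' `autoplot()` methods give quick diagnostic figures for each result type:
#' TS/NTS fractions per gene bin, TSS metaprofiles, dyad-aligned profiles
#' with rotational labels, TF core-vs-flank scatters, and trinucleotide
#' spectra.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cpdrepair-plots
NULL

#' @rdname cpdrepair-plots
#' @exportS3Method ggplot2::autoplot
autoplot.binned_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$bin <- factor(d$bin)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$bin, y = .data$fraction, fill = .data$frame
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(~ factor(.data$region,
      levels = c("upstream", "coding", "downstream")
    ), scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "bin (TSS → TES)", y = "fraction of CPDs remaining",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname cpdrepair-plots
#' @exportS3Method ggplot2::autoplot
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$offset, y = .data$fraction, colour = .data$frame
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "position relative to TSS (bp)",
      y = "fraction of CPDs remaining", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname cpdrepair-plots
#' @exportS3Method ggplot2::autoplot
autoplot.dyad_profile <- function(object, ...) {
  ylab <- if (identical(attr(object, "mode"), "count")) {
    "read count"
  } else {
    "fraction of CPDs remaining"
  }
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$offset, y = .data$value, colour = .data$strand
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-73, 73), linetype = "dotted") +
    ggplot2::labs(
      x = "position relative to dyad (bp)", y = ylab, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname cpdrepair-plots
#' @exportS3Method ggplot2::autoplot
autoplot.tf_scatter <- function(object, ...) {
  d <- tibble::as_tibble(object) |> dplyr::filter(!.data$excluded)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$delta, y = .data$f_core
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "core - flank fraction remaining (repair inhibition)",
      y = "core fraction of CPDs remaining"
    ) +
    ggplot2::theme_minimal()
  ref <- attr(object, "genome_fraction")
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed")
  }
  p
}

#' @rdname cpdrepair-plots
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_matrix <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$context, y = .data$count,
    fill = .data$dipy
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$class, nrow = 1, scales = "free_x") +
    ggplot2::labs(
      x = "trinucleotide context", y = "mutation count",
      fill = "dipyrimidine"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6
    ))
}

#' Plot a gel-derived repair time course
#'
#' @param summary A `repair_summary` from [gel_repair_summary()].
#' @return A ggplot object of percent repaired over time.
#' @export
plot_repair_timecourse <- function(summary) {
  ggplot2::ggplot(tibble::as_tibble(summary), ggplot2::aes(
    x = .data$timepoint, y = .data$pct_repaired
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "repair time (min)", y = "% CPDs repaired") +
    ggplot2::theme_minimal()
}
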