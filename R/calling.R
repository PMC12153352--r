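#' Call candidate CPD lesions from aligned reads
#'
#' The lesion site is the dinucleotide immediately upstream of the 5' end of
#' each sequencing read, on the opposite strand. For a plus-strand read with
#' 1-based 5' end `p`, the candidate lesion is on the minus strand covering
#' plus-coordinates `(p-2, p-1)`; for a minus-strand read with 1-based 5'
#' end `q`, it is on the plus strand at `(q+1, q+2)`. Candidates whose
#' dinucleotide (read 5'->3' on the lesion strand) is not TT, TC, CT or CC
#' are filtered as non-dipyrimidine background; reads whose upstream window
#' falls off the chromosome, or contains an ambiguous base, are dropped and
#' tallied.
#'
#' @param reads Tibble of BED6 reads (`chrom`, `start` 0-based half-open,
#'   `end`, `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with one row per read: `chrom`, `pos` (key of the 2-bp
#'   span; see [dipyrimidine_sites()]), `strand` (lesion strand), `dinuc`,
#'   and `status` (`"retained"`, `"non_dipyrimidine"`, `"off_end"` or
#'   `"ambiguous_base"`).
#' @export
call_lesions <- function(reads, genome) {
  assert_cols(reads, c("chrom", "start", "end", "strand"), "`reads`")
  unknown <- setdiff(unique(reads$chrom), names(genome))
  if (length(unknown)) {
    rlang::abort(sprintf(
      "read(s) on chromosome(s) absent from the genome: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  lens <- chrom_lengths(genome)
  plus <- reads$strand == "+"
  p5 <- ifelse(plus, reads$start + 1L, reads$end) # 1-based 5' end
  pos <- ifelse(plus, p5 - 2L, p5 + 1L) # key = lower coord of span
  lesion_strand <- ifelse(plus, "-", "+")
  off_end <- pos < 1L | (pos + 1L) > lens[reads$chrom]

  dinuc <- rep(NA_character_, nrow(reads))
  ok <- !off_end
  top <- genome_substr(genome, reads$chrom[ok], pos[ok], pos[ok] + 1L)
  dinuc[ok] <- ifelse(plus[ok], revcomp(top), top)

  status <- dplyr::case_when(
    off_end ~ "off_end",
    grepl("[^ACGT]", dinuc) ~ "ambiguous_base",
    dinuc %in% DIPYRIMIDINES ~ "retained",
    TRUE ~ "non_dipyrimidine"
  )
  tibble::tibble(
    chrom = as.character(reads$chrom), pos = as.integer(pos),
    strand = as.character(lesion_strand),
    dinuc = as.character(dinuc), status = as.character(status)
  )
}

#' Build a zero-filled, strand-resolved lesion-count track
#'
#' Aggregates retained lesion calls per (strand, position) and fills every
#' genomic dipyrimidine that mapped no lesion with an explicit zero, so the
#' track's denominator is the full dipyrimidine complement of the genome.
#' `N`, the library total, equals the number of retained reads exactly.
#'
#' @inheritParams call_lesions
#' @param meta Named list of library metadata (library id, timepoint,
#'   strain); stored on the track together with the drop tallies.
#' @return A `lesion_track` tibble.
#' @export
build_lesion_track <- function(reads, genome, meta = list()) {
  calls <- call_lesions(reads, genome)
  tallies <- as.list(table(calls$status))
  kept <- calls[calls$status == "retained", ] |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, name = "count")
  sites <- dipyrimidine_sites(genome) |>
    dplyr::left_join(kept, by = c("chrom", "pos", "strand")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  new_lesion_track(sites, meta = c(meta, list(dropped = tallies[
    setdiff(names(tallies), "retained")
  ])))
}

#' Dinucleotide composition of a lesion track
#'
#' Totals the retained lesion counts by dinucleotide class (TT, TC, CT, CC).
#' The four categories sum to the track's library total `N`.
#'
#' @param track A `lesion_track`.
#' @return Tibble with `dinuc` and `count`, all four classes present.
#' @export
dinucleotide_composition <- function(track) {
  track |>
    dplyr::group_by(dinuc = factor(.data$dinuc, levels = DIPYRIMIDINES)) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(dinuc, fill = list(count = 0)) |>
    tibble::as_tibble()
}

#' Write a lesion track as bedGraph or WIG
#'
#' One file per strand (`<prefix>.plus.<ext>` / `<prefix>.minus.<ext>`).
#' bedGraph rows cover the single key base of each site; WIG output is
#' variableStep with span 1. Paths ending in `.gz` are compressed
#' transparently.
#'
#' @param track A `lesion_track`.
#' @param prefix Output path prefix.
#' @param format `"bedgraph"` or `"wig"`.
#' @param keep_zero Write zero-count sites too (default TRUE, matching the
#'   zero-filled background convention).
#' @return Invisibly, the two paths written.
#' @export
write_track <- function(track, prefix, format = c("bedgraph", "wig"),
                        keep_zero = TRUE) {
  format <- match.arg(format)
  ext <- if (format == "bedgraph") "bedgraph" else "wig"
  paths <- c(
    sprintf("%s.plus.%s", prefix, ext),
    sprintf("%s.minus.%s", prefix, ext)
  )
  for (i in 1:2) {
    st <- c("+", "-")[i]
    d <- track[track$strand == st, ]
    if (!keep_zero) d <- d[d$count > 0, ]
    d <- d[order(d$chrom, d$pos), ]
    if (format == "bedgraph") {
      lines <- sprintf("%s\t%d\t%d\t%g", d$chrom, d$pos - 1L, d$pos, d$count)
    } else {
      lines <- unlist(lapply(split(d, d$chrom), function(x) {
        c(
          sprintf("variableStep chrom=%s span=1", x$chrom[1]),
          sprintf("%d\t%g", x$pos, x$count)
        )
      }), use.names = FALSE)
    }
    readr::write_lines(lines, paths[i])
  }
  invisible(paths)
}
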