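#' Generate synthetic gene, nucleosome-dyad and TFBS annotations
#'
#' Lays out non-overlapping features along each chromosome with enough
#' clearance that flank windows (gene flanks, dyad half-windows, TFBS
#' profiles) never run off a chromosome end. Genes carry a transcription rate
#' (mRNA/h) spanning the high (>10) / low (<1) stratification thresholds;
#' dyads carry positioning scores spanning the score > 5 filter; binding
#' sites carry occupancancies spanning the occupancy < 10 control threshold.
#'
#' @param genome A genome as returned by [make_genome()].
#' @param n_genes,n_dyads Number of genes / nucleosome dyads to place.
#' @param gene_length Coding span (TSS..TES) in bp.
#' @param gene_rates Transcription rates cycled across genes (mRNA/h).
#' @param gene_spacing,dyad_spacing,tfbs_spacing Center-to-center spacing.
#' @param dyad_scores Nucleosome positioning scores cycled across dyads.
#' @param tf_specs Optional tibble with `tf`, `n_sites`, `occupancy` (and
#'   optionally `strand`) describing binding sites to place.
#' @param seed Integer seed (layout is deterministic; the seed only shuffles
#'   gene strands).
#' @return An `annotation_set`: list of tibbles `genes` (gene_id, chrom, tss,
#'   tes, strand, rate), `dyads` (chrom, pos, score) and `tfbs` (tf, chrom,
#'   midpoint, strand, occupancy).
#' @export
make_annotations <- function(genome, n_genes = 0, n_dyads = 0,
                             tf_specs = NULL, seed = 1,
                             gene_length = 1002, gene_rates = c(0.1, 20),
                             gene_spacing = gene_length + 1100,
                             dyad_scores = c(1, 10), dyad_spacing = 200,
                             tfbs_spacing = 260) {
  lens <- chrom_lengths(genome)
  margin <- 1100L # keeps flanks, telomere filters and read windows on-chrom
  cursors <- stats::setNames(rep(margin, length(lens)), names(lens))
  chrom_of <- function(need) {
    ok <- names(lens)[cursors + need + margin <= lens]
    if (!length(ok)) {
      rlang::abort("infeasible packing: requested features do not fit")
    }
    ok[which.min(cursors[ok])]
  }

  genes <- tibble::tibble(
    gene_id = character(0), chrom = character(0), tss = integer(0),
    tes = integer(0), strand = character(0), rate = numeric(0)
  )
  strands <- withr::with_seed(as.integer(seed), {
    sample(rep_len(c("+", "-"), max(n_genes, 1L)))
  })
  if (n_genes > 0) {
    rate <- rep_len(gene_rates, n_genes)
    for (i in seq_len(n_genes)) {
      cn <- chrom_of(gene_spacing)
      start <- cursors[[cn]] + 501L
      end <- start + gene_length - 1L
      st <- strands[i]
      genes <- dplyr::add_row(genes,
        gene_id = sprintf("gene%04d", i), chrom = cn,
        tss = if (st == "+") start else end,
        tes = if (st == "+") end else start,
        strand = st, rate = rate[i]
      )
      cursors[[cn]] <- cursors[[cn]] + gene_spacing
    }
  }

  # Vectorized placement of `n` evenly spaced features; advances cursors.
  place <- function(n, spacing) {
    if (n == 0L) {
      return(tibble::tibble(chrom = character(0), pos = integer(0)))
    }
    cap <- (lens - margin - cursors) %/% spacing
    cap[cap < 0] <- 0
    if (sum(cap) < n) {
      rlang::abort("infeasible packing: requested features do not fit")
    }
    take <- integer(length(cap))
    names(take) <- names(cap)
    left <- n
    for (cn in names(sort(cap, decreasing = TRUE))) {
      take[cn] <- min(cap[cn], ceiling(left / max(1, sum(take == 0L))))
      take[cn] <- min(take[cn], left)
      left <- left - take[cn]
      if (left == 0L) break
    }
    out <- purrr::map_dfr(names(take)[take > 0L], function(cn) {
      k <- take[[cn]]
      pos <- cursors[[cn]] + spacing %/% 2L + (seq_len(k) - 1L) * spacing
      cursors[[cn]] <<- cursors[[cn]] + k * spacing
      tibble::tibble(chrom = cn, pos = as.integer(pos))
    })
    out[seq_len(n), ]
  }

  dyads <- place(n_dyads, dyad_spacing) |>
    dplyr::mutate(score = rep_len(dyad_scores, dplyr::n()))

  tfbs <- tibble::tibble(
    tf = character(0), chrom = character(0), midpoint = integer(0),
    strand = character(0), occupancy = numeric(0)
  )
  if (!is.null(tf_specs) && nrow(tf_specs) > 0) {
    assert_cols(tf_specs, c("tf", "n_sites", "occupancy"), "`tf_specs`")
    tfbs <- purrr::map_dfr(seq_len(nrow(tf_specs)), function(j) {
      place(tf_specs$n_sites[j], tfbs_spacing) |>
        dplyr::transmute(
          tf = tf_specs$tf[j], chrom = .data$chrom,
          midpoint = .data$pos,
          strand = if ("strand" %in% names(tf_specs)) {
            tf_specs$strand[j]
          } else {
            "+"
          },
          occupancy = tf_specs$occupancy[j]
        )
    })
  }

  structure(
    list(genes = genes, dyads = dyads, tfbs = tfbs, seed = as.integer(seed)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d genes, %d dyads, %d TFBS\n",
    nrow(x$genes), nrow(x$dyads), nrow(x$tfbs)
  ))
  invisible(x)
}

#' Write an annotation set to TSV files
#' @param ann An `annotation_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_annotations <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    dyads = file.path(dir, "dyads.tsv"),
    tfbs = file.path(dir, "tfbs.tsv")
  )
  readr::write_tsv(ann$genes, paths[["genes"]])
  readr::write_tsv(ann$dyads, paths[["dyads"]])
  readr::write_tsv(ann$tfbs, paths[["tfbs"]])
  invisible(paths)
}

#' Read annotation tables
#'
#' @param genes,dyads,tfbs Paths to the TSV tables written by
#'   [write_annotations()] (columns as documented there).
#' @return An `annotation_set`.
#' @export
read_annotations <- function(genes = NULL, dyads = NULL, tfbs = NULL) {
  empty <- make_annotations(
    structure(stats::setNames(strrep("A", 5000), "chr0"), class = "sim_genome")
  )
  out <- list(
    genes = if (is.null(genes)) empty$genes else {
      readr::read_tsv(genes, show_col_types = FALSE)
    },
    dyads = if (is.null(dyads)) empty$dyads else {
      readr::read_tsv(dyads, show_col_types = FALSE)
    },
    tfbs = if (is.null(tfbs)) empty$tfbs else {
      readr::read_tsv(tfbs, show_col_types = FALSE)
    },
    seed = NA_integer_
  )
  structure(out, class = "annotation_set")
}

#' Split genes into transcription cohorts
#'
#' Genes are stratified by transcription rate into a high cohort
#' (> 10 mRNA/h), a low cohort (< 1 mRNA/h) and an intermediate remainder.
#' Genes with a missing rate are dropped (they are excluded from
#' rate-stratified analyses only).
#'
#' @param genes Tibble with a `rate` column (mRNA/h).
#' @param high,low Cohort thresholds.
#' @return `genes` with an added `cohort` factor column.
#' @export
stratify_by_transcription <- function(genes, high = 10, low = 1) {
  assert_cols(genes, "rate", "`genes`")
  genes |>
    dplyr::filter(!is.na(.data$rate)) |>
    dplyr::mutate(cohort = factor(
      dplyr::case_when(
        .data$rate > high ~ "high",
        .data$rate < low ~ "low",
        TRUE ~ "intermediate"
      ),
      levels = c("high", "intermediate", "low")
    ))
}
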