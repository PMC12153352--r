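#' Emit aligned CPD-seq reads from a lesion track
#'
#' CPD-seq sequencing reads start immediately 3' of the ligation site created
#' at the cleaved lesion, so the lesion dinucleotide lies immediately
#' upstream of the read's 5' end on the opposite strand. This generator is
#' the exact inverse of that calling convention: a minus-strand lesion
#' spanning plus-coordinates (p, p+1) emits a plus-strand read whose 5' end
#' is p+2; a plus-strand lesion spanning (p, p+1) emits a minus-strand read
#' whose 5' end is p-1. One read is emitted per lesion occurrence (counts
#' greater than one emit multiple reads), so with no background the round
#' trip through lesion calling is the identity.
#'
#' Optionally, decoy reads whose upstream dinucleotide is not a dipyrimidine
#' are added uniformly over eligible positions; these exercise the
#' non-dipyrimidine filter downstream.
#'
#' @param surviving A `lesion_track`.
#' @param genome Genome the track was built on.
#' @param background_nondipy_reads Fraction of emitted reads that are decoys,
#'   in `[0, 0.5]`.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return Tibble of BED6-style reads (`chrom`, `start` 0-based, `end`,
#'   `name`, `score`, `strand`), with attribute `n_skipped` counting lesions
#'   too close to a chromosome end to host a read.
#' @export
lesions_to_reads <- function(surviving, genome, background_nondipy_reads = 0,
                             read_length = 25, seed = 1) {
  if (background_nondipy_reads < 0 || background_nondipy_reads > 0.5) {
    rlang::abort("`background_nondipy_reads` must be in [0, 0.5]")
  }
  lens <- chrom_lengths(genome)
  hit <- surviving[surviving$count > 0, ]
  hit <- hit[rep(seq_len(nrow(hit)), hit$count), ]

  # Minus-strand lesion at (p, p+1) -> plus read with 1-based 5' end p+2.
  # Plus-strand lesion at (p, p+1) -> minus read with 1-based 5' end p-1.
  # Reads are clipped at chromosome ends (a fragment cannot extend past
  # them); only the lesion's 5'-end placement matters for calling, so a
  # lesion is unrecoverable only when its read 5' end itself is off-chrom.
  read_strand <- ifelse(hit$strand == "-", "+", "-")
  start1 <- ifelse(read_strand == "+", hit$pos + 2L,
    pmax(hit$pos - 1L - (read_length - 1L), 1L)
  )
  end1 <- ifelse(read_strand == "+",
    pmin(hit$pos + 1L + read_length, lens[hit$chrom]),
    hit$pos - 1L
  )
  fits <- start1 >= 1L & end1 <= lens[hit$chrom] & start1 <= end1
  n_skipped <- sum(!fits)
  if (n_skipped > 0) {
    rlang::inform(sprintf(
      "%d lesion(s) too close to a chromosome end to host a read; skipped",
      n_skipped
    ))
  }
  reads <- tibble::tibble(
    chrom = hit$chrom[fits],
    start = as.integer(start1[fits] - 1L),
    end = as.integer(end1[fits]),
    name = sprintf("lesion_%06d", seq_len(sum(fits))),
    score = 0L,
    strand = read_strand[fits]
  )

  bg <- background_nondipy_reads
  if (bg > 0 && nrow(reads) > 0) {
    n_decoy <- round(nrow(reads) * bg / (1 - bg))
    pool <- decoy_positions(genome, read_length)
    idx <- withr::with_seed(as.integer(seed), {
      sample.int(nrow(pool), n_decoy, replace = TRUE)
    })
    dec <- pool[idx, ]
    start1 <- ifelse(dec$strand == "+", dec$p5,
      dec$p5 - (read_length - 1L)
    )
    decoys <- tibble::tibble(
      chrom = dec$chrom,
      start = as.integer(start1 - 1L),
      end = as.integer(start1 + read_length - 1L),
      name = sprintf("decoy_%06d", seq_len(n_decoy)),
      score = 0L,
      strand = dec$strand
    )
    reads <- dplyr::bind_rows(reads, decoys) |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  structure(reads, n_skipped = n_skipped)
}

# All 5'-end positions whose called upstream dinucleotide is NOT a
# dipyrimidine and whose read fits on the chromosome.
decoy_positions <- function(genome, read_length) {
  sites <- dipyrimidine_sites(genome)
  purrr::map_dfr(names(genome), function(cn) {
    len <- nchar(genome[[cn]])
    ds <- sites[sites$chrom == cn, ]
    # Plus-strand read 5' end p calls the minus strand at (p-2, p-1).
    p_all <- seq.int(3L, max(3L, len - read_length + 1L))
    p_dipy <- ds$pos[ds$strand == "-"] + 2L
    # Minus-strand read 5' end q calls the plus strand at (q+1, q+2).
    q_all <- seq.int(read_length, max(read_length, len - 2L))
    q_dipy <- ds$pos[ds$strand == "+"] - 1L
    dplyr::bind_rows(
      tibble::tibble(chrom = cn, strand = "+", p5 = setdiff(p_all, p_dipy)),
      tibble::tibble(chrom = cn, strand = "-", p5 = setdiff(q_all, q_dipy))
    )
  })
}

#' Read / write BED6 read intervals
#'
#' Disk format is standard 0-based half-open BED6; gzip paths are handled
#' transparently by readr.
#'
#' @param path BED file path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
}

#' @rdname read_bed
#' @param reads Tibble of reads as returned by [lesions_to_reads()].
#' @export
write_bed <- function(reads, path) {
  readr::write_tsv(
    reads[, c("chrom", "start", "end", "name", "score", "strand")],
    path,
    col_names = FALSE
  )
  invisible(path)
}
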