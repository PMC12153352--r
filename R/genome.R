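#' Generate a random genome for simulated CPD-seq experiments
#'
#' Draws i.i.d. bases at a fixed GC content. The result stands in for a real
#' reference assembly so that damage, repair and read simulation can run
#' end-to-end without downloads.
#'
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @param n_chrom Number of chromosomes.
#' @param length Length of each chromosome in bp (recycled to `n_chrom`).
#' @param gc GC content in (0, 1); at `gc = 0` the genome is all A/T.
#' @return A `sim_genome`: a named character vector of chromosome sequences
#'   with the seed stored as an attribute.
#' @examples
#' g <- make_genome(seed = 1, n_chrom = 1, length = 5000, gc = 0.38)
#' nchar(g)
#' @export
make_genome <- function(seed, n_chrom = 1, length = 100000, gc = 0.38) {
  if (any(length < 1000)) {
    rlang::abort("chromosome `length` must be at least 1000 bp")
  }
  if (gc < 0 || gc >= 1) {
    rlang::abort("`gc` must lie in [0, 1)")
  }
  length <- rep_len(as.integer(length), n_chrom)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(names(p), length[i], replace = TRUE, prob = p),
        collapse = ""
      )
    }, character(1))
  })
  names(seqs) <- sprintf("chr%s", utils::as.roman(seq_len(n_chrom)))
  structure(seqs, seed = as.integer(seed), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> %d chromosome(s), %s bp total (seed %s)\n",
    length(x), format(sum(nchar(x)), big.mark = ","),
    attr(x, "seed") %||% "?"
  ))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome Named character vector of chromosome sequences.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Enumerate every dipyrimidine site on both strands
#'
#' A CPD can only form between two adjacent pyrimidines on the same strand
#' (TT, TC, CT or CC read 5'->3'). On the plus strand these are pyrimidine
#' pairs of the reference; on the minus strand they appear as purine pairs in
#' plus-strand coordinates. Sites are keyed by the lower (5'-most in
#' plus-strand coordinates) position of the 2-bp span on both strands.
#'
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with `chrom`, `pos` (1-based key), `strand` and `dinuc`
#'   (the dinucleotide read 5'->3' on the lesion strand).
#' @export
dipyrimidine_sites <- function(genome) {
  purrr::map_dfr(names(genome), function(cn) {
    b <- strsplit(genome[[cn]], "", fixed = TRUE)[[1]]
    n <- length(b)
    b1 <- b[-n]
    b2 <- b[-1]
    pyr <- b %in% PYRIMIDINES
    pur <- b %in% c("A", "G")
    plus_i <- which(pyr[-n] & pyr[-1])
    minus_i <- which(pur[-n] & pur[-1])
    dplyr::bind_rows(
      tibble::tibble(
        chrom = cn, pos = plus_i, strand = "+",
        dinuc = paste0(b1[plus_i], b2[plus_i])
      ),
      tibble::tibble(
        chrom = cn, pos = minus_i, strand = "-",
        dinuc = paste0(comp_bases(b2[minus_i]), comp_bases(b1[minus_i]))
      )
    )
  }) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

#' Read / write genomes as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] returning the package's plain named
#' character representation.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()` returns a named character vector;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(genome)), path
  )
  invisible(path)
}

# Extract genome substrings (1-based inclusive), vectorized over positions.
genome_substr <- function(genome, chrom, lo, hi) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- substring(genome[[cn]], lo[sel], hi[sel])
  }
  out
}
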