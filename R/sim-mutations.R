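# Site table for mutation placement: every interior position, in the
# pyrimidine frame (each position has its pyrimidine on exactly one strand).
pyr_frame_sites <- function(genome) {
  purrr::map_dfr(names(genome), function(cn) {
    b <- strsplit(genome[[cn]], "", fixed = TRUE)[[1]]
    n <- length(b)
    pos <- 2:(n - 1)
    base <- b[pos]
    pyr <- base %in% PYRIMIDINES
    ctx_plus <- paste0(b[pos - 1L], base, b[pos + 1L])
    tibble::tibble(
      chrom = cn, pos = pos,
      pyr_strand = ifelse(pyr, "+", "-"),
      ref_pyr = ifelse(pyr, base, comp_bases(base)),
      context = ifelse(pyr, ctx_plus, revcomp(ctx_plus))
    )
  })
}

#' Simulate UV-passaging mutation accumulation
#'
#' Generates per-isolate substitution records with the statistical structure
#' the downstream analysis assumes: mutation classes drawn from a spectrum,
#' placement over matching pyrimidine-frame sites, and -- within gene bodies
#' -- per-context placement odds of `ts_fold : 1` for sites whose pyrimidine
#' lies on the transcribed (template) strand versus the non-transcribed
#' strand. Because odds are applied per site, the expected recovered
#' asymmetry after trinucleotide normalization equals `ts_fold`. A
#' configurable fraction of records is duplicated across isolates to
#' exercise the unique-mutation filter: `round(f*N/(2-f))` records are
#' copied into a second isolate so the filter removes about a fraction `f`
#' of the final records.
#'
#' @param genome Genome to mutate.
#' @param annotations An `annotation_set` (genes drive TS/NTS placement).
#' @param n_isolates Number of passaged isolates.
#' @param mean_per_isolate Poisson mean mutation count per isolate.
#' @param ts_fold TS:NTS per-site placement odds inside gene bodies (> 0).
#' @param class_weights Named weights over specs like `"C>T"` or
#'   `"T>A@NTA"` (see [exclude_class()] for the spec syntax). The default
#'   emulates a UV spectrum dominated by C>T in dipyrimidine contexts with a
#'   T>A\@NTA component from atypical thymine-adenine photoproducts.
#' @param recurrent_fraction Target fraction of final records that are
#'   cross-isolate duplicates.
#' @param seed Integer seed.
#' @return Mutation tibble: `isolate`, `chrom`, `pos`, `ref`, `alt`.
#' @export
simulate_passaging_mutations <- function(genome, annotations,
                                         n_isolates = 20,
                                         mean_per_isolate = 91,
                                         ts_fold = 4,
                                         class_weights = c(
                                           "C>T" = 0.55, "T>A@NTA" = 0.23,
                                           "T>C" = 0.10, "C>A" = 0.06,
                                           "C>G" = 0.03, "T>G" = 0.03
                                         ),
                                         recurrent_fraction = 0,
                                         seed = 1) {
  if (ts_fold <= 0) rlang::abort("`ts_fold` must be > 0")
  if (any(class_weights < 0) || sum(class_weights) <= 0) {
    rlang::abort("`class_weights` must be normalizable")
  }
  sites <- pyr_frame_sites(genome)
  genes <- annotations$genes
  w <- rep(1, nrow(sites))
  if (!is.null(genes) && nrow(genes) > 0) {
    body <- genes |>
      dplyr::mutate(
        lo = pmin(.data$tss, .data$tes), hi = pmax(.data$tss, .data$tes),
        template = ifelse(.data$strand == "+", "-", "+")
      )
    for (st in c("+", "-")) {
      sel <- sites$pyr_strand == st
      on_ts <- in_spans(
        sites$chrom[sel], sites$pos[sel],
        body[body$template == st, c("chrom", "lo", "hi")]
      )
      w[sel][on_ts] <- ts_fold
    }
  }

  specs <- lapply(names(class_weights), parse_class_spec)
  pools <- lapply(specs, function(p) {
    hit <- sites$ref_pyr == substr(p$class, 1, 1)
    if (!is.null(p$context)) {
      pat <- paste0("^", gsub("N", "[ACGT]", p$context), "$")
      hit <- hit & grepl(pat, sites$context)
    }
    which(hit)
  })

  withr::with_seed(as.integer(seed), {
    n_per <- stats::rpois(n_isolates, mean_per_isolate)
    total <- sum(n_per)
    cls_idx <- sample.int(length(specs), total,
      replace = TRUE,
      prob = class_weights / sum(class_weights)
    )
    site_idx <- integer(total)
    for (j in seq_along(specs)) {
      sel <- which(cls_idx == j)
      if (!length(sel)) next
      pool <- pools[[j]]
      if (!length(pool)) {
        rlang::abort(sprintf(
          "no genomic sites match class spec '%s'", names(class_weights)[j]
        ))
      }
      # Without replacement (when the pool allows) so the only cross-isolate
      # duplicates are the ones injected below.
      site_idx[sel] <- pool[sample.int(
        length(pool), length(sel),
        replace = length(sel) > length(pool), prob = w[pool]
      )]
    }
    s <- sites[site_idx, ]
    alt_pyr <- substr(vapply(
      specs, function(p) p$class, character(1)
    )[cls_idx], 3, 3)
    records <- tibble::tibble(
      isolate = rep(sprintf("iso%02d", seq_len(n_isolates)), n_per),
      chrom = s$chrom, pos = s$pos,
      ref = ifelse(s$pyr_strand == "+", s$ref_pyr, comp_bases(s$ref_pyr)),
      alt = ifelse(s$pyr_strand == "+", alt_pyr, comp_bases(alt_pyr))
    )
    if (recurrent_fraction > 0 && n_isolates > 1) {
      n_pair <- round(recurrent_fraction * total / (2 - recurrent_fraction))
      pick <- sample.int(total, n_pair)
      dup <- records[pick, ]
      others <- vapply(dup$isolate, function(iso) {
        sample(setdiff(unique(records$isolate), iso), 1)
      }, character(1))
      dup$isolate <- others
      records <- dplyr::bind_rows(records, dup)
    }
    dplyr::arrange(records, .data$isolate, .data$chrom, .data$pos)
  })
}

#' Read / write mutation tables
#'
#' @param path TSV path with columns `isolate`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return `read_mutations_tsv()` returns the mutation tibble.
#' @export
read_mutations_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      isolate = "c", chrom = "c", pos = "i", ref = "c", alt = "c"
    ), progress = FALSE
  )
}

#' @rdname read_mutations_tsv
#' @param records Mutation tibble.
#' @export
write_mutations_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
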