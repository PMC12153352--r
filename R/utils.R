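#' @keywords internal
#' @importFrom rlang .data :=
#' @importFrom stats setNames
"_PACKAGE"

# Watson-Crick complement of a character vector of bases or base strings.
comp_bases <- function(x) chartr("ACGTacgtn", "TGCAtgcan", x)

# Reverse-complement of short base strings (vectorized). For whole
# chromosomes use Biostrings::reverseComplement instead.
revcomp <- function(x) {
  vapply(
    strsplit(comp_bases(x), "", fixed = TRUE),
    function(b) paste(rev(b), collapse = ""),
    character(1)
  )
}

PYRIMIDINES <- c("C", "T")
DIPYRIMIDINES <- c("TT", "TC", "CT", "CC")

# Merge possibly-overlapping integer intervals into disjoint coverage.
reduce_spans <- function(lo, hi) {
  if (length(lo) == 0L) {
    return(list(lo = integer(0), hi = integer(0)))
  }
  o <- order(lo, hi)
  lo <- lo[o]
  hi <- hi[o]
  out_lo <- lo[1]
  out_hi <- hi[1]
  k <- 1L
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi[k] + 1L) {
      out_hi[k] <- max(out_hi[k], hi[i])
    } else {
      k <- k + 1L
      out_lo[k] <- lo[i]
      out_hi[k] <- hi[i]
    }
  }
  list(lo = out_lo, hi = out_hi)
}

# Is each (chrom, pos) covered by any span in `spans` (tibble with
# chrom, lo, hi)? Spans may overlap; membership only.
in_spans <- function(chrom, pos, spans) {
  out <- logical(length(pos))
  if (nrow(spans) == 0L) {
    return(out)
  }
  for (cn in unique(spans$chrom)) {
    sel <- chrom == cn
    if (!any(sel)) next
    sp <- spans[spans$chrom == cn, , drop = FALSE]
    red <- reduce_spans(sp$lo, sp$hi)
    idx <- findInterval(pos[sel], red$lo)
    out[sel] <- idx > 0L & pos[sel] <= red$hi[pmax(idx, 1L)]
  }
  out
}

# Sum track counts over regions. `track` needs chrom, pos, strand, count;
# `regions` needs chrom, lo, hi, strand (strand NA = both strands pooled).
# Returns one count per region row.
range_sums <- function(track, regions) {
  n <- nrow(regions)
  out <- numeric(n)
  if (n == 0L || nrow(track) == 0L) {
    return(out)
  }
  pool <- is.na(regions$strand)
  for (grp in split(seq_len(n), paste0(
    regions$chrom, "\r", ifelse(pool, "*", regions$strand)
  ))) {
    cn <- regions$chrom[grp[1]]
    st <- regions$strand[grp[1]]
    if (is.na(st)) {
      sel <- track$chrom == cn
    } else {
      sel <- track$chrom == cn & track$strand == st
    }
    if (!any(sel)) next
    pos <- track$pos[sel]
    cnt <- track$count[sel]
    o <- order(pos)
    pos <- pos[o]
    cs <- cumsum(cnt[o])
    hi_i <- findInterval(regions$hi[grp], pos)
    lo_i <- findInterval(regions$lo[grp] - 1L, pos)
    out[grp] <- ifelse(hi_i > 0, cs[pmax(hi_i, 1L)], 0) -
      ifelse(lo_i > 0, cs[pmax(lo_i, 1L)], 0)
  }
  out
}

# Circular distance between two phases (bp) on a cycle of `period`.
circular_dist <- function(a, b, period) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# Wrap a phase into (-period/2, period/2].
wrap_phase <- function(x, period) {
  y <- x %% period
  ifelse(y > period / 2, y - period, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    rlang::abort(sprintf(
      "%s must contain column(s): %s", what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}
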