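# Shared fixtures, built in code at load time.

# A plain named-character genome from literal sequences.
toy_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  seqs
}

# An all-zero lesion track for a genome, optionally with counts set at
# specific (chrom, pos, strand) triples.
zero_track <- function(genome, at = NULL) {
  sites <- dipyrimidine_sites(genome)
  sites$count <- 0L
  if (!is.null(at)) {
    for (i in seq_len(nrow(at))) {
      sel <- sites$chrom == at$chrom[i] & sites$pos == at$pos[i] &
        sites$strand == at$strand[i]
      stopifnot(sum(sel) == 1)
      sites$count[sel] <- at$count[i]
    }
  }
  new_lesion_track(sites)
}

# Mid-sized simulated repair experiment shared across profile tests:
# 100 kb genome, genes with high/low rates, dyads spanning the score filter.
fx_env <- new.env()
shared_fixture <- function() {
  if (is.null(fx_env$fx)) {
    genome <- make_genome(101, 1, 100000, 0.38)
    ann <- make_annotations(genome,
      n_genes = 12, n_dyads = 60, seed = 102,
      tf_specs = tibble::tibble(tf = "tfA", n_sites = 20, occupancy = 80)
    )
    t0 <- simulate_damage(genome, 0.5, seed = 103)
    sim <- simulate_repair(t0, repair_rate_model(), ann,
      timepoints = c(30, 60), strain = "rad14+PR", seed = 104
    )
    fx_env$fx <- list(genome = genome, ann = ann, t0 = t0, sim = sim)
  }
  fx_env$fx
}

# Binned-profile-shaped tibble from explicit TS/NTS fractions.
fake_binned_profile <- function(ts, nts, region = "coding") {
  n <- length(ts)
  tibble::tibble(
    bin = rep(seq_len(n), each = 2),
    region = region,
    frame = rep(c("TS", "NTS"), n),
    n0 = 100L, nt = 50L,
    fraction = as.vector(rbind(ts, nts))
  )
}

# Dyad-profile-shaped object from explicit per-offset values.
fake_dyad_profile <- function(offsets, value, strand = "combined",
                              mode = "fraction",
                              alignment = "combined", n0 = 1000L,
                              nt = 500L) {
  structure(
    tibble::tibble(
      offset = offsets, strand = strand, n0 = n0, nt = nt, value = value
    ),
    mode = mode, alignment = alignment, n_dyads = NA_integer_,
    half_window = max(abs(offsets)),
    class = c("dyad_profile", class(tibble::tibble()))
  )
}
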