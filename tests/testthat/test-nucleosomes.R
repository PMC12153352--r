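test_that("dyad score filter is strictly greater-than", {
  d <- tibble::tibble(
    chrom = "chrI", pos = c(100L, 200L, 300L), score = c(5.0, 5.01, 10)
  )
  out <- filter_dyads(d)
  expect_equal(out$pos, c(200L, 300L))
  expect_error(filter_dyads(d, min_score = 100), "no dyads")
})

test_that("uniform retention gives a flat dyad profile at F_gel", {
  fx <- shared_fixture()
  nz <- gel_anchor(fx$t0, fx$t0, 0.35)
  dp <- dyad_profile(fx$t0, fx$t0, filter_dyads(fx$ann$dyads), nz)
  expect_equal(nrow(dp), 181 * 2)
  expect_true(all(abs(dp$value[!is.na(dp$value)] - 0.35) < 1e-12))
  expect_identical(attr(dp, "alignment"), "genomic")
})

test_that("strand alignment flips the minus strand and is an involution", {
  prof <- structure(
    tibble::tibble(
      offset = rep(c(-30L, 30L), 2),
      strand = rep(c("+", "-"), each = 2),
      n0 = 10L, nt = 5L,
      value = c(0.1, 0.2, 0.3, 0.4)
    ),
    mode = "fraction", alignment = "genomic", n_dyads = 1L,
    half_window = 30,
    class = c("dyad_profile", class(tibble::tibble()))
  )
  al <- align_strands(prof)
  # minus-strand value at -30 now appears at +30
  expect_equal(al$value[al$strand == "-" & al$offset == 30], 0.3)
  expect_equal(al$value[al$strand == "+" & al$offset == 30], 0.2)
  back <- align_strands(al)
  expect_identical(attr(back, "alignment"), "genomic")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), strand, offset),
    dplyr::arrange(tibble::as_tibble(prof), strand, offset)
  )
})

test_that("strand combination is the unweighted mean of aligned strands", {
  prof <- structure(
    tibble::tibble(
      offset = rep(0L, 2), strand = c("+", "-"),
      n0 = 10L, nt = 5L, value = c(0.2, 0.4)
    ),
    mode = "fraction", alignment = "aligned", n_dyads = 1L, half_window = 0,
    class = c("dyad_profile", class(tibble::tibble()))
  )
  comb <- combine_strands(prof)
  expect_equal(comb$value, 0.3)
  expect_equal(comb$strand, "combined")
  expect_error(
    combine_strands(structure(prof, alignment = "genomic")),
    "aligned"
  )
})

test_that("rotational fit recovers a pure cosine phase and amplitude", {
  set.seed(2)
  offs <- -73:73
  val <- 0.4 + 0.05 * cos(2 * pi * (offs - 2.0) / 10.3) +
    stats::rnorm(147, 0, 0.002)
  prof <- fake_dyad_profile(offs, val)
  fit <- rotational_settings(prof)
  expect_true(fit$reliable)
  expect_lt(abs(fit$phase - 2.0), 0.5)
  expect_equal(fit$amplitude, 0.05, tolerance = 0.01)
  # labels: minima of fraction remaining are minor-out
  lab <- fit$labels
  minima <- lab$offset[lab$label == "minor_out"]
  expect_true(all(
    cpdrepair:::circular_dist(minima, fit$phase_minimum, 10.3) <= 2
  ))
  td <- generics::tidy(fit)
  expect_true(all(c("phase_max", "amplitude") %in% td$term))
  expect_gt(generics::glance(fit)$r.squared, 0.9)
})

test_that("a flat profile yields an unreliable rotational fit", {
  set.seed(1)
  prof <- fake_dyad_profile(-73:73, 0.4 + stats::rnorm(147, 0, 0.01))
  fit <- rotational_settings(prof)
  expect_false(fit$reliable)
  expect_true(all(is.na(fit$labels$label)))
})

test_that("asymmetry index reads the 3' minus 5' mean difference", {
  offs <- -90:90
  sym <- fake_dyad_profile(offs, rep(0.4, length(offs)))
  expect_equal(asymmetry_index(sym)$index, 0)
  stepped <- fake_dyad_profile(offs, ifelse(offs > 0, 0.5, 0.4))
  expect_equal(asymmetry_index(stepped)$index, 0.1)
  genomic <- structure(sym, alignment = "genomic")
  expect_error(asymmetry_index(genomic), "aligned")
})

test_that("translational attenuation leaves a damage peak over the dyad", {
  g <- make_genome(50, 1, 200000, 0.38)
  dyads <- tibble::tibble(
    chrom = "chrI", pos = seq(2000L, 198000L, by = 400L), score = 10
  )
  ann <- list(
    genes = tibble::tibble(), dyads = dyads, tfbs = tibble::tibble()
  )
  model <- repair_rate_model(
    base_rate_photolyase = 0.04, base_rate_ner = 0,
    nuc_rotational_amp = 0, nuc_3prime_attenuation = 1
  )
  t0 <- simulate_damage(g, 0.8, seed = 51)
  sim <- simulate_repair(t0, model, ann, 30, "rad14+PR", seed = 52)
  nz <- gel_anchor(t0, sim$tracks[["30"]], sim$true_fraction_remaining[["30"]])
  dp <- dyad_profile(t0, sim$tracks[["30"]], dyads, nz)
  comb <- combine_strands(align_strands(dp))
  core <- mean(comb$value[abs(comb$offset) <= 20])
  linker <- mean(comb$value[abs(comb$offset) >= 80])
  expect_gt(core, linker)
})
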