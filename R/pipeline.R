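default_params <- function() {
  list(
    bins = 6, flank_bins = 3, flank_width = 167,
    window = c(-500, 640),
    core_halfwidth = 4, flank_halfwidth = 100, min_core_cpds = 100,
    mask_below = 10, telomere_exclude = 1000,
    dyad_min_score = 5, half_window = 90,
    asym_min_count = 30
  )
}

write_tsv_with_header <- function(df, path, header) {
  readr::write_lines(header, path)
  readr::write_tsv(tibble::as_tibble(df), path, append = TRUE,
    col_names = TRUE
  )
  invisible(path)
}

#' Run the full CPD repair analysis pipeline from one config
#'
#' Executes the stages in dependency order -- lesion calling, gel
#' quantification and anchoring, gene/nucleosome/TFBS repair profiling,
#' mutation analysis -- reading all inputs from one configuration (a list,
#' or a path to a YAML/JSON file) and writing TSV outputs whose headers
#' carry the tool version, a config hash and the seed, so reruns with the
#' same config are byte-identical. Stages whose inputs are absent from the
#' config are skipped; a stage failure aborts with the stage named.
#'
#' Config fields: `genome` (FASTA), `reads` (named list timepoint -> BED;
#' must include `"0"`), `gel` (lane TSV) and optional `ladder`, `genes`,
#' `dyads`, `tfbs`, `mutations` (TSVs as written by the simulators),
#' `params` (overrides of the analysis defaults: bins 6, flank width 167,
#' TFBS core +/-4 and flank +/-100, >=100 core CPDs, mask <10, dyad score
#' >5, half-window 90, asymmetry min count 30, telomere exclusion 1000),
#' `seed`, `out_dir`.
#'
#' @param config List or path to a `.yaml`/`.json` config file.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a named list of the output paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% "cpdrepair_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  header <- c(
    sprintf("# cpdrepair %s", as.character(utils::packageVersion("cpdrepair"))),
    sprintf("# config_hash=%s", hash),
    sprintf("# seed=%s", seed)
  )
  outputs <- new.env(parent = emptyenv())
  register <- function(name, path) assign(name, path, envir = outputs)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_with_header(df, path, header)
    register(name, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  need <- function(path, what, stage_name) {
    if (is.null(path) || !file.exists(path)) {
      rlang::abort(sprintf(
        "stage '%s' failed: missing input %s (%s)", stage_name, what,
        path %||% "<unset>"
      ))
    }
    path
  }

  message("stage: lesion_calling")
  genome <- stage("lesion_calling", {
    read_genome_fasta(need(config$genome, "genome FASTA", "lesion_calling"))
  })
  tracks <- stage("lesion_calling", {
    reads <- config$reads
    if (is.null(reads) || !("0" %in% names(reads))) {
      rlang::abort("`reads` must include a \"0\" timepoint BED")
    }
    lapply(reads, function(p) {
      build_lesion_track(
        read_bed(need(p, "reads BED", "lesion_calling")), genome
      )
    })
  })
  emit(dinucleotide_composition(tracks[["0"]]), "dinuc_composition_t0.tsv")

  message("stage: gel_normalization")
  norm <- stage("gel_normalization", {
    lanes <- readr::read_tsv(
      need(config$gel, "gel lane TSV", "gel_normalization"),
      show_col_types = FALSE
    )
    ladder <- if (!is.null(config$ladder)) {
      readr::read_tsv(config$ladder, show_col_types = FALSE)
    }
    summ <- gel_repair_summary(lanes, ladder)
    emit(summ, "repair_summary.tsv")
    reps <- setdiff(names(tracks), "0")
    anchors <- lapply(reps, function(tp) {
      f <- summ$fraction_remaining[summ$timepoint == as.numeric(tp)]
      if (!length(f)) {
        rlang::abort(sprintf("no gel lane for timepoint %s", tp))
      }
      gel_anchor(tracks[["0"]], tracks[[tp]], f)
    })
    names(anchors) <- reps
    jsonlite::write_json(
      lapply(anchors, function(a) a$f_gel),
      file.path(out_dir, "normalization.json"),
      auto_unbox = TRUE, digits = NA
    )
    register("normalization.json", file.path(out_dir, "normalization.json"))
    anchors
  })

  ann <- stage("annotations", {
    read_annotations(
      genes = config$genes, dyads = config$dyads, tfbs = config$tfbs
    )
  })

  for (tp in names(norm)) {
    t0 <- tracks[["0"]]
    tt <- tracks[[tp]]
    nz <- norm[[tp]]
    if (nrow(ann$genes) > 0) {
      message("stage: gene_profiles (t=", tp, ")")
      stage("gene_profiles", {
        bp <- bin_genes(t0, tt, ann$genes, nz,
          n_bins = params$bins, flank_bins = params$flank_bins,
          flank_width = params$flank_width
        )
        emit(bp, sprintf("gene_bins_t%s.tsv", tp))
        emit(log2_asymmetry(bp), sprintf("gene_log2_asymmetry_t%s.tsv", tp))
        emit(paired_bin_test(bp), sprintf("gene_bin_test_t%s.tsv", tp))
        emit(
          tss_metaprofile(t0, tt, ann$genes, nz, window = params$window),
          sprintf("tss_metaprofile_t%s.tsv", tp)
        )
        emit(
          gene_cluster_matrix(t0, tt, ann$genes, nz,
            window = params$window
          ),
          sprintf("gene_matrix_t%s.tsv", tp)
        )
      })
    }
    if (nrow(ann$dyads) > 0) {
      message("stage: nucleosome_profiles (t=", tp, ")")
      stage("nucleosome_profiles", {
        dp <- dyad_profile(
          t0, tt, filter_dyads(ann$dyads, params$dyad_min_score), nz,
          half_window = params$half_window
        )
        emit(dp, sprintf("dyad_profile_t%s.tsv", tp))
        comb <- combine_strands(align_strands(dp))
        emit(comb, sprintf("dyad_profile_combined_t%s.tsv", tp))
        emit(
          asymmetry_index(comb), sprintf("dyad_asymmetry_t%s.tsv", tp)
        )
      })
    }
    if (nrow(ann$tfbs) > 0) {
      message("stage: tfbs_profiles (t=", tp, ")")
      stage("tfbs_profiles", {
        sites <- load_tfbs(ann$tfbs, genome,
          telomere_exclusion_bp = params$telomere_exclude
        )
        emit(
          tf_scatter(t0, tt, sites, nz,
            core_halfwidth = params$core_halfwidth,
            flank_halfwidth = params$flank_halfwidth,
            min_core_cpds = params$min_core_cpds
          ),
          sprintf("tf_scatter_t%s.tsv", tp)
        )
      })
    }
  }

  if (!is.null(config$mutations)) {
    message("stage: mutation_analysis")
    stage("mutation_analysis", {
      muts <- unique_filter(read_mutations_tsv(need(
        config$mutations, "mutations TSV", "mutation_analysis"
      )))
      emit(trinuc_spectrum(muts, genome), "mutation_spectrum.tsv")
      if (nrow(ann$genes) > 0) {
        emit(
          gene_body_distribution(muts, ann$genes, genome,
            n_bins = params$bins, flank_bins = params$flank_bins,
            flank_width = params$flank_width
          ),
          "mutation_gene_bins.tsv"
        )
        emit(
          transcriptional_asymmetry(muts, ann$genes, genome,
            min_count = params$asym_min_count
          ),
          "mutation_asymmetry.tsv"
        )
      }
    })
  }
  invisible(as.list(outputs))
}

#' Write a complete simulated experiment to disk
#'
#' Generates a genome, annotations, a damage/repair experiment, CPD-seq
#' reads per timepoint, matching gel lanes and passaging mutations, and
#' writes them in the on-disk formats the pipeline consumes (FASTA, BED6,
#' TSV) together with a `config.json` ready for [run_pipeline()].
#'
#' @param dir Output directory.
#' @param seed Integer seed controlling every random draw.
#' @param chrom_length,n_chrom,gc Genome parameters.
#' @param n_genes,n_dyads,tf_specs Annotation parameters.
#' @param dose_scale Damage dose (expected lesions per unit propensity).
#' @param timepoints Repair timepoints (minutes).
#' @param strain Strain label (see [simulate_repair()]).
#' @param model A [repair_rate_model()].
#' @param background Decoy read fraction.
#' @param n_isolates,mean_per_isolate,ts_fold Passaging parameters.
#' @return Invisibly, the config list (also written as `config.json`).
#' @export
simulate_experiment_files <- function(dir, seed = 1,
                                      chrom_length = 150000, n_chrom = 1,
                                      gc = 0.38,
                                      n_genes = 20, n_dyads = 100,
                                      tf_specs = NULL,
                                      dose_scale = 0.3,
                                      timepoints = c(30, 60),
                                      strain = "rad14+PR",
                                      model = repair_rate_model(),
                                      background = 0.05,
                                      n_isolates = 20,
                                      mean_per_isolate = 91,
                                      ts_fold = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(seed, n_chrom, chrom_length, gc)
  write_genome_fasta(genome, file.path(dir, "genome.fa"))
  ann <- make_annotations(genome,
    n_genes = n_genes, n_dyads = n_dyads,
    tf_specs = tf_specs, seed = seed
  )
  write_annotations(ann, dir)

  t0 <- simulate_damage(genome, dose_scale, seed = seed + 1)
  sim <- simulate_repair(t0, model, ann,
    timepoints = timepoints,
    strain = strain, seed = seed + 2
  )
  reads <- list()
  all_tracks <- c(list("0" = t0), sim$tracks)
  for (tp in names(all_tracks)) {
    r <- lesions_to_reads(all_tracks[[tp]], genome,
      background_nondipy_reads = background, seed = seed + 10 + as.numeric(tp)
    )
    p <- file.path(dir, sprintf("reads_t%s.bed", tp))
    write_bed(r, p)
    reads[[tp]] <- p
  }

  # Gel lanes consistent with the simulated genome-wide kinetics: the t0
  # lesion density scales the per-timepoint true fraction remaining.
  phi0 <- 0.8 # CPDs/kb at time 0, a typical UVC induction level
  dens <- tibble::tibble(
    timepoint = c(0, timepoints),
    density = phi0 * c(1, unname(sim$true_fraction_remaining))
  )
  lanes <- simulate_gel_lanes(dens, seed = seed + 3)
  readr::write_tsv(lanes, file.path(dir, "gel_lanes.tsv"))

  muts <- simulate_passaging_mutations(genome, ann,
    n_isolates = n_isolates, mean_per_isolate = mean_per_isolate,
    ts_fold = ts_fold, seed = seed + 4
  )
  write_mutations_tsv(muts, file.path(dir, "mutations.tsv"))

  config <- list(
    genome = file.path(dir, "genome.fa"),
    reads = reads,
    gel = file.path(dir, "gel_lanes.tsv"),
    genes = file.path(dir, "genes.tsv"),
    dyads = file.path(dir, "dyads.tsv"),
    tfbs = if (!is.null(tf_specs)) file.path(dir, "tfbs.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    params = default_params(),
    seed = seed,
    out_dir = file.path(dir, "out")
  )
  config <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(config, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(config)
}
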