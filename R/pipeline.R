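#' Pipeline configuration with study defaults
#'
#' One flat configuration object holding every stage parameter of the
#' end-to-end synthetic analysis. Defaults encode the study conditions the
#' generator emulates: a six-condition progression design with 2 ChIP / 3
#' expression replicates, 200 bp strand-specific tag extension, FDR <= 0.05
#' peak calling, a 400 bp summit-centered atlas, regularized-t variable
#' regions at p <= 0.05, 1000 bootstrap resamples with |Z| >= 3 calls, and
#' expression DE at BH FDR <= 0.001 over probes detected (score > 0.01) in
#' at least one sample.
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it deterministically.
#' @param ... Named overrides of any default listed below.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome
    n_chroms = 1L, length_per_chrom = 1e6, gc_fraction = 0.42,
    # planted regions
    n_regions = 200L, region_width = 400L, base_enrichment = 10,
    fraction_group_effect = 0.4, effect_fold = 0.25,
    motif_spec = tibble(
      motif_id = c("Gata2", "Cebpa"),
      iupac = c("WGATAR", "TTGCGCAA"),
      rate_deprived = c(3, 1),
      rate_other = c(1, 1)),
    # ChIP tags
    depth = 1e5, fragment_len = 200L,
    # peak calling
    extension = 200L, peak_fdr = 0.05, null_mode = "poisson",
    mc_iterations = 200L,
    # atlas + scoring
    atlas_width = 400L, score_mode = "overlap",
    # differential acetylation
    p_threshold = 0.05, prior_df = 10, window = 101L,
    # motif enrichment
    motifs = consensus_motifs(), bootstrap_B = 1000L, z_threshold = 3,
    # expression
    n_probes = 20000L, n_de_per_transition = 400L, expr_log_fc = 2,
    noise_sd = 0.5, detection_fraction = 0.458,
    n_shared_up = 40L, n_shared_down = 88L, shared_log_fc = 3,
    fdr_threshold = 0.001, detection_threshold = 0.01,
    # design
    design = sample_design()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes, under one master seed: genome simulation, region/motif
#' planting, ChIP tag simulation, per-sample peak calling, atlas
#' construction and scoring, differential acetylation between groups A and
#' B, bootstrap motif enrichment in the deprived and enriched sets, and the
#' expression arm (simulation, detection filter, per-transition DE,
#' non-redundant sets per model, shared progression intersection). Rerunning
#' with an identical configuration reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as FASTA/BED/TSV plus a JSON summary stamped with the config hash.
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_run` with elements `genome`, `planted`,
#'   `tags`, `peaks`, `atlas`, `scores`, `diffac`, `motif_deprived`,
#'   `motif_enriched`, `expression` (sim, expressed, de, nrde, shared),
#'   `summary` (flat named list of headline numbers), `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name,
        as.numeric(difftime(Sys.time(), s, units = "secs")))
    out
  }
  hash <- config_hash(unclass(config))
  design <- config$design

  genome0 <- stage("genome", generate_genome(
    config$n_chroms, config$length_per_chrom, config$gc_fraction,
    seed = derive_seed(config$seed, 1)))
  planted <- stage("plant_regions", plant_regions(
    genome0, config$n_regions, config$region_width, config$motif_spec,
    config$fraction_group_effect, config$effect_fold,
    config$base_enrichment, seed = derive_seed(config$seed, 2)))
  genome <- planted$genome
  lens <- genome_lengths(genome)

  tags <- stage("simulate_tags", simulate_chip_tags(
    genome, planted$regions, design, config$depth, config$fragment_len,
    seed = derive_seed(config$seed, 3)))
  peaks <- stage("call_peaks", call_peaks(
    tags, lens, L = config$extension, peak_fdr = config$peak_fdr,
    null_mode = config$null_mode, mc_iterations = config$mc_iterations,
    seed = derive_seed(config$seed, 4)))
  windows <- summit_windows(peaks, config$atlas_width, lens)
  atlas <- stage("build_atlas", build_atlas(windows, config$atlas_width))
  scores <- stage("score_regions", score_regions(
    atlas, tags, L = config$extension, chrom_lengths = lens,
    mode = config$score_mode))
  fit <- stage("diff_acetylation", diff_acetylation(
    scores, chip_groups(design), p_threshold = config$p_threshold,
    prior_df = config$prior_df, w = config$window))

  deprived_ids <- fit$table$region_id[fit$table$class == "deprived"]
  enriched_ids <- fit$table$region_id[fit$table$class == "enriched"]
  motif_deprived <- if (length(deprived_ids)) {
    stage("motif_deprived", motif_enrichment(
      deprived_ids, atlas, genome, config$motifs, B = config$bootstrap_B,
      seed = derive_seed(config$seed, 5), z_threshold = config$z_threshold))
  } else NULL
  motif_enriched <- if (length(enriched_ids)) {
    stage("motif_enriched", motif_enrichment(
      enriched_ids, atlas, genome, config$motifs, B = config$bootstrap_B,
      seed = derive_seed(config$seed, 6), z_threshold = config$z_threshold))
  } else NULL

  sim <- stage("simulate_expression", simulate_expression(
    design, config$n_probes, config$n_de_per_transition, config$expr_log_fc,
    config$noise_sd, config$detection_fraction,
    n_shared_up = config$n_shared_up, n_shared_down = config$n_shared_down,
    shared_log_fc = config$shared_log_fc,
    seed = derive_seed(config$seed, 7)))
  expressed <- detection_filter(sim$detection, config$detection_threshold)
  expressed_ids <- expressed$probe_id[expressed$expressed]
  de <- stage("expression_de", transitions_de(
    sim$exprs, sim$samples, fdr_threshold = config$fdr_threshold,
    probes = expressed_ids, prior_df = config$prior_df, w = config$window))
  nrde_me <- nonredundant_de(de[de$transition %in% model_transitions("ME")$name, ])
  nrde_mt <- nonredundant_de(de[de$transition %in% model_transitions("MT")$name, ])
  nrde_all <- nonredundant_de(de[de$transition != "WT_FDCP" &
                                   de$transition != "MEL_MTL", ])
  shared <- shared_progression_sets(de[de$transition == "ME_init", ],
                                    de[de$transition == "MT_prog", ])

  class_counts <- table(factor(fit$table$class,
                               levels = c("stable", "enriched", "deprived")))
  de_counts <- de %>%
    dplyr::filter(.data$call != "ns") %>%
    dplyr::count(.data$transition)
  summary <- c(
    list(
      config_hash = hash,
      seed = config$seed,
      atlas_size = nrow(atlas),
      n_stable = as.integer(class_counts[["stable"]]),
      n_enriched = as.integer(class_counts[["enriched"]]),
      n_deprived = as.integer(class_counts[["deprived"]]),
      n_probes = config$n_probes,
      n_expressed = length(expressed_ids),
      nrde_me = nrow(nrde_me),
      nrde_mt = nrow(nrde_mt),
      nrde_all = nrow(nrde_all),
      shared_up = sum(shared$direction == "up"),
      shared_down = sum(shared$direction == "down")
    ),
    if (!is.null(motif_deprived)) {
      setNames(as.list(round(motif_deprived$z, 6)),
               paste0("z_deprived_", motif_deprived$motif_id))
    },
    if (!is.null(motif_enriched)) {
      setNames(as.list(round(motif_enriched$z, 6)),
               paste0("z_enriched_", motif_enriched$motif_id))
    },
    setNames(as.list(de_counts$n), paste0("de_", de_counts$transition))
  )

  run <- structure(list(
    genome = genome, planted = planted[c("regions", "motif_placements")],
    tags = tags, peaks = peaks, atlas = atlas, scores = scores,
    diffac = fit, motif_deprived = motif_deprived,
    motif_enriched = motif_enriched,
    expression = list(sim = sim, expressed = expressed, de = de,
                      nrde_me = nrde_me, nrde_mt = nrde_mt,
                      nrde_all = nrde_all, shared = shared),
    summary = summary, config = config, config_hash = hash
  ), class = "pipeline_run")

  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  say("pipeline finished in %.1fs",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_genome_fasta(run$genome, p("genome.fa"))
  write_peaks_bed(run$peaks, p("peaks.bed"))
  write_atlas_bed(run$atlas, p("atlas.bed"))
  write_scores_tsv(run$scores, p("region_scores_rpm.tsv"), "rpm")
  write_scores_tsv(run$scores, p("region_scores_raw.tsv"), "raw")
  readr::write_tsv(run$diffac$table, p("differential_regions.tsv"))
  if (!is.null(run$motif_deprived)) {
    readr::write_tsv(as_tibble(run$motif_deprived), p("motif_deprived.tsv"))
  }
  if (!is.null(run$motif_enriched)) {
    readr::write_tsv(as_tibble(run$motif_enriched), p("motif_enriched.tsv"))
  }
  readr::write_tsv(run$planted$regions, p("planted_regions_truth.tsv"))
  readr::write_tsv(run$expression$de, p("expression_de.tsv"))
  readr::write_tsv(run$expression$shared, p("shared_progression_sets.tsv"))
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> config", x$config_hash, "seed", x$config$seed, "\n")
  s <- x$summary
  cat(sprintf("  atlas: %d regions; %d enriched / %d deprived / %d stable\n",
              s$atlas_size, s$n_enriched, s$n_deprived, s$n_stable))
  cat(sprintf("  expression: %d/%d expressed; shared up %d / down %d\n",
              s$n_expressed, s$n_probes, s$shared_up, s$shared_down))
  invisible(x)
}
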