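#' Pipeline configuration
#'
#' Collects the stage parameters of the whole analysis; validated against
#' each stage's preconditions before anything runs.
#'
#' @param sim A [sim_config()] describing the synthetic input (fragment BED
#'   input is supported through [read_fragment_bed()] + the stage functions;
#'   the bundled pipeline runs on simulated data).
#' @param min_coverage,peak_width Peak-caller parameters.
#' @param grid V-plot [vplot_grid()].
#' @param vae Named list of overrides for [vae_config()] (e.g.
#'   `list(total_steps = 500)`).
#' @param p_cut,lr_cut Selection cutoffs for [rank_regions()].
#' @param condition_a,condition_b Condition labels compared by the
#'   differential stage (A = treatment: negative log ratio means central
#'   nucleosome depletion in A).
#' @param seed Root seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), min_coverage = 10L,
                            peak_width = 500L, grid = vplot_grid(),
                            vae = list(), p_cut = 0.05, lr_cut = -0.2,
                            condition_a = "B", condition_b = "A",
                            seed = 1L) {
  stopifnot(min_coverage >= 1, peak_width >= 1, p_cut > 0, p_cut <= 1)
  if (sim$region_width != grid$window_width)
    stop("simulated region width must equal the V-plot window width",
         call. = FALSE)
  structure(list(sim = sim, min_coverage = as.integer(min_coverage),
                 peak_width = as.integer(peak_width), grid = grid,
                 vae = vae, p_cut = p_cut, lr_cut = lr_cut,
                 condition_a = condition_a, condition_b = condition_b,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Stages: simulate fragments; per-sample coverage and peak calling; union
#' peak set; motif deviation scores with PCA and clustering order;
#' open/closed grouping against two reference samples with annotation
#' enrichment; V-plot construction, VAE training and the chi-squared
#' differential test with BH adjustment and ranking. Every stage writes its
#' table into `out_dir` and a `manifest.json` records stages, seeds and
#' parameters. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with all in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  # 1. simulate
  config$sim$seed <- config$seed
  sim <- simulate_fragments(config$sim, dir = file.path(out_dir, "fragments"))
  note("simulate")

  # 2. coverage + peak calling per sample
  span <- genomic_intervals(config$sim$chrom, 0,
                            max(sim$fragments$end) + 500L)
  peak_sets <- lapply(sim$samples$sample_id, function(id) {
    tr <- coverage_track(
      sim$fragments[sim$fragments$sample_id == id, , drop = FALSE],
      config$sim$chrom, span)
    call_peaks(tr, config$min_coverage, config$peak_width, sample_id = id)
  })
  names(peak_sets) <- sim$samples$sample_id
  all_peaks <- do.call(rbind, peak_sets)
  data.table::fwrite(all_peaks, file.path(out_dir, "peaks.tsv"), sep = "\t")
  note("callpeaks")

  # 3. union interval set
  union <- union_intervals(peak_sets)
  data.table::fwrite(union, file.path(out_dir, "union_intervals.tsv"),
                     sep = "\t")
  note("union")

  # 4. motif deviations over the union set
  counts <- count_fragments(sim$fragments, union)
  sites <- data.frame(chrom = sim$regions$chrom,
                      start = sim$regions$motif_start,
                      end = sim$regions$motif_end,
                      motif_name = "ETS_sim", stringsAsFactors = FALSE)
  membership <- motif_membership(union, sites)
  dev <- deviation_scores(counts, membership, seed = config$seed + 1L)
  pca <- pca_deviations(dev$deviations)
  ord <- cluster_deviations(dev$deviations)
  data.table::fwrite(
    data.frame(motif = rownames(dev$deviations), dev$deviations,
               variability = dev$variability,
               variability_p = dev$variability_p),
    file.path(out_dir, "deviations.tsv"), sep = "\t")
  note("deviations")

  # 5. grouping against the two first-replicate reference samples
  ref_a <- sim$samples$sample_id[sim$samples$condition == "A"][1]
  ref_b <- sim$samples$sample_id[sim$samples$condition == "B"][1]
  groups <- assign_groups(sim$regions, peak_sets[[ref_a]],
                          peak_sets[[ref_b]])
  enrich <- group_enrichment(
    groups, sim$regions[sim$regions$displaced, , drop = FALSE])
  data.table::fwrite(groups, file.path(out_dir, "groups.tsv"), sep = "\t")
  data.table::fwrite(enrich, file.path(out_dir, "group_enrichment.tsv"),
                     sep = "\t")
  note("grouping")

  # 6. V-plots + VAE + differential test
  vc_args <- utils::modifyList(
    list(grid = config$grid, seed = config$seed + 2L), config$vae)
  vc <- do.call(vae_config, vc_args)
  vplots <- list(); ids <- character(0)
  for (id in sim$samples$sample_id) {
    vp <- build_vplots(
      sim$fragments[sim$fragments$sample_id == id, , drop = FALSE],
      sim$regions, config$grid)
    vplots <- c(vplots, vp)
    ids <- c(ids, rep(id, nrow(sim$regions)))
  }
  model <- train_vae(vplots, ids, vc)
  save_vae(model, file.path(out_dir, "model.rds"))
  res <- test_differential(model, sim$fragments, sim$regions, sim$samples,
                           config$condition_a, config$condition_b)
  ranked <- rank_regions(res, config$p_cut, config$lr_cut)
  res$selected <- res$p_adjusted < config$p_cut & res$log_ratio < config$lr_cut
  data.table::fwrite(res, file.path(out_dir, "differential.tsv"), sep = "\t")
  agg <- aggregate_vplots(vplots[ids %in%
    sim$samples$sample_id[sim$samples$condition == config$condition_a]])
  utils::write.table(agg$density,
                     file.path(out_dir, "aggregated_vplot_a.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  note("differential")

  manifest <- list(
    package_version = as.character(utils::packageVersion("vplotdiff")),
    seed = config$seed,
    stages = stages,
    n_regions = config$sim$n_regions,
    n_samples = nrow(sim$samples),
    n_selected = nrow(ranked$selected),
    parameters = list(min_coverage = config$min_coverage,
                      peak_width = config$peak_width,
                      K = vc$K, p_cut = config$p_cut, lr_cut = config$lr_cut)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, peaks = all_peaks, union = union,
                 deviations = dev, pca = pca, order = ord, groups = groups,
                 enrichment = enrich, model = model, results = res,
                 ranked = ranked, manifest = manifest))
}
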