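#' Default pipeline configuration
#'
#' Every stage threshold ships here with its canonical default: BH level
#' 0.05, I^2 ceiling 50%, factor-correlation ceiling 0.75, merge rule 4
#' genes at |log2FC| > 2, consensus rule 4-of-5. Simulation settings
#' describe the emulated study design (3 population groups, incomplete
#' 3-region coverage, Dirichlet-multinomial composition noise).
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_per_group = 30,
    region_coverage = 0.75,
    age_confound = -4,
    subclusters = sprintf("SC%d", 1:6),
    total_nuclei = 5000,
    concentration = 50,
    effects = list(),            # list of list(subcluster, phenotype, beta)
    alpha = 0.05,
    i2_max = 50,
    corr_max = 0.75,
    merge_min_genes = 4,
    merge_lfc_min = 2,
    consensus_splits = 5,
    consensus_min_agree = 4,
    weighted = TRUE,
    hc_type = "HC3",
    run_factors = TRUE,
    factors_k_grid = c(1, 2, 3, 4),
    factors_cells = 400,
    factors_genes = 150,
    factors_k_true = 3,
    subgroup_region = "STG",
    subgroup_k_range = 2:8
  )
}

#' Run the stratified conservation pipeline end to end
#'
#' Stages run in dependency order: simulate (cohort + composition + factor
#' counts), per-group association fits, cross-group meta-analysis with
#' conservation flags, factor scoring/associations (toggle
#' `run_factors`), and donor subgrouping. All randomness derives from the
#' single config seed through per-stage substreams (stage-name-hashed
#' offsets), so toggling one stage never perturbs another stage's draws.
#' Every stage output is written as TSV under `out_dir`, along with a
#' `manifest.json` recording the package version, seed, config hash and
#' per-stage record counts. The manifest is byte-stable across reruns of
#' the same config.
#'
#' @param config Config list (see [default_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts_rec <- list()

  # -- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config$n_per_group, config$region_coverage,
                            config$age_confound,
                            seed = stage_seed(config$seed, "cohort"))
  effects <- NULL
  if (length(config$effects)) {
    effects <- purrr::map_dfr(config$effects, function(e) {
      planted_effect(e$subcluster, e$phenotype, unlist(e$beta))
    })
  }
  composition <- generate_composition(
    cohort, config$subclusters, effects,
    total_nuclei = config$total_nuclei,
    concentration = config$concentration,
    seed = stage_seed(config$seed, "composition")
  )
  write_tsv_file(dplyr::select(cohort, -regions),
                 file.path(out_dir, "cohort.tsv"))
  write_composition(composition, file.path(out_dir, "composition"))
  truth <- list(effects = if (is.null(effects)) list() else effects,
                subclusters = config$subclusters)
  write_json_file(truth, file.path(out_dir, "truth.json"))
  counts_rec$donors <- nrow(cohort)
  counts_rec$samples <- nrow(composition)

  # -- per-group association fits --------------------------------------
  fits <- fit_group_associations(composition, cohort,
                                 weighted = config$weighted,
                                 hc_type = config$hc_type)
  write_tsv_file(fits, file.path(out_dir, "group_fits.tsv"))
  counts_rec$fits_attempted <- nrow(fits)
  counts_rec$fits_converged <- sum(fits$converged)

  # -- meta-analysis ----------------------------------------------------
  meta <- meta_analyze(fits, alpha = config$alpha, i2_max = config$i2_max)
  flat <- dplyr::select(meta, -dplyr::any_of(c("group_betas", "group_ses",
                                               "loo_estimates")))
  write_tsv_file(flat, file.path(out_dir, "meta.tsv"))
  write_tsv_file(dplyr::filter(flat, conserved),
                 file.path(out_dir, "meta_conserved.tsv"))
  counts_rec$meta_rows <- nrow(meta)
  counts_rec$conserved <- sum(meta$conserved)

  # -- factors (optional) ----------------------------------------------
  factor_scores <- NULL
  if (isTRUE(config$run_factors)) {
    fc <- generate_factor_counts(config$factors_cells, config$factors_genes,
                                 config$factors_k_true,
                                 seed = stage_seed(config$seed, "factors"))
    sel <- select_num_factors(fc$counts, config$factors_k_grid,
                              corr_max = config$corr_max,
                              seed = stage_seed(config$seed, "factors"))
    model <- sel$models[[paste0("K", sel$K)]]
    # spread simulated cells over the cohort's samples for scoring
    samples <- cohort_samples(cohort)
    cell_map <- tibble(
      cell = rownames(model$cell_scores),
      sample_id = rep_len(samples$sample_id, nrow(model$cell_scores))
    )
    med <- median_factor_scores(model, cell_map)
    write_tsv_file(med, file.path(out_dir, "factor_scores.tsv"))
    write_tsv_file(sel$corr_table, file.path(out_dir, "factor_selection.tsv"))
    factor_scores <- med
    counts_rec$factors_chosen_k <- sel$K
  }

  # -- donor subgrouping ------------------------------------------------
  props <- normalize_proportions(composition)
  props_reg <- dplyr::filter(props, region == config$subgroup_region)
  feats <- assemble_donor_features(list(comp = props_reg))
  if (!is.null(factor_scores)) {
    fs <- dplyr::inner_join(
      dplyr::distinct(cohort_samples(cohort), sample_id, donor_id),
      factor_scores, by = "sample_id"
    )
    fs <- dplyr::summarise(
      dplyr::group_by(dplyr::select(fs, -sample_id, -n_cells), donor_id),
      dplyr::across(dplyr::everything(), median), .groups = "drop"
    )
    feats <- assemble_donor_features(list(comp = props_reg),
                                     factor_scores = fs)
  }
  clust <- cluster_donors(feats, config$subgroup_k_range)
  write_tsv_file(tidy(clust), file.path(out_dir, "subgroups.tsv"))
  write_tsv_file(clust$silhouette, file.path(out_dir, "silhouette.tsv"))
  counts_rec$subgroups_k <- clust$chosen_k

  # -- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  write_json_file(config[order(names(config))], cfg_path)
  manifest <- list(
    package = "stratocyte",
    version = as.character(utils::packageVersion("stratocyte")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    records = counts_rec
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(cohort = cohort, composition = composition, fits = fits,
                 meta = meta, factor_scores = factor_scores,
                 clustering = clust, manifest = manifest))
}
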