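#' Pipeline configuration
#'
#' Describes one full analysis run: input tables (or a simulation block),
#' the density grid, kernel choice, null-model sizes, modularity restarts
#' and the master seed. Exactly one of `sim` and `thickness_path` must be
#' given.
#'
#' @param sim an [sim_config()] block to generate the cohort, or NULL.
#' @param thickness_path,covariate_path TSV inputs for a real cohort
#'   (see [load_thickness_table()]), or NULL.
#' @param metabolite_path,behavior_path optional TSV inputs for the
#'   metabolite and behavioral layers of a real cohort.
#' @param grid density grid (default [density_grid()], 0.05-0.30 step 0.01).
#' @param kernel,kernel_scale joint-variation kernel (default gaussian, c = 1).
#' @param fit_group group whose subjects define the covariate regression and
#'   z-score reference (default "HC").
#' @param screening_nulls rewired nulls per network for sigma during density
#'   screening (default 10; screening needs sigma at every subject x density,
#'   so a lean ensemble is used there).
#' @param final_nulls rewired nulls for the group-comparison sigma at the
#'   selected density (default 100).
#' @param n_restarts modularity restarts per network (default 20).
#' @param majority pass-all fraction required at a density (default 0.5).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list of class `idscn_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thickness_path = NULL, covariate_path = NULL,
                            metabolite_path = NULL, behavior_path = NULL,
                            grid = density_grid(),
                            kernel = "gaussian", kernel_scale = 1,
                            fit_group = "HC",
                            screening_nulls = 10, final_nulls = 100,
                            n_restarts = 20, majority = 0.5,
                            seed = 1L, out_dir = NULL) {
  if (is.null(sim) == is.null(thickness_path))
    abort("exactly one of `sim` and `thickness_path` must be provided")
  if (!is.null(thickness_path)) {
    for (p in c(thickness_path, covariate_path))
      if (is.null(p) || !file.exists(p)) abort("input file missing: %s", p)
  }
  structure(list(sim = sim, thickness_path = thickness_path,
                 covariate_path = covariate_path,
                 metabolite_path = metabolite_path, behavior_path = behavior_path,
                 grid = grid, kernel = kernel, kernel_scale = kernel_scale,
                 fit_group = fit_group,
                 screening_nulls = as.integer(screening_nulls),
                 final_nulls = as.integer(final_nulls),
                 n_restarts = as.integer(n_restarts), majority = majority,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "idscn_pipeline_config")
}

#' Partial Spearman correlations for variable pairs
#'
#' Computes [partial_spearman()] for every x-y pair and applies
#' Benjamini-Hochberg correction across the whole set (one family).
#'
#' @param x_df,y_df data.frames of numeric variables; every column of `x_df`
#'   is paired with every column of `y_df`.
#' @param covariates data.frame of covariates, or NULL for plain Spearman.
#' @return data.frame: x, y, rho, p, p_adj, n.
#' @export
correlate_table <- function(x_df, y_df, covariates = NULL) {
  rows <- list()
  for (xn in names(x_df)) for (yn in names(y_df)) {
    ps <- partial_spearman(x_df[[xn]], y_df[[yn]], covariates)
    rows[[length(rows) + 1L]] <- data.frame(
      x = xn, y = yn, rho = ps$rho, p = ps$p, n = ps$df + 2 + length(ps$covariates),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr_adjust(out$p)
  out
}

# Derive a stage seed from the master seed (stable, < 2^31).
stage_seed <- function(seed, stage) (seed * 1000L + stage) %% 2147483647L

#' Run the full individualized covariance-network pipeline
#'
#' Executes: (optional) cohort simulation -> covariate residualization and
#' z-scoring to the reference group -> per-subject network construction
#' across the density grid -> global metrics and density screening ->
#' selection of the analysis density -> group comparison of global metrics
#' (at the selected density, sigma recomputed with the full null ensemble)
#' and of rank-transformed regional centralities (averaged over the retained
#' range) -> metabolite comparisons (per-group outlier removal, ANCOVA for
#' tNAA with age) -> partial Spearman behavior correlations. All stages are
#' deterministic given the config seed. If `out_dir` is set, every stage's
#' table is persisted as TSV plus a JSON run manifest.
#'
#' @param config an [pipeline_config()].
#' @return list with elements cohort, metabolites, behavior, zscores,
#'   metrics, criteria, selection, global_comparison, regional_comparison,
#'   metabolite_comparison, ancova_tnaa, correlations, paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "idscn_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- inputs ---------------------------------------------------------------
  metabolites <- behavior <- NULL
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", simulate_cohort(config$sim))
    metabolites <- stage("simulate", simulate_metabolites(config$sim, cohort))
    behavior <- stage("simulate", simulate_behavior(config$sim, cohort))
  } else {
    cohort <- stage("load", load_thickness_table(config$thickness_path,
                                                 config$covariate_path))
    if (!is.null(config$metabolite_path))
      metabolites <- utils::read.delim(config$metabolite_path, stringsAsFactors = FALSE)
    if (!is.null(config$behavior_path))
      behavior <- utils::read.delim(config$behavior_path, stringsAsFactors = FALSE)
  }
  group <- cohort$subjects$group

  # --- normative prep and networks -----------------------------------------
  res <- stage("prep", residualize_thickness(cohort, fit_group = config$fit_group))
  zs <- stage("prep", zscore_to_reference(res, group == config$fit_group))
  nets <- stage("networks", build_all_networks(zs, grid = config$grid,
                                               kernel = config$kernel,
                                               scale = config$kernel_scale))

  # --- metrics and density screening ---------------------------------------
  metrics <- stage("metrics", metrics_table(
    nets,
    null_config = null_model_config(config$screening_nulls,
                                    seed = stage_seed(config$seed, 1L)),
    n_restarts = config$n_restarts, seed = stage_seed(config$seed, 2L)))
  criteria <- stage("screening", evaluate_criteria(metrics))
  selection <- stage("screening", select_density_range(criteria, config$majority))
  ksel <- selection$K_selected

  # --- global comparison at the selected density ---------------------------
  # On coarse grids the rounded run mean may fall between grid values;
  # evaluate at the nearest retained grid density (same convention as
  # select_density_range's pass-all audit).
  k_eval <- selection$retained[which.min(abs(selection$retained - ksel))]
  ksel_name <- sprintf("%.2f", k_eval)
  at_k <- metrics[sprintf("%.2f", metrics$density) == ksel_name, ]
  at_k <- at_k[match(cohort$subjects$subject_id, at_k$subject_id), ]
  sigma_final <- stage("global-comparison", vapply(seq_along(nets), function(s) {
    small_worldness(nets[[s]][[ksel_name]],
                    null_model_config(config$final_nulls,
                                      seed = stage_seed(config$seed, 100L + s)))
  }, numeric(1)))
  global_vals <- data.frame(clustering = at_k$clustering,
                            efficiency = at_k$efficiency,
                            modularity = at_k$modularity_Q,
                            small_worldness = sigma_final)
  global_cmp <- stage("global-comparison",
                      compare_groups_table(global_vals, group, family = "global"))

  # --- regional centralities over the retained range -----------------------
  cent <- stage("centralities", centrality_table(nets, densities = selection$retained))
  regional_cmp <- stage("regional-comparison", {
    per_type <- lapply(c("betweenness", "eigenvector", "closeness"), function(type) {
      wide <- stats::reshape(
        cent[c("subject_id", "region", type)],
        idvar = "subject_id", timevar = "region", direction = "wide")
      wide <- wide[match(cohort$subjects$subject_id, wide$subject_id), ]
      vals <- wide[-1]
      names(vals) <- sub(paste0("^", type, "\\."), "", names(vals))
      vals[] <- lapply(vals, tiedrank)     # rank-transform across subjects
      compare_groups_table(vals, group, family = type)
    })
    do.call(rbind, per_type)
  })

  # --- metabolites ----------------------------------------------------------
  metab_cmp <- ancova_tnaa <- NULL
  if (!is.null(metabolites)) {
    mvars <- metabolites[setdiff(names(metabolites), c("subject_id", "group"))]
    metab_cmp <- stage("metabolite-comparison",
                       compare_groups_table(mvars, metabolites$group,
                                            remove_outliers = TRUE,
                                            family = "metabolites"))
    if ("tNAA" %in% names(metabolites))
      ancova_tnaa <- stage("metabolite-comparison",
                           ancova_group_age(metabolites$tNAA, metabolites$group,
                                            cohort$subjects$age))
  }

  # --- behavior correlations ------------------------------------------------
  correlations <- NULL
  if (!is.null(behavior) && !is.null(metabolites)) {
    beh_all <- behavior[c("BIS_attention", "BIS_motor", "BIS_nonplanning",
                          "PANAS_negative", "PANAS_positive", "SHAPS")]
    covs <- cohort$subjects[c("age", "sex", "education", "global_mean_thickness")]
    correlations <- stage("correlations",
                          correlate_table(data.frame(tNAA = metabolites$tNAA),
                                          beh_all, covariates = covs))
  }

  results <- list(cohort = cohort, metabolites = metabolites, behavior = behavior,
                  zscores = zs, metrics = metrics, criteria = criteria,
                  selection = selection, global_comparison = global_cmp,
                  regional_comparison = regional_cmp,
                  metabolite_comparison = metab_cmp, ancova_tnaa = ancova_tnaa,
                  correlations = correlations, config = config, paths = NULL)

  if (!is.null(config$out_dir))
    results$paths <- stage("write", write_results(results, config$out_dir))
  results
}

# Persist every stage table plus a run manifest; returns written paths.
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_cohort_tables(results$cohort, results$metabolites,
                               results$behavior, dir)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(format(df, digits = 10), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }
  zt <- data.frame(subject_id = rownames(results$zscores$z), results$zscores$z,
                   check.names = FALSE)
  paths <- c(paths, wr(zt, "zscores.tsv"),
             wr(results$metrics, "metrics.tsv"),
             wr(results$criteria, "criteria.tsv"),
             wr(results$global_comparison, "global_comparison.tsv"),
             wr(results$regional_comparison, "regional_comparison.tsv"))
  if (!is.null(results$metabolite_comparison))
    paths <- c(paths, wr(results$metabolite_comparison, "metabolite_comparison.tsv"))
  if (!is.null(results$correlations))
    paths <- c(paths, wr(results$correlations, "correlations.tsv"))
  report <- file.path(dir, "report.txt")
  writeLines(write_report(results), report)
  manifest <- file.path(dir, "manifest.json")
  cfg <- results$config
  cfg_plain <- lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(list(
    seed = cfg$seed,
    config = cfg_plain,
    selected_density = results$selection$K_selected,
    file_md5 = as.list(tools::md5sum(sort(paths)))
  ), manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  c(paths, report, manifest)
}

#' Plain-text run report
#'
#' Summarizes the selected density, retained range, and FDR-significant
#' group differences with Cliff's delta and its CI in brackets.
#'
#' @param results output of [run_pipeline()].
#' @param alpha significance level for the adjusted p (default 0.05).
#' @return character vector of report lines.
#' @export
write_report <- function(results, alpha = 0.05) {
  sel <- results$selection
  lines <- c(
    "Individualized structural covariance network analysis",
    sprintf("Subjects: %d (%s)", nrow(results$cohort$subjects),
            paste(sprintf("%s n=%d", names(table(results$cohort$subjects$group)),
                          table(results$cohort$subjects$group)), collapse = ", ")),
    sprintf("Retained density range: K = %.2f-%.2f; selected K = %.2f (pass-all %.0f%% at K)",
            sel$K_low, sel$K_high, sel$K_selected, 100 * sel$frac_all_at_selected),
    ""
  )
  fmt_cmp <- function(cmp, label) {
    sig <- cmp[!is.na(cmp$p_adj) & cmp$p_adj < alpha, ]
    if (nrow(sig) == 0)
      return(sprintf("%s: no significant differences after FDR correction.", label))
    c(sprintf("%s (FDR < %.2f):", label, alpha),
      sprintf("  %s [%s]: delta = %.2f [%.2f, %.2f], p = %.4g, p-adj = %.4g",
              sig$variable, sig$family, sig$delta, sig$ci_low, sig$ci_high,
              sig$p, sig$p_adj))
  }
  lines <- c(lines, fmt_cmp(results$global_comparison, "Global metrics"))
  lines <- c(lines, fmt_cmp(results$regional_comparison, "Regional centralities"))
  if (!is.null(results$metabolite_comparison))
    lines <- c(lines, fmt_cmp(results$metabolite_comparison, "Metabolites"))
  if (!is.null(results$ancova_tnaa))
    lines <- c(lines, sprintf("ANCOVA (tNAA ~ group + age): F = %.3f, p = %.4g",
                              results$ancova_tnaa$F_group, results$ancova_tnaa$p_group))
  if (!is.null(results$correlations)) {
    sig <- results$correlations[results$correlations$p_adj < alpha, ]
    lines <- c(lines, if (nrow(sig) == 0)
      "Behavior correlations: no significant associations after FDR correction."
      else c("Behavior correlations (FDR-significant):",
             sprintf("  %s ~ %s: rho = %.2f, p-adj = %.4g",
                     sig$x, sig$y, sig$rho, sig$p_adj)))
  }
  lines
}
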