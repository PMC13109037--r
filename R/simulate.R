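#' Simulation configuration for a two-group cortical-thickness cohort
#'
#' Defines the generative model for a synthetic case-control cohort whose
#' regional thickness deviations carry a modular covariance structure. Each
#' subject k in group g has, for region r belonging to module m(r),
#'
#'   thickness[k, r] = mu_r + beta_age * (age_k - 40) + beta_sex * sex_k +
#'                     b_k + lambda_g * u[m(r), k] + eps[k, r] -
#'                     thinning_sm * 1(g = SM)
#'
#' where `u[m, k]` are standard-normal module factors shared by all regions of
#' module m within subject k, `b_k ~ N(0, sigma_subject^2)` is a global
#' subject offset, and `eps ~ N(0, sigma_noise^2)` is region noise. The module
#' loading `lambda_g` controls within-module coherence of thickness
#' deviations and is the ground-truth dial the network analysis should
#' recover: a lower loading in one group weakens its modular structure.
#'
#' @param n_per_group subjects per group (default 51).
#' @param n_regions number of atlas regions (default 34).
#' @param module_partition integer vector of length `n_regions` assigning each
#'   region to a module; default 4 modules of sizes 9/9/8/8.
#' @param lambda_hc,lambda_sm module-coherence loadings for the control and
#'   case group (unitless; defaults 1.2 and 0.6).
#' @param sigma_noise region noise SD in mm (default 0.3).
#' @param sigma_subject global subject-offset SD in mm (default 0.1).
#' @param beta_age age slope in mm/year (default -0.005).
#' @param beta_sex additive sex effect in mm for sex code 1 (default 0.03).
#' @param thinning_sm diffuse thinning applied to every region of the case
#'   group, in mm (default 0.02).
#' @param tnaa_params per-group location/scale (institutional units) for the
#'   tNAA metabolite; defaults match a control median 17.8 (IQR 1.92) and a
#'   case median 16.7 (IQR 2.27), with scale = IQR/1.349 for a Gaussian.
#' @param seed integer RNG seed.
#' @return object of class `idscn_sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = 51,
                       n_regions = 34,
                       module_partition = NULL,
                       lambda_hc = 1.2,
                       lambda_sm = 0.6,
                       sigma_noise = 0.3,
                       sigma_subject = 0.1,
                       beta_age = -0.005,
                       beta_sex = 0.03,
                       thinning_sm = 0.02,
                       tnaa_params = list(
                         HC = c(location = 17.8, scale = 1.92 / 1.349),
                         SM = c(location = 16.7, scale = 2.27 / 1.349)
                       ),
                       seed = 1L) {
  if (is.null(module_partition)) {
    sizes <- if (n_regions == 34) c(9, 9, 8, 8) else {
      base <- n_regions %/% 4
      extra <- n_regions %% 4
      base + (seq_len(4) <= extra)
    }
    module_partition <- rep(seq_along(sizes), times = sizes)
  }
  if (length(module_partition) != n_regions)
    abort("module_partition must assign each of the %d regions exactly once", n_regions)
  if (anyNA(module_partition)) abort("module_partition contains NA")
  if (n_per_group < 2) abort("n_per_group must be >= 2")
  for (nm in c("lambda_hc", "lambda_sm", "sigma_noise", "sigma_subject")) {
    if (get(nm) < 0) abort("%s must be >= 0", nm)
  }
  if (any(vapply(tnaa_params, function(p) p[["scale"]], 0) < 0))
    abort("tnaa scale parameters must be >= 0")
  structure(list(
    n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
    module_partition = as.integer(module_partition),
    lambda_hc = lambda_hc, lambda_sm = lambda_sm,
    sigma_noise = sigma_noise, sigma_subject = sigma_subject,
    beta_age = beta_age, beta_sex = beta_sex, thinning_sm = thinning_sm,
    tnaa_params = tnaa_params, seed = as.integer(seed)
  ), class = "idscn_sim_config")
}

#' Simulate a two-group cortical-thickness cohort
#'
#' Draws ages, sex and education per group (controls: age ~ N(40, 13^2),
#' P(female) = 0.45; cases: age ~ N(48, 12^2), P(female) = 0.51; ages
#' truncated to 21-65 years; education ~ N(15, 2.5^2) years truncated to
#' 8-22 in both groups), region means mu_r once per run uniformly in
#' [2.0, 3.0] mm, then the thickness matrix under the model documented in
#' [sim_config()]. Identical configurations yield bit-identical cohorts.
#'
#' @param config an `idscn_sim_config`.
#' @return an `idscn_cohort`: list with `subjects` (data.frame: subject_id,
#'   group, age, sex, education, global_mean_thickness) and `thickness`
#'   (subjects x regions matrix, mm, region columns `ROI01`..).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "idscn_sim_config"))
  with_seed(config$seed, {
    n <- config$n_per_group
    nr <- config$n_regions
    ntot <- 2L * n
    group <- rep(c("HC", "SM"), each = n)
    age <- numeric(ntot)
    age[group == "HC"] <- rtruncnorm(n, 40, 13, 21, 65)
    age[group == "SM"] <- rtruncnorm(n, 48, 12, 21, 65)
    sex <- numeric(ntot)
    sex[group == "HC"] <- stats::rbinom(n, 1, 0.45)
    sex[group == "SM"] <- stats::rbinom(n, 1, 0.51)
    education <- rtruncnorm(ntot, 15, 2.5, 8, 22)

    mu <- stats::runif(nr, 2.0, 3.0)
    n_mod <- max(config$module_partition)
    u <- matrix(stats::rnorm(n_mod * ntot), nrow = ntot)   # subject x module factors
    b <- stats::rnorm(ntot, 0, config$sigma_subject)
    eps <- matrix(stats::rnorm(ntot * nr, 0, config$sigma_noise), nrow = ntot)
    lambda <- ifelse(group == "HC", config$lambda_hc, config$lambda_sm)

    make_thick <- function() {
      matrix(mu, nrow = ntot, ncol = nr, byrow = TRUE) +
        config$beta_age * (age - 40) + config$beta_sex * sex + b +
        lambda * u[, config$module_partition, drop = FALSE] + eps -
        config$thinning_sm * (group == "SM")
    }
    thick <- make_thick()
    # Subjects whose stochastic terms push any region non-positive are
    # redrawn (implicitly truncating the deviation model at zero thickness).
    tries <- 0L
    while (any(bad <- rowSums(thick <= 0) > 0)) {
      tries <- tries + 1L
      if (tries > 1000L)
        abort("simulated thickness non-positive for %d subjects after resampling; reduce effect/noise scales",
              sum(bad))
      nb <- sum(bad)
      u[bad, ] <- stats::rnorm(n_mod * nb)
      b[bad] <- stats::rnorm(nb, 0, config$sigma_subject)
      eps[bad, ] <- stats::rnorm(nb * nr, 0, config$sigma_noise)
      thick <- make_thick()
    }
    colnames(thick) <- sprintf("ROI%02d", seq_len(nr))
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(ntot)),
      group = group, age = age, sex = sex, education = education,
      global_mean_thickness = rowMeans(thick),
      stringsAsFactors = FALSE
    )
    rownames(thick) <- subjects$subject_id
    structure(list(subjects = subjects, thickness = thick,
                   module_partition = config$module_partition),
              class = "idscn_cohort")
  })
}

#' Simulate dACC metabolite concentrations for a cohort
#'
#' tNAA is drawn per group from a Gaussian with the configured
#' location/scale; glutamate, glutathione and GABA are drawn with no group
#' effect (null metabolites). All values are in institutional (water-scaled)
#' units.
#'
#' @param config an `idscn_sim_config`.
#' @param cohort the matching `idscn_cohort`.
#' @return data.frame: subject_id, group, tNAA, Glu, GSH, GABA.
#' @export
simulate_metabolites <- function(config, cohort) {
  stopifnot(inherits(config, "idscn_sim_config"), inherits(cohort, "idscn_cohort"))
  if (any(vapply(config$tnaa_params, function(p) p[["scale"]], 0) < 0))
    abort("negative metabolite scale")
  with_seed(config$seed + 1L, {
    subj <- cohort$subjects
    n <- nrow(subj)
    tnaa <- numeric(n)
    for (g in c("HC", "SM")) {
      p <- config$tnaa_params[[g]]
      idx <- subj$group == g
      tnaa[idx] <- stats::rnorm(sum(idx), p[["location"]], p[["scale"]])
    }
    data.frame(
      subject_id = subj$subject_id, group = subj$group,
      tNAA = tnaa,
      Glu  = stats::rnorm(n, 9.6, 1.1),
      GSH  = stats::rnorm(n, 2.3, 0.35),
      GABA = stats::rnorm(n, 2.6, 0.45),
      stringsAsFactors = FALSE
    )
  })
}

# Behavioral instruments: location/scale per group and instrument range.
# Smoker-only measures carry NA for controls.
.behavior_defaults <- list(
  FTND            = list(HC = NULL, SM = c(4.2, 2.3),   range = c(0, 10)),
  years_smoking   = list(HC = NULL, SM = c(29.6, 13.5), range = c(1, 50)),
  QSU             = list(HC = NULL, SM = c(46.3, 26.5), range = c(10, 70)),
  BIS_attention   = list(HC = c(12.8, 2.4), SM = c(13.0, 3.5), range = c(8, 32)),
  BIS_motor       = list(HC = c(20.0, 2.6), SM = c(21.4, 4.5), range = c(11, 44)),
  BIS_nonplanning = list(HC = c(20.8, 4.6), SM = c(22.7, 5.3), range = c(11, 44)),
  PANAS_negative  = list(HC = c(14.1, 4.3), SM = c(16.0, 7.1), range = c(10, 50)),
  PANAS_positive  = list(HC = c(35.9, 6.9), SM = c(35.0, 7.2), range = c(10, 50)),
  SHAPS           = list(HC = c(4.9, 4.1),  SM = c(5.4, 5.0),  range = c(0, 14))
)

#' Simulate behavioral/questionnaire scores for a cohort
#'
#' Nicotine-dependence measures (FTND, years of smoking, QSU) are generated
#' for the case group only (controls get NA by design); impulsivity and
#' affect scales (BIS, PANAS, SHAPS) for all subjects. Scores are drawn from
#' Gaussians truncated to each instrument's range.
#'
#' @param config an `idscn_sim_config`.
#' @param cohort the matching `idscn_cohort`.
#' @param sd_scale multiplier on every instrument SD (0 collapses scores to
#'   their group locations; useful for degenerate checks).
#' @return data.frame with subject_id, group and one column per instrument.
#' @export
simulate_behavior <- function(config, cohort, sd_scale = 1) {
  stopifnot(inherits(config, "idscn_sim_config"), inherits(cohort, "idscn_cohort"))
  with_seed(config$seed + 2L, {
    subj <- cohort$subjects
    out <- data.frame(subject_id = subj$subject_id, group = subj$group,
                      stringsAsFactors = FALSE)
    for (nm in names(.behavior_defaults)) {
      def <- .behavior_defaults[[nm]]
      vals <- rep(NA_real_, nrow(subj))
      for (g in c("HC", "SM")) {
        p <- def[[g]]
        if (is.null(p)) next
        idx <- subj$group == g
        vals[idx] <- rtruncnorm(sum(idx), p[1], p[2] * sd_scale,
                                def$range[1], def$range[2])
      }
      out[[nm]] <- vals
    }
    out
  })
}

#' Analytic Cliff's delta for two Gaussian groups
#'
#' For independent X ~ N(mu_a, scale_a^2) and Y ~ N(mu_b, scale_b^2) with
#' shift = mu_a - mu_b, P(X > Y) - P(X < Y) = 2 Phi(shift / sqrt(scale_a^2 +
#' scale_b^2)) - 1. Used to calibrate the metabolite generator against a
#' target effect size.
#'
#' @param shift location difference mu_a - mu_b.
#' @param scale_a,scale_b group SDs (>= 0, not both 0 when shift is 0).
#' @return expected Cliff's delta in [-1, 1].
#' @export
expected_cliffs_delta <- function(shift, scale_a, scale_b) {
  if (scale_a < 0 || scale_b < 0) abort("scales must be >= 0")
  s <- sqrt(scale_a^2 + scale_b^2)
  if (s == 0) {
    if (shift == 0) abort("delta undefined for two identical point masses")
    return(sign(shift))
  }
  2 * stats::pnorm(shift / s) - 1
}

#' Write the four cohort tables as TSV
#'
#' Emits `subjects.tsv` (covariates incl. global mean thickness),
#' `thickness.tsv` (subject x region matrix), `metabolites.tsv` and
#' `behavior.tsv` into `dir`.
#'
#' @param cohort an `idscn_cohort`.
#' @param metabolites,behavior the matching tables (or NULL to skip).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort_tables <- function(cohort, metabolites = NULL, behavior = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(cohort$subjects, "subjects.tsv"))
  thick <- data.frame(subject_id = rownames(cohort$thickness),
                      cohort$thickness, check.names = FALSE,
                      stringsAsFactors = FALSE)
  paths <- c(paths, wr(thick, "thickness.tsv"))
  if (!is.null(metabolites)) paths <- c(paths, wr(metabolites, "metabolites.tsv"))
  if (!is.null(behavior)) paths <- c(paths, wr(behavior, "behavior.tsv"))
  invisible(paths)
}
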