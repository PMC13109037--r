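#' Load thickness and covariate tables into a cohort bundle
#'
#' Reads a subject x region thickness TSV (first column `subject_id`) and a
#' covariate TSV (`subject_id`, `group`, `age`, `sex`, `education`, optionally
#' `global_mean_thickness`), validates alignment, and assembles an
#' `idscn_cohort`. The global mean thickness is computed as the row mean of
#' the region columns when the covariate file does not provide it.
#'
#' @param path thickness TSV path.
#' @param covariate_path covariate TSV path.
#' @return an `idscn_cohort`.
#' @export
load_thickness_table <- function(path, covariate_path) {
  for (p in c(path, covariate_path)) if (!file.exists(p)) abort("file not found: %s", p)
  thick_df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cov <- utils::read.delim(covariate_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(thick_df)) abort("thickness table lacks a subject_id column")
  need <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(need, names(cov))
  if (length(miss)) abort("covariate table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(thick_df$subject_id))
    abort("duplicate subject IDs in thickness table: %s",
          paste(unique(thick_df$subject_id[duplicated(thick_df$subject_id)]), collapse = ", "))
  if (anyDuplicated(cov$subject_id))
    abort("duplicate subject IDs in covariate table: %s",
          paste(unique(cov$subject_id[duplicated(cov$subject_id)]), collapse = ", "))
  only_t <- setdiff(thick_df$subject_id, cov$subject_id)
  only_c <- setdiff(cov$subject_id, thick_df$subject_id)
  if (length(only_t) || length(only_c))
    abort("subject IDs do not align across files (thickness-only: %s; covariate-only: %s)",
          paste(only_t, collapse = ","), paste(only_c, collapse = ","))
  region_cols <- setdiff(names(thick_df), "subject_id")
  if (!length(region_cols)) abort("thickness table has no region columns")
  mat <- as.matrix(thick_df[region_cols])
  if (!is.numeric(mat)) abort("non-numeric cells in region columns")
  rownames(mat) <- thick_df$subject_id
  cov <- cov[match(thick_df$subject_id, cov$subject_id), , drop = FALSE]
  if (!"global_mean_thickness" %in% names(cov))
    cov$global_mean_thickness <- rowMeans(mat)
  rownames(cov) <- NULL
  if (length(unique(cov$group)) != 2)
    abort("group must have exactly two levels, found: %s",
          paste(unique(cov$group), collapse = ", "))
  structure(list(subjects = cov, thickness = mat), class = "idscn_cohort")
}

#' Residualize regional thickness on nuisance covariates
#'
#' Per region, fits ordinary least squares of thickness on intercept, age,
#' sex, education and global mean cortical thickness using the subjects in
#' `fit_group` (by default the healthy-control reference), then computes
#' residuals for all subjects from those coefficients — the normative-model
#' convention where cases are referenced to a model of typical covariate
#' effects.
#'
#' @param cohort an `idscn_cohort`.
#' @param fit_group group label whose subjects define the regression fit
#'   (default "HC"), or "all" to fit on everyone.
#' @param covariates covariate columns entering the design (default age, sex,
#'   education, global_mean_thickness).
#' @return subjects x regions residual matrix.
#' @export
residualize_thickness <- function(cohort, fit_group = "HC",
                                  covariates = c("age", "sex", "education",
                                                 "global_mean_thickness")) {
  stopifnot(inherits(cohort, "idscn_cohort"))
  subj <- cohort$subjects
  miss <- setdiff(covariates, names(subj))
  if (length(miss)) abort("missing covariate column(s): %s", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(subj[covariates]))
  if (anyNA(X)) abort("covariates contain missing values")
  fit_idx <- if (identical(fit_group, "all")) rep(TRUE, nrow(subj)) else subj$group == fit_group
  if (!any(fit_idx)) abort("fit_group '%s' selects no subjects", fit_group)
  if (sum(fit_idx) <= ncol(X)) abort("fewer fit subjects (%d) than regressors (%d)",
                                     sum(fit_idx), ncol(X))
  Xf <- X[fit_idx, , drop = FALSE]
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    abort("rank-deficient covariate design; offending column(s): %s",
          paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, cohort$thickness[fit_idx, , drop = FALSE])
  res <- cohort$thickness - X %*% beta
  dimnames(res) <- dimnames(cohort$thickness)
  res
}

#' Standardize residuals against the healthy-control reference
#'
#' z[k, i] = (res[k, i] - mean_HC,i) / sd_HC,i with the sample (n-1) SD taken
#' over the reference subjects. For reference subjects whose residuals come
#' from a fit on that same group, each region's reference column has mean 0
#' and SD 1 by construction.
#'
#' @param residuals subjects x regions residual matrix.
#' @param hc_mask logical vector marking the reference (healthy-control)
#'   subjects.
#' @return an `idscn_zscores`: list with `z` (matrix), `ref_mean`, `ref_sd`.
#' @export
zscore_to_reference <- function(residuals, hc_mask) {
  stopifnot(is.matrix(residuals), is.logical(hc_mask),
            length(hc_mask) == nrow(residuals))
  if (sum(hc_mask) < 3) abort("need at least 3 reference subjects")
  ref <- residuals[hc_mask, , drop = FALSE]
  m <- colMeans(ref)
  s <- apply(ref, 2, stats::sd)
  zero <- which(s <= 0 | !is.finite(s))
  if (length(zero))
    abort("zero reference SD in region(s): %s",
          paste(colnames(residuals)[zero], collapse = ", "))
  z <- sweep(sweep(residuals, 2, m), 2, s, "/")
  structure(list(z = z, ref_mean = m, ref_sd = s), class = "idscn_zscores")
}
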