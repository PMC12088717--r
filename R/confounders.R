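# Confounder analysis: cohort characteristic tests and standardized-beta
# linear regression of per-subject DSC scores on covariates.

.numeric_covariate_cols <- function(df) {
  drop <- c("subject_id", "group", "sex")
  nms <- setdiff(names(df), drop)
  nms[vapply(df[nms], is.numeric, logical(1))]
}

#' Z-score covariate columns
#'
#' Each retained numeric column is centred and scaled to unit sample SD
#' (n - 1 convention); zero-variance columns are flagged and dropped rather
#' than fitted. Binary covariates are standardized like numeric ones.
#'
#' @param table Covariate data frame.
#' @return Data frame of z-scored columns with attribute `dropped` naming any
#'   zero-variance columns.
#' @export
standardize_covariates <- function(table) {
  cols <- .numeric_covariate_cols(table)
  out <- list(); dropped <- character()
  for (nm in cols) {
    s <- stats::sd(table[[nm]])
    if (is.na(s) || s == 0) { dropped <- c(dropped, nm); next }
    out[[nm]] <- (table[[nm]] - mean(table[[nm]])) / s
  }
  res <- as.data.frame(out)
  attr(res, "dropped") <- dropped
  res
}

#' Standardized-beta regression of DSC scores on covariates
#'
#' Ordinary least squares of per-subject DSC on all covariates jointly (one
#' model, no selection), reported as standardized beta coefficients
#' (`coefficient * SD(covariate) / SD(DSC)`) with two-sided coefficient
#' p-values. Zero-variance covariates are noted and excluded; covariates
#' dropped by the fit for rank deficiency are flagged. A per-covariate
#' univariate mode is available for comparison.
#'
#' @param dsc Per-subject DSC scores.
#' @param covariates Covariate data frame (same row order as `dsc`).
#' @param mode `"joint"` (default) or `"univariate"`.
#' @return A `regression_report`: data frame with `covariate`, `beta_std`,
#'   `p_value`, plus a `notes` attribute listing inestimable covariates.
#' @export
fit_dsc_regression <- function(dsc, covariates, mode = c("joint", "univariate")) {
  mode <- match.arg(mode)
  z <- standardize_covariates(covariates)
  notes <- character()
  if (length(attr(z, "dropped")))
    notes <- paste0("zero variance, not fitted: ", attr(z, "dropped"))
  if (nrow(z) <= ncol(z) + 1 && mode == "joint")
    stop("need more subjects than covariates + 1")
  sd_y <- stats::sd(dsc)
  rows <- list()
  if (mode == "joint") {
    dat <- data.frame(.dsc = dsc, z)
    fit <- stats::lm(.dsc ~ ., data = dat)
    sm <- summary(fit)$coefficients
    for (nm in names(z)) {
      if (!nm %in% rownames(sm)) {
        notes <- c(notes, paste0("rank deficient, not estimable: ", nm))
        rows[[nm]] <- data.frame(covariate = nm, beta_std = NA_real_,
                                 p_value = NA_real_)
        next
      }
      rows[[nm]] <- data.frame(covariate = nm,
                               beta_std = sm[nm, "Estimate"] / sd_y,
                               p_value = sm[nm, "Pr(>|t|)"])
    }
  } else {
    for (nm in names(z)) {
      fit <- stats::lm(dsc ~ x, data = data.frame(dsc = dsc, x = z[[nm]]))
      sm <- summary(fit)$coefficients
      rows[[nm]] <- data.frame(covariate = nm,
                               beta_std = sm["x", "Estimate"] / sd_y,
                               p_value = sm["x", "Pr(>|t|)"])
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "notes") <- notes
  class(rep) <- c("regression_report", class(rep))
  rep
}

#' Per-covariate group means, SDs, and two-tailed t-tests
#'
#' Cohort-characteristics table: for every numeric covariate, the mean (SD)
#' per group and a two-tailed Student's t-test p-value, flagged significant
#' at p < 0.05.
#'
#' @param covariates Cohort covariate data frame with a `group` column.
#' @return Data frame with per-group mean/SD, `p_value`, `significant`.
#' @export
cohort_characteristic_tests <- function(covariates) {
  stopifnot(all(c("A", "B") %in% covariates$group))
  cols <- .numeric_covariate_cols(covariates)
  rows <- lapply(cols, function(nm) {
    xa <- covariates[[nm]][covariates$group == "A"]
    xb <- covariates[[nm]][covariates$group == "B"]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb))
        return(data.frame(covariate = nm, mean_a = mean(xa), sd_a = 0,
                          mean_b = mean(xb), sd_b = 0, p_value = 1,
                          significant = FALSE))
      stop("zero variance in both groups for ", nm)
    }
    p <- stats::t.test(xa, xb, var.equal = TRUE)$p.value
    data.frame(covariate = nm, mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb), p_value = p,
               significant = p < 0.05)
  })
  do.call(rbind, rows)
}

#' Simulate per-subject DSC outcomes from a known covariate mechanism
#'
#' A mechanism-level outcome generator for validating the confounder
#' regression: each subject's DSC is `base + sum_j effect_j * z_j + noise`,
#' where `z_j` is the z-scored covariate and `effects` are the injected
#' (approximately standardized) coefficients, clamped to (0, 1). Recovering
#' the signs and magnitudes of `effects` with [fit_dsc_regression()] is then
#' a check with ground truth known by construction.
#'
#' @param covariates Covariate data frame.
#' @param effects Named numeric vector of injected effects (names must be
#'   covariate columns); covariates not named get effect 0.
#' @param base Baseline DSC.
#' @param noise_sd Residual SD.
#' @return Numeric DSC vector.
#' @export
simulate_dsc_outcomes <- function(covariates, effects, base = 0.85,
                                  noise_sd = 0.05) {
  z <- standardize_covariates(covariates)
  stopifnot(all(names(effects) %in% names(z)))
  mu <- rep(base, nrow(z))
  for (nm in names(effects)) mu <- mu + effects[[nm]] * z[[nm]]
  pmin(pmax(mu + stats::rnorm(nrow(z), 0, noise_sd), 1e-3), 1 - 1e-3)
}
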