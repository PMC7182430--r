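# Quantification: external standard curves, standard addition,
# class composition, sphingolipid/ergosterol ratio statistics, and
# lipids-per-SMALP stoichiometry.

.check_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("conc_pmol_per_ul", "area") %in% names(series)))
  if (nrow(series) < 3L) stop("a standard series needs at least 3 points")
  conc <- series$conc_pmol_per_ul
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  if (stats::var(conc) == 0) stop("zero concentration variance")
  invisible(series)
}

#' Fit an external standard curve
#'
#' Ordinary least squares of peak area on spiked concentration. The fit
#' is not forced through the origin, so a constant instrument background
#' lands in the intercept. A linearity flag is raised when R-squared
#' drops below 0.98.
#'
#' @param series `standard_series` data.frame (columns
#'   `conc_pmol_per_ul`, `area`).
#' @return `curve_fit` list: slope (area per pmol/ul), intercept,
#'   r_squared, se_slope, se_intercept, covariance, n, flag.
#' @export
fit_external_curve <- function(series) {
  .check_series(series)
  fit <- stats::lm(area ~ conc_pmol_per_ul, data = series)
  # noiseless fixtures trigger the cosmetic "essentially perfect fit"
  # warning from summary.lm; a perfect calibration line is fine here
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(sm)
  slope <- cf["conc_pmol_per_ul", "Estimate"]
  if (abs(slope) < 1e-9 * max(1, mean(abs(series$area)))) {
    stop("degenerate series: zero slope (all areas equal?)")
  }
  vc <- suppressWarnings(stats::vcov(fit))
  structure(list(slope = slope,
                 intercept = cf["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 se_slope = cf["conc_pmol_per_ul", "Std. Error"],
                 se_intercept = cf["(Intercept)", "Std. Error"],
                 covariance = vc["(Intercept)", "conc_pmol_per_ul"],
                 n = nrow(series),
                 flag = if (sm$r.squared < 0.98) "nonlinear" else ""),
            class = "curve_fit")
}

#' Concentration from an external curve
#'
#' Inverts the calibration line: (area - intercept) / slope, floored at
#' zero (with a warning) when the area falls below the blank.
#'
#' @param area Peak area(s).
#' @param fit `curve_fit` from [fit_external_curve()].
#' @return Concentration(s) in pmol/ul.
#' @export
quantify_by_curve <- function(area, fit) {
  if (fit$slope <= 0) stop("non-positive calibration slope")
  conc <- (area - fit$intercept) / fit$slope
  if (any(conc < 0)) {
    warning("area below calibration intercept; concentration floored at 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Standard-addition quantification
#'
#' Fits area against spiked concentration and extrapolates the response
#' line to the x-axis: the endogenous concentration is the magnitude of
#' the x-intercept, intercept/slope. The standard error follows from
#' first-order propagation of the OLS coefficient covariance.
#'
#' @param series Addition-kind `standard_series` (areas include the
#'   endogenous analyte at every spike level).
#' @return List: `endogenous` (pmol/ul), `se`, `fit`.
#' @export
standard_addition <- function(series) {
  fit <- fit_external_curve(series)
  if (fit$slope <= 0) stop("non-positive slope in standard-addition series")
  b0 <- fit$intercept; b1 <- fit$slope
  if (b0 < 0) {
    warning("negative intercept: endogenous concentration reported as 0")
    return(list(endogenous = 0, se = NA_real_, fit = fit))
  }
  x0 <- b0 / b1
  # var(b0/b1) to first order
  se <- sqrt((fit$se_intercept / b1)^2 +
               (b0 * fit$se_slope / b1^2)^2 -
               2 * b0 * fit$covariance / b1^3)
  list(endogenous = x0, se = se, fit = fit)
}

#' Calibrate per-class conversion factors
#'
#' Standard addition (a true internal-standard method) is used to
#' correct external-curve estimates for matrix effects: the factor is
#' the ratio of the standard-addition estimate to the external-curve
#' estimate for the same analyte, and is applied per class.
#'
#' @param external_estimate External-curve concentration (pmol/ul).
#' @param addition_estimate Standard-addition concentration (pmol/ul).
#' @return Multiplicative correction factor.
#' @export
conversion_factor <- function(external_estimate, addition_estimate) {
  if (external_estimate <= 0) stop("external estimate must be positive")
  addition_estimate / external_estimate
}

#' Class composition in mol%
#'
#' Normalizes absolutely-quantified species to mol% per lipid class.
#' Species flagged `relative_only` (sphingolipids, for which no
#' synthetic standards exist) are excluded from the denominator.
#'
#' @param quants data.frame with columns `class`, `pmol`, and optional
#'   logical `relative_only`.
#' @return data.frame `class`, `mol_percent` (sums to 100).
#' @export
class_composition <- function(quants) {
  stopifnot(all(c("class", "pmol") %in% names(quants)))
  if (any(quants$pmol < 0)) stop("negative pmol")
  keep <- if ("relative_only" %in% names(quants)) !quants$relative_only
          else rep(TRUE, nrow(quants))
  q <- quants[keep, , drop = FALSE]
  tot <- tapply(q$pmol, q$class, sum)
  if (sum(tot) == 0) stop("all-zero class totals")
  out <- data.frame(class = names(tot),
                    mol_percent = 100 * as.numeric(tot) / sum(tot),
                    stringsAsFactors = FALSE)
  out[order(-out$mol_percent), , drop = FALSE]
}

#' Pooled two-sample Student's t-test
#'
#' Closed-form equal-variance two-tailed Student's t with
#' df = n_a + n_b - 2; `welch = TRUE` switches to the
#' Welch-Satterthwaite form.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use unequal-variance Welch test instead.
#' @return List: `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    sed2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(sed2)
    df <- sed2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (!is.finite(t)) { t <- 0; }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Sphingolipid / ergosterol ratio report for two membrane domains
#'
#' Computes per-replicate IPC/ergosterol and MIPC/ergosterol peak-area
#' ratios for an MCP group and an MCC group (ergosterol as internal
#' control, since sphingolipid standards are unavailable), group means
#' with SEM, the MCP/MCC fold change of each ratio, and a two-tailed
#' pooled Student's t-test. Significance labels: `**` for p < 0.005,
#' `ns` otherwise.
#'
#' @param mcp_samples,mcc_samples data.frames with replicate peak areas
#'   in columns `ipc`, `mipc`, `erg` (>= 2 rows each).
#' @return `ratio_report`: per-lipid list with replicate ratios, means,
#'   SEM, `fold_change` (mean MCP / mean MCC), `t`, `df`, `p`, `label`.
#' @export
sphingolipid_ratio_report <- function(mcp_samples, mcc_samples) {
  for (g in list(mcp_samples, mcc_samples)) {
    stopifnot(all(c("ipc", "mipc", "erg") %in% names(g)))
    if (nrow(g) < 2L) stop("each group needs at least 2 replicates")
    if (any(g$erg <= 0)) stop("zero ergosterol area in a replicate")
  }
  one <- function(col) {
    r_mcp <- mcp_samples[[col]] / mcp_samples$erg
    r_mcc <- mcc_samples[[col]] / mcc_samples$erg
    tt <- two_sample_ttest(r_mcp, r_mcc)
    list(ratios_mcp = r_mcp, ratios_mcc = r_mcc,
         mean_mcp = mean(r_mcp), sem_mcp = .sem(r_mcp),
         mean_mcc = mean(r_mcc), sem_mcc = .sem(r_mcc),
         fold_change = mean(r_mcp) / mean(r_mcc),
         t = tt$t, df = tt$df, p = tt$p,
         label = if (tt$p < 0.005) "**" else "ns")
  }
  structure(list(ipc_erg = one("ipc"), mipc_erg = one("mipc")),
            class = "ratio_report")
}

#' Lipids per SMALP
#'
#' Molar ratio of quantified lipid to input protein assuming a 1:1
#' SMALP-to-protein stoichiometry; reported rounded to the nearest
#' integer.
#'
#' @param total_lipid_pmol Summed absolutely-quantified lipid (pmol).
#' @param protein_pmol Input protein (pmol), > 0.
#' @return List: `ratio` (exact), `lipids_per_smalp` (integer).
#' @export
lipids_per_smalp <- function(total_lipid_pmol, protein_pmol) {
  if (protein_pmol <= 0) stop("protein amount must be positive")
  if (total_lipid_pmol < 0) stop("negative lipid amount")
  r <- total_lipid_pmol / protein_pmol
  list(ratio = r, lipids_per_smalp = as.integer(round(r)))
}
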