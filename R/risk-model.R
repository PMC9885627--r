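#' Multivariable logistic risk model
#'
#' Joint maximum-likelihood logistic regression of case status on genotype
#' indicators and lifestyle covariates (age class, smoking, drinking,
#' infection, ...), reporting per-term odds ratios with 95% Wald intervals
#' and p-values — the numbers behind a forest plot.
#'
#' @param data data.frame with a `status` column (`"case"`/`"control"`) and
#'   the covariates.
#' @param terms character vector of covariate column names; default all
#'   columns except `status`.
#' @return data.frame with one row per term: `term`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`; attributes `n` and `converged`.
#' @examples
#' cv <- simulateCovariates(
#'   data.frame(name = "smoking", prevalence = 0.3, beta = log(2)),
#'   baseline = -0.5, n = 2000, seed = 7)
#' fitRiskModel(cv)
#' @export
fitRiskModel <- function(data, terms = setdiff(names(data), "status")) {
  stopifnot("status" %in% names(data), length(terms) >= 1)
  y <- as.integer(data$status == "case")
  if (all(y == 1) || all(y == 0))
    stop("both cases and controls are required")
  X <- stats::model.matrix(
    stats::reformulate(terms), data = data)
  if (qr(X)$rank < ncol(X)) {
    const <- terms[vapply(terms, function(t) {
      v <- data[[t]]
      length(unique(v[!is.na(v)])) < 2
    }, logical(1))]
    stop("design matrix rank-deficient",
         if (length(const)) paste0(" (zero-variance terms: ",
                                   paste(const, collapse = ", "), ")"))
  }
  fit <- suppressWarnings(
    glm(stats::reformulate(terms, response = "y"),
        data = cbind(data, y = y), family = binomial(),
        control = list(epsilon = 1e-10, maxit = 25)))
  probs <- fitted(fit)
  if (all(probs < 1e-8 | probs > 1 - 1e-8)) {
    stop("complete separation in risk model (terms: ",
         paste(terms, collapse = ", "), ")")
  }
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  out <- data.frame(term = rownames(co), beta = co[, 1], se = co[, 2],
                    or = exp(co[, 1]),
                    ci_low = exp(co[, 1] - 1.96 * co[, 2]),
                    ci_high = exp(co[, 1] + 1.96 * co[, 2]),
                    p = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- length(y)
  attr(out, "converged") <- fit$converged
  out
}

#' Genotype-stratified risk models
#'
#' Refits the multivariable risk model separately within each level of a
#' stratifying variable (typically the genotype at a focal SNP), so that
#' covariate odds ratios can be compared across genotype strata. Strata
#' lacking either outcome are skipped with a warning.
#'
#' @param data data.frame with `status`, the stratifying column and the
#'   covariates.
#' @param stratum name of the stratifying column.
#' @param terms covariate names; default all columns except `status` and
#'   the stratum.
#' @return named list of per-stratum fits (as in [fitRiskModel()]).
#' @export
stratifiedRisk <- function(data, stratum,
                           terms = setdiff(names(data), c("status", stratum))) {
  stopifnot(stratum %in% names(data))
  out <- list()
  for (lv in unique(data[[stratum]])) {
    sub <- data[data[[stratum]] == lv, , drop = FALSE]
    if (length(unique(sub$status)) < 2) {
      warning("stratum '", lv, "' lacks both outcomes; skipped")
      next
    }
    fit <- tryCatch(fitRiskModel(sub, terms), error = function(e) {
      warning("stratum '", lv, "': ", conditionMessage(e)); NULL
    })
    if (!is.null(fit)) out[[as.character(lv)]] <- fit
  }
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the score thresholds (descending over distinct values) to produce
#' the operating points (FPR, TPR), and computes the AUC as the
#' Mann-Whitney concordance probability (ties count one half), which equals
#' the trapezoidal area under the curve exactly.
#'
#' @param scores numeric risk scores, higher = more case-like.
#' @param labels case indicator: logical, 0/1, or `"case"`/`"control"`.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`, both
#'   monotone nondecreasing), `auc`, `n_case`, `n_control`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))$auc  # 1
#' @export
rocCurve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "case"
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  # Mann-Whitney concordance via midranks; identical to the trapezoid area
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(curve = curve, auc = auc, n_case = n1, n_control = n0)
}

#' Multi-SNP diagnostic model with ROC/AUC
#'
#' Fits a joint logistic model of case status on several SNP dosage
#' columns, scores every sample by the linear predictor, and evaluates the
#' diagnostic efficiency of the score by ROC/AUC.
#'
#' @param data data.frame with `status` and the SNP dosage columns.
#' @param snps character vector of SNP column names; default all columns
#'   except `status`.
#' @return list with `fit` (per-term table as in [fitRiskModel()]),
#'   `scores`, and `roc` (as in [rocCurve()], including `$auc`).
#' @export
multiSNPDiagnostic <- function(data, snps = setdiff(names(data), "status")) {
  fit <- fitRiskModel(data, snps)
  X <- stats::model.matrix(stats::reformulate(snps), data = data)
  beta <- fit$beta[match(colnames(X)[-1], fit$term)]
  scores <- as.vector(X[, -1, drop = FALSE] %*% beta)
  roc <- rocCurve(scores, data$status)
  list(fit = fit, scores = scores, roc = roc)
}

#' Cholesterol concentration from a colorimetric assay
#'
#' Converts optical densities to a protein-normalized cholesterol
#' concentration:
#' `(OD_sample - OD_blank) / (OD_calibrator - OD_blank) * calibratorConc /
#' proteinConc`.
#'
#' @param odSample,odBlank,odCalibrator optical densities of the sample,
#'   blank and calibrator wells.
#' @param calibratorConc calibrator concentration (e.g. mmol/L).
#' @param proteinConc protein concentration of the sample (e.g. mg/ml);
#'   must be positive.
#' @return concentration per unit protein.
#' @examples
#' cholesterolConcentration(0.30, 0.05, 0.55, 5.17, 2.0)  # 1.2925
#' @export
cholesterolConcentration <- function(odSample, odBlank, odCalibrator,
                                     calibratorConc, proteinConc) {
  if (any(odCalibrator == odBlank))
    stop("calibrator and blank OD are equal: zero denominator")
  if (any(proteinConc <= 0)) stop("protein concentration must be positive")
  (odSample - odBlank) / (odCalibrator - odBlank) * calibratorConc / proteinConc
}
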