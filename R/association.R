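#' Genotype-to-score coding under a genetic model
#'
#' Additive counts minor alleles (0,1,2); dominant scores carriers (0,1,1);
#' recessive scores minor homozygotes (0,0,1). Missing dosages propagate as
#' `NA`.
#'
#' @param dosage integer vector of minor-allele dosages (0/1/2/`NA`).
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return numeric vector of coded scores.
#' @examples
#' codeGenotypes(c(0, 1, 2, NA), "dominant")
#' @export
codeGenotypes <- function(dosage, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  if (any(!dosage %in% c(0, 1, 2, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  map <- switch(model,
                additive = c(0, 1, 2),
                dominant = c(0, 1, 1),
                recessive = c(0, 0, 1))
  map[dosage + 1]
}

.modelScores <- function(model)
  switch(model, additive = c(0, 1, 2), dominant = c(0, 1, 1),
         recessive = c(0, 0, 1))

#' Unadjusted logistic association fit for one variant
#'
#' Fits `status ~ coded genotype` by maximum likelihood (iteratively
#' reweighted least squares via [stats::glm]) either from a 2x3
#' case/control genotype count table or from per-sample dosage/status
#' vectors, and reports the per-unit log-odds, its Wald standard error, the
#' odds ratio `exp(beta)` with 95% Wald interval `exp(beta +/- 1.96 SE)`,
#' and the Wald p-value. When the minor-homozygote cell is empty in both
#' groups the additive MLE coincides with the closed-form 2x2 cross-product
#' odds ratio.
#'
#' Empty genotype cells and separated fits are flagged rather than silently
#' reported; complete separation is an error naming the variant.
#'
#' @param caseCounts,controlCounts length-3 genotype count vectors
#'   `(major_hom, het, minor_hom)`; alternatively supply `dosage` and
#'   `status`.
#' @param dosage,status per-sample minor-allele dosage and
#'   `"case"`/`"control"` status (missing dosages dropped, complete-case).
#' @param model genetic model, see [codeGenotypes()].
#' @param variant optional variant id used in messages and output.
#' @return one-row data.frame: `variant`, `model`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p_wald`, `p_trend` (additive trend test, `NA`
#'   unless counts given), `maf_case`, `maf_control`, `flag`.
#' @examples
#' fitGenotypeLogistic(c(169, 22, 0), c(185, 99, 0))
#' @export
fitGenotypeLogistic <- function(caseCounts = NULL, controlCounts = NULL,
                                dosage = NULL, status = NULL,
                                model = c("additive", "dominant", "recessive"),
                                variant = NA_character_) {
  model <- match.arg(model)
  if (is.null(caseCounts)) {
    stopifnot(!is.null(dosage), !is.null(status))
    ok <- !is.na(dosage)
    dosage <- dosage[ok]; status <- status[ok]
    caseCounts <- tabulate(dosage[status == "case"] + 1L, 3L)
    controlCounts <- tabulate(dosage[status == "control"] + 1L, 3L)
  }
  stopifnot(length(caseCounts) == 3, length(controlCounts) == 3,
            all(caseCounts >= 0), all(controlCounts >= 0))
  R <- sum(caseCounts); S <- sum(controlCounts)
  if (R == 0 || S == 0)
    stop("both cases and controls are required (variant ", variant, ")")
  x <- .modelScores(model)
  flag <- character(0)
  # collapse to the distinct score levels actually observed
  w <- c(caseCounts, controlCounts)
  y <- rep(c(1, 0), each = 3)
  xx <- rep(x, 2)
  keep <- w > 0
  if (length(unique(xx[keep])) < 2) {
    # no variation in the coded genotype: undefined slope
    return(data.frame(variant = variant, model = model, beta = NA_real_,
                      se = NA_real_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_wald = NA_real_,
                      p_trend = cochranArmitageTrend(caseCounts, controlCounts)$p,
                      maf_case = computeMAF(caseCounts),
                      maf_control = computeMAF(controlCounts),
                      flag = "degenerate", stringsAsFactors = FALSE))
  }
  # complete separation: some score level all-case and another all-control
  caseRate <- vapply(unique(xx[keep]), function(v) {
    i <- keep & xx == v
    sum(w[i & y == 1]) / sum(w[i])
  }, numeric(1))
  if (all(caseRate %in% c(0, 1)))
    stop("complete separation for variant ", variant)
  if (any(caseRate %in% c(0, 1))) flag <- c(flag, "quasi_separation")
  if (caseCounts[3] == 0 && controlCounts[3] == 0) flag <- c(flag, "zero_cell")
  fit <- suppressWarnings(
    glm(y ~ xx, family = binomial(), weights = w,
        control = list(epsilon = 1e-10, maxit = 25)))
  if (!fit$converged) flag <- c(flag, "non_convergence")
  # Newton refinement of the IRLS solution to score ~ 0 at machine
  # precision, with the Wald SE from the exact observed information
  th <- coef(fit)
  X <- cbind(1, xx)
  info <- NULL
  for (it in 1:10) {
    mu <- as.vector(plogis(X %*% th))
    info <- crossprod(X, X * (w * mu * (1 - mu)))
    step <- solve(info, crossprod(X, w * (y - mu)))
    th <- th + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  beta <- unname(th[2])
  se <- sqrt(solve(info)[2, 2])
  data.frame(variant = variant, model = model, beta = beta, se = se,
             or = exp(beta), ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p_wald = 2 * pnorm(-abs(beta / se)),
             p_trend = cochranArmitageTrend(caseCounts, controlCounts)$p,
             maf_case = computeMAF(caseCounts),
             maf_control = computeMAF(controlCounts),
             flag = paste(flag, collapse = ";"), stringsAsFactors = FALSE)
}

#' Cochran-Armitage trend test
#'
#' Score test for a linear trend in case proportion across genotype classes
#' with scores `x = (0, 1, 2)`:
#' `chi2 = N (N sum(x_i r_i) - R sum(x_i n_i))^2 /
#'   (R (N - R) (N sum(x_i^2 n_i) - (sum(x_i n_i))^2))`
#' where `r_i` are case counts, `n_i` column totals, `R` total cases and `N`
#' the grand total. The two-sided p-value is the upper tail of chi-square
#' with 1 df.
#'
#' @param caseCounts,controlCounts length-3 genotype count vectors.
#' @param scores genotype scores (default `0:2`).
#' @return list with `chisq`, `p`, and `flag` (`"degenerate"` when all
#'   observations fall in one genotype class, in which case `p = 1`).
#' @examples
#' cochranArmitageTrend(c(169, 22, 0), c(185, 99, 0))$p  # 1.04e-08
#' @export
cochranArmitageTrend <- function(caseCounts, controlCounts, scores = 0:2) {
  stopifnot(length(caseCounts) == length(controlCounts),
            length(scores) == length(caseCounts),
            all(caseCounts >= 0), all(controlCounts >= 0))
  r <- caseCounts; n <- caseCounts + controlCounts
  N <- sum(n); R <- sum(r)
  if (N == 0) stop("empty table")
  den <- R * (N - R) * (N * sum(scores^2 * n) - sum(scores * n)^2)
  if (den <= 0)
    return(list(chisq = 0, p = 1, flag = "degenerate"))
  chisq <- N * (N * sum(scores * r) - R * sum(scores * n))^2 / den
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       flag = "")
}

#' Per-variant association scan
#'
#' Runs [fitGenotypeLogistic()] and [cochranArmitageTrend()] on every
#' variant of a (QC'd) [GenotypeData-class] object and attaches
#' quantile-quantile data and the genomic inflation factor
#' `lambda = median(chi2) / 0.4549` (the null median of a 1-df chi-square).
#'
#' @param gd a [GenotypeData-class] object.
#' @param model genetic model.
#' @param samples optional character vector restricting the scan to a
#'   sample subset (e.g. the training split).
#' @return data.frame with one row per variant (columns as in
#'   [fitGenotypeLogistic()] plus `chisq_trend`, `chrom`, `pos`), with
#'   attributes `lambda` (numeric) and `qq` (data.frame of `expected` and
#'   `observed` -log10 p quantiles, Manhattan-ready).
#' @export
runAssociationScan <- function(gd, model = c("additive", "dominant", "recessive"),
                               samples = NULL) {
  model <- match.arg(model)
  if (!is.null(samples)) gd <- gd[, colnames(gd) %in% samples]
  if (nrow(gd) == 0) {
    out <- data.frame()
    attr(out, "lambda") <- NA_real_
    attr(out, "qq") <- data.frame(expected = numeric(0), observed = numeric(0))
    return(out)
  }
  d <- dosages(gd)
  cc <- isCase(gd)
  vi <- variantInfo(gd)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    rc <- tabulate(d[i, cc][!is.na(d[i, cc])] + 1L, 3L)
    sc <- tabulate(d[i, !cc][!is.na(d[i, !cc])] + 1L, 3L)
    ca <- cochranArmitageTrend(rc, sc)
    res <- tryCatch(
      fitGenotypeLogistic(rc, sc, model = model, variant = rownames(d)[i]),
      error = function(e) data.frame(
        variant = rownames(d)[i], model = model, beta = NA_real_,
        se = NA_real_, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_wald = NA_real_, p_trend = ca$p,
        maf_case = suppressWarnings(computeMAF(rc)),
        maf_control = suppressWarnings(computeMAF(sc)),
        flag = "separation", stringsAsFactors = FALSE))
    res$chisq_trend <- ca$chisq
    res
  })
  out <- do.call(rbind, rows)
  out$chrom <- if ("chrom" %in% names(vi)) as.character(vi$chrom) else NA_character_
  out$pos <- if ("pos" %in% names(vi)) vi$pos else NA_integer_
  chis <- out$chisq_trend[!is.na(out$chisq_trend)]
  attr(out, "lambda") <- if (length(chis)) median(chis) / 0.4549364 else NA_real_
  p <- sort(out$p_trend[!is.na(out$p_trend)])
  attr(out, "qq") <- data.frame(
    expected = -log10(stats::ppoints(length(p))),
    observed = rev(-log10(p)))
  out
}

#' Training / validation / combined association workflow
#'
#' Ranks variants by the training-set association p-value (trend p for the
#' additive model, Wald p otherwise; ties broken by genomic position),
#' carries the top `topK` into the validation set, retains those with
#' validation p below `alpha`, and recomputes association statistics for
#' the retained variants on the combined sample.
#'
#' @param gd a [GenotypeData-class] whose `colData` has a `split` column
#'   with values `"train"` and `"valid"`.
#' @param model genetic model.
#' @param topK number of top training hits carried forward (default 5).
#' @param alpha validation significance level (default 0.05).
#' @return list with `training` (full training scan), `top` (the top-K
#'   training rows), `validation` (their validation statistics),
#'   `validated` (ids retained), and `combined` (combined-set statistics
#'   for the retained variants).
#' @export
trainValidateCombine <- function(gd, model = c("additive", "dominant", "recessive"),
                                 topK = 5, alpha = 0.05) {
  model <- match.arg(model)
  split <- sampleInfo(gd)$split
  if (is.null(split) || !all(c("train", "valid") %in% split))
    stop("colData 'split' must assign both 'train' and 'valid' samples")
  train <- colnames(gd)[split == "train"]
  valid <- colnames(gd)[split == "valid"]
  pcol <- if (model == "additive") "p_trend" else "p_wald"
  scanTrain <- runAssociationScan(gd, model, samples = train)
  if (topK > nrow(scanTrain)) {
    warning("fewer variants than topK; using all ", nrow(scanTrain))
    topK <- nrow(scanTrain)
  }
  ord <- order(scanTrain[[pcol]], scanTrain$chrom, scanTrain$pos,
               scanTrain$variant)
  top <- scanTrain[ord[seq_len(topK)], , drop = FALSE]
  scanValid <- runAssociationScan(gd[rownames(gd) %in% top$variant, ],
                                  model, samples = valid)
  scanValid <- scanValid[match(top$variant, scanValid$variant), , drop = FALSE]
  keep <- !is.na(scanValid[[pcol]]) & scanValid[[pcol]] < alpha
  validated <- top$variant[keep]
  combined <- if (length(validated)) {
    runAssociationScan(gd[rownames(gd) %in% validated, ], model)
  } else {
    data.frame()
  }
  list(training = scanTrain, top = top, validation = scanValid,
       validated = validated, combined = combined)
}
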