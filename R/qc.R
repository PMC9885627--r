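#' Minor-allele frequency from 2x3 genotype counts
#'
#' `MAF = (het + 2 * minor_hom) / (2 * (major_hom + het + minor_hom))`,
#' computed on observed genotypes only (missing entries are excluded before
#' counting).
#'
#' @param counts numeric length-3 vector `(major_hom, het, minor_hom)`, or a
#'   matrix with such rows.
#' @return minor-allele frequency per row; `NA` (with a warning) when no
#'   genotype was observed.
#' @examples
#' computeMAF(c(169, 22, 0))   # 0.0576 -> rounds to 0.058
#' computeMAF(c(25, 50, 25))   # 0.5
#' @export
computeMAF <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  stopifnot(ncol(m) == 3, all(m >= 0, na.rm = TRUE))
  tot <- rowSums(m)
  out <- (m[, 2] + 2 * m[, 3]) / (2 * tot)
  if (any(tot == 0)) {
    warning("all-missing variant: MAF undefined, returning NA")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on a 3-class genotype count vector: given the
#' observed allele counts, all heterozygote counts of compatible parity are
#' enumerated, each assigned its conditional probability, and the p-value is
#' the sum of probabilities not exceeding that of the observed
#' configuration. Valid at arbitrarily small counts where the chi-square
#' approximation is not.
#'
#' @param counts length-3 vector `(major_hom, het, minor_hom)`.
#' @return the exact two-sided p-value.
#' @examples
#' hweExactTest(c(3, 2, 1))
#' hweExactTest(c(50, 0, 0))  # monomorphic: p = 1
#' @export
hweExactTest <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  counts <- as.integer(round(counts))
  N <- sum(counts)
  if (N == 0) stop("no observed genotypes")
  nMinor <- counts[2] + 2L * counts[3]
  nMajor <- 2L * N - nMinor
  nRare <- min(nMinor, nMajor)
  hets <- seq(nRare %% 2L, nRare, by = 2L)
  # log P(het = h | N, allele counts), Levene/Haldane conditional distribution
  logp <- vapply(hets, function(h) {
    homRare <- (nRare - h) / 2
    homCom <- N - h - homRare
    h * log(2) + lgamma(N + 1) -
      lgamma(homRare + 1) - lgamma(h + 1) - lgamma(homCom + 1) +
      lgamma(nMinor + 1) + lgamma(nMajor + 1) - lgamma(2 * N + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pObs <- p[hets == counts[2]]
  min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Reported vs inferred sex concordance check
#'
#' @param meta data.frame with columns `sex` (reported) and optionally
#'   `inferred_sex`; rownames or a `sample_id` column give sample ids.
#' @return character vector of sample ids whose inferred sex is present and
#'   differs from the reported sex. Samples without an inferred sex pass,
#'   with a warning naming how many were unchecked.
#' @export
sampleSexCheck <- function(meta) {
  ids <- if ("sample_id" %in% names(meta)) meta$sample_id else rownames(meta)
  if (!"inferred_sex" %in% names(meta) || all(is.na(meta$inferred_sex))) {
    warning("no inferred sex available; sex check skipped for all samples")
    return(character(0))
  }
  unchecked <- is.na(meta$inferred_sex)
  if (any(unchecked))
    warning(sum(unchecked), " samples lack inferred sex and were not checked")
  bad <- !unchecked & !is.na(meta$sex) & meta$inferred_sex != meta$sex
  ids[bad]
}

#' Ancestry outlier detection by principal components
#'
#' Standardizes the dosage matrix (per-variant mean imputation of missing
#' entries, zero-variance variants dropped), computes sample principal
#' components, and flags samples farther than `kSd` robust standard
#' deviations (MAD about the median) from the centre on PC1 or PC2.
#'
#' @param gd a [GenotypeData-class] object with at least 3 samples and 2
#'   informative variants.
#' @param kSd robust-SD multiplier (default 6).
#' @return character vector of outlying sample ids; empty (with a warning)
#'   when the matrix is degenerate.
#' @export
ancestryOutliers <- function(gd, kSd = 6) {
  d <- t(dosages(gd))  # samples x variants
  if (nrow(d) < 3) stop("need at least 3 samples")
  for (j in seq_len(ncol(d))) {
    mj <- mean(d[, j], na.rm = TRUE)
    d[is.na(d[, j]), j] <- mj
  }
  v <- apply(d, 2, stats::var)
  d <- d[, v > 0 & is.finite(v), drop = FALSE]
  if (ncol(d) < 2) {
    warning("degenerate genotype matrix; no ancestry outliers computable")
    return(character(0))
  }
  pc <- prcomp(d, center = TRUE, scale. = TRUE)$x[, 1:2, drop = FALSE]
  out <- rep(FALSE, nrow(pc))
  for (j in 1:2) {
    ctr <- median(pc[, j])
    s <- mad(pc[, j])
    if (s == 0) s <- stats::sd(pc[, j])
    if (s == 0) next
    out <- out | abs(pc[, j] - ctr) > kSd * s
  }
  rownames(pc)[out]
}

#' QC cascade configuration
#'
#' Thresholds for [applyQC()]. Defaults: SNP and sample call rates 0.95,
#' MAF 0.05, Hardy-Weinberg exact-test alpha 1e-6 computed on controls
#' only, ancestry outlier multiplier 6 robust SDs.
#'
#' @param snpCallRateMin,mafMin,sampleCallRateMin,hweAlpha,ancestrySd
#'   numeric thresholds.
#' @param hweOn `"controls"` (default) or `"all"`: which samples enter the
#'   Hardy-Weinberg test.
#' @return a named list of class `qc_config`.
#' @export
qcConfig <- function(snpCallRateMin = 0.95, mafMin = 0.05,
                     sampleCallRateMin = 0.95, hweAlpha = 1e-6,
                     ancestrySd = 6, hweOn = c("controls", "all")) {
  stopifnot(snpCallRateMin > 0, snpCallRateMin <= 1,
            mafMin >= 0, mafMin < 1,
            sampleCallRateMin > 0, sampleCallRateMin <= 1,
            hweAlpha > 0, hweAlpha < 1, ancestrySd > 0)
  structure(list(snpCallRateMin = snpCallRateMin, mafMin = mafMin,
                 sampleCallRateMin = sampleCallRateMin,
                 hweAlpha = hweAlpha, ancestrySd = ancestrySd,
                 hweOn = match.arg(hweOn)),
            class = "qc_config")
}

.qcStepNames <- c("polymorphic", "sex_mismatch", "autosomes",
                  "snp_call_rate", "maf", "sample_call_rate",
                  "ancestry", "hwe")

#' Apply the eight-step genotype QC cascade
#'
#' Executes, in a fixed order, the standard chip-QC filter sequence:
#' \enumerate{
#'   \item \strong{polymorphic}: drop variants with zero observed minor
#'     alleles;
#'   \item \strong{sex_mismatch}: drop samples whose inferred sex
#'     contradicts the reported sex (see [sampleSexCheck()]);
#'   \item \strong{autosomes}: drop variants on non-autosomal chromosomes
#'     (anything other than 1-22);
#'   \item \strong{snp_call_rate}: drop variants genotyped in fewer than
#'     `snpCallRateMin` of samples;
#'   \item \strong{maf}: drop variants with pooled minor-allele frequency
#'     below `mafMin`;
#'   \item \strong{sample_call_rate}: drop samples genotyped at fewer than
#'     `sampleCallRateMin` of the remaining variants;
#'   \item \strong{ancestry}: drop principal-component ancestry outliers
#'     (see [ancestryOutliers()]);
#'   \item \strong{hwe}: drop variants failing the Hardy-Weinberg exact
#'     test (see [hweExactTest()]) at `hweAlpha`, computed on controls by
#'     default.
#' }
#' Every removal is recorded with its step in a [QCReport-class]; counts
#' are conserved at each step. Re-running the cascade on its own output
#' removes nothing.
#'
#' @param gd a [GenotypeData-class] object.
#' @param config a [qcConfig()] list.
#' @return list with elements `genotypes` (filtered [GenotypeData-class])
#'   and `report` ([QCReport-class]).
#' @export
applyQC <- function(gd, config = qcConfig()) {
  stopifnot(is(gd, "GenotypeData"), inherits(config, "qc_config"))
  steps <- list()
  removed <- list()
  note <- function(step, unit, before, ids) {
    steps[[step]] <<- data.frame(step = step, unit = unit,
                                 n_before = before,
                                 n_removed = length(ids),
                                 n_after = before - length(ids))
    removed[[step]] <<- as.character(ids)
  }
  dropVariants <- function(g, ids) if (length(ids)) g[!rownames(g) %in% ids, ] else g
  dropSamples <- function(g, ids) if (length(ids)) g[, !colnames(g) %in% ids] else g
  checkNonEmpty <- function(g, step) {
    if (nrow(g) == 0 || ncol(g) == 0)
      stop("QC step '", step, "' removed all remaining ",
           if (nrow(g) == 0) "variants" else "samples")
    g
  }

  # 1. polymorphic: zero observed minor alleles (among variants with data)
  d <- dosages(gd)
  obs <- rowSums(!is.na(d))
  minorCount <- rowSums(d, na.rm = TRUE)
  ids <- rownames(d)[obs > 0 & minorCount == 0]
  note("polymorphic", "variant", nrow(gd), ids)
  gd <- checkNonEmpty(dropVariants(gd, ids), "polymorphic")

  # 2. sex mismatch
  ids <- withCallingHandlers(sampleSexCheck(sampleInfo(gd)),
                             warning = function(w) invokeRestart("muffleWarning"))
  note("sex_mismatch", "sample", ncol(gd), ids)
  gd <- checkNonEmpty(dropSamples(gd, ids), "sex_mismatch")

  # 3. autosomes only
  vi <- variantInfo(gd)
  ids <- if ("chrom" %in% names(vi)) {
    rownames(gd)[!(.normChrom(vi$chrom) %in% as.character(1:22))]
  } else character(0)
  note("autosomes", "variant", nrow(gd), ids)
  gd <- checkNonEmpty(dropVariants(gd, ids), "autosomes")

  # 4. SNP call rate
  d <- dosages(gd)
  cr <- rowMeans(!is.na(d))
  ids <- rownames(d)[cr < config$snpCallRateMin]
  note("snp_call_rate", "variant", nrow(gd), ids)
  gd <- checkNonEmpty(dropVariants(gd, ids), "snp_call_rate")

  # 5. MAF (pooled over all samples)
  d <- dosages(gd)
  cnt <- cbind(rowSums(d == 0, na.rm = TRUE), rowSums(d == 1, na.rm = TRUE),
               rowSums(d == 2, na.rm = TRUE))
  maf <- suppressWarnings(computeMAF(cnt))
  ids <- rownames(d)[!is.na(maf) & maf < config$mafMin]
  note("maf", "variant", nrow(gd), ids)
  gd <- checkNonEmpty(dropVariants(gd, ids), "maf")

  # 6. sample call rate
  d <- dosages(gd)
  cr <- colMeans(!is.na(d))
  ids <- colnames(d)[cr < config$sampleCallRateMin]
  note("sample_call_rate", "sample", ncol(gd), ids)
  gd <- checkNonEmpty(dropSamples(gd, ids), "sample_call_rate")

  # 7. ancestry outliers
  ids <- if (nrow(gd) >= 2 && ncol(gd) >= 3) {
    withCallingHandlers(ancestryOutliers(gd, config$ancestrySd),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else character(0)
  note("ancestry", "sample", ncol(gd), ids)
  gd <- checkNonEmpty(dropSamples(gd, ids), "ancestry")

  # 8. Hardy-Weinberg (controls by default)
  d <- dosages(gd)
  keep <- if (config$hweOn == "controls" && any(!isCase(gd)))
    !isCase(gd) else rep(TRUE, ncol(gd))
  sub <- d[, keep, drop = FALSE]
  pv <- apply(sub, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(NA_real_)
    hweExactTest(tabulate(row + 1L, 3L))
  })
  ids <- rownames(d)[!is.na(pv) & pv < config$hweAlpha]
  note("hwe", "variant", nrow(gd), ids)
  gd <- checkNonEmpty(dropVariants(gd, ids), "hwe")

  report <- new("QCReport",
                steps = do.call(rbind, steps[.qcStepNames]),
                removed = removed[.qcStepNames],
                config = unclass(config))
  list(genotypes = gd, report = report)
}

#' Write a QC report to disk
#'
#' Emits the per-step table as TSV and the full report (steps, removed ids,
#' configuration) as JSON.
#'
#' @param report a [QCReport-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
writeQCReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "qc_steps.tsv")
  js <- file.path(dir, "qc_report.json")
  write.table(qcSteps(report), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(steps = qcSteps(report),
                            removed = qcRemoved(report),
                            config = report@config),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
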