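#' Largest-remainder allocation of counts to frequencies
#'
#' Deterministically converts a frequency vector into integer counts summing
#' exactly to `n`: each class gets `floor(freq * n)` and the remaining units
#' go to the classes with the largest fractional remainders (ties broken by
#' class order).
#'
#' @param freq numeric vector of nonnegative frequencies summing to 1.
#' @param n total count to allocate.
#' @return integer vector of counts summing to `n`.
#' @examples
#' largestRemainder(c(169, 22, 0) / 191, 191)
#' @export
largestRemainder <- function(freq, n) {
  stopifnot(n >= 0, all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", sum(freq), ")")
  raw <- freq * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

.normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

.caseFreqFromBeta <- function(g, beta) {
  # genotype distribution among cases under a per-allele log-odds effect:
  # case freqs proportional to control freqs times exp(beta * dosage)
  w <- g * exp(beta * 0:2)
  w / sum(w)
}

#' Simulate case-control genotype matrices
#'
#' Generates a [GenotypeData-class] object from per-variant genotype
#' frequency specifications. Each variant row of `variants` specifies the
#' case and control genotype-class frequencies either directly (columns
#' `f0,f1,f2` for cases and `g0,g1,g2` for controls, classes = major
#' homozygote / heterozygote / minor homozygote) or via a control
#' minor-allele frequency `maf` under Hardy-Weinberg proportions together
#' with a per-allele log-odds effect `beta` (case frequencies proportional
#' to control frequencies times `exp(beta * dosage)`).
#'
#' In `mode = "exact_counts"` the realized per-variant 2x3 case/control
#' genotype tables equal `largestRemainder(freq, n)` exactly, so printed
#' count tables can be reproduced deterministically; genotypes are then
#' permuted across samples. In `mode = "sampled"` genotype classes are
#' multinomial draws. Variants are simulated independently (no linkage
#' disequilibrium). Missingness, if requested, is overlaid afterwards by
#' masking entries at random, so with `missingRate > 0` the observed counts
#' no longer equal the exact-mode request.
#'
#' A third spec form takes observed genotype \emph{counts} directly
#' (columns `case0,case1,case2,ctrl0,ctrl1,ctrl2`, as in
#' [gastricVariantTable()]); per-variant counts may sum to less than the
#' group size, in which case the remaining samples are missing for that
#' variant — this reproduces published count tables, including their
#' missingness, exactly.
#'
#' @param nCases,nControls sample sizes per group.
#' @param variants data.frame, one row per variant: column `variant` (id),
#'   optional `chrom`, `pos`, `major`, `minor`, `gene`, and one of (a)
#'   `f0,f1,f2,g0,g1,g2` frequency columns, (b) `maf` (+ optional `beta`,
#'   default 0), or (c) `case0..2`/`ctrl0..2` observed count columns.
#' @param missingRate proportion of entries masked to `NA`, in `[0, 1)`.
#' @param mode `"exact_counts"` or `"sampled"`.
#' @param seed integer seed; identical seeds give identical output.
#' @param trainCases,trainControls optional counts assigned `split =
#'   "train"` (chosen at random); the remainder become `"valid"`. If `NA`
#'   (default) every sample gets `split = "unassigned"`.
#' @return a [GenotypeData-class] object.
#' @examples
#' v <- data.frame(variant = "rs104886038", chrom = "11", pos = 71444111,
#'                 f0 = 169/191, f1 = 22/191, f2 = 0,
#'                 g0 = 185/284, g1 = 99/284, g2 = 0)
#' gd <- simulateGenotypes(191, 284, v, mode = "exact_counts", seed = 1)
#' genotypeCounts(gd, "rs104886038")
#' @export
simulateGenotypes <- function(nCases, nControls, variants,
                              missingRate = 0,
                              mode = c("exact_counts", "sampled"),
                              seed = 1L,
                              trainCases = NA, trainControls = NA) {
  mode <- match.arg(mode)
  stopifnot(nCases >= 0, nControls >= 0,
            missingRate >= 0, missingRate < 1)
  if (!"variant" %in% names(variants))
    stop("'variants' needs a 'variant' id column")
  hasFreq <- all(c("f0", "f1", "f2", "g0", "g1", "g2") %in% names(variants))
  hasCounts <- all(c("case0", "case1", "case2",
                     "ctrl0", "ctrl1", "ctrl2") %in% names(variants))
  hasMaf <- "maf" %in% names(variants)
  if (!hasFreq && !hasMaf && !hasCounts)
    stop("'variants' needs f0..g2 frequencies, case0..ctrl2 counts, ",
         "or a 'maf' column")
  set.seed(as.integer(seed))
  nv <- nrow(variants)
  sampleIds <- c(sprintf("case%04d", seq_len(nCases)),
                 sprintf("ctrl%04d", seq_len(nControls)))
  status <- rep(c("case", "control"), c(nCases, nControls))
  dos <- matrix(NA_integer_, nrow = nv, ncol = nCases + nControls,
                dimnames = list(variants$variant, sampleIds))
  for (i in seq_len(nv)) {
    if (hasCounts) {
      rc <- as.integer(variants[i, c("case0", "case1", "case2")])
      sc <- as.integer(variants[i, c("ctrl0", "ctrl1", "ctrl2")])
      if (sum(rc) > nCases || sum(sc) > nControls)
        stop("counts exceed group sizes for variant ", variants$variant[i])
      if (any(rc < 0) || any(sc < 0)) stop("negative counts")
      if (nCases)
        dos[i, seq_len(nCases)] <-
          sample(c(rep(0:2, rc), rep(NA_integer_, nCases - sum(rc))))
      if (nControls)
        dos[i, nCases + seq_len(nControls)] <-
          sample(c(rep(0:2, sc), rep(NA_integer_, nControls - sum(sc))))
      next
    }
    if (hasFreq && !is.na(variants$f0[i])) {
      f <- as.numeric(variants[i, c("f0", "f1", "f2")])
      g <- as.numeric(variants[i, c("g0", "g1", "g2")])
    } else {
      p <- variants$maf[i]
      stopifnot(p >= 0, p <= 1)
      g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      b <- if ("beta" %in% names(variants)) variants$beta[i] else 0
      f <- .caseFreqFromBeta(g, if (is.na(b)) 0 else b)
    }
    if (any(f < 0) || any(g < 0)) stop("negative genotype frequencies")
    if (abs(sum(f) - 1) > 1e-9 || abs(sum(g) - 1) > 1e-9)
      stop("genotype frequencies must sum to 1 for variant ", variants$variant[i])
    geno <- function(freq, n) {
      cls <- if (mode == "exact_counts") {
        rep(0:2, largestRemainder(freq, n))
      } else {
        sample(0:2, n, replace = TRUE, prob = freq)
      }
      sample(cls)  # permute placement across samples
    }
    if (nCases) dos[i, seq_len(nCases)] <- geno(f, nCases)
    if (nControls) dos[i, nCases + seq_len(nControls)] <- geno(g, nControls)
  }
  if (missingRate > 0) {
    mask <- matrix(runif(length(dos)) < missingRate, nrow = nv)
    dos[mask] <- NA_integer_
  }
  split <- rep("unassigned", nCases + nControls)
  if (!is.na(trainCases) || !is.na(trainControls)) {
    stopifnot(trainCases <= nCases, trainControls <= nControls)
    split <- rep("valid", nCases + nControls)
    split[sample(seq_len(nCases), trainCases)] <- "train"
    split[nCases + sample(seq_len(nControls), trainControls)] <- "train"
  }
  vmeta <- variants[, intersect(c("chrom", "pos", "major", "minor", "gene"),
                                names(variants)), drop = FALSE]
  rownames(vmeta) <- variants$variant
  GenotypeData(dos,
               sampleData = data.frame(status = status, split = split,
                                       row.names = sampleIds),
               variantData = vmeta)
}

#' Case/control 2x3 genotype counts for one variant
#'
#' Tabulates observed (non-missing) genotype classes by group for one
#' variant of a [GenotypeData-class] object.
#'
#' @param gd a [GenotypeData-class] object.
#' @param variant variant id or row index.
#' @return 2x3 integer matrix, rows `case`/`control`, columns dosage classes
#'   `0`/`1`/`2`.
#' @export
genotypeCounts <- function(gd, variant) {
  d <- dosages(gd)[variant, ]
  cc <- isCase(gd)
  out <- rbind(case    = tabulate(d[cc] + 1L, 3L),
               control = tabulate(d[!cc] + 1L, 3L))
  colnames(out) <- 0:2
  storage.mode(out) <- "integer"
  out
}

#' Simulate binary covariates with a planted logistic case model
#'
#' Draws independent Bernoulli covariates and a case/control status from the
#' logistic model `logit P(case) = baseline + sum(beta_j x_j)`. Used to
#' emulate questionnaire-style lifestyle exposures (age class, smoking,
#' drinking, infection) with known planted odds ratios so that risk-model
#' estimates can be tested for parameter recovery.
#'
#' @param covariates data.frame with columns `name`, `prevalence` in
#'   `[0, 1]`, and `beta` (log-odds effect).
#' @param baseline baseline log-odds of case status.
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with one row per sample: the binary covariates plus
#'   `status` (`"case"`/`"control"`).
#' @examples
#' cv <- data.frame(name = c("age60", "smoking"), prevalence = c(0.4, 0.3),
#'                  beta = log(c(3, 2)))
#' head(simulateCovariates(cv, baseline = -1, n = 100, seed = 1))
#' @export
simulateCovariates <- function(covariates, baseline = 0, n, seed = 1L) {
  stopifnot(all(c("name", "prevalence", "beta") %in% names(covariates)),
            n >= 1)
  if (any(covariates$prevalence < 0 | covariates$prevalence > 1))
    stop("prevalence outside [0, 1]")
  set.seed(as.integer(seed))
  X <- vapply(covariates$prevalence,
              function(p) rbinom(n, 1L, p), integer(n))
  colnames(X) <- covariates$name
  eta <- baseline + as.vector(X %*% covariates$beta)
  status <- ifelse(rbinom(n, 1L, plogis(eta)) == 1L, "case", "control")
  data.frame(X, status = status, stringsAsFactors = FALSE)
}

#' Generate a toy single-chain protein structure
#'
#' Emits one C-alpha atom per residue along an ideal alpha-helix
#' (parameterized by rise per residue, twist per residue and helix radius;
#' defaults 1.5 Angstrom, 100 degrees, 2.3 Angstrom give the canonical
#' consecutive C-alpha spacing of ~3.83 Angstrom), a straight chain with
#' fixed spacing, or user-supplied coordinates. Optional Gaussian coordinate
#' noise is seeded and reproducible. These toy structures have analytically
#' known contact graphs, which makes network construction testable.
#'
#' @param nResidues number of residues (>= 2).
#' @param geometry `"ideal_helix"`, `"straight_chain"` or `"custom"`.
#' @param rise,twist,radius helix parameters: rise per residue (Angstrom),
#'   twist per residue (degrees), helix radius (Angstrom).
#' @param spacing consecutive C-alpha spacing for `"straight_chain"`
#'   (Angstrom).
#' @param coords `nResidues` x 3 matrix of C-alpha coordinates for
#'   `"custom"`.
#' @param noiseSd standard deviation of isotropic Gaussian coordinate noise
#'   (Angstrom).
#' @param resNames 3-letter residue names, recycled to `nResidues`.
#' @param seed integer seed (used for noise).
#' @param file optional path; if given, a PDB file is written (chain A,
#'   1-based contiguous residue numbering, occupancy 1.00).
#' @return invisibly, a list with `coords` (matrix), `resNames`, `resno`,
#'   and `file` (path or `NA`).
#' @examples
#' s <- generateToyStructure(10, "straight_chain", spacing = 5)
#' dist(s$coords[1:3, ])
#' @export
generateToyStructure <- function(nResidues,
                                 geometry = c("ideal_helix", "straight_chain", "custom"),
                                 rise = 1.5, twist = 100, radius = 2.3,
                                 spacing = 3.8, coords = NULL,
                                 noiseSd = 0, resNames = "ALA",
                                 seed = 1L, file = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(nResidues >= 2, is.finite(rise), is.finite(twist),
            is.finite(radius), is.finite(spacing), noiseSd >= 0)
  set.seed(as.integer(seed))
  i <- seq_len(nResidues) - 1
  xyz <- switch(geometry,
    ideal_helix = cbind(radius * cos(i * twist * pi / 180),
                        radius * sin(i * twist * pi / 180),
                        i * rise),
    straight_chain = cbind(i * spacing, 0, 0),
    custom = {
      if (is.null(coords) || nrow(coords) != nResidues || ncol(coords) != 3)
        stop("custom geometry needs an nResidues x 3 'coords' matrix")
      as.matrix(coords)
    })
  if (noiseSd > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noiseSd), ncol = 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  resNames <- rep_len(toupper(resNames), nResidues)
  if (!is.null(file)) {
    n <- nResidues
    bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                     resno = seq_len(n), resid = resNames,
                     eleno = seq_len(n), elety = rep("CA", n),
                     chain = rep("A", n), o = rep(1, n), b = rep(0, n))
  }
  invisible(list(coords = xyz, resNames = resNames,
                 resno = seq_len(nResidues),
                 file = if (is.null(file)) NA_character_ else file))
}
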