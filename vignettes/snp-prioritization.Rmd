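---
title: "From case-control genotypes to structure-ranked co-mutations"
author: "gwasnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From case-control genotypes to structure-ranked co-mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasnet)
```

## The problem this package addresses

Genome-wide association studies of cancer susceptibility routinely produce
lists of significant SNPs that never progress beyond the association table,
because a p-value alone says nothing about mechanism. `gwasnet` implements
one integrated route from chip genotypes to mechanistic candidates, built
around a gastric-cancer study of the DHCR7 coding variant rs104886038
(L68P): quality-controlled case-control association identifies a coding
variant; a multivariable risk model places its genotype among lifestyle
risk factors; and a residue-contact network over the protein structure
nominates *co-mutation* partners whose combined effect on protein
stability exceeds the single mutation's. Because the original
individual-level chip data and predicted structure are not published,
every stage here is driven either by the published summary tables (which
are bundled) or by a seeded synthetic-data module with known ground truth,
and the test suite checks the statistical machinery against independent
oracles rather than against unavailable raw data.

## Genotype container and quality control

Genotypes live in a `GenotypeData` object (a `SummarizedExperiment` with a
single `dosage` assay: minor-allele dosage 0/1/2, `NA` for missing;
variants in rows). Missingness is a dedicated sentinel, never conflated
with the reference-homozygote class, so call rates and allele frequencies
cannot be silently biased.

`applyQC()` runs the standard eight-step chip cascade in a fixed order:
polymorphic loci; sex concordance; autosomes only; SNP call rate; MAF;
sample call rate; ancestry outliers; Hardy–Weinberg. Each step records
its removals in a `QCReport` whose validity enforces
`before − removed = after`, and the cascade is idempotent by construction.
Where the original study named a step but not its parameters, the defaults
here are explicit, conventional, and configurable:

* **Hardy–Weinberg**: an exact conditional test (all heterozygote counts
  compatible with the observed allele counts are enumerated; the p-value
  sums the probabilities no larger than the observed configuration's).
  The chi-square approximation is invalid at the low minor-homozygote
  counts typical of rare variants — the bundled focal variant itself has
  an empty minor-homozygote cell. Threshold α = 10⁻⁶, computed on
  controls only, the usual case-control practice (a true association can
  distort HWE in cases).
* **"Polymorphic loci"** is read as: drop variants with zero observed
  minor alleles. Any laxer reading would make the later MAF step
  redundant.
* **Ancestry**: no method was named, so a transparent one is used —
  principal components of the standardized dosage matrix with
  median/MAD centring; samples beyond 6 robust SDs on PC1 or PC2 are
  outliers. On a simulated homogeneous cohort this flags nobody; five
  samples drawn from a shifted allele-frequency profile are flagged
  exactly (both are tests).
* **Sex concordance** compares reported against externally inferred sex;
  genotype-based sex inference is deliberately not implemented, because
  non-autosomal variants are removed by the cascade anyway and no
  X-heterozygosity procedure was specified.

## Association statistics

For a 2×3 genotype table the per-variant model is an unadjusted logistic
regression of case status on the coded genotype (additive 0/1/2, dominant
0/1/1, recessive 0/0/1), fitted by IRLS with a Newton refinement to
machine precision; OR = exp(β) with Wald 95% CI exp(β ± 1.96·SE). The
trend test is the Cochran–Armitage score statistic with scores (0,1,2)
and variance denominator N, two-sided against χ²₁. These two choices
jointly reproduce the published focal-variant row to printed precision:

```{r assoc}
fitGenotypeLogistic(c(169, 22, 0), c(185, 99, 0), variant = "rs104886038")
```

When the minor-homozygote cell is empty in both groups (as here) the
additive MLE collapses to the 2×2 cross-product ratio with
SE = √(Σ 1/cell), an identity the tests verify to ten significant digits.
Missing genotypes are handled per-variant complete-case; no imputation
was described and none is attempted. Degenerate tables (one genotype
class) return p = 1 with a flag; complete separation is an error naming
the variant, quasi-separation a flag.

The training → validation workflow ranks variants by training p (trend p
for the additive model), carries the top K (default 5) to the validation
set, retains those with validation p < 0.05, and recomputes statistics on
the combined samples — mirroring the published 150/200-case training,
41/88 validation design. At 41 validation cases, whether a genuinely
associated low-MAF variant clears α = 0.05 depends on the random split;
the pipeline therefore also emits the full combined-set scan, which is
what published per-variant statistics correspond to. The published
training-set model counts (12/16/5 significant SNPs across the three
codings) and the diagnostic AUC of 0.826 require the unpublished
individual-level chip data and are not claimed; the corresponding
machinery is instead validated by property: null-scan genomic inflation
λ ∈ [0.9, 1.1] at 1,000 variants, trend-test type-I error in [0.04, 0.06]
over 10,000 null tables of 400 subjects, Wald CI coverage ≈ 95% over
2,000 replicates.

## Risk models and diagnostics

`fitRiskModel()` fits the joint logistic model behind a forest plot;
`stratifiedRisk()` refits it within genotype strata (the published
stratified ORs of 12.33/20.42/11.39 among A/G carriers are likewise not
recomputable without the questionnaire data; recovery of planted ORs
0.2/2.0/3.0 at n = 50,000 stands in). "Heavy drinking" and the other
exposures are binary inputs whose operational definitions belong to the
data provider. `rocCurve()` computes the AUC as Mann–Whitney concordance
with midrank ties, which makes the threshold-sweep trapezoid and the
concordance numerically identical rather than approximately so.
`cholesterolConcentration()` implements the colorimetric assay equation
`(OD_s − OD_b)/(OD_c − OD_b) × calibrator ÷ protein` used downstream of
the genotype work.

## The residue network and the co-mutation rule

`buildAANetwork()` turns coordinates into an undirected, unweighted
residue graph. The upstream tool that inspired this stage publishes no
parameter set, so both common contact definitions are first-class and
recorded in every output: Cα–Cα ≤ 7 Å (default) and minimum heavy-atom
distance ≤ 4.5 Å. The selection rule — the study's actual contribution —
is: compute hop distances from the focal residue; let d̄ be their mean
over all *reachable* residues (unreachable ones are excluded and
counted); a catalogued site is a candidate iff its distance is finite and
strictly below d̄. "Strictly" follows the rule's wording; on a star graph
from the hub every distance equals d̄ and the candidate set is empty,
which the tests pin down. The mutation catalog is first filtered to
array-covered positions, and the focal entry's wild-type letter is
cross-checked against the structure (a mismatch is an error, not a
warning, because UniProt/PDB numbering offsets are the classic silent
failure here).

```{r comut}
sel <- selectComutationCandidates(pathNet <- local({
  g <- igraph::make_ring(9, circular = FALSE)
  igraph::V(g)$name <- as.character(1:9)
  new("AANetwork", graph = g, mode = "ca_distance", cutoff = 7,
      positions = 1:9, residueNames = rep("ALA", 9))
}), 1, data.frame(position = c(2, 3, 8)))
sel
```

ΔΔG values are consumed, never computed: `ddgLookupScorer()` is the
default implementation of the pluggable stability-scorer contract, and
querying an unpredicted mutation set is an explicit error.
`rankDDGTable()` sorts by the multiple-mutation ΔΔG column (negative =
destabilizing, the bundled table's convention). The source table prints
−2.9 in that column for the best pair while the surrounding text quotes
−2.31 (the partner's single-mutation column value); the ranking follows
the table column and the output surfaces both numbers. The published
eight-candidate list itself depended on an unpublished predicted
structure, so the pipeline's bundled run uses a synthetic helix
(explicitly labelled synthetic) and makes no claim to reproduce it.

## The synthetic-data module

`simulateGenotypes()` accepts three per-variant specifications: exact
published count tables (per-variant shortfalls from the group size become
missing genotypes — printed tables are post-QC observations and carry
residual missingness); genotype-class frequencies allocated by
largest-remainder rounding so realized tables equal the request
deterministically; or a control MAF under Hardy–Weinberg proportions plus
a per-allele log-odds effect (case frequencies ∝ control frequencies ×
exp(β·dosage), the exact retrospective-sampling identity). Variants are
independent — linkage disequilibrium is out of scope — and one integer
seed drives each generator call. `simulateCovariates()` draws Bernoulli
exposures and status from the stated logistic model, giving planted odds
ratios for recovery tests. `generateToyStructure()` emits ideal helices
(rise 1.5 Å, twist 100°, radius 2.3 Å → consecutive Cα spacing 3.83 Å),
straight chains, or custom coordinates, with seeded Gaussian noise; their
contact graphs are checkable by brute force. What these generators do
*not* emulate — LD, batch effects, genotyping-intensity artifacts,
realistic protein folds — bounds what green tests mean: they validate the
statistical machinery, not chip chemistry or structure prediction.

## Orchestration, sizes, determinism

`runPipeline()` chains the stages under one configuration (R list or YAML)
and one seed; every artifact directory contains the echoed configuration,
and the JSON report carries a digest of the configuration content
(excluding the output path), so identical configurations give
byte-identical reports. The bundled default run operates at the study's
scale: 479 subjects, three variants, a 475-residue toy structure; the
test-suite simulations use 10,000 null tables of 400 subjects for test
calibration, 50,000 subjects for parameter recovery, 1,000-variant null
scans, and 100 random graphs of up to 50 residues for the graph oracles —
sizes chosen so each property is measured with comfortable statistical
resolution. When reproducing the published count tables end to end, the
QC stage is toggled off: those tables are post-QC data, and re-applying a
per-sample call-rate filter to a three-variant digest of a several-hundred-
thousand-SNP chip would misread residual per-variant missingness as
sample failure.

## Known limitations

* Covariate-adjusted per-SNP association, imputation, LD pruning,
  relatedness checks and meta-analysis are out of scope, as in the
  original filter sequence.
* The published secondary p-value column for the combined analysis
  (e.g. 5.74×10⁻⁹ for the focal variant) is produced by an unstated test
  and is not reproduced by either the trend or the Wald statistic; it is
  left unimplemented rather than guessed. Likewise one published OR
  (rs240541, 0.546) is not derivable from its own printed counts under
  any unadjusted coding and is treated as likely covariate-adjusted.
* Stratified-model ORs and the multi-SNP AUC from the study require
  unpublished individual-level data; the package demonstrates the
  corresponding estimators on synthetic ground truth instead.
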