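#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pchisq pnorm prcomp mad median glm binomial coef vcov
#'   rbinom runif rnorm setNames plogis quantile fitted model.matrix
#'   reformulate ppoints var sd dist na.omit
#' @importFrom utils read.table write.table head
NULL

.VALID_DOSAGES <- c(0L, 1L, 2L)

#' Container for case-control genotype dosages
#'
#' `GenotypeData` extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"dosage"`
#' assay holding minor-allele dosages (0, 1, 2 or `NA` for missing), one row
#' per variant and one column per sample. Variant annotation (chromosome,
#' position, major/minor allele, gene) lives in `rowData`; sample annotation
#' (case/control status, reported and inferred sex, train/validation split,
#' binary covariates) lives in `colData`.
#'
#' The validity method enforces that every non-missing entry is 0, 1 or 2,
#' that `status` is `"case"`/`"control"`, and that ids are unique.
#'
#' @seealso [GenotypeData()], [simulateGenotypes()], [applyQC()]
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(d) & !(d %in% .VALID_DOSAGES)
    if (any(bad))
      msg <- c(msg, sprintf("%d dosage entries outside {0,1,2,NA}", sum(bad)))
  }
  if (!"status" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'status' is required")
  else {
    st <- SummarizedExperiment::colData(object)$status
    if (!all(st %in% c("case", "control")))
      msg <- c(msg, "status must be 'case' or 'control'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated variant ids")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of minor-allele dosages, variants in rows,
#'   samples in columns; entries 0/1/2/`NA`. Dimnames are used as variant and
#'   sample ids.
#' @param sampleData data.frame with one row per sample. Must contain
#'   `status` (`"case"`/`"control"`); typical further columns are `sex`,
#'   `inferred_sex`, `split` (`"train"`/`"valid"`/`"unassigned"`) and binary
#'   covariates.
#' @param variantData data.frame with one row per variant; typical columns
#'   are `chrom`, `pos`, `major`, `minor`, `gene`.
#' @return a [GenotypeData-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' gd <- GenotypeData(d, data.frame(status = c("case", "control")),
#'                    data.frame(chrom = c("1", "2"), pos = c(100L, 200L)))
#' dosages(gd)
#' @export
GenotypeData <- function(dosage,
                         sampleData = S4Vectors::DataFrame(status = rep("control", ncol(dosage))),
                         variantData = S4Vectors::DataFrame(row.names = rownames(dosage))) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("var", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(dosage)),
    rowData = S4Vectors::DataFrame(variantData))
  new("GenotypeData", se)
}

#' @describeIn GenotypeData the dosage matrix (variants x samples).
#' @param x,object a `GenotypeData` object.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeData logical vector, `TRUE` for case samples.
#' @export
isCase <- function(x) SummarizedExperiment::colData(x)$status == "case"

#' @describeIn GenotypeData variant annotation as a data.frame.
#' @export
variantInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn GenotypeData sample annotation as a data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d variants x %d samples (%d cases, %d controls)\n",
              nrow(object), ncol(object), sum(isCase(object)),
              sum(!isCase(object))))
  d <- dosages(object)
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(d))))
  callNextMethod()
})

#' Per-step report of the genotype QC cascade
#'
#' One row per executed filtering step, recording the step name, whether it
#' removes samples or variants, counts before/after, and the removed ids.
#' Count conservation (`before - removed == after`) is enforced by validity.
#'
#' @slot steps data.frame with columns `step`, `unit` ("sample"/"variant"),
#'   `n_before`, `n_removed`, `n_after`.
#' @slot removed named list of character vectors of removed ids, one element
#'   per step.
#' @slot config list echoing the thresholds used.
#' @seealso [applyQC()]
#' @exportClass QCReport
setClass("QCReport",
         representation(steps = "data.frame", removed = "list",
                        config = "list"))

setValidity("QCReport", function(object) {
  st <- object@steps
  need <- c("step", "unit", "n_before", "n_removed", "n_after")
  if (!all(need %in% colnames(st))) return("missing columns in steps")
  if (any(st$n_before - st$n_removed != st$n_after))
    return("count conservation violated (before - removed != after)")
  if (length(object@removed) != nrow(st))
    return("one removed-id entry per step required")
  if (any(vapply(object@removed, length, 1L) != st$n_removed))
    return("removed id lists inconsistent with counts")
  TRUE
})

#' @describeIn QCReport the per-step summary table.
#' @param x,object a `QCReport`.
#' @export
qcSteps <- function(x) x@steps

#' @describeIn QCReport named list of removed ids per step.
#' @export
qcRemoved <- function(x) x@removed

setMethod("show", "QCReport", function(object) {
  cat("QC cascade report\n")
  print(object@steps, row.names = FALSE)
  invisible(object)
})

#' Residue-contact (amino acid) network
#'
#' An undirected, unweighted graph whose nodes are residue positions of a
#' protein structure and whose edges join residues in spatial contact. Two
#' contact definitions are supported: `"ca_distance"` (C-alpha / C-alpha
#' distance at or below `cutoff`, default 7 Angstrom) and
#' `"heavy_atom_contact"` (minimum heavy-atom pair distance at or below
#' `cutoff`, default 4.5 Angstrom).
#'
#' @slot graph an [igraph::igraph] object with vertices named by residue
#'   position.
#' @slot mode character, the contact definition used.
#' @slot cutoff numeric, contact cutoff in Angstrom.
#' @slot positions integer residue positions (node ids).
#' @slot residueNames character 3-letter residue names, parallel to
#'   `positions`.
#' @seealso [buildAANetwork()], [shortestPathLengths()],
#'   [selectComutationCandidates()]
#' @exportClass AANetwork
setClass("AANetwork",
         representation(graph = "ANY", mode = "character",
                        cutoff = "numeric", positions = "integer",
                        residueNames = "character"))

setValidity("AANetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  if (igraph::is_directed(object@graph)) return("graph must be undirected")
  if (any(igraph::which_loop(object@graph))) return("self-loops not allowed")
  if (length(object@positions) != igraph::vcount(object@graph))
    return("positions must map 1:1 to graph vertices")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' @describeIn AANetwork two-column matrix of contacting residue positions.
#' @param x,object an `AANetwork`.
#' @export
contactEdges <- function(x) {
  e <- igraph::as_edgelist(x@graph)
  m <- matrix(as.integer(e), ncol = 2,
              dimnames = list(NULL, c("res_i", "res_j")))
  m
}

#' @describeIn AANetwork residue positions (node ids).
#' @export
networkPositions <- function(x) x@positions

#' @describeIn AANetwork the contact definition (`"ca_distance"` or
#'   `"heavy_atom_contact"`).
#' @export
networkMode <- function(x) x@mode

#' @describeIn AANetwork the contact cutoff in Angstrom.
#' @export
networkCutoff <- function(x) x@cutoff

setMethod("show", "AANetwork", function(object) {
  cat(sprintf("AANetwork: %d residues, %d contacts (%s, cutoff %.1f A)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@mode, object@cutoff))
  invisible(object)
})

#' Co-mutation candidate selection around a focal residue
#'
#' Holds the focal residue position, the mean shortest-path length from the
#' focal residue to all other reachable residues, and the per-site decision
#' for every catalogued mutation site: its hop distance to the focal residue
#' and whether it was selected (strictly closer than the mean).
#'
#' @slot focal integer focal residue position.
#' @slot meanDistance numeric mean hop distance from the focal residue to all
#'   other residues with a finite distance.
#' @slot sites data.frame with columns `position`, `mutation`, `distance`,
#'   `reachable`, `selected`.
#' @slot nUnreachable integer count of structure residues unreachable from
#'   the focal residue (excluded from the mean).
#' @seealso [selectComutationCandidates()]
#' @exportClass CoMutationSelection
setClass("CoMutationSelection",
         representation(focal = "integer", meanDistance = "numeric",
                        sites = "data.frame", nUnreachable = "integer"))

setValidity("CoMutationSelection", function(object) {
  s <- object@sites
  if (nrow(s) &&
      any(s$selected & !(is.finite(s$distance) & s$distance < object@meanDistance)))
    return("selected sites must have finite distance strictly below the mean")
  TRUE
})

#' @describeIn CoMutationSelection data.frame of selected candidate sites.
#' @param x,object a `CoMutationSelection`.
#' @export
candidateSites <- function(x) x@sites[x@sites$selected, , drop = FALSE]

#' @describeIn CoMutationSelection mean shortest-path length from the focal
#'   residue.
#' @export
meanPathLength <- function(x) x@meanDistance

setMethod("show", "CoMutationSelection", function(object) {
  cat(sprintf("Co-mutation selection around residue %d\n", object@focal))
  cat(sprintf("  mean shortest-path length: %.4f (%d unreachable excluded)\n",
              object@meanDistance, object@nUnreachable))
  cat(sprintf("  %d / %d catalogued sites selected\n",
              sum(object@sites$selected), nrow(object@sites)))
  if (any(object@sites$selected))
    print(candidateSites(object), row.names = FALSE)
  invisible(object)
})
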