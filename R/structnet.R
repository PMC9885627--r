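.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)

#' Read a protein structure from PDB
#'
#' Parses a PDB file (via [bio3d::read.pdb]), keeps the first model only,
#' and drops heteroatoms and waters. Residues missing a C-alpha atom are
#' excluded with a warning (they cannot enter a C-alpha contact network).
#'
#' @param file path to a PDB file.
#' @return a list of class `aa_structure`: `atoms` (data.frame of ATOM
#'   records: `resno`, `resid`, `elety`, `chain`, `x`, `y`, `z`),
#'   `residues` (data.frame `resno`, `resid`, `chain`), and `file`.
#' @export
readStructure <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no protein ATOM records in ", file)
  at <- at[, c("resno", "resid", "elety", "chain", "x", "y", "z")]
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", file)
  res <- unique(at[, c("resno", "resid", "chain")])
  noCa <- setdiff(res$resno, at$resno[at$elety == "CA"])
  if (length(noCa)) {
    warning(length(noCa), " residues lack a C-alpha atom and were excluded: ",
            paste(head(noCa, 5), collapse = ", "))
    at <- at[!at$resno %in% noCa, , drop = FALSE]
    res <- res[!res$resno %in% noCa, , drop = FALSE]
  }
  structure(list(atoms = at, residues = res, file = file),
            class = "aa_structure")
}

#' @export
print.aa_structure <- function(x, ...) {
  cat(sprintf("aa_structure: %d residues, %d atoms (chain %s)\n",
              nrow(x$residues), nrow(x$atoms),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

#' Build a residue-contact network from a structure
#'
#' Nodes are residue positions; an undirected, unweighted edge joins two
#' distinct residues when they are in spatial contact. Two contact
#' definitions are supported: `"ca_distance"` (C-alpha pair distance at or
#' below `cutoff`; default 7 Angstrom) and `"heavy_atom_contact"` (minimum
#' non-hydrogen atom pair distance at or below `cutoff`; default 4.5
#' Angstrom). The construction is invariant to residue input order, and
#' increasing the cutoff can only add edges.
#'
#' @param struct an `aa_structure` from [readStructure()], or a toy
#'   structure list from [generateToyStructure()].
#' @param mode contact definition.
#' @param cutoff contact cutoff in Angstrom; defaults to 7 (`ca_distance`)
#'   or 4.5 (`heavy_atom_contact`).
#' @return an [AANetwork-class] object.
#' @export
buildAANetwork <- function(struct,
                           mode = c("ca_distance", "heavy_atom_contact"),
                           cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "ca_distance") 7.0 else 4.5
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!inherits(struct, "aa_structure")) {
    # toy-structure list: one CA per residue
    stopifnot(!is.null(struct$coords))
    at <- data.frame(resno = struct$resno, resid = struct$resNames,
                     elety = "CA", chain = "A",
                     x = struct$coords[, 1], y = struct$coords[, 2],
                     z = struct$coords[, 3])
    struct <- structure(list(atoms = at,
                             residues = data.frame(resno = struct$resno,
                                                   resid = struct$resNames,
                                                   chain = "A")),
                        class = "aa_structure")
  }
  res <- struct$residues[order(struct$residues$resno), , drop = FALSE]
  pos <- res$resno
  if (anyDuplicated(pos)) stop("duplicate residue numbers across chains")
  n <- length(pos)
  if (mode == "ca_distance") {
    ca <- struct$atoms[struct$atoms$elety == "CA", , drop = FALSE]
    ca <- ca[match(pos, ca$resno), , drop = FALSE]
    dm <- as.matrix(stats::dist(ca[, c("x", "y", "z")]))
  } else {
    at <- struct$atoms[!grepl("^H", sub("^[0-9]+", "", struct$atoms$elety)), ,
                       drop = FALSE]
    dAll <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
    idx <- match(at$resno, pos)
    dm <- matrix(Inf, n, n)
    for (a in seq_len(nrow(at))) {
      ia <- idx[a]
      row <- dAll[a, ]
      agg <- tapply(row, idx, min)
      dm[ia, as.integer(names(agg))] <-
        pmin(dm[ia, as.integer(names(agg))], agg)
    }
    dm <- pmin(dm, t(dm))
  }
  adj <- dm <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(pos)
  new("AANetwork", graph = g, mode = mode, cutoff = cutoff,
      positions = as.integer(pos), residueNames = res$resid)
}

#' Shortest-path hop distances from a source residue
#'
#' Breadth-first hop counts from one residue to every residue of the
#' network; residues in other connected components get `Inf`.
#'
#' @param network an [AANetwork-class].
#' @param source residue position of the source node.
#' @return named numeric vector of hop distances (names = residue
#'   positions).
#' @export
shortestPathLengths <- function(network, source) {
  vn <- as.character(networkPositions(network))
  src <- as.character(source)
  if (!src %in% vn) stop("source residue ", source, " not in network")
  d <- igraph::distances(network@graph, v = src, to = igraph::V(network@graph),
                         algorithm = "unweighted")[1, ]
  d[vn]
}

#' Read a mutation catalog
#'
#' @param file TSV with columns `wt_aa` (1-letter wild-type), `position`
#'   (1-based), `mut_aa` (1-letter mutant) and optionally `source`,
#'   `on_array`.
#' @return data.frame with an added `mutation` label column (e.g. "L68P").
#' @export
readVariantCatalog <- function(file) {
  cat <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("wt_aa", "position", "mut_aa") %in% names(cat)),
            all(cat$position >= 1))
  cat$mutation <- paste0(cat$wt_aa, cat$position, cat$mut_aa)
  cat
}

#' Restrict a mutation catalog to array-covered positions
#'
#' Retains catalog entries whose protein position is interrogated by the
#' genotyping array, and logs the counts.
#'
#' @param catalog data.frame as from [readVariantCatalog()].
#' @param arrayPositions integer vector of array-covered positions.
#' @return the filtered catalog, with attribute `n_dropped`.
#' @examples
#' cat <- data.frame(wt_aa = c("L", "P", "G"), position = c(68, 51, 244),
#'                   mut_aa = c("P", "S", "R"))
#' filterCatalogByArray(cat, c(68, 51))
#' @export
filterCatalogByArray <- function(catalog, arrayPositions) {
  keep <- catalog$position %in% arrayPositions
  message(sum(keep), " of ", nrow(catalog),
          " catalogued mutations are covered by the array")
  out <- catalog[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Select co-mutation candidates around a focal residue
#'
#' The focal residue's mean shortest-path length `dbar` is computed over
#' all other residues of the network with a finite distance (unreachable
#' residues are excluded and counted). A catalogued mutation site is
#' selected as a co-mutation candidate when its hop distance to the focal
#' residue is finite and \emph{strictly} smaller than `dbar`. Sites at
#' exactly `dbar`, unreachable sites, and sites absent from the network are
#' not selected (the latter two are flagged).
#'
#' @param network an [AANetwork-class].
#' @param focal focal residue position (e.g. 68 for L68P).
#' @param catalog data.frame with `position` and (optionally) `mutation`,
#'   `wt_aa` columns; typically the array-filtered catalog.
#' @param checkWt if `TRUE` (default when `wt_aa` is present), the focal
#'   entry's wild-type letter is checked against the structure residue at
#'   that position; a mismatch is an error (guards against numbering
#'   offsets).
#' @return a [CoMutationSelection-class] object.
#' @export
selectComutationCandidates <- function(network, focal, catalog,
                                       checkWt = "wt_aa" %in% names(catalog)) {
  focal <- as.integer(focal)
  pos <- networkPositions(network)
  if (!focal %in% pos) stop("focal residue ", focal, " not in network")
  if (isTRUE(checkWt)) {
    fc <- catalog[catalog$position == focal, , drop = FALSE]
    if (nrow(fc)) {
      have <- unname(.AA3TO1[network@residueNames[match(focal, pos)]])
      if (!is.na(have) && any(fc$wt_aa != have))
        stop("wild-type mismatch at focal residue ", focal, ": catalog says ",
             paste(unique(fc$wt_aa), collapse = "/"), ", structure has ", have)
    }
  }
  d <- shortestPathLengths(network, focal)
  dOther <- d[names(d) != as.character(focal)]
  finite <- dOther[is.finite(dOther)]
  if (!length(finite))
    stop("focal residue ", focal, " is isolated: no finite path lengths")
  dbar <- mean(finite)
  sites <- catalog[catalog$position != focal, , drop = FALSE]
  sdist <- d[as.character(sites$position)]
  inNet <- sites$position %in% pos
  sdist[!inNet] <- NA_real_
  sites <- data.frame(
    position = sites$position,
    mutation = if ("mutation" %in% names(sites)) sites$mutation
               else as.character(sites$position),
    distance = unname(sdist),
    reachable = inNet & is.finite(sdist),
    selected = inNet & is.finite(sdist) & sdist < dbar,
    stringsAsFactors = FALSE)
  new("CoMutationSelection", focal = focal, meanDistance = dbar,
      sites = sites, nUnreachable = sum(!is.finite(dOther)))
}

#' Read a ddG table
#'
#' @param file CSV/TSV with columns `pair` (co-mutation label, e.g.
#'   "L68P + P51S"), `multi_ddg` (multiple-mutation ddG, kcal/mol) and
#'   `single_ddg` (single-mutation ddG of the partner, kcal/mol). Negative
#'   values denote destabilization.
#' @return data.frame of the table.
#' @export
readDDGTable <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  dd <- read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("pair", "multi_ddg", "single_ddg") %in% names(dd)),
            all(is.finite(dd$multi_ddg)), all(is.finite(dd$single_ddg)))
  if (anyDuplicated(dd$pair)) stop("duplicate co-mutation pair labels")
  dd
}

#' Rank co-mutation pairs by protein-stability change
#'
#' Sorts a ddG table ascending by the multiple-mutation ddG (most
#' destabilizing first, under the convention that negative values denote
#' destabilization), returns the minimizing pair(s) — all of them if tied —
#' and counts how many pairs are more destabilizing than the focal single
#' mutation's reference ddG.
#'
#' @param ddg data.frame as from [readDDGTable()].
#' @param reference single-mutation ddG of the focal mutation (kcal/mol),
#'   e.g. -0.36 for DHCR7 L68P.
#' @return list with `ranked` (the sorted table), `best` (row(s) at the
#'   minimum), and `n_below_reference`.
#' @examples
#' rankDDGTable(dhcr7StabilityTable(), reference = -0.36)$best
#' @export
rankDDGTable <- function(ddg, reference = NA_real_) {
  stopifnot(nrow(ddg) >= 1)
  ranked <- ddg[order(ddg$multi_ddg, ddg$pair), , drop = FALSE]
  rownames(ranked) <- NULL
  best <- ranked[ranked$multi_ddg == min(ranked$multi_ddg), , drop = FALSE]
  list(ranked = ranked, best = best,
       n_below_reference = if (is.na(reference)) NA_integer_
                           else sum(ranked$multi_ddg < reference))
}

#' Table-lookup protein-stability scorer
#'
#' The pipeline treats ddG prediction as a pluggable external contract: any
#' function mapping a mutation-set label to a ddG can be registered. This
#' default scorer looks labels up in a ddG table (whitespace-normalized);
#' querying a mutation set absent from the table is an explicit
#' "no prediction" error, never a silent default.
#'
#' @param ddg data.frame as from [readDDGTable()].
#' @return function taking a mutation-set label (e.g. "L68P + W248C") and
#'   returning its multiple-mutation ddG in kcal/mol.
#' @examples
#' scorer <- ddgLookupScorer(dhcr7StabilityTable())
#' scorer("L68P + W248C")  # -1.91
#' @export
ddgLookupScorer <- function(ddg) {
  norm <- function(x) gsub("\\s+", "", x)
  keys <- norm(ddg$pair)
  function(mutations) {
    i <- match(norm(mutations), keys)
    if (anyNA(i))
      stop("no prediction available for: ",
           paste(mutations[is.na(i)], collapse = ", "))
    ddg$multi_ddg[i]
  }
}
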