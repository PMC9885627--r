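#' Bundled gastric-cancer case-control genotype counts
#'
#' The published 2x3 genotype count tables (major homozygote / heterozygote
#' / minor homozygote, GRCh38 coordinates) for the three germline variants
#' validated in a 191-case / 288-control gastric-cancer association study:
#' rs191281603 (CFHR5), rs240541 (DCPS) and rs104886038 (DHCR7, the L68P
#' coding variant). These printed tables are inputs to the pipeline: they
#' drive the exact-counts simulator and the worked association example.
#'
#' @return data.frame with one row per variant: `variant`, `chrom`, `pos`,
#'   `major`, `minor`, `gene`, case counts `case0`, `case1`, `case2` and
#'   control counts `ctrl0`, `ctrl1`, `ctrl2`.
#' @examples
#' tb <- gastricVariantTable()
#' computeMAF(as.matrix(tb[, c("case0", "case1", "case2")]))
#' @export
gastricVariantTable <- function() {
  data.frame(
    variant = c("rs191281603", "rs240541", "rs104886038"),
    chrom = c("1", "11", "11"),
    pos = c(196989521L, 126339488L, 71444111L),
    major = c("C", "A", "A"),
    minor = c("G", "G", "G"),
    gene = c("CFHR5", "DCPS", "DHCR7"),
    case0 = c(102L, 46L, 169L),
    case1 = c(83L, 94L, 22L),
    case2 = c(3L, 29L, 0L),
    ctrl0 = c(258L, 13L, 185L),
    ctrl1 = c(29L, 117L, 99L),
    ctrl2 = c(0L, 157L, 0L),
    stringsAsFactors = FALSE)
}

#' Bundled DHCR7 co-mutation stability table
#'
#' Predicted folding free-energy changes (ddG, kcal/mol; negative =
#' destabilizing) for DHCR7 double mutants pairing the focal L68P variant
#' (rs104886038; single-mutation ddG -0.36 kcal/mol, stored as the
#' `"reference"` attribute) with each of its eight network-selected
#' co-mutation candidates, together with the partner's single-mutation
#' ddG. Consumed by [rankDDGTable()] and [ddgLookupScorer()]; the pipeline
#' never computes ddG itself.
#'
#' @return data.frame with columns `pair`, `multi_ddg`, `single_ddg` and
#'   attribute `reference` (the focal single-mutation ddG).
#' @examples
#' rankDDGTable(dhcr7StabilityTable(),
#'              reference = attr(dhcr7StabilityTable(), "reference"))$best
#' @export
dhcr7StabilityTable <- function() {
  out <- data.frame(
    pair = c("L68P + P51S", "L68P + G244R", "L68P + A247V", "L68P + W248C",
             "L68P + V326L", "L68P + Y408H", "L68P + G410R", "L68P + R443C"),
    multi_ddg = c(-2.9, -0.59, 0.37, -1.91, -1.16, -0.72, -1.59, -1.66),
    single_ddg = c(-2.31, -0.86, 0.87, -2.2, -0.37, -1.57, -0.77, -1.24),
    stringsAsFactors = FALSE)
  attr(out, "reference") <- -0.36
  out
}

#' Bundled DHCR7 mutation catalog
#'
#' The nine catalogued DHCR7 missense sites appearing in the bundled
#' stability table plus the focal L68P variant, in the standard catalog
#' layout (`wt_aa`, `position`, `mut_aa`, `source`, `on_array`,
#' `mutation`). Positions are 1-based protein coordinates.
#'
#' @return data.frame catalog.
#' @export
dhcr7MutationCatalog <- function() {
  m <- c("L68P", "P51S", "G244R", "A247V", "W248C",
         "V326L", "Y408H", "G410R", "R443C")
  data.frame(
    wt_aa = substr(m, 1, 1),
    position = as.integer(gsub("[A-Z]", "", m)),
    mut_aa = substr(m, nchar(m), nchar(m)),
    source = "uniprot",
    on_array = TRUE,
    mutation = m,
    stringsAsFactors = FALSE)
}
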