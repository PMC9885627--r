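#' Default pipeline configuration
#'
#' Returns the full default configuration for [runPipeline()] as a named
#' list; any element can be overridden, and a YAML file with the same keys
#' can be supplied instead. All defaults are echoed into the run report so
#' every tunable is auditable.
#'
#' @param seed integer seed driving every random stage.
#' @param outDir output directory for artifacts.
#' @return named configuration list.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("gwasnet_run_")) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    stages = c("simulate", "qc", "assoc", "risk", "structnet"),
    simulate = list(nCases = 191L, nControls = 288L,
                    trainCases = 150L, trainControls = 200L,
                    mode = "exact_counts", missingRate = 0),
    qc = list(snpCallRateMin = 0.95, mafMin = 0.05,
              sampleCallRateMin = 0.95, hweAlpha = 1e-6, ancestrySd = 6),
    assoc = list(model = "additive", topK = 3L, alpha = 0.05),
    risk = list(covariates = data.frame(
      name = c("age60", "smoking10", "heavy_drinking", "h_pylori"),
      prevalence = c(0.45, 0.30, 0.25, 0.40),
      beta = log(c(2.0, 1.8, 1.5, 2.2)))),
    structnet = list(mode = "ca_distance", cutoff = 7.0, focal = 68L)
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.data.frame(override[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full prioritization pipeline
#'
#' Orchestrates simulate -> QC -> association (train/validate/combine) ->
#' risk model -> structure network into one seeded, logged run. Every
#' stage persists its artifacts under `config$outDir`; the consolidated
#' report is written both as JSON and as TSV tables containing identical
#' numbers, and rerunning with the same configuration and seed reproduces
#' the JSON report byte for byte.
#'
#' By default the simulate stage draws exact-counts genotypes from the
#' bundled [gastricVariantTable()], so the association stage reproduces
#' the published per-variant statistics; the structnet stage runs on a
#' deterministic toy helix structure with the bundled mutation catalog and
#' stability table.
#'
#' @param config a list of overrides merged onto [pipelineConfig()], or a
#'   path to a YAML file of the same shape.
#' @return invisibly, the run report (list); also written to
#'   `<outDir>/report.json`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(pipelineConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "gwasnet",
                 version = as.character(utils::packageVersion("gwasnet")),
                 seed = cfg$seed, stages = list())
  cfgFile <- file.path(cfg$outDir, "config.json")
  cfgEcho <- cfg
  cfgEcho$risk$covariates <- as.list(cfgEcho$risk$covariates)
  jsonlite::write_json(cfgEcho, cfgFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  # digest over the configuration content, independent of where it is run
  digestFile <- tempfile(fileext = ".json")
  cfgEcho$outDir <- NULL
  jsonlite::write_json(cfgEcho, digestFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report$config_digest <- unname(tools::md5sum(digestFile))
  unlink(digestFile)
  stage <- function(name) name %in% cfg$stages
  failStage <- function(name, e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         " (partial artifacts in ", cfg$outDir, ")", call. = FALSE)

  gd <- NULL
  if (stage("simulate")) {
    tryCatch({
      # observed counts are taken literally; per-variant shortfalls from the
      # group sizes become missing genotypes
      gd <- simulateGenotypes(cfg$simulate$nCases, cfg$simulate$nControls,
                              gastricVariantTable(),
                              missingRate = cfg$simulate$missingRate,
                              mode = cfg$simulate$mode, seed = cfg$seed,
                              trainCases = cfg$simulate$trainCases,
                              trainControls = cfg$simulate$trainControls)
      writeGenotypesTSV(gd, file.path(cfg$outDir, "genotypes.tsv"))
      writeGenotypesVCF(gd, file.path(cfg$outDir, "genotypes.vcf"))
      report$stages$simulate <- list(
        status = "ok", n_samples = ncol(gd), n_variants = nrow(gd))
    }, error = function(e) failStage("simulate", e))
  }

  if (stage("qc")) {
    if (is.null(gd)) stop("qc stage requires the simulate stage (or input genotypes)")
    tryCatch({
      qc <- applyQC(gd, do.call(qcConfig, cfg$qc))
      gd <- qc$genotypes
      writeQCReport(qc$report, cfg$outDir)
      report$stages$qc <- list(status = "ok", steps = qcSteps(qc$report),
                               n_variants_out = nrow(gd),
                               n_samples_out = ncol(gd))
    }, error = function(e) failStage("qc", e))
  }

  if (stage("assoc")) {
    tryCatch({
      tvc <- trainValidateCombine(gd, model = cfg$assoc$model,
                                  topK = cfg$assoc$topK,
                                  alpha = cfg$assoc$alpha)
      full <- runAssociationScan(gd, model = cfg$assoc$model)
      for (nm in c("training", "validation", "combined"))
        write.table(tvc[[nm]], file.path(cfg$outDir, paste0("assoc_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(full, file.path(cfg$outDir, "assoc_full.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      qq <- attr(tvc$training, "qq")
      write.table(qq, file.path(cfg$outDir, "assoc_qq.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$stages$assoc <- list(
        status = "ok", validated = tvc$validated,
        lambda_training = attr(tvc$training, "lambda"),
        combined = tvc$combined, full = full)
    }, error = function(e) failStage("assoc", e))
  }

  if (stage("risk")) {
    tryCatch({
      cv <- simulateCovariates(cfg$risk$covariates, baseline = -1,
                               n = ncol(gd), seed = cfg$seed + 2L)
      # attach the focal-variant genotype indicator when available
      tb <- gastricVariantTable()
      focalVar <- tb$variant[tb$gene == "DHCR7"]
      if (focalVar %in% rownames(gd))
        cv$het_focal <- as.integer(dosages(gd)[focalVar, ] >= 1)
      fit <- fitRiskModel(cv)
      write.table(fit, file.path(cfg$outDir, "risk_forest.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      snpCols <- data.frame(t(dosages(gd)), status = sampleInfo(gd)$status,
                            check.names = TRUE)
      diag <- multiSNPDiagnostic(stats::na.omit(snpCols))
      write.table(diag$roc$curve, file.path(cfg$outDir, "risk_roc.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$risk <- list(status = "ok", forest = fit,
                                 auc = diag$roc$auc)
    }, error = function(e) failStage("risk", e))
  }

  if (stage("structnet")) {
    tryCatch({
      pdbFile <- file.path(cfg$outDir, "synthetic_structure.pdb")
      catalog <- dhcr7MutationCatalog()
      resNames <- rep("ALA", 475)
      resNames[catalog$position] <- .AA1TO3[catalog$wt_aa]
      generateToyStructure(475, "ideal_helix", seed = cfg$seed,
                           resNames = resNames, file = pdbFile)
      struct <- readStructure(pdbFile)
      net <- buildAANetwork(struct, mode = cfg$structnet$mode,
                            cutoff = cfg$structnet$cutoff)
      catalog <- filterCatalogByArray(catalog,
                                      catalog$position[catalog$on_array])
      sel <- selectComutationCandidates(net, cfg$structnet$focal, catalog)
      ddg <- dhcr7StabilityTable()
      rk <- rankDDGTable(ddg, reference = attr(ddg, "reference"))
      write.table(contactEdges(net), file.path(cfg$outDir, "network_edges.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(rk$ranked, file.path(cfg$outDir, "ddg_ranked.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(focal = sel@focal, mean_distance = sel@meanDistance,
             sites = sel@sites, mode = networkMode(net),
             cutoff = networkCutoff(net)),
        file.path(cfg$outDir, "comutation_selection.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$stages$structnet <- list(
        status = "ok", mode = networkMode(net), cutoff = networkCutoff(net),
        mean_distance = meanPathLength(sel),
        candidates = candidateSites(sel)$mutation,
        best_pair = rk$best$pair, best_multi_ddg = rk$best$multi_ddg,
        n_below_reference = rk$n_below_reference)
    }, error = function(e) failStage("structnet", e))
  }

  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  invisible(report)
}

#' Write the worked-example fixture bundle
#'
#' Materializes the bundled inputs as plain-text files: the three-variant
#' genotype-count table (TSV), the eight-row co-mutation stability table
#' (CSV), the mutation catalog (TSV), and a deterministic synthetic toy
#' helix structure (PDB). Regeneration is idempotent: identical content on
#' every call.
#'
#' @param dir output directory (created if absent).
#' @return named character vector of the file paths.
#' @export
exampleFixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- file.path(dir, "genotype_counts.tsv")
  ddg <- file.path(dir, "ddg_table.csv")
  catalog <- file.path(dir, "mutation_catalog.tsv")
  pdb <- file.path(dir, "synthetic_structure.pdb")
  write.table(gastricVariantTable(), counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dhcr7StabilityTable(), ddg, sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(dhcr7MutationCatalog(), catalog, sep = "\t", quote = FALSE,
              row.names = FALSE)
  generateToyStructure(475, "ideal_helix", seed = 1L, file = pdb)
  c(counts = counts, ddg = ddg, catalog = catalog, structure = pdb)
}
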