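#' Read genotype data from TSV or VCF
#'
#' TSV layout: first column `sample_id`, remaining columns one per variant,
#' cells 0/1/2/`NA` (minor-allele dosage). VCF: GT fields are converted to
#' ALT-allele dosage (`./.` = missing); the ALT allele is taken as the
#' minor allele. Sample metadata is joined by sample id.
#'
#' @param file genotype TSV or VCF path (format chosen by extension, or
#'   forced with `format`).
#' @param meta optional sample metadata data.frame or TSV path (column
#'   `sample_id`, then `status`, `sex`, `split`, covariates).
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return a [GenotypeData-class] object.
#' @export
readGenotypes <- function(file, meta = NULL, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", file)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean %in% c("0/0")] <- 0L
    dos[clean %in% c("0/1", "1/0")] <- 1L
    dos[clean %in% c("1/1")] <- 2L
    fx <- vcfR::getFIX(v)
    ids <- fx[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) | ids == "."))
    rownames(dos) <- ids
    vmeta <- data.frame(chrom = fx[, "CHROM"],
                        pos = as.integer(fx[, "POS"]),
                        major = fx[, "REF"], minor = fx[, "ALT"],
                        row.names = ids, stringsAsFactors = FALSE)
  } else {
    tab <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    stopifnot(names(tab)[1] == "sample_id")
    dos <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(dos) <- tab$sample_id
    vmeta <- data.frame(row.names = rownames(dos))
  }
  smeta <- if (is.null(meta)) {
    data.frame(status = rep("control", ncol(dos)), row.names = colnames(dos))
  } else {
    m <- if (is.character(meta))
      read.table(meta, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    else meta
    stopifnot("sample_id" %in% names(m))
    i <- match(colnames(dos), m$sample_id)
    if (anyNA(i)) stop("metadata missing for samples: ",
                       paste(colnames(dos)[is.na(i)], collapse = ", "))
    m <- m[i, , drop = FALSE]
    rownames(m) <- m$sample_id
    m[, setdiff(names(m), "sample_id"), drop = FALSE]
  }
  GenotypeData(dos, sampleData = smeta, variantData = vmeta)
}

#' Write genotype data as TSV
#'
#' Emits the sample-by-variant dosage matrix (`sample_id` first column,
#' `NA` for missing) and, alongside it, a `<file>.meta.tsv` with the sample
#' metadata.
#'
#' @param gd a [GenotypeData-class] object.
#' @param file output TSV path.
#' @return invisibly, the genotype file path.
#' @export
writeGenotypesTSV <- function(gd, file) {
  tab <- data.frame(sample_id = colnames(gd), t(dosages(gd)),
                    check.names = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(gd), sampleInfo(gd),
                     check.names = FALSE)
  write.table(meta, paste0(file, ".meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Write genotype data as a GT-only VCF
#'
#' Minimal VCFv4.2 with a single FORMAT field (GT); dosage 0/1/2 become
#' `0/0`, `0/1`, `1/1` and missing becomes `./.`. REF/ALT default to the
#' `major`/`minor` variant annotation when present.
#'
#' @param gd a [GenotypeData-class] object.
#' @param file output path (plain text).
#' @return invisibly, the file path.
#' @export
writeGenotypesVCF <- function(gd, file) {
  vi <- variantInfo(gd)
  n <- nrow(gd)
  chrom <- if ("chrom" %in% names(vi)) as.character(vi$chrom) else rep(".", n)
  pos <- if ("pos" %in% names(vi)) vi$pos else seq_len(n)
  ref <- if ("major" %in% names(vi)) vi$major else rep("A", n)
  alt <- if ("minor" %in% names(vi)) vi$minor else rep("G", n)
  gtmap <- c("0/0", "0/1", "1/1")
  d <- dosages(gd)
  body <- vapply(seq_len(n), function(i) {
    gt <- ifelse(is.na(d[i, ]), "./.", gtmap[d[i, ] + 1L])
    paste(c(chrom[i], pos[i], rownames(gd)[i], ref[i], alt[i], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gd)), collapse = "\t"),
               body), file)
  invisible(file)
}
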