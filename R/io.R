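# Plain-text cohort I/O. Formats:
#  - phenotypes: CSV (individual_id, family_id, sex, age, center, smoking,
#    tg1..tg4, hdl1..hdl4)
#  - methylation: TSV, rows = CpG ids, columns = sample ids (complete cases)
#  - CpG annotation: BED-like TSV with 1-based hg19 positions
#    (chrom, pos, cpg_id)
#  - genotypes: minimal single-variant VCF (GT field) or a dosage TSV

#' Write a cohort to plain-text files
#'
#' Writes `phenotypes.csv`, `methylation.tsv` (CpGs x complete-case samples),
#' `cpg_annotation.tsv` (chrom, 1-based pos, cpg_id) and either a minimal
#' single-variant VCF (`genotypes.vcf`) or a dosage TSV (`dosages.tsv`).
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir output directory (created if needed).
#' @param genotype_format `"vcf"` or `"tsv"`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("vcf", "tsv")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$data
  paths <- character(0)

  p <- file.path(dir, "phenotypes.csv")
  write.csv(d[, c("individual_id", "family_id", "sex", "age", "center",
                  "smoking", paste0("tg", 1:4), paste0("hdl", 1:4))],
            p, row.names = FALSE, quote = FALSE)
  paths <- c(phenotypes = p)

  keep <- d$complete_case
  m <- t(cohort$beta[keep, , drop = FALSE])  # rows = CpGs, cols = samples
  p <- file.path(dir, "methylation.tsv")
  write.table(data.frame(cpg_id = rownames(m), m, check.names = FALSE),
              p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, methylation = p)

  p <- file.path(dir, "cpg_annotation.tsv")
  write.table(cohort$annotation[, c("chrom", "pos", "cpg_id")], p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, annotation = p)

  if (genotype_format == "vcf") {
    p <- file.path(dir, "genotypes.vcf")
    write_snp_vcf(d$individual_id, d$dosage, cohort$config, p)
  } else {
    p <- file.path(dir, "dosages.tsv")
    write.table(data.frame(individual_id = d$individual_id,
                           dosage = d$dosage), p,
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  paths <- c(paths, genotypes = p)
  invisible(paths)
}

# Minimal VCF 4.2 with one biallelic record; dosage d -> GT 0/0, 0/1, 1/1
# with ALT = effect allele (dosage counts effect alleles).
write_snp_vcf <- function(ids, dosage, cfg, path) {
  gt <- c("0/0", "0/1", "1/1")[dosage + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lipidsem",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  rec <- paste(c(cfg$chrom, cfg$snp_pos, cfg$rsid, "C", "A", ".", "PASS",
                 ".", "GT", gt), collapse = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a wide phenotype table
#'
#' @param path CSV with columns individual_id, family_id, sex, age, center,
#'   smoking, tg1..tg4, hdl1..hdl4.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "family_id", "sex", "age", "center", "smoking",
            paste0("tg", 1:4), paste0("hdl", 1:4))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_bad_arg("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  d$individual_id <- as.character(d$individual_id)
  d$family_id <- as.character(d$family_id)
  d
}

#' Read a methylation beta-value matrix
#'
#' @param path TSV whose first column is `cpg_id` and remaining columns are
#'   samples (as written by [write_cohort()]).
#' @return samples x CpGs numeric matrix.
#' @export
read_methylation <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a BED-like CpG annotation (1-based hg19 positions)
#'
#' @param path TSV with columns chrom, pos, cpg_id.
#' @return data.frame with cpg_id, chrom, pos.
#' @export
read_cpg_annotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "cpg_id")
  if (!all(need %in% names(d)))
    stop_bad_arg("annotation must have columns chrom, pos, cpg_id")
  d$chrom <- as.character(d$chrom)
  d[, c("cpg_id", "chrom", "pos")]
}

#' Read SNP dosages from a dosage TSV or a VCF
#'
#' TSV: columns individual_id, dosage. VCF: parsed with VariantAnnotation
#' (Suggests); the first record's GT field is converted to an
#' effect(ALT)-allele count.
#' @param path file path; format inferred from the extension.
#' @return named integer vector of dosages.
#' @export
read_dosages <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop_bad_arg("reading VCF requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path, genome = "hg19")
    gt <- VariantAnnotation::geno(v)$GT[1L, ]
    dos <- vapply(strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE),
                  function(a) sum(a != "0" & a != "."), 0L)
    return(setNames(as.integer(dos), names(gt)))
  }
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "dosage") %in% names(d)))
    stop_bad_arg("dosage TSV must have columns individual_id, dosage")
  setNames(as.integer(d$dosage), as.character(d$individual_id))
}

#' Assemble a cohort object from user-supplied components
#'
#' Builds the same `lipid_cohort` container as [simulate_cohort()] from a
#' phenotype table, a dosage vector, a methylation matrix, and a CpG
#' annotation, so user data can run through [run_locus()].
#'
#' @param phenotypes data.frame as from [read_phenotypes()].
#' @param dosages named dosage vector (names = individual ids).
#' @param beta samples x CpGs methylation matrix (rownames = individual ids);
#'   individuals absent from its rows become incomplete cases.
#' @param annotation CpG annotation data.frame (cpg_id, chrom, pos).
#' @return a `lipid_cohort` object.
#' @export
as_cohort <- function(phenotypes, dosages, beta, annotation) {
  ids <- phenotypes$individual_id
  if (!all(ids %in% names(dosages)))
    stop_bad_arg("every phenotyped individual needs a dosage")
  full <- matrix(NA_real_, length(ids), ncol(beta),
                 dimnames = list(ids, colnames(beta)))
  shared <- intersect(ids, rownames(beta))
  full[shared, ] <- beta[shared, , drop = FALSE]
  d <- phenotypes
  d$dosage <- as.integer(dosages[ids])
  d$complete_case <- ids %in% shared & stats::complete.cases(full[ids, , drop = FALSE])
  out <- list(data = d, beta = full,
              annotation = annotation, pedigree = NULL, config = NULL,
              calibration = NULL, seed = NULL)
  class(out) <- "lipid_cohort"
  out
}
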