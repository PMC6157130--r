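#' Packaged table of TG-associated tag SNPs and their modeled CpGs
#'
#' Twelve established triglyceride-associated SNPs genotyped on the Affymetrix
#' 6.0 array, with hg19 positions, effect/other alleles, effect-allele
#' frequencies, the number of HM450K CpGs within +/- 10 kb, and the CpG ids
#' modeled at each locus. For rs10503669 (LPL) no CpG lies within 10 kb; its
#' single CpG comes from the +/- 20 kb fallback window.
#'
#' The `expected_tg_direction` column is required by the directional
#' consistency filter but is not part of the published locus table: for the
#' five loci with reported significant pathways it is set to the sign of the
#' reported chain products, and for the remaining seven it is a synthetic
#' convention of +1 (flagged `convention` in `direction_source`).
#'
#' @return data.frame with one row per locus: `rsid`, `chrom`, `pos`, `gene`,
#'   `effect_allele`, `other_allele`, `eaf`, `n_cpgs_10kb`, `cpgs_included`
#'   (comma-separated), `expected_tg_direction`, `direction_source`.
#' @examples
#' loci <- goldn_loci()
#' nrow(loci)  # 12
#' @export
goldn_loci <- function() {
  path <- system.file("extdata", "goldn_loci.tsv", package = "lipidsem",
                      mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  d$expected_tg_direction <- as.integer(d$expected_tg_direction)
  d
}
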