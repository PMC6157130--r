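# Methylation preparation: CpG selection by genomic window around the tag
# SNP, methylation principal components, and PC residualisation.

#' Select CpGs near a tag SNP
#'
#' Returns the CpGs on the SNP's chromosome within a closed +/- window of the
#' SNP position (default 10 kb). If none fall inside, the search is repeated
#' once with the fallback window (default 20 kb) -- the rule used when a tag
#' SNP had no CpG within 10 kb. Positions are 1-based (hg19).
#'
#' @param snp_chrom,snp_pos chromosome label and 1-based position of the SNP.
#' @param annotation data.frame with columns `cpg_id`, `chrom`, `pos`.
#' @param window half-width of the primary window in bp (boundary included).
#' @param fallback_window half-width tried once if the primary window is
#'   empty; must be >= `window`.
#' @return character vector of CpG ids sorted by position (possibly empty;
#'   an absent chromosome yields an empty result with a warning).
#' @examples
#' ann <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "8",
#'                   pos = c(19847690 + 14000, 19847690 + 30000))
#' select_cpgs("8", 19847690, ann)  # empty at 10 kb, cg1 at the 20 kb fallback
#' @export
select_cpgs <- function(snp_chrom, snp_pos, annotation,
                        window = 10000, fallback_window = 20000) {
  if (window > fallback_window)
    stop_bad_arg("window must not exceed fallback_window")
  ann <- annotation[as.character(ann_chrom(annotation)) == as.character(snp_chrom), ,
                    drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("chromosome ", snp_chrom, " absent from the CpG annotation",
            call. = FALSE)
    return(character(0))
  }
  pick <- function(w) {
    hit <- ann[abs(ann$pos - snp_pos) <= w, , drop = FALSE]
    hit$cpg_id[order(hit$pos)]
  }
  ids <- pick(window)
  if (length(ids) == 0L) ids <- pick(fallback_window)
  ids
}

ann_chrom <- function(annotation) {
  if (!all(c("cpg_id", "chrom", "pos") %in% names(annotation)))
    stop_bad_arg("annotation must have columns cpg_id, chrom, pos")
  annotation$chrom
}

#' Methylation principal components
#'
#' Column-centered SVD of the beta-value matrix across all CpGs (no scaling),
#' as used to adjust for cell purity and batch effects. Component signs are
#' fixed by making each component's largest-magnitude loading positive, so
#' results are deterministic.
#'
#' @param beta samples x CpGs matrix in `[0,1]`, no missing entries.
#' @param n_components number of components to retain (default 4).
#' @return an object of class `methylation_pcs`: list with `scores`
#'   (samples x k), `loadings` (CpGs x k), `centered_means` (per-CpG means),
#'   `sdev` (all singular-value SDs).
#' @export
compute_methylation_pcs <- function(beta, n_components = 4L) {
  if (anyNA(beta))
    stop_bad_arg("beta matrix has missing values; filter to complete cases ",
                 "before computing methylation PCs")
  n_components <- as.integer(n_components)
  if (n_components < 0L) stop_bad_arg("n_components must be >= 0")
  if (nrow(beta) < n_components + 1L)
    stop_bad_arg("need at least n_components + 1 samples")
  if (n_components > min(dim(beta)))
    stop_bad_arg("n_components exceeds min(samples, CpGs)")
  pc <- prcomp(beta, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- list(scores = scores, loadings = loadings,
              centered_means = colMeans(beta), sdev = pc$sdev,
              n_components = k)
  class(out) <- "methylation_pcs"
  out
}

#' @export
print.methylation_pcs <- function(x, ...) {
  ev <- x$sdev^2
  cat(sprintf("Methylation PCs: %d retained of %d samples x %d CpGs\n",
              x$n_components, nrow(x$scores), nrow(x$loadings)))
  k <- seq_len(x$n_components)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", k, 100 * ev[k] / sum(ev)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Residualize methylation beta values on principal components
#'
#' Replaces each CpG column by the residual from a least-squares regression on
#' the retained PC scores plus an intercept. Residualized values are centered,
#' uncorrelated with every retained PC, and may leave `[0,1]`; downstream
#' modeling treats them as continuous. With `n_components = 0` the output is
#' simply the column-centered input. Applying the projection twice equals
#' applying it once.
#'
#' @param beta samples x CpGs matrix (same samples as `pcs`).
#' @param pcs a [compute_methylation_pcs()] object.
#' @return matrix of adjusted values, same dimensions and dimnames as `beta`.
#' @export
residualize_methylation <- function(beta, pcs) {
  if (!inherits(pcs, "methylation_pcs"))
    stop_bad_arg("pcs must come from compute_methylation_pcs()")
  if (nrow(beta) != nrow(pcs$scores))
    stop_bad_arg("beta and PC scores cover different numbers of samples")
  centered <- sweep(beta, 2L, colMeans(beta))
  if (pcs$n_components == 0L) return(centered)
  s <- pcs$scores
  fit <- qr(cbind(1, s))
  res <- qr.resid(fit, beta)
  dimnames(res) <- dimnames(beta)
  res
}

#' Write adjusted methylation and PC scores
#'
#' @param adjusted samples x CpGs adjusted matrix.
#' @param pcs a [compute_methylation_pcs()] object.
#' @param dir output directory.
#' @return invisibly, the two paths.
#' @export
write_methylation_adjusted <- function(adjusted, pcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "methylation_adjusted.tsv")
  write.table(data.frame(cpg_id = colnames(adjusted), t(adjusted),
                         check.names = FALSE),
              p1, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, "methylation_pcs.csv")
  write.csv(data.frame(sample_id = rownames(pcs$scores), pcs$scores,
                       check.names = FALSE),
            p2, row.names = FALSE, quote = FALSE)
  invisible(c(adjusted = p1, pcs = p2))
}
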