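# Per-locus orchestration: assemble the analysis frame, fit the full model
# with family-clustered inference, gate on fit indices, prune nonsignificant
# CpGs once and refit if needed, decompose SNP -> TG4 pathway effects, and
# summarise across loci with a Bonferroni threshold.

default_pipeline_options <- function() {
  list(alpha = 0.05,            # nominal pathway significance
       prune_threshold = 0.2,   # CpG path p-value above which a CpG may go
       prune_rule = "both",     # both paths nonsignificant (conjunction)
       iterate_prune = FALSE,   # one pruning pass by default
       fit_rule = "any",        # any failing index flags poor fit
       n_pcs = 4L,              # methylation PCs removed before modeling
       min_complete = 100L,
       small_sample = FALSE)
}

#' Build the per-locus analysis frame from a cohort
#'
#' Restricts to complete cases, computes methylation PCs across all CpGs in
#' the cohort's beta matrix, residualizes the beta values on the first
#' `n_pcs` PCs, and returns a modeling frame with columns `SNP`, the
#' covariates, `TG1..TG4`, `HDL1..HDL4`, one column per CpG (adjusted beta
#' values) and `family_id`.
#'
#' @param cohort a `lipid_cohort`.
#' @param n_pcs number of methylation PCs to remove (default 4).
#' @return data.frame of complete cases.
#' @export
cohort_to_model_frame <- function(cohort, n_pcs = 4L) {
  d <- cohort$data
  keep <- d$complete_case & stats::complete.cases(
    d[, c("sex", "age", "center", "smoking", "dosage",
          paste0("tg", 1:4), paste0("hdl", 1:4))])
  d <- d[keep, , drop = FALSE]
  beta <- cohort$beta[keep, , drop = FALSE]
  # PCs are estimated across all supplied CpGs; with only a handful of locus
  # CpGs (synthetic cohorts) the leading PCs ARE the locus biology, so the
  # adjustment is skipped unless the matrix is wide enough for the PCs to
  # capture array-level structure instead.
  adj <- if (n_pcs > 0L && ncol(beta) > 5L * n_pcs &&
             nrow(beta) > n_pcs + 1L) {
    pcs <- compute_methylation_pcs(beta, n_pcs)
    residualize_methylation(beta, pcs)
  } else scale(beta, center = TRUE, scale = FALSE)
  out <- data.frame(SNP = d$dosage, sex = d$sex, age = d$age,
                    center = d$center, smoking = d$smoking,
                    family_id = d$family_id,
                    stringsAsFactors = FALSE)
  for (t in 1:4) {
    out[[paste0("TG", t)]] <- d[[paste0("tg", t)]]
    out[[paste0("HDL", t)]] <- d[[paste0("hdl", t)]]
  }
  for (j in colnames(beta)) out[[j]] <- adj[, j]
  rownames(out) <- d$individual_id
  out
}

#' Prune nonsignificant CpGs from a fitted model
#'
#' A CpG is removed when its mQTL path (SNP -> CpG) and its outcome path
#' (CpG -> TG2) are BOTH nonsignificant at the threshold (robust-z p > 0.2 by
#' default); `rule = "either"` removes a CpG when at least one path is
#' nonsignificant. All qualifying CpGs are removed in one pass and the default
#' structure is rebuilt on the reduced CpG set.
#'
#' @param fit a converged [sem_fit()] with robust covariance.
#' @param threshold p-value threshold (default 0.2).
#' @param rule `"both"` (conjunction, default) or `"either"`.
#' @return list with `model` (reduced [path_model()]) and `trace`
#'   (data.frame: cpg, p_snp_to_cpg, p_cpg_to_tg2, removed).
#' @export
prune_cpgs <- function(fit, threshold = 0.2, rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (!fit$converged) stop_bad_arg("fit did not converge; cannot prune")
  model <- fit$model
  cpgs <- model$cpg_ids
  ptab <- summary(fit)$coefficients
  trace <- data.frame(cpg = character(0), p_snp_to_cpg = numeric(0),
                      p_cpg_to_tg2 = numeric(0), removed = logical(0))
  if (length(cpgs)) {
    p_in <- ptab[paste0(cpgs, "~SNP"), "p"]
    p_out <- ptab[paste0("TG2~", cpgs), "p"]
    removed <- if (rule == "both") p_in > threshold & p_out > threshold
               else p_in > threshold | p_out > threshold
    trace <- data.frame(cpg = cpgs, p_snp_to_cpg = unname(p_in),
                        p_cpg_to_tg2 = unname(p_out), removed = removed,
                        stringsAsFactors = FALSE)
  }
  kept <- trace$cpg[!trace$removed]
  locus <- model$locus
  locus$cpg_ids <- kept
  covariates <- setdiff(model$exogenous, "SNP")
  list(model = path_model(locus, covariates), trace = trace)
}

#' Run the full per-locus analysis
#'
#' Pipeline: build the a priori model, fit by ML with family-clustered robust
#' covariance, compute fit indices; if the full model fits poorly, prune
#' nonsignificant CpGs once and refit; enumerate all SNP -> TG4 pathways,
#' compute delta-method effects, and retain the nominally significant,
#' directionally consistent ones. Pathway claims are suppressed when even the
#' pruned model fails the fit gates.
#'
#' @param cohort a `lipid_cohort` (simulated or assembled from files).
#' @param locus a [locus_config()] / `goldn_loci()` row; by default derived
#'   from the cohort's own configuration (synthetic cohorts) with expected
#'   direction +1 unless `options$expected_direction` says otherwise.
#' @param covariates covariate names, default sex, age, center, smoking.
#' @param options named list overriding [default_pipeline_options()] entries.
#' @return object of class `locus_report`: locus, model_stage
#'   (`"full"`/`"pruned"`), removed_cpgs, fit (the final [sem_fit()]),
#'   fit_indices, pathway_table (NULL when suppressed), significant_table,
#'   total_effect, bonferroni_alpha (filled by [run_all_loci()]), pruning
#'   trace and provenance.
#' @export
run_locus <- function(cohort, locus = NULL,
                      covariates = c("sex", "age", "center", "smoking"),
                      options = list()) {
  opts <- utils::modifyList(default_pipeline_options(), options)
  if (is.null(locus)) {
    cfg <- cohort$config
    if (is.null(cfg))
      stop_bad_arg("locus is required for cohorts assembled from files")
    locus <- locus_config(cfg$rsid, cfg$chrom, cfg$snp_pos,
                          eaf = cfg$eaf,
                          expected_tg_direction =
                            opts$expected_direction %||% 1,
                          cpg_ids = colnames(cohort$beta))
  }
  if (inherits(locus, "data.frame")) {
    cpgs <- trimws(strsplit(locus$cpgs_included, ",", fixed = TRUE)[[1L]])
    locus <- locus_config(locus$rsid, locus$chrom, locus$pos,
                          locus$effect_allele, locus$other_allele, locus$eaf,
                          locus$expected_tg_direction, cpgs)
  }
  frame <- cohort_to_model_frame(cohort, opts$n_pcs)
  if (nrow(frame) < opts$min_complete)
    stop_bad_arg("only ", nrow(frame), " complete cases; need at least ",
                 opts$min_complete)
  miss_cpg <- setdiff(locus$cpg_ids, names(frame))
  if (length(miss_cpg))
    stop_bad_arg("cohort lacks CpGs: ", paste(miss_cpg, collapse = ", "))

  model <- path_model(locus, covariates)
  fit <- sem_fit(model, frame, method = "ml", cluster = frame$family_id,
                 small_sample = opts$small_sample)
  idx <- fit_indices(fit, rule = opts$fit_rule)
  stage <- "full"
  trace <- NULL
  removed <- character(0)

  repeat {
    if (idx$acceptable || length(fit$model$cpg_ids) == 0L) break
    pr <- prune_cpgs(fit, opts$prune_threshold, opts$prune_rule)
    trace <- if (is.null(trace)) pr$trace else rbind(trace, pr$trace)
    newly <- pr$trace$cpg[pr$trace$removed]
    if (length(newly) == 0L) break
    removed <- c(removed, newly)
    fit <- sem_fit(pr$model, frame, method = "ml",
                   cluster = frame$family_id,
                   small_sample = opts$small_sample)
    idx <- fit_indices(fit, rule = opts$fit_rule)
    stage <- "pruned"
    if (!opts$iterate_prune) break
  }

  pathway_table <- NULL
  significant_table <- NULL
  total <- NULL
  if (idx$acceptable) {
    pathway_table <- pathway_effects(fit, "SNP", "TG4")
    significant_table <- significant_pathways(pathway_table, opts$alpha,
                                              locus$expected_tg_direction)
    total <- total_effect(fit, "SNP", "TG4")
  }

  out <- list(locus = locus, model_stage = stage, removed_cpgs = removed,
              fit = fit, fit_indices = idx,
              pathway_table = pathway_table,
              significant_table = significant_table,
              total_effect = total,
              bonferroni_alpha = NA_real_,
              pruning_trace = trace,
              provenance = list(
                seed = cohort$seed,
                n = fit$n, n_clusters = fit$n_clusters,
                package_version = as.character(utils::packageVersion("lipidsem")),
                r_version = R.version.string,
                data_digest = sprintf("%.10e", sum(frame$TG4) + sum(frame$SNP)),
                options = opts))
  class(out) <- "locus_report"
  out
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("Locus %s: %s model, n = %d (%d families)\n",
              x$locus$rsid, x$model_stage, x$fit$n, x$fit$n_clusters))
  if (length(x$removed_cpgs))
    cat("  pruned CpGs:", paste(x$removed_cpgs, collapse = ", "), "\n")
  print(x$fit_indices)
  if (is.null(x$pathway_table)) {
    cat("  model fit poor even after pruning: pathway table suppressed\n")
  } else {
    st <- x$significant_table
    cat(sprintf("  significant directionally consistent pathways: %d of %d\n",
                nrow(st), nrow(x$pathway_table)))
    if (nrow(st))
      for (i in seq_len(nrow(st)))
        cat(sprintf("    %s: beta %.4g (se %.4g), p %.4g\n",
                    st$pathway[i], st$beta[i], st$se[i], st$p[i]))
    cat(sprintf("  total SNP effect on TG4: %.4g (se %.4g)\n",
                x$total_effect$beta, x$total_effect$se))
  }
  invisible(x)
}

#' Run the pipeline across several loci
#'
#' Fits each locus on its own cohort and summarises all retained pathways,
#' flagging those passing the Bonferroni threshold `alpha / n_loci`.
#'
#' @param loci a data.frame in [goldn_loci()] layout (one row per locus).
#' @param cohorts optional named list of `lipid_cohort` objects keyed by rsid;
#'   loci without a supplied cohort get a synthetic one from
#'   [cohort_config_for_locus()].
#' @param n_individuals size of simulated cohorts (default 810).
#' @param seed base seed; locus i uses `seed + i`.
#' @param covariates,options passed to [run_locus()].
#' @return object of class `multi_locus_report`: per-locus reports, a summary
#'   data.frame of retained chains with `bonferroni_significant`, and the
#'   threshold used.
#' @export
run_all_loci <- function(loci, cohorts = NULL, n_individuals = 810L,
                         seed = 1L,
                         covariates = c("sex", "age", "center", "smoking"),
                         options = list()) {
  if (nrow(loci) < 1L) stop_bad_arg("need at least one locus")
  if (anyDuplicated(loci$rsid))
    stop_bad_arg("duplicate rsids in the locus table")
  thr <- bonferroni_threshold(0.05, nrow(loci))
  reports <- vector("list", nrow(loci))
  names(reports) <- loci$rsid
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, , drop = FALSE]
    coh <- if (!is.null(cohorts) && row$rsid %in% names(cohorts))
      cohorts[[row$rsid]]
    else simulate_cohort(cohort_config_for_locus(row,
                                                 n_individuals = n_individuals),
                         seed = seed + i)
    rep_i <- run_locus(coh, locus = row, covariates = covariates,
                       options = options)
    rep_i$bonferroni_alpha <- as.numeric(thr)
    reports[[i]] <- rep_i
    st <- rep_i$significant_table
    if (!is.null(st) && nrow(st)) {
      st$locus <- row$rsid
      st$rmsea <- rep_i$fit_indices$rmsea
      st$cfi <- rep_i$fit_indices$cfi
      st$tli <- rep_i$fit_indices$tli
      st$bonferroni_significant <- st$p < as.numeric(thr)
      rows[[length(rows) + 1L]] <- st
    }
  }
  summary_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(0), beta = numeric(0), se = numeric(0),
               p = numeric(0), locus = character(0),
               bonferroni_significant = logical(0))
  out <- list(reports = reports, summary = summary_tab,
              bonferroni_alpha = as.numeric(thr),
              bonferroni_display = attr(thr, "display"),
              n_loci = nrow(loci))
  class(out) <- "multi_locus_report"
  out
}

#' @export
print.multi_locus_report <- function(x, ...) {
  cat(sprintf("Multi-locus report: %d loci, Bonferroni threshold %.3g (reported %.3g)\n",
              x$n_loci, x$bonferroni_alpha, x$bonferroni_display))
  s <- x$summary
  if (nrow(s) == 0L) {
    cat("  no significant directionally consistent pathways\n")
  } else {
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %s %s: beta %.4g, p %.4g%s\n", s$locus[i], s$pathway[i],
                  s$beta[i], s$p[i],
                  if (s$bonferroni_significant[i]) " **Bonferroni**" else ""))
  }
  invisible(x)
}

#' Write a locus report to TSV and JSON
#'
#' The TSV mirrors the published per-locus layout: locus, intermediate,
#' pathway, beta, se, p, rmsea, cfi, tli (retained pathways only). The JSON
#' carries the full report including provenance and the pruning trace.
#'
#' @param report a [run_locus()] object.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_locus_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rsid <- report$locus$rsid
  tsv <- file.path(dir, paste0(rsid, "_pathways.tsv"))
  st <- report$significant_table
  tab <- if (is.null(st) || nrow(st) == 0L) {
    data.frame(locus = character(0), intermediate = character(0),
               pathway = character(0), beta = numeric(0), se = numeric(0),
               p = numeric(0), rmsea = numeric(0), cfi = numeric(0),
               tli = numeric(0))
  } else {
    data.frame(locus = rsid,
               intermediate = vapply(strsplit(st$pathway, " \u2192 ",
                                              fixed = TRUE),
                                     function(ch) if (length(ch) > 2L)
                                       ch[2L] else "direct", ""),
               pathway = st$pathway, beta = st$beta, se = st$se, p = st$p,
               rmsea = report$fit_indices$rmsea,
               cfi = report$fit_indices$cfi, tli = report$fit_indices$tli)
  }
  write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)

  js <- file.path(dir, paste0(rsid, "_report.json"))
  obj <- list(locus = unclass(report$locus),
              model_stage = report$model_stage,
              removed_cpgs = report$removed_cpgs,
              fit_indices = unclass(report$fit_indices),
              acceptable = report$fit_indices$acceptable,
              pathways = report$pathway_table,
              significant = st,
              total_effect = report$total_effect,
              bonferroni_alpha = report$bonferroni_alpha,
              pruning_trace = report$pruning_trace,
              provenance = report$provenance)
  jsonlite::write_json(obj, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  invisible(c(tsv = tsv, json = js))
}
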