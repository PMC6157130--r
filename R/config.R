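#' Generator configuration for synthetic family cohorts
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate the GOLDN-like cohort the path models were designed for: 172
#' nuclear families totalling 810 genotyped adults, 707 of whom carry complete
#' CD4+ T-cell methylation data; ~50% women; mean baseline age 48 years;
#' fasting triglycerides (TG) and HDL cholesterol measured at four visits with
#' a fenofibrate-induced drop in both the mean and the variance of TG between
#' visits 2 and 3.
#'
#' The structural data model is recursive and operates on the log scale
#' (lipids are strictly positive and right-skewed, so marginal distributions
#' are lognormal with visit-specific moments matched to `tg_target` /
#' `hdl_target`):
#' \itemize{
#'   \item SNP dosage and covariates act on every TG and HDL visit;
#'   \item lag-1 carryover `log TG[t-1] -> log TG[t]` and likewise for HDL;
#'   \item contemporaneous `log HDL[t] -> log TG[t]`;
#'   \item the SNP shifts CpG beta values (mQTL effect) and CpG beta values
#'     act on visit-2 TG (methylation is measured at visit 2);
#'   \item a shared family random intercept on each trait;
#'   \item visit-specific lognormal residuals.
#' }
#' All slopes are therefore proportional (per log-unit) effects. When
#' `calibrate = TRUE` (default) the per-visit intercepts and residual
#' variances are solved analytically so that the population mean and SD of
#' TG/HDL at every visit equal the targets *exactly* (see the methods
#' vignette); effect sizes must be modest enough to leave a positive residual
#' variance.
#'
#' @param n_individuals total genotyped individuals (default 810).
#' @param n_families number of nuclear families (default 172, scaled
#'   proportionally when `n_individuals` differs from 810).
#' @param n_complete number of complete-case individuals (methylation
#'   present); default scales the 707/810 complete-case fraction.
#' @param family_size_probs family-size distribution, see
#'   [default_family_size_probs()].
#' @param rsid,chrom,snp_pos,eaf tag-SNP identity and effect-allele frequency
#'   (default rs1748195: chr1:63049593, EAF 0.636).
#' @param cpg_ids optional CpG identifiers; default `n_cpgs` synthetic ids.
#' @param n_cpgs number of CpGs at the locus (ignored when `cpg_ids` given).
#' @param cpg_base baseline methylation beta value per CpG (recycled).
#' @param snp_to_cpg_effect beta-value shift per effect allele, per CpG
#'   (recycled; default: first CpG is a true mQTL at 0.04/allele, the rest
#'   null).
#' @param cpg_noise_sd SD of the CpG measurement noise on the beta scale.
#' @param cpg_to_tg_effect log-TG shift per unit beta value, per CpG
#'   (recycled; default: first CpG affects visit-2 TG, the rest null).
#' @param sex_prob,age_mean,age_sd,center_prob,smoking_prob covariate
#'   distributions (sex 0 = male / 1 = female; age in years; center and
#'   smoking binary).
#' @param snp_to_tg,snp_to_hdl per-allele log-scale effect on each TG / HDL
#'   visit.
#' @param lag_tg,lag_hdl autoregressive (visit t-1 to t) coefficients.
#' @param hdl_to_tg contemporaneous log HDL -> log TG slope (negative:
#'   TG and HDL are inversely related).
#' @param covariate_effects_tg,covariate_effects_hdl named numeric vectors of
#'   log-scale covariate effects (names `sex`, `age`, `center`, `smoking`).
#' @param family_sd_tg,family_sd_hdl SD of the shared family intercept on the
#'   log scale.
#' @param tg_target 2 x 2 matrix-like `data.frame(mean, sd)` for visits 1-2 of
#'   TG in mg/dL. Defaults to the printed cohort moments
#'   (106.35\[106.35\], 140.16\[99.34\]). Visit 3-4 targets are constructed as
#'   the visit-2 target times the fenofibrate multipliers.
#' @param fenofibrate_mean_shift,fenofibrate_scale multiplicative shifts of
#'   the TG mean and SD at visits 3 and 4 relative to visit 2 (length 2,
#'   recycled). Defaults are the printed post/pre-treatment ratios, so default
#'   visit 3-4 targets are 92.26\[57.41\] and 90.14\[55.07\]. Setting both to 1
#'   ("no fenofibrate") makes visit 3-4 moments equal visit-2 moments.
#' @param hdl_mean,hdl_sd HDL target moments per visit (mg/dL; not printed in
#'   the source study -- invented defaults 47\[13\]).
#' @param calibrate logical; solve intercepts/residual SDs from the targets
#'   (default) or use `residual_sd_tg`/`residual_sd_hdl` directly.
#' @param residual_sd_tg,residual_sd_hdl log-scale residual SDs per visit
#'   (recycled to length 4), used only when `calibrate = FALSE`.
#' @param missing_rate optional MCAR methylation missingness rate; when
#'   supplied it overrides `n_complete` targeting.
#' @param seed default seed stored in the config (used by [simulate_cohort()]
#'   when no seed is passed).
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [goldn_loci()]
#' @export
cohort_config <- function(n_individuals = 810L,
                          n_families = max(1L, round(172 * n_individuals / 810)),
                          n_complete = round(707 * n_individuals / 810),
                          family_size_probs = default_family_size_probs(),
                          rsid = "rs1748195",
                          chrom = "1",
                          snp_pos = 63049593L,
                          eaf = 0.636,
                          cpg_ids = NULL,
                          n_cpgs = 2L,
                          cpg_base = c(0.55, 0.45),
                          snp_to_cpg_effect = c(0.04, 0),
                          cpg_noise_sd = 0.03,
                          cpg_to_tg_effect = c(0.8, 0),
                          sex_prob = 0.5,
                          age_mean = 48,
                          age_sd = 12,
                          center_prob = 0.5,
                          smoking_prob = 0.18,
                          snp_to_tg = 0.04,
                          snp_to_hdl = -0.05,
                          lag_tg = 0.5,
                          lag_hdl = 0.6,
                          hdl_to_tg = -0.35,
                          covariate_effects_tg = c(sex = -0.10, age = 0.004,
                                                   center = 0.02, smoking = 0.05),
                          covariate_effects_hdl = c(sex = 0.15, age = 0.001,
                                                    center = 0.01, smoking = -0.05),
                          family_sd_tg = 0.12,
                          family_sd_hdl = 0.05,
                          tg_target = data.frame(mean = c(106.35, 140.16),
                                                 sd = c(106.35, 99.34)),
                          fenofibrate_mean_shift = c(92.26, 90.14) / 140.16,
                          fenofibrate_scale = c(57.41, 55.07) / 99.34,
                          hdl_mean = 47,
                          hdl_sd = 13,
                          calibrate = TRUE,
                          residual_sd_tg = 0.45,
                          residual_sd_hdl = 0.22,
                          missing_rate = NULL,
                          seed = NULL) {
  if (n_individuals < 2L * n_families)
    stop_bad_arg("n_individuals must allow two founders per family")
  check_prob(eaf, "eaf"); check_prob(sex_prob, "sex_prob")
  check_prob(center_prob, "center_prob"); check_prob(smoking_prob, "smoking_prob")
  check_pos(age_sd, "age_sd", strict = FALSE)
  check_pos(cpg_noise_sd, "cpg_noise_sd", strict = FALSE)
  check_pos(family_sd_tg, "family_sd_tg", strict = FALSE)
  check_pos(family_sd_hdl, "family_sd_hdl", strict = FALSE)
  check_pos(c(tg_target$mean, tg_target$sd), "tg_target")
  check_pos(c(hdl_mean, hdl_sd), "hdl target moments")
  check_pos(fenofibrate_mean_shift, "fenofibrate_mean_shift")
  check_pos(fenofibrate_scale, "fenofibrate_scale")
  if (nrow(tg_target) != 2L)
    stop_bad_arg("tg_target must give visit-1 and visit-2 moments (2 rows)")
  if (!is.null(missing_rate)) check_prob(missing_rate, "missing_rate")
  if (is.null(n_complete) && is.null(missing_rate))
    stop_bad_arg("one of n_complete or missing_rate is required")

  if (!is.null(cpg_ids)) n_cpgs <- length(cpg_ids)
  n_cpgs <- as.integer(n_cpgs)
  if (n_cpgs < 1L) stop_bad_arg("n_cpgs must be >= 1")
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cgS%06d", seq_len(n_cpgs))
  if (anyDuplicated(cpg_ids)) stop_bad_arg("cpg_ids must be distinct")
  # default effect patterns adapt to the locus's CpG count: first CpG is the
  # active mQTL/mediator, the rest are null
  if (missing(snp_to_cpg_effect))
    snp_to_cpg_effect <- c(0.04, numeric(max(n_cpgs - 1L, 0L)))[seq_len(n_cpgs)]
  if (missing(cpg_to_tg_effect))
    cpg_to_tg_effect <- c(0.8, numeric(max(n_cpgs - 1L, 0L)))[seq_len(n_cpgs)]
  pad <- function(x, nm) {
    if (length(x) > n_cpgs)
      stop_bad_arg(nm, " longer than the number of CpGs")
    c(x, rep(0, n_cpgs - length(x)))
  }
  cpg_base <- rep_len(cpg_base, n_cpgs)
  snp_to_cpg_effect <- pad(snp_to_cpg_effect, "snp_to_cpg_effect")
  cpg_to_tg_effect <- pad(cpg_to_tg_effect, "cpg_to_tg_effect")
  check_prob(cpg_base, "cpg_base")

  fenofibrate_mean_shift <- rep_len(fenofibrate_mean_shift, 2L)
  fenofibrate_scale <- rep_len(fenofibrate_scale, 2L)
  # visit 3-4 targets: untreated continuation of visit 2, times the shift
  tg_moments <- data.frame(
    visit = 1:4,
    mean = c(tg_target$mean,
             tg_target$mean[2L] * fenofibrate_mean_shift),
    sd = c(tg_target$sd, tg_target$sd[2L] * fenofibrate_scale))
  hdl_moments <- data.frame(visit = 1:4,
                            mean = rep_len(hdl_mean, 4L),
                            sd = rep_len(hdl_sd, 4L))

  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_families = as.integer(n_families),
    n_complete = if (is.null(missing_rate)) as.integer(n_complete) else NULL,
    missing_rate = missing_rate,
    family_size_probs = family_size_probs,
    rsid = rsid, chrom = as.character(chrom), snp_pos = as.integer(snp_pos),
    eaf = eaf,
    cpg_ids = cpg_ids, n_cpgs = n_cpgs, cpg_base = cpg_base,
    snp_to_cpg_effect = snp_to_cpg_effect, cpg_noise_sd = cpg_noise_sd,
    cpg_to_tg_effect = cpg_to_tg_effect,
    sex_prob = sex_prob, age_mean = age_mean, age_sd = age_sd,
    center_prob = center_prob, smoking_prob = smoking_prob,
    snp_to_tg = snp_to_tg, snp_to_hdl = snp_to_hdl,
    lag_tg = lag_tg, lag_hdl = lag_hdl, hdl_to_tg = hdl_to_tg,
    covariate_effects_tg = covariate_effects_tg,
    covariate_effects_hdl = covariate_effects_hdl,
    family_sd_tg = family_sd_tg, family_sd_hdl = family_sd_hdl,
    tg_moments = tg_moments, hdl_moments = hdl_moments,
    fenofibrate_mean_shift = fenofibrate_mean_shift,
    fenofibrate_scale = fenofibrate_scale,
    calibrate = isTRUE(calibrate),
    residual_sd_tg = rep_len(residual_sd_tg, 4L),
    residual_sd_hdl = rep_len(residual_sd_hdl, 4L),
    seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Configuration for a locus from the packaged locus table
#'
#' Convenience wrapper: fills the SNP identity, position, EAF and CpG ids of
#' [cohort_config()] from one row of [goldn_loci()].
#' @param locus a single-row data.frame as returned by `goldn_loci()`.
#' @param ... further arguments passed to [cohort_config()].
#' @export
cohort_config_for_locus <- function(locus, ...) {
  stopifnot(nrow(locus) == 1L)
  cpgs <- strsplit(locus$cpgs_included, ",", fixed = TRUE)[[1L]]
  cohort_config(rsid = locus$rsid, chrom = as.character(locus$chrom),
                snp_pos = locus$pos, eaf = locus$eaf,
                cpg_ids = trimws(cpgs), ...)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic family-cohort configuration\n")
  cat(sprintf("  %d individuals in %d families; complete cases: %s\n",
              x$n_individuals, x$n_families,
              if (is.null(x$n_complete)) sprintf("MCAR rate %.3f", x$missing_rate)
              else x$n_complete))
  cat(sprintf("  SNP %s (chr%s:%d), EAF %.3f; %d CpGs\n",
              x$rsid, x$chrom, x$snp_pos, x$eaf, x$n_cpgs))
  cat("  TG targets (mg/dL):\n")
  for (t in 1:4)
    cat(sprintf("    visit %d: mean %.2f, SD %.2f\n", t,
                x$tg_moments$mean[t], x$tg_moments$sd[t]))
  cat(sprintf("  calibrated: %s\n", x$calibrate))
  invisible(x)
}
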