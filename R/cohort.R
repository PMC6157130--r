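# Cohort generation.
#
# The structural model is linear and recursive on the log scale, so every
# log-lipid is a linear combination of mutually independent primitives
# (dosage, covariates, CpG noise, family intercepts, visit residuals) plus a
# constant. Exact two-moment calibration per visit: with K1 = prod MGF_k(c_k)
# and K2 = prod MGF_k(2 c_k) over the non-residual primitives,
#   E exp(L) = exp(a + v/2) K1,   E exp(2L) = exp(2a + 2v) K2,
# so the residual variance v and flattened constant a solving mean m / SD s are
#   v = log(((s^2 + m^2) / m^2) * K1^2 / K2),   a = log(m / K1) - v / 2.
# Effect sizes must leave v > 0.

prim_specs <- function(cfg) {
  specs <- list(
    g = list(type = "binom2", p = cfg$eaf),
    sex = list(type = "bern", p = cfg$sex_prob),
    age = list(type = "norm", mu = cfg$age_mean, sd = cfg$age_sd),
    center = list(type = "bern", p = cfg$center_prob),
    smoking = list(type = "bern", p = cfg$smoking_prob))
  for (j in seq_len(cfg$n_cpgs))
    specs[[paste0("w", j)]] <- list(type = "norm", mu = 0, sd = cfg$cpg_noise_sd)
  specs$u_tg <- list(type = "norm", mu = 0, sd = cfg$family_sd_tg)
  specs$u_hdl <- list(type = "norm", mu = 0, sd = cfg$family_sd_hdl)
  specs
}

prim_mgf <- function(spec, c) {
  if (c == 0) return(1)
  switch(spec$type,
         binom2 = (1 - spec$p + spec$p * exp(c))^2,
         bern = 1 - spec$p + spec$p * exp(c),
         norm = exp(spec$mu * c + 0.5 * spec$sd^2 * c^2))
}

prim_mean <- function(spec) {
  switch(spec$type, binom2 = 2 * spec$p, bern = spec$p, norm = spec$mu)
}

prim_var <- function(spec) {
  switch(spec$type,
         binom2 = 2 * spec$p * (1 - spec$p),
         bern = spec$p * (1 - spec$p),
         norm = spec$sd^2)
}

# Solve residual variance + flattened constant hitting mean m, SD s exactly.
solve_lognormal <- function(coefs, specs, m, s, label) {
  k1 <- prod(vapply(seq_along(specs),
                    function(k) prim_mgf(specs[[k]], coefs[k]), 0))
  k2 <- prod(vapply(seq_along(specs),
                    function(k) prim_mgf(specs[[k]], 2 * coefs[k]), 0))
  v <- log(((s^2 + m^2) / m^2) * k1^2 / k2)
  if (!is.finite(v) || v <= 0)
    stop_bad_arg("calibration failed for ", label,
                 ": structural variance exceeds the target; ",
                 "reduce effect sizes or raise the target SD")
  list(v = v, const = log(m / k1) - v / 2)
}

# Flattened coefficient vectors (over primitives) and structural constants for
# log HDL and log TG at all visits; intercepts/residual SDs solved when
# calibrating, mean-matched under a normal approximation otherwise. The
# primitive list GROWS as each visit's residual is solved, so residual
# carryover through the lags is propagated exactly.
calibrate_cohort <- function(cfg) {
  specs <- prim_specs(cfg)
  cov_nm <- c("sex", "age", "center", "smoking")
  pad <- function(co) c(co, numeric(length(specs) - length(co)))

  h_coef <- vector("list", 4L); h_const <- numeric(4L)
  l_coef <- vector("list", 4L); l_const <- numeric(4L)
  nu_h <- numeric(4L); nu_l <- numeric(4L)
  sd_h <- numeric(4L); sd_l <- numeric(4L)

  solve_visit <- function(co, cc, m, s, fixed_sd, label) {
    # returns list(sd, nu, const); co excludes the visit's own residual
    if (cfg$calibrate) {
      sol <- solve_lognormal(co, specs, m, s, label)
      list(sd = sqrt(sol$v), nu = sol$const - cc, const = sol$const)
    } else {
      vv <- sum(co^2 * vapply(specs, prim_var, 0)) + fixed_sd^2
      mc <- sum(co * vapply(specs, prim_mean, 0))
      tot <- log(m) - vv / 2 - mc
      list(sd = fixed_sd, nu = tot - cc, const = tot)
    }
  }

  for (t in 1:4) {
    co <- setNames(numeric(length(specs)), names(specs))
    co["g"] <- cfg$snp_to_hdl
    co[cov_nm] <- cfg$covariate_effects_hdl[cov_nm]
    co["u_hdl"] <- 1
    cc <- 0
    if (t > 1L) {
      co <- co + pad(cfg$lag_hdl * h_coef[[t - 1L]])
      cc <- cc + cfg$lag_hdl * h_const[t - 1L]
    }
    sol <- solve_visit(co, cc, cfg$hdl_moments$mean[t], cfg$hdl_moments$sd[t],
                       cfg$residual_sd_hdl[t], paste0("HDL", t))
    sd_h[t] <- sol$sd; nu_h[t] <- sol$nu; h_const[t] <- sol$const
    specs[[paste0("eh", t)]] <- list(type = "norm", mu = 0, sd = sd_h[t])
    co <- pad(co); co[length(co)] <- 1
    names(co) <- names(specs)
    h_coef[[t]] <- co
  }

  for (t in 1:4) {
    co <- setNames(numeric(length(specs)), names(specs))
    co["g"] <- cfg$snp_to_tg
    co[cov_nm] <- cfg$covariate_effects_tg[cov_nm]
    co["u_tg"] <- 1
    cc <- 0
    if (t > 1L) {
      co <- co + pad(cfg$lag_tg * l_coef[[t - 1L]])
      cc <- cc + cfg$lag_tg * l_const[t - 1L]
    }
    co <- co + pad(cfg$hdl_to_tg * h_coef[[t]])
    cc <- cc + cfg$hdl_to_tg * h_const[t]
    if (t == 2L) {
      # CpG beta_j = base_j + slope_j * g + w_j feeds visit-2 TG
      co["g"] <- co["g"] + sum(cfg$cpg_to_tg_effect * cfg$snp_to_cpg_effect)
      for (j in seq_len(cfg$n_cpgs))
        co[paste0("w", j)] <- co[paste0("w", j)] + cfg$cpg_to_tg_effect[j]
      cc <- cc + sum(cfg$cpg_to_tg_effect * cfg$cpg_base)
    }
    sol <- solve_visit(co, cc, cfg$tg_moments$mean[t], cfg$tg_moments$sd[t],
                       cfg$residual_sd_tg[t], paste0("TG", t))
    sd_l[t] <- sol$sd; nu_l[t] <- sol$nu; l_const[t] <- sol$const
    specs[[paste0("el", t)]] <- list(type = "norm", mu = 0, sd = sd_l[t])
    co <- pad(co); co[length(co)] <- 1
    names(co) <- names(specs)
    l_coef[[t]] <- co
  }

  list(nu_hdl = nu_h, nu_tg = nu_l, sd_hdl = sd_h, sd_tg = sd_l)
}

#' Simulate a synthetic family cohort
#'
#' Draws a full cohort -- nuclear-family pedigree, Mendelian SNP dosages,
#' covariates, CpG beta values with an mQTL effect, and four visits of
#' lognormal TG/HDL with lag-1 carryover, a contemporaneous HDL-to-TG arrow, a
#' visit-2 methylation effect on TG, shared family intercepts, and a
#' fenofibrate mean/variance drop between visits 2 and 3 -- following the
#' configuration from [cohort_config()]. Under the default calibrated mode,
#' the population mean and SD of TG and HDL at each visit equal the
#' configuration targets exactly (sample moments converge as n grows).
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed (falls back to `config$seed`); the same
#'   config + seed reproduce the cohort exactly.
#' @return an object of class `lipid_cohort`: a list with elements
#'   \describe{
#'     \item{data}{per-individual data.frame: ids, covariates, `dosage`,
#'       `tg1..tg4`, `hdl1..hdl4`, `complete_case`.}
#'     \item{beta}{individuals x CpGs matrix of methylation beta values in
#'       `[0,1]`; rows of incomplete cases are `NA`.}
#'     \item{annotation}{CpG annotation (cpg_id, chrom, 1-based pos).}
#'     \item{pedigree, config, calibration}{provenance.}
#'   }
#' @examples
#' cfg <- cohort_config(n_individuals = 400)
#' coh <- simulate_cohort(cfg, seed = 1)
#' colMeans(coh$data[paste0("tg", 1:4)])
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config"))
    stop_bad_arg("config must come from cohort_config()")
  cfg <- config
  if (length(cfg$snp_to_cpg_effect) != cfg$n_cpgs ||
      length(cfg$cpg_to_tg_effect) != cfg$n_cpgs)
    stop_bad_arg("CpG effect vectors must match n_cpgs")
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  cal <- calibrate_cohort(cfg)

  ped <- simulate_pedigrees(cfg$n_families, cfg$family_size_probs,
                            n_total = cfg$n_individuals)
  n <- nrow(ped)
  g <- simulate_genotypes(ped, cfg$eaf)

  sex <- ped$sex
  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  center <- rbinom(n, 1L, cfg$center_prob)
  smoking <- rbinom(n, 1L, cfg$smoking_prob)
  fam <- factor(ped$family_id)
  u_tg <- rnorm(nlevels(fam), 0, cfg$family_sd_tg)[fam]
  u_hdl <- rnorm(nlevels(fam), 0, cfg$family_sd_hdl)[fam]

  beta <- matrix(NA_real_, n, cfg$n_cpgs,
                 dimnames = list(ped$individual_id, cfg$cpg_ids))
  for (j in seq_len(cfg$n_cpgs))
    beta[, j] <- pmin(1, pmax(0, cfg$cpg_base[j] +
                                cfg$snp_to_cpg_effect[j] * g +
                                rnorm(n, 0, cfg$cpg_noise_sd)))

  cov_tg <- cfg$covariate_effects_tg
  cov_hdl <- cfg$covariate_effects_hdl
  xb_tg <- cfg$snp_to_tg * g + cov_tg["sex"] * sex + cov_tg["age"] * age +
    cov_tg["center"] * center + cov_tg["smoking"] * smoking + u_tg
  xb_hdl <- cfg$snp_to_hdl * g + cov_hdl["sex"] * sex + cov_hdl["age"] * age +
    cov_hdl["center"] * center + cov_hdl["smoking"] * smoking + u_hdl

  H <- matrix(0, n, 4L); L <- matrix(0, n, 4L)
  for (t in 1:4) {
    H[, t] <- cal$nu_hdl[t] + xb_hdl +
      (if (t > 1L) cfg$lag_hdl * H[, t - 1L] else 0) +
      rnorm(n, 0, cal$sd_hdl[t])
    L[, t] <- cal$nu_tg[t] + xb_tg +
      (if (t > 1L) cfg$lag_tg * L[, t - 1L] else 0) +
      cfg$hdl_to_tg * H[, t] +
      (if (t == 2L) drop(beta %*% cfg$cpg_to_tg_effect) else 0) +
      rnorm(n, 0, cal$sd_tg[t])
  }
  tg <- exp(L); hdl <- exp(H)
  colnames(tg) <- paste0("tg", 1:4); colnames(hdl) <- paste0("hdl", 1:4)

  complete <- if (!is.null(cfg$missing_rate)) {
    runif(n) >= cfg$missing_rate
  } else {
    n_c <- min(cfg$n_complete, n)
    seq_len(n) %in% sample.int(n, n_c)
  }
  beta[!complete, ] <- NA_real_

  offs <- round(seq(-8000, 8000, length.out = cfg$n_cpgs + 2L))
  offs <- offs[seq_len(cfg$n_cpgs) + 1L]  # interior points, never at the SNP
  annotation <- data.frame(cpg_id = cfg$cpg_ids, chrom = cfg$chrom,
                           pos = cfg$snp_pos + offs,
                           stringsAsFactors = FALSE)

  dat <- data.frame(individual_id = ped$individual_id,
                    family_id = ped$family_id,
                    sex = sex, age = age, center = center, smoking = smoking,
                    dosage = g, tg, hdl, complete_case = complete,
                    stringsAsFactors = FALSE)
  out <- list(data = dat, beta = beta, annotation = annotation,
              pedigree = ped, config = cfg, calibration = cal, seed = seed)
  class(out) <- "lipid_cohort"
  out
}

#' @export
print.lipid_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("Synthetic lipid cohort: %d individuals, %d families, %d CpGs\n",
              nrow(d), length(unique(d$family_id)), ncol(x$beta)))
  cat(sprintf("  SNP %s, EAF %.3f (sample mean dosage %.3f)\n",
              x$config$rsid, x$config$eaf, mean(d$dosage)))
  cat(sprintf("  complete cases: %d; women: %.1f%%; mean age %.1f\n",
              sum(d$complete_case), 100 * mean(d$sex), mean(d$age)))
  for (t in 1:4)
    cat(sprintf("  TG%d mean %.2f SD %.2f | HDL%d mean %.2f SD %.2f\n",
                t, mean(d[[paste0("tg", t)]]), sd(d[[paste0("tg", t)]]),
                t, mean(d[[paste0("hdl", t)]]), sd(d[[paste0("hdl", t)]])))
  invisible(x)
}
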