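# pedigree, genotype and cohort generator

test_that("degenerate pedigree: one family of two founders", {
  ped <- simulate_pedigrees(1, size_probs = c(`2` = 1), seed = 1)
  expect_equal(nrow(ped), 2L)
  expect_equal(length(unique(ped$family_id)), 1L)
  expect_true(all(is.na(ped$father_id)))
  expect_true(all(is.na(ped$mother_id)))
  expect_equal(sort(ped$sex), c(0L, 1L))
})

test_that("pedigree has the requested family count and is seed-deterministic", {
  ped <- simulate_pedigrees(172, seed = 1)
  expect_equal(length(unique(ped$family_id)), 172L)
  expect_identical(ped, simulate_pedigrees(172, seed = 1))
  ped810 <- simulate_pedigrees(172, n_total = 810, seed = 2)
  expect_equal(nrow(ped810), 810L)
  # non-founders reference two members of their own family
  off <- ped810[!is.na(ped810$father_id), ]
  fam_of <- setNames(ped810$family_id, ped810$individual_id)
  expect_true(all(fam_of[off$father_id] == off$family_id))
  expect_true(all(fam_of[off$mother_id] == off$family_id))
  expect_error(simulate_pedigrees(0), "positive")
})

test_that("genotypes: fixed alleles, HWE mean, Mendelian consistency", {
  ped <- simulate_pedigrees(5000, size_probs = c(`2` = 1), seed = 3)
  expect_true(all(simulate_genotypes(ped, 0, seed = 1) == 0L))
  expect_true(all(simulate_genotypes(ped, 1, seed = 1) == 2L))
  # 10,000 founders at the rs1748195 allele frequency: mean within 3 SE
  g <- simulate_genotypes(ped, 0.636, seed = 4)
  se <- sqrt(2 * 0.636 * (1 - 0.636) / length(g))
  expect_lt(abs(mean(g) - 1.272), 3 * se)
  expect_error(simulate_genotypes(ped, 1.2), "\\[0, 1\\]")

  # Mendelian transmission: offspring dosage attainable from parent dosages
  ped <- simulate_pedigrees(300, seed = 5)
  g <- simulate_genotypes(ped, 0.4, seed = 6)
  names(g) <- ped$individual_id
  off <- ped[!is.na(ped$father_id), ]
  gf <- g[off$father_id]; gm <- g[off$mother_id]; go <- g[off$individual_id]
  expect_true(all(go >= (gf == 2L) + (gm == 2L)))
  expect_true(all(go <= (gf > 0L) + (gm > 0L)))
})

test_that("noiseless zero-effect limit: TG equals the visit target exactly", {
  cfg <- cohort_config(n_individuals = 40, n_families = 10, n_complete = 40,
                       calibrate = FALSE,
                       snp_to_tg = 0, snp_to_hdl = 0, lag_tg = 0, lag_hdl = 0,
                       hdl_to_tg = 0, snp_to_cpg_effect = c(0, 0),
                       cpg_to_tg_effect = c(0, 0), cpg_noise_sd = 0,
                       covariate_effects_tg = c(sex = 0, age = 0, center = 0,
                                                smoking = 0),
                       covariate_effects_hdl = c(sex = 0, age = 0, center = 0,
                                                 smoking = 0),
                       family_sd_tg = 0, family_sd_hdl = 0,
                       residual_sd_tg = 0, residual_sd_hdl = 0)
  coh <- simulate_cohort(cfg, seed = 1)
  for (t in 1:4) {
    expect_equal(unique(round(coh$data[[paste0("tg", t)]], 9)),
                 round(cfg$tg_moments$mean[t], 9))
    expect_equal(unique(round(coh$data[[paste0("hdl", t)]], 9)),
                 round(cfg$hdl_moments$mean[t], 9))
  }
})

test_that("cohort is byte-identical under the same config and seed", {
  cfg <- cohort_config(n_individuals = 200)
  expect_identical(simulate_cohort(cfg, seed = 11),
                   simulate_cohort(cfg, seed = 11))
})

test_that("dominant family effect drives within-family TG correlation to ~1", {
  cfg <- cohort_config(n_individuals = 2000, calibrate = FALSE,
                       family_sd_tg = 2, residual_sd_tg = 0.01,
                       snp_to_tg = 0, hdl_to_tg = 0, lag_tg = 0,
                       covariate_effects_tg = c(sex = 0, age = 0, center = 0,
                                                smoking = 0))
  coh <- simulate_cohort(cfg, seed = 2)
  y <- log(coh$data$tg1)
  fam <- coh$data$family_id
  within <- y - stats::ave(y, fam)
  icc <- 1 - var(within) / var(y)
  expect_gt(icc, 0.95)
})

test_that("without the fenofibrate shift, visit 3-4 moments match visit 2", {
  cfg <- cohort_config(n_individuals = 20000,
                       fenofibrate_mean_shift = 1, fenofibrate_scale = 1)
  expect_equal(cfg$tg_moments$mean[3:4], rep(cfg$tg_moments$mean[2], 2))
  expect_equal(cfg$tg_moments$sd[3:4], rep(cfg$tg_moments$sd[2], 2))
  coh <- simulate_cohort(cfg, seed = 3)
  for (t in 3:4) {
    expect_lt(abs(mean(coh$data[[paste0("tg", t)]]) /
                    cfg$tg_moments$mean[2] - 1), 0.04)
    expect_lt(abs(sd(coh$data[[paste0("tg", t)]]) /
                    cfg$tg_moments$sd[2] - 1), 0.08)
  }
})

test_that("cohort invariants: beta in [0,1], positive lipids, dosage coding", {
  coh <- simulate_cohort(cohort_config(n_individuals = 400), seed = 4)
  b <- coh$beta[coh$data$complete_case, ]
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(is.na(coh$beta[!coh$data$complete_case, ])))
  expect_true(all(as.matrix(coh$data[paste0("tg", 1:4)]) > 0))
  expect_true(all(as.matrix(coh$data[paste0("hdl", 1:4)]) > 0))
  expect_true(all(coh$data$dosage %in% 0:2))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(eaf = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(n_cpgs = 2,
                             snp_to_cpg_effect = c(0.1, 0.1, 0.1)),
               "longer than")
  expect_error(cohort_config(n_individuals = 100, n_families = 60),
               "two founders")
  expect_error(simulate_cohort(list()), "cohort_config")
})

test_that("MCAR missingness rate reproduces the expected complete fraction", {
  cfg <- cohort_config(n_individuals = 4000, missing_rate = 0.13,
                       n_complete = NULL)
  coh <- simulate_cohort(cfg, seed = 5)
  expect_lt(abs(mean(coh$data$complete_case) - 0.87), 0.02)
})
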