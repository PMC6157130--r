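# chain products, delta-method SEs, total-effect conservation, filters

test_that("two-edge delta SE reproduces the Sobel closed form", {
  out <- chain_product_se(c(0.5, 2.0), diag(c(0.1, 0.2)^2))
  expect_equal(out$beta, 1.0)
  expect_equal(out$se, sqrt(2^2 * 0.1^2 + 0.5^2 * 0.2^2), tolerance = 1e-12)
  expect_equal(round(out$se, 4), 0.2236)
  # a zero coefficient annihilates the product
  expect_equal(chain_product_se(c(0.5, 0, 2), diag(3) * 0.01)$beta, 0)
  expect_error(chain_product_se(c(1, 2), diag(3)), "disagree")
})

test_that("single-edge chain returns the coefficient and its robust SE", {
  set.seed(1)
  sys <- random_system(31)
  d <- sys$data
  d$fam <- rep(1:60, length.out = nrow(d))
  f <- sem_fit(sys$model, d, cluster = "fam")
  edge <- sys$model$edges[sys$model$edges$from %in% sys$model$exogenous, ][1, ]
  eff <- indirect_effect(f, c(edge$from, edge$to))
  nm <- paste0(edge$to, "~", edge$from)
  expect_equal(eff$beta, unname(coef(f)[nm]))
  expect_equal(eff$se, unname(sqrt(f$vcov_robust[nm, nm])))
  expect_error(indirect_effect(f, c(edge$to, edge$from)), "non-edges")
})

test_that("total effect equals the sum of enumerated chain products exactly", {
  set.seed(2)
  coh <- simulate_cohort(cohort_config(n_individuals = 600), seed = 9)
  rep1 <- run_locus(coh, options = list(min_complete = 50))
  f <- rep1$fit
  pt <- pathway_effects(f, "SNP", "TG4")
  tot <- total_effect(f, "SNP", "TG4")
  expect_equal(tot$beta, sum(pt$beta), tolerance = 1e-10)
  # conservation: direct edge + indirect chains
  direct <- coef(f)["TG4~SNP"]
  indirect <- sum(pt$beta[pt$n_edges > 1])
  expect_equal(tot$beta, unname(direct + indirect), tolerance = 1e-10)
})

test_that("total effect handles disconnection and single edges", {
  set.seed(3)
  m1 <- new_path_model(c("M", "Y"), "X",
                       data.frame(from = c("X", "M"), to = c("M", "Y")))
  d <- simulate_from_theta(
    m1, setNames(c(0.5, 2, 0, 0, 1, 1),
                 c("M~X", "Y~M", "M~1", "Y~1", "M~~M", "Y~~Y")),
    data.frame(X = rnorm(400)))
  f1 <- sem_fit(m1, d)
  # X reaches Y only through M: total = product of the two edges
  expect_equal(total_effect(f1, "X", "Y")$beta,
               unname(coef(f1)["M~X"] * coef(f1)["Y~M"]), tolerance = 1e-12)
  # no path at all
  m2 <- new_path_model(c("M", "Y"), "X", data.frame(from = "X", to = "M"))
  f2 <- sem_fit(m2, d)
  expect_equal(total_effect(f2, "X", "Y")$beta, 0)
  # a single direct edge is its own total
  m3 <- new_path_model(c("M", "Y"), "X", data.frame(from = "X", to = "Y"))
  f3 <- sem_fit(m3, d)
  expect_equal(total_effect(f3, "X", "Y")$beta, unname(coef(f3)["Y~X"]),
               tolerance = 1e-12)
})

test_that("delta-method SE of longer chains matches a parametric bootstrap", {
  set.seed(4)
  cfg <- cohort_config(n_individuals = 810, snp_to_hdl = -0.08,
                       hdl_to_tg = -0.5, snp_to_tg = 0)
  coh <- simulate_cohort(cfg, seed = 17)
  rep1 <- run_locus(coh)
  f <- rep1$fit
  chain <- c("SNP", "HDL1", "HDL2", "HDL3", "TG3", "TG4")
  eff <- indirect_effect(f, chain)
  nm <- paste0(chain[-1], "~", chain[-length(chain)])
  V <- f$vcov_robust[nm, nm]
  draws <- rmvn(10000, coef(f)[nm], V)
  boot_se <- sd(apply(draws, 1, prod))
  expect_lt(abs(eff$se / boot_se - 1), 0.05)
})

test_that("significance and direction filters follow the reporting rule", {
  eff <- data.frame(
    pathway = c("a", "b", "c", "d"),
    n_edges = c(3L, 3L, 3L, 1L),
    beta = c(0.4, 0.5, -0.3, 0.2),
    se = c(0.2, 0.26, 0.1, 0.11),
    p = c(0.046, 0.06, 0.01, 0.04))
  kept <- significant_pathways(eff, alpha = 0.05, expected_direction = 1)
  expect_equal(kept$pathway, c("a", "d"))     # p<.05 and positive
  dropped <- attr(kept, "direction_dropped")
  expect_equal(dropped$pathway, "c")          # significant but wrong sign
  expect_error(significant_pathways(eff, expected_direction = 0), "\\+1")
})

test_that("Bonferroni threshold is exact and displays to one digit", {
  thr <- bonferroni_threshold(0.05, 12)
  expect_equal(as.numeric(thr), 0.05 / 12, tolerance = 1e-15)
  expect_equal(attr(thr, "display"), 0.004)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 10)), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})
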