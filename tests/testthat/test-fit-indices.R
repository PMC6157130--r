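# chi-square, RMSEA, CFI/TLI and the poor-fit gates

test_that("closed forms match hand arithmetic", {
  expect_equal(rmsea(50, 20, 300), sqrt(30 / 6000), tolerance = 1e-12)
  expect_equal(round(rmsea(50, 20, 300), 4), 0.0707)
  expect_equal(rmsea(20, 20, 300), 0)      # T = df: perfect fit
  expect_equal(rmsea(10, 20, 300), 0)      # T < df clamps to zero
  expect_error(rmsea(50, 0, 300), "df = 0")

  ct <- cfi_tli(50, 20, 500, 36)
  expect_equal(round(ct$cfi, 4), 0.9353)
  expect_equal(round(ct$tli, 4), 0.8836)
  expect_equal(cfi_tli(20, 20, 500, 36)$cfi, 1)   # zero noncentrality
  ct0 <- cfi_tli(500, 36, 500, 37)
  expect_lt(ct0$cfi, 0.05)                        # model ~ baseline
  expect_warning(ctd <- cfi_tli(50, 20, 30, 36), "degenerate")
  expect_equal(ctd$cfi, 1)
})

test_that("index monotonicities hold", {
  # rmsea non-increasing in df at fixed T, n
  vals <- vapply(5:40, function(df) rmsea(50, df, 300), 0)
  expect_true(all(diff(vals) <= 1e-12))
  # cfi non-increasing in T at fixed baseline
  cfis <- vapply(seq(20, 400, by = 20),
                 function(T) cfi_tli(T, 20, 500, 36)$cfi, 0)
  expect_true(all(diff(cfis) <= 1e-12))
})

test_that("the poor-fit gate is disjunctive with poor boundaries", {
  ok <- list(rmsea = 0.083, cfi = 0.96, tli = 0.93)
  expect_true(assess_fit(ok))
  expect_false(assess_fit(list(rmsea = 0.10, cfi = 0.96, tli = 0.93)))
  expect_false(assess_fit(list(rmsea = 0.05, cfi = 0.90, tli = 0.93)))
  expect_false(assess_fit(list(rmsea = 0.05, cfi = 0.96, tli = 0.90)))
  # conjunctive option: only all-fail counts as poor
  expect_true(assess_fit(list(rmsea = 0.12, cfi = 0.95, tli = 0.95),
                         rule = "all"))
  expect_false(assess_fit(list(rmsea = 0.12, cfi = 0.8, tli = 0.8),
                          rule = "all"))
})

test_that("a saturated model has T = 0, df = 0 and perfect indices", {
  set.seed(1)
  p <- 4; q <- 2
  endo <- paste0("Y", 1:p); exo <- paste0("X", 1:q)
  full <- rbind(
    do.call(rbind, lapply(2:p, function(j)
      data.frame(from = endo[seq_len(j - 1)], to = endo[j]))),
    expand.grid(from = exo, to = endo, stringsAsFactors = FALSE))
  m <- new_path_model(endo, exo, full)
  theta <- setNames(runif(length(lipidsem:::parameter_index(m)), 0.2, 1),
                    names(lipidsem:::parameter_index(m)))
  d <- simulate_from_theta(m, theta,
                           as.data.frame(matrix(rnorm(300 * q), 300,
                                                dimnames = list(NULL, exo))))
  f <- sem_fit(m, d, method = "ols")
  ch <- chi_square(f)
  expect_equal(ch$df, 0)
  expect_lt(abs(ch$T), 1e-6)
  idx <- fit_indices(f)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$cfi, 1)
  expect_true(idx$acceptable)
})

test_that("null simulation: mean chi-square tracks df, poor-fit rate is low", {
  set.seed(2)
  sys <- random_system(21)
  reps <- 300L
  n <- 400L
  exo <- sys$data[, sys$model$exogenous, drop = FALSE]
  Ts <- numeric(reps)
  poor <- logical(reps)
  for (r in seq_len(reps)) {
    exo_r <- as.data.frame(lapply(exo, function(.) rnorm(n)))
    d <- simulate_from_theta(sys$model, sys$theta, exo_r)
    f <- sem_fit(sys$model, d, method = "ols")
    idx <- fit_indices(f)
    Ts[r] <- idx$T
    poor[r] <- !idx$acceptable
  }
  df <- fit_indices(sem_fit(sys$model, sys$data, method = "ols"))$df
  expect_gt(df, 0)
  expect_lt(abs(mean(Ts) / df - 1), 0.10)
  expect_lt(mean(poor), 0.20)
})

test_that("dropping a truly active edge strictly increases the chi-square", {
  set.seed(3)
  m <- path_model(default_locus(0))
  theta <- true_theta(m)
  d <- simulate_from_theta(m, theta, make_exo_frame(800))
  T_full <- chi_square(sem_fit(m, d, method = "ols"))$T
  m_red <- path_model(default_locus(0),
                      overrides = list(remove = data.frame(from = "HDL4",
                                                           to = "TG4")))
  T_red <- chi_square(sem_fit(m_red, d, method = "ols"))$T
  expect_gt(T_red, T_full)
})
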