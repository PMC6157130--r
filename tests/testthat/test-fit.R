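# estimation: least-squares oracle, numeric ML, robust sandwich

test_that("noiseless chain is identified exactly", {
  set.seed(1)
  m <- new_path_model(c("M", "Y"), "X",
                      data.frame(from = c("X", "M"), to = c("M", "Y")))
  x <- rnorm(100)
  d <- data.frame(X = x, M = 0.5 * x, Y = 2 * (0.5 * x))
  f <- fit_ols_equations(m, d)
  expect_equal(unname(coef(f)["M~X"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(coef(f)["Y~M"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(coef(f)[c("M~1", "Y~1")]), c(0, 0), tolerance = 1e-10)
})

test_that("parameters are recovered within 3 SE at n = 5000", {
  set.seed(2)
  m <- path_model(default_locus(1))
  theta <- true_theta(m)
  d <- simulate_from_theta(m, theta, make_exo_frame(5000))
  f <- sem_fit(m, d, method = "ols")
  se <- sqrt(diag(f$vcov_model))
  slopes <- grep("~~", names(theta), invert = TRUE, value = TRUE)
  expect_true(all(abs(coef(f)[slopes] - theta[slopes]) <
                    3.3 * se[slopes] + 1e-12))
})

test_that("numeric ML equals per-equation least squares", {
  set.seed(3)
  for (seed in c(101, 202)) {
    sys <- random_system(seed)
    f1 <- fit_ols_equations(sys$model, sys$data)
    f2 <- fit_ml(sys$model, sys$data)
    expect_true(f2$converged)
    expect_lt(max(abs(coef(f1) - coef(f2))), 1e-6)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  }
})

test_that("ML initialised at the optimum converges immediately", {
  set.seed(4)
  sys <- random_system(7)
  f_ols <- fit_ols_equations(sys$model, sys$data)
  f_ml <- fit_ml(sys$model, sys$data, init = coef(f_ols))
  expect_true(f_ml$converged)
  # at most two Newton iterations per equation from a stationary start
  expect_lte(f_ml$iterations, 2L * length(sys$model$endogenous))
  expect_lt(max(abs(coef(f_ml) - coef(f_ols))), 1e-8)
})

test_that("tightening the tolerance leaves estimates stable", {
  sys <- random_system(9)
  f1 <- fit_ml(sys$model, sys$data, tol = 1e-8)
  f2 <- fit_ml(sys$model, sys$data, tol = 1e-9)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-6)
})

test_that("collinear parents raise a rank-deficiency error naming the equation", {
  set.seed(5)
  m <- new_path_model("Y", c("X1", "X2"),
                      data.frame(from = c("X1", "X2"), to = "Y"))
  d <- data.frame(X1 = rnorm(50))
  d$X2 <- 2 * d$X1
  d$Y <- d$X1 + rnorm(50)
  expect_error(sem_fit(m, d), "rank-deficient.*Y")
})

test_that("missing data and absent variables are rejected", {
  sys <- random_system(11)
  d <- sys$data
  d[1, sys$model$endogenous[1]] <- NA
  expect_error(sem_fit(sys$model, d), "missing")
  expect_error(sem_fit(sys$model, d[, -1]), "lacks")
})

test_that("singleton clusters reproduce the HC0 covariance", {
  set.seed(6)
  n <- 200
  m <- new_path_model("Y", "X", data.frame(from = "X", to = "Y"))
  d <- data.frame(X = rnorm(n))
  d$Y <- 1 + 0.7 * d$X + rnorm(n, 0, sqrt(1 + d$X^2))  # heteroskedastic
  f <- sem_fit(m, d, cluster = seq_len(n))
  # independent HC0 arithmetic for the coefficient block
  Xm <- cbind(1, d$X)
  r <- d$Y - Xm %*% coef(f)[c("Y~1", "Y~X")]
  bread <- solve(crossprod(Xm))
  meat <- crossprod(Xm * as.vector(r))
  hc0 <- bread %*% meat %*% bread
  expect_equal(unname(f$vcov_robust[c("Y~1", "Y~X"), c("Y~1", "Y~X")]),
               unname(hc0), tolerance = 1e-10)
})

test_that("family clustering inflates the SNP coefficient's robust SE", {
  set.seed(7)
  # Moulton setup: dosage shared within a family AND a family random
  # intercept in the outcome -- the model-based SE is then too small and the
  # clustered sandwich must exceed it in nearly every replicate
  m <- new_path_model("Y", "SNP", data.frame(from = "SNP", to = "Y"))
  theta <- setNames(c(0.5, 0, 1), c("Y~SNP", "Y~1", "Y~~Y"))
  n <- 600; n_fam <- 150
  fam <- rep(seq_len(n_fam), each = n / n_fam)
  wins <- 0L
  reps <- 50L
  for (r in seq_len(reps)) {
    exo <- data.frame(SNP = rbinom(n_fam, 2, 0.5)[fam])
    d <- simulate_from_theta(m, theta, exo, cluster = fam, cluster_sd = 1.5)
    d$family_id <- fam
    f <- sem_fit(m, d, cluster = "family_id", method = "ols")
    if (f$vcov_robust["Y~SNP", "Y~SNP"] > f$vcov_model["Y~SNP", "Y~SNP"])
      wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.9)
})

test_that("i.i.d. data: robust and model-based SEs agree within 15%", {
  set.seed(77)
  m <- new_path_model("Y", "SNP", data.frame(from = "SNP", to = "Y"))
  theta <- setNames(c(0.5, 0, 1), c("Y~SNP", "Y~1", "Y~~Y"))
  n <- 1000; n_fam <- 200
  fam <- rep(seq_len(n_fam), each = n / n_fam)
  ratios <- replicate(30, {
    exo <- data.frame(SNP = rbinom(n, 2, 0.5))
    d <- simulate_from_theta(m, theta, exo)  # no cluster effect
    d$family_id <- fam
    f <- sem_fit(m, d, cluster = "family_id", method = "ols")
    sqrt(f$vcov_robust["Y~SNP", "Y~SNP"] / f$vcov_model["Y~SNP", "Y~SNP"])
  })
  expect_true(all(abs(ratios - 1) < 0.15))
})

test_that("robust covariance requires sane inputs", {
  sys <- random_system(13)
  f <- sem_fit(sys$model, sys$data)
  expect_error(robust_vcov(f, cluster = rep(1, 5)), "every observation")
  expect_warning(robust_vcov(f, cluster = rep(1:3, length.out = f$n)),
                 "anti-conservative")
})

test_that("simulate and predict methods are coherent", {
  set.seed(8)
  sys <- random_system(15)
  f <- sem_fit(sys$model, sys$data)
  sims <- simulate(f, nsim = 200, seed = 1)
  mu <- predict(f)
  # Monte-Carlo mean of simulated endogenous matches the reduced-form mean
  v <- sys$model$endogenous[length(sys$model$endogenous)]
  mc <- rowMeans(sapply(sims, function(s) s[[v]]))
  expect_lt(mean(abs(mc - mu[, v])), 0.5)
  expect_equal(dim(residuals(f)), c(f$n, length(sys$model$endogenous)))
})
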