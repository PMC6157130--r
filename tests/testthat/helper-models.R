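# shared fixtures: small models, random recursive systems, exogenous frames

default_locus <- function(n_cpgs = 1L, direction = 1) {
  locus_config("rsTEST", "1", 1000000L, eaf = 0.636,
               expected_tg_direction = direction,
               cpg_ids = if (n_cpgs) sprintf("cg%02d", seq_len(n_cpgs))
                         else character(0))
}

# exogenous frame: SNP dosage + the four default covariates
make_exo_frame <- function(n, eaf = 0.636) {
  data.frame(SNP = rbinom(n, 2L, eaf),
             sex = rbinom(n, 1L, 0.5),
             age = rnorm(n, 48, 12),
             center = rbinom(n, 1L, 0.5),
             smoking = rbinom(n, 1L, 0.2))
}

# plausible true theta for the default locus model, O(1) scale
true_theta <- function(model) {
  idx <- lipidsem:::parameter_index(model)
  theta <- setNames(numeric(length(idx)), names(idx))
  set.seed(model_theta_seed)
  for (nm in names(theta)) {
    theta[nm] <- if (grepl("~~", nm)) runif(1, 0.5, 1.5)
    else if (grepl("~1$", nm)) runif(1, -1, 1)
    else runif(1, 0.2, 0.8) * sample(c(-1, 1), 1)
  }
  theta
}
model_theta_seed <- 20240915

# random small recursive model + matching random theta and exogenous data
random_system <- function(seed) {
  set.seed(seed)
  p <- sample(3:6, 1)
  q <- sample(2:3, 1)
  endo <- paste0("Y", seq_len(p))
  exo <- paste0("X", seq_len(q))
  edges <- list()
  for (j in 2:p) for (i in seq_len(j - 1))
    if (runif(1) < 0.5) edges[[length(edges) + 1L]] <-
      data.frame(from = endo[i], to = endo[j])
  for (x in exo) for (y in endo)
    if (runif(1) < 0.6) edges[[length(edges) + 1L]] <-
      data.frame(from = x, to = y)
  # guarantee at least one edge
  edges[[length(edges) + 1L]] <- data.frame(from = exo[1], to = endo[1])
  e <- unique(do.call(rbind, edges))
  model <- new_path_model(endo, exo, e)
  idx <- lipidsem:::parameter_index(model)
  theta <- setNames(numeric(length(idx)), names(idx))
  for (nm in names(theta)) {
    theta[nm] <- if (grepl("~~", nm)) runif(1, 0.5, 2)
    else runif(1, -1, 1)
  }
  n <- 300L
  exo_data <- as.data.frame(setNames(lapply(exo, function(.) rnorm(n)), exo))
  data <- simulate_from_theta(model, theta, exo_data)
  list(model = model, theta = theta, data = data)
}

# brute-force path count oracle: in a DAG every directed walk is simple, so
# the number of s->t paths is sum_k (A^k)[s, t]
brute_force_path_count <- function(model, source, sink) {
  vars <- c(model$endogenous, model$exogenous)
  V <- length(vars)
  A <- matrix(0, V, V, dimnames = list(vars, vars))
  for (i in seq_len(nrow(model$edges)))
    A[model$edges$from[i], model$edges$to[i]] <- 1
  total <- 0
  P <- diag(V)
  dimnames(P) <- list(vars, vars)
  for (k in seq_len(V)) {
    P <- P %*% A
    total <- total + P[source, sink]
  }
  total
}

# multivariate normal sampler (Cholesky), for parametric-bootstrap oracles
rmvn <- function(n, mu, Sigma) {
  L <- chol((Sigma + t(Sigma)) / 2)
  matrix(rnorm(n * length(mu)), n) %*% L + rep(mu, each = n)
}

# default locus matching a synthetic cohort's own configuration
run_locus_locus <- function(coh) {
  locus_config(coh$config$rsid, coh$config$chrom, coh$config$snp_pos,
               eaf = coh$config$eaf, cpg_ids = colnames(coh$beta))
}
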