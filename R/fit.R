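# Maximum-likelihood estimation of the recursive path model.
#
# The model is y = nu + B y + G x + e with B strictly triangular in some
# ordering (recursive) and diagonal residual covariance psi. Conditional on
# the exogenous x, the likelihood factorises over equations in topological
# order, so the ML solution coincides with per-equation least squares with
# variance divisor n. Two routes are provided: "ols" (closed form) and "ml"
# (numeric optimisation of the per-equation Gaussian likelihood), which serve
# as oracles for each other.

#' Fit a path model by maximum likelihood
#'
#' Estimates all free parameters (edge coefficients, intercepts, residual
#' variances) of a recursive path model from complete-case data, conditioning
#' on the exogenous variables. `method = "ols"` solves each equation by least
#' squares (the exact ML solution for a recursive model with diagonal residual
#' covariance); `method = "ml"` maximises the conditional Gaussian
#' log-likelihood numerically (BFGS with analytic gradients on internally
#' standardised data) and must agree with the closed form to high precision.
#' When `cluster` is supplied, a family-clustered Huber-White sandwich
#' covariance is attached (see [robust_vcov()]).
#'
#' @param model a [path_model()].
#' @param data data.frame containing every model variable as a numeric column;
#'   rows with missing values in model variables are an error (complete-case
#'   analysis only).
#' @param method `"ml"` (default) or `"ols"`.
#' @param cluster optional cluster (family) assignment, length `nrow(data)`,
#'   or the name of a column of `data`.
#' @param small_sample logical; apply the G/(G-1) cluster correction to the
#'   sandwich (default `FALSE`, plain HC0-style).
#' @param init optional named starting vector (theta scale) for `method="ml"`.
#' @param tol gradient-norm convergence tolerance for `method = "ml"`.
#' @return an object of class `sem_fit`: list with `theta` (named parameter
#'   vector: edge coefficients `to~from`, intercepts `v~1`, residual variances
#'   `v~~v`), `vcov_model`, `vcov_robust` (NULL without clusters), `loglik`,
#'   `n`, `n_clusters`, `converged`, `iterations`, `model`, plus the stored
#'   model frame for refits.
#' @seealso [robust_vcov()], [fit_indices()], [pathway_effects()]
#' @export
sem_fit <- function(model, data, method = c("ml", "ols"), cluster = NULL,
                    small_sample = FALSE, init = NULL, tol = 1e-10) {
  method <- match.arg(method)
  if (!inherits(model, "path_model"))
    stop_bad_arg("model must come from path_model()")
  vars <- c(model$endogenous, model$exogenous)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop_bad_arg("data lacks model variables: ", paste(miss, collapse = ", "))
  if (is.character(cluster) && length(cluster) == 1L) {
    if (!cluster %in% names(data)) stop_bad_arg("no column named ", cluster)
    cluster <- data[[cluster]]
  }
  X <- data[, vars, drop = FALSE]
  if (anyNA(X))
    stop_bad_arg("model variables contain missing values; supply complete cases")
  n <- nrow(X)

  eqs <- lapply(model$endogenous, function(v) {
    pa <- model_parents(model, v)
    dm <- cbind(`(Intercept)` = rep(1, n),
                as.matrix(X[, pa, drop = FALSE]))
    list(var = v, parents = pa, design = dm, y = X[[v]])
  })
  names(eqs) <- model$endogenous

  index <- parameter_index(model)
  theta <- setNames(numeric(length(index)), names(index))
  iterations <- 0L
  converged <- TRUE

  for (eq in eqs) {
    qrd <- qr(eq$design)
    if (qrd$rank < ncol(eq$design))
      stop_bad_arg("rank-deficient design in the equation for ", eq$var,
                   " (collinear parents)")
    if (method == "ols") {
      b <- qr.coef(qrd, eq$y)
      r <- eq$y - eq$design %*% b
      psi <- sum(r^2) / n
    } else {
      init_eq <- NULL
      if (!is.null(init)) {
        nm <- c(paste0(eq$var, "~1"),
                if (length(eq$parents)) paste0(eq$var, "~", eq$parents),
                paste0(eq$var, "~~", eq$var))
        if (all(nm %in% names(init)))
          init_eq <- c(init[nm[-length(nm)]], log(init[nm[length(nm)]]))
      }
      opt <- ml_one_equation(eq$design, eq$y, init_eq, tol)
      b <- opt$beta
      psi <- opt$psi
      iterations <- iterations + opt$iterations
      converged <- converged && opt$converged
    }
    theta[paste0(eq$var, "~1")] <- b[1L]
    if (length(eq$parents))
      theta[paste0(eq$var, "~", eq$parents)] <- b[-1L]
    theta[paste0(eq$var, "~~", eq$var)] <- psi
  }

  fit <- structure(list(theta = theta, parameter_index = index,
                        model = model, data = X, n = n,
                        cluster = cluster,
                        n_clusters = if (is.null(cluster)) n
                                     else length(unique(cluster)),
                        method = method, converged = converged,
                        iterations = iterations,
                        small_sample = small_sample),
                   class = "sem_fit")
  fit$loglik <- sem_loglik(fit)
  fit$vcov_model <- model_vcov(fit)
  fit$vcov_robust <- if (!is.null(cluster)) robust_vcov(fit, cluster,
                                                        small_sample)
  fit
}

# theta layout: all edge coefficients (B then Gamma, in edge-table order),
# then intercepts, then residual variances
parameter_index <- function(model) {
  e <- model$edges
  endo <- e$from %in% model$endogenous
  nm <- c(paste0(e$to[endo], "~", e$from[endo]),
          paste0(e$to[!endo], "~", e$from[!endo]),
          paste0(model$endogenous, "~1"),
          paste0(model$endogenous, "~~", model$endogenous))
  setNames(seq_along(nm), nm)
}

# One-equation Gaussian ML on (beta, log psi), standardised internally:
# BFGS from a neutral start, then Newton-Raphson with monotone step-halving
# until the gradient norm meets the tolerance. With a supplied init the
# optimiser starts Newton directly from it (a stationary start converges
# immediately).
ml_one_equation <- function(design, y, init = NULL, tol = 1e-10) {
  n <- length(y)
  scales <- apply(design, 2L, function(c) {
    s <- sd(c); if (!is.finite(s) || s < .Machine$double.eps) 1 else s
  })
  scales[1L] <- 1  # intercept column
  ys <- sd(y); if (!is.finite(ys) || ys < .Machine$double.eps) ys <- 1
  Xs <- sweep(design, 2L, scales, "/")
  yy <- y / ys
  XtX <- crossprod(Xs)

  negll <- function(par) {
    b <- par[-length(par)]; lp <- par[length(par)]
    r <- yy - Xs %*% b
    0.5 * n * (log(2 * pi) + lp) + 0.5 * sum(r^2) / exp(lp)
  }
  grad <- function(par) {
    b <- par[-length(par)]; lp <- par[length(par)]
    r <- drop(yy - Xs %*% b)
    c(-crossprod(Xs, r) / exp(lp),
      0.5 * n - 0.5 * sum(r^2) / exp(lp))
  }
  hess <- function(par) {
    b <- par[-length(par)]; lp <- par[length(par)]
    r <- drop(yy - Xs %*% b)
    k <- length(b)
    H <- matrix(0, k + 1L, k + 1L)
    H[seq_len(k), seq_len(k)] <- XtX / exp(lp)
    H[seq_len(k), k + 1L] <- H[k + 1L, seq_len(k)] <- crossprod(Xs, r) / exp(lp)
    H[k + 1L, k + 1L] <- 0.5 * sum(r^2) / exp(lp)
    H
  }

  iterations <- 0L
  if (!is.null(init)) {
    par <- c(init[-length(init)] * scales / ys, init[length(init)] - 2 * log(ys))
  } else {
    par <- c(numeric(ncol(Xs)), 0)
    opt <- optim(par, negll, grad, method = "BFGS",
                 control = list(maxit = 500L, reltol = 1e-15))
    par <- opt$par
    iterations <- iterations + opt$counts[["gradient"]]
  }

  gtol <- max(tol * n, 1e-12 * n)
  f0 <- negll(par)
  for (it in seq_len(60L)) {
    g <- grad(par)
    if (sqrt(sum(g^2)) <= gtol) break
    step <- tryCatch(solve(hess(par), g), error = function(e) g / n)
    lambda <- 1
    repeat {  # monotone line search: the likelihood never decreases
      cand <- par - lambda * step
      f1 <- negll(cand)
      if (is.finite(f1) && f1 <= f0 + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- par; f1 <- f0; break }
    }
    par <- cand; f0 <- f1
    iterations <- iterations + 1L
  }
  gn <- sqrt(sum(grad(par)^2))
  beta <- par[-length(par)] / scales * ys
  psi <- exp(par[length(par)]) * ys^2
  list(beta = beta, psi = psi,
       converged = gn <= max(gtol, 1e-6 * n),
       iterations = iterations)
}

# joint conditional log-likelihood (sum over equations, ML psi)
sem_loglik <- function(fit) {
  ll <- 0
  n <- fit$n
  for (v in fit$model$endogenous) {
    pa <- model_parents(fit$model, v)
    mu <- fit$theta[paste0(v, "~1")] +
      if (length(pa)) as.matrix(fit$data[, pa, drop = FALSE]) %*%
        fit$theta[paste0(v, "~", pa)] else 0
    psi <- fit$theta[paste0(v, "~~", v)]
    ll <- ll + sum(dnorm(fit$data[[v]], mu, sqrt(psi), log = TRUE))
  }
  unname(ll)
}

# per-observation score matrix (n x K) in theta order
score_matrix <- function(fit) {
  K <- length(fit$theta)
  S <- matrix(0, fit$n, K, dimnames = list(NULL, names(fit$theta)))
  for (v in fit$model$endogenous) {
    pa <- model_parents(fit$model, v)
    dm <- cbind(1, as.matrix(fit$data[, pa, drop = FALSE]))
    cn <- c(paste0(v, "~1"), if (length(pa)) paste0(v, "~", pa))
    b <- fit$theta[cn]
    psi <- fit$theta[paste0(v, "~~", v)]
    r <- drop(fit$data[[v]] - dm %*% b)
    S[, cn] <- dm * (r / psi)
    S[, paste0(v, "~~", v)] <- (r^2 - psi) / (2 * psi^2)
  }
  S
}

# inverse expected information, inverted block-by-block (the information is
# block diagonal per equation, with a zero beta/psi cross term in
# expectation); blockwise inversion sidesteps the severe cross-equation
# scale differences (mg/dL lipids vs beta-value CpGs)
information_inverse <- function(fit) {
  K <- length(fit$theta)
  Ainv <- matrix(0, K, K,
                 dimnames = list(names(fit$theta), names(fit$theta)))
  for (v in fit$model$endogenous) {
    pa <- model_parents(fit$model, v)
    dm <- cbind(1, as.matrix(fit$data[, pa, drop = FALSE]))
    cn <- c(paste0(v, "~1"), if (length(pa)) paste0(v, "~", pa))
    psi <- fit$theta[paste0(v, "~~", v)]
    Ainv[cn, cn] <- solve(crossprod(dm)) * psi
    vn <- paste0(v, "~~", v)
    Ainv[vn, vn] <- 2 * psi^2 / fit$n
  }
  Ainv
}

model_vcov <- function(fit) information_inverse(fit)

#' Family-clustered Huber-White sandwich covariance
#'
#' Computes the sandwich A^-1 B A^-1 where A is the expected information of
#' the stacked per-equation likelihood and B sums outer products of
#' per-cluster score sums. With every observation its own cluster this reduces
#' to the heteroskedasticity-robust (HC0) covariance. The estimator accounts
#' for arbitrary within-family correlation of all equations' scores.
#'
#' @param fit a converged [sem_fit()].
#' @param cluster cluster ids, length `fit$n`.
#' @param small_sample apply the G/(G-1) correction (off by default).
#' @return K x K covariance matrix over `fit$theta`.
#' @export
robust_vcov <- function(fit, cluster, small_sample = FALSE) {
  if (!inherits(fit, "sem_fit")) stop_bad_arg("fit must come from sem_fit()")
  if (!fit$converged) stop_bad_arg("fit did not converge; no robust inference")
  if (length(cluster) != fit$n)
    stop_bad_arg("every observation needs a cluster assignment")
  if (anyNA(cluster)) stop_bad_arg("cluster ids must not be missing")
  S <- score_matrix(fit)
  G <- rowsum(S, group = as.character(cluster))
  n_g <- nrow(G)
  if (n_g <= length(fit$theta))
    warning("fewer clusters (", n_g, ") than parameters (",
            length(fit$theta), "): sandwich variance is anti-conservative",
            call. = FALSE)
  Ainv <- information_inverse(fit)
  B <- crossprod(G)
  V <- Ainv %*% B %*% Ainv
  if (small_sample) V <- V * n_g / (n_g - 1)
  dimnames(V) <- list(names(fit$theta), names(fit$theta))
  (V + t(V)) / 2
}

#' @export
coef.sem_fit <- function(object, ...) object$theta

#' @export
vcov.sem_fit <- function(object, robust = !is.null(object$vcov_robust), ...) {
  if (robust) {
    if (is.null(object$vcov_robust))
      stop_bad_arg("no robust covariance: refit with a cluster argument")
    object$vcov_robust
  } else object$vcov_model
}

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), nobs = object$n,
            class = "logLik")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Path model fit (%s): %s, n = %d%s, logLik = %.2f, %s\n",
              x$method, x$model$locus$rsid, x$n,
              if (!is.null(x$cluster)) sprintf(" in %d families", x$n_clusters)
              else "",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, robust = !is.null(object$vcov_robust),
                            ...) {
  V <- vcov(object, robust = robust)
  est <- object$theta
  se <- sqrt(pmax(diag(V), 0))
  z <- est / se
  tab <- data.frame(estimate = est, se = se, z = z,
                    p = 2 * pnorm(-abs(z)), row.names = names(est))
  out <- list(coefficients = tab, robust = robust, n = object$n,
              n_clusters = object$n_clusters, loglik = object$loglik,
              converged = object$converged, rsid = object$model$locus$rsid)
  class(out) <- "summary.sem_fit"
  out
}

#' @export
print.summary.sem_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Path model fit for %s (n = %d, %d clusters, %s SEs)\n",
              x$rsid, x$n, x$n_clusters,
              if (x$robust) "family-robust" else "model-based"))
  printCoefmat(as.matrix(x$coefficients), digits = digits,
               cs.ind = 1:2, tst.ind = 3, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("logLik: %.2f; converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
residuals.sem_fit <- function(object, ...) {
  sapply(object$model$endogenous, function(v) {
    pa <- model_parents(object$model, v)
    mu <- object$theta[paste0(v, "~1")] +
      if (length(pa)) as.matrix(object$data[, pa, drop = FALSE]) %*%
        object$theta[paste0(v, "~", pa)] else 0
    object$data[[v]] - drop(mu)
  })
}

#' Model-implied endogenous means given exogenous data
#'
#' Solves the reduced form `(I - B)^-1 (nu + Gamma x)` for each row of
#' `newdata`, i.e. the expected value of every endogenous variable given the
#' exogenous variables only.
#'
#' @param object a [sem_fit()].
#' @param newdata data.frame with the exogenous columns (defaults to the
#'   training data).
#' @param ... unused.
#' @return matrix rows = observations, columns = endogenous variables.
#' @export
predict.sem_fit <- function(object, newdata = NULL, ...) {
  mats <- coefficient_matrices(object)
  xd <- (if (is.null(newdata)) object$data else newdata)
  x <- as.matrix(xd[, object$model$exogenous, drop = FALSE])
  rhs <- sweep(x %*% t(mats$Gamma), 2L, mats$nu, "+")
  t(solve(diag(nrow(mats$B)) - mats$B, t(rhs)))
}

#' Simulate endogenous data from a fitted path model
#'
#' Draws new endogenous values given the stored exogenous data by propagating
#' the structural equations in topological order with Gaussian residuals.
#'
#' @param object a [sem_fit()].
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` data.frames (exogenous columns + fresh endogenous).
#' @export
simulate.sem_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE,
            simulate_from_theta(object$model, object$theta,
                                object$data[, object$model$exogenous,
                                            drop = FALSE]))
}

#' Simulate endogenous data from explicit parameter values
#'
#' Generates endogenous variables for given exogenous data under a path model
#' and a named theta vector (names as in [sem_fit()]'s `theta`). Used for
#' parameter-recovery, coverage, and null-calibration simulations. The
#' optional cluster intercept is drawn INDEPENDENTLY per endogenous equation:
#' each equation's residual gains its own shared family component, which
#' induces within-family correlation (so model-based SEs undercover and the
#' clustered sandwich is needed) while staying independent of that equation's
#' parents, leaving every coefficient's estimand equal to `theta`. A single
#' intercept shared across equations would instead be correlated with the
#' endogenous parents and bias the coefficients themselves.
#'
#' @param model a [path_model()].
#' @param theta named parameter vector (edge coefficients, intercepts `v~1`,
#'   residual variances `v~~v`).
#' @param exo_data data.frame of exogenous columns.
#' @param cluster optional cluster ids (length `nrow(exo_data)`).
#' @param cluster_sd SD of the per-equation cluster intercept (default 0).
#' @return data.frame of exogenous + simulated endogenous columns.
#' @export
simulate_from_theta <- function(model, theta, exo_data, cluster = NULL,
                                cluster_sd = 0) {
  n <- nrow(exo_data)
  out <- as.data.frame(exo_data)
  f <- if (!is.null(cluster) && cluster_sd > 0) factor(cluster)
  for (v in model$topo_order) {
    pa <- model_parents(model, v)
    mu <- theta[paste0(v, "~1")] +
      if (length(pa)) as.matrix(out[, pa, drop = FALSE]) %*%
        theta[paste0(v, "~", pa)] else 0
    u <- if (!is.null(f)) rnorm(nlevels(f), 0, cluster_sd)[f] else numeric(n)
    out[[v]] <- drop(mu) + u + rnorm(n, 0, sqrt(theta[paste0(v, "~~", v)]))
  }
  out
}

# B (endo x endo), Gamma (endo x exo), nu, psi from a theta vector
coefficient_matrices <- function(fit, theta = fit$theta) {
  model <- fit$model
  p <- length(model$endogenous); q <- length(model$exogenous)
  B <- matrix(0, p, p, dimnames = list(model$endogenous, model$endogenous))
  Gamma <- matrix(0, p, q, dimnames = list(model$endogenous, model$exogenous))
  for (i in seq_len(nrow(model$edges))) {
    fr <- model$edges$from[i]; to <- model$edges$to[i]
    val <- theta[paste0(to, "~", fr)]
    if (fr %in% model$endogenous) B[to, fr] <- val else Gamma[to, fr] <- val
  }
  nu <- theta[paste0(model$endogenous, "~1")]
  psi <- theta[paste0(model$endogenous, "~~", model$endogenous)]
  list(B = B, Gamma = Gamma, nu = nu, psi = psi)
}

#' Serialize a fit to structured text (JSON)
#'
#' Writes the parameter table (name, estimate, robust/model SE, z, p), the
#' log-likelihood and convergence metadata.
#' @param fit a [sem_fit()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  s <- summary(fit)
  obj <- list(locus = fit$model$locus$rsid,
              n = fit$n, n_clusters = fit$n_clusters,
              loglik = fit$loglik, converged = fit$converged,
              robust = s$robust,
              parameters = cbind(parameter = rownames(s$coefficients),
                                 s$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Per-equation least-squares route
#'
#' Convenience wrapper: `sem_fit(..., method = "ols")`. For recursive models
#' with diagonal residual covariance this closed form IS the ML solution, and
#' serves as the oracle for the numeric optimiser.
#' @inheritParams sem_fit
#' @return a `sem_fit` object.
#' @export
fit_ols_equations <- function(model, data, cluster = NULL, ...) {
  sem_fit(model, data, method = "ols", cluster = cluster, ...)
}

#' Numeric maximum-likelihood route
#'
#' Convenience wrapper: `sem_fit(..., method = "ml")`.
#' @inheritParams sem_fit
#' @return a `sem_fit` object.
#' @export
fit_ml <- function(model, data, cluster = NULL, init = NULL, tol = 1e-10, ...) {
  sem_fit(model, data, method = "ml", cluster = cluster, init = init,
          tol = tol, ...)
}
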