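# Model-fit assessment: likelihood-ratio chi-square against the saturated
# conditional model, RMSEA, CFI, TLI, and the poor-fit gates
# (RMSEA >= 0.10 or CFI <= 0.9 or TLI <= 0.9).

#' Likelihood-ratio chi-square against the saturated model
#'
#' `T = 2 (loglik_saturated - loglik_model)` where the saturated model is the
#' unrestricted conditional Gaussian of all endogenous variables given the
#' exogenous ones (full multivariate regression with free residual
#' covariance). `df` is the difference in free-parameter counts.
#'
#' @param fit a converged [sem_fit()].
#' @return list with `T`, `df`, plus `T_baseline`, `df_baseline` for the
#'   independence baseline (all endogenous mutually independent and
#'   independent of the exogenous variables, free means and variances).
#' @export
chi_square <- function(fit) {
  if (!inherits(fit, "sem_fit")) stop_bad_arg("fit must come from sem_fit()")
  if (!fit$converged)
    stop_bad_arg("fit did not converge; indices would be meaningless")
  model <- fit$model
  p <- length(model$endogenous); q <- length(model$exogenous)
  n <- fit$n
  Y <- as.matrix(fit$data[, model$endogenous, drop = FALSE])
  X <- cbind(1, as.matrix(fit$data[, model$exogenous, drop = FALSE]))

  if (n <= ncol(X))
    stop_bad_arg("too few observations for the saturated model")
  R <- qr.resid(qr(X), Y)
  Sigma <- crossprod(R) / n
  ld <- determinant(Sigma, logarithm = TRUE)
  if (ld$sign <= 0) stop_bad_arg("degenerate saturated covariance")
  ll_sat <- -n / 2 * (p * log(2 * pi) + as.numeric(ld$modulus) + p)

  # independence baseline: free mean + variance per endogenous variable
  v_ml <- apply(Y, 2L, function(y) mean((y - mean(y))^2))
  ll_base <- sum(-n / 2 * (log(2 * pi) + log(v_ml) + 1))

  k_sat <- p * (q + 1) + p * (p + 1) / 2
  k_model <- count_free_parameters(model)
  k_base <- 2 * p
  df <- k_sat - k_model
  if (df < 0)
    stop_bad_arg("over-parameterized model: more free parameters than the ",
                 "saturated conditional model")
  list(T = max(2 * (ll_sat - fit$loglik), 0),
       df = df,
       T_baseline = max(2 * (ll_sat - ll_base), 0),
       df_baseline = k_sat - k_base)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(T - df, 0) / (df * n))`; zero when the chi-square does not exceed
#' its degrees of freedom.
#' @param T chi-square statistic.
#' @param df model degrees of freedom (> 0).
#' @param n sample size (> 1).
#' @return non-negative scalar.
#' @examples
#' rmsea(50, 20, 300)  # 0.0707
#' @export
rmsea <- function(T, df, n) {
  if (df <= 0) stop_bad_arg("RMSEA is undefined at df = 0")
  if (n <= 1) stop_bad_arg("RMSEA needs n > 1")
  sqrt(max(T - df, 0) / (df * n))
}

#' Comparative fit index and Tucker-Lewis index
#'
#' `cfi = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)` (clamped to
#' `[0, 1]`) and `tli = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)` (unclamped,
#' may exceed 1). A degenerate baseline (`T_b <= df_b`) yields both indices 1
#' with a warning.
#' @param T,df model chi-square and degrees of freedom (df > 0).
#' @param T_baseline,df_baseline independence-baseline values
#'   (`df_baseline > df`).
#' @return list with `cfi` and `tli`.
#' @examples
#' cfi_tli(50, 20, 500, 36)  # cfi 0.9353, tli 0.8836
#' @export
cfi_tli <- function(T, df, T_baseline, df_baseline) {
  if (df_baseline <= df)
    stop_bad_arg("baseline must have more degrees of freedom than the model")
  if (T_baseline <= df_baseline) {
    warning("degenerate baseline (T <= df): indices reported as 1",
            call. = FALSE)
    return(list(cfi = 1, tli = 1))
  }
  num <- max(T - df, 0)
  den <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tli <- ((T_baseline / df_baseline) - (T / df)) /
    ((T_baseline / df_baseline) - 1)
  list(cfi = cfi, tli = tli)
}

#' Compute all fit indices for a fitted path model
#'
#' @param fit a converged [sem_fit()].
#' @param rule how the poor-fit gates combine, see [assess_fit()].
#' @return object of class `sem_fitindices`: `T`, `df`, `T_baseline`,
#'   `df_baseline`, `rmsea`, `cfi`, `tli`, `n`, `acceptable`.
#' @export
fit_indices <- function(fit, rule = c("any", "all")) {
  rule <- match.arg(rule)
  ch <- chi_square(fit)
  ct <- if (ch$df > 0) {
    cfi_tli(ch$T, ch$df, ch$T_baseline, ch$df_baseline)
  } else list(cfi = 1, tli = 1)
  out <- list(T = ch$T, df = ch$df,
              T_baseline = ch$T_baseline, df_baseline = ch$df_baseline,
              rmsea = if (ch$df > 0) rmsea(ch$T, ch$df, fit$n) else 0,
              cfi = ct$cfi, tli = ct$tli, n = fit$n, rule = rule)
  out$acceptable <- assess_fit(out, rule)
  class(out) <- "sem_fitindices"
  out
}

#' Apply the poor-fit gates
#'
#' A model fits poorly when RMSEA >= 0.10, or CFI <= 0.9, or TLI <= 0.9
#' (boundaries count as poor). `rule = "any"` (default) flags poor fit if any
#' index fails -- the conservative disjunctive reading; `rule = "all"` requires
#' all three to fail.
#' @param indices a [fit_indices()] object (or list with `rmsea`, `cfi`,
#'   `tli`).
#' @param rule `"any"` or `"all"`.
#' @return logical: `TRUE` when the fit is acceptable.
#' @export
assess_fit <- function(indices, rule = c("any", "all")) {
  rule <- match.arg(rule)
  fails <- c(indices$rmsea >= 0.10, indices$cfi <= 0.9, indices$tli <= 0.9)
  poor <- if (rule == "any") any(fails) else all(fails)
  !poor
}

#' @export
print.sem_fitindices <- function(x, ...) {
  cat(sprintf("Fit: T = %.3f on df = %d (baseline T = %.1f, df = %d), n = %d\n",
              x$T, x$df, x$T_baseline, x$df_baseline, x$n))
  cat(sprintf("  RMSEA = %.3f, CFI = %.3f, TLI = %.3f -> %s\n",
              x$rmsea, x$cfi, x$tli,
              if (x$acceptable) "acceptable" else "POOR FIT"))
  invisible(x)
}
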