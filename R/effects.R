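# Direct, indirect and total SNP effects on visit-4 TG: chain products with
# delta-method standard errors from the (robust) parameter covariance.

#' Delta-method SE of a product of coefficients
#'
#' For a chain product `b = prod(est)` the gradient with respect to the k-th
#' coefficient is the product of all the others; the variance is `g' V g`.
#' With two independent coefficients this is the Sobel formula
#' `sqrt(b2^2 sa^2 + a^2 sb^2)`. Cross-equation covariances in `V` are used in
#' full -- under the stacked sandwich they are generally non-zero.
#'
#' @param est numeric vector of chain coefficients.
#' @param V covariance matrix of `est` (same order).
#' @return list with `beta` (product) and `se`.
#' @examples
#' chain_product_se(c(0.5, 2), diag(c(0.1, 0.2)^2))  # Sobel: se 0.2236
#' @export
chain_product_se <- function(est, V) {
  V <- as.matrix(V)
  if (length(est) != nrow(V) || nrow(V) != ncol(V))
    stop_bad_arg("est and V dimensions disagree")
  beta <- prod(est)
  grad <- vapply(seq_along(est), function(k) prod(est[-k]), 0)
  list(beta = beta, se = sqrt(max(drop(t(grad) %*% V %*% grad), 0)))
}

#' Indirect (or direct) effect along one pathway chain
#'
#' The pathway effect is the product of the chain's edge coefficients; its SE
#' comes from the multivariate delta method using the robust covariance of the
#' involved coefficients; p-values use the two-sided normal reference.
#'
#' @param fit a converged [sem_fit()] with a robust covariance (falls back to
#'   the model-based covariance with a warning).
#' @param chain ordered variable names from source to sink; every consecutive
#'   pair must be a model edge. A single edge gives the direct effect.
#' @return object of class `pathway_effect`: `chain`, `pathway` (rendered
#'   string), `beta`, `se`, `z`, `p`.
#' @export
indirect_effect <- function(fit, chain) {
  if (!fit$converged) stop_bad_arg("fit did not converge; no inference")
  if (length(chain) < 2L) stop_bad_arg("a chain needs at least two variables")
  nm <- paste0(chain[-1L], "~", chain[-length(chain)])
  missing_edge <- !(nm %in% names(fit$theta))
  if (any(missing_edge))
    stop_bad_arg("chain uses non-edges: ",
                 paste(gsub("~", " <- ", nm[missing_edge]), collapse = ", "))
  V <- if (!is.null(fit$vcov_robust)) fit$vcov_robust else {
    warning("no robust covariance attached; using model-based covariance",
            call. = FALSE)
    fit$vcov_model
  }
  pr <- chain_product_se(fit$theta[nm], V[nm, nm, drop = FALSE])
  z <- if (pr$se > 0) pr$beta / pr$se else NA_real_
  structure(list(chain = chain, pathway = format_chain(chain),
                 beta = pr$beta, se = pr$se, z = z,
                 p = 2 * pnorm(-abs(z))),
            class = "pathway_effect")
}

#' @export
print.pathway_effect <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.4g\n",
              x$pathway, x$beta, x$se, x$p))
  invisible(x)
}

#' All source-to-sink pathway effects of a fitted model
#'
#' Enumerates every simple directed path (the single-edge path is the direct
#' effect) and computes each chain's product effect with delta-method SE.
#'
#' @param fit a converged [sem_fit()].
#' @param source,sink variable names (defaults SNP and TG4).
#' @return data.frame with columns `pathway`, `n_edges`, `beta`, `se`, `z`,
#'   `p`; the chains themselves are kept in `attr(, "chains")`.
#' @export
pathway_effects <- function(fit, source = "SNP", sink = "TG4") {
  chains <- enumerate_paths(fit$model, source, sink)
  effs <- lapply(chains, function(ch) indirect_effect(fit, ch))
  out <- data.frame(
    pathway = vapply(effs, `[[`, "", "pathway"),
    n_edges = vapply(chains, length, 0L) - 1L,
    beta = vapply(effs, `[[`, 0, "beta"),
    se = vapply(effs, `[[`, 0, "se"),
    z = vapply(effs, `[[`, 0, "z"),
    p = vapply(effs, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  attr(out, "chains") <- chains
  out
}

#' Total effect of a source on a sink
#'
#' Read off the reduced-form matrix `(I - B)^-1 Gamma`; equals the sum of
#' chain products over all simple directed paths. The delta-method SE uses the
#' analytic gradient of the reduced form with respect to every edge
#' coefficient.
#'
#' @param fit a converged [sem_fit()].
#' @param source exogenous (or endogenous) source variable.
#' @param sink endogenous sink variable.
#' @return list with `beta`, `se`.
#' @export
total_effect <- function(fit, source = "SNP", sink = "TG4") {
  model <- fit$model
  if (!sink %in% model$endogenous) stop_bad_arg("sink must be endogenous")
  mats <- coefficient_matrices(fit)
  p <- nrow(mats$B)
  IB <- diag(p) - mats$B
  if (abs(det(IB)) < .Machine$double.eps)
    stop_bad_arg("singular (I - B); the model is not recursive")
  IBinv <- solve(IB)
  dimnames(IBinv) <- dimnames(mats$B)

  if (source %in% model$exogenous) {
    total <- (IBinv %*% mats$Gamma)[sink, source]
  } else {
    total <- IBinv[sink, source] - (sink == source)
  }

  V <- if (!is.null(fit$vcov_robust)) fit$vcov_robust else fit$vcov_model
  red <- if (source %in% model$exogenous) (IBinv %*% mats$Gamma)[, source] else
    IBinv[, source]
  grad <- setNames(numeric(length(fit$theta)), names(fit$theta))
  for (i in seq_len(nrow(model$edges))) {
    fr <- model$edges$from[i]; to <- model$edges$to[i]
    nm <- paste0(to, "~", fr)
    grad[nm] <- if (fr %in% model$endogenous) {
      # d/dB[to,fr] (I-B)^-1 A = (I-B)^-1 E_{to,fr} (I-B)^-1 A
      IBinv[sink, to] * red[fr]
    } else if (fr == source) IBinv[sink, to] else 0
  }
  se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  list(beta = unname(total), se = se)
}

#' Filter pathways by nominal significance and directional consistency
#'
#' Keeps pathway rows with `p < alpha` whose product sign matches the locus's
#' expected TG-effect direction from prior GWAS (the product-sign convention:
#' a multi-edge chain is consistent when the sign of the whole product matches
#' the expected direction). Dropped-but-significant rows with the wrong sign
#' are recorded in `attr(, "direction_dropped")`.
#'
#' @param effects data.frame from [pathway_effects()].
#' @param alpha nominal level (default 0.05).
#' @param expected_direction `+1` or `-1`.
#' @return filtered data.frame (possibly 0 rows) with a `directionally_consistent`
#'   column.
#' @export
significant_pathways <- function(effects, alpha = 0.05, expected_direction) {
  if (!expected_direction %in% c(-1, 1))
    stop_bad_arg("expected_direction must be +1 or -1")
  consistent <- sign(effects$beta) == expected_direction
  keep <- effects$p < alpha & consistent
  keep[is.na(keep)] <- FALSE
  out <- effects[keep, , drop = FALSE]
  out$directionally_consistent <- rep(TRUE, nrow(out))
  dropped <- effects[effects$p < alpha & !consistent & !is.na(effects$p), ,
                     drop = FALSE]
  attr(out, "direction_dropped") <- dropped
  out
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_loci`, exact; the reporting layer rounds to one significant
#' digit (0.05 / 12 prints as 0.004).
#' @param alpha family-wise level.
#' @param n_loci number of loci examined (>= 1).
#' @return exact threshold, with the rounded display value in
#'   `attr(, "display")`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_loci) {
  if (length(n_loci) != 1L || n_loci < 1)
    stop_bad_arg("n_loci must be a positive count")
  x <- alpha / n_loci
  attr(x, "display") <- signif(x, 1)
  x
}
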