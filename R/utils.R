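#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases dnorm logLik optim pnorm predict
#'   prcomp qnorm rbinom residuals rnorm runif sd setNames simulate var vcov
#' @importFrom utils read.csv read.delim write.csv
NULL

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_bad_arg(name, " must lie in [0, 1]")
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(if (strict) x <= 0 else x < 0))
    stop_bad_arg(name, if (strict) " must be strictly positive" else
      " must be non-negative")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
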