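#' Elementwise loss specification for the generalized CP objective
#'
#' The generalized CP decomposition minimizes a mask-weighted sum of an
#' elementwise loss `l(x, m)` between data `x` and model value `m`. The
#' catalog follows the generalized CP literature:
#' \describe{
#'   \item{gaussian}{`(x - m)^2`; unbounded domain.}
#'   \item{poisson_log}{`exp(m) - x * m`, the Poisson deviance with a log
#'     link; requires `x >= 0`, `m` unbounded.}
#'   \item{gamma}{`x / (m + offset) + log(m + offset)`; requires `x >= 0`
#'     and nonnegative model values.}
#'   \item{beta_divergence}{the standard beta-divergence
#'     `m^b/b - x m^(b-1)/(b-1) + x^b/(b(b-1))` with `b = beta`
#'     (`b` outside \{0, 1\}); requires `x >= 0` and nonnegative model
#'     values. Zero exactly when `m = x`.}
#' }
#'
#' @param name one of `"gaussian"`, `"gamma"`, `"beta_divergence"`,
#'   `"poisson_log"`.
#' @param beta beta-divergence parameter (ignored by the other losses).
#' @param offset small positive stabilizer added to model values inside
#'   logs and divisions.
#' @return An object of class `"loss_spec"`.
#' @export
loss_spec <- function(name = c("gaussian", "gamma", "beta_divergence",
                               "poisson_log"),
                      beta = 1.5, offset = 1e-10) {
  name <- match.arg(name)
  stopifnot(offset > 0)
  if (name == "beta_divergence" && beta %in% c(0, 1)) {
    stop("beta must lie outside {0, 1} (those limits are other losses)",
         call. = FALSE)
  }
  structure(list(name = name, beta = beta, offset = offset,
                 nonnegative_domain = name %in% c("gamma", "beta_divergence"),
                 nonnegative_data = name != "gaussian"),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec>", x$name)
  if (x$name == "beta_divergence") cat(sprintf(" (beta = %g)", x$beta))
  cat("\n")
  invisible(x)
}

#' Evaluate a loss and its derivative in the model value
#'
#' Vectorized over `x` and `m` (recycled).
#'
#' @param spec a [loss_spec()].
#' @param x observed data values.
#' @param m model values.
#' @return A list with numeric vectors `value` and `deriv` (the derivative
#'   of the loss with respect to `m`).
#' @export
loss_eval <- function(spec, x, m) {
  stopifnot(inherits(spec, "loss_spec"))
  eps <- spec$offset
  if (spec$nonnegative_data && any(x < 0)) {
    stop(sprintf("loss '%s' requires nonnegative data values", spec$name),
         call. = FALSE)
  }
  if (spec$nonnegative_domain && any(m < 0)) {
    stop(sprintf("loss '%s' requires nonnegative model values", spec$name),
         call. = FALSE)
  }
  switch(spec$name,
    gaussian = list(value = (x - m)^2, deriv = 2 * (m - x)),
    poisson_log = {
      em <- exp(pmin(m, 700))
      list(value = em - x * m, deriv = em - x)
    },
    gamma = {
      me <- m + eps
      list(value = x / me + log(me), deriv = 1 / me - x / me^2)
    },
    beta_divergence = {
      b <- spec$beta
      me <- m + eps
      xe <- x + eps
      list(
        value = me^b / b - xe * me^(b - 1) / (b - 1) + xe^b / (b * (b - 1)),
        deriv = me^(b - 1) - xe * me^(b - 2)
      )
    }
  )
}
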