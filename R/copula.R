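#' Gaussian copula synthesis of a latent table
#'
#' Three-step Gaussian copula: (1) draw correlated standard normals whose
#' correlation matrix is that of the latent columns; (2) push them through
#' the normal CDF to uniforms; (3) invert each column's fitted marginal.
#' Because sampling is never exact, draws are repeated (up to `max_tries`)
#' until the Frobenius distance between the synthetic and original
#' correlation matrices falls below `epsilon`; otherwise the best draw seen
#' is returned with `attr(, "accepted") = FALSE`.
#'
#' @param latent a [latent_table()] with at least 3 rows.
#' @param n_out number of synthetic rows to draw.
#' @param marginal marginal estimator: `"empirical_cdf"` (midpoint-rank ECDF
#'   with linear interpolation between order statistics, the default),
#'   `"kernel"` (Gaussian kernel-smoothed CDF), or the parametric
#'   `"gamma"`, `"beta"`, `"truncated_gaussian"` fitted by maximum
#'   likelihood (gamma/beta after an affine map onto their support; the
#'   truncated Gaussian uses the observed min/max as truncation bounds).
#' @param epsilon Frobenius acceptance threshold; default `0.05 * R` scales
#'   with the number of latent columns.
#' @param max_tries retry cap for the acceptance loop.
#' @param seed integer seed; the draw is deterministic given it.
#' @return A `latent_table` of `n_out` rows with the input's column names
#'   and kinds, plus attributes `accepted` (logical), `frobenius` (the
#'   achieved correlation distance), and `tries`.
#' @examples
#' lt <- latent_table(data.frame(f1 = rnorm(50), f2 = rnorm(50)))
#' syn <- copula_sample(lt, 100, seed = 1)
#' attr(syn, "frobenius")
#' @export
copula_sample <- function(latent, n_out,
                          marginal = c("empirical_cdf", "kernel", "gamma",
                                       "beta", "truncated_gaussian"),
                          epsilon = NULL, max_tries = 100L, seed = 1L) {
  stopifnot(inherits(latent, "latent_table"))
  marginal <- match.arg(marginal)
  if (nrow(latent) < 3L) stop("latent table needs >= 3 rows", call. = FALSE)
  n_out <- as.integer(n_out)
  stopifnot(n_out >= 1, max_tries >= 1)
  R <- ncol(latent)
  if (is.null(epsilon)) epsilon <- 0.05 * R
  stopifnot(epsilon > 0)

  X <- as.matrix(as.data.frame(latent))
  Sigma <- latent_correlation(X)
  U <- chol(Sigma)
  inv_cdfs <- lapply(seq_len(R), function(j) fit_marginal(X[, j], marginal))

  set.seed(as.integer(seed))
  best <- NULL
  tries <- 0L
  repeat {
    tries <- tries + 1L
    Z <- matrix(stats::rnorm(n_out * R), n_out, R) %*% U
    u <- stats::pnorm(Z)
    syn <- vapply(seq_len(R), function(j) inv_cdfs[[j]](u[, j]),
                  numeric(n_out))
    syn <- matrix(syn, n_out, R)
    frob <- if (R == 1L || n_out < 3L) 0 else {
      norm(latent_correlation(syn) - Sigma, type = "F")
    }
    if (is.null(best) || frob < best$frob) best <- list(syn = syn, frob = frob)
    if (frob < epsilon || tries >= max_tries) break
  }

  out <- relabel_latent(best$syn, latent)
  attr(out, "accepted") <- best$frob < epsilon
  attr(out, "frobenius") <- best$frob
  attr(out, "tries") <- tries
  out
}

# Pearson correlation with a positive-semidefiniteness repair by eigenvalue
# clipping; constant columns get zero correlation with a warning.
latent_correlation <- function(X) {
  R <- ncol(X)
  if (R == 1L) return(matrix(1, 1, 1))
  sds <- apply(X, 2, stats::sd)
  Sigma <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("constant latent column(s): correlations set to 0")
    Sigma[is.na(Sigma)] <- 0
    diag(Sigma) <- 1
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    warning("correlation matrix not positive definite; eigenvalues clipped")
    vals <- pmax(ev$values, 1e-8)
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(Sigma))
    Sigma <- Sigma / tcrossprod(d)
  }
  Sigma
}

# Returns an inverse-CDF function u in [0,1] -> value.
fit_marginal <- function(v, kind) {
  n <- length(v)
  switch(kind,
    empirical_cdf = {
      s <- sort(v)
      p <- (seq_len(n) - 0.5) / n
      function(u) stats::approx(p, s, xout = u, rule = 2, ties = "ordered")$y
    },
    kernel = {
      de <- stats::density(v, n = 512)
      cdf <- cumsum(de$y)
      cdf <- cdf / cdf[length(cdf)]
      keep <- !duplicated(cdf)
      function(u) stats::approx(cdf[keep], de$x[keep], xout = u, rule = 2,
                                ties = "ordered")$y
    },
    gamma = {
      # gamma support is (0, Inf); shift data that touches or crosses zero
      shift <- if (min(v) <= 0) min(v) - 1e-6 * max(diff(range(v)), 1) else 0
      w <- v - shift
      m <- mean(w); s2 <- stats::var(w)
      par0 <- log(c(shape = m^2 / s2, rate = m / s2))
      nll <- function(p) -sum(stats::dgamma(w, exp(p[1]), exp(p[2]), log = TRUE))
      fit <- stats::optim(par0, nll, method = "Nelder-Mead")
      sh <- exp(fit$par[1]); ra <- exp(fit$par[2])
      function(u) stats::qgamma(u, sh, ra) + shift
    },
    beta = {
      rng <- range(v)
      pad <- 1e-6 * max(diff(rng), 1)
      lo <- rng[1] - pad; hi <- rng[2] + pad
      w <- (v - lo) / (hi - lo)
      m <- mean(w); s2 <- max(stats::var(w), 1e-8)
      k <- m * (1 - m) / s2 - 1
      par0 <- log(pmax(c(m * k, (1 - m) * k), 0.05))
      nll <- function(p) -sum(stats::dbeta(w, exp(p[1]), exp(p[2]), log = TRUE))
      fit <- stats::optim(par0, nll, method = "Nelder-Mead")
      a <- exp(fit$par[1]); b <- exp(fit$par[2])
      function(u) stats::qbeta(u, a, b) * (hi - lo) + lo
    },
    truncated_gaussian = {
      lo <- min(v); hi <- max(v)
      nll <- function(p) {
        mu <- p[1]; sdv <- exp(p[2])
        z <- stats::pnorm(hi, mu, sdv) - stats::pnorm(lo, mu, sdv)
        if (z <= 0) return(1e10)
        -sum(stats::dnorm(v, mu, sdv, log = TRUE)) + n * log(z)
      }
      fit <- stats::optim(c(mean(v), log(stats::sd(v) + 1e-8)), nll,
                          method = "Nelder-Mead")
      mu <- fit$par[1]; sdv <- exp(fit$par[2])
      plo <- stats::pnorm(lo, mu, sdv); phi <- stats::pnorm(hi, mu, sdv)
      function(u) stats::qnorm(plo + u * (phi - plo), mu, sdv)
    }
  )
}
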