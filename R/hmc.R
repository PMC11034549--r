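#' Hamiltonian Monte Carlo inference for the latent covariance
#'
#' Models the latent patient factor rows as draws from a multivariate
#' Gaussian with a known mean vector and unknown covariance
#' `Sigma = diag(sigma) %*% Omega %*% diag(sigma)`, with independent
#' half-Cauchy priors on the standard deviations `sigma` and an LKJ-type
#' prior on the correlation matrix `Omega` (parameterized through canonical
#' partial correlations). The posterior is explored by Hamiltonian Monte
#' Carlo with analytic gradients, dual-averaging step-size adaptation
#' during warmup, and jittered leapfrog path lengths; split R-hat and
#' effective sample sizes are computed for every parameter.
#'
#' The latent table must carry Gaussian-loss provenance (see
#' [latent_table()]): factor distributions depend on the GCP loss, and the
#' multivariate Gaussian model is only appropriate for the Gaussian one.
#' Tables of unknown origin are accepted; a non-Gaussian loss is refused
#' unless `override_loss_check = TRUE`.
#'
#' @param latent a [latent_table()] with at least 10 rows.
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup,sampling iterations per chain.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param sigma_prior_scale half-Cauchy scale for the standard deviations.
#' @param lkj_concentration concentration of the correlation prior
#'   (1 = uniform over correlation matrices; larger favors independence).
#' @param leapfrog integer range (min, max) of leapfrog steps per proposal.
#' @param mean `"empirical"` treats the column means as the known mean
#'   vector (centering before inference, restoring when sampling);
#'   `"zero"` uses a zero mean.
#' @param adapt_target dual-averaging acceptance target.
#' @param override_loss_check accept non-Gaussian-provenance latent tables.
#' @return An object of class `"hmc_posterior"`: retained draws of `Sigma`
#'   (array draws x d x d), the parameter draws, the known mean, per-parameter
#'   `diagnostics` (split R-hat, ESS), and the average acceptance rate.
#'   A convergence warning is attached (and signalled) if any scale
#'   parameter has split R-hat above 1.1.
#' @seealso [hmc_sample()]
#' @export
hmc_fit <- function(latent, chains = 4L, warmup = 400L, sampling = 400L,
                    seed = 1L, sigma_prior_scale = 2.5,
                    lkj_concentration = 1.5, leapfrog = c(15L, 30L),
                    mean = c("empirical", "zero"), adapt_target = 0.8,
                    override_loss_check = FALSE) {
  stopifnot(inherits(latent, "latent_table"))
  mean <- match.arg(mean)
  prov <- attr(latent, "loss")
  if (!override_loss_check && !is.na(prov) && prov != "gaussian") {
    stop(sprintf(paste0("latent table has '%s'-loss provenance; the ",
                        "multivariate Gaussian model expects Gaussian-loss ",
                        "factors (set override_loss_check = TRUE to force)"),
                 prov), call. = FALSE)
  }
  if (nrow(latent) < 10L) stop("HMC needs >= 10 latent rows", call. = FALSE)
  stopifnot(chains >= 2, warmup >= 50, sampling >= 1)

  X <- as.matrix(as.data.frame(latent))
  n <- nrow(X); d <- ncol(X)
  mu <- if (mean == "empirical") colMeans(X) else numeric(d)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc)

  pairs <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  P <- d + nrow(pairs)
  lkj_beta <- lkj_concentration + (d - 1 - (pairs[, 1] - pairs[, 2])) / 2

  # jittered start near the sample moments
  sds <- pmax(apply(Xc, 2, stats::sd), 1e-8)
  Omega0 <- latent_correlation(Xc)
  z0 <- chol_to_cpc(Omega0, pairs)

  lp_fun <- function(theta) {
    mvn_cov_logpost(theta, S, n, d, pairs, sigma_prior_scale, lkj_beta)
  }

  chain_draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    theta0 <- c(log(sds) + stats::rnorm(d, 0, 0.05),
                atanh(pmin(pmax(z0, -0.97), 0.97)) +
                  stats::rnorm(nrow(pairs), 0, 0.05))
    run <- hmc_chain(lp_fun, theta0, warmup, sampling, leapfrog, adapt_target)
    chain_draws[[ch]] <- run$draws
    accept[ch] <- run$accept_rate
  }

  pn <- c(paste0("sigma[", seq_len(d), "]"),
          sprintf("z[%d,%d]", pairs[, 1], pairs[, 2]))
  diagnostics <- data.frame(
    parameter = pn,
    rhat = split_rhat(chain_draws),
    ess = ess_basic(chain_draws)
  )
  rhat_warning <- any(diagnostics$rhat[seq_len(d)] > 1.1, na.rm = TRUE)
  if (rhat_warning) {
    warning("split R-hat > 1.1 on a scale parameter; chains may not have converged")
  }

  draws <- do.call(rbind, chain_draws)
  nd <- nrow(draws)
  Sigma <- array(NA_real_, c(nd, d, d))
  for (g in seq_len(nd)) {
    Lc <- exp(draws[g, seq_len(d)]) *
      cpc_chol(tanh(draws[g, d + seq_len(nrow(pairs))]), d, pairs)$L
    Sigma[g, , ] <- tcrossprod(Lc)
  }
  dimnames(Sigma) <- list(NULL, names(latent), names(latent))

  structure(
    list(Sigma = Sigma, draws = draws, parameter_names = pn, mu = mu,
         diagnostics = diagnostics, rhat_warning = rhat_warning,
         accept_rate = mean(accept), chains = chains, warmup = warmup,
         sampling = sampling, d = d, template = latent,
         seed = as.integer(seed)),
    class = "hmc_posterior"
  )
}

#' @export
print.hmc_posterior <- function(x, ...) {
  cat(sprintf("<hmc_posterior> %d draws of a %dx%d covariance (%d chains, accept %.2f)\n",
              nrow(x$draws), x$d, x$d, x$chains, x$accept_rate))
  cat(sprintf("  max split R-hat: %.3f   min ESS: %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  if (x$rhat_warning) cat("  WARNING: convergence suspect (R-hat > 1.1)\n")
  invisible(x)
}

#' Posterior mean of the latent covariance
#'
#' @param object an `"hmc_posterior"`.
#' @param ... unused.
#' @export
summary.hmc_posterior <- function(object, ...) {
  apply(object$Sigma, c(2, 3), mean)
}

#' Draw synthetic latent rows from the HMC posterior
#'
#' Each synthetic row picks a retained posterior draw of `Sigma` and draws
#' `x ~ MVN(mu, Sigma)`.
#'
#' @param posterior an [hmc_fit()] result.
#' @param n_out number of rows.
#' @param seed integer seed.
#' @return A `latent_table` of `n_out` rows matching the training table.
#' @export
hmc_sample <- function(posterior, n_out, seed = 1L) {
  stopifnot(inherits(posterior, "hmc_posterior"))
  n_out <- as.integer(n_out)
  stopifnot(n_out >= 1)
  set.seed(as.integer(seed))
  nd <- dim(posterior$Sigma)[1]
  d <- posterior$d
  idx <- sample.int(nd, n_out, replace = TRUE)
  out <- matrix(NA_real_, n_out, d)
  for (g in unique(idx)) {
    rows <- which(idx == g)
    U <- chol(posterior$Sigma[g, , ])
    out[rows, ] <- matrix(stats::rnorm(length(rows) * d), length(rows), d) %*%
      U + rep(posterior$mu, each = length(rows))
  }
  relabel_latent(out, posterior$template)
}

# ---- model internals -------------------------------------------------------

# Cholesky factor of a correlation matrix from canonical partial
# correlations z (one per lower-triangular pair, row-major). Also returns
# the partial products needed for the analytic gradient.
cpc_chol <- function(z, d, pairs) {
  L <- diag(1, d)
  Cm <- matrix(1, d, d)  # Cm[i, j] = prod_{k < j} sqrt(1 - z[i,k]^2)
  m <- 0L
  for (i in seq_len(d)[-1]) {
    cprev <- 1
    for (j in seq_len(i - 1L)) {
      m <- m + 1L
      Cm[i, j] <- cprev
      L[i, j] <- z[m] * cprev
      cprev <- cprev * sqrt(1 - z[m]^2)
    }
    Cm[i, i] <- cprev
    L[i, i] <- cprev
  }
  list(L = L, Cm = Cm)
}

# Invert cpc_chol for a given correlation matrix (used to initialize chains).
chol_to_cpc <- function(Omega, pairs) {
  d <- nrow(Omega)
  L <- t(chol(Omega))
  z <- numeric(nrow(pairs))
  m <- 0L
  for (i in seq_len(d)[-1]) {
    cprev <- 1
    for (j in seq_len(i - 1L)) {
      m <- m + 1L
      z[m] <- max(min(L[i, j] / cprev, 1 - 1e-10), -1 + 1e-10)
      cprev <- cprev * sqrt(1 - z[m]^2)
    }
  }
  z
}

# Log posterior and analytic gradient of the known-mean MVN covariance model.
# theta = (log sigma_1..d, atanh(z) over lower-tri pairs); S = crossprod of
# the centered data; half-Cauchy(s) on sigma; LKJ-type prior exponents
# lkj_beta per pair (density over CPCs proportional to (1 - z^2)^(beta - 1)).
mvn_cov_logpost <- function(theta, S, n, d, pairs, sscale, lkj_beta) {
  eta <- theta[seq_len(d)]
  y <- theta[-seq_len(d)]
  sigma <- exp(eta)
  z <- tanh(y)
  cc <- cpc_chol(z, d, pairs)
  L <- cc$L
  Lc <- sigma * L                       # diag(sigma) %*% L
  ld <- diag(Lc)
  if (any(ld <= 0) || any(!is.finite(Lc))) {
    return(list(lp = -Inf, grad = rep(0, length(theta))))
  }
  Siginv <- chol2inv(t(Lc))
  Sigma <- tcrossprod(Lc)

  loglik <- -n * d / 2 * log(2 * pi) - n * sum(log(ld)) -
    0.5 * sum(Siginv * S)
  rel <- sigma / sscale
  lp_sigma <- sum(log(2 / pi) - log(sscale) - log1p(rel^2)) + sum(eta)
  lp_z <- sum(lkj_beta * log1p(-z^2))   # prior exponent + tanh Jacobian
  lp <- loglik + lp_sigma + lp_z
  if (!is.finite(lp)) return(list(lp = -Inf, grad = rep(0, length(theta))))

  G <- -n / 2 * Siginv + 0.5 * Siginv %*% S %*% Siginv
  grad_eta <- 2 * rowSums(G * Sigma) + 1 - 2 * rel^2 / (1 + rel^2)

  grad_y <- numeric(length(y))
  GS <- t(t(G) * sigma)                 # GS[i, b] = G[i, b] * sigma_b
  for (m in seq_len(nrow(pairs))) {
    i <- pairs[m, 1]; j <- pairs[m, 2]
    zi <- z[m]
    dl <- numeric(d)
    dl[j] <- cc$Cm[i, j]
    if (j < i) {
      q <- seq.int(j + 1L, i)
      dl[q] <- L[i, q] * (-zi / (1 - zi^2))
    }
    tvec <- L %*% dl
    dLL_dz <- 2 * sigma[i] * sum(GS[i, ] * tvec)
    grad_y[m] <- dLL_dz * (1 - zi^2) - 2 * lkj_beta[m] * zi
  }
  list(lp = lp, grad = c(grad_eta, grad_y))
}

# ---- sampler ---------------------------------------------------------------

hmc_chain <- function(lp_fun, theta0, warmup, sampling, leapfrog,
                      adapt_target) {
  theta <- theta0
  cur <- lp_fun(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initialization",
                               call. = FALSE)
  P <- length(theta)
  eps <- 0.1 / P^0.25
  # dual averaging (Nesterov) state
  mu_da <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  total <- warmup + sampling
  draws <- matrix(NA_real_, sampling, P)
  n_accept <- 0L

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(P)
    nstep <- sample.int(leapfrog[2] - leapfrog[1] + 1L, 1L) + leapfrog[1] - 1L
    th <- theta; p <- p0; gr <- cur$grad
    p <- p + 0.5 * eps * gr
    ok <- TRUE
    for (s in seq_len(nstep)) {
      th <- th + eps * p
      prop <- lp_fun(th)
      if (!is.finite(prop$lp)) { ok <- FALSE; break }
      p <- p + (if (s < nstep) eps else 0.5 * eps) * prop$grad
    }
    if (ok) {
      log_ratio <- (prop$lp - 0.5 * sum(p^2)) - (cur$lp - 0.5 * sum(p0^2))
      a_prob <- min(1, exp(log_ratio))
      if (stats::runif(1) < a_prob) {
        theta <- th; cur <- prop
        if (it > warmup) n_accept <- n_accept + 1L
      }
    } else {
      a_prob <- 0
      stats::runif(1)  # keep the random stream aligned across branches
    }
    if (it <= warmup) {
      frac <- 1 / (it + t0)
      h_bar <- (1 - frac) * h_bar + frac * (adapt_target - a_prob)
      log_eps <- mu_da - sqrt(it) / gamma * h_bar
      w <- it^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = n_accept / sampling, stepsize = eps)
}

# ---- diagnostics -----------------------------------------------------------

# Split R-hat per parameter over a list of per-chain draw matrices.
split_rhat <- function(chain_draws) {
  halves <- unlist(lapply(chain_draws, function(m) {
    n2 <- floor(nrow(m) / 2)
    list(m[seq_len(n2), , drop = FALSE],
         m[seq.int(nrow(m) - n2 + 1L, nrow(m)), , drop = FALSE])
  }), recursive = FALSE)
  P <- ncol(chain_draws[[1]])
  n <- nrow(halves[[1]])
  vapply(seq_len(P), function(p) {
    x <- vapply(halves, function(m) m[, p], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# Basic multi-chain effective sample size (Geyer initial positive sequence
# on chain-averaged autocorrelations).
ess_basic <- function(chain_draws, max_lag = 200L) {
  M <- length(chain_draws)
  n <- nrow(chain_draws[[1]])
  P <- ncol(chain_draws[[1]])
  max_lag <- min(max_lag, n - 2L)
  vapply(seq_len(P), function(p) {
    acs <- vapply(chain_draws, function(m) {
      v <- m[, p]
      if (stats::sd(v) == 0) return(rep(0, max_lag + 1L))
      stats::acf(v, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[, 1, 1]
    }, numeric(max_lag + 1L))
    rho <- rowMeans(acs)
    # sum consecutive pairs while they stay positive
    tot <- 0
    t <- 2L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (pair < 0) break
      tot <- tot + pair
      t <- t + 2L
    }
    max(M * n / (1 + 2 * tot), 1)
  }, numeric(1))
}
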