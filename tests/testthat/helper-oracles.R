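# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are deliberately written as plain loops so they stay
# independent of the vectorized implementation paths they check.

# triple-loop Kruskal reconstruction
oracle_reconstruct <- function(lambda, A, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C); R <- ncol(A)
  out <- array(0, c(I, J, K))
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
    s <- 0
    for (r in seq_len(R)) s <- s + lambda[r] * A[i, r] * B[j, r] * C[k, r]
    out[i, j, k] <- s
  }
  out
}

# loop-based masked objective
oracle_objective <- function(x, model, spec) {
  m <- oracle_reconstruct(model$lambda, model$A, model$B, model$C)
  d <- dim(x$values)
  tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (x$mask[i, j, k] == 1) {
      tot <- tot + loss_eval(spec, x$values[i, j, k], m[i, j, k])$value
    }
  }
  tot
}

# central finite differences of the objective in every factor entry
numeric_gcp_gradient <- function(x, model, spec, h = 1e-6) {
  lapply(stats::setNames(c("A", "B", "C"), c("A", "B", "C")), function(nm) {
    M <- model[[nm]]
    G <- M * 0
    for (i in seq_along(M)) {
      step <- h * max(abs(M[i]), 1)
      up <- model; up[[nm]][i] <- M[i] + step
      dn <- model; dn[[nm]][i] <- M[i] - step
      G[i] <- (gcp_objective(x, up, spec) - gcp_objective(x, dn, spec)) /
        (2 * step)
    }
    G
  })
}

random_masked_tensor <- function(I, J, K, obs_rate = 0.7, positive = FALSE,
                                 seed = 1) {
  set.seed(seed)
  vals <- if (positive) {
    array(stats::runif(I * J * K, 0.2, 3), c(I, J, K))
  } else {
    array(stats::rnorm(I * J * K), c(I, J, K))
  }
  mask <- array(stats::rbinom(I * J * K, 1, obs_rate), c(I, J, K))
  if (sum(mask) == 0) mask[1, 1, 1] <- 1
  tensor3(vals, mask)
}

# bivariate Gaussian latent table with a target correlation
bivariate_latent <- function(n, rho, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * 2), n, 2) %*%
    chol(matrix(c(1, rho, rho, 1), 2))
  latent_table(data.frame(f1 = z[, 1], f2 = z[, 2]), loss = "gaussian")
}

mvn_latent <- function(n, Sigma, seed = 1) {
  d <- nrow(Sigma)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d) %*% chol(Sigma)
  latent_table(as.data.frame(X), loss = "gaussian")
}
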