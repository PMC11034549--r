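# Gaussian copula ------------------------------------------------------------

test_that("copula with one latent column reproduces the marginal", {
  set.seed(1)
  lt <- latent_table(data.frame(f1 = rgamma(400, 2, 1)))
  syn <- copula_sample(lt, 1000, seed = 3)
  ks <- suppressWarnings(ks.test(syn$f1, lt$f1)$statistic)
  expect_lt(ks, 0.1)
  expect_true(all(syn$f1 >= min(lt$f1) & syn$f1 <= max(lt$f1)))
})

test_that("copula preserves a generated bivariate correlation", {
  lt <- bivariate_latent(300, 0.8, seed = 11)
  syn <- copula_sample(lt, 2000, seed = 5)
  expect_lt(abs(cor(syn$f1, syn$f2) - 0.8), 0.05)
  expect_identical(names(syn), names(lt))
  expect_identical(nrow(syn), 2000L)
  # accepted draws satisfy the Frobenius bound by construction
  if (attr(syn, "accepted")) {
    expect_lt(attr(syn, "frobenius"), 0.05 * 2)
  }
})

test_that("copula acceptance loop stops immediately with infinite epsilon", {
  lt <- bivariate_latent(100, 0.5, seed = 2)
  syn <- copula_sample(lt, 50, epsilon = Inf, seed = 1)
  expect_identical(attr(syn, "tries"), 1L)
  expect_true(attr(syn, "accepted"))
})

test_that("copula is deterministic under seed across marginal estimators", {
  lt <- bivariate_latent(150, 0.6, seed = 4)
  for (mk in c("empirical_cdf", "kernel", "gamma", "beta",
               "truncated_gaussian")) {
    s1 <- copula_sample(lt, 200, marginal = mk, seed = 9)
    s2 <- copula_sample(lt, 200, marginal = mk, seed = 9)
    expect_identical(as.data.frame(s1), as.data.frame(s2))
    expect_false(anyNA(s1))
  }
})

test_that("a non-positive-definite correlation is repaired with a warning", {
  set.seed(3)
  a <- rnorm(50)
  lt <- latent_table(data.frame(f1 = a, f2 = a, f3 = rnorm(50)))
  expect_warning(copula_sample(lt, 20, seed = 1), "positive definite")
})

# Sequential decision trees ---------------------------------------------------

test_that("sequential trees preserve a constant column exactly", {
  set.seed(5)
  lt <- latent_table(data.frame(a1 = rnorm(60), a2 = rep(3.5, 60)))
  syn <- seqtree_sample(seqtree_fit(lt), 100, seed = 1)
  expect_true(all(syn$a2 == 3.5))
})

test_that("sequential trees recover a generated dependence", {
  set.seed(7)
  a1 <- rnorm(500)
  lt <- latent_table(data.frame(a1 = a1, a2 = 2 * a1 + rnorm(500, 0, 0.1)))
  syn <- seqtree_sample(seqtree_fit(lt), 1000, seed = 3)
  expect_lt(abs(cor(syn$a1, syn$a2) - cor(lt$a1, lt$a2)), 0.1)
  # leaf resampling: every synthetic value was observed in training
  expect_true(all(syn$a1 %in% lt$a1))
  expect_true(all(syn$a2 %in% lt$a2))
})

test_that("sequential trees honor the requested output size (250 from 226)", {
  set.seed(8)
  lt <- latent_table(as.data.frame(matrix(rnorm(226 * 4), 226, 4)))
  syn <- seqtree_sample(seqtree_fit(lt), 250, seed = 2)
  expect_identical(nrow(syn), 250L)
  expect_identical(names(syn), names(lt))
  s2 <- seqtree_sample(seqtree_fit(lt), 250, seed = 2)
  expect_identical(as.data.frame(syn), as.data.frame(s2))
})

test_that("degenerate sequential-tree inputs error or fall back sensibly", {
  expect_error(seqtree_fit(latent_table(data.frame(a = 1))), ">= 2 rows")
  # single column degenerates to marginal resampling
  lt1 <- latent_table(data.frame(a = rnorm(30)))
  syn <- seqtree_sample(seqtree_fit(lt1), 50, seed = 1)
  expect_true(all(syn$a %in% lt1$a))
})

# Hamiltonian Monte Carlo ------------------------------------------------------

test_that("the HMC log-posterior gradient matches finite differences", {
  set.seed(13)
  d <- 3; n <- 40
  X <- matrix(rnorm(n * d), n, d)
  S <- crossprod(scale(X, scale = FALSE))
  pairs <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  lb <- 1.5 + (d - 1 - (pairs[, 1] - pairs[, 2])) / 2
  lp <- function(th) tensorsynth:::mvn_cov_logpost(th, S, n, d, pairs, 2.5, lb)
  for (rep in 1:3) {
    theta <- c(rnorm(d, 0, 0.3), rnorm(nrow(pairs), 0, 0.4))
    g <- lp(theta)$grad
    num <- vapply(seq_along(theta), function(i) {
      h <- 1e-6
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (lp(tp)$lp - lp(tm)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("HMC recovers a known small covariance and mixes", {
  Sig <- matrix(c(1, 0.6, 0.6, 1.3), 2, 2)
  lt <- mvn_latent(300, Sig, seed = 21)
  post <- hmc_fit(lt, chains = 2, warmup = 200, sampling = 200, seed = 1)
  expect_lt(max(abs(summary(post) - Sig)), 0.15)
  expect_true(all(post$diagnostics$rhat < 1.1))
  # scale draws are positive by construction
  expect_true(all(apply(post$Sigma, 1, function(S) all(diag(S) > 0))))
  # deterministic under seed
  post2 <- hmc_fit(lt, chains = 2, warmup = 200, sampling = 200, seed = 1)
  expect_identical(post$draws, post2$draws)
  samp <- hmc_sample(post, 123, seed = 2)
  expect_identical(nrow(samp), 123L)
  expect_identical(names(samp), names(lt))
})

test_that("HMC refuses non-Gaussian latent provenance unless overridden", {
  set.seed(4)
  lt <- latent_table(data.frame(f1 = rnorm(30), f2 = rnorm(30)),
                     loss = "gamma")
  expect_error(hmc_fit(lt, warmup = 50, sampling = 10), "provenance")
  expect_s3_class(
    hmc_fit(lt, chains = 2, warmup = 50, sampling = 10, seed = 1,
            override_loss_check = TRUE),
    "hmc_posterior")
})
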