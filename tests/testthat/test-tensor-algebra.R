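test_that("Kruskal reconstruction matches the brute-force triple-loop oracle", {
  # identity case: all-ones factors
  ones <- matrix(1, 2, 1)
  expect_equal(reconstruct(kruskal(ones, ones, ones)),
               array(1, c(2, 2, 2)))

  # zero weight annihilates the tensor (lambda validation requires > 0, so
  # use a zero factor column instead of lambda = 0)
  expect_equal(reconstruct(kruskal(ones * 0, ones, ones)),
               array(0, c(2, 2, 2)))

  # random integer factors vs the loop oracle, exactly
  set.seed(42)
  for (case in 1:4) {
    R <- sample(1:4, 1)
    A <- matrix(sample(-3:3, 3 * R, TRUE), 3, R)
    B <- matrix(sample(-3:3, 4 * R, TRUE), 4, R)
    C <- matrix(sample(-3:3, 2 * R, TRUE), 2, R)
    lam <- seq_len(R)
    expect_identical(reconstruct(kruskal(A, B, C, lambda = lam)),
                     oracle_reconstruct(lam, A, B, C))
  }
})

test_that("kruskal validates factor shapes and weights", {
  A <- matrix(1, 3, 2)
  expect_error(kruskal(A, matrix(1, 4, 3), matrix(1, 2, 2)), "column count")
  expect_error(kruskal(A, A, A, lambda = c(1, -1)), "positive")
  expect_error(kruskal(-A, A, A, nonnegative = TRUE), "negative")
})

test_that("unfold/fold round-trip and the Kruskal unfolding identities hold", {
  set.seed(7)
  x <- array(rnorm(60), c(3, 4, 5))
  for (mode in 1:3) {
    expect_identical(fold(unfold(x, mode), mode, dim(x)), x)
  }
  expect_equal(unfold(array(1, c(2, 2, 2)), 1), matrix(1, 2, 4))
  expect_error(unfold(x, 4), "mode")

  A <- matrix(rnorm(6), 3, 2); B <- matrix(rnorm(8), 4, 2)
  C <- matrix(rnorm(10), 5, 2)
  lam <- c(2, 0.5)
  m <- reconstruct(kruskal(A, B, C, lambda = lam))
  dl <- diag(lam)
  expect_equal(unfold(m, 1), A %*% dl %*% t(khatri_rao(C, B)),
               tolerance = 1e-12)
  expect_equal(unfold(m, 2), B %*% dl %*% t(khatri_rao(C, A)),
               tolerance = 1e-12)
  expect_equal(unfold(m, 3), C %*% dl %*% t(khatri_rao(B, A)),
               tolerance = 1e-12)
})

test_that("khatri_rao matches its definition", {
  # row vectors -> elementwise product row
  expect_equal(khatri_rao(matrix(1:3, 1), matrix(4:6, 1)),
               matrix(c(4, 10, 18), 1))
  # identity with identity: direct definition oracle
  I2 <- diag(2)
  kr <- khatri_rao(I2, I2)
  oracle <- sapply(1:2, function(r) kronecker(I2[, r], I2[, r]))
  expect_equal(kr, oracle)
  expect_equal(khatri_rao(matrix(1, 2, 3), matrix(1, 2, 3)),
               matrix(1, 4, 3))
  expect_error(khatri_rao(matrix(1, 2, 2), matrix(1, 2, 3)), "column count")
})

test_that("fit_score matches a loop oracle and ignores masked entries", {
  x <- random_masked_tensor(4, 3, 5, obs_rate = 0.7, seed = 11)
  m <- array(rnorm(60), c(4, 3, 5))
  expect_equal(fit_score(x, x$values), 1)
  expect_equal(fit_score(x, m * 0), 0)

  num <- den <- 0
  for (i in 1:4) for (j in 1:3) for (k in 1:5) {
    if (x$mask[i, j, k] == 1) {
      num <- num + (x$values[i, j, k] - m[i, j, k])^2
      den <- den + x$values[i, j, k]^2
    }
  }
  expect_equal(fit_score(x, m), 1 - sqrt(num) / sqrt(den), tolerance = 1e-12)

  # altering masked sentinels changes nothing
  y <- x
  y$values[y$mask == 0] <- 999
  expect_identical(fit_score(y, m), fit_score(x, m))

  z <- tensor3(array(0, c(2, 2, 2)))
  expect_error(fit_score(z, array(0, c(2, 2, 2))), "undefined")
})

test_that("standardization round-trips and uses observed entries only", {
  x <- random_masked_tensor(6, 3, 4, obs_rate = 0.8, seed = 3)
  st <- standardize_tensor(x)
  for (j in 1:3) {
    obs <- st$tensor$values[, j, ][x$mask[, j, ] == 1]
    expect_equal(mean(obs), 0, tolerance = 1e-12)
    expect_equal(sd(obs), 1, tolerance = 1e-12)
  }
  back <- destandardize_tensor(st$tensor, st$transform)
  obs <- x$mask == 1
  expect_equal(back$values[obs], x$values[obs], tolerance = 1e-12)

  # idempotence: standardizing an already standardized tensor is identity
  st2 <- standardize_tensor(st$tensor)
  expect_equal(st2$tensor$values[obs], st$tensor$values[obs],
               tolerance = 1e-12)

  # hand oracle: observed values {2, 4} -> center 3, sample sd sqrt(2)
  v <- array(NA_real_, c(2, 1, 1)); v[, 1, 1] <- c(2, 4)
  h <- standardize_tensor(tensor3(v))
  expect_equal(h$transform$center, 3)
  expect_equal(h$transform$scale, sqrt(2))

  # masked values do not leak into the statistics
  y <- x
  y$values[y$mask == 0] <- 1e6
  sty <- standardize_tensor(y)
  expect_identical(sty$transform$center, st$transform$center)

  # degenerate variable errors, naming it
  vc <- array(rnorm(8), c(2, 2, 2)); vc[, 2, ] <- 7
  expect_error(standardize_tensor(tensor3(vc, variables = c("a", "flat"))),
               "flat")
})
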