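test_that("loss values and derivatives match direct substitution", {
  g <- loss_spec("gaussian")
  expect_equal(loss_eval(g, 1.7, 1.7), list(value = 0, deriv = 0))
  expect_equal(loss_eval(g, 3, 1), list(value = 4, deriv = -4))
  p <- loss_spec("poisson_log")
  expect_equal(loss_eval(p, 0, 0), list(value = 1, deriv = 1))
  expect_error(loss_eval(loss_spec("gamma"), -1, 1), "nonnegative data")
  expect_error(loss_eval(loss_spec("gamma"), 1, -1), "nonnegative model")
})

test_that("every loss derivative matches central finite differences", {
  set.seed(99)
  for (name in c("gaussian", "poisson_log", "gamma", "beta_divergence")) {
    spec <- loss_spec(name, offset = 1e-8)
    for (t in 1:20) {
      x <- runif(1, 0.05, 4)
      m <- runif(1, 0.05, 4)
      h <- 1e-6 * max(m, 1)
      num <- (loss_eval(spec, x, m + h)$value -
                loss_eval(spec, x, m - h)$value) / (2 * h)
      expect_equal(loss_eval(spec, x, m)$deriv, num, tolerance = 1e-6,
                   label = paste(name, "derivative"))
    }
  }
})

test_that("masked objective matches the loop oracle and ignores masked cells", {
  x <- random_masked_tensor(3, 3, 2, obs_rate = 0.6, positive = TRUE,
                            seed = 5)
  set.seed(6)
  mod <- kruskal(matrix(runif(6, 0.1, 1), 3, 2),
                 matrix(runif(6, 0.1, 1), 3, 2),
                 matrix(runif(4, 0.1, 1), 2, 2))
  for (name in c("gaussian", "gamma")) {
    spec <- loss_spec(name)
    expect_equal(gcp_objective(x, mod, spec), oracle_objective(x, mod, spec),
                 tolerance = 1e-12)
  }
  # a model that reproduces the data exactly has objective zero (gaussian)
  x2 <- tensor3(reconstruct(mod), array(1, c(3, 3, 2)))
  expect_equal(gcp_objective(x2, mod, loss_spec("gaussian")), 0,
               tolerance = 1e-20)
  # perturbing only masked cells leaves the objective unchanged
  y <- x
  y$values[y$mask == 0] <- 123
  expect_identical(gcp_objective(y, mod, loss_spec("gaussian")),
                   gcp_objective(x, mod, loss_spec("gaussian")))
})

test_that("analytic factor gradients match finite differences for all losses", {
  x <- random_masked_tensor(4, 3, 2, obs_rate = 0.7, positive = TRUE,
                            seed = 8)
  set.seed(9)
  mod <- kruskal(matrix(runif(8, 0.1, 1), 4, 2),
                 matrix(runif(6, 0.1, 1), 3, 2),
                 matrix(runif(4, 0.1, 1), 2, 2))
  for (name in c("gaussian", "poisson_log", "gamma", "beta_divergence")) {
    spec <- loss_spec(name, offset = 1e-8)
    g <- gcp_gradient(x, mod, spec)
    num <- numeric_gcp_gradient(x, mod, spec)
    for (nm in c("A", "B", "C")) {
      rel <- max(abs(g[[nm]] - num[[nm]]) / pmax(abs(num[[nm]]), 1e-4))
      expect_lt(rel, 1e-5)
    }
  }
  # all-zero mask: zero gradient
  x0 <- tensor3(x$values, mask = array(0, dim(x)))
  g0 <- gcp_gradient(x0, mod, loss_spec("gaussian"))
  expect_equal(g0$A, mod$A * 0)
  # stationarity at an exact optimum
  xe <- tensor3(reconstruct(mod), array(1, dim(x)))
  ge <- gcp_gradient(xe, mod, loss_spec("gaussian"))
  expect_lt(max(abs(unlist(ge))), 1e-10)
})

test_that("gcp recovers generated low-rank structure", {
  sim <- sim_lowrank(20, 5, 6, rank = 2, noise_sd = 0, seed = 1)
  fit <- gcp(sim$tensor, rank = 2, seed = 1)
  expect_gte(fit$fit_score, 0.999)

  # rank-1 is identifiable up to scaling
  sim1 <- sim_lowrank(10, 4, 5, rank = 1, noise_sd = 0, seed = 2)
  fit1 <- gcp(sim1$tensor, rank = 1, seed = 1)
  expect_gte(fit1$fit_score, 0.9999)
})

test_that("gcp is deterministic under seed and invariant to masked sentinels", {
  sim <- sim_lowrank(12, 4, 5, rank = 2, noise_sd = 0.1, mcar = 0.25,
                     seed = 3)
  f1 <- gcp(sim$tensor, rank = 2, seed = 7)
  f2 <- gcp(sim$tensor, rank = 2, seed = 7)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$objective, f2$objective)

  pert <- sim$tensor
  pert$values[pert$mask == 0] <- -55
  f3 <- gcp(pert, rank = 2, seed = 7)
  expect_identical(f1$A, f3$A)
})

test_that("gcp enforces loss domains and flags degenerate input", {
  x <- tensor3(array(rnorm(24), c(2, 3, 4)))
  expect_error(gcp(x, 2, loss = "gamma"), "nonnegative data")
  expect_error(gcp(x, 2, loss = "gaussian", nonnegative = FALSE,
                   control = gcp_control(max_iterations = 5)), NA)
  xp <- tensor3(array(runif(24, 0.5, 2), c(2, 3, 4)))
  expect_error(gcp(xp, 2, loss = "gamma", nonnegative = FALSE),
               "nonnegative = TRUE")
})

test_that("the adam optimizer drives the objective down with projection", {
  sim <- sim_lowrank(10, 4, 4, rank = 2, noise_sd = 0, nonnegative = TRUE,
                     seed = 5)
  fit <- gcp(sim$tensor, rank = 2, nonnegative = TRUE, seed = 2,
             control = gcp_control(optimizer = "adam",
                                   max_iterations = 800, adam_rate = 0.05))
  expect_gte(fit$fit_score, 0.9)
  expect_true(all(fit$A >= 0), all(fit$B >= 0))
})

test_that("gcp_normalize moves scale into lambda without changing the tensor", {
  sim <- sim_lowrank(8, 3, 4, rank = 2, seed = 6)
  fit <- gcp(sim$tensor, rank = 2, seed = 1)
  nrm <- gcp_normalize(fit)
  expect_equal(sqrt(colSums(nrm$A^2)), rep(1, 2), ignore_attr = TRUE)
  expect_equal(reconstruct(nrm), reconstruct(fit), tolerance = 1e-10)
})

test_that("fitted/predict/residuals/summary methods are coherent", {
  sim <- sim_lowrank(10, 3, 4, rank = 2, noise_sd = 0.05, seed = 8)
  fit <- gcp(sim$tensor, rank = 2, standardize = TRUE, seed = 1)
  m <- fitted(fit, scale = "original")
  expect_identical(dim(m), c(10L, 3L, 4L))
  expect_equal(predict(fit, fit$A, scale = "original"), m)
  r <- residuals(fit, sim$tensor)
  expect_identical(dim(r), dim(m))
  s <- summary(fit)
  expect_s3_class(s, "summary.gcp")
  expect_equal(nrow(s$components), 2)
  expect_output(print(fit), "Generalized CP")
})
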