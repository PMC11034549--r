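test_that("latent_table validates completeness, names, and kinds", {
  expect_error(latent_table(data.frame(a = c(1, NA))), "missing")
  df <- data.frame(a = 1:3, b = 4:6)
  names(df) <- c("a", "a")
  expect_error(latent_table(df), "unique")
  expect_error(latent_table(data.frame(a = letters[1:3])), "numeric")
  lt <- latent_table(data.frame(a = 1:3 / 2), kinds = "count",
                     loss = "gaussian")
  expect_identical(attr(lt, "kinds"), "count")
  expect_identical(attr(lt, "loss"), "gaussian")
})

test_that("augment_latent concatenates tagged blocks and splits back exactly", {
  set.seed(2)
  A <- latent_table(as.data.frame(matrix(rnorm(226 * 3), 226, 3)))
  # A only: equal to A
  aug0 <- augment_latent(A)
  expect_equal(as.data.frame(aug0), as.data.frame(A), ignore_attr = TRUE)

  Aw <- latent_table(as.data.frame(matrix(rnorm(226 * 2), 226, 2)))
  v <- sample(3:10, 226, TRUE)
  base <- data.frame(age = rnorm(226, 60, 10))
  aug <- augment_latent(A, mask_factors = Aw, visit_counts = v,
                        baselines = base)
  expect_identical(dim(aug), c(226L, 3L + 2L + 1L + 1L))
  blocks <- split_latent(aug)
  expect_named(blocks, c("gcp_factors", "mask_factors", "visit_count",
                         "baselines"))
  expect_equal(blocks$gcp_factors, as.data.frame(A), ignore_attr = TRUE)
  expect_equal(unname(as.matrix(blocks$mask_factors)),
               unname(as.matrix(Aw)))
  expect_equal(blocks$visit_count$n_visits, as.numeric(v))
  expect_equal(blocks$baselines$age, base$age)
  # re-concatenation is the identity
  expect_equal(unname(as.matrix(do.call(cbind, blocks))),
               unname(as.matrix(as.data.frame(aug))))

  expect_error(augment_latent(A, mask_factors = latent_table(
    data.frame(w = rnorm(10)))), "mismatch")
})

test_that("latent_factors carries provenance from the fitted loss", {
  sim <- sim_lowrank(10, 3, 4, rank = 2, seed = 1)
  fit <- gcp(sim$tensor, rank = 2, seed = 1)
  lt <- latent_factors(fit)
  expect_identical(attr(lt, "loss"), "gaussian")
  expect_identical(dim(lt), c(10L, 2L))
  expect_named(lt, c("f1", "f2"))
})
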