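test_that("hellinger distance behaves at its extremes and by hand", {
  x <- rnorm(200)
  expect_equal(hellinger(x, x), 0, tolerance = 1e-12)
  expect_equal(hellinger(1:100, 201:300), 1)
  # hand Bhattacharyya computation for p = (.5,.5), q = (.9,.1)
  x2 <- c(rep(1, 5), rep(2, 5))
  y2 <- c(rep(1, 9), rep(2, 1))
  expect_equal(hellinger(x2, y2, categorical = TRUE),
               sqrt(1 - (sqrt(0.45) + sqrt(0.05))), tolerance = 1e-12)
  # symmetry and shuffle invariance
  set.seed(1)
  a <- rnorm(300); b <- rnorm(300, 0.5)
  expect_equal(hellinger(a, b), hellinger(b, a))
  expect_equal(hellinger(sample(a), b), hellinger(a, b))
  # resampling self-consistency at n = 1000 with default bins
  p <- rnorm(1000); q <- rnorm(1000)
  expect_lte(hellinger(p, q), 0.1)
  expect_error(hellinger(numeric(0), a), "empty")
})

test_that("rmsdc and abs_corr_diffs match hand and loop oracles", {
  C1 <- diag(3)
  expect_equal(rmsdc(C1, C1), 0)
  C2 <- C1
  C2[upper.tri(C2)] <- c(0.1, -0.2, 0)
  C2[lower.tri(C2)] <- t(C2)[lower.tri(C2)]
  expect_equal(rmsdc(C2, C1), sqrt(0.05 / 3), tolerance = 1e-12)
  expect_equal(rmsdc(C1, C2), rmsdc(C2, C1))
  expect_equal(sort(abs_corr_diffs(C1, C2)), c(0, 0.1, 0.2))

  # loop oracle on random symmetric matrices
  set.seed(3)
  for (t in 1:5) {
    n <- sample(3:6, 1)
    M <- matrix(runif(n * n, -1, 1), n, n); Ca <- (M + t(M)) / 2; diag(Ca) <- 1
    M <- matrix(runif(n * n, -1, 1), n, n); Cb <- (M + t(M)) / 2; diag(Cb) <- 1
    acc <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) acc <- c(acc, Ca[i, j] - Cb[i, j])
    expect_equal(rmsdc(Ca, Cb), sqrt(mean(acc^2)), tolerance = 1e-12)
    expect_lte(rmsdc(Ca, Cb), 2)
  }
  expect_error(rmsdc(diag(3), diag(4)), "same shape")
})

test_that("correlation_matrix widens to variable-visit columns", {
  set.seed(5)
  n <- 500
  df <- rbind(
    data.frame(patient_id = sprintf("p%03d", 1:n), variable = "a",
               visit = 1L, value = rnorm(n)),
    data.frame(patient_id = sprintf("p%03d", 1:n), variable = "b",
               visit = 1L, value = rnorm(n))
  )
  # duplicated column pair: correlation exactly 1
  df2 <- df
  df2$value[df2$variable == "b"] <- df2$value[df2$variable == "a"]
  C <- correlation_matrix(long_table(df2))
  expect_equal(C["a.v1", "b.v1"], 1)
  # independent columns: off-diagonals inside the null sampling band
  C0 <- correlation_matrix(long_table(df))
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.12)
  # symmetric with unit diagonal
  expect_equal(C0, t(C0))
  expect_equal(unname(diag(C0)), rep(1, ncol(C0)))
  # sparse column exclusion warns
  df3 <- df
  df3$value[df3$variable == "b"][-(1:2)] <- NA
  expect_warning(correlation_matrix(long_table(rbind(
    df3, data.frame(patient_id = sprintf("p%03d", 1:n), variable = "c",
                    visit = 1L, value = rnorm(n))))), "excluding")
})

test_that("descriptive_summary matches a hand computation and counts missing", {
  df <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    variable = "lab",
    visit = 1L,
    value = c(0.2, 1.0, 1.6, 16.2)
  )
  s <- descriptive_summary(long_table(df))
  expect_equal(s$min, 0.2)
  expect_equal(s$max, 16.2)
  expect_equal(s$median, 1.3)
  expect_equal(s$mean, mean(df$value))
  expect_equal(s$missing, 0)
  # one empty cell in the grid -> one missing
  df$value[2] <- NA
  expect_equal(descriptive_summary(long_table(df))$missing, 1)
})

test_that("utility reports assemble, print, and round-trip through JSON", {
  long <- sim_ehr_like(sim_spec(n_patients = 40, n_visits = 3, seed = 2))
  syn <- sim_ehr_like(sim_spec(n_patients = 50, n_visits = 3, seed = 9))
  rep <- utility_report(long, syn, seed = 2L)
  expect_s3_class(rep, "utility_report")
  expect_true(all(rep$hellinger >= 0 & rep$hellinger <= 1))
  expect_gte(rep$rmsdc, 0)
  expect_true(all(rep$abs_corr_diffs >= 0 & rep$abs_corr_diffs <= 2))
  expect_output(print(rep), "RMSDC")

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$rmsdc, rep$rmsdc)
  expect_equal(back$hellinger, rep$hellinger)
  expect_equal(back$abs_corr_diffs, rep$abs_corr_diffs)
  expect_equal(back$summary_real, rep$summary_real)
  expect_equal(back$missing_fraction_synthetic,
               rep$missing_fraction_synthetic)
  # self-comparison is exact agreement
  self <- utility_report(long, long)
  expect_equal(self$rmsdc, 0)
  expect_true(all(self$hellinger < 1e-12))
})
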