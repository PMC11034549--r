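test_that("sim_lowrank is deterministic with calibrated noise", {
  s1 <- sim_lowrank(10, 4, 5, rank = 2, noise_sd = 0.3, seed = 9)
  s2 <- sim_lowrank(10, 4, 5, rank = 2, noise_sd = 0.3, seed = 9)
  expect_identical(s1$tensor$values, s2$tensor$values)

  # noiseless tensor scores a perfect fit against its own truth
  s0 <- sim_lowrank(10, 4, 5, rank = 2, noise_sd = 0, seed = 1)
  expect_equal(fit_score(s0$tensor, reconstruct(s0$truth)), 1)

  # empirical noise sd within 5% of the request at >= 1e4 cells
  sb <- sim_lowrank(30, 20, 20, rank = 2, noise_sd = 0.5, seed = 3)
  res <- sb$tensor$values - reconstruct(sb$truth)
  expect_lt(abs(sd(res) - 0.5) / 0.5, 0.05)
})

test_that("sim_ehr_like hits its missingness and correlation targets", {
  # MCAR 0.21 on a large panel
  long <- sim_ehr_like(sim_spec(n_patients = 226, n_visits = 36,
                                mcar = 0.21, seed = 3))
  expect_lt(abs(mean(is.na(long$value)) - 0.21), 0.02)

  # cross-variable correlation target at I = 500
  spec <- sim_spec(n_patients = 500, n_visits = 4, target_cor = 0.6,
                   patient_share = 0.7, seed = 5)
  tl <- sim_ehr_like(spec)
  W <- as_tensor3(tl)$values
  cors <- c()
  for (j1 in 1:3) for (j2 in (j1 + 1):4) {
    cors <- c(cors, cor(as.vector(W[, j1, ]), as.vector(W[, j2, ])))
  }
  expect_lt(max(abs(cors - 0.6)), 0.1)

  # dense fixed-K table has exactly I*J*K rows
  dense <- sim_ehr_like(sim_spec(n_patients = 20, n_visits = 3, seed = 1))
  expect_identical(nrow(dense), 20L * 4L * 3L)
  expect_false(anyNA(dense$value))
})

test_that("irregular visit counts stay inside the requested range", {
  spec <- sim_spec(n_patients = 60, n_visits = 10, visit_range = c(3, 10),
                   seed = 7)
  tl <- sim_ehr_like(spec)
  v_i <- tapply(tl$visit, tl$patient_id, max)
  expect_true(all(v_i >= 3 & v_i <= 10))
  expect_gt(length(unique(v_i)), 1)
})

test_that("categorical variables follow their marginals with persistence", {
  spec <- sim_profile("admissions", seed = 2)
  tl <- sim_ehr_like(spec)
  expect_setequal(unique(tl$variable),
                  c("admission_type", "admission_location"))
  at <- tl$value[tl$variable == "admission_type"]
  expect_true(all(at %in% 1:4))
  freq <- tabulate(at, 4) / length(at)
  expect_lt(max(abs(freq - c(0.5, 0.3, 0.15, 0.05))), 0.06)
})

test_that("generated tables round-trip bit-identically through CSV", {
  long <- sim_ehr_like(sim_spec(n_patients = 15, n_visits = 4, mcar = 0.2,
                                seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(long, path)
  back <- read_long_csv(path)
  expect_identical(back$value, long$value)
  expect_identical(back$patient_id, long$patient_id)
  expect_identical(sum(is.na(back$value)), sum(is.na(long$value)))
})
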