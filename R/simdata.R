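#' Simulation specification for EHR-like longitudinal data
#'
#' Describes the generative process of [sim_ehr_like()]. Continuous
#' variables follow a patient random effect plus an AR(1) visit process:
#' with shared patient factor `g_i ~ N(0,1)`, idiosyncratic patient factor
#' `h_ij ~ N(0,1)`, and a unit-variance AR(1) process `w_ijk`,
#' \deqn{x_{ijk} = \mu_j + s_j (\sqrt{v}\, z_{ij} + \sqrt{1 - v}\, w_{ijk}),
#'   \quad z_{ij} = \sqrt{c}\, g_i + \sqrt{1 - c}\, h_{ij},}
#' where `v` is the patient-level variance share and `c` is chosen so that
#' the correlation between two variables at the same visit equals
#' `target_cor` (`c = target_cor / v`). Categorical variables draw a
#' per-patient preferred level from the marginals and repeat it at each
#' visit with probability `persistence`, otherwise redrawing from the
#' marginals. Missingness is MCAR; irregular visit counts are uniform over
#' `visit_range`.
#'
#' @param n_patients,n_visits tensor dimensions I and K.
#' @param variables data frame with columns `name`, `mean`, `sd`, one row
#'   per continuous variable (may have zero rows for purely categorical
#'   data).
#' @param target_cor same-visit correlation between two continuous
#'   variables; must not exceed `patient_share`.
#' @param patient_share fraction of each variable's variance explained at
#'   the patient level.
#' @param ar AR(1) coefficient of the visit process, in (-1, 1).
#' @param mcar missing-completely-at-random rate in [0, 1).
#' @param visit_range `NULL` for a fixed number of visits, or an integer
#'   range from which each patient's visit count is drawn uniformly.
#' @param categorical `NULL`, or a list of specs `list(name=, probs=,
#'   persistence=)`; levels are coded 1..length(probs).
#' @param seed integer seed.
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_patients = 226L, n_visits = 5L,
                     variables = data.frame(
                       name = c("creatinine", "potassium", "sodium",
                                "hematocrit"),
                       mean = c(1.6, 4.2, 138, 32),
                       sd = c(1.2, 0.6, 6, 5.5)),
                     target_cor = 0.45, patient_share = 0.65, ar = 0.6,
                     mcar = 0, visit_range = NULL, categorical = NULL,
                     seed = 1L) {
  stopifnot(n_patients >= 1, n_visits >= 1,
            mcar >= 0, mcar < 1, ar > -1, ar < 1,
            patient_share > 0, patient_share <= 1,
            target_cor >= 0, target_cor <= patient_share)
  if (nrow(variables) > 0) {
    stopifnot(all(c("name", "mean", "sd") %in% names(variables)),
              all(variables$sd > 0))
  }
  if (!is.null(visit_range)) {
    visit_range <- as.integer(range(visit_range))
    stopifnot(visit_range[1] >= 1, visit_range[2] <= n_visits)
  }
  if (!is.null(categorical)) {
    for (cs in categorical) {
      stopifnot(!is.null(cs$name), !is.null(cs$probs),
                abs(sum(cs$probs) - 1) < 1e-8, all(cs$probs >= 0),
                cs$persistence >= 0, cs$persistence <= 1)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), n_visits = as.integer(n_visits),
         variables = variables, target_cor = target_cor,
         patient_share = patient_share, ar = ar, mcar = mcar,
         visit_range = visit_range, categorical = categorical,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Canned simulation profiles
#'
#' Shapes matching the regimes the package is exercised in: a dense
#' 226 x 4 x 5 laboratory panel (`"labs_dense"`), the same four labs over
#' 36 visits with 21% MCAR missingness (`"labs_missing"`), an
#' irregular-visit variant with 3-10 visits per patient
#' (`"labs_irregular"`), and a dense 246 x 2 x 5 categorical panel of
#' admission-style features (`"admissions"`). All values are synthetic.
#'
#' @param name profile name.
#' @param seed integer seed stored in the spec.
#' @return A [sim_spec()].
#' @export
sim_profile <- function(name = c("labs_dense", "labs_missing",
                                 "labs_irregular", "admissions"),
                        seed = 1L) {
  name <- match.arg(name)
  switch(name,
    labs_dense = sim_spec(n_patients = 226L, n_visits = 5L, seed = seed),
    labs_missing = sim_spec(n_patients = 226L, n_visits = 36L, mcar = 0.21,
                            seed = seed),
    labs_irregular = sim_spec(n_patients = 226L, n_visits = 10L,
                              visit_range = c(3L, 10L), seed = seed),
    admissions = sim_spec(
      n_patients = 246L, n_visits = 5L,
      variables = data.frame(name = character(), mean = numeric(),
                             sd = numeric()),
      target_cor = 0, patient_share = 0.65,
      categorical = list(
        list(name = "admission_type", probs = c(0.5, 0.3, 0.15, 0.05),
             persistence = 0.8),
        list(name = "admission_location", probs = c(0.35, 0.25, 0.2, 0.12,
                                                    0.08),
             persistence = 0.8)),
      seed = seed)
  )
}

#' Generate a noisy low-rank tensor with known ground truth
#'
#' Factor matrices are drawn i.i.d. (standard normal, or uniform on
#' (0.1, 1) when `nonnegative`), the tensor is their Kruskal reconstruction
#' plus Gaussian noise, and an optional MCAR mask is applied. The full
#' noise-free truth is returned alongside, so fitting and imputation can be
#' checked against it.
#'
#' @param I,J,K dimensions.
#' @param rank true rank (within `min(IJ, IK, JK)`).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param mcar MCAR masking rate in [0, 1).
#' @param nonnegative draw nonnegative factors.
#' @param seed integer seed.
#' @return A list with `tensor` (a [tensor3()]) and `truth` (a
#'   [kruskal()] model).
#' @export
sim_lowrank <- function(I, J, K, rank, noise_sd = 0, mcar = 0,
                        nonnegative = FALSE, seed = 1L) {
  stopifnot(rank >= 1, rank <= min(I * J, I * K, J * K),
            noise_sd >= 0, mcar >= 0, mcar < 1)
  set.seed(as.integer(seed))
  draw <- function(n) {
    if (nonnegative) stats::runif(n, 0.1, 1) else stats::rnorm(n)
  }
  truth <- kruskal(matrix(draw(I * rank), I, rank),
                   matrix(draw(J * rank), J, rank),
                   matrix(draw(K * rank), K, rank))
  vals <- reconstruct(truth)
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  mask <- array(1, c(I, J, K))
  if (mcar > 0) mask[stats::runif(length(mask)) < mcar] <- 0
  list(tensor = tensor3(vals, mask), truth = truth)
}

#' Generate an EHR-like longitudinal long table
#'
#' Realizes a [sim_spec()] (see its help for the generative equations) as a
#' long-format table. Deterministic given the spec's seed. Missing cells
#' within a patient's visit range are kept as `NA`-valued rows; visits
#' beyond an irregular patient's count are absent entirely.
#'
#' @param spec a [sim_spec()].
#' @return A [long_table()] with attribute `"sim_spec"`.
#' @export
sim_ehr_like <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  I <- spec$n_patients; K <- spec$n_visits
  Jc <- nrow(spec$variables)
  patients <- sprintf("p%04d", seq_len(I))

  rows <- list()
  if (Jc > 0) {
    v <- spec$patient_share
    c_lat <- spec$target_cor / v
    phi <- spec$ar
    g <- stats::rnorm(I)
    for (j in seq_len(Jc)) {
      h <- stats::rnorm(I)
      z <- sqrt(c_lat) * g + sqrt(1 - c_lat) * h
      w <- matrix(NA_real_, I, K)
      w[, 1] <- stats::rnorm(I)
      if (K > 1) for (k in 2:K) {
        w[, k] <- phi * w[, k - 1] + sqrt(1 - phi^2) * stats::rnorm(I)
      }
      x <- spec$variables$mean[j] + spec$variables$sd[j] *
        (sqrt(v) * z + sqrt(1 - v) * w)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rep(patients, K),
        variable = spec$variables$name[j],
        visit = rep(seq_len(K), each = I),
        value = as.vector(x)
      )
    }
  }
  if (!is.null(spec$categorical)) {
    for (cs in spec$categorical) {
      L <- length(cs$probs)
      pref <- sample.int(L, I, replace = TRUE, prob = cs$probs)
      x <- matrix(NA_real_, I, K)
      for (k in seq_len(K)) {
        stay <- stats::runif(I) < cs$persistence
        x[, k] <- ifelse(stay, pref,
                         sample.int(L, I, replace = TRUE, prob = cs$probs))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rep(patients, K),
        variable = cs$name,
        visit = rep(seq_len(K), each = I),
        value = as.vector(x)
      )
    }
  }
  df <- do.call(rbind, rows)

  if (spec$mcar > 0) {
    df$value[stats::runif(nrow(df)) < spec$mcar] <- NA_real_
  }
  if (!is.null(spec$visit_range)) {
    v_i <- sample(seq.int(spec$visit_range[1], spec$visit_range[2]), I,
                  replace = TRUE)
    names(v_i) <- patients
    df <- df[df$visit <= v_i[df$patient_id], ]
  }
  out <- long_table(df)
  attr(out, "sim_spec") <- spec
  out
}
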