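#' Configuration of the end-to-end synthesis pipeline
#'
#' @param rank decomposition rank R for the values tensor; a vector of
#'   candidates triggers elbow-rule selection ([select_rank()]).
#' @param loss loss name (see [loss_spec()]).
#' @param beta,offset forwarded to [loss_spec()].
#' @param mask_rank rank R' for the Gaussian decomposition of the binary
#'   mask tensor (used only when the input has missing cells).
#' @param sampler `"copula"`, `"seqtree"`, or `"hmc"`.
#' @param n_out number of synthetic patients; defaults to the input count.
#' @param standardize standardize variables before fitting (recommended
#'   with the Gaussian loss).
#' @param nonnegative factor constraint; default follows the loss.
#' @param model_missingness decompose and resynthesize the missingness
#'   pattern when the input has missing cells.
#' @param model_visit_counts `"auto"` adds a visit-count latent column when
#'   patients have unequal visit counts; `TRUE`/`FALSE` force it.
#' @param categorical named list: variable name -> vector of admissible
#'   integer codes, enabling categorical postprocessing for those
#'   variables.
#' @param binarize_threshold threshold turning the reconstructed mask
#'   tensor into 0/1.
#' @param clamp clamp synthetic continuous values to the observed
#'   per-variable range (off by default; synthetic ranges may legitimately
#'   exceed the original).
#' @param copula,seqtree,hmc lists of extra arguments for the chosen
#'   sampler (see [copula_sample()], [seqtree_fit()], [hmc_fit()]).
#' @param max_iterations,restarts optimizer settings (see [gcp_control()]).
#' @param plateau elbow threshold when `rank` is a candidate vector.
#' @param eval_method,eval_bins utility-report settings.
#' @param seed master seed; every stage derives its own stream from it.
#' @param verbose emit per-stage log lines with timings.
#' @export
synthesis_config <- function(rank, loss = "gaussian", beta = 1.5,
                             offset = 1e-10, mask_rank = 4L,
                             sampler = c("copula", "seqtree", "hmc"),
                             n_out = NULL, standardize = TRUE,
                             nonnegative = NULL, model_missingness = TRUE,
                             model_visit_counts = "auto",
                             categorical = NULL, binarize_threshold = 0.5,
                             clamp = FALSE, copula = list(),
                             seqtree = list(), hmc = list(),
                             max_iterations = 500L, restarts = 1L,
                             plateau = 0.01, eval_method = "pearson",
                             eval_bins = 30L, seed = 1L, verbose = FALSE) {
  sampler <- match.arg(sampler)
  stopifnot(all(rank >= 1), mask_rank >= 1,
            is.null(n_out) || n_out >= 1,
            binarize_threshold > 0, binarize_threshold < 1)
  structure(
    list(rank = as.integer(rank), loss = loss, beta = beta, offset = offset,
         mask_rank = as.integer(mask_rank), sampler = sampler,
         n_out = if (is.null(n_out)) NULL else as.integer(n_out),
         standardize = standardize, nonnegative = nonnegative,
         model_missingness = model_missingness,
         model_visit_counts = model_visit_counts, categorical = categorical,
         binarize_threshold = binarize_threshold, clamp = clamp,
         copula = copula, seqtree = seqtree, hmc = hmc,
         max_iterations = as.integer(max_iterations),
         restarts = as.integer(restarts), plateau = plateau,
         eval_method = eval_method, eval_bins = as.integer(eval_bins),
         seed = as.integer(seed), verbose = verbose),
    class = "synthesis_config"
  )
}

#' Binary mask tensor of a long table
#'
#' Encodes, for every (patient, variable, visit) cell, whether a non-empty
#' value exists (1) or not (0), as a [tensor3()] whose *values* are the
#' 0/1 weights (fully observed), ready to be decomposed.
#'
#' @param table a [long_table()].
#' @param n_visits number of visit slices; defaults to the maximum present.
#' @export
build_mask <- function(table, n_visits = NULL) {
  t3 <- as_tensor3(table, n_visits = n_visits)
  tensor3(t3$mask, mask = array(1, dim(t3)), patients = t3$patients,
          variables = t3$variables, visits = t3$visits)
}

#' Regularize irregular visit counts
#'
#' Pads every patient to the panel's maximum visit count `K = max_i v_i`
#' by marking cells beyond a patient's last observed visit as missing, and
#' returns the per-patient visit counts for latent augmentation.
#'
#' @param table a [long_table()].
#' @return A list with `tensor` (the padded [tensor3()]) and
#'   `visit_counts` (named integer vector `v_i`, the last visit with any
#'   observed value per patient).
#' @export
regularize_visits <- function(table) {
  stopifnot(inherits(table, "long_table"))
  obs <- table[!is.na(table$value), ]
  v_i <- tapply(obs$visit, obs$patient_id, max)
  all_pat <- unique(table$patient_id)
  if (length(v_i) < length(all_pat)) {
    bad <- setdiff(all_pat, names(v_i))
    stop("patient(s) with no observed visits: ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  tens <- as_tensor3(table)
  v_i <- as.integer(v_i[tens$patients])
  names(v_i) <- tens$patients
  list(tensor = tens, visit_counts = v_i)
}

#' Round and clip reconstructed categorical codes
#'
#' Rounds values half-up to the nearest integer, clips them into the
#' admissible code range, and snaps any remaining off-set value to the
#' nearest admissible code. Poisson log-link reconstructions must be
#' exponentiated before calling this (done by the pipeline via
#' `log_link`).
#'
#' @param values numeric vector/array of reconstructed codes.
#' @param levels non-empty vector of admissible integer codes.
#' @param log_link exponentiate first (Poisson log-link reconstruction).
#' @export
postprocess_categorical <- function(values, levels, log_link = FALSE) {
  if (!length(levels)) stop("empty level set", call. = FALSE)
  levels <- sort(as.integer(levels))
  v <- values
  if (log_link) v <- exp(v)
  v <- floor(v + 0.5)                   # round half-up
  v <- pmin(pmax(v, min(levels)), max(levels))
  if (!all(v[!is.na(v)] %in% levels)) {
    snap <- function(x) levels[which.min(abs(levels - x))]
    off <- which(!is.na(v) & !(v %in% levels))
    v[off] <- vapply(v[off], snap, numeric(1))
  }
  v
}

#' End-to-end synthesis of longitudinal records
#'
#' Runs the full pipeline: tensorize (padding irregular visits), optionally
#' standardize, fit the GCP decomposition of the values tensor, fit a
#' Gaussian GCP of the binary mask tensor when cells are missing, augment
#' the latent patient table (GCP factors + mask factors + visit counts +
#' baselines), synthesize it with the chosen sampler, reconstruct synthetic
#' values and a synthetic missingness pattern from the sampled factors and
#' the fitted variable/visit factors, truncate each synthetic patient to
#' its synthetic visit count, post-process categorical codes, and emit a
#' long table with fresh `synth-` patient ids along with a utility report
#' against the input.
#'
#' @param x a [long_table()] (or [tensor3()], converted internally).
#' @param config a [synthesis_config()].
#' @param baselines optional per-patient baseline attribute data frame
#'   (rows in patient order); standardized alongside the tensor when the
#'   standardize flag is on, and restored after sampling.
#' @return An object of class `"gcp_synthesis"`: `synthetic` (long table),
#'   `report` ([utility_report()]), the fitted `fit` and `mask_fit`,
#'   `latent` and `sampled` tables, `visit_counts`, `timings`, `config`.
#' @examples
#' \donttest{
#' long <- sim_ehr_like(sim_spec(n_patients = 60, n_visits = 4))
#' out <- synthesize(long, synthesis_config(rank = 4, sampler = "copula",
#'                                          seed = 7))
#' out$report$rmsdc
#' }
#' @export
synthesize <- function(x, config, baselines = NULL) {
  stopifnot(inherits(config, "synthesis_config"))
  if (inherits(x, "tensor3")) x <- as_long_table(x, keep_missing = TRUE)
  stopifnot(inherits(x, "long_table"))
  timings <- c()
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    if (config$verbose) {
      message(sprintf("stage=%s elapsed=%.2fs", name, dt))
    }
    res
  }
  seed <- config$seed

  rv <- log_stage("tensorize", regularize_visits(x))
  tens <- rv$tensor
  v_i <- rv$visit_counts
  K <- dim(tens)[3]
  irregular <- stats::var(v_i) > 0
  use_visits <- isTRUE(config$model_visit_counts) ||
    (identical(config$model_visit_counts, "auto") && irregular)
  has_missing <- any(tens$mask == 0)

  ctrl <- gcp_control(max_iterations = config$max_iterations,
                      restarts = config$restarts)
  spec <- loss_spec(config$loss, beta = config$beta, offset = config$offset)
  fit_args <- list(tens, rank = config$rank, loss = spec,
                   nonnegative = config$nonnegative,
                   standardize = config$standardize, seed = seed,
                   control = ctrl)
  if (length(config$rank) > 1L) fit_args$plateau <- config$plateau
  fit <- log_stage("fit_gcp", do.call(gcp, fit_args))

  mask_fit <- NULL
  if (has_missing && config$model_missingness) {
    mask_fit <- log_stage("fit_mask_gcp", gcp(
      build_mask(x, n_visits = K), rank = config$mask_rank,
      loss = "gaussian", seed = seed + 1L, control = ctrl))
  }

  baseline_scale <- NULL
  if (!is.null(baselines)) {
    baselines <- as.data.frame(baselines)
    if (config$standardize) {
      baseline_scale <- lapply(baselines, function(col) {
        list(center = mean(col), scale = stats::sd(col))
      })
      baselines[] <- lapply(baselines, function(col) {
        (col - mean(col)) / stats::sd(col)
      })
    }
  }
  latent <- log_stage("augment_latent", augment_latent(
    latent_factors(fit),
    mask_factors = if (is.null(mask_fit)) NULL else latent_factors(mask_fit, "w"),
    visit_counts = if (use_visits) v_i else NULL,
    baselines = baselines))

  n_out <- if (is.null(config$n_out)) nrow(latent) else config$n_out
  sampled <- log_stage("sample_latent", switch(config$sampler,
    copula = do.call(copula_sample,
                     c(list(latent = latent, n_out = n_out,
                            seed = seed + 2L), config$copula)),
    seqtree = {
      m <- do.call(seqtree_fit, c(list(latent = latent), config$seqtree))
      seqtree_sample(m, n_out, seed = seed + 2L)
    },
    hmc = {
      post <- do.call(hmc_fit, c(list(latent = latent, seed = seed + 2L),
                                 config$hmc))
      hmc_sample(post, n_out, seed = seed + 3L)
    }))

  blocks <- split_latent(sampled)
  syn <- log_stage("reconstruct", {
    vals <- predict(fit, as.matrix(blocks$gcp_factors), scale = "original")
    mask <- array(1, dim(vals))
    if (!is.null(mask_fit)) {
      w <- predict(mask_fit, as.matrix(blocks$mask_factors))
      mask <- array(as.numeric(w >= config$binarize_threshold), dim(vals))
    }
    if (!is.null(blocks$visit_count)) {
      vhat <- pmin(pmax(floor(blocks$visit_count[[1]] + 0.5), 1L), K)
      for (i in seq_len(nrow(vals))) {
        if (vhat[i] < K) mask[i, , seq.int(vhat[i] + 1L, K)] <- 0
      }
    } else {
      vhat <- rep(K, nrow(vals))
    }
    list(vals = vals, mask = mask, vhat = as.integer(vhat))
  })

  syn_long <- log_stage("postprocess", {
    vals <- syn$vals
    vars <- fit$variables
    if (!is.null(config$categorical)) {
      for (v in names(config$categorical)) {
        j <- match(v, vars)
        if (is.na(j)) stop("categorical variable not in data: ", v,
                           call. = FALSE)
        vals[, j, ] <- postprocess_categorical(
          vals[, j, ], config$categorical[[v]],
          log_link = FALSE)  # log link already applied by predict()
      }
    }
    if (config$clamp) {
      for (j in seq_along(vars)) {
        obs <- x$value[x$variable == vars[j]]
        rng <- range(obs, na.rm = TRUE)
        vals[, j, ] <- pmin(pmax(vals[, j, ], rng[1]), rng[2])
      }
    }
    ids <- sprintf("synth-%06d", seq_len(nrow(vals)))
    out <- tensor3(vals, mask = syn$mask, patients = ids, variables = vars,
                   visits = seq_len(K))
    as_long_table(out)
  })

  report <- log_stage("evaluate", utility_report(
    x, syn_long, method = config$eval_method, bins = config$eval_bins,
    categorical_vars = names(config$categorical), seed = seed,
    config_hash = config_hash(config)))

  structure(
    list(synthetic = syn_long, report = report, fit = fit,
         mask_fit = mask_fit, latent = latent, sampled = sampled,
         visit_counts = list(real = v_i, synthetic = syn$vhat),
         timings = unlist(timings), config = config),
    class = "gcp_synthesis"
  )
}

#' @export
print.gcp_synthesis <- function(x, ...) {
  cat(sprintf("GCP synthesis: %d -> %d patients (%s sampler, rank %d%s)\n",
              x$report$metadata$n_patients_real,
              x$report$metadata$n_patients_synthetic,
              x$config$sampler, x$fit$rank,
              if (!is.null(x$mask_fit))
                sprintf(", mask rank %d", x$mask_fit$rank) else ""))
  cat(sprintf("  fit score %.4f   RMSDC %.4f   median Hellinger %.4f\n",
              x$fit$fit_score, x$report$rmsdc,
              stats::median(x$report$hellinger)))
  invisible(x)
}

# small polynomial rolling hash of the serialized config, for report metadata
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate synthetic records from a fitted GCP model
#'
#' Convenience dense-path synthesis: samples the model's latent patient
#' factors with the chosen method and reconstructs a fully observed
#' synthetic tensor (no mask or visit-count modelling; use [synthesize()]
#' for the full pipeline).
#'
#' @param object a fitted `"gcp"` model.
#' @param nsim number of synthetic patients (default: as fitted).
#' @param seed integer seed.
#' @param method `"copula"`, `"seqtree"`, or `"hmc"`.
#' @param output return a `"tensor3"` or a `"long_table"`.
#' @param ... forwarded to the sampler.
#' @export
simulate.gcp <- function(object, nsim = NULL, seed = 1L,
                         method = c("copula", "seqtree", "hmc"),
                         output = c("long", "tensor"), ...) {
  method <- match.arg(method)
  output <- match.arg(output)
  if (is.null(nsim)) nsim <- nrow(object$A)
  latent <- latent_factors(object)
  sampled <- switch(method,
    copula = copula_sample(latent, nsim, seed = seed, ...),
    seqtree = seqtree_sample(seqtree_fit(latent, ...), nsim, seed = seed),
    hmc = hmc_sample(hmc_fit(latent, seed = seed, ...), nsim,
                     seed = seed + 1L))
  vals <- predict(object, as.matrix(sampled), scale = "original")
  out <- tensor3(vals, mask = array(1, dim(vals)),
                 patients = sprintf("synth-%06d", seq_len(nsim)),
                 variables = object$variables, visits = object$visits)
  if (output == "tensor") out else as_long_table(out)
}
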