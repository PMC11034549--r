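#' Masked generalized CP objective
#'
#' `sum over cells of mask * l(x, m)` where `m` is the Kruskal reconstruction
#' of `model`. Masked cells contribute exactly zero, whatever sentinel they
#' hold.
#'
#' @param x a [tensor3()].
#' @param model a `"kruskal"`/`"gcp"` model with matching dimensions.
#' @param spec a [loss_spec()]; defaults to the model's own loss.
#' @return The scalar objective value.
#' @export
gcp_objective <- function(x, model, spec = model$loss) {
  stopifnot(inherits(x, "tensor3"))
  m <- reconstruct(model)
  check_loss_domain(x, spec)
  xv <- zeroed_values(x)
  if (spec$nonnegative_domain) m[m < 0] <- 0  # masked cells may stray below 0
  le <- loss_eval(spec, xv, m)
  sum(x$mask * le$value)
}

#' Gradient of the masked GCP objective in the factor matrices
#'
#' With `Y[i,j,k] = mask * dl/dm` at each cell, the gradients are
#' `dF/dA = unfold(Y, 1) %*% khatri_rao(C, B) %*% diag(lambda)` and its
#' cyclic analogues.
#'
#' @inheritParams gcp_objective
#' @return A list of matrices `A`, `B`, `C` shaped like the factors.
#' @export
gcp_gradient <- function(x, model, spec = model$loss) {
  stopifnot(inherits(x, "tensor3"))
  m <- reconstruct(model)
  check_loss_domain(x, spec)
  xv <- zeroed_values(x)
  if (spec$nonnegative_domain) m[m < 0] <- 0
  Y <- x$mask * loss_eval(spec, xv, m)$deriv
  grad_from_Y(Y, model)
}

grad_from_Y <- function(Y, model) {
  A <- model$A; B <- model$B; C <- model$C
  lam <- model$lambda
  scale_cols <- function(M) M * rep(lam, each = nrow(M))
  list(
    A = scale_cols(unfold(Y, 1L) %*% khatri_rao(C, B)),
    B = scale_cols(unfold(Y, 2L) %*% khatri_rao(C, A)),
    C = scale_cols(unfold(Y, 3L) %*% khatri_rao(B, A))
  )
}

check_loss_domain <- function(x, spec) {
  if (spec$nonnegative_data) {
    bad <- which(x$mask == 1 & !is.na(x$values) & x$values < 0)
    if (length(bad)) {
      idx <- arrayInd(bad[1], dim(x$values))
      stop(sprintf(
        "loss '%s' requires nonnegative data; observed cell [%d,%d,%d] is negative",
        spec$name, idx[1], idx[2], idx[3]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Optimizer options for [gcp()]
#'
#' @param max_iterations iteration cap for the optimizer.
#' @param gradient_tolerance projected-gradient tolerance (`pgtol` for
#'   L-BFGS-B; gradient-norm stop for Adam).
#' @param init_scale scale of the random initialization; `NULL` picks a
#'   data-driven default `(rms(x)/R)^(1/3)`.
#' @param restarts number of seeded random initializations; the best final
#'   objective wins.
#' @param optimizer `"lbfgs"` (bound-constrained quasi-Newton, default) or
#'   `"adam"` (first-order, with projection onto the nonnegative orthant
#'   when constrained).
#' @param adam_rate,adam_beta1,adam_beta2 Adam hyperparameters.
#' @export
gcp_control <- function(max_iterations = 500L, gradient_tolerance = 1e-8,
                        init_scale = NULL, restarts = 1L,
                        optimizer = c("lbfgs", "adam"),
                        adam_rate = 0.05, adam_beta1 = 0.9,
                        adam_beta2 = 0.999) {
  optimizer <- match.arg(optimizer)
  stopifnot(max_iterations >= 1, gradient_tolerance > 0, restarts >= 1)
  list(max_iterations = as.integer(max_iterations),
       gradient_tolerance = gradient_tolerance, init_scale = init_scale,
       restarts = as.integer(restarts), optimizer = optimizer,
       adam_rate = adam_rate, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2)
}

#' Fit a generalized CP decomposition
#'
#' Minimizes the mask-weighted elementwise loss over the three factor
#' matrices, with the weight vector fixed to 1 (scale is absorbed into the
#' factors). Nonnegativity, when requested or required by the loss, is
#' enforced by constraining every factor entry to the nonnegative orthant.
#' The fit is deterministic given `seed`.
#'
#' @param x a [tensor3()] (or a long table, which is tensorized first).
#' @param rank the number of components R (>= 1). A vector of candidates is
#'   forwarded to [select_rank()].
#' @param loss loss name or [loss_spec()].
#' @param nonnegative constrain all factors to be nonnegative. Defaults to
#'   `TRUE` for losses whose model domain requires it.
#' @param standardize standardize each variable to observed mean 0 / sd 1
#'   before fitting; the transform is stored on the result and undone by
#'   `fitted(, scale = "original")`.
#' @param seed integer seed for the initialization(s).
#' @param control a [gcp_control()] list.
#' @param init optional warm start: a list with matrices `A`, `B`, `C`.
#' @param ... passed to [loss_spec()] (`beta`, `offset`) when `loss` is a
#'   name, or to [select_rank()] when `rank` is a candidate vector.
#' @return An object of class `c("gcp", "kruskal")` with the fitted factors,
#'   final `objective`, `fit_score`, convergence info, and (optionally) the
#'   standardization transform. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `simulate`.
#' @examples
#' sim <- sim_lowrank(10, 4, 6, rank = 2, noise_sd = 0, seed = 1)
#' fit <- gcp(sim$tensor, rank = 2, seed = 1)
#' fit$fit_score
#' @export
gcp <- function(x, rank, loss = "gaussian", nonnegative = NULL,
                standardize = FALSE, seed = 1L, control = gcp_control(),
                init = NULL, ...) {
  if (inherits(x, "long_table")) x <- as_tensor3(x)
  stopifnot(inherits(x, "tensor3"))
  if (length(rank) > 1L) {
    sel <- select_rank(x, candidates = rank, loss = loss,
                       nonnegative = nonnegative, standardize = standardize,
                       seed = seed, control = control, ...)
    return(sel$fit)
  }
  rank <- as.integer(rank)
  stopifnot(rank >= 1)
  spec <- if (inherits(loss, "loss_spec")) loss else loss_spec(loss, ...)
  if (is.null(nonnegative)) nonnegative <- spec$nonnegative_domain
  if (spec$nonnegative_domain && !nonnegative) {
    stop(sprintf("loss '%s' requires nonnegative = TRUE", spec$name),
         call. = FALSE)
  }
  check_loss_domain(x, spec)

  transform <- NULL
  if (standardize) {
    st <- standardize_tensor(x)
    x_fit <- st$tensor
    transform <- st$transform
  } else {
    x_fit <- x
  }

  d <- dim(x_fit)
  xv <- zeroed_values(x_fit)
  w <- x_fit$mask
  n_obs <- sum(w)
  if (n_obs == 0) stop("tensor has no observed entries", call. = FALSE)

  iscale <- control$init_scale
  if (is.null(iscale)) {
    rms <- sqrt(sum(w * xv^2) / n_obs)
    iscale <- max((max(rms, 1e-3) / rank)^(1/3), 1e-3)
  }

  sizes <- c(d[1], d[2], d[3]) * rank
  unpack <- function(par) {
    list(A = matrix(par[seq_len(sizes[1])], d[1], rank),
         B = matrix(par[sizes[1] + seq_len(sizes[2])], d[2], rank),
         C = matrix(par[sizes[1] + sizes[2] + seq_len(sizes[3])], d[3], rank))
  }
  krC <- function(fac) khatri_rao(fac$C, fac$B)
  fn <- function(par) {
    fac <- unpack(par)
    m <- fold(fac$A %*% t(krC(fac)), 1L, d)
    if (spec$nonnegative_domain) m[m < 0] <- 0
    val <- sum(w * loss_eval(spec, xv, m)$value)
    if (!is.finite(val)) .Machine$double.xmax else val
  }
  gr <- function(par) {
    fac <- unpack(par)
    m <- fold(fac$A %*% t(krC(fac)), 1L, d)
    if (spec$nonnegative_domain) m[m < 0] <- 0
    Y <- w * loss_eval(spec, xv, m)$deriv
    g <- grad_from_Y(Y, list(A = fac$A, B = fac$B, C = fac$C,
                             lambda = rep(1, rank)))
    c(g$A, g$B, g$C)
  }

  best <- NULL
  for (r in seq_len(control$restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    if (!is.null(init) && r == 1L) {
      par0 <- c(init$A, init$B, init$C)
      if (length(par0) != sum(sizes)) stop("`init` has wrong shapes", call. = FALSE)
      if (nonnegative) par0 <- pmax(par0, 0)
    } else if (nonnegative) {
      par0 <- stats::runif(sum(sizes), 0, iscale)
    } else {
      par0 <- stats::rnorm(sum(sizes), 0, iscale)
    }
    res <- if (control$optimizer == "lbfgs") {
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   lower = if (nonnegative) 0 else -Inf,
                   control = list(maxit = control$max_iterations,
                                  factr = 1e4,
                                  pgtol = control$gradient_tolerance))
    } else {
      adam_minimize(par0, fn, gr, nonnegative = nonnegative,
                    control = control)
    }
    if (!is.finite(res$value)) {
      stop("non-finite objective during optimization (restart ", r, ")",
           call. = FALSE)
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- r
    }
  }

  fac <- unpack(best$par)
  rownames(fac$A) <- x$patients
  rownames(fac$B) <- x$variables
  rownames(fac$C) <- paste0("visit", x$visits)
  model <- kruskal(fac$A, fac$B, fac$C, lambda = rep(1, rank), loss = spec,
                   nonnegative = nonnegative)
  model$objective <- best$value
  model$fit_score <- fit_score(x_fit, reconstruct(model))
  model$convergence <- best$convergence
  model$counts <- best$counts
  model$seed <- as.integer(seed)
  model$restart_used <- best$restart
  model$standardization <- transform
  model$dims <- d
  model$patients <- x$patients
  model$variables <- x$variables
  model$visits <- x$visits
  model$n_observed <- n_obs
  model$call <- match.call()
  class(model) <- c("gcp", "kruskal")
  model
}

adam_minimize <- function(par, fn, gr, nonnegative, control) {
  m <- v <- numeric(length(par))
  b1 <- control$adam_beta1; b2 <- control$adam_beta2
  rate <- control$adam_rate
  n_eval <- 0L
  for (t in seq_len(control$max_iterations)) {
    g <- gr(par)
    n_eval <- n_eval + 1L
    if (sqrt(sum(g^2)) < control$gradient_tolerance) break
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    par <- par - rate * mh / (sqrt(vh) + 1e-8)
    if (nonnegative) par <- pmax(par, 0)  # projection onto the orthant
  }
  list(par = par, value = fn(par), convergence = 0L,
       counts = c(`function` = n_eval, gradient = n_eval))
}

#' Rescale a fitted model so every factor column has unit norm
#'
#' Populates `lambda` with the product of the column norms; off by default in
#' fitting, where scale is absorbed into the factors.
#'
#' @param model a `"kruskal"` or `"gcp"` model.
#' @export
gcp_normalize <- function(model) {
  stopifnot(inherits(model, "kruskal"))
  nrm <- function(M) sqrt(colSums(M^2))
  na <- nrm(model$A); nb <- nrm(model$B); nc <- nrm(model$C)
  if (any(c(na, nb, nc) == 0)) stop("zero factor column; cannot normalize",
                                    call. = FALSE)
  model$A <- sweep(model$A, 2, na, "/")
  model$B <- sweep(model$B, 2, nb, "/")
  model$C <- sweep(model$C, 2, nc, "/")
  model$lambda <- model$lambda * na * nb * nc
  model
}

# ---- methods ---------------------------------------------------------------

#' @export
print.gcp <- function(x, ...) {
  cat(sprintf("Generalized CP decomposition (rank %d, %s loss%s)\n",
              x$rank, x$loss$name, if (x$nonnegative) ", nonnegative" else ""))
  cat(sprintf("  tensor: %d patients x %d variables x %d visits (%d observed cells)\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_observed))
  cat(sprintf("  objective: %.6g   fit score: %.4f\n", x$objective, x$fit_score))
  if (!is.null(x$standardization)) cat("  fitted on standardized variables\n")
  invisible(x)
}

#' @export
summary.gcp <- function(object, ...) {
  colnorm <- function(M) sqrt(colSums(M^2))
  comp <- data.frame(
    component = seq_len(object$rank),
    lambda = object$lambda,
    patient_norm = colnorm(object$A),
    variable_norm = colnorm(object$B),
    visit_norm = colnorm(object$C)
  )
  structure(list(model = object, components = comp), class = "summary.gcp")
}

#' @export
print.summary.gcp <- function(x, ...) {
  print(x$model)
  cat("\nComponent scales:\n")
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.gcp <- function(object, mode = c("patients", "variables", "visits"), ...) {
  mode <- match.arg(mode)
  switch(mode, patients = object$A, variables = object$B, visits = object$C)
}

#' Reconstruction of a fitted GCP model
#'
#' @param object a fitted `"gcp"` model.
#' @param scale `"model"` returns the reconstruction on the scale the model
#'   was fitted on; `"original"` undoes any standardization (and exponentiates
#'   Poisson log-link fits).
#' @param ... unused.
#' @export
fitted.gcp <- function(object, scale = c("model", "original"), ...) {
  scale <- match.arg(scale)
  m <- reconstruct(object)
  if (scale == "original") {
    if (object$loss$name == "poisson_log") m <- exp(m)
    if (!is.null(object$standardization)) {
      m <- destandardize_tensor(m, object$standardization)
    }
  }
  m
}

#' @export
residuals.gcp <- function(object, x = NULL, ...) {
  if (is.null(x)) stop("supply the tensor the model was fitted to", call. = FALSE)
  if (!is.null(object$standardization)) x <- standardize_tensor(x)$tensor
  r <- x$values - reconstruct(object)
  r[x$mask == 0] <- NA
  r
}

#' Reconstruct values for new patient factor rows
#'
#' Keeps the fitted variable and visit factors and rebuilds the tensor for a
#' new patient factor matrix, e.g. one drawn by a latent sampler.
#'
#' @param object a fitted `"gcp"` model.
#' @param newfactors matrix (or `latent_table`) with `rank` columns, one row
#'   per (synthetic) patient.
#' @param scale as in [fitted.gcp()].
#' @param ... unused.
#' @return A 3-way array `nrow(newfactors)` x variables x visits.
#' @export
predict.gcp <- function(object, newfactors = NULL,
                        scale = c("model", "original"), ...) {
  scale <- match.arg(scale)
  if (is.null(newfactors)) return(fitted(object, scale = scale))
  Ahat <- as.matrix(newfactors)
  if (ncol(Ahat) != object$rank) {
    stop("`newfactors` must have `rank` columns", call. = FALSE)
  }
  tmp <- object
  tmp$A <- Ahat
  m <- reconstruct(tmp)
  if (scale == "original") {
    if (object$loss$name == "poisson_log") m <- exp(m)
    if (!is.null(object$standardization)) {
      m <- destandardize_tensor(m, object$standardization)
    }
  }
  m
}
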