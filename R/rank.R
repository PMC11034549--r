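#' Choose the decomposition rank by an elbow rule
#'
#' Fits every candidate rank (warm-starting each fit from the previous one,
#' padded with a small random column) and returns the smallest rank beyond
#' which the relative improvement in the objective plateaus: the first
#' candidate whose improvement to the next candidate is below
#' `plateau` as a fraction of the total improvement accumulated since the
#' first candidate.
#'
#' @inheritParams gcp
#' @param candidates strictly increasing integer ranks, all within the
#'   admissible bound `min(I*J, I*K, J*K)`.
#' @param plateau relative-improvement threshold (default 1%).
#' @param warm_start reuse the previous candidate's factors (padded) as the
#'   next initialization, which makes the objective sequence non-increasing
#'   up to optimizer tolerance.
#' @return An object of class `"rank_selection"`: a list with `rank` (the
#'   chosen value), `fit` (the fitted model at that rank), and `diagnostics`
#'   (a data frame of objective, fit score, and observed-cell mean squared
#'   error per candidate). Methods: `print`, `plot`.
#' @export
select_rank <- function(x, candidates, loss = "gaussian", nonnegative = NULL,
                        standardize = FALSE, seed = 1L,
                        control = gcp_control(), plateau = 0.01,
                        warm_start = TRUE, ...) {
  if (inherits(x, "long_table")) x <- as_tensor3(x)
  stopifnot(inherits(x, "tensor3"))
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  if (any(diff(candidates) <= 0)) {
    stop("candidate ranks must be strictly increasing", call. = FALSE)
  }
  d <- dim(x)
  bound <- min(d[1] * d[2], d[1] * d[3], d[2] * d[3])
  if (any(candidates > bound)) {
    stop(sprintf("candidate ranks must be <= min(IJ, IK, JK) = %d", bound),
         call. = FALSE)
  }
  stopifnot(plateau > 0)

  fits <- vector("list", length(candidates))
  init <- NULL
  for (t in seq_along(candidates)) {
    fits[[t]] <- gcp(x, rank = candidates[t], loss = loss,
                     nonnegative = nonnegative, standardize = standardize,
                     seed = seed, control = control, init = init, ...)
    if (warm_start && t < length(candidates)) {
      f <- fits[[t]]
      extra <- candidates[t + 1L] - candidates[t]
      set.seed(as.integer(seed) + 1000L + t)
      pad <- function(M, n) cbind(M, matrix(stats::rnorm(n * extra, 0, 1e-3),
                                            n, extra))
      init <- list(A = pad(f$A, d[1]), B = pad(f$B, d[2]), C = pad(f$C, d[3]))
    }
  }

  obj <- vapply(fits, function(f) f$objective, numeric(1))
  fsc <- vapply(fits, function(f) f$fit_score, numeric(1))
  mse <- vapply(fits, function(f) {
    xs <- if (standardize) standardize_tensor(x)$tensor else x
    sum(xs$mask * (zeroed_values(xs) - reconstruct(f))^2) / sum(xs$mask)
  }, numeric(1))
  diagnostics <- data.frame(rank = candidates, objective = obj,
                            fit_score = fsc, mse = mse)

  chosen <- length(candidates)
  if (length(candidates) > 1L) {
    eps <- .Machine$double.eps * max(abs(obj), 1)
    for (t in seq_len(length(candidates) - 1L)) {
      gain <- obj[t] - obj[t + 1L]
      total <- obj[1L] - obj[t + 1L]
      if (gain / max(total, eps) < plateau) { chosen <- t; break }
    }
  }

  structure(
    list(rank = candidates[chosen], fit = fits[[chosen]],
         diagnostics = diagnostics, plateau = plateau),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("Rank selection (elbow rule, plateau %.3g): chose R = %d\n",
              x$plateau, x$rank))
  print(x$diagnostics, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.rank_selection <- function(x, ...) {
  d <- x$diagnostics
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(d$rank, d$objective, type = "b", xlab = "rank",
                 ylab = "objective", main = "GCP objective", ...)
  graphics::abline(v = x$rank, lty = 2)
  graphics::plot(d$rank, d$fit_score, type = "b", xlab = "rank",
                 ylab = "fit score", main = "Fit score", ...)
  graphics::abline(v = x$rank, lty = 2)
  invisible(x)
}
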