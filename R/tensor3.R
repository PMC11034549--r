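#' Three-way tensor with an observation mask
#'
#' Container for a dense patients x variables x visits array paired with a
#' binary mask marking which cells were observed. Masked cells may hold any
#' sentinel value (conventionally `NA`); no objective, metric, or transform in
#' this package ever reads them.
#'
#' @param values numeric 3-way array (patients x variables x visits).
#' @param mask array of the same shape with entries in \{0, 1\} (1 = observed).
#'   Defaults to "observed wherever `values` is not `NA`".
#' @param patients,variables,visits axis labels. Patients and variables are
#'   character vectors; visits are positive integers. Defaults are generated.
#' @return An object of class `"tensor3"`: a list with elements `values`,
#'   `mask`, `patients`, `variables`, `visits`.
#' @examples
#' x <- tensor3(array(rnorm(24), c(2, 3, 4)))
#' dim(x)
#' @export
tensor3 <- function(values, mask = NULL, patients = NULL, variables = NULL,
                    visits = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-way array", call. = FALSE)
  }
  d <- dim(values)
  if (is.null(mask)) {
    mask <- array(as.numeric(!is.na(values)), d)
  }
  if (!is.array(mask) || !identical(dim(mask), d)) {
    stop("`mask` must have the same shape as `values`", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("`mask` entries must be exactly 0 or 1", call. = FALSE)
  }
  if (any(mask == 1 & is.na(values))) {
    stop("observed cells (mask = 1) must not be NA", call. = FALSE)
  }
  if (is.null(patients)) patients <- sprintf("p%03d", seq_len(d[1]))
  if (is.null(variables)) variables <- sprintf("v%02d", seq_len(d[2]))
  if (is.null(visits)) visits <- seq_len(d[3])
  visits <- as.integer(visits)
  if (length(patients) != d[1] || length(variables) != d[2] ||
      length(visits) != d[3]) {
    stop("axis label lengths must match the tensor dimensions", call. = FALSE)
  }
  if (any(visits < 1L)) stop("visit indices must be >= 1", call. = FALSE)
  structure(
    list(values = values, mask = mask, patients = as.character(patients),
         variables = as.character(variables), visits = visits),
    class = "tensor3"
  )
}

#' @export
dim.tensor3 <- function(x) dim(x$values)

#' @export
print.tensor3 <- function(x, ...) {
  d <- dim(x)
  obs <- mean(x$mask)
  cat(sprintf("<tensor3> %d patients x %d variables x %d visits (%.1f%% observed)\n",
              d[1], d[2], d[3], 100 * obs))
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

# values with masked cells replaced by 0 so they can never propagate NA/NaN
zeroed_values <- function(x) {
  v <- x$values
  v[x$mask == 0] <- 0
  v
}

#' Mode-n matricization of a 3-way array
#'
#' Unfolds a 3-way array into a matrix along the given mode. The column
#' ordering follows the convention in which earlier remaining modes vary
#' fastest, so that the mode-1 unfolding of a Kruskal tensor equals
#' `A %*% diag(lambda) %*% t(khatri_rao(C, B))` (and cyclically for
#' modes 2 and 3).
#'
#' @param a 3-way array (or a `tensor3`, whose values are used).
#' @param mode 1, 2 or 3.
#' @return A matrix with `dim(a)[mode]` rows.
#' @seealso [fold()], [khatri_rao()]
#' @export
unfold <- function(a, mode) {
  if (inherits(a, "tensor3")) a <- a$values
  stopifnot(is.array(a), length(dim(a)) == 3L)
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3", call. = FALSE)
  d <- dim(a)
  switch(mode,
    `1` = { dim(a) <- c(d[1], d[2] * d[3]); a },
    `2` = { a <- aperm(a, c(2L, 1L, 3L)); dim(a) <- c(d[2], d[1] * d[3]); a },
    `3` = { a <- aperm(a, c(3L, 1L, 2L)); dim(a) <- c(d[3], d[1] * d[2]); a }
  )
}

#' Fold a matricized array back into a 3-way array
#'
#' Inverse of [unfold()]: `fold(unfold(a, m), m, dim(a))` returns `a`.
#'
#' @param m matrix produced by [unfold()].
#' @param mode the mode it was unfolded along.
#' @param dims the target 3-way dimensions.
#' @export
fold <- function(m, mode, dims) {
  stopifnot(length(dims) == 3L, is.matrix(m))
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3", call. = FALSE)
  switch(mode,
    `1` = { dim(m) <- dims; m },
    `2` = { dim(m) <- c(dims[2], dims[1], dims[3]); aperm(m, c(2L, 1L, 3L)) },
    `3` = { dim(m) <- c(dims[3], dims[1], dims[2]); aperm(m, c(2L, 3L, 1L)) }
  )
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' @param m1,m2 matrices with the same number of columns.
#' @return A matrix with `nrow(m1) * nrow(m2)` rows; column r is
#'   `kronecker(m1[, r], m2[, r])`, i.e. the row index of `m2` varies fastest.
#' @export
khatri_rao <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (ncol(m1) != ncol(m2)) {
    stop("`m1` and `m2` must share their column count", call. = FALSE)
  }
  n1 <- nrow(m1); n2 <- nrow(m2)
  m1[rep(seq_len(n1), each = n2), , drop = FALSE] *
    m2[rep.int(seq_len(n2), n1), , drop = FALSE]
}

#' Kruskal model container
#'
#' A rank-R factorization lambda, A (patients x R), B (variables x R),
#' C (visits x R). [gcp()] returns a subclass of this with fitting metadata.
#'
#' @param A,B,C factor matrices sharing the column count R.
#' @param lambda positive weights of length R (default all 1).
#' @param loss a [loss_spec()] or loss name recording the loss the factors
#'   were fitted under.
#' @param nonnegative logical constraint flag.
#' @return An object of class `"kruskal"`.
#' @export
kruskal <- function(A, B, C, lambda = NULL, loss = "gaussian",
                    nonnegative = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  R <- ncol(A)
  if (ncol(B) != R || ncol(C) != R) {
    stop("factor matrices must share their column count", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- rep(1, R)
  if (length(lambda) != R) stop("length(lambda) must equal the rank", call. = FALSE)
  if (any(lambda <= 0)) stop("lambda entries must be positive", call. = FALSE)
  if (nonnegative && (min(A) < 0 || min(B) < 0 || min(C) < 0)) {
    stop("nonnegative model has negative factor entries", call. = FALSE)
  }
  if (is.character(loss)) loss <- loss_spec(loss)
  structure(
    list(lambda = lambda, A = A, B = B, C = C, rank = R, loss = loss,
         nonnegative = nonnegative),
    class = "kruskal"
  )
}

#' Reconstruct the full tensor of a Kruskal model
#'
#' Computes `m[i, j, k] = sum_r lambda_r A[i, r] B[j, r] C[k, r]`.
#'
#' @param model a `"kruskal"` (or `"gcp"`) object.
#' @return The dense 3-way reconstruction array.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "kruskal"))
  A <- model$A; B <- model$B; C <- model$C
  R <- model$rank
  Al <- A * rep(model$lambda, each = nrow(A))
  fold(Al %*% t(khatri_rao(C, B)), 1L, c(nrow(A), nrow(B), nrow(C)))
}

#' Fit score of a reconstruction
#'
#' The standard CP fit, `1 - ||W * (X - M)||_F / ||W * X||_F`, computed over
#' observed entries only. 1 is a perfect fit; the score is unbounded below.
#'
#' @param x a `tensor3` (its mask weights the residual).
#' @param m reconstruction array (or `kruskal` model, which is reconstructed).
#' @export
fit_score <- function(x, m) {
  stopifnot(inherits(x, "tensor3"))
  if (inherits(m, "kruskal")) m <- reconstruct(m)
  if (!identical(dim(m), dim(x$values))) stop("shape mismatch", call. = FALSE)
  xv <- zeroed_values(x)
  denom <- sqrt(sum(x$mask * xv^2))
  if (denom == 0) stop("fit score undefined: all observed entries are zero",
                       call. = FALSE)
  1 - sqrt(sum(x$mask * (xv - m)^2)) / denom
}

#' Per-variable standardization of a tensor
#'
#' Centers and scales each variable slice to observed-entry mean 0 and sample
#' standard deviation 1 (n - 1 denominator). The mask is passed through
#' unchanged and masked entries never influence the statistics.
#'
#' @param x a `tensor3`; every variable needs >= 2 observed entries and
#'   nonzero variance.
#' @return A list with elements `tensor` (the standardized `tensor3`) and
#'   `transform` (class `"standardization"`, with per-variable `center` and
#'   `scale`), which [destandardize_tensor()] inverts.
#' @export
standardize_tensor <- function(x) {
  stopifnot(inherits(x, "tensor3"))
  J <- dim(x)[2]
  center <- scale <- numeric(J)
  v <- x$values
  for (j in seq_len(J)) {
    obs <- x$values[, j, ][x$mask[, j, ] == 1]
    if (length(obs) < 2L || stats::sd(obs) == 0) {
      stop(sprintf("variable '%s' is degenerate (constant or < 2 observations)",
                   x$variables[j]), call. = FALSE)
    }
    center[j] <- mean(obs)
    scale[j] <- stats::sd(obs)
    v[, j, ] <- (v[, j, ] - center[j]) / scale[j]
  }
  transform <- structure(
    list(center = center, scale = scale, variables = x$variables),
    class = "standardization"
  )
  out <- x
  out$values <- v
  list(tensor = out, transform = transform)
}

#' @rdname standardize_tensor
#' @param transform a `"standardization"` transform.
#' @export
destandardize_tensor <- function(x, transform) {
  stopifnot(inherits(transform, "standardization"))
  arr <- if (inherits(x, "tensor3")) x$values else x
  J <- dim(arr)[2]
  if (J != length(transform$center)) stop("variable count mismatch", call. = FALSE)
  for (j in seq_len(J)) {
    arr[, j, ] <- arr[, j, ] * transform$scale[j] + transform$center[j]
  }
  if (inherits(x, "tensor3")) { x$values <- arr; x } else arr
}
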