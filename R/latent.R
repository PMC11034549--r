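#' Latent patient table
#'
#' Per-patient rows over named real-valued latent columns: GCP patient
#' factors, optionally mask factors, a visit-count column, and baseline
#' attributes. This is the object every sampler consumes and produces.
#' Latent tables are complete (no missing cells).
#'
#' @param x data frame or matrix of latent values (rows = patients).
#' @param kinds optional character vector, one per column, in
#'   `c("continuous", "count", "categorical")`; defaults to all continuous.
#' @param loss name of the GCP loss that produced the factors (provenance
#'   used by [hmc_fit()], which by default accepts only Gaussian-loss
#'   factors); `NA` for tables of unknown origin.
#' @return A data frame of class `"latent_table"` with attributes `kinds`
#'   and `loss`.
#' @export
latent_table <- function(x, kinds = NULL, loss = NA_character_) {
  df <- as.data.frame(x)
  if (!nrow(df) || !ncol(df)) stop("latent table must be non-empty", call. = FALSE)
  if (anyNA(df)) stop("latent tables must have no missing cells", call. = FALSE)
  if (anyDuplicated(names(df))) stop("latent column names must be unique",
                                     call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("latent columns must be numeric", call. = FALSE)
  }
  if (is.null(kinds)) kinds <- rep("continuous", ncol(df))
  if (length(kinds) != ncol(df) ||
      !all(kinds %in% c("continuous", "count", "categorical"))) {
    stop("`kinds` must name one of continuous/count/categorical per column",
         call. = FALSE)
  }
  structure(df, kinds = kinds, loss = loss,
            class = c("latent_table", "data.frame"))
}

#' Extract the latent patient factor table of a fitted model
#'
#' @param fit a fitted `"gcp"` model.
#' @param prefix column-name prefix (columns are `prefix1..prefixR`).
#' @export
latent_factors <- function(fit, prefix = "f") {
  stopifnot(inherits(fit, "gcp"))
  A <- fit$A
  colnames(A) <- paste0(prefix, seq_len(ncol(A)))
  latent_table(A, loss = fit$loss$name)
}

#' Augment the patient factor table with mask factors, visit counts, and
#' baseline attributes
#'
#' Column-wise concatenation with block tags; [split_latent()] is its exact
#' inverse.
#'
#' @param gcp_factors `latent_table` of GCP patient factors.
#' @param mask_factors optional `latent_table` of mask-tensor patient factors.
#' @param visit_counts optional numeric vector of per-patient visit counts.
#' @param baselines optional data frame of per-patient baseline attributes.
#' @return A `latent_table` with an additional `blocks` attribute naming the
#'   column indices of each block, and class `"augmented_latent"`.
#' @export
augment_latent <- function(gcp_factors, mask_factors = NULL,
                           visit_counts = NULL, baselines = NULL) {
  stopifnot(inherits(gcp_factors, "latent_table"))
  n <- nrow(gcp_factors)
  parts <- list(gcp_factors = as.data.frame(gcp_factors))
  kinds <- attr(gcp_factors, "kinds")
  if (!is.null(mask_factors)) {
    if (nrow(mask_factors) != n) stop("mask factor row count mismatch", call. = FALSE)
    mf <- as.data.frame(mask_factors)
    names(mf) <- paste0("w", seq_len(ncol(mf)))
    parts$mask_factors <- mf
    kinds <- c(kinds, rep("continuous", ncol(mf)))
  }
  if (!is.null(visit_counts)) {
    if (length(visit_counts) != n) stop("visit count length mismatch", call. = FALSE)
    parts$visit_count <- data.frame(n_visits = as.numeric(visit_counts))
    kinds <- c(kinds, "count")
  }
  if (!is.null(baselines)) {
    if (nrow(baselines) != n) stop("baseline row count mismatch", call. = FALSE)
    parts$baselines <- as.data.frame(baselines)
    kinds <- c(kinds, rep("continuous", ncol(baselines)))
  }
  df <- do.call(cbind, unname(parts))
  sizes <- vapply(parts, ncol, integer(1))
  ends <- cumsum(sizes)
  blocks <- Map(function(e, s) seq.int(e - s + 1L, e), ends, sizes)
  out <- latent_table(df, kinds = kinds, loss = attr(gcp_factors, "loss"))
  attr(out, "blocks") <- blocks
  class(out) <- c("augmented_latent", class(out))
  out
}

#' @rdname augment_latent
#' @param x an `"augmented_latent"` table (block tags are preserved by all
#'   samplers).
#' @return For `split_latent`, a named list of data frames, one per block.
#' @export
split_latent <- function(x) {
  blocks <- attr(x, "blocks")
  if (is.null(blocks)) stop("`x` carries no block tags", call. = FALSE)
  lapply(blocks, function(idx) as.data.frame(x)[, idx, drop = FALSE])
}

#' @export
print.latent_table <- function(x, ...) {
  cat(sprintf("<latent_table> %d patients x %d latent columns (loss: %s)\n",
              nrow(x), ncol(x), attr(x, "loss")))
  blocks <- attr(x, "blocks")
  if (!is.null(blocks)) {
    cat("blocks:", paste(sprintf("%s[%d]", names(blocks),
                                 lengths(blocks)), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 4L), digits = 4)
  if (nrow(x) > 4L) cat("... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

# rebuild a latent_table like `template` around new values
relabel_latent <- function(values, template) {
  df <- as.data.frame(values)
  names(df) <- names(template)
  out <- latent_table(df, kinds = attr(template, "kinds"),
                      loss = attr(template, "loss"))
  if (!is.null(attr(template, "blocks"))) {
    attr(out, "blocks") <- attr(template, "blocks")
    class(out) <- unique(c("augmented_latent", class(out)))
  }
  out
}
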