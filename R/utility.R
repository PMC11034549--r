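#' Hellinger distance between two samples
#'
#' Continuous samples are binned on shared equal-width bins spanning the
#' pooled range and the binned version
#' `H = sqrt(1 - sum_b sqrt(p_b q_b))` is returned; categorical samples use
#' category frequencies over the union of levels. H lies in [0, 1]: 0 for
#' identical distributions, 1 for disjoint supports.
#'
#' @param x,y non-empty numeric samples (`NA`s dropped).
#' @param bins number of shared bins for continuous samples (>= 2).
#' @param categorical treat the values as category codes.
#' @export
hellinger <- function(x, y, bins = 30L, categorical = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (categorical) {
    lev <- sort(unique(c(x, y)))
    p <- tabulate(match(x, lev), length(lev)) / length(x)
    q <- tabulate(match(y, lev), length(lev)) / length(y)
  } else {
    stopifnot(bins >= 2)
    rng <- range(c(x, y))
    if (diff(rng) == 0) return(0)
    br <- seq(rng[1], rng[2], length.out = bins + 1L)
    p <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), bins) / length(x)
    q <- tabulate(findInterval(y, br, rightmost.closed = TRUE,
                               all.inside = TRUE), bins) / length(y)
  }
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

#' Correlation matrix over variable-visit columns
#'
#' Widens the long table to a patients x (variable, visit) matrix and
#' computes pairwise correlations on pairwise-complete observations.
#' Columns with fewer than `min_obs` observed values, or with zero
#' variance, are excluded with a warning.
#'
#' @param table a [long_table()].
#' @param method `"pearson"` (default) or `"kendall"`.
#' @param min_obs minimum observed values per column.
#' @return A symmetric correlation matrix with `variable.v<visit>` labels.
#' @export
correlation_matrix <- function(table, method = c("pearson", "kendall"),
                               min_obs = 3L) {
  stopifnot(inherits(table, "long_table"))
  method <- match.arg(method)
  W <- widen_long(table)
  if (nrow(W) < 3L) stop("need >= 3 patients", call. = FALSE)
  nobs <- colSums(!is.na(W))
  sds <- apply(W, 2, stats::sd, na.rm = TRUE)
  drop <- nobs < min_obs | is.na(sds) | sds == 0
  if (any(drop)) {
    warning("excluding ", sum(drop),
            " column(s) with too few observations or zero variance")
    W <- W[, !drop, drop = FALSE]
  }
  if (ncol(W) < 2L) stop("fewer than 2 usable columns", call. = FALSE)
  suppressWarnings(stats::cor(W, use = "pairwise.complete.obs",
                              method = method))
}

widen_long <- function(table) {
  patients <- sort(unique(table$patient_id))
  cols <- unique(table[c("variable", "visit")])
  cols <- cols[order(cols$variable, cols$visit), ]
  W <- matrix(NA_real_, length(patients), nrow(cols),
              dimnames = list(patients,
                              paste0(cols$variable, ".v", cols$visit)))
  j <- match(paste0(table$variable, ".v", table$visit), colnames(W))
  W[cbind(match(table$patient_id, patients), j)] <- table$value
  W
}

#' Root mean square difference of correlations (RMSDC)
#'
#' Root mean square of the strict upper-triangle differences between the
#' real and synthetic correlation matrices; lower is better capture of the
#' dependency structure. `NA` entries (insufficient pairwise data) are
#' excluded.
#'
#' @param c_real,c_syn symmetric correlation matrices of the same shape.
#' @export
rmsdc <- function(c_real, c_syn) {
  check_corr_pair(c_real, c_syn)
  d <- (c_real - c_syn)[upper.tri(c_real)]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no comparable correlation pairs", call. = FALSE)
  sqrt(mean(d^2))
}

#' @rdname rmsdc
#' @return For `abs_corr_diffs`, the flat vector of absolute
#'   upper-triangle differences (the box-plot source).
#' @export
abs_corr_diffs <- function(c_real, c_syn) {
  check_corr_pair(c_real, c_syn)
  d <- abs(c_real - c_syn)[upper.tri(c_real)]
  d[!is.na(d)]
}

check_corr_pair <- function(c_real, c_syn) {
  if (!is.matrix(c_real) || !identical(dim(c_real), dim(c_syn))) {
    stop("correlation matrices must be matrices of the same shape",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-variable descriptive summary of a long table
#'
#' Minimum, quartiles, median, mean, standard deviation, maximum, and the
#' number of missing cells per variable, pooling values across visits.
#' Missing counts are taken against the full patients x visits grid of the
#' table (absent rows count as missing), matching how missingness is
#' reported for longitudinal panels.
#'
#' @param table a [long_table()].
#' @export
descriptive_summary <- function(table) {
  stopifnot(inherits(table, "long_table"))
  if (!nrow(table)) stop("empty table", call. = FALSE)
  n_pat <- length(unique(table$patient_id))
  K <- max(table$visit)
  vars <- sort(unique(table$variable))
  out <- lapply(vars, function(v) {
    x <- table$value[table$variable == v]
    obs <- x[!is.na(x)]
    q <- stats::quantile(obs, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(variable = v, n = length(obs),
               missing = n_pat * K - length(obs),
               min = min(obs), q1 = q[1], median = q[2], q3 = q[3],
               mean = mean(obs), sd = stats::sd(obs), max = max(obs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Utility report: real versus synthetic longitudinal data
#'
#' The utility assessment bundle: per-variable Hellinger distances (values
#' pooled across visits), the vector of absolute pairwise correlation
#' differences over variable-visit columns, RMSDC, per-variable descriptive
#' summaries of both tables, and overall missing fractions.
#'
#' @param real,synthetic [long_table()]s over the same variables.
#' @param method correlation method, `"pearson"` or `"kendall"`.
#' @param bins Hellinger bins for continuous variables.
#' @param categorical_vars character vector of variables to treat as
#'   categorical in the Hellinger computation.
#' @param seed,config_hash optional metadata recorded in the report.
#' @return An object of class `"utility_report"`.
#' @export
utility_report <- function(real, synthetic, method = "pearson", bins = 30L,
                           categorical_vars = NULL, seed = NA_integer_,
                           config_hash = NA_character_) {
  stopifnot(inherits(real, "long_table"), inherits(synthetic, "long_table"))
  vars <- sort(unique(real$variable))
  if (!setequal(vars, unique(synthetic$variable))) {
    stop("real and synthetic tables must share their variables", call. = FALSE)
  }
  hell <- vapply(vars, function(v) {
    hellinger(real$value[real$variable == v],
              synthetic$value[synthetic$variable == v],
              bins = bins, categorical = v %in% categorical_vars)
  }, numeric(1))

  cr <- correlation_matrix(real, method = method)
  cs <- correlation_matrix(synthetic, method = method)
  common <- intersect(colnames(cr), colnames(cs))
  if (length(common) < 2L) stop("fewer than 2 shared correlation columns",
                                call. = FALSE)
  cr <- cr[common, common]; cs <- cs[common, common]

  miss_frac <- function(tb) {
    n_cells <- length(unique(tb$patient_id)) * length(unique(tb$variable)) *
      max(tb$visit)
    1 - sum(!is.na(tb$value)) / n_cells
  }

  structure(
    list(
      hellinger = hell,
      abs_corr_diffs = abs_corr_diffs(cr, cs),
      rmsdc = rmsdc(cr, cs),
      summary_real = descriptive_summary(real),
      summary_synthetic = descriptive_summary(synthetic),
      missing_fraction_real = miss_frac(real),
      missing_fraction_synthetic = miss_frac(synthetic),
      metadata = list(
        n_patients_real = length(unique(real$patient_id)),
        n_patients_synthetic = length(unique(synthetic$patient_id)),
        method = method, bins = as.integer(bins),
        categorical_vars = categorical_vars,
        seed = seed, config_hash = config_hash)
    ),
    class = "utility_report"
  )
}

#' @export
print.utility_report <- function(x, ...) {
  cat("Utility report: real vs synthetic\n")
  cat(sprintf("  patients: %d real / %d synthetic   correlations: %s\n",
              x$metadata$n_patients_real, x$metadata$n_patients_synthetic,
              x$metadata$method))
  cat(sprintf("  RMSDC: %.4f   median |corr diff|: %.4f (n = %d)\n",
              x$rmsdc, stats::median(x$abs_corr_diffs),
              length(x$abs_corr_diffs)))
  cat("  Hellinger distances:\n")
  for (v in names(x$hellinger)) {
    cat(sprintf("    %-16s %.4f\n", v, x$hellinger[[v]]))
  }
  cat(sprintf("  missing fraction: %.3f real / %.3f synthetic\n",
              x$missing_fraction_real, x$missing_fraction_synthetic))
  invisible(x)
}

#' @export
plot.utility_report <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::boxplot(x$abs_corr_diffs, main = "|corr(real) - corr(syn)|",
                    ylab = "absolute difference", ...)
  graphics::boxplot(x$hellinger, main = "Hellinger distance",
                    ylab = "distance", ...)
  invisible(x)
}

#' Serialize / restore a utility report as JSON
#'
#' Numeric values are written at full precision so that the round trip is
#' lossless.
#'
#' @param report a [utility_report()].
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "utility_report"))
  report <- unclass(report)
  report$hellinger <- as.list(report$hellinger)  # keep variable names in JSON
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$hellinger <- unlist(obj$hellinger)
  obj$summary_real <- as.data.frame(obj$summary_real)
  obj$summary_synthetic <- as.data.frame(obj$summary_synthetic)
  obj$metadata$seed <- if (is.null(obj$metadata$seed)) NA_integer_ else
    obj$metadata$seed
  structure(obj, class = "utility_report")
}
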