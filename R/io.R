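#' Long-format longitudinal records
#'
#' Tidy representation of a longitudinal panel: one row per (patient,
#' variable, visit) cell, with `NA` in `value` marking an observed-grid cell
#' whose measurement is missing. Cells absent from the table entirely (e.g.
#' visits beyond an irregular patient's last visit) are also treated as
#' unobserved when tensorizing.
#'
#' @param df data frame with columns `patient_id`, `variable`, `visit`,
#'   `value`.
#' @return A data frame of class `"long_table"`, sorted by (patient,
#'   variable, visit).
#' @export
long_table <- function(df) {
  need <- c("patient_id", "variable", "visit", "value")
  if (!all(need %in% names(df))) {
    stop("long table needs columns patient_id, variable, visit, value",
         call. = FALSE)
  }
  df <- df[need]
  df$patient_id <- as.character(df$patient_id)
  df$variable <- as.character(df$variable)
  df$visit <- as.integer(df$visit)
  df$value <- as.numeric(df$value)
  if (anyNA(df$visit) || any(df$visit < 1L)) {
    stop("visit indices must be positive integers", call. = FALSE)
  }
  key <- paste(df$patient_id, df$variable, df$visit, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (patient, variable, visit) records: ",
         paste(utils::head(gsub("\r", "/", dup), 3L), collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$patient_id, df$variable, df$visit), ]
  rownames(df) <- NULL
  class(df) <- c("long_table", "data.frame")
  df
}

#' @export
print.long_table <- function(x, ...) {
  cat(sprintf("<long_table> %d records, %d patients, %d variables, visits 1..%d (%d missing values)\n",
              nrow(x), length(unique(x$patient_id)),
              length(unique(x$variable)), max(x$visit), sum(is.na(x$value))))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read / write long-format CSV
#'
#' The file format is UTF-8 CSV with the exact header
#' `patient_id,variable,visit,value`; an empty `value` field denotes a
#' missing cell. Values are written with 17 significant digits so that
#' write/read round-trips are exact.
#'
#' @param path file path.
#' @return `read_long_csv` returns a [long_table()].
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(header, "patient_id,variable,visit,value")) {
    stop("line 1: header must be exactly 'patient_id,variable,visit,value'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character")
  visit <- suppressWarnings(as.integer(df$visit))
  bad <- which(is.na(visit) | visit < 1L | df$visit != as.character(visit))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": visit must be a positive integer, got '",
         df$visit[bad[1]], "'", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(df$value != "" & is.na(value))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": value must be numeric or empty, got '",
         df$value[bad[1]], "'", call. = FALSE)
  }
  long_table(data.frame(patient_id = df$patient_id, variable = df$variable,
                        visit = visit, value = value))
}

#' @rdname read_long_csv
#' @param table a [long_table()].
#' @export
write_long_csv <- function(table, path) {
  stopifnot(inherits(table, "long_table"))
  value <- ifelse(is.na(table$value), "",
                  sprintf("%.17g", table$value))
  lines <- c("patient_id,variable,visit,value",
             paste(table$patient_id, table$variable, table$visit, value,
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Tensorize a long table
#'
#' Builds the dense values tensor and its binary observation mask. A cell
#' is observed (mask 1) iff a non-`NA` value exists for it; cells that are
#' `NA`-valued or absent from the table get mask 0.
#'
#' @param table a [long_table()].
#' @param n_visits number of visit slices K; defaults to the largest visit
#'   index present.
#' @return A [tensor3()].
#' @export
as_tensor3 <- function(table, n_visits = NULL) {
  stopifnot(inherits(table, "long_table"))
  patients <- sort(unique(table$patient_id))
  variables <- sort(unique(table$variable))
  K <- if (is.null(n_visits)) max(table$visit) else as.integer(n_visits)
  if (any(table$visit > K)) stop("visit index exceeds n_visits", call. = FALSE)
  vals <- array(NA_real_, c(length(patients), length(variables), K))
  idx <- cbind(match(table$patient_id, patients),
               match(table$variable, variables),
               table$visit)
  vals[idx] <- table$value
  tensor3(vals, patients = patients, variables = variables,
          visits = seq_len(K))
}

#' Flatten a tensor back to a long table
#'
#' Emits one row per observed cell; masked cells are dropped (set
#' `keep_missing = TRUE` to keep them as `NA`-valued rows instead).
#'
#' @param x a [tensor3()].
#' @param keep_missing keep masked cells as explicit `NA` rows.
#' @param visit_limits optional named per-patient visit counts; cells beyond
#'   a patient's count are dropped even when `keep_missing = TRUE`.
#' @export
as_long_table <- function(x, keep_missing = FALSE, visit_limits = NULL) {
  stopifnot(inherits(x, "tensor3"))
  d <- dim(x)
  df <- data.frame(
    patient_id = rep(x$patients, times = d[2] * d[3]),
    variable = rep(rep(x$variables, each = d[1]), times = d[3]),
    visit = rep(x$visits, each = d[1] * d[2]),
    value = as.vector(x$values)
  )
  obs <- as.vector(x$mask) == 1
  df$value[!obs] <- NA_real_
  if (!keep_missing) df <- df[obs, ]
  if (!is.null(visit_limits)) {
    df <- df[df$visit <= visit_limits[df$patient_id], ]
  }
  long_table(df)
}

# ---- model serialization ---------------------------------------------------

#' Save / load a fitted GCP model as a directory of delimited text files
#'
#' Writes `A.tsv`, `B.tsv`, `C.tsv` (tab-separated, 17 significant digits,
#' labelled rows) and a `metadata.json` with the rank, loss, weights, axis
#' labels, and any standardization transform.
#'
#' @param model a fitted `"gcp"` model.
#' @param path directory to create.
#' @export
write_gcp <- function(model, path) {
  stopifnot(inherits(model, "gcp"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, file) {
    df <- data.frame(label = rownames(M),
                     apply(M, 2, function(cc) sprintf("%.17g", cc)))
    names(df) <- c("label", paste0("r", seq_len(ncol(M))))
    utils::write.table(df, file.path(path, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wm(model$A, "A.tsv"); wm(model$B, "B.tsv"); wm(model$C, "C.tsv")
  meta <- list(
    rank = model$rank,
    loss = list(name = model$loss$name, beta = model$loss$beta,
                offset = model$loss$offset),
    lambda = model$lambda,
    nonnegative = model$nonnegative,
    objective = model$objective,
    fit_score = model$fit_score,
    seed = model$seed,
    patients = model$patients,
    variables = model$variables,
    visits = model$visits,
    standardization = if (is.null(model$standardization)) NULL else
      list(center = model$standardization$center,
           scale = model$standardization$scale,
           variables = model$standardization$variables)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gcp
#' @export
read_gcp <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  rm_ <- function(file) {
    df <- utils::read.table(file.path(path, file), sep = "\t", header = TRUE,
                            colClasses = "character")
    M <- apply(as.matrix(df[, -1, drop = FALSE]), 2, as.numeric)
    M <- matrix(M, nrow = nrow(df))
    rownames(M) <- df$label
    M
  }
  spec <- loss_spec(meta$loss$name, beta = meta$loss$beta,
                    offset = meta$loss$offset)
  model <- kruskal(rm_("A.tsv"), rm_("B.tsv"), rm_("C.tsv"),
                   lambda = meta$lambda, loss = spec,
                   nonnegative = meta$nonnegative)
  model$objective <- meta$objective
  model$fit_score <- meta$fit_score
  model$seed <- meta$seed
  model$patients <- meta$patients
  model$variables <- meta$variables
  model$visits <- as.integer(meta$visits)
  model$dims <- c(nrow(model$A), nrow(model$B), nrow(model$C))
  model$n_observed <- NA_integer_
  if (!is.null(meta$standardization)) {
    model$standardization <- structure(
      list(center = meta$standardization$center,
           scale = meta$standardization$scale,
           variables = meta$standardization$variables),
      class = "standardization")
  }
  class(model) <- c("gcp", "kruskal")
  model
}
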