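#' Sequential decision-tree synthesis: fitting
#'
#' Fits the sequential synthesis chain of R - 1 regression trees: model j
#' predicts latent column j from columns 1..j-1, in the table's column
#' order. Sampling ([seqtree_sample()]) bootstraps the first column and then
#' walks each fitted tree, drawing uniformly from the training values in the
#' terminal node reached by the already-synthesized columns, so every
#' synthetic value is one observed in that column's training data.
#'
#' @param latent a [latent_table()] with at least 2 rows.
#' @param min_leaf minimum terminal-node size (default 5).
#' @param cp rpart complexity parameter; the small default lets trees grow
#'   until the leaf-size floor binds.
#' @param max_depth depth cap (rpart's maximum, 30, i.e. effectively none).
#' @return An object of class `"seqtree_model"`.
#' @export
seqtree_fit <- function(latent, min_leaf = 5L, cp = 1e-4, max_depth = 30L) {
  stopifnot(inherits(latent, "latent_table"))
  if (nrow(latent) < 2L) {
    stop("sequential synthesis needs >= 2 rows", call. = FALSE)
  }
  df <- as.data.frame(latent)
  orig_names <- names(df)
  names(df) <- paste0("V", seq_along(df))  # syntactically safe
  R <- ncol(df)
  models <- vector("list", max(R - 1L, 0L))
  ctrl <- rpart::rpart.control(minbucket = min_leaf, cp = cp,
                               maxdepth = max_depth, xval = 0L,
                               maxcompete = 0L, maxsurrogate = 0L)
  for (j in seq_len(R)[-1]) {
    form <- stats::as.formula(paste(names(df)[j], "~",
                                    paste(names(df)[seq_len(j - 1L)],
                                          collapse = " + ")))
    fit <- rpart::rpart(form, data = df, method = "anova", control = ctrl)
    # training values per terminal node, for leaf resampling
    leaf_values <- split(df[[j]], fit$where)
    models[[j - 1L]] <- list(tree = fit, leaf_values = leaf_values)
  }
  structure(
    list(models = models, first = df[[1L]], template = latent,
         names = orig_names, min_leaf = min_leaf, cp = cp,
         max_depth = max_depth),
    class = "seqtree_model"
  )
}

#' @export
print.seqtree_model <- function(x, ...) {
  cat(sprintf("<seqtree_model> %d sequential tree(s) over %d latent columns (n = %d)\n",
              length(x$models), length(x$names), length(x$first)))
  invisible(x)
}

#' Sequential decision-tree synthesis: sampling
#'
#' @param model a [seqtree_fit()] result.
#' @param n_out number of synthetic rows.
#' @param seed integer seed; the draw is deterministic given it.
#' @return A `latent_table` of `n_out` rows matching the training table's
#'   columns.
#' @export
seqtree_sample <- function(model, n_out, seed = 1L) {
  stopifnot(inherits(model, "seqtree_model"))
  n_out <- as.integer(n_out)
  stopifnot(n_out >= 1)
  set.seed(as.integer(seed))
  R <- length(model$names)
  syn <- matrix(NA_real_, n_out, R)
  syn[, 1L] <- sample(model$first, n_out, replace = TRUE)
  for (j in seq_len(R)[-1]) {
    mj <- model$models[[j - 1L]]
    newdata <- as.data.frame(syn[, seq_len(j - 1L), drop = FALSE])
    names(newdata) <- paste0("V", seq_len(j - 1L))
    nodes <- predict_leaf(mj$tree, newdata)
    for (node in unique(nodes)) {
      idx <- which(nodes == node)
      pool <- mj$leaf_values[[as.character(node)]]
      syn[idx, j] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
  }
  relabel_latent(syn, model$template)
}

# Terminal-node (row of fit$frame) reached by each new observation. rpart's
# anova predict returns the leaf's fitted mean, so temporarily replacing the
# leaf values with frame row indices makes predict() return the node itself.
predict_leaf <- function(fit, newdata) {
  fit$frame$yval <- seq_len(nrow(fit$frame))
  as.integer(stats::predict(fit, newdata = newdata))
}
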