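# Affinity-regression metrics: MSE, RMSE, concordance index, rm2 index,
# Spearman correlation, plus the per-threshold sweep report.

#' Concordance index
#'
#' Fraction of concordant pairs among all pairs with distinct true values:
#' a pair (i, j) with `y_i > y_j` scores 1 if `yhat_i > yhat_j`, 1/2 if the
#' predictions tie, 0 otherwise. Invariant under strictly monotone
#' transforms of the predictions.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return a value in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    input_error("concordance_index: lengths differ")
  }
  dy <- outer(y_true, y_true, ">")
  if (!any(dy)) {
    domain_error("concordance_index: all true values are equal (no ordered pairs)")
  }
  dp <- outer(y_pred, y_pred, "-")
  sum(dy * ((dp > 0) + 0.5 * (dp == 0))) / sum(dy)
}

#' rm2 index
#'
#' External-validation metric `r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r` is
#' the Pearson correlation of predictions and observations (with intercept)
#' and `r0^2` the coefficient of determination of the least-squares fit of
#' the observations on the predictions through the origin. Equals `r^2` when
#' the two agree, and never exceeds `r^2`.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 3 points,
#'   non-constant).
#' @return a real value.
#' @export
rm2_index <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) input_error("rm2_index: lengths differ")
  if (length(y_true) < 3) domain_error("rm2_index: need at least 3 points")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    domain_error("rm2_index: constant input vector")
  }
  r2 <- stats::cor(y_true, y_pred)^2
  k <- sum(y_true * y_pred) / sum(y_pred^2)
  r02 <- 1 - sum((y_true - k * y_pred)^2) / sum((y_true - mean(y_true))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Affinity-regression metrics report
#'
#' Computes MSE, RMSE, concordance index, rm2 index and Spearman correlation
#' over a set of (true, predicted) affinities. Pairs with missing truth are
#' excluded.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param metadata named list recorded in the report (dataset name, delta,
#'   k, seed, ...).
#' @return an object of class `dta_metrics`.
#' @export
dta_metrics <- function(y_true, y_pred, metadata = list()) {
  keep <- !is.na(y_true) & !is.na(y_pred)
  y_true <- as.numeric(y_true[keep]); y_pred <- as.numeric(y_pred[keep])
  if (length(y_true) < 2) input_error("dta_metrics: need at least 2 labeled pairs")
  mse <- mean((y_true - y_pred)^2)
  structure(list(
    mse = mse, rmse = sqrt(mse),
    ci = concordance_index(y_true, y_pred),
    rm2 = rm2_index(y_true, y_pred),
    spearman = stats::cor(y_true, y_pred, method = "spearman"),
    n_pairs = length(y_true), metadata = metadata
  ), class = "dta_metrics")
}

#' @export
print.dta_metrics <- function(x, ...) {
  cat(format_metrics(x), sep = "\n")
  invisible(x)
}

format_metrics <- function(x) {
  c(sprintf("  %-10s %10.6f", "MSE", x$mse),
    sprintf("  %-10s %10.6f", "RMSE", x$rmse),
    sprintf("  %-10s %10.6f", "CI", x$ci),
    sprintf("  %-10s %10.6f", "rm2", x$rm2),
    sprintf("  %-10s %10.6f", "Spearman", x$spearman),
    sprintf("  %-10s %10d", "n_pairs", x$n_pairs))
}

#' Evaluate a fitted model on a data split
#'
#' @param fit a fitted [sisdta()] model.
#' @param split `"test"` (default), `"train"` or `"all"` labeled pairs.
#' @return a [dta_metrics()] report.
#' @export
evaluate_fit <- function(fit, split = c("test", "train", "all")) {
  stopifnot(inherits(fit, "sisdta"))
  split <- match.arg(split)
  idx <- switch(split,
                test = fit$test_index,
                train = fit$train_index,
                all = seq_len(nrow(fit$pairs)))
  if (length(idx) == 0) input_error("no %s pairs available", split)
  pairs <- fit$pairs[idx, ]
  y_hat <- predict(fit, pairs = pairs)
  dta_metrics(pairs$y, y_hat, metadata = c(
    fit$config[c("similarity", "delta", "k", "seed")], list(split = split)))
}

#' Metrics across a range of similarity thresholds
#'
#' Retrains the model once per threshold (shared seed and folds) and reports
#' the held-out metrics per threshold.
#'
#' @param data a [dta_dataset()] with a test split.
#' @param deltas numeric vector of thresholds to try.
#' @param ... further arguments to [sisdta()].
#' @param seed seed shared by every run.
#' @return data.frame with one row per threshold: `threshold`, `mse`,
#'   `rmse`, `ci`, `rm2`, `spearman`, `n_pairs`.
#' @export
threshold_sweep <- function(data, deltas, ..., seed = 1) {
  if (length(deltas) < 1) config_error("threshold_sweep: need at least one delta")
  rows <- lapply(deltas, function(d) {
    fit <- sisdta(data, delta = d, seed = seed, ...)
    m <- evaluate_fit(fit, split = if (length(fit$test_index) > 0) "test" else "train")
    data.frame(threshold = d, mse = m$mse, rmse = m$rmse, ci = m$ci,
               rm2 = m$rm2, spearman = m$spearman, n_pairs = m$n_pairs)
  })
  do.call(rbind, rows)
}

#' Write a metrics report / sweep table
#'
#' Reports serialize as JSON (and pretty text via `print`); sweep tables as
#' CSV with the threshold, MSE, CI and rm2 columns first.
#'
#' @param x a `dta_metrics` report or a [threshold_sweep()] data.frame.
#' @param path output file.
#' @export
write_metrics <- function(x, path) {
  if (inherits(x, "dta_metrics")) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    first <- intersect(c("threshold", "mse", "ci", "rm2"), names(x))
    x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
    utils::write.table(x, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::fromJSON(path)
    x$metadata <- as.list(x$metadata)
    structure(x, class = "dta_metrics")
  } else {
    utils::read.csv(path)
  }
}
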