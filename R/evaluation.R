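#' Split a dataset into training and test sets
#'
#' Uniform random partition without replacement: the test set holds
#' `round(n * test_fraction)` rows (at least 1), the training set the rest.
#' Reproducible for a fixed seed.
#'
#' @param ds a [fitness_dataset()] with at least 5 subjects.
#' @param test_fraction fraction of rows held out, in (0, 0.5]; default 0.2,
#'   the study's 80/20 protocol.
#' @param seed integer RNG seed.
#' @return A list with `train`, `test` (datasets) and `train_indices`,
#'   `test_indices`.
#' @export
split_dataset <- function(ds, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(ds, "fitness_dataset"))
  stopifnot_scalar_in(test_fraction, "test_fraction", 0, 0.5, open_lo = TRUE)
  n <- nrow(ds$X)
  if (n < 5L) stop("need at least 5 subjects to split", call. = FALSE)
  n_test <- max(1L, as.integer(round(n * test_fraction)))
  test_idx <- sort(with_seed(derive_seed(seed, "split"), sample.int(n, n_test)))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = ds[train_idx], test = ds[test_idx],
       train_indices = train_idx, test_indices = test_idx)
}

#' Prediction accuracy of a response matrix
#'
#' Default metric `"mare"`: per-response accuracy is
#' `100 * (1 - mean_i |yhat - y| / y)` — one hundred minus the mean absolute
#' relative error in percent — floored at 0; overall accuracy is the mean
#' over responses. Alternatives: `"nrmse"` (100 * (1 - RMSE / sd(y))) and
#' `"r2"` (coefficient of determination * 100), both floored at 0.
#'
#' @param Y observed k x p matrix, strictly positive.
#' @param Y_hat predicted k x p matrix.
#' @param metric one of `"mare"`, `"nrmse"`, `"r2"`.
#' @return A list with `per_response` (percent, length p) and `overall`.
#' @export
prediction_accuracy <- function(Y, Y_hat, metric = c("mare", "nrmse", "r2")) {
  metric <- match.arg(metric)
  Y <- as_matrix(Y, "Y"); Y_hat <- as_matrix(Y_hat, "Y_hat")
  if (!all(dim(Y) == dim(Y_hat))) stop("Y and Y_hat shapes differ", call. = FALSE)
  if (any(Y <= 0)) stop("observed responses must be strictly positive", call. = FALSE)
  per <- vapply(seq_len(ncol(Y)), function(k) {
    y <- Y[, k]; yh <- Y_hat[, k]
    switch(metric,
           mare = 100 * (1 - mean(abs(yh - y) / y)),
           nrmse = 100 * (1 - sqrt(mean((yh - y)^2)) / stats::sd(y)),
           r2 = 100 * (1 - sum((yh - y)^2) / sum((y - mean(y))^2)))
  }, numeric(1))
  per <- pmax(per, 0)
  names(per) <- colnames(Y)
  list(per_response = per, overall = mean(per))
}

# Leave-one-out predictions for every row: the fold for row i is fit without
# row i, so its prediction never sees that row's response.
loo_predictions <- function(X, Y, h) {
  n <- nrow(X)
  Y_hat <- matrix(NA_real_, n, ncol(Y), dimnames = list(NULL, colnames(Y)))
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], h = h)
    Y_hat[i, ] <- predict(fit, X[i, , drop = FALSE])
  }
  Y_hat
}

#' Leave-one-out evaluation report
#'
#' Assembles leave-one-out predictions for the training rows into a full
#' prediction matrix and scores them with [prediction_accuracy()]; when a
#' test fraction is given, additionally splits the data, runs leave-one-out
#' on the training portion only, refits on the full training portion and
#' scores the held-out rows. With `test_fraction = NULL` leave-one-out runs
#' over every subject and no split is made.
#'
#' @param ds a [fitness_dataset()].
#' @param h component count for every fit.
#' @param test_fraction held-out fraction (default 0.2) or `NULL` for no
#'   split.
#' @param seed split RNG seed.
#' @param metric accuracy metric, see [prediction_accuracy()].
#' @return An object of class `evaluation_report`: indices, per-response and
#'   overall training (leave-one-out) and test accuracies, the leave-one-out
#'   prediction matrix, and the metric name.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' loo_report(ds, h = 2, seed = 1)
#' @export
loo_report <- function(ds, h, test_fraction = 0.2, seed = 1,
                       metric = c("mare", "nrmse", "r2")) {
  stopifnot(inherits(ds, "fitness_dataset"))
  metric <- match.arg(metric)
  n <- nrow(ds$X)
  if (is.null(test_fraction)) {
    Y_hat <- loo_predictions(ds$X, ds$Y, h)
    acc <- prediction_accuracy(ds$Y, Y_hat, metric)
    rep <- list(train_indices = seq_len(n), test_indices = integer(0),
                train_per_response = acc$per_response,
                train_overall = acc$overall,
                test_per_response = NULL, test_overall = NA_real_,
                loo_predictions = Y_hat, h = h, metric = metric, seed = NA_integer_)
  } else {
    sp <- split_dataset(ds, test_fraction, seed)
    Y_hat <- loo_predictions(sp$train$X, sp$train$Y, h)
    acc_tr <- prediction_accuracy(sp$train$Y, Y_hat, metric)
    fit <- fit_plsr(sp$train, h = h)
    acc_te <- prediction_accuracy(sp$test$Y, predict(fit, sp$test), metric)
    rep <- list(train_indices = sp$train_indices, test_indices = sp$test_indices,
                train_per_response = acc_tr$per_response,
                train_overall = acc_tr$overall,
                test_per_response = acc_te$per_response,
                test_overall = acc_te$overall,
                loo_predictions = Y_hat, h = h, metric = metric,
                seed = as.integer(seed))
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> metric=%s, h=%d\n", x$metric, x$h))
  cat(sprintf("  training (leave-one-out, n=%d): overall %.2f%%\n",
              length(x$train_indices), x$train_overall))
  if (length(x$test_indices) > 0L) {
    cat(sprintf("  test (held-out, n=%d): overall %.2f%%\n",
                length(x$test_indices), x$test_overall))
  }
  invisible(x)
}
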