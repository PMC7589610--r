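#' Leave-one-out PRESS for an h-component model
#'
#' For every row i, fits an h-component PLS model on the remaining n-1 rows
#' (centering and scaling re-estimated inside each fold, so no information
#' leaks from the held-out row) and accumulates the squared prediction error
#' of row i per response. Errors are measured on a standardized response
#' scale — by default the full-data response standard deviations — so that
#' responses with larger raw variance do not dominate the total.
#'
#' @param X a [fitness_dataset()] or n x m predictor matrix.
#' @param Y n x p response matrix (ignored when `X` is a dataset).
#' @param h component count; needs `h <= min(n - 2, m)`.
#' @param y_scale optional length-p scale divisors; `NULL` uses the full-data
#'   response standard deviations; `1` gives raw-scale PRESS.
#' @return A list with `press_j` (per-response) and `press` (total).
#' @export
compute_press <- function(X, Y = NULL, h, y_scale = NULL) {
  if (inherits(X, "fitness_dataset")) { Y <- X$Y; X <- X$X }
  X <- as_matrix(X, "X"); Y <- as_matrix(Y, "Y")
  n <- nrow(X); p <- ncol(Y)
  if (h > min(n - 2L, ncol(X))) {
    stop(sprintf("h=%d too large for leave-one-out with n=%d", h, n), call. = FALSE)
  }
  if (is.null(y_scale)) y_scale <- apply(Y, 2, stats::sd)
  y_scale <- rep_len(y_scale, p)
  press_j <- numeric(p)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_plsr(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], h = h),
      error = function(e) {
        stop(sprintf("leave-one-out fold %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    err <- (predict(fit, X[i, , drop = FALSE]) - Y[i, , drop = FALSE]) / y_scale
    press_j <- press_j + drop(err)^2
  }
  list(press_j = press_j, press = sum(press_j))
}

#' In-sample residual sum of squares for an h-component model
#'
#' Residual sum of squares of the h-component fit on all rows, on the same
#' standardized response scale as [compute_press()]. `h = 0` is the
#' baseline: deviations of each response from its mean, which on the
#' standardized scale equals `n - 1` per response.
#'
#' @inheritParams compute_press
#' @param h component count, `0` allowed.
#' @return A list with `ss_j` (per-response) and `ss` (total).
#' @export
compute_ss <- function(X, Y = NULL, h, y_scale = NULL) {
  if (inherits(X, "fitness_dataset")) { Y <- X$Y; X <- X$X }
  X <- as_matrix(X, "X"); Y <- as_matrix(Y, "Y")
  p <- ncol(Y)
  if (is.null(y_scale)) y_scale <- apply(Y, 2, stats::sd)
  y_scale <- rep_len(y_scale, p)
  if (h == 0L) {
    res <- sweep(Y, 2, colMeans(Y), "-")
  } else {
    fit <- fit_plsr(X, Y, h = h)
    res <- Y - fit$fitted
  }
  res <- sweep(res, 2, y_scale, "/")
  ss_j <- colSums(res^2)
  list(ss_j = as.numeric(ss_j), ss = sum(ss_j))
}

#' Cross-validity statistic Q-squared
#'
#' `Q2_h = 1 - PRESS(h) / SS(h-1)`. A component is conventionally worth
#' retaining while Q2 is at least `1 - 0.95^2 = 0.0975`.
#'
#' @param press_h leave-one-out PRESS of the h-component model.
#' @param ss_prev in-sample residual sum of squares of the (h-1)-component
#'   model; must be positive.
#' @return The Q-squared value.
#' @export
q_squared <- function(press_h, ss_prev) {
  if (!is.numeric(ss_prev) || length(ss_prev) != 1L || ss_prev <= 0) {
    stop("ss_prev must be a positive scalar", call. = FALSE)
  }
  1 - press_h / ss_prev
}

#' Q-squared retention threshold
#'
#' The conventional cross-validity limit `1 - 0.95^2 = 0.0975`.
#' @return 0.0975, computed from the 0.95 convention.
#' @export
q2_threshold <- function() 1 - 0.95^2

#' Choose the number of PLS components by cross-validity
#'
#' Extracts components in order; component h is retained while
#' `Q2_h >= threshold` and extraction stops at the first violation.
#' Extraction also stops when the response block is already explained
#' (residual SS numerically zero) or no further component can be extracted.
#' At least one component is always returned so downstream stages have a
#' model; when even the first component fails the threshold the result is
#' flagged non-significant.
#'
#' @inheritParams compute_press
#' @param h_max maximum components to consider, capped at `min(n - 2, m)`.
#' @param threshold retention threshold, default [q2_threshold()] = 0.0975.
#' @param y_scale optional response scale divisors passed through.
#' @return An object of class `cv_selection`: `h` (retained count), `table`
#'   (a data frame with columns `h`, `press`, `ss`, `q2`, `retained`),
#'   `significant` (whether the first component met the threshold).
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' sel <- select_components(ds, h_max = 4)
#' sel$table
#' @export
select_components <- function(X, Y = NULL, h_max = NULL,
                              threshold = q2_threshold(), y_scale = NULL) {
  if (inherits(X, "fitness_dataset")) { Y <- X$Y; X <- X$X }
  X <- as_matrix(X, "X"); Y <- as_matrix(Y, "Y")
  n <- nrow(X); m <- ncol(X)
  cap <- min(n - 2L, m)
  if (is.null(h_max)) h_max <- cap
  h_max <- min(as.integer(h_max), cap)
  if (h_max < 1L) stop("not enough rows for leave-one-out selection", call. = FALSE)
  if (is.null(y_scale)) y_scale <- apply(Y, 2, stats::sd)

  ss0 <- compute_ss(X, Y, 0L, y_scale = y_scale)$ss
  rows <- list()
  ss_prev <- ss0
  stopped <- FALSE
  for (h in seq_len(h_max)) {
    if (ss_prev <= 1e-10 * ss0) break  # responses already fully explained
    pr <- tryCatch(compute_press(X, Y, h, y_scale = y_scale),
                   error = function(e) e)
    if (inherits(pr, "error")) {
      if (h == 1L) stop(pr)
      break
    }
    ss_h <- compute_ss(X, Y, h, y_scale = y_scale)$ss
    q2 <- q_squared(pr$press, ss_prev)
    retained <- !stopped && q2 >= threshold
    rows[[h]] <- data.frame(h = h, press = pr$press, ss = ss_h,
                            q2 = q2, retained = retained)
    if (!retained) { stopped <- TRUE; break }
    ss_prev <- ss_h
  }
  table <- do.call(rbind, rows)
  h_sel <- sum(table$retained)
  significant <- h_sel >= 1L
  if (h_sel == 0L) h_sel <- 1L  # minimum-model convention
  structure(list(h = h_sel, table = table, significant = significant,
                 threshold = threshold),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection> retained h=%d (threshold %.4f%s)\n", x$h,
              x$threshold,
              if (x$significant) "" else "; first component non-significant"))
  print(x$table, row.names = FALSE)
  invisible(x)
}
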