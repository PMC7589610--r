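#' Build the one-at-a-time perturbation grid
#'
#' Eight levels per predictor at `x_min + c * x_dif` for
#' `c = -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2`, i.e. from 20% of the range
#' below the observed minimum to 20% above the observed maximum. The levels
#' at `c = 0` and `c = 1` equal the observed minimum and maximum.
#'
#' @param summary a [predictor_summary()].
#' @return An object of class `perturbation_grid` with `coefficients`
#'   (length 8) and `levels` (8 x m matrix, predictor units).
#' @examples
#' build_grid(reference_predictor_summary())
#' @export
build_grid <- function(summary) {
  stopifnot(inherits(summary, "predictor_summary"))
  coefficients <- c(-0.2, 0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  levels <- outer(coefficients, summary$x_dif) +
    matrix(summary$x_min, 8L, length(summary$x_min), byrow = TRUE)
  dimnames(levels) <- list(sprintf("c=%+.1f", coefficients), summary$x_names)
  structure(list(coefficients = coefficients, levels = levels,
                 x_names = summary$x_names),
            class = "perturbation_grid")
}

#' @export
print.perturbation_grid <- function(x, ...) {
  cat("<perturbation_grid> levels (x_min + c * x_dif):\n")
  print(x$levels, ...)
  invisible(x)
}

#' Predicted response curves under one-at-a-time perturbation
#'
#' For each predictor in turn, steps that predictor across its grid levels
#' while every other predictor sits at its cohort mean, and predicts all
#' responses from the fitted model. The grid's outermost levels (c = -0.2
#' and c = 1.2) extrapolate beyond the observed range; a notice is emitted
#' rather than refusing.
#'
#' @param model a fitted `pls_model` (see [fit_plsr()]).
#' @param summary a [predictor_summary()] consistent with the model's
#'   predictor ordering.
#' @param grid a [build_grid()] result; defaults to `build_grid(summary)`.
#' @param quiet suppress the extrapolation notice.
#' @return An object of class `sensitivity_curves`: a list of 8 x p
#'   prediction matrices, one per predictor, with the all-means prediction
#'   attached as `baseline`.
#' @export
perturb_predict <- function(model, summary, grid = build_grid(summary),
                            quiet = FALSE) {
  stopifnot(inherits(model, "pls_model"), inherits(summary, "predictor_summary"),
            inherits(grid, "perturbation_grid"))
  m <- length(summary$x_ave)
  if (nrow(model$B) != m) {
    stop(sprintf("model has %d predictors; summary has %d", nrow(model$B), m),
         call. = FALSE)
  }
  if (!quiet && any(grid$coefficients < 0 | grid$coefficients > 1)) {
    message("note: grid levels at c < 0 or c > 1 extrapolate outside the observed predictor range")
  }
  baseline <- drop(predict(model, matrix(summary$x_ave, nrow = 1)))
  curves <- vector("list", m)
  names(curves) <- summary$x_names
  for (j in seq_len(m)) {
    probe <- matrix(summary$x_ave, nrow = nrow(grid$levels), ncol = m, byrow = TRUE)
    probe[, j] <- grid$levels[, j]
    cj <- predict(model, probe)
    rownames(cj) <- rownames(grid$levels)
    curves[[j]] <- cj
  }
  structure(curves, baseline = baseline, coefficients = grid$coefficients,
            class = "sensitivity_curves")
}

#' @export
print.sensitivity_curves <- function(x, ...) {
  cat(sprintf("<sensitivity_curves> %d predictors x %d grid levels x %d responses\n",
              length(x), nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}

#' Classify predictor-response trends
#'
#' For every (predictor, task) pair, labels the perturbation curve
#' `"increasing"`, `"decreasing"` or `"negligible"`. A curve is negligible
#' when its total excursion (max minus min over the grid) is below
#' `flat_tol` times the all-means baseline prediction — the operational
#' reading of "little change in the time required"; otherwise the label is
#' the slope sign.
#'
#' @param curves a [perturb_predict()] result.
#' @param flat_tol relative excursion below which a curve counts as flat;
#'   default 0.02 (2% of the baseline prediction).
#' @return An m x p character matrix of trend labels.
#' @export
classify_trends <- function(curves, flat_tol = 0.02) {
  stopifnot(inherits(curves, "sensitivity_curves"))
  baseline <- attr(curves, "baseline")
  out <- matrix(NA_character_, length(curves), ncol(curves[[1]]),
                dimnames = list(names(curves), colnames(curves[[1]])))
  for (j in seq_along(curves)) {
    cj <- curves[[j]]
    for (k in seq_len(ncol(cj))) {
      excursion <- max(cj[, k]) - min(cj[, k])
      if (excursion < flat_tol * abs(baseline[k])) {
        out[j, k] <- "negligible"
      } else {
        out[j, k] <- if (cj[nrow(cj), k] > cj[1, k]) "increasing" else "decreasing"
      }
    }
  }
  out
}
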