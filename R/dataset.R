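#' Construct a fitness dataset
#'
#' Bundles a subjects-by-predictors block `X` (physical fitness measurements)
#' and a subjects-by-responses block `Y` (ability-task completion times,
#' seconds) into a validated container. All values must be strictly positive:
#' every study variable (body mass, aerobic capacity, body-fat percentage,
#' muscular power, task time) is physically positive, so zero or negative
#' cells are treated as data errors.
#'
#' @param X numeric matrix or data frame, n x m predictors. Canonical study
#'   layout is m = 5: weight (kg), VO2max (mL/kg/min), body-fat (%),
#'   upper-body peak power (W), lower-body peak power (W).
#' @param Y numeric matrix or data frame, n x p task completion times
#'   (seconds). Canonical study layout is p = 7.
#' @param subject_ids optional character vector of subject labels.
#' @param x_names,y_names optional variable names; default `X1..Xm`, `Y1..Yp`.
#' @return An object of class `fitness_dataset` with elements `X`, `Y`,
#'   `subject_ids`, `x_names`, `y_names`.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' dim(ds$X)
#' @export
fitness_dataset <- function(X, Y, subject_ids = NULL,
                            x_names = NULL, y_names = NULL) {
  X <- as_matrix(X, "X")
  Y <- as_matrix(Y, "Y")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows", call. = FALSE)
  if (n < 2L) stop("a dataset needs at least 2 subjects (n >= 2)", call. = FALSE)
  if (is.null(x_names)) x_names <- colnames(X)
  if (is.null(x_names)) x_names <- paste0("X", seq_len(ncol(X)))
  if (is.null(y_names)) y_names <- colnames(Y)
  if (is.null(y_names)) y_names <- paste0("Y", seq_len(ncol(Y)))
  if (length(x_names) != ncol(X)) stop("x_names length must match ncol(X)", call. = FALSE)
  if (length(y_names) != ncol(Y)) stop("y_names length must match ncol(Y)", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(n))
  if (length(subject_ids) != n) stop("subject_ids length must match n", call. = FALSE)
  check_block <- function(M, names, block) {
    bad <- which(!is.finite(M), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("missing or non-numeric value in %s at row %d, column %s",
                   block, bad[1, 1], names[bad[1, 2]]), call. = FALSE)
    }
    neg <- which(M <= 0, arr.ind = TRUE)
    if (nrow(neg) > 0L) {
      stop(sprintf("non-positive value (%g) in %s at row %d, column %s",
                   M[neg[1, , drop = FALSE]], block, neg[1, 1],
                   names[neg[1, 2]]), call. = FALSE)
    }
  }
  check_block(X, x_names, "X")
  check_block(Y, y_names, "Y")
  colnames(X) <- x_names
  colnames(Y) <- y_names
  rownames(X) <- rownames(Y) <- NULL
  structure(list(X = X, Y = Y, subject_ids = as.character(subject_ids),
                 x_names = x_names, y_names = y_names),
            class = "fitness_dataset")
}

#' @export
print.fitness_dataset <- function(x, ...) {
  cat(sprintf("<fitness_dataset> %d subjects, %d predictors, %d responses\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  cat("  predictors:", paste(x$x_names, collapse = ", "), "\n")
  cat("  responses: ", paste(x$y_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.fitness_dataset` <- function(x, i) {
  # rows of an already-validated dataset; a single-row subset (e.g. a
  # held-out test subject) is legitimate here, so skip the n >= 2 gate
  structure(list(X = x$X[i, , drop = FALSE], Y = x$Y[i, , drop = FALSE],
                 subject_ids = x$subject_ids[i],
                 x_names = x$x_names, y_names = x$y_names),
            class = "fitness_dataset")
}

#' @export
dim.fitness_dataset <- function(x) c(nrow(x$X), ncol(x$X), ncol(x$Y))

#' Read a fitness dataset from delimited text
#'
#' Expects a header row naming a `subject` column (optional), the five
#' predictor columns `X1..X5` and the seven response columns `Y1..Y7`.
#' Rejects missing columns, non-numeric cells and non-positive values with
#' a message naming the offending row/column.
#'
#' @param path file path.
#' @param delimiter field delimiter, default comma.
#' @return A [fitness_dataset()].
#' @export
read_dataset <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  nm <- names(df)
  x_cols <- paste0("X", 1:5)
  y_cols <- paste0("Y", 1:7)
  miss <- setdiff(c(x_cols, y_cols), nm)
  if (length(miss) > 0L) {
    stop(sprintf("missing column %s", miss[1]), call. = FALSE)
  }
  for (col in c(x_cols, y_cols)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric cell at row %d, column %s",
                   if (is.na(bad)) 1L else bad, col), call. = FALSE)
    }
  }
  ids <- if ("subject" %in% nm) as.character(df$subject) else NULL
  fitness_dataset(df[x_cols], df[y_cols], subject_ids = ids,
                  x_names = x_cols, y_names = y_cols)
}

#' Write a fitness dataset to delimited text
#'
#' Emits a header `subject,X1,...,Y1,...` followed by one row per subject at
#' full double precision (17 significant digits), so that
#' `read_dataset(write_dataset(ds))` round-trips exactly.
#'
#' @param ds a [fitness_dataset()].
#' @param path output file path.
#' @param delimiter field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, delimiter = ",") {
  stopifnot(inherits(ds, "fitness_dataset"))
  num <- cbind(ds$X, ds$Y)
  df <- data.frame(subject = ds$subject_ids,
                   apply(num, 2, function(v) format(v, digits = 17, trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write dataset to %s: %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Construct a per-predictor summary
#'
#' Holds the mean, maximum, minimum and range of each predictor; the range is
#' always recomputed as `x_max - x_min`.
#'
#' @param x_ave,x_max,x_min numeric vectors, one entry per predictor.
#' @param x_names predictor names.
#' @return An object of class `predictor_summary` with fields `x_ave`,
#'   `x_max`, `x_min`, `x_dif`, `x_names`.
#' @export
predictor_summary <- function(x_ave, x_max, x_min, x_names = NULL) {
  m <- length(x_ave)
  if (length(x_max) != m || length(x_min) != m) {
    stop("x_ave, x_max, x_min must have equal length", call. = FALSE)
  }
  if (any(x_min > x_ave + 1e-12) || any(x_ave > x_max + 1e-12)) {
    stop("summary must satisfy x_min <= x_ave <= x_max", call. = FALSE)
  }
  if (is.null(x_names)) x_names <- paste0("X", seq_len(m))
  s <- list(x_ave = stats::setNames(as.numeric(x_ave), x_names),
            x_max = stats::setNames(as.numeric(x_max), x_names),
            x_min = stats::setNames(as.numeric(x_min), x_names),
            x_dif = stats::setNames(as.numeric(x_max) - as.numeric(x_min), x_names),
            x_names = x_names)
  structure(s, class = "predictor_summary")
}

#' Summarize the predictors of a dataset
#'
#' Computes, for every predictor column, the mean (`x_ave`), maximum
#' (`x_max`), minimum (`x_min`) and range (`x_dif = x_max - x_min`).
#'
#' @param ds a [fitness_dataset()] or a numeric predictor matrix.
#' @return A [predictor_summary()].
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' compute_summary(ds)
#' @export
compute_summary <- function(ds) {
  X <- if (inherits(ds, "fitness_dataset")) ds$X else as_matrix(ds, "ds")
  predictor_summary(x_ave = colMeans(X),
                    x_max = apply(X, 2, max),
                    x_min = apply(X, 2, min),
                    x_names = colnames(X))
}

#' @export
print.predictor_summary <- function(x, ...) {
  m <- rbind(X_ave = x$x_ave, X_max = x$x_max, X_min = x$x_min, X_dif = x$x_dif)
  print(m, ...)
  invisible(x)
}

#' @export
as.data.frame.predictor_summary <- function(x, ...) {
  data.frame(statistic = c("X_ave", "X_max", "X_min", "X_dif"),
             rbind(x$x_ave, x$x_max, x$x_min, x$x_dif),
             check.names = FALSE, row.names = NULL)
}

#' Published predictor summary of the firefighter cohort
#'
#' The per-predictor mean, maximum, minimum and range of the 20-firefighter
#' study cohort: weight (kg), VO2max (mL/kg/min), body-fat percentage,
#' upper-body peak power (W) and lower-body peak power (W). These printed
#' marginals are the only cohort-level data the study released; they anchor
#' both the synthetic generator's default ranges and the perturbation grid.
#'
#' @return A [predictor_summary()] for the five study predictors.
#' @examples
#' reference_predictor_summary()
#' @export
reference_predictor_summary <- function() {
  predictor_summary(
    x_ave = c(69, 46.85, 14.655, 675.35, 1705),
    x_max = c(90, 62, 22.2, 921, 2564),
    x_min = c(56, 29, 7.7, 483, 1408),
    x_names = paste0("X", 1:5)
  )
}
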