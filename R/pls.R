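#' Column standardization (autoscaling)
#'
#' Centers each column and divides by its sample standard deviation. When
#' `center`/`scale` are supplied (e.g. applying a training-set scaling to new
#' rows) they are used as-is rather than re-estimated.
#'
#' @param M numeric matrix.
#' @param center,scale optional per-column centers/scales to apply.
#' @return A list with `x` (the standardized matrix), `center`, `scale`.
#' @export
standardize <- function(M, center = NULL, scale = NULL) {
  M <- as_matrix(M, "M")
  if (is.null(center)) center <- colMeans(M)
  if (is.null(scale)) {
    scale <- apply(M, 2, stats::sd)
    zero <- which(scale < .Machine$double.eps^0.5 * pmax(1, abs(center)))
    if (length(zero) > 0L) {
      nm <- colnames(M)[zero[1]] %||% as.character(zero[1])
      stop(sprintf("zero-variance column: %s", nm), call. = FALSE)
    }
  }
  x <- sweep(sweep(M, 2, center, "-"), 2, scale, "/")
  list(x = x, center = as.numeric(center), scale = as.numeric(scale))
}

#' Extract one PLS component
#'
#' Finds the predictor weight vector `w` (unit norm) as the dominant left
#' singular vector of `E'F`, i.e. the direction whose score `t = E w`
#' (a linear combination of the predictor columns) has maximal covariance
#' with a response-block combination. The block loadings are the
#' least-squares regressions of each block on the score:
#' `alpha = E't / ||t||^2`, `beta = F't / ||t||^2`; `u = F beta / ||beta||`
#' is the corresponding response score. The sign of `w` is fixed so its
#' largest-magnitude entry is positive, removing the singular-vector sign
#' indeterminacy.
#'
#' @param E,F current predictor/response residual matrices (n x m, n x p).
#' @return A list with `w`, `t`, `u`, `alpha`, `beta`.
#' @export
extract_component <- function(E, F) {
  E <- as_matrix(E, "E"); F <- as_matrix(F, "F")
  S <- crossprod(E, F)
  snorm <- sqrt(sum(S^2))
  ref <- sqrt(sum(E^2)) * sqrt(sum(F^2))
  if (snorm <= 1e-12 * max(ref, 1)) {
    stop("no extractable component: predictor-response cross-product is numerically zero",
         call. = FALSE)
  }
  sv <- svd(S, nu = 1, nv = 0)
  w <- sv$u[, 1]
  imax <- which.max(abs(w))
  if (w[imax] < 0) w <- -w
  t_ <- drop(E %*% w)
  tt <- sum(t_^2)
  alpha <- drop(crossprod(E, t_)) / tt
  beta <- drop(crossprod(F, t_)) / tt
  u <- drop(F %*% beta) / sqrt(sum(beta^2))
  list(w = w, t = t_, u = u, alpha = alpha, beta = beta)
}

#' Deflate both blocks by a component
#'
#' Subtracts the rank-one reconstruction of the score from each block:
#' `E - t alpha'` and `F - t beta'`. After deflation the predictor residual
#' is orthogonal to the score up to round-off. The response block is
#' deflated by the same score `t` used to estimate `beta` (regression-mode
#' deflation), keeping the decomposition consistent with the loading
#' estimates.
#'
#' @param E,F current residual matrices.
#' @param t score vector.
#' @param alpha,beta block loading vectors.
#' @return A list with `E` and `F`, the next residual matrices.
#' @export
deflate <- function(E, F, t, alpha, beta) {
  list(E = E - tcrossprod(t, alpha),
       F = F - tcrossprod(t, beta))
}

#' Fit a partial least-squares regression
#'
#' Autoscales both blocks (the predictors span incomparable units — kg, %,
#' W, mL/kg/min — so correlation-scale PLS is the defensible default), then
#' runs `h` extract/deflate cycles and accumulates the coefficient matrix.
#' The original-units coefficients `B` (m x p) and intercepts `b0` satisfy
#' `Y_hat = X B + b0` and reproduce the component-wise predictions exactly.
#'
#' @param X a [fitness_dataset()] or an n x m predictor matrix.
#' @param Y an n x p response matrix (ignored when `X` is a dataset).
#' @param h number of components, `1 <= h <= min(n - 1, m)`.
#' @return An object of class `pls_model`: weights `W`, scores `scores`,
#'   predictor loadings `x_loadings`, response loadings `y_loadings`,
#'   centering/scaling parameters, standardized and original-units
#'   coefficients, intercepts and training fit.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 1))
#' fit <- fit_plsr(ds, h = 2)
#' fit$B
#' @export
fit_plsr <- function(X, Y = NULL, h) {
  if (inherits(X, "fitness_dataset")) {
    Y <- X$Y
    X <- X$X
  }
  X <- as_matrix(X, "X"); Y <- as_matrix(Y, "Y")
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  h <- as.integer(h)
  h_cap <- min(n - 1L, m)
  if (h < 1L || h > h_cap) {
    stop(sprintf("h must be in 1..%d for n=%d, m=%d", h_cap, n, m), call. = FALSE)
  }
  sx <- standardize(X)
  sy <- standardize(Y)
  E <- sx$x; F <- sy$x
  W <- matrix(0, m, h); Tt <- matrix(0, n, h)
  A <- matrix(0, m, h); B_load <- matrix(0, p, h); U <- matrix(0, n, h)
  R <- matrix(0, m, h)  # weights mapped to the original standardized X basis
  for (a in seq_len(h)) {
    cmp <- extract_component(E, F)
    W[, a] <- cmp$w; Tt[, a] <- cmp$t; U[, a] <- cmp$u
    A[, a] <- cmp$alpha; B_load[, a] <- cmp$beta
    r <- cmp$w
    if (a > 1L) {
      for (b in seq_len(a - 1L)) r <- r - R[, b] * sum(A[, b] * cmp$w)
    }
    R[, a] <- r
    dfl <- deflate(E, F, cmp$t, cmp$alpha, cmp$beta)
    E <- dfl$E; F <- dfl$F
  }
  B_std <- R %*% t(B_load)
  B <- sweep(sweep(B_std, 2, sy$scale, "*"), 1, sx$scale, "/")
  b0 <- sy$center - drop(sx$center %*% B)
  fitted <- sweep(X %*% B, 2, b0, "+")
  colnames(B) <- colnames(Y); rownames(B) <- colnames(X)
  structure(list(h = h, W = W, scores = Tt, u_scores = U,
                 x_loadings = A, y_loadings = B_load, R = R,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = sy$center, y_scale = sy$scale,
                 B_std = B_std, B = B, b0 = b0,
                 fitted = fitted,
                 x_names = colnames(X) %||% paste0("X", seq_len(m)),
                 y_names = colnames(Y) %||% paste0("Y", seq_len(p)),
                 n = n),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictors -> %d responses, fit on n=%d\n",
              x$h, nrow(x$B), ncol(x$B), x$n))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the original-units coefficients: `X_new B + b0`. A row equal to
#' the training predictor means returns the training response means exactly.
#'
#' @param object a `pls_model`.
#' @param newdata a k x m matrix, a [fitness_dataset()], or a numeric vector
#'   of length m (one subject).
#' @param ... unused.
#' @return A k x p matrix of predicted responses in original units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fitness_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as_matrix(newdata, "newdata")
  if (ncol(newdata) != nrow(object$B)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), nrow(object$B)), call. = FALSE)
  }
  out <- sweep(newdata %*% object$B, 2, object$b0, "+")
  colnames(out) <- object$y_names
  out
}

#' Serialize a PLS model to plain text
#'
#' Writes every model matrix row-major with its shape, one `key:` block per
#' field, so fits are inspectable and diffable. [read_pls_model()] inverts
#' the format exactly.
#'
#' @param model a `pls_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(key, value) {
    if (is.matrix(value)) {
      cat(sprintf("%s: matrix %d %d\n", key, nrow(value), ncol(value)), file = con)
      for (i in seq_len(nrow(value))) {
        cat(paste(format(value[i, ], digits = 17, trim = TRUE), collapse = " "),
            "\n", sep = "", file = con)
      }
    } else if (is.numeric(value)) {
      cat(sprintf("%s: vector %d\n", key, length(value)), file = con)
      cat(paste(format(value, digits = 17, trim = TRUE), collapse = " "),
          "\n", sep = "", file = con)
    } else {
      cat(sprintf("%s: names %s\n", key, paste(value, collapse = " ")), file = con)
    }
  }
  cat(sprintf("pls_model: h %d n %d\n", model$h, model$n), file = con)
  for (key in c("W", "scores", "u_scores", "x_loadings", "y_loadings", "R",
                "B_std", "B", "b0", "x_center", "x_scale", "y_center", "y_scale")) {
    emit(key, model[[key]])
  }
  emit("x_names", model$x_names)
  emit("y_names", model$y_names)
  invisible(path)
}

#' Read a serialized PLS model
#'
#' @param path file written by [write_pls_model()].
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " +")[[1]]
  if (hdr[1] != "pls_model:") stop("not a serialized pls_model file", call. = FALSE)
  out <- list(h = as.integer(hdr[3]), n = as.integer(hdr[5]))
  i <- 2L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], " +")[[1]]
    key <- sub(":$", "", parts[1])
    if (parts[2] == "matrix") {
      nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
      vals <- lapply(lines[i + seq_len(nr)], function(s) as.numeric(strsplit(s, " +")[[1]]))
      out[[key]] <- matrix(unlist(vals), nr, nc, byrow = TRUE)
      i <- i + nr + 1L
    } else if (parts[2] == "vector") {
      out[[key]] <- as.numeric(strsplit(lines[i + 1L], " +")[[1]])
      i <- i + 2L
    } else {
      out[[key]] <- parts[-(1:2)]
      i <- i + 1L
    }
  }
  rownames(out$B) <- out$x_names
  colnames(out$B) <- out$y_names
  out$fitted <- NULL
  structure(out, class = "pls_model")
}
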