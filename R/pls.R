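#' Dummy response matrix from group labels
#'
#' One indicator column per class; each row sums to 1. The two-class case may
#' equivalently be handled as a single +/-1 column via [contrast_response()].
#' @param labels character/factor vector with >= 2 distinct values.
#' @return samples x classes 0/1 matrix with class column names.
#' @export
response_matrix <- function(labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L) stop_fly("need at least 2 distinct labels")
  Y <- vapply(lev, function(l) as.numeric(labels == l), numeric(length(labels)))
  rownames(Y) <- names(labels)
  Y
}

#' Signed response vector for a two-group contrast
#'
#' Codes the first contrast level -1 and the second +1, so a positive
#' correlation loading means higher intensity in the second (e.g. survivor)
#' group.
#' @param labels group labels.
#' @param contrast character vector of two levels, `c(negative, positive)`.
#' @return numeric vector of -1/+1, with the contrast stored as an attribute.
#' @export
contrast_response <- function(labels, contrast) {
  labels <- as.character(labels)
  stopifnot(length(contrast) == 2L)
  if (!all(labels %in% contrast))
    stop_fly("labels outside the contrast: %s",
             paste(setdiff(labels, contrast), collapse = ", "))
  y <- ifelse(labels == contrast[2L], 1, -1)
  attr(y, "contrast") <- contrast
  y
}

# Coerce a response argument (matrix, labels, numeric) to a numeric matrix.
as_y_matrix <- function(y) {
  if (is.matrix(y)) y
  else if (is.numeric(y)) matrix(as.numeric(y), ncol = 1L)
  else response_matrix(y)
}

#' Partial least squares regression (NIPALS PLS2)
#'
#' From-scratch NIPALS: per component the X-weight maximizes covariance with
#' the Y scores; X and Y are deflated by the extracted component. The response
#' is column-centered internally. With the three group-indicator columns as Y
#' this is the PLS-DA model used to screen for overall group separation.
#'
#' @param x centered/scaled `bucket_table` or matrix.
#' @param y response: dummy matrix, labels, or numeric vector/matrix.
#' @param n_components number of latent components.
#' @param tol,max_iter NIPALS inner-loop convergence controls.
#' @return `latent_model` (kind "pls") with scores `T_pred`, weights `W`,
#'   loadings `P`, Y-loadings `C`, regression coefficients `B`, `R2Y`.
#' @export
fit_pls <- function(x, y, n_components = 2L, tol = 1e-12, max_iter = 500L) {
  X <- as_x_matrix(x)
  Y <- as_y_matrix(y)
  if (nrow(Y) != nrow(X)) stop_fly("X and Y row counts differ")
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2L, ybar)
  if (all(abs(Yc) < 1e-14)) stop_fly("constant response: nothing to fit")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stop_fly("n_components must be in 1..%d", min(n - 1L, p))
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, q, A)
  Tm <- matrix(0, n, A)
  Xd <- X; Yd <- Yc
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1L]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stop_fly("degenerate component %d (zero weight)", a)
      w <- w / nw
      tt <- (Xd %*% w)[, 1L]
      cc <- crossprod(Yd, tt)[, 1L] / sum(tt^2)
      u <- (Yd %*% cc)[, 1L] / sum(cc^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), 1e-300) < tol^2) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt)[, 1L] / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
  }
  R2Y <- 1 - sum(Yd^2) / sum(Yc^2)
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(C)
  rownames(Tm) <- rownames(X)
  structure(list(kind = "pls", n_predictive = A, n_orthogonal = 0L,
                 T_pred = Tm, T_orth = NULL, W = W, P = P, C = C, B = B,
                 y_center = ybar, y_levels = colnames(Y),
                 R2Y = R2Y, Q2Y = NA_real_),
            class = "latent_model")
}

predict_pls <- function(model, newdata) {
  Xn <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  Yhat <- Xn %*% model$B
  sweep(Yhat, 2L, model$y_center, "+")
}
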