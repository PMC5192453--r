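# Orthogonal projections to latent structures, single-y Trygg-Wold algorithm.
#
# The engine never materializes the deflated matrix: X_k = X - sum_j to_j po_j'
# is carried implicitly through the accumulated (To, Po) pairs, so each fit
# costs a handful of matrix-vector products. That keeps leave-one-out
# cross-validation inside permutation loops affordable at full spectral width.
opls_engine <- function(X, yc, n_orth) {
  n <- nrow(X); p <- ncol(X)
  w <- crossprod(X, yc)[, 1L]
  nw <- sqrt(sum(w^2))
  if (nw < 1e-300) {
    # no covariance between X and y (e.g. constant X): the null model, which
    # predicts the training mean everywhere
    zero <- matrix(0, n, 0L); zerop <- matrix(0, p, 0L)
    return(list(w = numeric(p), Wo = zerop, Po = zerop, To = zero,
                n_orth = 0L, t_pred = numeric(n), p_pred = numeric(p), c = 0))
  }
  w <- w / nw
  To <- matrix(0, n, n_orth); Po <- matrix(0, p, n_orth); Wo <- matrix(0, p, n_orth)
  kdone <- 0L
  # deflated products: Xd v = X v - To (Po' v);  Xd' t = X' t - Po (To' t)
  dx <- function(v) {
    out <- (X %*% v)[, 1L]
    if (kdone > 0L) {
      kk <- seq_len(kdone)
      out <- out - (To[, kk, drop = FALSE] %*% crossprod(Po[, kk, drop = FALSE], v))[, 1L]
    }
    out
  }
  dtx <- function(t) {
    out <- crossprod(X, t)[, 1L]
    if (kdone > 0L) {
      kk <- seq_len(kdone)
      out <- out - (Po[, kk, drop = FALSE] %*% crossprod(To[, kk, drop = FALSE], t))[, 1L]
    }
    out
  }
  for (k in seq_len(n_orth)) {
    tt <- dx(w)
    pl <- dtx(tt) / sum(tt^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) { n_orth <- k - 1L; break }  # no y-orthogonal variation left
    wo <- wo / nwo
    to <- dx(wo)
    po <- dtx(to) / sum(to^2)
    To[, k] <- to; Po[, k] <- po; Wo[, k] <- wo
    kdone <- k
  }
  if (kdone < ncol(To)) {
    To <- To[, seq_len(kdone), drop = FALSE]
    Po <- Po[, seq_len(kdone), drop = FALSE]
    Wo <- Wo[, seq_len(kdone), drop = FALSE]
  }
  t_pred <- dx(w)
  p_pred <- dtx(t_pred) / sum(t_pred^2)
  c_pred <- sum(yc * t_pred) / sum(t_pred^2)
  list(w = w, Wo = Wo, Po = Po, To = To, n_orth = kdone,
       t_pred = t_pred, p_pred = p_pred, c = c_pred)
}

# Predict centered y for new scaled rows.
opls_predict_engine <- function(eng, Xn) {
  if (!is.matrix(Xn)) Xn <- matrix(Xn, nrow = 1L)
  if (eng$n_orth > 0L)
    for (k in seq_len(eng$n_orth)) {
      to <- (Xn %*% eng$Wo[, k])[, 1L]
      Xn <- Xn - tcrossprod(to, eng$Po[, k])
    }
  (Xn %*% eng$w)[, 1L] * eng$c
}

#' Orthogonal PLS (O-PLS) for a two-class response
#'
#' Trygg-Wold O-PLS with a single predictive component: the predictive weight
#' is `X'y` normalized; each orthogonal round extracts from the loading of the
#' current predictive score the part orthogonal to the predictive weight,
#' scores it, and deflates X by it. Orthogonal score vectors are uncorrelated
#' with the response by construction; with zero orthogonal components the
#' predictive scores coincide with one-component PLS scores.
#'
#' @param x centered/scaled `bucket_table` or matrix.
#' @param y two-class response: labels (exactly two distinct values) or a
#'   numeric +/-1 (or 0/1) vector.
#' @param n_orthogonal number of orthogonal components; must be less than
#'   `nrow - 2`.
#' @param contrast optional `c(negative, positive)` ordering when `y` is a
#'   label vector; default: order of first appearance.
#' @return `latent_model` (kind "opls") with `T_pred`, `T_orth`, predictive
#'   weight `W`, orthogonal weights/loadings `W_orth`/`P_orth`, Y-loading `C`,
#'   and training `R2Y`.
#' @export
fit_opls <- function(x, y, n_orthogonal = 1L, contrast = NULL) {
  X <- as_x_matrix(x)
  if (!is.numeric(y)) {
    lev <- contrast %||% unique(as.character(y))
    if (length(lev) != 2L) stop_fly("OPLS requires exactly two classes (got %d)", length(lev))
    y <- contrast_response(y, lev)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_fly("X and y lengths differ")
  if (length(unique(y)) < 2L) stop_fly("constant response: nothing to fit")
  n_orthogonal <- as.integer(n_orthogonal)
  if (n_orthogonal < 0L || n_orthogonal >= nrow(X) - 2L)
    stop_fly("n_orthogonal must be in 0..%d", nrow(X) - 3L)
  ybar <- mean(y)
  yc <- y - ybar
  eng <- opls_engine(X, yc, n_orthogonal)
  yhat <- eng$t_pred * eng$c
  R2Y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  Tm <- matrix(eng$t_pred, ncol = 1L, dimnames = list(rownames(X), "t_pred"))
  structure(list(kind = "opls", n_predictive = 1L, n_orthogonal = eng$n_orth,
                 T_pred = Tm, T_orth = eng$To,
                 W = matrix(eng$w, ncol = 1L), P = matrix(eng$p_pred, ncol = 1L),
                 W_orth = eng$Wo, P_orth = eng$Po,
                 C = eng$c, y = y, y_center = ybar,
                 engine = eng, R2Y = R2Y, Q2Y = NA_real_),
            class = "latent_model")
}

#' Predict from a fitted PLS/OPLS model
#'
#' `newdata` must be on the same (training) centering/scaling as the fitted X.
#' @param object a `latent_model` of kind "pls" or "opls".
#' @param newdata matrix or single row vector.
#' @param ... unused.
#' @return predicted response matrix (PLS) or numeric vector (OPLS).
#' @export
predict.latent_model <- function(object, newdata, ...) {
  switch(object$kind,
         pls = predict_pls(object, newdata),
         opls = opls_predict_engine(object$engine,
                                    if (is.matrix(newdata)) newdata
                                    else matrix(newdata, nrow = 1L)) + object$y_center,
         stop_fly("predict not available for kind '%s'", object$kind))
}
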