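as_x_matrix <- function(x) {
  if (inherits(x, "bucket_table")) x$values
  else if (is.matrix(x)) x
  else as.matrix(x)
}

#' Principal component analysis (SVD-based)
#'
#' Fits PCA on an already centered (and optionally scaled) matrix: used to
#' screen for outlier samples and technical confounders before any supervised
#' modelling. Loadings are orthonormal, scores orthogonal, and explained
#' variance is non-increasing by component, so the rank-k reconstruction
#' `T P'` is the Frobenius-optimal rank-k approximation.
#'
#' @param x scaled `bucket_table` or numeric matrix (samples x variables).
#' @param n_components number of components, at most
#'   `min(nrow - 1, ncol)`.
#' @return `latent_model` with kind "pca": scores `T_pred`, loadings `P`,
#'   `explained_variance` (fractions), `score_distance` (Hotelling-type
#'   normalized squared score distance per sample).
#' @export
fit_pca <- function(x, n_components = 2L) {
  X <- as_x_matrix(x)
  n_components <- as.integer(n_components)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L || n_components > kmax)
    stop_fly("n_components must be in 1..%d", kmax)
  sv <- svd(X, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  rownames(scores) <- rownames(X)
  ev <- sv$d^2 / sum(sv$d^2)
  lambda <- d^2 / (nrow(X) - 1)
  sdist <- rowSums(sweep(scores^2, 2L, lambda, "/"))
  structure(list(kind = "pca", n_predictive = n_components, n_orthogonal = 0L,
                 T_pred = scores, P = sv$v, W = sv$v, C = NULL,
                 singular_values = sv$d,
                 explained_variance = ev[seq_len(n_components)],
                 score_distance = sdist,
                 R2Y = NA_real_, Q2Y = NA_real_),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> %s: %d predictive + %d orthogonal component(s)",
              toupper(x$kind), x$n_predictive, x$n_orthogonal))
  if (!is.na(x$R2Y)) cat(sprintf("; R2Y = %.3f", x$R2Y))
  if (!is.na(x$Q2Y)) cat(sprintf("; Q2Y = %.3f", x$Q2Y))
  cat("\n")
  invisible(x)
}
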