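# Per-fold training matrices for leave-one-out CV, scaled with training-fold
# parameters only (no leakage). Built once and reused across a permutation
# loop, since fold scaling does not depend on the response.
#
# With compress = TRUE each scaled fold is rotated onto its row space
# (thin SVD): every NIPALS weight/loading vector lies in the row space, so
# PLS/OPLS fits, scores and held-out predictions on the compressed
# (n-1) x (n-1) matrix are exactly those on the full (n-1) x p matrix, at a
# fraction of the cost. This keeps full-resolution permutation testing
# (hundreds of refits of leave-one-out loops) tractable.
make_loo_folds <- function(X, scaling = "center_unit_variance",
                           compress = ncol(X) > 4L * nrow(X)) {
  n <- nrow(X)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    xte <- X[i, ]
    if (scaling %in% c("center", "center_unit_variance")) {
      ctr <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2L, ctr)
      xte <- xte - ctr
      if (scaling == "center_unit_variance") {
        sds <- sqrt(colSums(Xtr^2) / (n - 2L))
        sds[!is.finite(sds) | sds < 1e-12] <- 1  # degenerate: center only
        Xtr <- sweep(Xtr, 2L, sds, "/")
        xte <- xte / sds
      }
    }
    if (compress) {
      k <- min(n - 1L, ncol(Xtr))
      sv <- svd(Xtr, nu = k, nv = k)
      Xtr <- sv$u * rep(sv$d[seq_len(k)], each = nrow(sv$u))  # U D: rotated basis
      xte <- drop(xte %*% sv$v)
    }
    folds[[i]] <- list(Xtr = Xtr, xte = xte)
  }
  folds
}

# Q2Y over prebuilt LOO folds. Y: numeric vector (opls) or matrix (pls).
q2y_engine <- function(folds, Y, kind, n_components, n_orthogonal,
                       check_classes = TRUE) {
  vecy <- !is.matrix(Y)
  Ym <- if (vecy) matrix(as.numeric(Y), ncol = 1L) else Y
  n <- nrow(Ym)
  if (check_classes) {
    uv <- unique(asplit(Ym, 1L))
    classlike <- length(uv) <= max(2L, ncol(Ym))
  } else classlike <- FALSE
  press <- 0; ss <- 0
  pred <- matrix(NA_real_, n, ncol(Ym))
  for (i in seq_len(n)) {
    Ytr <- Ym[-i, , drop = FALSE]
    if (classlike && nrow(unique(Ytr)) < length(unique(asplit(Ym, 1L))))
      stop_fly("leave-one-out fold %d loses an entire class; need >= 2 samples per class", i)
    ybar <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2L, ybar)
    fold <- folds[[i]]
    if (kind == "opls") {
      eng <- opls_engine(fold$Xtr, Yc[, 1L], n_orthogonal)
      yhat <- opls_predict_engine(eng, fold$xte) + ybar
    } else {
      m <- fit_pls(fold$Xtr, Yc, n_components = n_components)
      yhat <- predict_pls(m, fold$xte) + rep(ybar, each = 1L)
    }
    pred[i, ] <- yhat
    press <- press + sum((Ym[i, ] - yhat)^2)
    ss <- ss + sum((Ym[i, ] - ybar)^2)
  }
  list(q2y = 1 - press / ss, press = press, ss = ss, predictions = pred)
}

#' Leave-one-out cross-validated Q2Y
#'
#' For every left-out sample the centering/scaling and the model are refit on
#' the remaining samples (stored training-fold parameters are applied to the
#' held-out sample), its response is predicted, and
#' `Q2Y = 1 - PRESS / SS` with SS computed against training-fold response
#' means. Q2Y is at most 1 and may be negative; it is invariant to sample
#' ordering.
#'
#' @param x unscaled (e.g. PQN-normalized) `bucket_table` or matrix; per-fold
#'   scaling is applied internally.
#' @param y response: labels, +/-1 vector, numeric vector, or dummy matrix.
#' @param kind "opls" (single numeric y) or "pls".
#' @param n_components predictive components for PLS.
#' @param n_orthogonal orthogonal components for OPLS.
#' @param scaling per-fold scaling method.
#' @return object of class `cv_result`: `q2y`, `press`, `ss`, `predictions`,
#'   `residuals`, `n`, `n_components` (total model components).
#' @export
q2y_loo <- function(x, y, kind = c("opls", "pls"), n_components = 2L,
                    n_orthogonal = 1L,
                    scaling = c("center_unit_variance", "center", "none")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  X <- as_x_matrix(x)
  if (nrow(X) < 3L) stop_fly("need at least 3 samples for leave-one-out CV")
  Y <- if (kind == "opls") {
    if (!is.numeric(y)) {
      lev <- unique(as.character(y))
      if (length(lev) != 2L) stop_fly("OPLS requires exactly two classes")
      contrast_response(y, lev)
    } else as.numeric(y)
  } else as_y_matrix(y)
  folds <- make_loo_folds(X, scaling)
  res <- q2y_engine(folds, Y, kind, n_components, n_orthogonal)
  ncomp_total <- if (kind == "opls") 1L + as.integer(n_orthogonal)
                 else as.integer(n_components)
  Ym <- if (is.matrix(Y)) Y else matrix(as.numeric(Y), ncol = 1L)
  structure(list(q2y = res$q2y, press = res$press, ss = res$ss,
                 predictions = res$predictions,
                 residuals = Ym - res$predictions,
                 n = nrow(X), n_components = ncomp_total,
                 kind = kind, scaling = scaling),
            class = "cv_result")
}

#' CV-ANOVA significance of cross-validated predictions
#'
#' Eriksson-style F-test comparing the cross-validated predictive residual sum
#' of squares (PRESS) against the total corrected sum of squares:
#' `F = ((SS - PRESS)/A) / (PRESS/(n - A - 1))` with `A` the number of model
#' components, referred to an F(A, n - A - 1) distribution. Convention chosen
#' and documented here; if PRESS >= SS the model predicts no better than the
#' mean and p = 1. A (near-)zero PRESS returns the numeric lower bound with a
#' flag.
#'
#' @param cv a `cv_result` from [q2y_loo()], or NULL if the sums are given
#'   directly.
#' @param press,ss,n,n_components direct inputs (used when `cv` is NULL).
#' @return p-value in `[0, 1]` with attributes `F`, `df1`, `df2`, and
#'   `zero_residual` flag.
#' @export
cv_anova <- function(cv = NULL, press = cv$press, ss = cv$ss, n = cv$n,
                     n_components = cv$n_components) {
  A <- as.integer(n_components)
  df2 <- n - A - 1L
  if (df2 < 1L) stop_fly("CV-ANOVA needs n > components + 1")
  zero <- press <= 1e-12 * ss
  if (zero) {
    p <- .Machine$double.xmin
    Fstat <- Inf
  } else {
    Fstat <- ((ss - press) / A) / (press / df2)
    p <- if (Fstat <= 0) 1 else pf(Fstat, A, df2, lower.tail = FALSE)
  }
  structure(p, F = Fstat, df1 = A, df2 = df2, zero_residual = zero)
}

#' Permutation validation of Q2Y
#'
#' Shuffles the response rows `n_permutations` times, recomputing the full
#' leave-one-out Q2Y (per-fold rescaling included) for each shuffle. The model
#' is accepted when the observed Q2Y exceeds the empirical 99th percentile of
#' the permuted Q2Y distribution; an empirical p-value
#' `(1 + #{perm >= observed}) / (n_permutations + 1)` and the CV-ANOVA p of the
#' observed model are also reported. Deterministic for a fixed seed.
#'
#' @inheritParams q2y_loo
#' @param n_permutations number of shuffles (default 999; fewer than 100 gives
#'   an unstable percentile and triggers a warning).
#' @param seed mandatory integer seed.
#' @return object of class `validation_report`.
#' @export
permutation_test <- function(x, y, kind = c("opls", "pls"), n_components = 2L,
                             n_orthogonal = 1L, n_permutations = 999L,
                             seed,
                             scaling = c("center_unit_variance", "center", "none")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  if (missing(seed)) stop_fly("a seed is required for the permutation test")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    warn_fly("only %d permutations: the 99th percentile is unstable", n_permutations)
  X <- as_x_matrix(x)
  Y <- if (kind == "opls") {
    if (!is.numeric(y)) contrast_response(y, unique(as.character(y))) else as.numeric(y)
  } else as_y_matrix(y)
  folds <- make_loo_folds(X, scaling)
  obs <- q2y_engine(folds, Y, kind, n_components, n_orthogonal)
  ncomp_total <- if (kind == "opls") 1L + as.integer(n_orthogonal) else as.integer(n_components)
  cv_p <- cv_anova(press = obs$press, ss = obs$ss, n = nrow(X),
                   n_components = ncomp_total)
  perm <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(nrow(X))
      Yp <- if (is.matrix(Y)) Y[idx, , drop = FALSE] else Y[idx]
      perm[b] <- q2y_engine(folds, Yp, kind, n_components, n_orthogonal,
                            check_classes = FALSE)$q2y
    }
  })
  pct99 <- quantile(perm, 0.99, names = FALSE)
  structure(list(n_permutations = n_permutations, permuted_Q2Y = perm,
                 percentile_99 = pct99, observed_Q2Y = obs$q2y,
                 passes = obs$q2y > pct99,
                 p_value = (1 + sum(perm >= obs$q2y)) / (n_permutations + 1),
                 cv_anova_p = as.numeric(cv_p),
                 observed_press = obs$press, observed_ss = obs$ss,
                 kind = kind, n_components = ncomp_total,
                 seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s (%d comp): Q2Y = %.3f vs 99th pct of %d permutations = %.3f -> %s\n  permutation p = %.4g, CV-ANOVA p = %.4g\n",
    toupper(x$kind), x$n_components, x$observed_Q2Y, x$n_permutations,
    x$percentile_99, if (x$passes) "ACCEPT" else "REJECT",
    x$p_value, x$cv_anova_p))
  invisible(x)
}
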