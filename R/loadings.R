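#' Covariance and correlation loadings
#'
#' Per bucket: the covariance between bucket intensity and the response
#' (loading-plot heights) and the Pearson correlation R (loading-plot colors).
#' Computed on the normalization scale (PQN), not the unit-variance scale, so
#' covariances keep intensity units; Pearson R is scale-invariant either way.
#' A positive R means higher intensity in the class coded +1. Zero-variance
#' buckets get R = 0 and are flagged.
#'
#' @param x PQN-normalized (unscaled) `bucket_table` or matrix.
#' @param y response: +/-1 vector (see [contrast_response()]) or any numeric
#'   vector; labels are accepted for a two-class table.
#' @return object of class `loading_profile`: data.frame with columns
#'   `center`, `covariance`, `r`, `flagged`.
#' @export
correlation_loadings <- function(x, y) {
  X <- as_x_matrix(x)
  centers <- if (inherits(x, "bucket_table")) {
    x$centers
  } else {
    cn <- suppressWarnings(as.numeric(colnames(X)))
    if (length(cn) == ncol(X) && !anyNA(cn)) cn else seq_len(ncol(X))
  }
  if (!is.numeric(y)) {
    lev <- unique(as.character(y))
    if (length(lev) != 2L) stop_fly("labels must have exactly two levels here")
    y <- contrast_response(y, lev)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_fly("X and y lengths differ")
  n <- nrow(X)
  yc <- y - mean(y)
  xc <- sweep(X, 2L, colMeans(X))
  covv <- crossprod(xc, yc)[, 1L] / (n - 1)
  sdx <- sqrt(colSums(xc^2) / (n - 1))
  sdy <- sqrt(sum(yc^2) / (n - 1))
  flagged <- sdx < 1e-300 | !is.finite(sdx)
  r <- ifelse(flagged, 0, covv / (sdx * sdy))
  out <- data.frame(center = centers, covariance = covv, r = r,
                    flagged = flagged, row.names = NULL)
  class(out) <- c("loading_profile", "data.frame")
  out
}

#' Select discriminant metabolites by correlation loading
#'
#' Maps buckets to metabolites through the chemical-shift library, assigns
#' each metabolite the signed R of its maximal-|R| assigned bucket (ties
#' broken towards lower ppm), and marks metabolites with `|R| >= threshold`
#' (inclusive) as discriminant. Metabolites whose regions contain no bucket of
#' the table are skipped with a warning.
#'
#' @param profile a `loading_profile` from [correlation_loadings()].
#' @param library a `metabolite_library` (see [load_library()]).
#' @param threshold inclusive |R| cutoff, default 0.5.
#' @return data.frame (metabolite, r, center, selected), sorted by |R|
#'   descending. Discriminant metabolites are the rows with `selected`.
#' @export
select_discriminant <- function(profile, library, threshold = 0.5) {
  stopifnot(inherits(profile, "loading_profile"),
            inherits(library, "metabolite_library"))
  res <- list()
  skipped <- character(0)
  for (e in library$entries) {
    iv <- entry_intervals(e, library$tolerance)
    hit <- rep(FALSE, nrow(profile))
    for (r in iv) hit <- hit | (profile$center >= r[1] & profile$center <= r[2])
    if (!any(hit)) { skipped <- c(skipped, e$name); next }
    sub <- profile[hit, , drop = FALSE]
    best <- sub[order(-abs(sub$r), sub$center), ][1L, ]
    res[[e$name]] <- data.frame(metabolite = e$name, r = best$r,
                                center = best$center)
  }
  if (length(skipped))
    warn_fly("no bucket in table for: %s", paste(skipped, collapse = ", "))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[order(-abs(out$r), out$metabolite), , drop = FALSE]
  out$selected <- abs(out$r) >= threshold
  out
}
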