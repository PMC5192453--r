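# Shared fixtures, built lazily once per test run.
.fix <- new.env(parent = emptyenv())

# Default paper-shaped cohort (3 x 10, planted survivor effects), cached.
fix_cohort <- function() {
  if (is.null(.fix$cohort))
    .fix$cohort <- generate_cohort(cohort_design(seed = 42L))
  .fix$cohort
}

# Raw and PQN-normalized bucket tables of the cached cohort.
fix_table_raw <- function() {
  if (is.null(.fix$bt_raw))
    .fix$bt_raw <- bucket_table(fix_cohort()$spectra)
  .fix$bt_raw
}
fix_table_pqn <- function() {
  if (is.null(.fix$bt_pqn))
    .fix$bt_pqn <- pqn_normalize(fix_table_raw())
  .fix$bt_pqn
}

# Small planted two-class matrix: y-correlated block + structured
# y-orthogonal variation + noise. Cheap stand-in for module-level tests.
toy_two_class <- function(n_per = 10L, p = 60L, effect = 2, seed = 1L,
                          orth_strength = 0) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n_per)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[, 1:5] <- X[, 1:5] + effect * y
  if (orth_strength > 0) {
    z <- rnorm(2 * n_per)
    z <- z - mean(z) - y * sum(z * y) / sum(y^2)  # orthogonal to y
    X[, 6:15] <- X[, 6:15] + orth_strength * z
  }
  list(X = scale(X), Xraw = X, y = y)
}

# Tiny spectrum on an arbitrary grid.
toy_spectrum <- function(ppm, intensity, id = "toy") nmr_spectrum(ppm, intensity, id)

expect_same_up_to_sign <- function(a, b, tol = 1e-8) {
  s <- sign(sum(a * b))
  if (s == 0) s <- 1
  expect_equal(unname(a), unname(s * b), tolerance = tol)
}
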