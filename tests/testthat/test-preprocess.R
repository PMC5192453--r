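test_that("spectrum reader parses, skips headers, and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0 5.0", "2.0 7.0"), f)
  s <- read_spectrum(f)
  expect_equal(s$ppm, c(1, 2))
  expect_equal(s$intensity, c(5, 7))

  writeLines(c("ppm,intensity", "1.0,5.0", "0.5,2.0", "2.0,7.0"), f)
  s <- read_spectrum(f)                      # header skipped, rows re-sorted
  expect_equal(s$ppm, c(0.5, 1, 2))
  expect_equal(s$intensity, c(2, 5, 7))

  writeLines(c("1.0 5.0", "oops bad", "2.0 7.0"), f)
  expect_error(read_spectrum(f), "line 2")
  writeLines(c("1.0 5.0", "1.0 7.0"), f)
  expect_error(read_spectrum(f), "duplicated ppm")
})

test_that("write/read round-trips a rendered spectrum", {
  s <- render_spectrum(default_spectral_library(), c(Succinate = 1.234),
                       axis = seq(2.2, 2.6, by = 2e-4), noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, sample_id = s$sample_id)
  expect_equal(s2$ppm, s$ppm, tolerance = 1e-12)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
})

test_that("acetate referencing shifts the tallest window peak to 1.92 ppm", {
  ax <- seq(1.5, 2.5, by = 2e-4)
  spec_off <- list(metabolite_spec("Acetate", 1.95))
  names(spec_off) <- "Acetate"
  s <- render_spectrum(spec_off, c(Acetate = 1), axis = ax, noise_sd = 0)
  r <- reference_to_acetate(s)
  expect_equal(attr(r, "shift"), -0.03, tolerance = 1e-9)
  expect_equal(r$ppm[which.max(r$intensity)], 1.92, tolerance = 1e-9)
  expect_identical(r$intensity, s$intensity)

  spec_on <- list(metabolite_spec("Acetate", 1.92)); names(spec_on) <- "Acetate"
  s2 <- render_spectrum(spec_on, c(Acetate = 1), axis = ax, noise_sd = 0)
  expect_equal(attr(reference_to_acetate(s2), "shift"), 0, tolerance = 1e-9)

  # two peaks in the window: the taller one wins
  two <- list(metabolite_spec("Acetate", c(1.86, 1.96), areas = c(3, 5)))
  names(two) <- "Acetate"
  s3 <- render_spectrum(two, c(Acetate = 1), axis = ax, noise_sd = 0)
  r3 <- reference_to_acetate(s3)
  expect_equal(attr(r3, "shift"), 1.92 - 1.96, tolerance = 1e-9)

  flat <- toy_spectrum(ax, rep(1, length(ax)))
  expect_warning(rf <- reference_to_acetate(flat), "no peak")
  expect_identical(rf$ppm, flat$ppm)
})

test_that("bucketing sums grid points into half-open anchored buckets", {
  # 10-point toy, width spanning 2 points -> 5 buckets of pairwise sums
  s <- toy_spectrum(seq(1, 1.9, by = 0.1), 1:10)
  b <- bucket(s, width = 0.2, exclude = list())
  expect_equal(unname(b), c(1 + 2, 3 + 4, 5 + 6, 7 + 8, 9 + 10),
               ignore_attr = TRUE)
  expect_equal(attr(b, "centers"), c(1.1, 1.3, 1.5, 1.7, 1.9))

  # constant intensity c with k grid points per bucket -> every bucket = k c
  s2 <- toy_spectrum(seq(0, 0.99, by = 0.01), rep(3, 100))
  b2 <- bucket(s2, width = 0.05, exclude = list())
  expect_true(all(b2 == 5 * 3))
})

test_that("the water region is eliminated and mass is conserved elsewhere", {
  co <- fix_cohort()
  s <- co$spectra[[1]]
  b <- bucket(s)
  centers <- attr(b, "centers")
  expect_false(any(centers >= 4.6 & centers <= 5.0))
  # exact conservation: default bucket edges align with the 4.6/5.0 bounds
  kept_mass <- sum(s$intensity[s$ppm < 4.6 | s$ppm >= 5.0])
  expect_identical(sum(b), kept_mass)
})

test_that("PQN removes dilution and satisfies its toy oracles", {
  mk <- function(values) {
    bt <- fix_table_raw()
    bt$values <- values
    bt$centers <- seq_len(ncol(values))
    bt
  }
  ref <- c(1, 2, 3, 4, 5)
  v <- rbind(ref = ref, s1 = ref, s2 = 3 * ref, s3 = c(2, 4, 6, 8, 10))
  for (est in c("mode", "median")) {
    out <- pqn_normalize(mk(v), reference = ref, estimator = est)
    expect_equal(unname(out$quotients), c(1, 1, 3, 2))
    expect_equal(unname(out$values["s2", ]), ref)
    expect_equal(unname(out$values["s3", ]), ref)   # elementwise oracle
  }
  # all-zero overlap rejected with the sample id
  v2 <- rbind(s1 = ref, bad = c(0, 0, 0, 0, 0))
  expect_error(pqn_normalize(mk(v2), reference = ref), "bad")
})

test_that("PQN is idempotent against a fixed reference", {
  bt <- fix_table_raw()
  ref <- apply(bt$values, 2, median)
  once <- pqn_normalize(bt, reference = ref)
  twice <- pqn_normalize(once, reference = ref)
  expect_equal(unname(twice$quotients), rep(1, nrow(bt$values)),
               tolerance = 1e-12)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("PQN undoes a planted log-normal dilution on noise-free cohorts", {
  d <- cohort_design(groups = c(sham = 4L, sepsis_survivor = 4L),
                     within_cv = 0, dilution_sd = 0.4, noise_sd = 0, seed = 9L)
  co <- generate_cohort(d, water_artifact = FALSE)
  bt <- pqn_normalize(bucket_table(co$spectra))
  v <- bt$values
  for (g in list(1:4, 5:8))                  # same-composition samples agree
    for (i in g[-1]) {
      rel <- abs(v[i, ] - v[g[1], ]) / pmax(abs(v[g[1], ]), 1e-300)
      expect_lt(max(rel[v[g[1], ] != 0]), 1e-8)
    }
})

test_that("scaling centers, unit-scales, and flags degenerate columns", {
  bt <- fix_table_raw()
  ctr <- scale_buckets(bt, "center")
  expect_lt(max(abs(colMeans(ctr$values))), 1e-10)
  uv <- scale_buckets(bt, "center_unit_variance")
  sds <- apply(uv$values, 2, sd)
  expect_equal(unname(sds[sds > 0.5]), rep(1, sum(sds > 0.5)), tolerance = 1e-10)

  small <- bt
  small$values <- cbind(matrix(rnorm(8), 4), constant = rep(7, 4))
  small$centers <- 1:3
  uv2 <- scale_buckets(small, "center_unit_variance")
  expect_true(3L %in% uv2$degenerate)
  expect_equal(unname(uv2$values[, 3]), rep(0, 4))

  one <- bt; one$values <- bt$values[1, , drop = FALSE]
  expect_error(scale_buckets(one), "at least 2")
})

test_that("bucket tables round-trip through CSV with their sidecar", {
  bt <- fix_table_pqn()
  f <- withr::local_tempfile(fileext = ".csv")
  write_bucket_table(bt, f)
  bt2 <- read_bucket_table(f)
  expect_equal(bt2$values, bt$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(bt2$normalization, "pqn")
  expect_equal(unname(bt2$quotients), unname(bt$quotients), tolerance = 1e-10)
})
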