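test_that("rendering handles null input, unknown names and bad values", {
  lib <- default_spectral_library()
  s <- render_spectrum(lib, c(Succinate = 0, Acetate = 0), noise_sd = 0)
  expect_true(all(s$intensity == 0))
  expect_error(render_spectrum(lib, c(NotAMetabolite = 1)), "NotAMetabolite")
  expect_error(render_spectrum(lib, c(Succinate = -1)), "negative concentration")
  expect_error(render_spectrum(lib, c(Succinate = 1),
                               axis = seq(0.5, 10, by = 0.001)), "step")
})

test_that("a lone succinate resonance peaks at 2.41 ppm and is symmetric", {
  s <- render_spectrum(default_spectral_library(), c(Succinate = 1),
                       noise_sd = 0)
  apex <- s$ppm[which.max(s$intensity)]
  expect_equal(apex, 2.41)
  left <- s$intensity[s$ppm >= 2.40 & s$ppm < 2.41]
  right <- rev(s$intensity[s$ppm > 2.41 & s$ppm <= 2.42])
  expect_equal(left, right, tolerance = 1e-9)
})

test_that("peak areas are linear in concentration and match the analytic area", {
  lib <- default_spectral_library()
  h <- 0.00025
  s1 <- render_spectrum(lib, c(Succinate = 1), noise_sd = 0)
  s2 <- render_spectrum(lib, c(Succinate = 2), noise_sd = 0)
  trapz <- function(s) sum((s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2) * h
  expect_equal(trapz(s2) / trapz(s1), 2, tolerance = 1e-6)
  analytic <- lorentzian_area(2.41, lib$Succinate$linewidth, 1,
                              from = 0.5, to = 10)
  expect_lt(abs(sum(s1$intensity) * h - analytic) / analytic, 1e-6)
})

test_that("dilution is a pure multiplicative factor", {
  lib <- default_spectral_library()
  conc <- c(Succinate = 1, Glucose = 3, Acetate = 0.5)
  base <- render_spectrum(lib, conc, noise_sd = 0, dilution = 1)
  dil <- render_spectrum(lib, conc, noise_sd = 0, dilution = 2.5)
  expect_equal(dil$intensity / 2.5, base$intensity, tolerance = 1e-12)
})

test_that("the water artifact is confined to the suppressed region", {
  lib <- default_spectral_library()
  dry <- render_spectrum(lib, c(Succinate = 1), noise_sd = 0)
  wet <- render_spectrum(lib, c(Succinate = 1), noise_sd = 0,
                         water_artifact = TRUE)
  delta <- wet$intensity - dry$intensity
  expect_equal(wet$ppm[which.max(delta)], 4.8)
  expect_lt(max(delta[dry$ppm < 4.5 | dry$ppm > 5.1]) / max(delta), 0.01)
})

test_that("cohort generation is a pure function of design and seed", {
  d <- cohort_design(groups = c(sham = 2L, sepsis_survivor = 2L), seed = 11L)
  a <- generate_cohort(d); b <- generate_cohort(d)
  expect_identical(a, b)
  expect_error(cohort_design(groups = c(mystery_group = 3L)), "unknown group")
  expect_error(cohort_design(group_effects = list(sham = c(Maltose = -1))),
               "strictly positive")
})

test_that("degenerate variance collapses a group to identical spectra", {
  d <- cohort_design(groups = c(sham = 3L), within_cv = 0, dilution_sd = 0,
                     noise_sd = 0, seed = 3L)
  co <- generate_cohort(d)
  expect_identical(co$spectra[[1]]$intensity, co$spectra[[2]]$intensity)
  expect_identical(co$spectra[[2]]$intensity, co$spectra[[3]]$intensity)
})

test_that("the default cohort plants the reported succinate sign", {
  co <- fix_cohort()
  bt <- fix_table_raw()
  succ <- which.min(abs(bt$centers - 2.4105))
  m <- tapply(bt$values[, succ], co$metadata$group, mean)
  # survivor succinate below sham: the sign behind the reported R = -0.708
  expect_lt(m[["sepsis_survivor"]], m[["sham"]])
})
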