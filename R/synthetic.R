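#' Render one synthetic 1H-NMR spectrum
#'
#' Builds a frequency-domain trace on a uniform ppm grid as a sum of Lorentzian
#' resonances:
#' `intensity = dilution * sum_m conc_m * sum_k area_mk * L(center_mk, fwhm) +
#' noise`, optionally plus a broad Gaussian water-suppression artifact centred
#' at 4.8 ppm. Peak areas are exactly linear in concentration and the dilution
#' factor multiplies the whole metabolite signal, which is what probabilistic
#' quotient normalization assumes and must undo.
#'
#' @param specs list of [metabolite_spec()] objects.
#' @param concentrations named non-negative numeric vector; names must be a
#'   subset of the spec names. Metabolites absent from the vector default to 0.
#' @param axis strictly increasing uniform ppm grid with step at most
#'   0.0005 ppm (finer than the 0.001-ppm bucket width).
#' @param noise_sd standard deviation of additive Gaussian baseline noise, in
#'   intensity units; 0 gives a noise-free trace.
#' @param dilution positive per-sample multiplicative dilution factor.
#' @param water_artifact logical; add a broad Gaussian artifact (height
#'   `water_height`, sd 0.07 ppm) at 4.8 ppm, inside the 4.6--5.0 ppm region
#'   excluded at bucketing time.
#' @param water_height artifact apex height (intensity units).
#' @param sample_id identifier stored on the returned spectrum.
#' @return an `nmr_spectrum` object (see [read_spectrum()]).
#' @examples
#' s <- render_spectrum(default_spectral_library(),
#'                      c(Succinate = 1), noise_sd = 0)
#' s$ppm[which.max(s$intensity)]  # 2.41
#' @export
render_spectrum <- function(specs, concentrations, axis = default_axis(),
                            noise_sd = 0, dilution = 1,
                            water_artifact = FALSE, water_height = 2000,
                            sample_id = "sample") {
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  step <- diff(axis)
  if (length(axis) < 2L || any(step <= 0))
    stop_fly("axis must be strictly increasing")
  if (max(step) > 0.0005 + 1e-12)
    stop_fly("axis step must be <= 0.0005 ppm (got %.6g)", max(step))
  concentrations <- unlist(concentrations)
  unknown <- setdiff(names(concentrations), names(specs))
  if (length(unknown))
    stop_fly("unknown metabolite(s) in concentrations: %s",
             paste(unknown, collapse = ", "))
  if (any(concentrations < 0))
    stop_fly("negative concentration for: %s",
             paste(names(concentrations)[concentrations < 0], collapse = ", "))
  if (!is.finite(dilution) || dilution <= 0)
    stop_fly("dilution must be a positive finite scalar")

  intensity <- numeric(length(axis))
  for (m in names(concentrations)) {
    conc <- concentrations[[m]]
    if (conc == 0) next
    sp <- specs[[m]]
    gamma <- sp$linewidth / 2  # FWHM -> half width at half maximum
    rng <- range(axis)
    for (k in seq_along(sp$centers)) {
      ctr <- sp$centers[k]
      if (ctr < rng[1] || ctr > rng[2])
        stop_fly("metabolite '%s': peak at %.4g ppm outside axis range", m, ctr)
      intensity <- intensity +
        conc * sp$areas[k] * (gamma / pi) / ((axis - ctr)^2 + gamma^2)
    }
  }
  intensity <- dilution * intensity
  if (isTRUE(water_artifact))
    intensity <- intensity + water_height * exp(-((axis - 4.8)^2) / (2 * 0.07^2))
  if (noise_sd > 0)
    intensity <- intensity + rnorm(length(axis), 0, noise_sd)
  if (any(!is.finite(intensity)))
    stop_fly("rendered spectrum contains non-finite intensities")
  nmr_spectrum(axis, intensity, sample_id)
}

#' Describe a synthetic cohort
#'
#' Captures everything the generator needs: group sizes, baseline
#' concentrations, per-group multiplicative fold-changes, within-group
#' biological spread, per-sample dilution spread, spectral noise, and the seed.
#' Defaults emulate the fly sepsis-survival design: three groups of ten pooled
#' 50-fly extracts, carbohydrate-dominated spectra, survivor effects planted
#' with the reported signs.
#'
#' @param groups named integer vector, label -> number of samples; labels must
#'   come from [GROUP_LEVELS]. Designs intended for modelling need >= 2 per
#'   group.
#' @param base_concentrations named numeric vector (arbitrary units).
#' @param group_effects named list (group -> named fold-change vector);
#'   fold-changes must be strictly positive. Groups/metabolites not listed
#'   default to 1.
#' @param within_cv log-scale sd of per-sample, per-metabolite biological
#'   variation (default 0.1: pooled extracts are less variable than single
#'   flies).
#' @param dilution_sd log-scale sd of the per-sample dilution factor
#'   (log-normal, median 1); exercises PQN's multiplicative-error assumption.
#' @param noise_sd additive spectral noise sd (intensity units).
#' @param seed integer RNG seed; mandatory for reproducible cohorts.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(unmanipulated = 10L, sham = 10L,
                                     sepsis_survivor = 10L),
                          base_concentrations = default_base_concentrations(),
                          group_effects = default_group_effects(),
                          within_cv = 0.1, dilution_sd = 0.15, noise_sd = 5,
                          seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_fly("groups must be a named vector (label -> n_samples)")
  bad <- setdiff(names(groups), GROUP_LEVELS)
  if (length(bad))
    stop_fly("unknown group label(s): %s (allowed: %s)",
             paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", "))
  groups <- vapply(groups, as.integer, integer(1))
  if (any(groups < 1L)) stop_fly("each group needs at least one sample")
  for (g in names(group_effects)) {
    fx <- group_effects[[g]]
    if (any(!is.finite(fx)) || any(fx <= 0))
      stop_fly("group '%s': fold-changes must be strictly positive", g)
    if (length(setdiff(names(fx), names(base_concentrations))))
      stop_fly("group '%s': fold-change for unknown metabolite", g)
  }
  stopifnot(within_cv >= 0, dilution_sd >= 0, noise_sd >= 0)
  structure(list(groups = groups,
                 base_concentrations = base_concentrations,
                 group_effects = group_effects,
                 within_cv = within_cv, dilution_sd = dilution_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Null (no-effect) cohort design
#'
#' Same world as [cohort_design()] but with all fold-changes equal to 1, so the
#' group labels carry no information. Used for permutation-test calibration.
#' @param groups named integer vector of group sizes.
#' @param seed integer seed.
#' @param ... passed to [cohort_design()].
#' @export
null_cohort_design <- function(groups = c(sham = 8L, sepsis_survivor = 8L),
                               seed = 1L, ...) {
  cohort_design(groups = groups, group_effects = list(), seed = seed, ...)
}

#' Generate a synthetic cohort of spectra
#'
#' Deterministic for a fixed design seed (the caller's RNG state is restored).
#' Per-sample concentrations are
#' `base * fold(group) * exp(N(0, within_cv))`; the per-sample dilution is
#' log-normal with sd `dilution_sd` and median 1.
#'
#' @param design a [cohort_design()].
#' @param library list of [metabolite_spec()]s (default
#'   [default_spectral_library()]).
#' @param axis simulated ppm grid.
#' @param water_artifact add the broad 4.8-ppm artifact (default TRUE, so the
#'   water-exclusion step is consequential).
#' @return list with elements `spectra` (list of `nmr_spectrum`) and
#'   `metadata` (data.frame: sample_id, group).
#' @export
generate_cohort <- function(design, library = default_spectral_library(),
                            axis = default_axis(), water_artifact = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    base <- design$base_concentrations
    mets <- names(base)
    spectra <- list()
    ids <- character(0); grp <- character(0)
    for (g in names(design$groups)) {
      fold <- rep(1, length(mets)); names(fold) <- mets
      fx <- design$group_effects[[g]]
      if (!is.null(fx)) fold[names(fx)] <- fx
      for (i in seq_len(design$groups[[g]])) {
        id <- sprintf("%s_%02d", g, i)
        conc <- base * fold
        if (design$within_cv > 0)
          conc <- conc * exp(rnorm(length(mets), 0, design$within_cv))
        dil <- if (design$dilution_sd > 0) exp(rnorm(1, 0, design$dilution_sd)) else 1
        spectra[[id]] <- render_spectrum(
          library, conc, axis = axis, noise_sd = design$noise_sd,
          dilution = dil, water_artifact = water_artifact, sample_id = id)
        ids <- c(ids, id); grp <- c(grp, g)
      }
    }
    list(spectra = spectra,
         metadata = data.frame(sample_id = ids, group = grp,
                               stringsAsFactors = FALSE))
  })
}

#' Write a cohort to disk
#'
#' One two-column text file per spectrum plus a `metadata.csv`
#' (sample_id, group).
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$spectra)
    write_spectrum(s, file.path(dir, paste0(s$sample_id, ".txt")))
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Analytic area of a rendered Lorentzian peak over a finite window
#'
#' Closed-form integral of the rendered lineshape, used as the independent
#' oracle for the area-linearity property of [render_spectrum()].
#' @param center,fwhm peak position and full width at half maximum (ppm).
#' @param area nominal (full-line) peak area.
#' @param from,to integration window (ppm).
#' @return numeric scalar.
#' @export
lorentzian_area <- function(center, fwhm, area = 1, from = -Inf, to = Inf) {
  gamma <- fwhm / 2
  area / pi * (atan((to - center) / gamma) - atan((from - center) / gamma))
}
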