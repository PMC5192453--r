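#' Construct a metabolite lineshape specification
#'
#' A `metabolite_spec` describes how one metabolite appears in a simulated 1D
#' proton spectrum: one to a few Lorentzian resonances, each with a chemical
#' shift (ppm) and a relative area, plus a shared linewidth (FWHM, ppm).
#' J-coupling fine structure is deliberately not modelled: at 0.001-ppm buckets
#' and the default 0.003-ppm linewidth it is immaterial to the downstream
#' statistics.
#'
#' @param name metabolite name; must match the chemical-shift library so that
#'   rendered peaks land inside the assignment regions.
#' @param centers numeric vector of peak positions (ppm).
#' @param areas relative peak areas, recycled to `length(centers)`; default
#'   equal areas. A rendered peak's absolute area is `concentration * area`.
#' @param linewidth full width at half maximum in ppm (> 0).
#' @return an object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, centers, areas = 1, linewidth = 0.003) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  centers <- as.numeric(centers)
  if (length(centers) < 1L || anyNA(centers))
    stop_fly("metabolite '%s': at least one finite peak center required", name)
  areas <- rep_len(as.numeric(areas), length(centers))
  if (any(!is.finite(areas)) || any(areas < 0) || sum(areas) <= 0)
    stop_fly("metabolite '%s': relative areas must be >= 0 and sum to a positive number", name)
  if (!is.finite(linewidth) || linewidth <= 0)
    stop_fly("metabolite '%s': linewidth must be > 0", name)
  structure(list(name = name, centers = centers, areas = areas,
                 linewidth = linewidth),
            class = "metabolite_spec")
}

#' @export
print.metabolite_spec <- function(x, ...) {
  cat(sprintf("<metabolite_spec> %s: %d peak(s) at %s ppm, FWHM %.4g ppm\n",
              x$name, length(x$centers),
              paste(format(x$centers), collapse = ", "), x$linewidth))
  invisible(x)
}

#' Default simulated ppm axis
#'
#' 0.5 to 10 ppm in 0.00025-ppm steps (four grid points per 0.001-ppm bucket),
#' covering the displayed aliphatic/carbohydrate window plus the aromatic
#' signals (tyrosine, histidine).
#' @return strictly increasing numeric vector.
#' @export
default_axis <- function() seq(0.5, 10, by = 0.00025)

#' Default spectral library for the fly-extract simulator
#'
#' One `metabolite_spec` per row of the packaged chemical-shift table. Rows
#' listing a shift range (the crowded carbohydrate region) are represented by
#' up to three singlet-like peaks placed inside the range; point shifts are
#' used as given. Relative areas are equal within a metabolite.
#' @return named list of `metabolite_spec` objects.
#' @export
default_spectral_library <- function() {
  specs <- list(
    metabolite_spec("Fatty acid",                c(0.90, 1.28)),
    metabolite_spec("Leucine/Isoleucine/Valine", c(0.99, 1.04)),
    metabolite_spec("Lactate",                   1.33),
    metabolite_spec("Alanine",                   1.48),
    metabolite_spec("Acetate",                   1.92),
    metabolite_spec("Glutamine + Glutamate",     c(2.03, 2.16, 2.34)),
    metabolite_spec("Succinate",                 2.41),
    metabolite_spec("Beta-alanine",              2.56),
    metabolite_spec("Dimethylamine",             2.75),
    metabolite_spec("Lysine",                    3.01),
    metabolite_spec("Choline",                   3.22),
    metabolite_spec("Glucose",                   c(3.45, 3.75, 5.23)),
    metabolite_spec("Maltose",                   c(3.65, 4.45, 5.42)),
    metabolite_spec("Glycerol",                  c(4.10, 4.15)),
    metabolite_spec("Tyrosine",                  c(6.89, 7.20)),
    metabolite_spec("Methyl-histidine",          7.12),
    metabolite_spec("Histidine",                 7.94)
  )
  specs <- c(specs, background_specs())
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Unassigned background resonances: stand-ins for the many minor compounds of
# a whole-organism extract. They carry no group information (never planted,
# absent from the assignment library) but they anchor quotient normalization:
# PQN assumes that the majority of signal-bearing variables is unchanged
# between samples, which in real crowded spectra is guaranteed by exactly this
# background. Positions form a fixed 0.08-ppm comb over the sweep width,
# skipping the water region and a guard band around every library point
# shift.
background_positions <- function() {
  pos <- seq(0.55, 9.55, by = 0.08)
  lib_pts <- c(0.90, 1.28, 0.99, 1.04, 1.33, 1.48, 1.92, 2.03, 2.16, 2.34,
               2.41, 2.56, 2.75, 3.01, 3.22, 4.10, 4.15, 4.45, 4.62, 5.23,
               5.42, 6.89, 7.12, 7.20, 7.94)
  near_lib <- vapply(pos, function(p) any(abs(p - lib_pts) < 0.025), logical(1))
  in_water <- pos > 4.55 & pos < 5.05
  pos[!near_lib & !in_water]
}

background_specs <- function() {
  pos <- background_positions()
  lapply(seq_along(pos), function(i)
    metabolite_spec(sprintf("background_%02d", i), pos[i]))
}

#' Default baseline concentrations (arbitrary units)
#'
#' Levels for the unmanipulated group. Disaccharide and glucose pools dominate,
#' reproducing spectra dominated by carbohydrate resonances between roughly
#' 3.05 and 4.0 ppm.
#' @return named numeric vector.
#' @export
default_base_concentrations <- function() {
  npos <- length(background_positions())
  bg <- rep(c(5, 7, 9), length.out = npos)
  names(bg) <- sprintf("background_%02d", seq_len(npos))
  c("Fatty acid" = 8, "Leucine/Isoleucine/Valine" = 6, "Lactate" = 10,
    "Alanine" = 12, "Acetate" = 8, "Glutamine + Glutamate" = 15,
    "Succinate" = 6, "Beta-alanine" = 5, "Dimethylamine" = 3,
    "Lysine" = 5, "Choline" = 5, "Glucose" = 60, "Maltose" = 80,
    "Glycerol" = 10, "Tyrosine" = 4, "Methyl-histidine" = 2, "Histidine" = 3,
    bg)
}

#' Default planted group effects
#'
#' Multiplicative fold-changes relative to the unmanipulated baseline. Signs
#' follow the reported group contrasts: sham flies lose maltose, alanine and
#' glutamine/glutamate and gain choline (dimethylamine drops); sepsis survivors
#' additionally lose glucose, maltose, succinate, beta-alanine, acetate,
#' glutamine/glutamate and tyrosine relative to sham. Magnitudes are a design
#' choice (the source reports only correlation signs), fixed once and
#' documented in the methods vignette.
#' @return named list of named numeric vectors, one per non-baseline group.
#' @export
default_group_effects <- function() {
  sham <- c("Maltose" = 0.70, "Alanine" = 0.70, "Glutamine + Glutamate" = 0.75,
            "Choline" = 1.40, "Dimethylamine" = 0.75)
  survivor <- c(
    "Glucose" = 0.55,
    "Maltose" = 0.70 * 0.55,               # sham loss compounded by sepsis loss
    "Succinate" = 0.60,
    "Beta-alanine" = 0.60,
    "Acetate" = 0.65,
    "Glutamine + Glutamate" = 0.75 * 0.60,
    "Tyrosine" = 0.60,
    "Alanine" = 0.70,                      # matches sham: not discriminant
    "Choline" = 1.40,
    "Dimethylamine" = 0.75)
  list(sham = sham, sepsis_survivor = survivor)
}

#' Metabolites carrying a planted sham-vs-survivor effect
#'
#' The seven metabolites whose survivor fold-change differs from sham in the
#' default design; the discriminant-selection stage is expected to recover
#' exactly this set.
#' @return character vector.
#' @export
planted_discriminant_set <- function() {
  c("Glucose", "Maltose", "Succinate", "Beta-alanine", "Acetate",
    "Glutamine + Glutamate", "Tyrosine")
}
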