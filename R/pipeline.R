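#' Assemble a pipeline configuration
#'
#' Defaults mirror the published workflow: 0.001-ppm buckets, water exclusion
#' 4.6--5.0 ppm, PQN then mean-centering with unit-variance scaling, a 3-group
#' PLS overview model, pairwise OPLS contrasts (1 orthogonal component for
#' unmanipulated-vs-sham, 2 for sham-vs-survivor, i.e. the reported "two" and
#' "three component" models), 999 permutations, and an inclusive |R| >= 0.5
#' discriminant threshold.
#'
#' @param design a [cohort_design()] used when `spectra_dir` is NULL.
#' @param spectra_dir optional directory of measured spectra + `metadata.csv`;
#'   overrides simulation.
#' @param width,exclude bucketing parameters.
#' @param scaling scaling method for model fitting.
#' @param contrasts list of 2-vectors `c(negative, positive)`.
#' @param n_orthogonal integer vector, one per contrast.
#' @param n_permutations permutation count for validation.
#' @param threshold inclusive |R| cutoff for discriminant metabolites.
#' @param reference_acetate logical: calibrate each spectrum on the 1.92-ppm
#'   acetate singlet before bucketing (off by default; synthetic axes are
#'   exact).
#' @param seed master seed; cohort and permutation seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            spectra_dir = NULL,
                            width = 0.001,
                            exclude = list(c(4.6, 5.0)),
                            scaling = "center_unit_variance",
                            contrasts = list(c("unmanipulated", "sham"),
                                             c("sham", "sepsis_survivor")),
                            n_orthogonal = c(1L, 2L),
                            n_permutations = 999L,
                            threshold = 0.5,
                            reference_acetate = FALSE,
                            seed = 1L) {
  stopifnot(width > 0, threshold >= 0, length(n_orthogonal) == length(contrasts))
  structure(list(design = design, spectra_dir = spectra_dir, width = width,
                 exclude = exclude, scaling = scaling, contrasts = contrasts,
                 n_orthogonal = as.integer(n_orthogonal),
                 n_permutations = as.integer(n_permutations),
                 threshold = threshold,
                 reference_acetate = isTRUE(reference_acetate),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_as_list <- function(cfg) {
  list(width = cfg$width, exclude = cfg$exclude, scaling = cfg$scaling,
       contrasts = cfg$contrasts, n_orthogonal = cfg$n_orthogonal,
       n_permutations = cfg$n_permutations, threshold = cfg$threshold,
       reference_acetate = cfg$reference_acetate, seed = cfg$seed,
       design = if (!is.null(cfg$design)) unclass(cfg$design))
}

#' Run the full analysis pipeline
#'
#' `simulate (or read) -> bucket -> PQN -> scale -> PCA screen -> PLS
#' (all groups) -> OPLS per contrast -> permutation + CV-ANOVA validation ->
#' correlation loadings -> discriminant selection -> pathway mapping ->
#' report`. Every numeric output is reproducible from config + seed; the run
#' directory receives the resolved config, a manifest with file hashes, CSV/
#' JSON artifacts and SVG score/loading plots. A stage failure halts the run,
#' leaving partial outputs and a `FAILED` marker naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; contents overwritten).
#' @param library chemical-shift library for annotation.
#' @param network metabolic network for pathway mapping.
#' @return invisibly, a list with the bucket table, models, validation
#'   reports, discriminant table, pathway report and manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         library = load_library(),
                         network = load_network()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop_fly("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  tryCatch({
    unlink(file.path(out_dir, "FAILED"))
    jsonlite::write_json(config_as_list(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

    stage <- "input"
    cohort <- if (!is.null(config$spectra_dir)) read_cohort(config$spectra_dir)
              else {
                design <- config$design
                design$seed <- derive_seed(config$seed, 1L)
                generate_cohort(design)
              }
    meta <- cohort$metadata
    spectra <- cohort$spectra
    if (config$reference_acetate)
      spectra <- lapply(spectra, reference_to_acetate)

    stage <- "preprocess"
    bt_raw <- bucket_table(spectra, width = config$width, exclude = config$exclude)
    bt <- pqn_normalize(bt_raw)
    bt_scaled <- scale_buckets(bt, config$scaling)
    write_bucket_table(bt, file.path(out_dir, "table.csv"))
    data.table::fwrite(meta, file.path(out_dir, "metadata.csv"))

    stage <- "pca"
    pca <- fit_pca(bt_scaled, n_components = min(3L, nrow(bt$values) - 1L))
    grDevices::svg(file.path(out_dir, "pca_scores.svg"), width = 6, height = 5)
    plot_scores(pca, meta$group, main = "PCA score plot")
    grDevices::dev.off()

    stage <- "pls_all_groups"
    models <- list(); reports <- list()
    pls_model <- fit_pls(bt_scaled, meta$group, n_components = 2L)
    pls_model$Q2Y <- q2y_loo(bt, meta$group, kind = "pls", n_components = 2L,
                             scaling = config$scaling)$q2y
    reports$pls_all_groups <- permutation_test(
      bt, meta$group, kind = "pls", n_components = 2L,
      n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, 2L), scaling = config$scaling)
    models$pls_all_groups <- pls_model

    stage <- "opls_contrasts"
    profiles <- list()
    for (ci in seq_along(config$contrasts)) {
      ctr <- config$contrasts[[ci]]
      nm <- paste(ctr, collapse = "_vs_")
      sel <- meta$group %in% ctr
      y <- contrast_response(meta$group[sel], ctr)
      sub_raw <- bt; sub_raw$values <- bt$values[sel, , drop = FALSE]
      sub_scaled <- scale_buckets(sub_raw, config$scaling)
      m <- fit_opls(sub_scaled, y, n_orthogonal = config$n_orthogonal[ci])
      m$Q2Y <- q2y_loo(sub_raw, y, kind = "opls",
                       n_orthogonal = config$n_orthogonal[ci],
                       scaling = config$scaling)$q2y
      reports[[nm]] <- permutation_test(
        sub_raw, y, kind = "opls", n_orthogonal = config$n_orthogonal[ci],
        n_permutations = config$n_permutations,
        seed = derive_seed(config$seed, 10L + ci), scaling = config$scaling)
      models[[nm]] <- m
      profiles[[nm]] <- correlation_loadings(sub_raw, y)

      mdir <- file.path(out_dir, nm)
      dir.create(mdir, showWarnings = FALSE)
      data.table::fwrite(data.table::data.table(
        sample_id = meta$sample_id[sel], group = meta$group[sel],
        t_pred = m$T_pred[, 1L],
        t_orth1 = if (m$n_orthogonal >= 1L) m$T_orth[, 1L] else NA_real_),
        file.path(mdir, "scores.csv"))
      data.table::fwrite(profiles[[nm]], file.path(mdir, "loadings.csv"))
      grDevices::svg(file.path(mdir, "scores.svg"), width = 6, height = 5)
      plot_scores(m, meta$group[sel], main = paste("OPLS:", nm))
      grDevices::dev.off()
      grDevices::svg(file.path(mdir, "loadings.svg"), width = 8, height = 4)
      plot_loadings(profiles[[nm]], main = paste("Loadings:", nm))
      grDevices::dev.off()
    }

    stage <- "annotate"
    last <- paste(config$contrasts[[length(config$contrasts)]], collapse = "_vs_")
    disc <- select_discriminant(profiles[[last]], library,
                                threshold = config$threshold)
    data.table::fwrite(disc, file.path(out_dir, "discriminant.csv"))

    stage <- "pathways"
    detected <- disc$metabolite
    discriminant <- disc$metabolite[disc$selected]
    pw <- suppressWarnings(map_metabolites(network, detected, discriminant))
    data.table::fwrite(pw, file.path(out_dir, "pathways.csv"))
    network_to_dot(extract_subnetwork(network, discriminant),
                   attr(pw, "node_states"),
                   path = file.path(out_dir, "subnetwork.dot"))

    stage <- "report"
    summaries <- lapply(names(models), function(nm) {
      m <- models[[nm]]; r <- reports[[nm]]
      list(model = nm, kind = m$kind,
           n_predictive = m$n_predictive, n_orthogonal = m$n_orthogonal,
           R2Y = m$R2Y, Q2Y = m$Q2Y,
           permutation_percentile_99 = r$percentile_99,
           permutation_p = r$p_value, passes = r$passes,
           cv_anova_p = r$cv_anova_p, n_permutations = r$n_permutations)
    })
    names(summaries) <- names(models)
    jsonlite::write_json(summaries, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- setdiff(list.files(out_dir, recursive = TRUE),
                     c("manifest.json", "report.md"))
    manifest <- list(
      package = "flynmr",
      version = as.character(utils::packageVersion("flynmr")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      n_models = length(models),
      hashes = as.list(tools::md5sum(file.path(out_dir, files))))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report_md(out_dir, summaries, disc, pw)

    invisible(list(table = bt, models = models, reports = reports,
                   profiles = profiles, discriminant = disc, pathways = pw,
                   manifest = manifest, metadata = meta))
  }, error = on_fail)
}

write_report_md <- function(out_dir, summaries, disc, pw) {
  lines <- c("# flynmr run report", "",
             "## Models", "",
             "| model | R2Y | Q2Y | perm 99th pct | perm p | CV-ANOVA p | accepted |",
             "|---|---|---|---|---|---|---|")
  for (s in summaries)
    lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.3f | %.4g | %.4g | %s |",
                              s$model, s$R2Y, s$Q2Y, s$permutation_percentile_99,
                              s$permutation_p, s$cv_anova_p, s$passes))
  lines <- c(lines, "", "## Discriminant metabolites (|R| >= threshold)", "")
  sel <- disc[disc$selected, ]
  lines <- c(lines,
             if (nrow(sel)) sprintf("- %s (R = %.3f at %.4f ppm)",
                                    sel$metabolite, sel$r, sel$center)
             else "- none")
  lines <- c(lines, "", "## Top pathways", "",
             utils::capture.output(print(utils::head(pw, 5))))
  writeLines(lines, file.path(out_dir, "report.md"))
}
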