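#' Construct a frequency-domain spectrum
#'
#' @param ppm strictly increasing chemical-shift grid.
#' @param intensity finite intensities, same length as `ppm`.
#' @param sample_id identifier.
#' @return object of class `nmr_spectrum`: list(ppm, intensity, sample_id).
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop_fly("ppm and intensity lengths differ (%d vs %d)",
             length(ppm), length(intensity))
  if (length(ppm) && is.unsorted(ppm, strictly = TRUE))
    stop_fly("ppm axis must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop_fly("intensities must be finite")
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.4g..%.4g ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read a spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-separated files with at least two numeric
#' columns (ppm, intensity). A single leading non-numeric header line is
#' skipped. Rows are re-sorted by ppm if needed; duplicated ppm values and
#' non-numeric data rows are rejected with the offending line number.
#'
#' @param path file path.
#' @param sample_id identifier; defaults to the file name without extension.
#' @return an `nmr_spectrum`.
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_fly("no such file: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_fly("%s: empty file", path)
  tokens <- strsplit(trimws(lines), "[,;[:space:]]+")
  first <- suppressWarnings(as.numeric(tokens[[1L]]))
  if (anyNA(first)) {           # header line
    tokens <- tokens[-1L]; lineno <- lineno[-1L]
    if (!length(tokens)) stop_fly("%s: no data rows", path)
  }
  ncols <- lengths(tokens)
  if (any(ncols < 2L))
    stop_fly("%s: line %d has fewer than 2 columns", path, lineno[which(ncols < 2L)[1L]])
  vals <- suppressWarnings(lapply(tokens, function(tk) as.numeric(tk[1:2])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop_fly("%s: non-numeric row at line %d", path, lineno[bad[1L]])
  m <- do.call(rbind, vals)
  if (anyDuplicated(m[, 1L]))
    stop_fly("%s: duplicated ppm values", path)
  o <- order(m[, 1L])
  nmr_spectrum(m[o, 1L], m[o, 2L], sample_id)
}

#' Write a spectrum as two-column text
#'
#' Full double precision (15 significant digits), space separated; round-trips
#' through [read_spectrum()] to within text precision.
#' @param s an `nmr_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  data.table::fwrite(data.table::data.table(ppm = s$ppm, intensity = s$intensity),
                     path, sep = " ", col.names = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `*.txt` spectra and `metadata.csv`.
#' @return list(spectra, metadata) as in [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop_fly("no metadata.csv in %s", dir)
  metadata <- as.data.frame(data.table::fread(meta_path))
  spectra <- lapply(metadata$sample_id, function(id)
    read_spectrum(file.path(dir, paste0(id, ".txt")), sample_id = id))
  names(spectra) <- metadata$sample_id
  list(spectra = spectra, metadata = metadata)
}
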