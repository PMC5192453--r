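#' Load a metabolite chemical-shift library
#'
#' CSV with columns `name`, `regions`, `label`. `regions` is a
#' semicolon-separated list of point shifts (`"2.41"`) and intervals
#' (`"3.23-4.0"`), in ppm. Point shifts are matched with a +/- `tolerance`
#' window at assignment time; intervals are used as given. Duplicate names
#' have their regions merged with a warning; malformed rows are rejected with
#' their row number. The packaged fixture `table1_library.csv` carries the
#' assignments of the study's shift table (peak numbers are the figure
#' labels).
#'
#' @param path CSV path; default: the packaged fixture.
#' @param tolerance half-width (ppm) of the window around point shifts,
#'   default 0.005 (five 0.001-ppm buckets each side).
#' @return object of class `metabolite_library`: `entries` (list of
#'   name/points/intervals/label), `tolerance`.
#' @export
load_library <- function(path = system.file("extdata", "table1_library.csv",
                                            package = "flynmr"),
                         tolerance = 0.005) {
  dt <- data.table::fread(path, colClasses = "character")
  if (nrow(dt) == 0L)
    return(structure(list(entries = list(), tolerance = tolerance),
                     class = "metabolite_library"))
  need <- c("name", "regions")
  if (!all(need %in% names(dt)))
    stop_fly("library file needs columns: %s", paste(need, collapse = ", "))
  entries <- list()
  for (i in seq_len(nrow(dt))) {
    nm <- dt$name[i]
    toks <- trimws(strsplit(dt$regions[i], ";")[[1]])
    toks <- toks[nzchar(toks)]
    if (!nzchar(nm) || !length(toks))
      stop_fly("malformed library row %d", i)
    points <- numeric(0); intervals <- list()
    for (tk in toks) {
      parts <- suppressWarnings(as.numeric(strsplit(tk, "-", fixed = TRUE)[[1]]))
      if (length(parts) == 1L && !anyNA(parts)) {
        points <- c(points, parts)
      } else if (length(parts) == 2L && !anyNA(parts)) {
        if (parts[1] > parts[2])
          stop_fly("malformed library row %d: interval bounds out of order", i)
        intervals <- c(intervals, list(parts))
      } else stop_fly("malformed library row %d: cannot parse region '%s'", i, tk)
    }
    allv <- c(points, unlist(intervals))
    if (any(allv < 0 | allv > 10))
      stop_fly("malformed library row %d: shifts outside 0-10 ppm", i)
    if (nm %in% names(entries)) {
      warn_fly("duplicate library entry '%s': regions merged", nm)
      entries[[nm]]$points <- sort(unique(c(entries[[nm]]$points, points)))
      entries[[nm]]$intervals <- c(entries[[nm]]$intervals, intervals)
    } else {
      entries[[nm]] <- list(name = nm, points = points, intervals = intervals,
                            label = if ("label" %in% names(dt)) dt$label[i] else NA_character_)
    }
  }
  structure(list(entries = entries, tolerance = tolerance),
            class = "metabolite_library")
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf("<metabolite_library> %d metabolites, point tolerance +/- %.3g ppm\n",
              length(x$entries), x$tolerance))
  invisible(x)
}

# All matching windows of a library entry as closed ppm intervals.
entry_intervals <- function(entry, tolerance) {
  c(lapply(entry$points, function(p) c(p - tolerance, p + tolerance)),
    entry$intervals)
}

#' Write a metabolite library back to CSV
#'
#' Inverse of [load_library()]: point shifts are written as points (not as
#' expanded windows), so load -> write -> load is the identity.
#' @param library a `metabolite_library`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  fmt <- function(x) sub("\\.$", "", sub("0+$", "", sprintf("%.10f", x))) # trim
  rows <- lapply(library$entries, function(e) {
    regions <- c(vapply(e$points, fmt, character(1)),
                 vapply(e$intervals, function(iv)
                   paste0(fmt(iv[1]), "-", fmt(iv[2])), character(1)))
    data.frame(name = e$name, regions = paste(regions, collapse = ";"),
               label = e$label)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Assign buckets to metabolites
#'
#' Every bucket center is matched against every library region (point windows
#' and intervals, closed bounds); buckets in overlapping regions (for example
#' the shared glucose/maltose 3.5--4.0 ppm band) carry multiple names, and
#' unmatched buckets map to an empty set. Enlarging the tolerance never
#' removes an assignment.
#'
#' @param library a `metabolite_library`.
#' @param centers sorted numeric vector of bucket centers (ppm).
#' @param tolerance overrides the library's point tolerance if given.
#' @return list, parallel to `centers`, of character vectors of metabolite
#'   names (possibly empty).
#' @export
assign_buckets <- function(library, centers, tolerance = NULL) {
  stopifnot(inherits(library, "metabolite_library"))
  tolerance <- tolerance %||% library$tolerance
  out <- vector("list", length(centers))
  for (i in seq_along(out)) out[[i]] <- character(0)
  for (e in library$entries) {
    for (iv in entry_intervals(e, tolerance)) {
      hit <- which(centers >= iv[1] & centers <= iv[2])
      for (i in hit) out[[i]] <- unique(c(out[[i]], e$name))
    }
  }
  names(out) <- sprintf("%.4f", centers)
  out
}
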