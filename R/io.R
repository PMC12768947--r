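#' Read a spectrum from a two-column CSV
#'
#' Expects two numeric columns (wavenumber cm^-1, intensity); a single header
#' line is tolerated. Rows are sorted by wavenumber; exact duplicate
#' wavenumbers are an error.
#'
#' @param path file path.
#' @param grid_policy `"strict"` keeps the file's own grid (which must be
#'   uniform); `"resample"` linearly interpolates onto `grid`.
#' @param grid target [wavenumber_grid()] when `grid_policy = "resample"`.
#' @param label label for the returned spectrum (default: file name).
#'
#' @return A [spectrum_1d()].
#' @export
read_spectrum_csv <- function(path, grid_policy = c("strict", "resample"),
                              grid = NULL, label = NULL) {
  grid_policy <- match.arg(grid_policy)
  if (!file.exists(path)) stop("read_spectrum_csv: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_spectrum_csv: empty file: ", path)
  first_fields <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_fields[1:2]))))
  data_lines <- if (has_header) lines[-1L] else lines
  if (!length(data_lines)) stop("read_spectrum_csv: no data rows in ", path)
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) < 2L)
  if (length(bad_shape))
    stop(sprintf("read_spectrum_csv: line %d of %s has fewer than 2 fields",
                 bad_shape[1L] + has_header, path))
  wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(wn) | is.na(it))
  if (length(bad))
    stop(sprintf("read_spectrum_csv: non-numeric value on line %d of %s",
                 bad[1L] + has_header, path))
  o <- order(wn)
  wn <- wn[o]; it <- it[o]
  if (anyDuplicated(wn))
    stop("read_spectrum_csv: duplicated wavenumbers in ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (grid_policy == "strict") {
    sp <- diff(wn)
    if (length(wn) > 2L && diff(range(sp)) > 1e-6 * mean(sp))
      stop("read_spectrum_csv: non-uniform grid in ", path,
           " (use grid_policy = 'resample')")
    g <- wavenumber_grid(wn[1L], wn[length(wn)], length(wn))
    spectrum_1d(it, g, label)
  } else {
    if (is.null(grid)) stop("read_spectrum_csv: resample needs a target grid")
    yi <- stats::approx(wn, it, xout = grid$wavenumbers, rule = 2)$y
    spectrum_1d(yi, grid, label)
  }
}

#' Write a spectrum to a two-column CSV
#'
#' Full-precision two-column (wavenumber, intensity) CSV with a header row,
#' one data row per grid point.
#'
#' @param spectrum a [spectrum_1d()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  rows <- paste(format(spectrum$grid$wavenumbers, digits = 17, trim = TRUE),
                format(spectrum$intensities, digits = 17, trim = TRUE),
                sep = ",")
  ok <- try(writeLines(c("wavenumber,intensity", rows), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("write_spectrum_csv: cannot write ", path)
  invisible(path)
}

#' Write a spectrum set as a directory of CSVs with a JSON manifest
#'
#' @param set a [spectrum_set()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_spectrum_set <- function(set, dir) {
  stopifnot(inherits(set, "spectrum_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(set$spectra))
  for (i in seq_along(set$spectra)) {
    files[i] <- sprintf("spectrum_%03d.csv", i)
    write_spectrum_csv(set$spectra[[i]], file.path(dir, files[i]))
  }
  manifest <- list(role = set$role,
                   labels = unname(names(set$spectra)),
                   files = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Read a spectrum set written by [write_spectrum_set()]
#'
#' @param dir directory containing `manifest.json` and the CSV files.
#' @return A [spectrum_set()].
#' @export
read_spectrum_set <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("read_spectrum_set: no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  spectra <- mapply(function(f, lab)
    read_spectrum_csv(file.path(dir, f), label = lab),
    manifest$files, manifest$labels, SIMPLIFY = FALSE)
  spectrum_set(unname(spectra), role = manifest$role)
}
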