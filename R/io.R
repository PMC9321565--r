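#' Read a raster layer from an ESRI ASCII grid file
#'
#' Reads the standard 6-line `.asc` header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by the value rows
#' (north to south). The CRS is taken from a `.prj` sidecar file next to the
#' raster; a raster without a CRS is refused unless one is supplied
#' explicitly.
#'
#' @param path Path to a `.asc` file.
#' @param crs Optional CRS override; required if no `.prj` sidecar exists.
#' @return A [raster_grid()] with nodata cells mapped to `NA`.
#' @export
read_grid <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("not a valid ASCII grid header in ", path)
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " values in ", path, ", found ", length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(crs)) {
    prj <- prj_path(path)
    if (!file.exists(prj)) {
      stop("no CRS: missing sidecar ", prj,
           " and no 'crs' argument given", call. = FALSE)
    }
    crs <- paste(readLines(prj, warn = FALSE), collapse = "\n")
  }
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs, nodata = nodata)
}

prj_path <- function(path) sub("\\.[^.]+$", ".prj", path)

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Writes the grid with its `.prj` CRS sidecar. `NA` cells are written as the
#' grid's nodata sentinel. Output is deterministic for a given grid (fixed
#' `%.*g` formatting), so re-writing identical data is byte-stable.
#'
#' @param g A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param digits Significant digits used for formatting (default 7, enough
#'   for lossless float32-precision round trips).
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path, digits = 7) {
  stopifnot(is_raster_grid(g))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  m <- g$values
  d <- dim(m)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  fmt <- function(x) {
    out <- formatC(x, digits = digits, format = "g")
    out[is.na(x)] <- formatC(g$nodata, digits = digits, format = "g")
    out
  }
  rows <- apply(m, 1, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(g$crs, prj_path(path))
  invisible(path)
}

#' Read an annual stack from a directory
#'
#' Expects a `<name>_years.csv` manifest (columns `year`, `file`) written by
#' [write_stack()], with one `.asc` layer per year.
#'
#' @param dir Directory holding the layers.
#' @param name Stack name (manifest prefix).
#' @export
read_stack <- function(dir, name) {
  manifest <- file.path(dir, paste0(name, "_years.csv"))
  if (!file.exists(manifest)) stop("stack manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  layers <- lapply(tab$file, function(f) read_grid(file.path(dir, f)))
  annual_stack(tab$year, layers)
}

#' Write an annual stack to a directory
#' @param s An [annual_stack()].
#' @param dir Output directory (created if needed).
#' @param name Stack name; layers become `<name>_<year>.asc`.
#' @param digits Formatting precision, see [write_grid()].
#' @export
write_stack <- function(s, dir, name, digits = 7) {
  stopifnot(is_annual_stack(s))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%d.asc", name, s$years)
  for (i in seq_along(files)) {
    write_grid(s$layers[[i]], file.path(dir, files[i]), digits = digits)
  }
  utils::write.csv(data.frame(year = s$years, file = files),
                   file.path(dir, paste0(name, "_years.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a run configuration from a YAML file
#'
#' The configuration is a declarative key/value file with nested sections;
#' every model parameter (allocation coefficients, slope reclassification,
#' animal-unit factors, uncertainty specifications, class thresholds) can be
#' overridden there. Unspecified entries fall back to the package defaults,
#' see [run_config()].
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}
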