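SCHEMA_VERSION <- "1"

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
}

#' Import primary emission spectra from a CSV or spreadsheet file
#'
#' The file must have a header row, a first column of strictly increasing
#' wavelengths (nm) and one column per primary (3--5 columns) of
#' non-negative intensities in any unit. Columns become primaries in file
#' order and their headers become the primary names. Spectra are resampled
#' onto the canonical 390--780 nm / 2 nm grid.
#'
#' @param path CSV (comma-separated, dot decimal, UTF-8) or xlsx file
#' @return named list of `spectrum` objects, in file column order
#' @export
read_spectra <- function(path) {
  tab <- read_table_any(path)
  if (ncol(tab) < 2L) stop("spectra file needs a wavelength column plus ",
                           "value columns")
  wl <- as.numeric(tab[[1]])
  vals <- tab[-1]
  n <- ncol(vals)
  if (n < 3L || n > 5L)
    stop("found ", n, " primary column(s); a stimulator device needs ",
         "between 3 and 5 primaries")
  if (any(!is.finite(wl)) || any(diff(wl) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  out <- list()
  for (j in seq_len(n)) {
    v <- as.numeric(vals[[j]])
    if (any(!is.finite(v)) || any(v < 0))
      stop("column '", names(vals)[j],
           "' contains negative or non-finite intensities")
    out[[names(vals)[j]]] <-
      resample_spectrum(spectrum(wl, v, unit = "relative"), canonical_grid())
  }
  out
}

#' Write a named list of spectra to CSV (spectral dialect)
#'
#' First column `wavelength` (nm), one named column per spectrum. All
#' spectra must share a grid. Inverse of [read_spectra()] for 3--5 columns.
#'
#' @param spectra named list of `spectrum` objects on one grid
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L, !is.null(names(spectra)))
  for (s in spectra) stop_if_grid_mismatch(spectra[[1L]], s, "spectra")
  tab <- data.frame(wavelength = spectra[[1L]]$wl)
  for (nm in names(spectra)) tab[[nm]] <- spectra[[nm]]$values
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

solution_table_export <- function(solution) {
  tab <- solution$table
  data.frame(primary = tab$primary,
             Contrast = 100 * tab$contrast,          # percent, as displayed
             MinLuminance = tab$min_luminance,
             MaxLuminance = tab$max_luminance,
             feasible = tab$feasible,
             stringsAsFactors = FALSE)
}

#' Export a stimulus solution to JSON or CSV
#'
#' The result table (one row per primary, columns `primary`, `Contrast`
#' (percent), `MinLuminance`, `MaxLuminance` (cd/m^2), `feasible`) plus the
#' overall feasibility, the maximization factor and any warnings. JSON
#' exports round-trip through [read_solution()]; a validation report can be
#' attached. The CSV format writes the table only.
#'
#' @param solution an `ss_solution`
#' @param path output file path
#' @param format `"json"` or `"csv"`
#' @param report optional `ss_validation` to embed (JSON only)
#' @return `path`, invisibly
#' @export
export_solution <- function(solution, path, format = c("json", "csv"),
                            report = NULL) {
  stopifnot(inherits(solution, "ss_solution"))
  format <- match.arg(format)
  tab <- solution_table_export(solution)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  obj <- list(schema_version = SCHEMA_VERSION,
              feasible = solution$feasible,
              scale_applied = solution$scale_applied,
              warnings = as.list(solution$warnings),
              table = tab)
  if (!is.null(report)) {
    stopifnot(inherits(report, "ss_validation"))
    obj$validation <- list(
      observer_params = report$observer_params,
      achieved = as.list(report$achieved),
      uncontrolled = as.list(report$uncontrolled))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stimulus solution exported as JSON
#'
#' @param path JSON file written by [export_solution()]
#' @return an `ss_solution` (table, overall feasibility, scale factor,
#'   warnings; the attached validation report, if any, is in
#'   `$validation`)
#' @export
read_solution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$schema_version), SCHEMA_VERSION))
    stop("solution schema version '", obj$schema_version,
         "' not supported (expected ", SCHEMA_VERSION, ")")
  tab <- obj$table
  sol <- structure(list(
    table = data.frame(primary = tab$primary,
                       contrast = tab$Contrast / 100,
                       min_luminance = tab$MinLuminance,
                       max_luminance = tab$MaxLuminance,
                       feasible = tab$feasible,
                       stringsAsFactors = FALSE),
    feasible = obj$feasible,
    scale_applied = obj$scale_applied,
    warnings = as.character(unlist(obj$warnings))),
    class = "ss_solution")
  if (!is.null(obj$validation)) sol$validation <- obj$validation
  sol
}

#' Save a device configuration (with embedded spectra) to JSON
#'
#' Persists primary names, mean luminances, luminance ranges, the
#' area-normalized emission spectra and the calibration V(lambda), all on
#' the canonical grid, so that [load_device_config()] reproduces the
#' device. Serves the same purpose as bookmarking a fully described
#' stimulator.
#'
#' @param dev an `ss_device`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
save_device_config <- function(dev, path) {
  stopifnot(inherits(dev, "ss_device"))
  prims <- lapply(dev$primaries, function(p) {
    rng <- p$lum_range
    # an infinite upper bound ("range not specified") is stored as null
    lr <- list(min = rng[1])
    if (is.finite(rng[2])) lr$max <- rng[2]
    list(name = p$name,
         mean_luminance = p$mean_luminance,
         lum_range = lr,
         emission = p$emission$values)
  })
  obj <- list(schema_version = SCHEMA_VERSION,
              grid = list(start = min(canonical_grid()),
                          stop = max(canonical_grid()), step = 2),
              vlambda = dev$vlambda$values,
              primaries = unname(prims))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a device configuration saved by [save_device_config()]
#'
#' A configuration whose mean luminance lies outside its own stated range
#' is rejected. A missing luminance range defaults to unspecified
#' (`[0, Inf)`) with a warning.
#'
#' @param path JSON path
#' @return an `ss_device`
#' @export
load_device_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(obj$schema_version), SCHEMA_VERSION))
    stop("device config schema version '", obj$schema_version,
         "' not supported (expected ", SCHEMA_VERSION, ")")
  wl <- wavelength_grid(obj$grid$start, obj$grid$stop, obj$grid$step)
  vl <- spectrum(wl, unlist(obj$vlambda), unit = "sensitivity")
  prims <- lapply(obj$primaries, function(p) {
    if (is.null(p$lum_range)) {
      warning("primary '", p$name, "': no luminance range in config; ",
              "defaulting to [0, Inf)")
      rng <- c(0, Inf)
    } else {
      lo <- if (is.null(p$lum_range$min)) 0 else p$lum_range$min
      hi <- if (is.null(p$lum_range$max)) Inf else p$lum_range$max
      rng <- c(lo, hi)
    }
    if (p$mean_luminance < rng[1] || p$mean_luminance > rng[2])
      stop("primary '", p$name, "': configured mean luminance ",
           p$mean_luminance, " cd/m2 lies outside its own range [",
           rng[1], ", ", rng[2], "]")
    primary(p$name, spectrum(wl, unlist(p$emission), unit = "relative"),
            p$mean_luminance, lum_range = rng)
  })
  device(prims, vlambda = vl)
}

#' Write an observer bundle: one CSV per spectral table
#'
#' Files in the spectral CSV dialect (wavelength column plus named value
#' columns): `fundamentals.csv` (L, M, S cone fundamentals),
#' `scotopic.csv` (rod), `melanopsin.csv` (mel), `vlambda.csv`,
#' `macular.csv`, `lens.csv` (TL1, TL2), `cmf1964.csv` (xbar, ybar, zbar).
#'
#' @param dir output directory (created if missing)
#' @param obs `ss_observer`
#' @param vlambda photopic luminous efficiency `spectrum`
#' @param templates `ss_templates`
#' @param cmfs list of `x`, `y`, `z` colour-matching `spectrum` objects
#' @return `dir`, invisibly
#' @export
write_observer_bundle <- function(dir, obs, vlambda, templates, cmfs) {
  stopifnot(inherits(obs, "ss_observer"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- obs$fundamentals
  write_spectra(list(L = f$L, M = f$M, S = f$S),
                file.path(dir, "fundamentals.csv"))
  write_spectra(list(rod = f$rod), file.path(dir, "scotopic.csv"))
  write_spectra(list(mel = f$mel), file.path(dir, "melanopsin.csv"))
  write_spectra(list(vlambda = vlambda), file.path(dir, "vlambda.csv"))
  write_spectra(list(macular = templates$macular),
                file.path(dir, "macular.csv"))
  write_spectra(list(TL1 = templates$lens_tl1, TL2 = templates$lens_tl2),
                file.path(dir, "lens.csv"))
  write_spectra(list(xbar = cmfs$x, ybar = cmfs$y, zbar = cmfs$z),
                file.path(dir, "cmf1964.csv"))
  invisible(dir)
}

read_bundle_csv <- function(path, units) {
  tab <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(tab[[1]])
  out <- list()
  for (j in seq_len(ncol(tab) - 1L)) {
    u <- if (length(units) == 1L) units else units[j]
    out[[names(tab)[j + 1L]]] <-
      resample_spectrum(spectrum(wl, as.numeric(tab[[j + 1L]]), unit = u),
                        canonical_grid())
  }
  out
}

#' Read an observer bundle written by [write_observer_bundle()]
#'
#' @param dir bundle directory
#' @return list with components `observer` (`ss_observer`), `vlambda`,
#'   `templates` (`ss_templates`) and `cmfs`
#' @export
read_observer_bundle <- function(dir) {
  lms <- read_bundle_csv(file.path(dir, "fundamentals.csv"), "sensitivity")
  rod <- read_bundle_csv(file.path(dir, "scotopic.csv"), "sensitivity")
  mel <- read_bundle_csv(file.path(dir, "melanopsin.csv"), "sensitivity")
  vl <- read_bundle_csv(file.path(dir, "vlambda.csv"), "sensitivity")
  mac <- read_bundle_csv(file.path(dir, "macular.csv"), "OD")
  lens <- read_bundle_csv(file.path(dir, "lens.csv"), "OD")
  cmf <- read_bundle_csv(file.path(dir, "cmf1964.csv"), "sensitivity")
  list(observer = observer(list(L = lms$L, M = lms$M, S = lms$S,
                                rod = rod$rod, mel = mel$mel)),
       vlambda = vl$vlambda,
       templates = density_templates(mac$macular, lens$TL1, lens$TL2),
       cmfs = list(x = cmf$xbar, y = cmf$ybar, z = cmf$zbar))
}

#' Path to the packaged synthetic observer bundle
#'
#' The shipped bundle is a fully synthetic stand-in (generated from the
#' analytic templates in this package, see `tools/make_synthetic_bundle.R`)
#' for the real standard-observer tables, which users can regenerate from
#' the public CVRL downloads with `tools/fetch_cvrl.R`. Every computation
#' and test in the package runs against synthetic data; swap in a real
#' bundle for production stimulus design.
#'
#' @return directory path
#' @export
bundled_observer_dir <- function() {
  system.file("extdata", "synthetic_cvrl", package = "silentsub",
              mustWork = TRUE)
}
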