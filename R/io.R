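#' Read / write an impedance spectrum as CSV
#'
#' The on-disk format is a plain comma-separated file (dot decimal, UTF-8)
#' with one header line and exactly two data columns whose names carry the
#' unit suffix: `frequency_hz` or `frequency_khz`, and `z_mod_ohm` or
#' `z_mod_kohm`. Writing then reading a spectrum reproduces its values to
#' full printed precision (15 significant digits).
#'
#' @param path File path.
#' @param spectrum An [eis_spectrum()].
#' @return `read_spectrum_csv` returns an [eis_spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_spectrum_csv(fixture_table2()$experimental, tmp)
#' s <- read_spectrum_csv(tmp)
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path))
    stop_io(sprintf("spectrum file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop_io(sprintf("cannot parse CSV %s: %s",
                                        path, conditionMessage(e))))
  f_col <- grep("^frequency_", names(df), value = TRUE)
  z_col <- grep("^z_mod_", names(df), value = TRUE)
  if (length(f_col) == 0L || length(z_col) == 0L)
    stop_validation(sprintf(
      "missing column: need one 'frequency_<unit>' and one 'z_mod_<unit>' header, got: %s",
      paste(names(df), collapse = ", ")))
  if (length(f_col) > 1L || length(z_col) > 1L)
    stop_validation("duplicate frequency or z_mod columns in header")
  f_unit <- sub("^frequency_", "", f_col)
  z_unit <- sub("^z_mod_", "", z_col)
  if (!f_unit %in% c("hz", "khz"))
    stop_validation(sprintf(
      "unknown frequency unit suffix '%s' (expected hz or khz)", f_unit))
  if (!z_unit %in% c("ohm", "kohm"))
    stop_validation(sprintf(
      "unknown impedance unit suffix '%s' (expected ohm or kohm)", z_unit))
  f <- df[[f_col]]
  z <- df[[z_col]]
  if (!is.numeric(f) || !is.numeric(z))
    stop_validation("frequency and z_mod columns must be numeric")
  if (is.unsorted(f, strictly = TRUE))
    stop_validation("frequencies out of order: column must be strictly increasing")
  if (any(!is.finite(z)) || any(z <= 0))
    stop_validation("non-positive impedance magnitude in z_mod column")
  eis_spectrum(f, z, f_unit = f_unit, z_unit = z_unit)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  df <- data.frame(f = format(spectrum$frequency, digits = 15,
                              trim = TRUE, scientific = FALSE),
                   z = format(spectrum$z_mod, digits = 15, trim = TRUE))
  names(df) <- c(paste0("frequency_", spectrum$f_unit),
                 paste0("z_mod_", spectrum$z_unit))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8"),
    error = function(e) stop_io(sprintf("cannot write %s: %s",
                                        path, conditionMessage(e))))
  invisible(path)
}

# Minimal TOML-subset reader: [section] tables and flat `key = value` pairs
# with string, number and boolean scalars, plus one-line numeric arrays.
# Written in-package because no installed R package parses TOML; sufficient
# for run configuration files, not a general TOML implementation.
parse_toml_subset <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(v) {
    v <- trimws(v)
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl("^\\[.*\\]$", v)) {
      items <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
      return(vapply(items, function(x) as.numeric(trimws(x)), numeric(1),
                    USE.NAMES = FALSE))
    }
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num))
      stop_validation(sprintf("config: cannot parse value '%s'", v))
    num
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      out[[section]] <- out[[section]] %||% list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L)
      stop_validation(sprintf("config: cannot parse line '%s'", raw))
    val <- parse_scalar(m[3])
    if (is.null(section)) out[[m[2]]] <- val
    else out[[section]][[m[2]]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration
#'
#' Assembles a validated configuration for the command-line entry points.
#' Values come from an optional TOML file (flat `key = value` pairs and
#' `[section]` tables) overridden by anything passed directly.
#'
#' @param path Optional TOML config file.
#' @param ... Named overrides (see Details for recognized keys).
#' @details Recognized keys (defaults in parentheses): `f_unit` ("khz"),
#'   `z_unit` ("kohm"), `gauge` ("fix-a"), `ftol` (1e-12), `ptol` (1e-12),
#'   `max_iter` (500), `noise_sd` (0), `seed` (1), `glucose_mode`
#'   ("paper-normalized"), `molar_mass` (180.16), `mass_density` (1.54),
#'   `tolerance_pct` (1.5, the table-validation gate), `verbose` (FALSE).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(f_unit = "khz", z_unit = "kohm", gauge = "fix-a",
                   ftol = 1e-12, ptol = 1e-12, max_iter = 500,
                   noise_sd = 0, seed = 1, glucose_mode = "paper-normalized",
                   molar_mass = 180.16, mass_density = 1.54,
                   tolerance_pct = 1.5, verbose = FALSE)
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- parse_toml_subset(path)
    # flatten one level of [section] tables
    flat <- list()
    for (nm in names(file_cfg)) {
      if (is.list(file_cfg[[nm]])) flat <- c(flat, file_cfg[[nm]])
      else flat[[nm]] <- file_cfg[[nm]]
    }
    for (nm in names(flat)) cfg[[nm]] <- flat[[nm]]
  }
  overrides <- list(...)
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  if (!cfg$f_unit %in% c("hz", "khz"))
    stop_validation("config: f_unit must be hz or khz")
  if (!cfg$z_unit %in% c("ohm", "kohm"))
    stop_validation("config: z_unit must be ohm or kohm")
  if (!cfg$gauge %in% c("fix-a", "fix-g"))
    stop_validation("config: gauge must be fix-a or fix-g")
  if (!cfg$glucose_mode %in% c("paper-normalized", "physical"))
    stop_validation("config: glucose_mode must be paper-normalized or physical")
  for (nm in c("ftol", "ptol", "max_iter", "tolerance_pct"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop_validation(sprintf("config: %s must be a positive number", nm))
  if (cfg$noise_sd < 0) stop_validation("config: noise_sd must be >= 0")
  structure(cfg, class = "run_config")
}
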