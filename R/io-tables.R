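# Delimited-table readers and writers. All tables are RFC-4180 style CSV
# with a mandatory header row; writers prepend '#'-comment lines recording
# canonical units and metadata, which the readers parse back.

.schemas <- list(
  transient  = c(time = "time_s", absorbance = "abs_au"),
  rates      = c(conc = "conc_mM", rate = "rate_per_s"),
  tempseries = c(temperature = "temperature_K", rate = "rate_per_s")
)

.read_meta <- function(path) {
  lines <- readLines(path, n = 20L)
  meta <- list()
  for (ln in lines[startsWith(lines, "#")]) {
    body <- sub("^#\\s*", "", ln)
    for (kv in strsplit(body, "\\s+")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) meta[[parts[1]]] <- parts[2]
    }
  }
  meta
}

.parse_numeric_col <- function(df, col) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad) > 0)
    .stopf("non-numeric value '%s' in column '%s' at data row %d",
           x[bad[1]], col, bad[1])
  out
}

#' Read a typed table from CSV
#'
#' Supported schemas and their canonical columns:
#' \describe{
#'   \item{transient}{`time_s`, `abs_au` (seconds, AU)}
#'   \item{rates}{`conc_mM`, `rate_per_s` (mM, s^-1)}
#'   \item{tempseries}{`temperature_K`, `rate_per_s`, optional `rate_se`}
#'   \item{eem}{first column `emission_nm`, remaining columns one per
#'     excitation wavelength (header is the wavelength in nm)}
#' }
#' Arbitrary source headers are supported through `col_map`, a named
#' character vector mapping canonical names to source headers. Temperatures
#' may be supplied in degrees Celsius and rates in min^-1 by declaring
#' `temp_unit = "C"` / `rate_unit = "per_min"`; units are never guessed
#' from magnitudes. Conversions are exact: K = C + 273.15, s^-1 = min^-1/60.
#'
#' @param path CSV file path
#' @param schema one of "transient", "rates", "tempseries", "eem"
#' @param col_map optional named character vector, canonical -> source header
#' @param temp_unit "K" (default) or "C" for temperature columns/metadata
#' @param rate_unit "per_s" (default) or "per_min" for rate columns
#' @param ... metadata overrides passed to the record constructor
#'   (e.g. `substrate`, `temperature`, `enzyme_conc`)
#' @return a validated record of the matching class
#' @export
read_table <- function(path, schema = c("transient", "rates", "tempseries", "eem"),
                       col_map = NULL, temp_unit = c("K", "C"),
                       rate_unit = c("per_s", "per_min"), ...) {
  schema <- match.arg(schema)
  temp_unit <- match.arg(temp_unit)
  rate_unit <- match.arg(rate_unit)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (schema == "eem") return(.read_eem(path))

  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  want <- .schemas[[schema]]
  src <- want
  if (!is.null(col_map)) {
    for (nm in names(col_map)) src[nm] <- col_map[[nm]]
  }
  missing_cols <- src[!(src %in% names(df))]
  if (length(missing_cols) > 0)
    .stopf("schema '%s': missing column '%s'", schema, missing_cols[1])
  cols <- lapply(src, function(cn) .parse_numeric_col(df, cn))

  dots <- list(...)
  get_meta <- function(key, default = NA_real_, chr = FALSE) {
    if (!is.null(dots[[key]])) return(dots[[key]])
    if (!is.null(meta[[key]])) {
      return(if (chr) meta[[key]] else as.numeric(meta[[key]]))
    }
    default
  }
  k_of <- function(x) if (temp_unit == "C") celsius_to_kelvin(x) else x
  s_of <- function(x) if (rate_unit == "per_min") per_min_to_per_s(x) else x

  if (schema == "transient") {
    absorbance_transient(cols$time, cols$absorbance,
                         temperature = k_of(get_meta("temperature_K")),
                         label = get_meta("label", "", chr = TRUE))
  } else if (schema == "rates") {
    rate_conc_series(cols$conc, s_of(cols$rate),
                     temperature = k_of(get_meta("temperature_K")),
                     enzyme_conc = get_meta("enzyme_conc_uM"),
                     substrate = get_meta("substrate", "", chr = TRUE),
                     isotopologue = get_meta("isotopologue", "H", chr = TRUE))
  } else {
    se_col <- if (!is.null(col_map) && "rate_se" %in% names(col_map))
      col_map[["rate_se"]] else "rate_se"
    rate_se <- if (se_col %in% names(df))
      s_of(.parse_numeric_col(df, se_col)) else NULL
    temperature_rate_series(k_of(cols$temperature), s_of(cols$rate),
                            rate_se = rate_se,
                            substrate = get_meta("substrate", "", chr = TRUE),
                            isotopologue = get_meta("isotopologue", "H", chr = TRUE))
  }
}

.read_eem <- function(path) {
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "emission_nm")
    .stopf("schema 'eem': missing column 'emission_nm'")
  emission <- as.numeric(df[[1]])
  excitation <- as.numeric(names(df)[-1])
  if (anyNA(excitation))
    .stopf("schema 'eem': non-numeric excitation wavelength in header")
  intensity <- t(as.matrix(df[, -1, drop = FALSE]))  # excitation x emission
  eem(excitation, emission, intensity,
      label = if (!is.null(meta$label)) meta$label else "")
}

.meta_line <- function(kv) {
  kv <- kv[!vapply(kv, function(v) is.null(v) || (is.numeric(v) && is.na(v)) ||
                     identical(v, ""), logical(1))]
  if (length(kv) == 0) return(character(0))
  paste("#", paste(sprintf("%s=%s", names(kv),
                           vapply(kv, format, character(1), digits = 17)),
                   collapse = " "))
}

#' Write a typed record to CSV in canonical units
#'
#' The written file starts with '#'-comment lines recording canonical
#' units and the record metadata, so that `read_table()` round-trips the
#' record exactly (to full printed precision, 17 significant digits).
#'
#' @param x a record created by the package's constructors or readers
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_table <- function(x, path) {
  fmt <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "absorbance_transient")) {
    writeLines(c("# thermokin schema=transient units=s,AU",
                 .meta_line(list(temperature_K = attr(x, "temperature"),
                                 label = attr(x, "label")))), con)
    writeLines("time_s,abs_au", con)
    writeLines(paste(fmt(x$time), fmt(x$absorbance), sep = ","), con)
  } else if (inherits(x, "rate_conc_series")) {
    writeLines(c("# thermokin schema=rates units=mM,per_s",
                 .meta_line(list(temperature_K = attr(x, "temperature"),
                                 enzyme_conc_uM = attr(x, "enzyme_conc"),
                                 substrate = attr(x, "substrate"),
                                 isotopologue = attr(x, "isotopologue")))), con)
    writeLines("conc_mM,rate_per_s", con)
    writeLines(paste(fmt(x$conc), fmt(x$rate), sep = ","), con)
  } else if (inherits(x, "temperature_rate_series")) {
    writeLines(c("# thermokin schema=tempseries units=K,per_s",
                 .meta_line(list(substrate = attr(x, "substrate"),
                                 isotopologue = attr(x, "isotopologue")))), con)
    if (is.null(x$rate_se)) {
      writeLines("temperature_K,rate_per_s", con)
      writeLines(paste(fmt(x$temperature), fmt(x$rate), sep = ","), con)
    } else {
      writeLines("temperature_K,rate_per_s,rate_se", con)
      writeLines(paste(fmt(x$temperature), fmt(x$rate), fmt(x$rate_se),
                       sep = ","), con)
    }
  } else if (inherits(x, "eem")) {
    writeLines(c("# thermokin schema=eem units=nm",
                 .meta_line(list(label = x$label))), con)
    writeLines(paste(c("emission_nm", fmt(x$excitation)), collapse = ","), con)
    for (j in seq_along(x$emission)) {
      writeLines(paste(c(fmt(x$emission[j]), fmt(x$intensity[, j])),
                       collapse = ","), con)
    }
  } else {
    .stopf("don't know how to write objects of class '%s'", class(x)[1])
  }
  invisible(path)
}
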