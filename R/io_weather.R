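#' Default image filename pattern
#'
#' Image names encode the acquisition date, field trial and plot UID as
#' `<YYYY-MM-DD>_<trial>_<plotUID>.<ext>`. The pattern is a configurable
#' regex with capture groups (date, trial, plot_uid, ext) so archives with a
#' different encoding can supply their own.
#'
#' @export
default_filename_pattern <- function() {
  "^(\\d{4}-\\d{2}-\\d{2})_([A-Za-z0-9-]+)_([A-Za-z0-9-]+)\\.([A-Za-z0-9]+)$"
}

#' Parse image filenames into (date, trial, plot_uid)
#'
#' @param names character vector of file names (basenames are taken).
#' @param pattern regex with four capture groups: date, trial, plot_uid,
#'   extension.
#' @return data.frame: name, date (`Date`), trial, plot_uid, ext.
#' @export
parse_image_filename <- function(names, pattern = default_filename_pattern()) {
  bn <- basename(names)
  m <- regmatches(bn, regexec(pattern, bn))
  bad <- vapply(m, length, 0L) == 0
  if (any(bad))
    stop(sprintf("filename(s) do not match the expected pattern '%s': %s",
                 pattern, paste(bn[bad], collapse = ", ")))
  parts <- do.call(rbind, m)
  data.frame(name = bn, date = as.Date(parts[, 2]), trial = parts[, 3],
             plot_uid = parts[, 4], ext = parts[, 5], stringsAsFactors = FALSE)
}

#' Format an image filename from its components
#'
#' Inverse of [parse_image_filename()] under the default pattern.
#'
#' @param date acquisition date (`Date` or ISO string).
#' @param trial trial identifier.
#' @param plot_uid plot identifier.
#' @param ext file extension (no dot).
#' @export
format_image_filename <- function(date, trial, plot_uid, ext = "png") {
  sprintf("%s_%s_%s.%s", format(as.Date(date), "%Y-%m-%d"), trial, plot_uid, ext)
}

#' Convert shortwave radiation to PPFR
#'
#' Photosynthetic photon fluence rate from radiation in MJ m-2, using the
#' standard linear conversion factor 2.04.
#'
#' @param radiation numeric, MJ m-2, >= 0.
#' @param factor conversion factor; default 2.04.
#' @return `factor * radiation`.
#' @export
radiation_to_ppfr <- function(radiation, factor = 2.04) {
  if (any(radiation < 0, na.rm = TRUE))
    stop("radiation must be >= 0")
  factor * radiation
}

#' Correlation between two sensors over overlapping hours
#'
#' Pearson correlation computed on the intersection of the two timestamp
#' sets only, as used to confirm cross-sensor measurement consistency.
#'
#' @param series_a,series_b data.frames with columns `timestamp` and `value`.
#' @return list: `r`, `n` (overlapping hours).
#' @export
cross_sensor_correlation <- function(series_a, series_b) {
  stopifnot(all(c("timestamp", "value") %in% names(series_a)),
            all(c("timestamp", "value") %in% names(series_b)))
  common <- intersect(series_a$timestamp, series_b$timestamp)
  if (length(common) < 3)
    stop("need >= 3 overlapping timestamps between the two sensors")
  a <- series_a$value[match(common, series_a$timestamp)]
  b <- series_b$value[match(common, series_b$timestamp)]
  list(r = stats::cor(a, b), n = length(common))
}

#' Aggregate hourly weather to per-image-date covariates
#'
#' For each image date, hours within a trailing window of `window_days`
#' ending at the end of that date are aggregated: mean/min/max temperature,
#' radiation and precipitation sums, mean humidity and wind. Missing hours
#' are counted per date and fully uncovered dates yield an all-NA row with a
#' warning.
#'
#' @param weather data.frame from [simulate_weather()] or the archive schema
#'   (hourly `timestamp` plus variables).
#' @param dates `Date` vector of image acquisition dates.
#' @param window_days trailing window length in days; default 1 (the date
#'   itself).
#' @return data.frame, one row per date.
#' @export
align_weather_to_dates <- function(weather, dates, window_days = 1) {
  stopifnot("timestamp" %in% names(weather), window_days >= 1)
  dates <- as.Date(dates)
  wd <- as.Date(weather$timestamp)
  out <- lapply(dates, function(d) {
    sel <- wd > d - window_days & wd <= d
    n <- sum(sel)
    if (!n) {
      warning(sprintf("no weather hours cover date %s", format(d)))
      return(data.frame(date = d, temp_mean = NA_real_, temp_min = NA_real_,
                        temp_max = NA_real_, radiation_sum = NA_real_,
                        precip_sum = NA_real_, humidity_mean = NA_real_,
                        windspeed_mean = NA_real_, n_hours = 0L,
                        n_missing = as.integer(24 * window_days)))
    }
    w <- weather[sel, , drop = FALSE]
    data.frame(date = d,
               temp_mean = mean(w$temperature), temp_min = min(w$temperature),
               temp_max = max(w$temperature),
               radiation_sum = sum(w$radiation),
               precip_sum = sum(w$precipitation),
               humidity_mean = mean(w$humidity),
               windspeed_mean = mean(w$windspeed),
               n_hours = n,
               n_missing = as.integer(24 * window_days - n))
  })
  do.call(rbind, out)
}

#' @keywords internal
miappe_alias_map <- function() {
  c("observation.unit.ID" = "plot_uid", "plot.UID" = "plot_uid",
    "material.source.ID" = "genotype", "genotype.name" = "genotype",
    "block" = "replicate", "rep" = "replicate",
    "spatial.distribution.row" = "row", "spatial.distribution.range" = "range",
    "study.ID" = "trial", "border" = "is_border")
}

#' Read and validate a trial design CSV
#'
#' Required columns: `plot_uid`, `genotype`, `replicate`, `row`, `range`;
#' optional `trial` and `is_border` (default FALSE). Common MIAPPE-style
#' aliases are mapped onto the canonical names. `plot_uid` and the
#' `(row, range)` position must be unique within a trial.
#'
#' @param path CSV file path.
#' @param exclude_border drop border plots on read.
#' @return validated data.frame.
#' @export
read_design <- function(path, exclude_border = FALSE) {
  if (!file.exists(path)) stop(sprintf("design file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  alias <- miappe_alias_map()
  hit <- names(d) %in% names(alias)
  names(d)[hit] <- alias[names(d)[hit]]
  need <- c("plot_uid", "genotype", "replicate", "row", "range")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"trial" %in% names(d)) d$trial <- "trial1"
  if (!"is_border" %in% names(d)) d$is_border <- FALSE
  d$is_border <- as.logical(d$is_border)
  for (tr in unique(d$trial)) {
    sub <- d[d$trial == tr, ]
    if (anyDuplicated(sub$plot_uid))
      stop(sprintf("duplicate plot_uid within trial '%s': %s", tr,
                   paste(unique(sub$plot_uid[duplicated(sub$plot_uid)]),
                         collapse = ", ")))
    if (anyDuplicated(sub[, c("row", "range")]))
      stop(sprintf("duplicate (row, range) position within trial '%s'", tr))
  }
  if (exclude_border) d <- d[!d$is_border, , drop = FALSE]
  d
}

#' Write a trial design CSV
#'
#' @param design data.frame as returned by [read_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  cols <- intersect(c("plot_uid", "trial", "genotype", "replicate", "row",
                      "range", "is_border"), names(design))
  utils::write.csv(design[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @keywords internal
raw_cc_columns <- function() {
  c("plot_uid", "timestamp", "cc", "n_green", "n_total", "n_rows_detected",
    "method", "provenance")
}

#' Write the raw and cleaned CC tables
#'
#' The raw table carries the full per-image extraction record (counts,
#' detected rows, method and boundary provenance); the cleaned table is the
#' analysis-ready plot_uid x date x value view, joined with genotype when a
#' design is given. CSVs are written bit-stably: fixed column order, ISO
#' dates, '.' decimal separator, no quoting.
#'
#' @param records merged season table from [extract_season()] /
#'   [merge_datasets()].
#' @param raw_path,clean_path output CSV paths (either may be NULL to skip).
#' @param design optional design data.frame to attach genotypes.
#' @return list of the written paths, invisibly.
#' @export
write_cc_tables <- function(records, raw_path = NULL, clean_path = NULL,
                            design = NULL) {
  miss <- setdiff(raw_cc_columns(), names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(raw_path)) {
    raw <- records[, raw_cc_columns(), drop = FALSE]
    raw$timestamp <- format_stamp(raw$timestamp)
    utils::write.csv(raw, raw_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(clean_path)) {
    clean <- data.frame(plot_uid = records$plot_uid,
                        date = format_stamp(records$timestamp),
                        value = records$cc, stringsAsFactors = FALSE)
    if (!is.null(design))
      clean$genotype <- design$genotype[match(clean$plot_uid, design$plot_uid)]
    utils::write.csv(clean, clean_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(raw = raw_path, clean = clean_path))
}

#' @keywords internal
format_stamp <- function(x) {
  if (inherits(x, "Date")) format(x, "%Y-%m-%d")
  else if (inherits(x, "POSIXt")) format(x, "%Y-%m-%dT%H:%M:%S")
  else as.character(x)
}

#' Read a raw CC table written by [write_cc_tables()]
#'
#' @param path CSV path.
#' @return data.frame with the raw CC schema.
#' @export
read_cc_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("CC table not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(raw_cc_columns(), names(d))
  if (length(miss))
    stop("CC table is missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read an hourly weather CSV
#'
#' Validates the archive weather schema (hourly timestamp, temperature,
#' radiation, ppfr, humidity, precipitation, windspeed) and basic physical
#' invariants (radiation >= 0, humidity within \[0, 100\]).
#'
#' @param path CSV path.
#' @return data.frame with POSIXct `timestamp`.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop(sprintf("weather file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temperature", "radiation", "ppfr", "humidity",
            "precipitation", "windspeed")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("weather file is missing column(s): ", paste(miss, collapse = ", "))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S"))
  if (any(d$radiation < 0, na.rm = TRUE)) stop("negative radiation values")
  if (any(d$humidity < 0 | d$humidity > 100, na.rm = TRUE))
    stop("humidity outside [0, 100]")
  d
}

#' Write an hourly weather CSV
#'
#' @param weather data.frame from [simulate_weather()] / [read_weather()].
#' @param path output path.
#' @export
write_weather <- function(weather, path) {
  w <- weather
  w$timestamp <- format(w$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
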