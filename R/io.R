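# Data ingestion and the lag-indexed climate matrix.
#
# Conventions used throughout the package:
#   * event days are integer days since 1 April, with 1 April = day 1;
#   * lags count calendar days before an anchor date (lag 0 = the anchor
#     itself), walking back through real dates so leap days are included
#     naturally and no day is skipped or duplicated.

#' Day-of-season origin
#'
#' Event days are expressed as days since 1 April, with 1 April = day 1.
#' This constant records the origin used everywhere in the package.
#'
#' @return A string, `"04-01"` (month-day).
#' @export
pc_day_origin <- function() "04-01"

#' Convert event days to calendar dates and back
#'
#' @param year Integer vector of calendar years.
#' @param event_day Integer vector of days since 1 April (1 April = 1).
#' @param date A `Date` vector.
#' @return `event_date()` returns a `Date`; `days_since_origin()` returns an
#'   integer vector of days since 1 April of the year of each date.
#' @export
event_date <- function(year, event_day) {
  as.Date(sprintf("%d-%s", year, pc_day_origin())) + (event_day - 1)
}

#' @rdname event_date
#' @export
days_since_origin <- function(date) {
  year <- as.integer(format(date, "%Y"))
  as.integer(date - as.Date(sprintf("%d-%s", year, pc_day_origin()))) + 1L
}

# Accept ISO-8601 and dd/mm/yyyy date strings.
parse_pc_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  if (anyNA(out)) {
    bad <- x[is.na(out)][1]
    stop("unparseable date (expected ISO-8601 or dd/mm/yyyy): ", bad)
  }
  out
}

match_column <- function(nms, aliases, what, path) {
  hit <- which(tolower(gsub("[^a-z0-9]+", "_", tolower(nms))) %in% aliases)
  if (length(hit) == 0)
    stop("could not find a ", what, " column in ", path,
         " (looked for: ", paste(aliases, collapse = ", "), ")")
  hit[1]
}

#' Construct a phenology series
#'
#' A `pheno_series` holds one mean event date per year, in days since
#' 1 April. Years must be unique; they are stored in increasing order.
#' Non-integer event days are rounded to the nearest whole day.
#'
#' @param year Integer vector of calendar years.
#' @param event_day Numeric vector of mean event dates (days since 1 April).
#' @param bounds Length-2 numeric; permissible event-day range.
#' @return A data frame of class `pheno_series` with columns `year` and
#'   `event_day`.
#' @export
pheno_series <- function(year, event_day, bounds = c(1, 120)) {
  if (length(year) != length(event_day))
    stop("year and event_day must have equal length")
  year <- as.integer(year)
  if (anyNA(year) || anyNA(event_day)) stop("missing values in phenology data")
  if (anyDuplicated(year)) {
    dup <- year[duplicated(year)][1]
    stop("duplicate year in phenology data: ", dup)
  }
  event_day <- round(as.numeric(event_day))
  out_of_bounds <- event_day < bounds[1] | event_day > bounds[2]
  if (any(out_of_bounds))
    stop("event day outside bounds [", bounds[1], ", ", bounds[2],
         "] for year ", year[which(out_of_bounds)[1]])
  o <- order(year)
  structure(data.frame(year = year[o], event_day = as.integer(event_day[o])),
            class = c("pheno_series", "data.frame"), bounds = bounds)
}

#' Read an annual phenology CSV
#'
#' Expects a header with (at least) a year column and a mean-event-day column
#' (days since 1 April); column order is irrelevant and common aliases are
#' accepted. Additional columns (calendar date, day of month, month, day of
#' year) are ignored.
#'
#' @param path Path to a CSV file.
#' @param bounds Permissible event-day range (see [pheno_series()]).
#' @return A [pheno_series()].
#' @export
read_phenology <- function(path, bounds = c(1, 120)) {
  if (!file.exists(path)) stop("phenology file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  iy <- match_column(names(raw), c("year", "yr"), "year", path)
  id <- match_column(
    names(raw),
    c("event_day", "mean_lay_date", "lay_date", "mean_lay_date_in_days_since_1_april",
      "mean_lay_date_days_since_1_april", "days_since_1_april", "mean_event_day",
      "laydate", "day"),
    "mean event day", path)
  pheno_series(raw[[iy]], raw[[id]], bounds = bounds)
}

#' Write a phenology series to CSV
#'
#' @param x A [pheno_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenology <- function(x, path) {
  stopifnot(inherits(x, "pheno_series"))
  utils::write.csv(data.frame(year = x$year, event_day = x$event_day),
                   path, row.names = FALSE)
  invisible(path)
}

#' Annual means from individual nest records
#'
#' Collapses per-nest clutch-initiation days to an annual mean, excluding
#' likely second or replacement clutches: within each year, records more than
#' 30 days after the first (earliest) lay date of that year are dropped
#' (a record exactly 30 days after is retained). Surviving records are
#' averaged and rounded to the nearest whole day.
#'
#' @param records Data frame with columns `year` and `lay_day`
#'   (days since 1 April).
#' @param late_cutoff Days after the first lay date beyond which records are
#'   excluded (strict inequality). Default 30.
#' @param bounds Passed to [pheno_series()].
#' @return A [pheno_series()].
#' @export
annual_means_from_nests <- function(records, late_cutoff = 30,
                                    bounds = c(1, 120)) {
  stopifnot(is.data.frame(records), all(c("year", "lay_day") %in% names(records)))
  if (nrow(records) == 0) stop("no nest records supplied")
  means <- vapply(split(records$lay_day, records$year), function(d) {
    keep <- d <= min(d) + late_cutoff
    mean(d[keep])
  }, numeric(1))
  pheno_series(as.integer(names(means)), round(means), bounds = bounds)
}

#' Construct / read a daily climate series
#'
#' A `climate_series` holds one mean daily temperature per calendar day with
#' contiguous coverage (no gaps, no duplicates) and finite values.
#'
#' @param date `Date` vector (or strings in ISO-8601 / dd/mm/yyyy form).
#' @param temp Numeric daily mean temperature, degrees Celsius.
#' @return A data frame of class `climate_series` with columns `date`, `temp`.
#' @export
climate_series <- function(date, temp) {
  date <- parse_pc_date(date)
  temp <- as.numeric(temp)
  if (length(date) != length(temp)) stop("date and temp lengths differ")
  o <- order(date)
  date <- date[o]; temp <- temp[o]
  if (anyDuplicated(date))
    stop("duplicate date in climate data: ", date[duplicated(date)][1])
  gaps <- diff(as.integer(date))
  if (any(gaps != 1L)) {
    i <- which(gaps != 1L)[1]
    stop("gap in climate data after ", date[i], " (next record ", date[i + 1], ")")
  }
  if (any(!is.finite(temp)))
    stop("non-finite temperature on ", date[which(!is.finite(temp))[1]])
  structure(data.frame(date = date, temp = temp),
            class = c("climate_series", "data.frame"))
}

#' @rdname climate_series
#' @param path Path to a CSV with a date column (ISO-8601 or dd/mm/yyyy) and
#'   a temperature column; extra columns are ignored.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idate <- match_column(names(raw), c("date"), "date", path)
  itemp <- match_column(names(raw),
                        c("temp", "temperature", "temperature_c", "mean_temp",
                          "temperature_oc", "temperature_degc"),
                        "temperature", path)
  climate_series(raw[[idate]], raw[[itemp]])
}

#' @rdname climate_series
#' @param x A `climate_series`.
#' @export
write_climate <- function(x, path) {
  stopifnot(inherits(x, "climate_series"))
  utils::write.csv(data.frame(date = format(x$date, "%Y-%m-%d"), temp = x$temp),
                   path, row.names = FALSE)
  invisible(path)
}

#' Build the years-by-lag climate matrix
#'
#' For each event year, collects daily mean temperatures on the calendar days
#' `lag` days before the reference day of that year, for `lag = 0, ..., 364`
#' (lag 0 is the reference day itself). The walk-back uses real calendar
#' dates, so a 365-lag row spans 29 February in years where it occurs.
#'
#' @param climate A [climate_series()].
#' @param years Integer vector of event years.
#' @param reference_day Month-day anchor, `"MM-DD"`; default `"05-20"`
#'   (20 May).
#' @param lags Integer vector of lags to include; default `0:364`.
#' @return A numeric matrix of class `climate_matrix` (rows = years, columns
#'   `d0 ... d364`) with attributes `years`, `lags`, `reference_day`.
#' @export
build_climate_matrix <- function(climate, years, reference_day = "05-20",
                                 lags = 0:364) {
  stopifnot(inherits(climate, "climate_series"))
  years <- sort(unique(as.integer(years)))
  lags <- as.integer(lags)
  if (any(lags < 0)) stop("lags must be non-negative")
  ref <- as.Date(sprintf("%d-%s", years, reference_day))
  if (anyNA(ref)) stop("invalid reference_day: ", reference_day)
  M <- matrix(NA_real_, nrow = length(years), ncol = length(lags),
              dimnames = list(years, paste0("d", lags)))
  for (i in seq_along(years)) {
    wanted <- ref[i] - lags
    idx <- match(wanted, climate$date)
    if (anyNA(idx)) {
      miss <- wanted[is.na(idx)][1]
      stop("climate data missing ", format(miss, "%Y-%m-%d"),
           " needed for year ", years[i])
    }
    M[i, ] <- climate$temp[idx]
  }
  structure(M, class = c("climate_matrix", "matrix"),
            years = years, lags = lags, reference_day = reference_day)
}

#' Matrix of daily temperatures at lags before each year's event
#'
#' Companion to [build_climate_matrix()] for relative (event-anchored)
#' windows: entry `(year, lag)` is the temperature `lag` days before that
#' year's observed event date.
#'
#' @param climate A [climate_series()].
#' @param phenology A [pheno_series()].
#' @param lags Integer vector of lags; default `1:365` (the event day itself
#'   is excluded).
#' @return A `climate_matrix` whose `reference_day` attribute is `"event"`.
#' @export
build_relative_matrix <- function(climate, phenology, lags = 1:365) {
  stopifnot(inherits(climate, "climate_series"), inherits(phenology, "pheno_series"))
  lags <- as.integer(lags)
  ev <- event_date(phenology$year, phenology$event_day)
  M <- matrix(NA_real_, nrow = nrow(phenology), ncol = length(lags),
              dimnames = list(phenology$year, paste0("d", lags)))
  for (i in seq_len(nrow(phenology))) {
    wanted <- ev[i] - lags
    idx <- match(wanted, climate$date)
    if (anyNA(idx)) {
      miss <- wanted[is.na(idx)][1]
      stop("climate data missing ", format(miss, "%Y-%m-%d"),
           " needed for year ", phenology$year[i], " (event-anchored lags)")
    }
    M[i, ] <- climate$temp[idx]
  }
  structure(M, class = c("climate_matrix", "matrix"),
            years = phenology$year, lags = lags, reference_day = "event")
}

#' Subset a climate matrix to a set of years
#'
#' @param matrix A `climate_matrix`.
#' @param years Years to keep (must all be present).
#' @return A `climate_matrix` restricted to `years`.
#' @export
subset_years <- function(matrix, years) {
  have <- attr(matrix, "years")
  if (!all(years %in% have))
    stop("years not present in climate matrix: ",
         paste(setdiff(years, have), collapse = ", "))
  keep <- match(sort(as.integer(years)), have)
  structure(matrix[keep, , drop = FALSE],
            class = class(matrix), years = have[keep],
            lags = attr(matrix, "lags"),
            reference_day = attr(matrix, "reference_day"))
}

#' Write / read a climate matrix as CSV
#'
#' Serialized with a `year` column followed by lag columns `d0 ... d364`.
#'
#' @param x A `climate_matrix`.
#' @param path CSV path.
#' @param reference_day Anchor recorded when reading back.
#' @return `write_climate_matrix()` returns `path` invisibly;
#'   `read_climate_matrix()` returns a `climate_matrix`.
#' @export
write_climate_matrix <- function(x, path) {
  stopifnot(inherits(x, "climate_matrix"))
  df <- data.frame(year = attr(x, "years"), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_matrix
#' @export
read_climate_matrix <- function(path, reference_day = "05-20") {
  raw <- utils::read.csv(path, check.names = FALSE)
  stopifnot("year" %in% names(raw))
  lag_cols <- grep("^d\\d+$", names(raw), value = TRUE)
  lags <- as.integer(sub("^d", "", lag_cols))
  M <- as.matrix(raw[, lag_cols, drop = FALSE])
  rownames(M) <- raw$year
  structure(M, class = c("climate_matrix", "matrix"),
            years = as.integer(raw$year), lags = lags,
            reference_day = reference_day)
}

#' @export
print.pheno_series <- function(x, ...) {
  cat("<pheno_series> ", nrow(x), " years (", min(x$year), "-", max(x$year),
      "), mean event day ", round(mean(x$event_day), 1),
      " (days since 1 April)\n", sep = "")
  invisible(x)
}

#' @export
print.climate_series <- function(x, ...) {
  cat("<climate_series> ", nrow(x), " days, ", format(min(x$date)), " to ",
      format(max(x$date)), ", mean ", round(mean(x$temp), 2), " degC\n", sep = "")
  invisible(x)
}

#' @export
print.climate_matrix <- function(x, ...) {
  lg <- attr(x, "lags")
  cat("<climate_matrix> ", nrow(x), " years x ", ncol(x), " lags (",
      min(lg), "..", max(lg), "), anchor ", attr(x, "reference_day"), "\n",
      sep = "")
  invisible(x)
}
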