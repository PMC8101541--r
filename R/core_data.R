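#' @keywords internal
"_PACKAGE"

# Closed code sets ------------------------------------------------------------

#' Region and species code sets
#'
#' The closed sets of codes accepted in incident tables. `UNK` marks records
#' whose state could not be established; they contribute to the national
#' (`AUS`) aggregate only. `AUS` itself is never a record-level code: it is
#' always computed by aggregating incidents across regions.
#'
#' @return character vector of valid codes.
#' @export
region_codes <- function() {
  c("NSW", "QLD", "WA", "SA", "VIC", "TAS", "NT", "UNK")
}

#' @rdname region_codes
#' @export
species_codes <- function() {
  c("white", "tiger", "bull", "whaler", "other", "unknown")
}

#' Species alias table
#'
#' Free-text species labels commonly found in incident registries mapped onto
#' the closed species set. Matching is case-insensitive on the trimmed label.
#' Bronze whaler and dusky sharks are recorded as `whaler`; bull and whaler
#' records are kept distinct here and only merged inside relative-abundance
#' scenarios.
#'
#' @return named character vector: names are raw labels, values canonical codes.
#' @export
species_aliases <- function() {
  c(
    "bronze whaler"   = "whaler",
    "dusky"           = "whaler",
    "dusky whaler"    = "whaler",
    "white pointer"   = "white",
    "white shark"     = "white",
    "tiger shark"     = "tiger",
    "bull shark"      = "bull",
    "unidentified"    = "unknown",
    "unspecified"     = "unknown"
  )
}

canonical_species <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  alias <- species_aliases()
  hit <- match(raw, names(alias))
  out <- ifelse(is.na(hit), raw, alias[hit])
  unname(out)
}

parse_flag <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("1", "true", "t", "yes")] <- TRUE
  out[raw %in% c("0", "false", "f", "no")] <- FALSE
  out
}

# Incident records ------------------------------------------------------------

#' Validate a table of shark-bite incident records
#'
#' Checks one row per shark-human interaction against the closed region and
#' species code sets, parses fatal/provoked flags (accepting 0/1/true/false,
#' case-insensitively), maps species aliases onto the canonical labels, and
#' enforces the study window on the year column. All problems are collected
#' and reported together, indexed by row number.
#'
#' @param df data.frame with columns `year`, `region`, `species`, `fatal`,
#'   `provoked`.
#' @param year_window integer length-2 inclusive study window, or `NULL` to
#'   accept any year. Default 1900-2019: series start chosen where the record
#'   becomes dense enough for model fitting, and the final fitted year is the
#'   last complete one before the projection window opens.
#' @return validated data.frame of class `shark_incidents` with columns
#'   `year` (integer), `region`, `species` (canonical), `fatal`, `provoked`
#'   (logical).
#' @export
incident_records <- function(df, year_window = c(1900L, 2019L)) {
  required <- c("year", "region", "species", "fatal", "provoked")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_sc(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "sharkcast_format_error"
    )
  }

  n <- nrow(df)
  problems <- character(0)
  row_id <- seq_len(n)

  year <- suppressWarnings(as.integer(df$year))
  bad <- row_id[is.na(year)]
  if (length(bad)) problems <- c(problems, sprintf("row %d: unparseable year '%s'", bad, df$year[bad]))
  if (!is.null(year_window)) {
    bad <- row_id[!is.na(year) & (year < year_window[1] | year > year_window[2])]
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "row %d: year %d outside study window %d-%d",
        bad, year[bad], year_window[1], year_window[2]
      ))
    }
  }

  region <- toupper(trimws(as.character(df$region)))
  bad <- row_id[!(region %in% region_codes())]
  if (length(bad)) problems <- c(problems, sprintf("row %d: unknown region '%s'", bad, df$region[bad]))

  species <- canonical_species(df$species)
  bad <- row_id[!(species %in% species_codes())]
  if (length(bad)) problems <- c(problems, sprintf("row %d: unknown species '%s'", bad, df$species[bad]))

  fatal <- parse_flag(df$fatal)
  bad <- row_id[is.na(fatal)]
  if (length(bad)) problems <- c(problems, sprintf("row %d: unparseable fatal flag '%s'", bad, df$fatal[bad]))

  provoked <- parse_flag(df$provoked)
  bad <- row_id[is.na(provoked)]
  if (length(bad)) problems <- c(problems, sprintf("row %d: unparseable provoked flag '%s'", bad, df$provoked[bad]))

  if (length(problems) > 0) {
    abort_sc(
      paste0("invalid incident record(s):\n", paste(problems, collapse = "\n")),
      "sharkcast_validation_error"
    )
  }

  out <- data.frame(
    year = year, region = region, species = species,
    fatal = fatal, provoked = provoked,
    stringsAsFactors = FALSE
  )
  class(out) <- c("shark_incidents", "data.frame")
  attr(out, "year_window") <- year_window
  attr(out, "n_unknown_region") <- sum(region == "UNK")
  out
}

#' Read incident records from CSV
#'
#' Reads a comma-separated incident table (UTF-8, header required, columns
#' `year,region,species,fatal,provoked`) and validates it with
#' [incident_records()].
#'
#' @param path path to the CSV file.
#' @inheritParams incident_records
#' @return a `shark_incidents` data.frame.
#' @export
read_incidents <- function(path, year_window = c(1900L, 2019L)) {
  if (!file.exists(path)) {
    abort_sc(sprintf("incident file not found: %s", path), "sharkcast_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  incident_records(df, year_window = year_window)
}

#' Write incident records to CSV
#'
#' @param records a `shark_incidents` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidents <- function(records, path) {
  utils::write.csv(
    records[, c("year", "region", "species", "fatal", "provoked")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Filters ---------------------------------------------------------------------

#' Filter presets for incident subsets
#'
#' The five record subsets analysed throughout: all incidents, fatalities
#' only, unprovoked incidents only, white sharks only, and the three species
#' responsible for most bites (white, tiger, bull).
#'
#' @return character vector of preset names.
#' @export
filter_presets <- function() {
  c("all", "fatal_only", "unprovoked_only", "white_only", "white_tiger_bull")
}

#' Subset incident records by a named preset
#'
#' @param records a `shark_incidents` data.frame.
#' @param preset one of [filter_presets()].
#' @return the filtered `shark_incidents` data.frame (possibly empty).
#' @export
filter_incidents <- function(records, preset = filter_presets()) {
  preset <- match.arg(preset)
  keep <- switch(preset,
    all              = rep(TRUE, nrow(records)),
    fatal_only       = records$fatal,
    unprovoked_only  = !records$provoked,
    white_only       = records$species == "white",
    white_tiger_bull = records$species %in% c("white", "tiger", "bull")
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count / population / rate series --------------------------------------------

new_series <- function(df, region, class, extra = list()) {
  rownames(df) <- NULL
  attr(df, "region") <- region
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c(class, "data.frame")
  df
}

#' Yearly incident counts for one region
#'
#' Tallies incident records into a yearly count series over a consecutive
#' window; years without incidents get zero. `region = "AUS"` aggregates
#' every region code, including records with unknown state (`UNK`), which
#' contribute to the national series only.
#'
#' @param records a `shark_incidents` data.frame.
#' @param region a region code or `"AUS"`.
#' @param years consecutive integer years of the output window.
#' @return a `count_series` data.frame with columns `year`, `count`.
#' @export
build_count_series <- function(records, region, years) {
  years <- as.integer(years)
  if (!is_consecutive(years)) {
    abort_sc("`years` must be strictly consecutive integers", "sharkcast_config_error")
  }
  if (!(region %in% c("AUS", setdiff(region_codes(), "UNK")))) {
    abort_sc(sprintf("unknown region '%s'", region), "sharkcast_validation_error")
  }
  sub <- if (region == "AUS") records else records[records$region == region, , drop = FALSE]
  counts <- as.integer(table(factor(sub$year, levels = years)))
  new_series(
    data.frame(year = years, count = counts),
    region, "count_series"
  )
}

#' Convert yearly counts to per-capita bite rates
#'
#' Divides yearly incident counts by the human population of the same region
#' and year, giving bites per person per year.
#'
#' @param counts a `count_series`.
#' @param pop a `population_series` covering at least the same years.
#' @return a `rate_series` data.frame with columns `year`, `rate`.
#' @export
to_per_capita <- function(counts, pop) {
  idx <- match(counts$year, pop$year)
  if (anyNA(idx)) {
    abort_sc(
      sprintf(
        "population series does not cover year(s): %s",
        paste(counts$year[is.na(idx)], collapse = ", ")
      ),
      "sharkcast_alignment_error"
    )
  }
  new_series(
    data.frame(year = counts$year, rate = counts$count / pop$population[idx]),
    attr(counts, "region"), "rate_series"
  )
}

#' Population series constructor
#'
#' @param region region code.
#' @param years consecutive integer years.
#' @param population positive person counts, one per year.
#' @return a `population_series` data.frame with columns `year`, `population`.
#' @export
population_series <- function(region, years, population) {
  years <- as.integer(years)
  if (!is_consecutive(years)) {
    abort_sc("population years must be strictly consecutive", "sharkcast_config_error")
  }
  if (length(population) != length(years) || any(!is.finite(population)) || any(population <= 0)) {
    abort_sc("population must be positive and one value per year", "sharkcast_validation_error")
  }
  new_series(
    data.frame(year = years, population = as.numeric(population)),
    region, "population_series"
  )
}

#' Read a long-format population table
#'
#' Expects columns `region,year,population`, one row per region-year, covering
#' both the fitting and projection windows.
#'
#' @param path CSV path.
#' @return named list of `population_series`, one per region present.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) {
    abort_sc(sprintf("population file not found: %s", path), "sharkcast_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region", "year", "population")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_sc(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "sharkcast_format_error"
    )
  }
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$year), ]
    population_series(d$region[1], d$year, d$population)
  })
  out
}

#' Write population series to a long-format CSV
#'
#' @param pops named list of `population_series` (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pops, path) {
  if (inherits(pops, "population_series")) pops <- list(pops)
  long <- do.call(rbind, lapply(pops, function(p) {
    data.frame(region = attr(p, "region"), year = p$year, population = p$population)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# RMS scaling -----------------------------------------------------------------

#' Scale a rate series by its root mean square
#'
#' Divides a per-capita rate series by its root mean square computed with the
#' n-1 denominator, `sqrt(sum(rate^2) / (n - 1))` (the divisor used by
#' `scale(x, center = FALSE)`), giving a dimensionless series. The divisor is
#' stored so the transform is exactly invertible with [unscale()].
#'
#' @param rates a `rate_series` with at least two observations, not all zero.
#' @param denominator `"n-1"` (default) or `"n"` for the RMS divisor.
#' @return a `scaled_rate_series` with columns `year`, `scaled` and attribute
#'   `scale_factor`.
#' @export
rms_scale <- function(rates, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  x <- rates$rate
  n <- length(x)
  if (n < 2) {
    abort_sc("need at least 2 observations to scale", "sharkcast_degenerate_error")
  }
  if (all(x == 0)) {
    abort_sc("all-zero rate series cannot be RMS-scaled", "sharkcast_degenerate_error")
  }
  denom <- if (denominator == "n-1") n - 1 else n
  scale_factor <- sqrt(sum(x^2) / denom)
  new_series(
    data.frame(year = rates$year, scaled = x / scale_factor),
    attr(rates, "region"), "scaled_rate_series",
    extra = list(scale_factor = scale_factor)
  )
}

#' Invert an RMS scaling
#'
#' Multiplies a scaled series by its stored scale factor, recovering the
#' per-capita rate series exactly.
#'
#' @param scaled a `scaled_rate_series` carrying a `scale_factor` attribute.
#' @return a `rate_series`.
#' @export
unscale <- function(scaled) {
  sf <- attr(scaled, "scale_factor")
  if (is.null(sf)) {
    abort_sc("scaled series has no stored scale_factor", "sharkcast_state_error")
  }
  new_series(
    data.frame(year = scaled$year, rate = scaled$scaled * sf),
    attr(scaled, "region"), "rate_series"
  )
}
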