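#' @name dialects
#' @title Input dialects for panel files
#'
#' @description A dialect declares, up front, how a delimited panel file is
#' laid out: the delimiter, the column names, whether rates are percentages
#' or proportions, and (for wide exports) which file columns hold which
#' ladder levels or factors. Nothing is ever sniffed from file content.
#'
#' `access_dialect()` describes access-rate files, `covariate_dialect()`
#' describes covariate files. The canonical layout is long format (one record
#' per row). A wide layout is declared by supplying `value_columns`, a named
#' character vector mapping file columns to ladder levels (access) or factors
#' (covariates); for wide access files the constant `service` and `area` of
#' the file must also be declared.
#'
#' @param delim field delimiter; comma by default, tab accepted.
#' @param unit `"proportion"` (rates already in \[0, 1\]) or `"percent"`
#'   (divided by 100 exactly once at read time).
#' @param range `"unit"` enforces rates in \[0, 1\] after ingestion (the rule
#'   for real JMP-style exports); `"extended"` admits rates slightly outside
#'   it, as produced by the untruncated Gaussian observation model of the
#'   synthetic generator.
#' @param columns named character vector mapping canonical column names to
#'   the names used in the file header.
#' @param value_columns named character vector declaring a wide layout:
#'   names are file columns, values are ladder levels / factor names.
#' @param service,area constants for wide access files.
#' @return a list of class `"wash_dialect"`.
#' @examples
#' access_dialect(unit = "percent")
#' covariate_dialect(delim = "\t")
NULL

.access_ladders <- c("safely_managed", "basic", "at_least_basic", "limited",
                     "unimproved", "surface_water", "open_defecation",
                     "basic_or_higher")
.services <- c("drinking_water", "sanitation")
.areas <- c("total", "urban", "rural")
.factors <- c("gdp_pc", "gdp_ppp_pc", "urban_pop_rate", "democracy_index",
              "renewable_water_pc")
.log_factors <- c("gdp_pc", "gdp_ppp_pc", "renewable_water_pc")

#' @rdname dialects
#' @export
access_dialect <- function(delim = ",", unit = c("proportion", "percent"),
                           range = c("unit", "extended"),
                           columns = NULL, value_columns = NULL,
                           service = NULL, area = NULL) {
  unit <- match.arg(unit)
  range <- match.arg(range)
  std <- c(country_code = "country_code", country_name = "country_name",
           year = "year", service = "service", area = "area",
           ladder = "ladder", rate = "rate")
  if (!is.null(columns)) std[names(columns)] <- columns
  if (!is.null(value_columns)) {
    if (is.null(service) || is.null(area))
      stop("wide access dialects must declare the file's service and area")
    service <- match.arg(service, .services)
    area <- match.arg(area, .areas)
  }
  structure(list(kind = "access", delim = delim, unit = unit, range = range,
                 columns = std, value_columns = value_columns,
                 service = service, area = area),
            class = "wash_dialect")
}

#' @rdname dialects
#' @export
covariate_dialect <- function(delim = ",", columns = NULL,
                              value_columns = NULL) {
  std <- c(country_code = "country_code", year = "year",
           factor = "factor", value = "value")
  if (!is.null(columns)) std[names(columns)] <- columns
  structure(list(kind = "covariate", delim = delim,
                 columns = std, value_columns = value_columns),
            class = "wash_dialect")
}

.read_delim <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, header = TRUE, sep = delim, quote = "\"",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

.require_cols <- function(raw, cols, path) {
  miss <- setdiff(cols, names(raw))
  if (length(miss))
    stop("file ", path, " lacks declared column(s): ",
         paste(miss, collapse = ", "))
}

.load_report <- function(read, dropped, what) {
  rep <- list(records_read = read, records_dropped = dropped)
  message(sprintf("[washbayes] %s: %d record(s) read, %d dropped", what,
                  read, dropped))
  rep
}

#' Read an access-rate panel
#'
#' Reads a delimited access-rate file under a declared [access_dialect()] and
#' validates it: rates are rescaled from percent to proportion exactly once
#' when the dialect says so, out-of-range rates and ladder/service
#' inconsistencies are errors (with the offending line number), duplicate
#' (country, year, service, area, ladder) keys are errors, and rows with a
#' missing rate are dropped and counted in the load report (attached as
#' attribute `"load_report"`).
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect an [access_dialect()].
#' @return a `data.frame` of class `"wash_access"` with columns
#'   `country_code`, `country_name`, `year`, `service`, `area`, `ladder`,
#'   `rate` (proportions).
#' @export
read_access_panel <- function(path, dialect = access_dialect()) {
  stopifnot(inherits(dialect, "wash_dialect"), dialect$kind == "access")
  raw <- .read_delim(path, dialect$delim)
  cl <- dialect$columns

  if (!is.null(dialect$value_columns)) {
    .require_cols(raw, c(cl[["country_code"]], cl[["year"]],
                         names(dialect$value_columns)), path)
    pieces <- lapply(names(dialect$value_columns), function(fc) {
      data.frame(country_code = as.character(raw[[cl[["country_code"]]]]),
                 country_name = if (cl[["country_name"]] %in% names(raw))
                   as.character(raw[[cl[["country_name"]]]]) else
                     rep(NA_character_, nrow(raw)),
                 year = raw[[cl[["year"]]]],
                 service = rep(dialect$service, nrow(raw)),
                 area = rep(dialect$area, nrow(raw)),
                 ladder = rep(unname(dialect$value_columns[[fc]]), nrow(raw)),
                 rate_raw = raw[[fc]],
                 line = seq_len(nrow(raw)) + 1L,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, pieces)
  } else {
    .require_cols(raw, unname(cl[c("country_code", "year", "service", "area",
                                   "ladder", "rate")]), path)
    d <- data.frame(country_code = as.character(raw[[cl[["country_code"]]]]),
                    country_name = if (cl[["country_name"]] %in% names(raw))
                      as.character(raw[[cl[["country_name"]]]]) else
                        rep(NA_character_, nrow(raw)),
                    year = raw[[cl[["year"]]]],
                    service = as.character(raw[[cl[["service"]]]]),
                    area = as.character(raw[[cl[["area"]]]]),
                    ladder = as.character(raw[[cl[["ladder"]]]]),
                    rate_raw = raw[[cl[["rate"]]]],
                    line = seq_len(nrow(raw)) + 1L,
                    stringsAsFactors = FALSE)
  }

  n_read <- nrow(d)
  d$year <- suppressWarnings(as.integer(d$year))
  d$rate_raw <- suppressWarnings(as.numeric(d$rate_raw))
  bad <- which(is.na(d$year) | d$country_code == "" |
                 !(d$service %in% .services) | !(d$area %in% .areas) |
                 !(d$ladder %in% .access_ladders))
  if (length(bad))
    stop("malformed access row at line ", d$line[bad[1]], " of ", path)

  miss <- is.na(d$rate_raw)
  d <- d[!miss, , drop = FALSE]

  d$rate <- if (dialect$unit == "percent") d$rate_raw / 100 else d$rate_raw
  if (dialect$range == "unit") {
    out <- which(d$rate < 0 | d$rate > 1)
    if (length(out))
      stop("rate out of range at line ", d$line[out[1]], " of ", path,
           " (", format(d$rate_raw[out[1]]), ")")
  }

  mismatch <- which((d$ladder == "surface_water" & d$service != "drinking_water") |
                      (d$ladder == "open_defecation" & d$service != "sanitation"))
  if (length(mismatch))
    stop("ladder/service mismatch at line ", d$line[mismatch[1]], " of ", path)

  key <- paste(d$country_code, d$year, d$service, d$area, d$ladder, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate access key at line ", d$line[which(duplicated(key))[1]],
         " of ", path)

  d <- d[, c("country_code", "country_name", "year", "service", "area",
             "ladder", "rate")]
  rownames(d) <- NULL
  structure(d, class = c("wash_access", "data.frame"),
            load_report = .load_report(n_read, sum(miss), "access panel"))
}

#' Read a covariate panel
#'
#' Reads a delimited country-by-year covariate file (World Bank / EIU-style,
#' reshaped long or declared wide) under a [covariate_dialect()]. Values stay
#' on the raw scale; no transformation is applied at read time. Non-positive
#' values of factors that are later log-transformed (`gdp_pc`, `gdp_ppp_pc`,
#' `renewable_water_pc`) are excluded with a warning, and an out-of-range
#' urban population rate is an error.
#'
#' @inheritParams read_access_panel
#' @param dialect a [covariate_dialect()].
#' @return a `data.frame` of class `"wash_cov"` with columns `country_code`,
#'   `year`, `factor`, `value`, plus a `"load_report"` attribute.
#' @export
read_covariates <- function(path, dialect = covariate_dialect()) {
  stopifnot(inherits(dialect, "wash_dialect"), dialect$kind == "covariate")
  raw <- .read_delim(path, dialect$delim)
  cl <- dialect$columns

  if (!is.null(dialect$value_columns)) {
    .require_cols(raw, c(cl[["country_code"]], cl[["year"]],
                         names(dialect$value_columns)), path)
    pieces <- lapply(names(dialect$value_columns), function(fc) {
      data.frame(country_code = as.character(raw[[cl[["country_code"]]]]),
                 year = raw[[cl[["year"]]]],
                 factor = rep(unname(dialect$value_columns[[fc]]), nrow(raw)),
                 value = raw[[fc]],
                 line = seq_len(nrow(raw)) + 1L, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, pieces)
  } else {
    .require_cols(raw, unname(cl), path)
    d <- data.frame(country_code = as.character(raw[[cl[["country_code"]]]]),
                    year = raw[[cl[["year"]]]],
                    factor = as.character(raw[[cl[["factor"]]]]),
                    value = raw[[cl[["value"]]]],
                    line = seq_len(nrow(raw)) + 1L, stringsAsFactors = FALSE)
  }

  n_read <- nrow(d)
  d$year <- suppressWarnings(as.integer(d$year))
  d$value <- suppressWarnings(as.numeric(d$value))
  bad <- which(is.na(d$year) | d$country_code == "" | !(d$factor %in% .factors))
  if (length(bad))
    stop("malformed covariate row at line ", d$line[bad[1]], " of ", path)

  miss <- is.na(d$value)
  d <- d[!miss, , drop = FALSE]

  urb <- d$factor == "urban_pop_rate"
  if (any(urb & (d$value < 0 | d$value > 100)))
    stop("urban population rate outside [0, 100] at line ",
         d$line[which(urb & (d$value < 0 | d$value > 100))[1]], " of ", path)

  nonpos <- d$factor %in% .log_factors & d$value <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " non-positive value(s) of log-transformed factor(s)",
            " excluded (cannot be log-transformed)")
    d <- d[!nonpos, , drop = FALSE]
  }

  key <- paste(d$country_code, d$year, d$factor, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate covariate key at line ", d$line[which(duplicated(key))[1]],
         " of ", path)

  d <- d[, c("country_code", "year", "factor", "value")]
  rownames(d) <- NULL
  structure(d, class = c("wash_cov", "data.frame"),
            load_report = .load_report(n_read, sum(miss) + sum(nonpos),
                                       "covariate panel"))
}

#' Carry the 2006 democracy index back to 2000
#'
#' The democracy index series starts in 2006, so analyses anchored at 2000
#' use the 2006 score as the 2000 value. For every country with a
#' `democracy_index` value at `from_year` and none at `to_year`, a copy at
#' `to_year` is added; existing `to_year` values are left untouched. The
#' number of carried records is reported and attached as attribute
#' `"carried"`.
#'
#' @param covariates a covariate panel (`wash_cov` or plain data frame with
#'   the same columns).
#' @param from_year,to_year source and destination years.
#' @return the augmented covariate panel.
#' @export
carry_democracy_2006_to_2000 <- function(covariates, from_year = 2006L,
                                         to_year = 2000L) {
  dem <- covariates[covariates$factor == "democracy_index", , drop = FALSE]
  have_to <- unique(dem$country_code[dem$year == to_year])
  src <- dem[dem$year == from_year & !(dem$country_code %in% have_to), ,
             drop = FALSE]
  if (nrow(src)) {
    src$year <- as.integer(to_year)
    out <- rbind(as.data.frame(covariates), as.data.frame(src))
  } else {
    out <- as.data.frame(covariates)
  }
  rownames(out) <- NULL
  message(sprintf("[washbayes] democracy index: %d record(s) carried %d -> %d",
                  nrow(src), from_year, to_year))
  structure(out, class = c("wash_cov", "data.frame"), carried = nrow(src))
}

#' Aggregate ladder levels into the basic-or-higher category
#'
#' Builds the analysis category "basic or higher" from JMP ladder rows. In
#' JMP exports "at least basic" is already the cumulative category (basic +
#' safely managed), so when an `at_least_basic` row exists for a
#' (country, year, service, area) key it is used verbatim
#' (`policy = "prefer_at_least_basic"`, the default); otherwise the disjoint
#' `safely_managed` and `basic` rows are summed. Summing all three would
#' double-count. A computed sum exceeding 1 by more than `tol` signals
#' inconsistent ladder input and is an error naming the key, never a silent
#' clip.
#'
#' @param access an access panel.
#' @param policy `"prefer_at_least_basic"` or `"sum_components"` (always sum
#'   `safely_managed + basic`, ignoring any `at_least_basic` row).
#' @param tol tolerance above 1 allowed for computed sums before erroring.
#' @return the access panel with one `basic_or_higher` row appended per key
#'   that has the required inputs.
#' @export
aggregate_basic_or_higher <- function(access,
                                      policy = c("prefer_at_least_basic",
                                                 "sum_components"),
                                      tol = 1e-9) {
  policy <- match.arg(policy)
  a <- as.data.frame(access)
  rel <- a[a$ladder %in% c("safely_managed", "basic", "at_least_basic"), ,
           drop = FALSE]
  if (!nrow(rel)) return(access)
  key <- interaction(rel$country_code, rel$year, rel$service, rel$area,
                     drop = TRUE, sep = "|")
  pieces <- lapply(split(rel, key), function(g) {
    alb <- g$rate[g$ladder == "at_least_basic"]
    if (policy == "prefer_at_least_basic" && length(alb) == 1) {
      val <- alb
    } else {
      sm <- g$rate[g$ladder == "safely_managed"]
      ba <- g$rate[g$ladder == "basic"]
      if (!length(sm) && !length(ba)) return(NULL)
      val <- sum(sm, ba)
      if (val > 1 + tol)
        stop("basic_or_higher aggregate ", format(val), " exceeds 1 for key ",
             g$country_code[1], "/", g$year[1], "/", g$service[1], "/",
             g$area[1], " (inconsistent ladder input)")
    }
    out <- g[1, , drop = FALSE]
    out$ladder <- "basic_or_higher"
    out$rate <- val
    out
  })
  agg <- do.call(rbind, pieces)
  out <- rbind(a, agg)
  rownames(out) <- NULL
  structure(out, class = c("wash_access", "data.frame"))
}

#' Write and read result tables
#'
#' Result tables (model summaries, improvement tables) are written as
#' delimited UTF-8 text with a header row. Numeric columns are printed with
#' 17 significant digits so that writing and re-reading reproduces the table
#' exactly.
#'
#' @param table a data frame (e.g. from [fit_summary()] or
#'   [improvement_table()]).
#' @param path output/input file path.
#' @param delim field delimiter.
#' @return `write_result_table()` returns `path` invisibly;
#'   `read_result_table()` returns the data frame.
#' @export
write_result_table <- function(table, path, delim = ",") {
  d <- as.data.frame(table)
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  }
  ok <- tryCatch({
    write.table(d, path, sep = delim, row.names = FALSE, quote = FALSE,
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write result table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path, delim = ",") {
  d <- read.table(path, header = TRUE, sep = delim, quote = "\"",
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  rownames(d) <- NULL
  d
}

#' Write panels in the canonical dialect
#'
#' @param panel an access or covariate panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_access_panel <- function(panel, path) {
  d <- as.data.frame(panel)
  d$rate <- sprintf("%.17g", d$rate)
  write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_access_panel
#' @export
write_covariate_panel <- function(panel, path) {
  d <- as.data.frame(panel)
  d$value <- sprintf("%.17g", d$value)
  write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
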