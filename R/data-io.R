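#' Default column mapping for DHI record tables
#'
#' Maps the internal field names used throughout the package to the column
#' names of an input file. Override entries to match a file whose headers
#' differ, e.g. `default_column_map(fat_pct = "FatPercent")`.
#'
#' @param ... Named overrides, `internal_name = "file column name"`.
#' @return Named character vector, internal name -> file column.
#' @export
default_column_map <- function(...) {
  map <- c(
    cow_id = "cow_id", farm_id = "farm_id",
    farm_size_count = "farm_size_count",
    test_date = "test_date", calving_date = "calving_date",
    parity = "parity", days_in_milk = "days_in_milk",
    fat_pct = "fat_pct", calving_interval_days = "calving_interval_days",
    milk_305d_kg = "milk_305d_kg"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    map[names(over)] <- over
  }
  map
}

.mandatory_fields <- c("cow_id", "calving_date", "parity", "days_in_milk",
                       "fat_pct")

#' Read DHI test-day records from a delimited file
#'
#' Reads one test-day record per row. Dates must be ISO 8601
#' (`YYYY-MM-DD`). Rows whose mandatory fields (cow id, calving date,
#' parity, days in milk, fat percentage) cannot be parsed are removed from
#' the returned table and reported in the `parse_failures` attribute with
#' the failing field, never silently dropped. Optional fields that fail to
#' parse become `NA`.
#'
#' @param path Path to a CSV (or other delimited) file with a header row.
#' @param column_map Named character vector from [default_column_map()].
#' @param sep Field separator, default comma.
#'
#' @return A `data.frame` of test-day records with internal column names;
#'   attribute `parse_failures` is a data.frame (`row`, `field`) of rejected
#'   rows.
#' @export
read_dhi_records <- function(path, column_map = default_column_map(),
                             sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("input file has no data rows", call. = FALSE)
  }
  out <- data.frame(row.names = NULL)
  numf <- c("farm_size_count", "parity", "days_in_milk", "fat_pct",
            "calving_interval_days", "milk_305d_kg")
  datef <- c("test_date", "calving_date")
  for (field in names(column_map)) {
    v <- raw[[column_map[[field]]]]
    if (is.null(v)) v <- rep(NA_character_, nrow(raw))
    parsed <- if (field %in% numf) {
      suppressWarnings(as.numeric(v))
    } else if (field %in% datef) {
      suppressWarnings(as.Date(v, format = "%Y-%m-%d"))
    } else {
      v
    }
    if (nrow(out) == 0L && ncol(out) == 0L) {
      out <- data.frame(x = parsed)
      names(out) <- field
    } else {
      out[[field]] <- parsed
    }
  }
  fail_row <- integer(0)
  fail_field <- character(0)
  for (field in .mandatory_fields) {
    blank <- is.na(out[[field]]) |
      (is.character(out[[field]]) & !nzchar(trimws(as.character(out[[field]]))))
    new <- which(blank & !(seq_len(nrow(out)) %in% fail_row))
    fail_row <- c(fail_row, new)
    fail_field <- c(fail_field, rep(field, length(new)))
  }
  failures <- data.frame(row = fail_row, field = fail_field,
                         stringsAsFactors = FALSE)
  if (nrow(failures)) {
    warning(nrow(failures), " row(s) with unparseable mandatory fields ",
            "moved to the parse-failure report", call. = FALSE)
    out <- out[-failures$row, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "parse_failures") <- failures
  out
}

#' Write DHI test-day records to CSV
#'
#' Inverse of [read_dhi_records()] with the default column map; dates are
#' written as ISO 8601.
#'
#' @param records Data frame of records with internal column names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dhi_records <- function(records, path) {
  out <- records
  for (field in c("test_date", "calving_date")) {
    if (field %in% names(out)) out[[field]] <- format(out[[field]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality screening of DHI test-day records
#'
#' Keeps records with parity 1-5, days in milk 1-305, and milk fat
#' percentage 1-7%. Each rejected record is counted under the first rule it
#' fails, in the fixed order parity, days-in-milk, fat-range, so the report
#' is deterministic; a missing value fails its rule. The filter is
#' idempotent.
#'
#' @param records Data frame with columns `parity`, `days_in_milk`,
#'   `fat_pct`.
#' @param parity_range,dim_range,fat_range Inclusive acceptance bounds for
#'   the three rules.
#'
#' @return List with `records` (the kept rows) and `report`, a `qc_report`
#'   list: `n_input`, `n_kept`, `n_rejected_by_rule` (named counts for
#'   `parity`, `days_in_milk`, `fat_pct`).
#' @export
qc_filter <- function(records, parity_range = c(1, 5),
                      dim_range = c(1, 305), fat_range = c(1, 7)) {
  stopifnot(all(c("parity", "days_in_milk", "fat_pct") %in% names(records)))
  in_range <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]
  ok_parity <- in_range(records$parity, parity_range)
  ok_dim <- in_range(records$days_in_milk, dim_range)
  ok_fat <- in_range(records$fat_pct, fat_range)
  first_fail <- ifelse(!ok_parity, "parity",
                ifelse(!ok_dim, "days_in_milk",
                ifelse(!ok_fat, "fat_pct", NA_character_)))
  kept <- records[is.na(first_fail), , drop = FALSE]
  rownames(kept) <- NULL
  counts <- c(
    parity = sum(first_fail == "parity", na.rm = TRUE),
    days_in_milk = sum(first_fail == "days_in_milk", na.rm = TRUE),
    fat_pct = sum(first_fail == "fat_pct", na.rm = TRUE)
  )
  report <- structure(list(
    n_input = nrow(records), n_kept = nrow(kept),
    n_rejected_by_rule = counts
  ), class = "qc_report")
  list(records = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC screening: %d of %d records kept\n", x$n_kept, x$n_input))
  for (nm in names(x$n_rejected_by_rule)) {
    cat(sprintf("  rejected by %-13s %d\n", paste0(nm, ":"),
                x$n_rejected_by_rule[[nm]]))
  }
  invisible(x)
}

#' Write a QC report as CSV and JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param csv_path Output CSV path (rule, count rows).
#' @param json_path Optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_qc_report <- function(report, csv_path, json_path = NULL) {
  df <- data.frame(
    rule = c("input", "kept", names(report$n_rejected_by_rule)),
    count = c(report$n_input, report$n_kept,
              unname(report$n_rejected_by_rule))
  )
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE)
  }
  invisible(csv_path)
}

#' Lactation month of a test day
#'
#' One lactation month per 30 days in milk (`ceiling(days/30)`); anything
#' beyond day 300 belongs to the final, eleventh month, so there are exactly
#' 11 months.
#'
#' @param days_in_milk Integer days since calving, at least 1 (vectorised).
#' @return Integer lactation month in 1..11.
#' @export
lactation_month <- function(days_in_milk) {
  if (!is.numeric(days_in_milk) || any(!is.finite(days_in_milk)) ||
      any(days_in_milk < 1)) {
    stop("`days_in_milk` must be finite and at least 1", call. = FALSE)
  }
  as.integer(pmin(ceiling(days_in_milk / 30), 11L))
}

.season_levels <- c("spring", "summer", "autumn", "winter")

#' Calving season from a calving date
#'
#' Spring is March-May, summer June-August, autumn September-November, and
#' winter December-February of the following year.
#'
#' @param calving_date `Date` vector.
#' @return Factor with levels spring, summer, autumn, winter.
#' @export
calving_season <- function(calving_date) {
  m <- as.integer(format(as.Date(calving_date), "%m"))
  lab <- c("winter", "winter", "spring", "spring", "spring",
           "summer", "summer", "summer", "autumn", "autumn", "autumn",
           "winter")[m]
  factor(lab, levels = .season_levels)
}

.farm_size_levels <- c("<1000", "1000-2000", "2001-5000", ">5000")
.ci_levels <- c("none", "300-365", "366-400", "401-420", "421-440", ">=441")
.milk_levels <- c("3000-5000", "5001-7000", "7001-9000", "9001-11000",
                  "11001-13000", ">13000")

#' Assign factor classes and lactation month to QC'd records
#'
#' Adds the five non-genetic factor classifications used by the fixed-effects
#' analysis, plus the lactation month:
#' * `farm_size_class`: <1000, 1000-2000, 2001-5000, >5000 head;
#' * `parity_class`: parity 1-5 as a factor;
#' * `season`: calving season from `calving_date` (an existing `season`
#'   column, if present, is kept verbatim);
#' * `ci_class`: calving interval 300-365, 366-400, 401-420, 421-440,
#'   >=441 days; parity-1 records, which have no previous calving, get the
#'   explicit level `"none"`; intervals under 300 days are out of range;
#' * `milk_class`: 305-day yield 3000-5000, 5001-7000, 7001-9000,
#'   9001-11000, 11001-13000, >13000 kg (13001-15000 folded into the open
#'   top class); yields under 3000 or over 15000 kg are out of range;
#' * `lactation_month`: from [lactation_month()].
#'
#' A value outside all bins of a factor yields `NA` in that class column and
#' is counted, with its reason, in the `factor_exclusions` attribute; the
#' record itself is kept.
#'
#' @param records QC'd record data frame.
#' @return `records` with the class columns added; attribute
#'   `factor_exclusions` is a named count of out-of-range values per factor.
#' @export
assign_factor_bins <- function(records) {
  out <- records
  excl <- c(farm_size_class = 0L, ci_class = 0L, milk_class = 0L)

  if ("farm_size_count" %in% names(out)) {
    out$farm_size_class <- cut(out$farm_size_count,
                               breaks = c(0, 999, 2000, 5000, Inf),
                               labels = .farm_size_levels)
    excl[["farm_size_class"]] <-
      sum(!is.na(out$farm_size_count) & is.na(out$farm_size_class))
  }
  out$parity_class <- factor(out$parity, levels = 1:5)
  if (!("season" %in% names(out))) {
    out$season <- calving_season(out$calving_date)
  } else {
    out$season <- factor(as.character(out$season), levels = .season_levels)
  }
  ci <- out$calving_interval_days
  ci_class <- as.character(cut(ci, breaks = c(299, 365, 400, 420, 440, Inf),
                               labels = .ci_levels[-1L]))
  ci_class[!is.na(out$parity) & out$parity == 1] <- "none"
  out$ci_class <- factor(ci_class, levels = .ci_levels)
  excl[["ci_class"]] <- sum(!is.na(ci) & ci < 300 &
                              !(!is.na(out$parity) & out$parity == 1))
  if ("milk_305d_kg" %in% names(out)) {
    out$milk_class <- cut(out$milk_305d_kg,
                          breaks = c(3000, 5000, 7000, 9000, 11000, 13000,
                                     15000),
                          labels = .milk_levels, include.lowest = TRUE)
    excl[["milk_class"]] <-
      sum(!is.na(out$milk_305d_kg) & is.na(out$milk_class))
  }
  out$lactation_month <- lactation_month(out$days_in_milk)
  attr(out, "factor_exclusions") <- excl
  out
}
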