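#' Indicator ids of the instrument
#'
#' @return Character vector `c("x1", ..., "x20")`.
#' @export
indicator_ids <- function() paste0("x", 1:20)

#' Load the indicator catalogue
#'
#' The catalogue defines, for each of the 20 test indicators, its dimension
#' (one of balance, rhythm, spatial_orientation, limb_range,
#' body_coordination, perceptual_judgment), measurement unit and score
#' direction. The shipped default encodes the published index system;
#' directions follow the monotone ordering of the published norm bands.
#' Several indicator names are only partially documented in the source
#' instrument; those are marked `provisional` — ids, not names, are
#' authoritative throughout the package.
#'
#' @param path Optional path to an alternative catalogue JSON file.
#' @return A data frame with columns `id`, `name`, `provisional`,
#'   `dimension`, `unit`, `direction`, one row per indicator, of class
#'   `coord_catalogue`.
#' @export
load_catalogue <- function(path = NULL) {
  path <- path %||% .extdata("catalogue.json")
  raw <- .read_json(path)
  cat <- as.data.frame(raw$indicators, stringsAsFactors = FALSE)
  validate_catalogue(cat)
  class(cat) <- c("coord_catalogue", "data.frame")
  cat
}

validate_catalogue <- function(cat) {
  dims <- c("balance", "rhythm", "spatial_orientation", "limb_range",
            "body_coordination", "perceptual_judgment")
  units <- c("seconds", "count", "rating_1_5", "centimeters")
  if (anyDuplicated(cat$id)) stop("duplicate indicator id in catalogue")
  if (!setequal(cat$id, indicator_ids())) {
    stop("catalogue must define exactly the indicators x1..x20")
  }
  if (!all(cat$dimension %in% dims)) stop("unknown dimension in catalogue")
  if (!all(cat$unit %in% units)) stop("unknown unit in catalogue")
  if (!all(cat$direction %in% c("higher_is_better", "lower_is_better"))) {
    stop("direction must be higher_is_better or lower_is_better")
  }
  sizes <- table(cat$dimension)
  if (any(sizes < 2L | sizes > 4L)) {
    stop("each dimension must own 2-4 indicators")
  }
  invisible(cat)
}

#' Assign a child to an age group from birth and test dates
#'
#' Age is computed as the whole-month difference between the dates (a month
#' counts as completed once the test day-of-month reaches the birth
#' day-of-month) divided by 12 and truncated to one decimal. Children aged
#' 4.0--4.9 fall in `group4`, 5.0--5.9 in `group5`; anyone younger or older
#' (including 6-year-olds) is `excluded`.
#'
#' @param birth_date,test_date `Date` vectors (or strings coercible to
#'   `Date`), recycled to a common length.
#' @return Character vector of `"group4"`, `"group5"` or `"excluded"`.
#' @examples
#' assign_age_group(as.Date("2014-01-15"), as.Date("2018-10-15")) # group4
#' assign_age_group(as.Date("2013-03-01"), as.Date("2018-10-01")) # group5
#' @export
assign_age_group <- function(birth_date, test_date) {
  age <- age_in_years(birth_date, test_date)
  grp <- rep("excluded", length(age))
  dec <- trunc(age * 10 + 1e-9) / 10
  grp[dec >= 4.0 & dec <= 4.9] <- "group4"
  grp[dec >= 5.0 & dec <= 5.9] <- "group5"
  grp
}

#' Decimal age in years from whole months
#'
#' @inheritParams assign_age_group
#' @return Numeric vector: completed months between the dates divided by 12.
#' @export
age_in_years <- function(birth_date, test_date) {
  birth_date <- as.Date(birth_date)
  test_date <- as.Date(test_date)
  n <- max(length(birth_date), length(test_date))
  birth_date <- rep_len(birth_date, n)
  test_date <- rep_len(test_date, n)
  if (any(test_date < birth_date, na.rm = TRUE)) {
    stop("test_date precedes birth_date", call. = FALSE)
  }
  b <- as.POSIXlt(birth_date)
  t <- as.POSIXlt(test_date)
  months <- 12L * (t$year - b$year) + (t$mon - b$mon) - as.integer(t$mday < b$mday)
  months / 12
}

#' Validate a single child record
#'
#' A record is valid when its age group is not excluded, sex and both dates
#' are present, and all 20 indicator measurements are present and finite.
#' All measurements except the limb-range centimeters (x13, x14, which may
#' legitimately be negative) must also be non-negative.
#'
#' @param record A one-row data frame (or named list) with fields
#'   `child_id`, `sex`, `birth_date`, `test_date` and `x1`..`x20`.
#' @param catalogue Indicator catalogue, see [load_catalogue()].
#' @return A list with `valid` (logical) and `reasons` (character vector of
#'   failure descriptions, empty when valid).
#' @export
validate_record <- function(record, catalogue = load_catalogue()) {
  reasons <- character()
  ids <- catalogue$id
  rec <- as.list(record)
  if (is.null(rec$sex) || is.na(rec$sex) || !(rec$sex %in% c("female", "male"))) {
    reasons <- c(reasons, "missing or unknown sex")
  }
  if (is.null(rec$birth_date) || is.null(rec$test_date) ||
      is.na(rec$birth_date) || is.na(rec$test_date)) {
    reasons <- c(reasons, "missing dates")
  } else {
    grp <- tryCatch(assign_age_group(rec$birth_date, rec$test_date),
                    error = function(e) "excluded")
    if (grp == "excluded") reasons <- c(reasons, "age outside 4.0-5.9")
  }
  vals <- suppressWarnings(as.numeric(unlist(rec[ids])))
  missing <- ids[!(ids %in% names(rec))]
  if (length(missing)) {
    reasons <- c(reasons, paste0("missing: ", paste(missing, collapse = ", ")))
  } else {
    bad <- ids[!is.finite(vals)]
    if (length(bad)) {
      reasons <- c(reasons, paste0("missing: ", paste(bad, collapse = ", ")))
    }
    allow_neg <- ids %in% c("x13", "x14")
    neg <- ids[is.finite(vals) & vals < 0 & !allow_neg]
    if (length(neg)) {
      reasons <- c(reasons, paste0("negative: ", paste(neg, collapse = ", ")))
    }
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Load a cohort from a delimited text file
#'
#' Expects a CSV with header columns `child_id`, `sex`, `birth_date`,
#' `test_date` (ISO-8601) and `x1`..`x20`. Age groups are assigned from the
#' dates; each record is validated. Invalid records are reported through the
#' `invalid` attribute and, unless `drop_invalid = TRUE`, retained in the
#' returned data frame (flagged by the `valid` column) so nothing is
#' silently lost.
#'
#' @param path CSV file path, or a data frame already in cohort layout.
#' @param catalogue Indicator catalogue.
#' @param drop_invalid Drop invalid records from the returned cohort?
#' @return A `coord_cohort` data frame with added columns `age_years`,
#'   `age_group`, `valid`, and attributes `invalid` (data frame of row
#'   index + reasons) and `counts` (table by age_group and sex).
#' @export
load_cohort <- function(path, catalogue = load_catalogue(), drop_invalid = FALSE) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  required <- c("child_id", "sex", "birth_date", "test_date", indicator_ids())
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("cohort file lacks required columns: ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  extra_x <- grep("^x[0-9]+$", extra, value = TRUE)
  if (length(extra_x)) {
    stop("unknown indicator columns: ", paste(extra_x, collapse = ", "))
  }
  if (anyDuplicated(df$child_id)) {
    dup <- which(duplicated(df$child_id))[1]
    stop(sprintf("duplicate child_id at row %d: %s", dup, df$child_id[dup]))
  }
  df$birth_date <- as.Date(df$birth_date)
  df$test_date <- as.Date(df$test_date)
  for (id in indicator_ids()) df[[id]] <- as.numeric(df[[id]])
  has_dates <- !is.na(df$birth_date) & !is.na(df$test_date) &
    df$test_date >= df$birth_date
  df$age_years <- NA_real_
  df$age_years[has_dates] <- age_in_years(df$birth_date[has_dates],
                                          df$test_date[has_dates])
  df$age_group <- "excluded"
  df$age_group[has_dates] <- assign_age_group(df$birth_date[has_dates],
                                              df$test_date[has_dates])
  checks <- lapply(seq_len(nrow(df)), function(i) validate_record(df[i, ], catalogue))
  df$valid <- vapply(checks, `[[`, logical(1), "valid")
  invalid <- data.frame(
    row = which(!df$valid),
    child_id = df$child_id[!df$valid],
    reasons = vapply(checks[!df$valid], function(x) paste(x$reasons, collapse = "; "),
                     character(1)),
    stringsAsFactors = FALSE
  )
  if (drop_invalid) df <- df[df$valid, , drop = FALSE]
  attr(df, "invalid") <- invalid
  attr(df, "counts") <- table(age_group = df$age_group[df$valid],
                              sex = df$sex[df$valid])
  class(df) <- c("coord_cohort", "data.frame")
  df
}

#' Write a cohort back to CSV
#'
#' Inverse of [load_cohort()]: only the canonical columns are written so a
#' write/read cycle is the identity on valid cohorts.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("child_id", "sex", "birth_date", "test_date", indicator_ids())
  write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.coord_cohort <- function(x, ...) {
  cat(sprintf("<coord_cohort> %d records (%d valid)\n", nrow(x), sum(x$valid)))
  print(attr(x, "counts"))
  invisible(x)
}
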