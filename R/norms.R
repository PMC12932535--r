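# Internal representation of a single-indicator norm table:
# list(id, direction, floor, cuts[4], closures[4], weight, weighted_scores[5])
# `floor` is the P3 no-score edge on the worse side; `cuts` are the
# worse-side edges of levels 4,3,2,1, ordered worst-to-best along the raw
# axis implied by `direction`. On the direction-adjusted axis (higher =
# better) a value passes a cut with closure "ge" when adj >= cut and with
# "gt" when adj > cut; the level is 5 minus the number of cuts passed.

.EPS <- 1e-9

.adjust <- function(v, direction) if (direction == "lower_is_better") -v else v

.validate_indicator_norm <- function(nt) {
  stopifnot(nt$direction %in% c("higher_is_better", "lower_is_better"),
            length(nt$cuts) == 4L, length(nt$closures) == 4L,
            all(nt$closures %in% c("ge", "gt")),
            length(nt$weighted_scores) == 5L)
  adj <- .adjust(c(nt$floor, nt$cuts), nt$direction)
  if (any(diff(adj) < -.EPS)) {
    stop(sprintf("norm table for %s is not monotone along its direction",
                 nt$id %||% "?"), call. = FALSE)
  }
  invisible(nt)
}

#' Load the published norm tables
#'
#' The shipped artifacts are verbatim transcriptions of the published
#' five-level scoring tables for each age group, including the P3 no-score
#' floors and the weighted level scores. The loader validates band
#' monotonicity along each indicator's direction.
#'
#' @param age_group `"group4"`, `"group5"`, or `"all"` for a named list of
#'   both.
#' @param path Optional alternative JSON artifact (for a single group).
#' @return A `coord_norms` object (or named list of two).
#' @export
load_norm_tables <- function(age_group = c("group4", "group5", "all"), path = NULL) {
  age_group <- match.arg(age_group)
  if (age_group == "all") {
    return(list(group4 = load_norm_tables("group4"),
                group5 = load_norm_tables("group5")))
  }
  file <- path %||% .extdata(sprintf("norms_%s.json", age_group))
  raw <- .read_json(file)
  norms <- lapply(names(raw$indicators), function(id) {
    nt <- raw$indicators[[id]]
    nt$id <- id
    nt$cuts <- as.numeric(nt$cuts)
    nt$weighted_scores <- as.numeric(nt$weighted_scores)
    .validate_indicator_norm(nt)
    nt
  })
  names(norms) <- names(raw$indicators)
  structure(list(age_group = raw$age_group %||% age_group,
                 level_points = as.numeric(raw$level_points %||% c(20, 40, 60, 80, 100)),
                 indicators = norms),
            class = "coord_norms")
}

#' Build a five-level norm table for one indicator
#'
#' Cuts the empirical distribution of `samples` at the percentile `anchors`
#' along the direction-adjusted axis (worse to better). The first anchor is
#' the no-score floor (P3 by convention); the remaining four anchors are the
#' worse-side edges of levels 4, 3, 2 and 1. Percentiles use linear
#' interpolation between closest ranks (type 7).
#'
#' @param samples Raw measurements (at least 30, non-constant).
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param final_weight Final weight of the indicator; weighted level scores
#'   are `final_weight * c(20, 40, 60, 80, 100)`.
#' @param anchors Increasing percentiles in (0, 100); default
#'   `c(3, 25, 50, 75, 90)`.
#' @param id Indicator id carried in the result.
#' @param quantile_type Passed to [stats::quantile()].
#' @return A single-indicator norm table (list).
#' @export
build_indicator_norms <- function(samples, direction, final_weight,
                                  anchors = c(3, 25, 50, 75, 90), id = NULL,
                                  quantile_type = 7) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30L) stop("need at least 30 samples to build norms")
  if (length(anchors) != 5L || any(diff(anchors) <= 0) ||
      any(anchors <= 0 | anchors >= 100)) {
    stop("anchors must be 5 strictly increasing percentiles in (0, 100)")
  }
  adj <- .adjust(samples, direction)
  q <- as.numeric(quantile(adj, anchors / 100, type = quantile_type, names = FALSE))
  if (q[1] >= max(adj) || diff(range(samples)) == 0) {
    stop("degenerate sample: norms undefined for (near-)constant measurements")
  }
  raw <- if (direction == "lower_is_better") -q else q
  nt <- list(id = id, direction = direction, floor = raw[1], cuts = raw[2:5],
             closures = rep("ge", 4L), weight = final_weight,
             weighted_scores = final_weight * c(20, 40, 60, 80, 100))
  .validate_indicator_norm(nt)
  nt
}

#' Assign norm levels to raw values
#'
#' Looks values up in a single-indicator norm table. Values on the worse
#' side of the P3 floor receive no score (level `NA`, scores 0); values
#' exactly on an interior cut take the better band (unless the published
#' band was strict, closure `"gt"`).
#'
#' @param values Numeric vector of raw measurements.
#' @param nt Single-indicator norm table (from a `coord_norms` object or
#'   [build_indicator_norms()]).
#' @return Data frame with `level` (1 best .. 5 worst, `NA` = no score),
#'   `level_score` (100..20, 0 for no score) and `weighted_score`.
#' @export
assign_level <- function(values, nt) {
  .validate_indicator_norm(nt)
  adj <- .adjust(values, nt$direction)
  cuts <- .adjust(nt$cuts, nt$direction)
  floor_adj <- .adjust(nt$floor, nt$direction)
  passed <- matrix(FALSE, length(adj), 4L)
  for (k in 1:4) {
    passed[, k] <- if (nt$closures[k] == "ge") adj >= cuts[k] - .EPS
                   else adj > cuts[k] + .EPS
  }
  scored <- adj >= floor_adj - .EPS
  level <- ifelse(scored, 5L - rowSums(passed), NA_integer_)
  level_score <- ifelse(scored, 20 * (6L - level), 0)
  weighted <- ifelse(scored, nt$weighted_scores[6L - level], 0)
  data.frame(level = level, level_score = level_score, weighted_score = weighted)
}

#' Score a single child record
#'
#' Maps each of the 20 raw measurements to its norm level and weighted
#' score, sums the weighted scores within dimensions and overall, and
#' (optionally) classifies the composite.
#'
#' @param record One-row data frame or named list with `x1`..`x20` (and
#'   ideally `age_group`).
#' @param norms `coord_norms` for the record's age group.
#' @param catalogue Indicator catalogue (for dimension membership).
#' @param bands Optional `composite_bands` for classification.
#' @return A `score_report` list: `indicators` (per-indicator data frame),
#'   `dimension_scores`, `composite`, `n_no_score`, `band` (or `NA`).
#' @export
score_record <- function(record, norms, catalogue = load_catalogue(),
                         bands = NULL) {
  rec <- as.list(record)
  ids <- indicator_ids()
  if (!all(ids %in% names(rec))) {
    stop("record lacks measurements: ",
         paste(setdiff(ids, names(rec)), collapse = ", "))
  }
  missing_norms <- setdiff(ids, names(norms$indicators))
  if (length(missing_norms)) {
    stop("no norm table for: ", paste(missing_norms, collapse = ", "))
  }
  per <- do.call(rbind, lapply(ids, function(id) {
    out <- assign_level(as.numeric(rec[[id]]), norms$indicators[[id]])
    cbind(data.frame(id = id, raw = as.numeric(rec[[id]]),
                     dimension = catalogue$dimension[match(id, catalogue$id)]),
          out)
  }))
  dim_scores <- tapply(per$weighted_score, per$dimension, sum)
  composite <- sum(per$weighted_score)
  band <- if (!is.null(bands)) classify_composite(composite, bands) else NA_character_
  structure(list(indicators = per,
                 dimension_scores = dim_scores,
                 composite = composite,
                 n_no_score = sum(is.na(per$level)),
                 band = band),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> composite %.2f%s, %d indicator(s) below floor\n",
              x$composite,
              if (!is.na(x$band)) paste0(" [", x$band, "]") else "",
              x$n_no_score))
  print(round(x$dimension_scores, 2))
  invisible(x)
}

#' Score a whole cohort
#'
#' Vectorized scoring of every valid record against the norms of its age
#' group. Excluded/invalid records are skipped.
#'
#' @param cohort A `coord_cohort` (or data frame in cohort layout).
#' @param norms Named list `list(group4 = , group5 = )` of `coord_norms`
#'   (default: the published tables).
#' @param catalogue Indicator catalogue.
#' @param bands Optional named list of `composite_bands` per age group for
#'   classification.
#' @return Data frame, one row per scored record: `child_id`, `sex`,
#'   `age_group`, `x*_score` (unweighted level scores, 0 = below floor),
#'   one column per dimension (weighted subtotals), `composite`, `band`.
#' @export
score_cohort <- function(cohort, norms = load_norm_tables("all"),
                         catalogue = load_catalogue(), bands = NULL) {
  keep <- (cohort$age_group %in% names(norms))
  if ("valid" %in% names(cohort)) keep <- keep & cohort$valid
  df <- cohort[keep, , drop = FALSE]
  if (!nrow(df)) stop("no scorable records in cohort")
  ids <- indicator_ids()
  dims <- unique(catalogue$dimension)
  out <- data.frame(child_id = df$child_id, sex = df$sex,
                    age_group = df$age_group, stringsAsFactors = FALSE)
  weighted <- matrix(0, nrow(df), length(ids), dimnames = list(NULL, ids))
  for (g in unique(df$age_group)) {
    sel <- df$age_group == g
    for (id in ids) {
      al <- assign_level(df[[id]][sel], norms[[g]]$indicators[[id]])
      out[sel, paste0(id, "_score")] <- al$level_score
      weighted[sel, id] <- al$weighted_score
    }
  }
  for (d in dims) {
    out[[d]] <- rowSums(weighted[, catalogue$id[catalogue$dimension == d],
                                 drop = FALSE])
  }
  out$composite <- rowSums(weighted)
  out$band <- NA_character_
  if (!is.null(bands)) {
    for (g in unique(out$age_group)) {
      sel <- out$age_group == g
      out$band[sel] <- classify_composite(out$composite[sel], bands[[g]])
    }
  }
  out
}

#' Composite band labels, best first
#' @export
band_levels <- function() c("Excellent", "Good", "Qualified", "Unqualified")

#' Build four-band composite classification cutoffs
#'
#' Cuts the modeling sample's composite scores (and optionally each
#' dimension subtotal) at the P90/P65/P15 percentiles, yielding the
#' Excellent / Good / Qualified / Unqualified bands with theoretical shares
#' 10/25/50/15 percent. Cutoffs are rounded to `digits` decimals, mirroring
#' the published tables.
#'
#' @param composite Numeric vector of composite scores (at least 50).
#' @param dimension_scores Optional data frame/matrix of weighted dimension
#'   subtotals (one column per dimension).
#' @param anchors Percentiles of the three cuts, best to worst.
#' @param digits Rounding applied to the cutoffs (`NULL` for none).
#' @param age_group Label carried in the result.
#' @return A `composite_bands` list: `composite` (3 decreasing cutoffs),
#'   `dimensions`, `theoretical_percent`, `anchors`.
#' @export
build_composite_bands <- function(composite, dimension_scores = NULL,
                                  anchors = c(90, 65, 15), digits = 2,
                                  age_group = NULL) {
  if (length(composite) < 50L) stop("need at least 50 modeling scores")
  cutfun <- function(v) {
    q <- as.numeric(quantile(v, anchors / 100, type = 7, names = FALSE))
    if (!is.null(digits)) q <- round(q, digits)
    q
  }
  dims <- NULL
  if (!is.null(dimension_scores)) {
    dims <- lapply(as.data.frame(dimension_scores), cutfun)
  }
  structure(list(age_group = age_group, composite = cutfun(composite),
                 dimensions = dims, theoretical_percent = c(10, 25, 50, 15),
                 anchors = anchors),
            class = "composite_bands")
}

#' Load the published composite band tables
#'
#' @param path Optional alternative JSON artifact.
#' @return Named list `group4`/`group5` of `composite_bands`.
#' @export
load_composite_bands <- function(path = NULL) {
  raw <- .read_json(path %||% .extdata("composite_bands.json"))
  build <- function(g) {
    structure(list(age_group = g,
                   composite = as.numeric(raw[[g]]$composite),
                   dimensions = lapply(raw[[g]]$dimensions, as.numeric),
                   theoretical_percent = as.numeric(raw$theoretical_percent),
                   anchors = as.numeric(raw$percentile_anchors)),
              class = "composite_bands")
  }
  list(group4 = build("group4"), group5 = build("group5"))
}

#' Classify composite scores into the four bands
#'
#' Interval lookup against the three cutoffs; a score exactly on a cutoff
#' takes the better band.
#'
#' @param score Numeric vector of composite (or dimension) scores.
#' @param bands A `composite_bands` object, or a numeric vector of three
#'   decreasing cutoffs.
#' @return Character vector of band labels.
#' @export
classify_composite <- function(score, bands) {
  cuts <- if (inherits(bands, "composite_bands")) bands$composite else as.numeric(bands)
  if (length(cuts) != 3L || any(diff(cuts) >= 0)) {
    stop("bands must provide 3 strictly decreasing cutoffs")
  }
  lab <- band_levels()
  out <- rep(lab[4], length(score))
  out[score >= cuts[3] - .EPS] <- lab[3]
  out[score >= cuts[2] - .EPS] <- lab[2]
  out[score >= cuts[1] - .EPS] <- lab[1]
  out
}

#' Write a norm artifact to JSON
#'
#' Serializes a `coord_norms` object (plus optional composite bands) in the
#' same layout as the shipped artifacts, so [read_norms()] round-trips.
#'
#' @param norms `coord_norms` object.
#' @param path Output path.
#' @export
write_norms <- function(norms, path) {
  payload <- list(age_group = norms$age_group,
                  level_points = norms$level_points,
                  indicators = lapply(norms$indicators, function(nt) {
                    nt[c("direction", "floor", "cuts", "closures",
                         "weight", "weighted_scores")]
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a norm artifact written by [write_norms()]
#'
#' @param path JSON path.
#' @return A `coord_norms` object (monotonicity validated).
#' @export
read_norms <- function(path) {
  grp <- .read_json(path)$age_group
  load_norm_tables(if (identical(grp, "group5")) "group5" else "group4", path = path)
}
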