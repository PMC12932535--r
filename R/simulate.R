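#' Published sex effects used as generator defaults
#'
#' Cohen's d (female minus male, positive = female advantage) per indicator
#' and age group, as reported for the reference cohort.
#'
#' @return Named list `group4`/`group5` of named numeric vectors.
#' @export
default_sex_effects <- function() {
  raw <- .read_json(.extdata("sex_effects.json"))
  lapply(raw[c("group4", "group5")], function(g) unlist(g))
}

#' Published means/SDs of the CV-weighted indicators
#'
#' @return Named list `group4`/`group5`; each a named list of
#'   `list(mean, sd, cv, cv_weight)` per indicator (x17--x20).
#' @export
indicator_moments <- function() {
  raw <- .read_json(.extdata("indicator_moments.json"))
  raw[c("group4", "group5")]
}

# Per-band sampler for one indicator norm table. Maps u in (0,1) — the
# position from worst (0) to best (1) — to a raw value: a band is chosen by
# the configured proportions, the value drawn uniformly within the band's
# raw interval. Open outer bands get a tail extension of `tail_factor`
# times the adjacent band's width; point bands (printed single-value bands,
# e.g. integer ratings) return the band's value exactly.
.band_sampler <- function(nt, unit, proportions, tail_factor = 0.5) {
  pr <- proportions / sum(proportions)
  if (length(pr) != 6L) stop("need 6 band proportions (floor, levels 5..1)")
  cum <- cumsum(c(0, pr))
  if (unit == "count") {
    if (nt$direction != "higher_is_better") {
      stop("integer band sampling assumes higher_is_better counts")
    }
    f <- nt$floor; cts <- nt$cuts
    w5 <- max(1, cts[1] - f)
    ext0 <- max(1, round(tail_factor * w5))
    ext1 <- max(1, round(tail_factor * max(1, cts[4] - cts[3])))
    top_lo <- if (nt$closures[4] == "gt") cts[4] + 1 else cts[4]
    lo <- c(max(0, f - ext0), f, cts[1], cts[2], cts[3], top_lo)
    hi <- c(max(0, f - 1), cts[1] - 1, cts[2] - 1, cts[3] - 1,
            if (nt$closures[4] == "gt") cts[4] else cts[4] - 1,
            top_lo + ext1)
    hi <- pmax(hi, lo)
    function(u) {
      k <- findInterval(pmin(pmax(u, 0), 1), cum, rightmost.closed = TRUE,
                        all.inside = TRUE)
      frac <- (u - cum[k]) / pr[k]
      frac[!is.finite(frac)] <- 0
      pmin(lo[k] + floor(frac * (hi[k] - lo[k] + 1)), hi[k])
    }
  } else {
    s <- if (nt$direction == "lower_is_better") -1 else 1
    af <- s * nt$floor; ac <- s * nt$cuts
    ext0 <- tail_factor * max(ac[1] - af, 0)
    top <- if (nt$closures[4] == "gt") {
      ac[4] + tail_factor * max(ac[4] - ac[3], 0)
    } else ac[4]                      # closed single-value best band
    e <- c(af - ext0, af, ac[1], ac[2], ac[3], ac[4], top)
    if (any(diff(e) < -1e-9)) stop("non-monotone band edges")
    function(u) {
      k <- findInterval(pmin(pmax(u, 0), 1), cum, rightmost.closed = TRUE,
                        all.inside = TRUE)
      frac <- (u - cum[k]) / pr[k]
      frac[!is.finite(frac)] <- 0
      s * (e[k] + frac * (e[k + 1] - e[k]))
    }
  }
}

# band proportions for one indicator: rating scales with pure point bands
# have no below-floor region; its share folds into level 5
.band_props <- function(nt, unit, base) {
  if (unit == "rating_1_5" && all(nt$cuts == round(nt$cuts)) &&
      nt$floor == round(nt$floor)) {
    c(0, base[1] + base[2], base[3:6])
  } else base
}

#' Sample raw values anchored to a published norm table
#'
#' Draws a norm band per the configured proportions, then a value uniformly
#' within the band's raw interval (see the generator documentation for the
#' handling of open and point bands). Inverts the norm construction: the
#' empirical percentiles of a large sample converge to the table's edges.
#'
#' @param nt Single-indicator norm table.
#' @param proportions Six band shares (below-floor, level 5 .. level 1),
#'   any positive scale; default `c(3, 22, 25, 25, 15, 10)` matching the
#'   P3/P25/P50/P75/P90 anchors.
#' @param n Number of draws (0 gives an empty vector).
#' @param seed Optional seed.
#' @param unit Indicator unit (`"count"` triggers integer sampling).
#' @param tail_factor Tail extension of the open outer bands, as a fraction
#'   of the adjacent band's width.
#' @return Numeric vector of n raw values.
#' @export
band_anchored_sample <- function(nt, proportions = c(3, 22, 25, 25, 15, 10),
                                 n, seed = NULL, unit = "seconds",
                                 tail_factor = 0.5) {
  if (n == 0) return(numeric(0))
  sampler <- .band_sampler(nt, unit, .band_props(nt, unit, proportions),
                           tail_factor)
  with_seed(seed, sampler(runif(n)))
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the instrument's reference population: cell sizes of
#' the reported valid cohort (266/264 girls/boys aged 4.0--4.9, 270/268
#' aged 5.0--5.9), within-dimension correlation 0.4, the published sex
#' effects planted as latent mean shifts, marginals anchored to the
#' published norm bands for x1--x16 and to the published means/SDs for
#' x17--x20.
#'
#' @param n Named integer vector of cell sizes
#'   (`group4.female`, `group4.male`, `group5.female`, `group5.male`).
#' @param rho Within-dimension latent correlation in `[0, 0.9]`.
#' @param sex_effects Named list per age group of per-indicator d values
#'   (positive = female advantage), or `NULL` for none.
#' @param global_shift Common latent shift (SD units, along the better
#'   direction) applied to every indicator — useful for sensitivity checks
#'   with a shifted population.
#' @param band_proportions Six band shares for band-anchored marginals.
#' @param tail_factor Tail extension for open bands.
#' @param norms Norm tables anchoring the band marginals (default:
#'   published).
#' @param moments Normal-marginal moments (default: published, x17--x20).
#' @param test_date Common test date used to synthesize birth dates.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = c(group4.female = 266L, group4.male = 264L,
                                   group5.female = 270L, group5.male = 268L),
                             rho = 0.4,
                             sex_effects = default_sex_effects(),
                             global_shift = 0,
                             band_proportions = c(3, 22, 25, 25, 15, 10),
                             tail_factor = 0.5,
                             norms = load_norm_tables("all"),
                             moments = indicator_moments(),
                             test_date = as.Date("2018-10-15")) {
  stopifnot(all(n > 0), rho >= 0, rho <= 0.9)
  structure(list(n = n, rho = rho, sex_effects = sex_effects,
                 global_shift = global_shift,
                 band_proportions = band_proportions,
                 tail_factor = tail_factor, norms = norms, moments = moments,
                 test_date = as.Date(test_date)),
            class = "generator_config")
}

.subtract_months <- function(date, months) {
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon - months
  as.Date(sprintf("%d-%02d-%02d", total %/% 12L + 1900L, total %% 12L + 1L,
                  lt$mday))
}

#' Generate a synthetic cohort
#'
#' Draws, per age group, a latent "ability" variable for each dimension
#' (loading `sqrt(rho)` on every indicator of the dimension) plus
#' independent indicator noise, shifts the latent score by half the planted
#' sex effect toward each sex (so the female-male latent difference equals
#' d standard deviations along the better direction), and maps the latent
#' normal scores to the configured marginals (band-anchored or normal).
#' Count indicators are rounded to non-negative integers and time
#' measurements truncated at zero after the shifts.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   (config, seed).
#' @param validate Run the result through [load_cohort()] (default TRUE).
#' @return A `coord_cohort`.
#' @export
generate_cohort <- function(config = generator_config(), seed, validate = TRUE) {
  if (missing(seed)) stop("a seed is required")
  catalogue <- load_catalogue()
  with_seed(seed, {
    out <- list(); next_id <- 1L
    for (g in c("group4", "group5")) {
      cell <- function(key) if (key %in% names(config$n)) config$n[[key]] else 0L
      nf <- cell(paste0(g, ".female"))
      nm <- cell(paste0(g, ".male"))
      n <- nf + nm
      if (n == 0) next
      sex <- c(rep("female", nf), rep("male", nm))
      months_lo <- if (g == "group4") 48L else 60L
      months <- sample(months_lo:(months_lo + 11L), n, replace = TRUE)
      df <- data.frame(
        child_id = sprintf("C%05d", seq.int(next_id, next_id + n - 1L)),
        sex = sex,
        birth_date = .subtract_months(config$test_date, months),
        test_date = config$test_date,
        stringsAsFactors = FALSE
      )
      next_id <- next_id + n
      d_eff <- config$sex_effects[[g]]
      for (dim in unique(catalogue$dimension)) {
        f_latent <- rnorm(n)
        for (id in catalogue$id[catalogue$dimension == dim]) {
          z <- sqrt(config$rho) * f_latent + sqrt(1 - config$rho) * rnorm(n)
          d <- if (!is.null(d_eff) && id %in% names(d_eff)) d_eff[[id]] else 0
          z <- z + ifelse(sex == "female", d / 2, -d / 2) + config$global_shift
          unit <- catalogue$unit[catalogue$id == id]
          mom <- config$moments[[g]][[id]]
          if (!is.null(mom)) {
            s <- if (catalogue$direction[catalogue$id == id] == "lower_is_better") -1 else 1
            v <- mom$mean + mom$sd * s * z
          } else {
            nt <- config$norms[[g]]$indicators[[id]]
            sampler <- .band_sampler(nt, unit,
                                     .band_props(nt, unit, config$band_proportions),
                                     config$tail_factor)
            v <- sampler(pnorm(z))
          }
          if (unit == "seconds") v <- pmax(v, 0.01)
          if (unit == "count") v <- pmax(round(v), 0)
          if (unit == "rating_1_5") v <- pmin(pmax(v, 1), 5)
          df[[id]] <- v
        }
      }
      out[[g]] <- df
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    if (validate) load_cohort(df, catalogue = catalogue) else df
  })
}
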