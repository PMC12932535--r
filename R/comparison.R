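#' Cohen's d from group summaries or raw data
#'
#' Standardized mean difference with the pooled standard deviation:
#' `d = (mean_a - mean_b) / s_p`,
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`.
#' No small-sample (Hedges) correction is applied — this is the form that
#' reproduces the published effect sizes from the reported group summaries.
#'
#' @param a,b Either numeric vectors of raw values, or group summaries as
#'   lists/data frames with `mean`, `sd`, `n` (sample SD, n-1).
#' @return Cohen's d (sign: a minus b).
#' @export
cohen_d <- function(a, b) {
  summarize <- function(g) {
    if (is.numeric(g) && is.null(dim(g)) && length(g) > 1L) {
      list(mean = mean(g), sd = sd(g), n = length(g))
    } else {
      g <- as.list(g)
      stopifnot(all(c("mean", "sd", "n") %in% names(g)))
      g
    }
  }
  a <- summarize(a); b <- summarize(b)
  if (a$n < 2 || b$n < 2) stop("each group needs at least 2 observations")
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation; d undefined")
  (a$mean - b$mean) / sqrt(sp2)
}

#' Verbal magnitude of an effect size
#'
#' `|d| >= 0.8` large, `|d| >= 0.5` medium, otherwise small (the
#' conventional anchors leave (0.2, 0.5) unnamed; it is banded as small).
#'
#' @param d Cohen's d value(s).
#' @return Character vector of `"small"`, `"medium"`, `"large"`.
#' @export
effect_magnitude <- function(d) {
  out <- rep("small", length(d))
  out[abs(d) >= 0.5] <- "medium"
  out[abs(d) >= 0.8] <- "large"
  out
}

#' Independent-samples t test
#'
#' Pooled-variance t test by default (the instrument's workflow gates on
#' Levene's test and proceeds with equal variances assumed); Welch's t is
#' available via `equal_variance = FALSE`.
#'
#' @param a,b Numeric vectors (each at least 2 values; not both constant).
#' @param equal_variance Pooled-variance (TRUE, default) or Welch.
#' @return List `t`, `df`, `p` (two-sided).
#' @export
independent_t <- function(a, b, equal_variance = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) stop("both groups constant; t undefined")
  ht <- t.test(a, b, var.equal = equal_variance)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Levene's test for homogeneity of variance
#'
#' Dispersion comparison of two (or more) groups via the spread of absolute
#' deviations from a group center. `center = "mean"` is the classical
#' Levene statistic (the instrument's workflow); `center = "median"` is the
#' Brown-Forsythe variant.
#'
#' @param a,b Numeric vectors, or (`a` only) a list of groups.
#' @param center `"mean"` or `"median"`.
#' @return List `statistic` (F), `df`, `p`.
#' @export
levene_test <- function(a, b = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- if (is.list(a) && is.null(b)) a else list(a, b)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(y)) == 1L) {
    return(list(statistic = 0, df = c(length(groups) - 1L,
                                      length(y) - length(groups)), p = 1))
  }
  centerfun <- if (center == "mean") mean else stats::median
  lt <- car::leveneTest(y, g, center = centerfun)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"])
}

#' Group comparison table of a scored cohort
#'
#' Reproduces the layout of the published sex-difference tables for one age
#' group: one row per indicator (unweighted level scores), one per
#' dimension (weighted subtotals) and one for the composite, each with the
#' group summaries, pooled t test, Cohen's d (first group minus second) and
#' its verbal magnitude.
#'
#' @param scored Output of [score_cohort()] for (at least) one age group.
#' @param age_group Age group to tabulate.
#' @param by Grouping column (default `"sex"`); the first level is the
#'   d-positive group (`"female"` first for sex, matching the published
#'   orientation).
#' @param catalogue Indicator catalogue.
#' @return Data frame with columns `measure`, `type`, `n_<g1>`,
#'   `mean_<g1>`, `sd_<g1>`, same for g2, `t`, `p`, `d`, `magnitude`.
#' @export
comparison_table <- function(scored, age_group, by = "sex",
                             catalogue = load_catalogue()) {
  df <- scored[scored$age_group == age_group, , drop = FALSE]
  lev <- if (by == "sex") c("female", "male") else sort(unique(df[[by]]))
  if (length(lev) != 2L) stop("grouping must have exactly 2 levels")
  g1 <- df[df[[by]] == lev[1], , drop = FALSE]
  g2 <- df[df[[by]] == lev[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2)) stop("empty comparison group")
  dims <- unique(catalogue$dimension)
  measures <- c(paste0(indicator_ids(), "_score"), dims, "composite")
  type <- c(rep("indicator", 20), rep("dimension", length(dims)), "total")
  rows <- lapply(seq_along(measures), function(i) {
    v1 <- g1[[measures[i]]]; v2 <- g2[[measures[i]]]
    tt <- independent_t(v1, v2)
    d <- cohen_d(v1, v2)
    out <- data.frame(measure = sub("_score$", "", measures[i]), type = type[i],
                      stringsAsFactors = FALSE)
    out[[paste0("n_", lev[1])]] <- length(v1)
    out[[paste0("mean_", lev[1])]] <- mean(v1)
    out[[paste0("sd_", lev[1])]] <- sd(v1)
    out[[paste0("n_", lev[2])]] <- length(v2)
    out[[paste0("mean_", lev[2])]] <- mean(v2)
    out[[paste0("sd_", lev[2])]] <- sd(v2)
    out$t <- tt$t; out$p <- tt$p; out$d <- d
    out$magnitude <- effect_magnitude(d)
    out
  })
  do.call(rbind, rows)
}
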