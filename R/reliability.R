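#' Test-retest reliability (Pearson r)
#'
#' @param occasion1,occasion2 Paired measurements from the two occasions
#'   (equal length, at least 3, non-constant).
#' @return Pearson product-moment correlation.
#' @export
test_retest_r <- function(occasion1, occasion2) {
  if (length(occasion1) != length(occasion2)) stop("occasions must be paired")
  if (length(occasion1) < 3L) stop("need at least 3 paired measurements")
  if (sd(occasion1) == 0 || sd(occasion2) == 0) {
    stop("correlation undefined for constant measurements")
  }
  cor(occasion1, occasion2)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation, from the mean squares of the two-way ANOVA on a complete
#' subjects-by-raters table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval uses the F-based bounds for this form
#' (Satterthwaite degrees of freedom for the column/error mixture).
#'
#' @param table Numeric matrix/data frame, subjects in rows, raters in
#'   columns; complete, at least 2 x 2.
#' @param conf_level Confidence level of the interval.
#' @return List `icc`, `lower`, `upper`, plus the mean squares.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (any(!is.finite(x))) stop("rater table must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse + 1e-12 * max(1, mse)) {
    warning("no between-subject variance; ICC reported as 0")
    return(list(icc = 0, lower = NA_real_, upper = NA_real_,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, msr = msr, msc = msc, mse = mse)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the sum)`,
#' with sample (n-1) variances.
#'
#' @param x Subjects-by-items data (at least 2 items), or an item
#'   covariance matrix.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  v <- if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    x
  } else {
    if (ncol(x) < 2L) stop("need at least 2 items")
    var(x)
  }
  k <- ncol(v)
  total <- sum(v)
  if (total <= 0) stop("zero total variance; alpha undefined")
  k / (k - 1) * (1 - sum(diag(v)) / total)
}

#' McDonald's omega from factor loadings
#'
#' `omega = (sum loadings)^2 / ((sum loadings)^2 + sum uniqueness)` —
#' the factor-based internal-consistency coefficient.
#'
#' @param loadings Standardized factor loadings.
#' @param uniqueness Item uniquenesses (non-negative), same length.
#' @export
mcdonald_omega <- function(loadings, uniqueness) {
  if (length(loadings) != length(uniqueness)) {
    stop("loadings and uniqueness must have equal length")
  }
  if (any(uniqueness < 0)) stop("uniqueness must be non-negative")
  l2 <- sum(loadings)^2
  denom <- l2 + sum(uniqueness)
  if (denom == 0) stop("all-zero loadings and uniqueness; omega undefined")
  l2 / denom
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among m experts ranking n items, with the tie correction:
#' `W = (12 sum(R_j^2) - 3 m^2 n (n+1)^2) / (m^2 n (n^2 - 1) - m sum(T_i))`
#' where `T_i = sum(t^3 - t)` over tie groups of expert i. Significance via
#' `chi^2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' @param ratings Experts-by-items matrix of ratings (ranked within each
#'   expert, average ranks for ties).
#' @param tie_correction Apply the tie correction (default TRUE; the
#'   uncorrected form is available for cross-checks).
#' @return List `w`, `chi2`, `df`, `p`.
#' @export
kendalls_w <- function(ratings, tie_correction = TRUE) {
  x <- as.matrix(ratings)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L || n < 2L) stop("need at least 2 experts and 2 items")
  ranks <- t(apply(x, 1, rank))
  rj <- colSums(ranks)
  s <- sum(rj^2)
  tt <- 0
  if (tie_correction) {
    tt <- sum(apply(ranks, 1, function(r) {
      tab <- table(r)
      sum(tab^3 - tab)
    }))
  }
  denom <- m^2 * n * (n^2 - 1) - m * tt
  w <- if (denom <= 0) 1 else (12 * s - 3 * m^2 * n * (n + 1)^2) / denom
  w <- min(max(w, 0), 1)
  chi2 <- m * (n - 1) * w
  df <- n - 1
  list(w = w, chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Delphi consensus: per-item coefficient of variation
#'
#' `cv = sd/mean` of the experts' ratings of each item (sample SD by
#' default). Consensus is conventionally declared when cv < 0.25.
#'
#' @param ratings Experts-by-items matrix, or a vector of one item's
#'   ratings.
#' @param threshold Consensus threshold on cv.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return Data frame `mean`, `sd`, `cv`, `consensus` per item.
#' @export
expert_cv <- function(ratings, threshold = 0.25,
                      sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- if (is.null(dim(ratings))) matrix(ratings, ncol = 1) else as.matrix(ratings)
  mu <- colMeans(x)
  if (any(mu <= 0)) stop("zero or negative mean rating; cv undefined")
  s <- apply(x, 2, sd)
  if (sd_type == "population") s <- s * sqrt((nrow(x) - 1) / nrow(x))
  cv <- s / mu
  data.frame(mean = mu, sd = s, cv = cv, consensus = cv < threshold,
             row.names = colnames(x) %||% NULL)
}

#' Delphi expert authority coefficient
#'
#' `Cr = (judgment basis + familiarity) / 2`, the conventional composition;
#' an expert (or panel) is considered authoritative when Cr > 0.80.
#'
#' @param judgment_basis,familiarity Values in `[0, 1]`.
#' @param threshold Authority threshold.
#' @return List `cr`, `authoritative`.
#' @export
authority_coefficient <- function(judgment_basis, familiarity, threshold = 0.80) {
  if (any(judgment_basis < 0 | judgment_basis > 1) ||
      any(familiarity < 0 | familiarity > 1)) {
    stop("judgment basis and familiarity must lie in [0, 1]")
  }
  cr <- (judgment_basis + familiarity) / 2
  list(cr = cr, authoritative = cr > threshold)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf_level Confidence level.
#' @return List `estimate`, `lower`, `upper`.
#' @export
wilson_interval <- function(successes, n, conf_level = 0.95) {
  .assert_number(n, "n", lo = 1)
  .assert_number(successes, "successes", lo = 0, hi = n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p,
       lower = max(0, center - half),
       upper = min(1, center + half))
}
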