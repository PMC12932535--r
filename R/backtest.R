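#' Stratified train/test split of a cohort
#'
#' Splits the valid records into a modeling (train) and testing set,
#' stratified by age group and sex, using largest-remainder rounding of the
#' per-stratum test counts so the overall fraction is honoured as closely
#' as integer counts allow. Reproducible under `seed`.
#'
#' @param cohort A `coord_cohort` (or cohort-layout data frame).
#' @param train_fraction Fraction assigned to the modeling set.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param min_per_group Minimum valid records required per age group.
#' @return List `train`, `test` (disjoint data frames partitioning the
#'   valid records).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed,
                         min_per_group = 50L) {
  if (missing(seed)) stop("a seed is required for a reproducible split")
  df <- cohort[if ("valid" %in% names(cohort)) cohort$valid else TRUE, ,
               drop = FALSE]
  df <- df[df$age_group %in% c("group4", "group5"), , drop = FALSE]
  per_group <- table(df$age_group)
  if (any(per_group < min_per_group)) {
    stop(sprintf("need at least %d valid records per age group", min_per_group))
  }
  strata <- interaction(df$age_group, df$sex, drop = TRUE)
  sizes <- table(strata)
  exact <- (1 - train_fraction) * as.numeric(sizes)
  base <- floor(exact)
  total_test <- round((1 - train_fraction) * nrow(df))
  rem <- total_test - sum(base)
  frac <- exact - base
  if (rem > 0) {
    order_idx <- order(frac, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(sizes), function(i) {
      members <- which(strata == names(sizes)[i])
      sample(members, base[i])
    }))
  })
  list(train = df[-test_idx, , drop = FALSE],
       test = df[test_idx, , drop = FALSE])
}

.theoretical_band <- function(q, shares = c(10, 25, 50, 15)) {
  # q = position of a composite in the modeling set's ECDF; top `shares[1]`%
  # is Excellent, etc.
  cum <- rev(cumsum(rev(shares)))[-1] / 100      # 0.90, 0.65, 0.15
  lab <- band_levels()
  out <- rep(lab[4], length(q))
  out[q >= cum[3] - 1e-12] <- lab[3]
  out[q >= cum[2] - 1e-12] <- lab[2]
  out[q >= cum[1] - 1e-12] <- lab[1]
  out
}

#' Back-test an evaluation standard on a held-out set
#'
#' Builds the complete standard on the modeling (train) set only — per-
#' indicator five-level norms at the configured anchors and composite band
#' cutoffs at P90/P65/P15 — then scores and classifies the held-out (test)
#' records. Two notions of error are reported, mirroring how such
#' validations are presented:
#' \itemize{
#'   \item per-band signed errors: observed band percentage minus the
#'     theoretical 10/25/50/15 share, per age group;
#'   \item an overall per-record misclassification rate: the fraction of
#'     test records whose classified band (lookup in the rounded cut table)
#'     differs from the theoretical-quantile band of their composite within
#'     the train distribution (ECDF position against the theoretical
#'     shares), with its Wilson confidence interval. The pass flag requires
#'     a point estimate below 5 percent.
#' }
#'
#' @param train,test Cohort data frames (from [split_cohort()]).
#' @param weights Weight table (default: the published system), see
#'   [load_weight_table()].
#' @param anchors Five-level percentile anchors for norm construction.
#' @param digits Rounding of the published-style composite cutoffs.
#' @param catalogue Indicator catalogue.
#' @return A `backtest_report` list: `n_train`, `n_test`, `norms`, `bands`,
#'   `by_group` (counts, percentages, signed errors per band), `error_rate`,
#'   `wilson`, `pass`.
#' @export
run_backtest <- function(train, test, weights = load_weight_table(),
                         anchors = c(3, 25, 50, 75, 90), digits = 2,
                         catalogue = load_catalogue()) {
  groups <- intersect(c("group4", "group5"), unique(train$age_group))
  norms <- list(); bands <- list(); train_scored <- list()
  for (g in groups) {
    tr <- train[train$age_group == g, , drop = FALSE]
    wg <- weights[weights$age_group == g, ]
    ind <- lapply(indicator_ids(), function(id) {
      build_indicator_norms(tr[[id]],
                            direction = catalogue$direction[catalogue$id == id],
                            final_weight = wg$final_weight[wg$id == id],
                            anchors = anchors, id = id)
    })
    names(ind) <- indicator_ids()
    norms[[g]] <- structure(list(age_group = g,
                                 level_points = c(20, 40, 60, 80, 100),
                                 indicators = ind),
                            class = "coord_norms")
    sc <- score_cohort(tr, norms = norms[g], catalogue = catalogue)
    train_scored[[g]] <- sc
    dims <- unique(catalogue$dimension)
    bands[[g]] <- build_composite_bands(sc$composite, sc[, dims, drop = FALSE],
                                        digits = digits, age_group = g)
  }
  test_scored <- score_cohort(test[test$age_group %in% groups, , drop = FALSE],
                              norms = norms, catalogue = catalogue,
                              bands = bands)
  shares <- c(10, 25, 50, 15)
  by_group <- list()
  mismatch <- 0L
  for (g in groups) {
    ts <- test_scored[test_scored$age_group == g, , drop = FALSE]
    counts <- table(factor(ts$band, levels = band_levels()))
    pct <- 100 * as.numeric(counts) / nrow(ts)
    q <- ecdf(train_scored[[g]]$composite)(ts$composite)
    theo <- .theoretical_band(q, shares)
    mismatch <- mismatch + sum(theo != ts$band)
    by_group[[g]] <- data.frame(band = band_levels(),
                                count = as.numeric(counts),
                                percent = pct,
                                theoretical = shares,
                                signed_error = pct - shares)
  }
  n_test <- nrow(test_scored)
  wil <- wilson_interval(mismatch, n_test)
  structure(list(n_train = nrow(train), n_test = n_test, norms = norms,
                 bands = bands, by_group = by_group,
                 error_count = mismatch, error_rate = mismatch / n_test,
                 wilson = wil, pass = (mismatch / n_test) < 0.05),
            class = "backtest_report")
}

#' @export
print.backtest_report <- function(x, ...) {
  cat(sprintf("<backtest_report> train %d / test %d\n", x$n_train, x$n_test))
  for (g in names(x$by_group)) {
    cat(g, ":\n", sep = "")
    print(x$by_group[[g]], row.names = FALSE, digits = 3)
  }
  cat(sprintf("overall error rate %.1f%% (95%% CI %.1f%%-%.1f%%) -> %s\n",
              100 * x$error_rate, 100 * x$wilson$lower, 100 * x$wilson$upper,
              if (x$pass) "pass (<5%)" else "FAIL (>=5%)"))
  invisible(x)
}
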