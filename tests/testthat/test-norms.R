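test_that("built norm bands equal the empirical percentiles from a sort-based oracle", {
  set.seed(41)
  anchors <- c(3, 25, 50, 75, 90)
  # independent oracle: interpolation between closest ranks on sorted data
  sort_quantile <- function(v, p) {
    s <- sort(v); h <- (length(s) - 1) * p
    lo <- floor(h) + 1
    s[lo] + (h - floor(h)) * (s[pmin(lo + 1, length(s))] - s[lo])
  }
  for (direction in c("higher_is_better", "lower_is_better")) {
    v <- runif(501, 10, 40)
    nt <- build_indicator_norms(v, direction, final_weight = 0.05,
                                anchors = anchors, id = "x")
    adj <- if (direction == "lower_is_better") -v else v
    expected <- sort_quantile(adj, anchors / 100)
    s <- if (direction == "lower_is_better") -1 else 1
    expect_equal(s * c(nt$floor, nt$cuts), expected, tolerance = 1e-12)
    expect_equal(nt$weighted_scores, 0.05 * c(20, 40, 60, 80, 100))
  }
  expect_error(build_indicator_norms(rep(5, 100), "higher_is_better", 0.1),
               "degenerate")
  expect_error(build_indicator_norms(runif(10), "higher_is_better", 0.1),
               "30 samples")
})

test_that("level assignment honours the published bands, floor and closure", {
  n4 <- load_norm_tables("group4")
  # single-leg stance, 4-year group
  x3 <- assign_level(c(10, 1.0, 13.49, 28.65, 28.66), n4$indicators$x3)
  expect_equal(x3$level, c(3L, NA, 2L, 2L, 1L))
  expect_equal(x3$level_score, c(60, 0, 80, 80, 100))
  expect_equal(x3$weighted_score, c(0.66, 0, 0.88, 0.88, 1.1))
  # interior edge belongs to the better band
  expect_equal(assign_level(13.49, n4$indicators$x3)$level, 2L)
  # a lower-is-better indicator: faster is better, beyond-floor is no score
  x1 <- assign_level(c(3.0, 3.16, 11.25, 8.66), n4$indicators$x1)
  expect_equal(x1$level, c(1L, 2L, NA, 4L))
  # value exactly on the floor is still scored at level 5
  expect_equal(assign_level(2.22, n4$indicators$x3)$level, 5L)
})

test_that("improving a raw measurement never lowers the assigned level", {
  norms <- load_norm_tables("all")
  cat <- load_catalogue()
  for (g in names(norms)) {
    for (id in indicator_ids()) {
      nt <- norms[[g]]$indicators[[id]]
      lo <- min(nt$floor, nt$cuts) - 3
      hi <- max(nt$floor, nt$cuts) + 3
      grid <- seq(lo, hi, length.out = 201)
      if (nt$direction == "lower_is_better") grid <- rev(grid)
      sc <- assign_level(grid, nt)$level_score
      expect_true(all(diff(sc) >= 0),
                  info = sprintf("%s/%s not monotone", g, id))
    }
  }
})

test_that("scoring a record sums weighted level scores within and across dimensions", {
  n4 <- load_norm_tables("group4")
  best_value <- function(nt) {
    s <- if (nt$direction == "lower_is_better") -1 else 1
    nt$cuts[4] + s * 1
  }
  worst_scored <- function(nt) nt$floor
  rec_best <- lapply(n4$indicators, best_value)
  rec_worst <- lapply(n4$indicators, worst_scored)

  sr <- score_record(rec_best, n4)
  # published weighted level-100 scores total 100.1 (rounded weights)
  expect_lt(abs(sr$composite - 100), 0.2)
  expect_equal(sr$n_no_score, 0)
  expect_equal(sum(sr$dimension_scores), sr$composite, tolerance = 1e-9)

  sw <- score_record(rec_worst, n4)
  expect_lt(abs(sw$composite - 20), 0.2)
  expect_true(all(sw$indicators$level == 5L))

  # a record below one floor: that indicator contributes 0 and is flagged
  rec_fl <- rec_best; rec_fl$x3 <- 1.0
  sf <- score_record(rec_fl, n4)
  expect_equal(sf$n_no_score, 1)
  expect_equal(sf$composite, sr$composite - 1.1, tolerance = 1e-9)
})

test_that("cohort scoring is row-order invariant and partitions the composite", {
  cfg <- generator_config(n = c(group4.female = 40L, group4.male = 40L,
                                group5.female = 40L, group5.male = 40L))
  cohort <- generate_cohort(cfg, seed = 5)
  sc <- score_cohort(cohort)
  dims <- unique(load_catalogue()$dimension)
  expect_equal(rowSums(sc[, dims]), sc$composite, tolerance = 1e-9)
  perm <- sample(nrow(cohort))
  sc2 <- score_cohort(cohort[perm, ])
  expect_equal(sc2[order(match(sc2$child_id, sc$child_id)), "composite"],
               sc$composite, ignore_attr = TRUE)
})

test_that("composite bands come from P90/P65/P15 and classify by better-band closure", {
  set.seed(42)
  scores <- rnorm(400, 60, 12)
  cb <- build_composite_bands(scores, digits = NULL)
  expect_equal(cb$composite,
               unname(quantile(scores, c(0.90, 0.65, 0.15), type = 7)),
               tolerance = 1e-12)
  # classifying the modeling sample by its own cutoffs reproduces the shares
  cls <- classify_composite(scores, cb)
  shares <- 100 * as.numeric(table(factor(cls, band_levels()))) / 400
  expect_equal(shares, c(10, 25, 50, 15), tolerance = 0.5)
  expect_error(build_composite_bands(rnorm(20)), "at least 50")

  pub <- load_composite_bands()
  expect_equal(classify_composite(c(80, 45, 76.05, 67.01, 51.40, 51.39),
                                  pub$group4),
               c("Excellent", "Unqualified", "Excellent", "Good",
                 "Qualified", "Unqualified"))
})

test_that("norms rebuilt from band-anchored samples converge to the source table", {
  norms <- load_norm_tables("all")
  wt <- load_weight_table()
  set.seed(43)
  for (g in c("group4", "group5")) {
    nt <- norms[[g]]$indicators$x3
    edges <- rowMeans(sapply(1:4, function(i) {
      v <- band_anchored_sample(nt, n = 20000, unit = "seconds")
      rebuilt <- build_indicator_norms(v, nt$direction, nt$weight, id = "x3")
      c(rebuilt$floor, rebuilt$cuts)
    }))
    rel <- abs(edges - c(nt$floor, nt$cuts)) / abs(c(nt$floor, nt$cuts))
    expect_lt(max(rel), 0.05)
  }
})

test_that("norm artifacts round-trip through JSON with validation", {
  n4 <- load_norm_tables("group4")
  path <- withr::local_tempfile(fileext = ".json")
  write_norms(n4, path)
  again <- read_norms(path)
  expect_equal(again$age_group, "group4")
  for (id in indicator_ids()) {
    expect_equal(again$indicators[[id]]$cuts, n4$indicators[[id]]$cuts)
    expect_equal(again$indicators[[id]]$weighted_scores,
                 n4$indicators[[id]]$weighted_scores)
  }
})
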