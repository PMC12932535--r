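test_that("KMO matches closed-form and regression-based partial correlations", {
  set.seed(31)
  # equicorrelated 3 variables, rho = 0.5: population partials are
  # rho/(1+rho) = 1/3, so KMO = rho^2 / (rho^2 + (1/3)^2) = 0.25/0.3611
  x <- equicorrelated(20000, 3, 0.5)
  expect_equal(kmo(x), 0.25 / (0.25 + (1 / 3)^2), tolerance = 0.02)
  # exact population check through the correlation-matrix interface
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  expect_equal(kmo(r), 0.25 / (0.25 + (1 / 3)^2), tolerance = 1e-12)

  # random 4-variable sample vs regression-residual partial correlations
  y <- matrix(rnorm(400 * 4), 400, 4) %*% matrix(runif(16, -0.5, 1), 4, 4)
  rr <- cor(y)
  pc <- function(i, j) {
    oth <- setdiff(1:4, c(i, j))
    cor(stats::resid(stats::lm(y[, i] ~ y[, oth])),
        stats::resid(stats::lm(y[, j] ~ y[, oth])))
  }
  pairs <- utils::combn(4, 2)
  r2 <- sum(rr[upper.tri(rr)]^2)
  p2 <- sum(apply(pairs, 2, function(ij) pc(ij[1], ij[2])^2))
  expect_equal(kmo(y), r2 / (r2 + p2), tolerance = 1e-10)

  # singular correlation matrix: adequacy undefined
  z <- cbind(a = rnorm(100))
  z <- cbind(z, b = z[, 1], c = rnorm(100))
  expect_error(kmo(z), "singular")
})

test_that("correlation PCA has unit-sum eigenvalue structure and reconstructs R", {
  set.seed(32)
  x <- equicorrelated(300, 4, 0.6)
  p <- pca_eigen(x)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(p$cumulative_pct[4], 100, tolerance = 1e-9)
  expect_true(all(abs(p$loadings) <= 1 + 1e-9))
  expect_equal(p$loadings %*% t(p$loadings), cor(x),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: the dominant loading of each component is positive
  for (j in 1:4) expect_gt(max(p$loadings[, j]), 0)

  # two perfectly correlated standardized variables
  v <- rnorm(100)
  p2 <- pca_eigen(cbind(v, v))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(unname(p2$loadings[, 1]), c(1, 1), tolerance = 1e-9)

  const <- cbind(rnorm(50), rep(1, 50))
  colnames(const) <- c("a", "b")
  expect_error(pca_eigen(const), "zero-variance.*b")
})

test_that("component selection applies the eigenvalue floor and variance threshold", {
  printed <- list(eigenvalues = c(1.887, 1.231, 0.897, 0.185),
                  cumulative_pct = c(47.185, 82.963, 95.377, 100))
  expect_equal(as.integer(select_components(printed)), 2L)
  expect_false(attr(select_components(printed), "extended"))

  one <- list(eigenvalues = c(3.8, 0.1, 0.1), cumulative_pct = c(95, 97.5, 100))
  expect_equal(as.integer(select_components(one)), 1L)

  ext <- list(eigenvalues = c(1.5, 1.2, 0.9, 0.4),
              cumulative_pct = c(37.5, 67.5, 90, 100))
  k <- select_components(ext)
  expect_equal(as.integer(k), 3L)
  expect_true(attr(k, "extended"))
})

test_that("the printed weighting chain reproduces the published balance weights", {
  fx <- jsonlite::read_json(system.file("extdata", "pca_balance.json",
                                        package = "coordeval"),
                            simplifyVector = TRUE)$group4
  loads <- do.call(rbind, fx$loadings)
  a <- loading_coefficients(loads, fx$eigenvalues[1:2])
  expect_equal(unname(a["x1", 1]), 0.936 / sqrt(1.887), tolerance = 1e-9)
  expect_equal(unname(round(a["x1", 1], 3)), 0.681)
  expect_equal(unname(round(a["x3", 2], 3)), 0.793)
  # the printed coefficient table carries its own last-digit rounding
  expect_lt(max(abs(a - do.call(rbind, fx$coefficients))), 0.0015)

  b <- composite_coefficients(a, fx$variance_pct[1:2])
  expect_lt(max(abs(b - unlist(fx$composite_coefficients))), 0.0015)
  expect_equal(unname(round(b[1], 3)), 0.377)
  expect_equal(unname(round(b[3], 3)), 0.309)

  # normalizing the printed composite coefficients reproduces the printed
  # weight column (which carries its own last-digit rounding: the fourth
  # entry normalizes to 0.2505, printed 0.250)
  w <- normalize_to_weights(unlist(fx$composite_coefficients))
  expect_equal(sum(w), 1)
  expect_equal(unname(round(w[1:3], 3)), c(0.273, 0.253, 0.224))
  expect_lt(max(abs(w - c(0.273, 0.253, 0.224, 0.250))), 0.0015)

  # published 5-year balance row (printed weights carry their own rounding)
  fx5 <- jsonlite::read_json(system.file("extdata", "pca_balance.json",
                                         package = "coordeval"),
                             simplifyVector = TRUE)$group5
  w5 <- normalize_to_weights(unlist(fx5$composite_coefficients))
  expect_lt(max(abs(w5 - unlist(fx5$weights))), 0.0015)
})

test_that("composite coefficients reduce correctly in degenerate settings", {
  # equal coefficients across components pass through unchanged
  a <- cbind(c(0.4, 0.4), c(0.4, 0.4))
  expect_equal(composite_coefficients(a, c(60, 20)), c(0.4, 0.4))
  # single retained component: the variance weighting is a no-op
  a1 <- cbind(c(0.7, 0.2))
  expect_equal(composite_coefficients(a1, 47.2), c(0.7, 0.2))
  expect_error(composite_coefficients(a, c(0, 0)), "positive")
  expect_error(loading_coefficients(a, c(1.5, -0.1)), "positive")
})

test_that("weight normalization guards against uninterpretable coefficients", {
  expect_equal(normalize_to_weights(c(a = 2)), c(a = 1))
  expect_error(normalize_to_weights(c(0.3, -0.1)), "non-positive")
  expect_warning(w <- normalize_to_weights(c(0.3, -0.1), negative = "absolute"),
                 "absolute")
  expect_equal(sum(w), 1)
})

test_that("CV weights match the published moments and are scale invariant", {
  mom <- indicator_moments()
  m4 <- mom$group4
  cw <- cv_weights(c(x17 = m4$x17$mean, x18 = m4$x18$mean),
                   c(x17 = m4$x17$sd, x18 = m4$x18$sd))
  expect_equal(round(cw["x17", "cv"], 3), 0.338)
  expect_equal(round(cw["x17", "weight"], 3), 0.358)
  expect_equal(round(cw["x18", "weight"], 3), 0.642)
  expect_equal(sum(cw$weight), 1)

  m5 <- mom$group5
  cw5 <- cv_weights(c(m5$x19$mean, m5$x20$mean), c(m5$x19$sd, m5$x20$sd))
  expect_equal(round(cw5$cv, 3), c(0.186, 0.125))
  expect_equal(round(cw5$weight, 3), c(0.598, 0.402))

  # unit changes multiplying mean and sd equally leave weights unchanged
  cw2 <- cv_weights(c(x17 = m4$x17$mean * 60, x18 = m4$x18$mean),
                    c(x17 = m4$x17$sd * 60, x18 = m4$x18$sd))
  expect_equal(cw2$weight, cw$weight)
  expect_equal(cv_weights(c(2, 2), c(0.5, 0.5))$weight, c(0.5, 0.5))
  expect_error(cv_weights(c(a = -1, b = 2), c(1, 1)), "a")
})

test_that("final weights multiply through the hierarchy and total one", {
  wt <- load_weight_table()
  dimw <- attr(wt, "dimension_weights")
  expect_equal(sum(dimw), 1)
  for (g in c("group4", "group5")) {
    sub <- wt[wt$age_group == g, ]
    # published final weights are the rounded dimension x indicator products
    recomputed <- dimw[sub$dimension] * sub$indicator_weight
    expect_lt(max(abs(recomputed - sub$final_weight)), 0.005)
    # published grand total carries rounding only
    expect_lt(abs(sum(sub$final_weight) - 1), 2e-3)
    # recomputing through final_weights() gives an exact unit total
    iw <- split(setNames(sub$indicator_weight, sub$id), sub$dimension)
    iw <- lapply(iw, function(v) v / sum(v))
    fw <- final_weights(dimw, iw)
    expect_equal(sum(fw$final_weight), 1, tolerance = 1e-12)
  }
  expect_error(final_weights(c(balance = 1), list(flying = c(x1 = 1))),
               "unknown dimension")
})

test_that("EFA screening drops exactly the planted weak items and flags cross-loaders", {
  expect_equal(efa_screen(matrix(0.3, 1, 1))$dropped, "item1")
  fl <- efa_screen(rbind(item1 = c(0.7, 0.65)))
  expect_equal(fl$flagged, "item1")

  # 28-item battery, 8 planted low-convergence items
  set.seed(33)
  strong <- t(sapply(1:20, function(i) {
    row <- runif(3, 0, 0.15)
    row[sample(3, 1)] <- runif(1, 0.55, 0.9)
    row
  }))
  weak <- matrix(runif(8 * 3, 0, 0.45), 8, 3)
  weak <- weak / apply(weak, 1, max) * runif(8, 0.2, 0.45)
  loads <- rbind(strong, weak)
  rownames(loads) <- paste0("item", 1:28)
  sc <- efa_screen(loads)
  expect_setequal(sc$dropped, paste0("item", 21:28))
  expect_true(all(paste0("item", 1:20) %in% sc$retained))
})

test_that("weights are invariant to rescaling raw indicators", {
  set.seed(34)
  x <- equicorrelated(500, 4, 0.5) + 10
  x <- sweep(x, 2, c(3, 10, 1, 0.5), "*")
  w1 <- pca_weights(x, cum_threshold = 60)$weights
  w2 <- pca_weights(sweep(x, 2, c(10, 0.1, 2, 7), "*"), cum_threshold = 60)$weights
  expect_equal(w1, w2, tolerance = 1e-9)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
})
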