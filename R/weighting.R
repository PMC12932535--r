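#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO statistic comparing zero-order correlations with the
#' anti-image partial correlations derived from the inverse correlation
#' matrix: `KMO = sum(r^2) / (sum(r^2) + sum(partial^2))` over off-diagonal
#' pairs. Values near 1 indicate the correlation structure is suitable for
#' component analysis.
#'
#' @param x Numeric data matrix/data frame (records by indicators), or a
#'   correlation matrix (symmetric, unit diagonal).
#' @return KMO value in `[0, 1]`.
#' @export
kmo <- function(x) {
  r <- if (is.matrix(x) && nrow(x) == ncol(x) &&
           all(abs(diag(as.matrix(x)) - 1) < 1e-8)) {
    as.matrix(x)
  } else {
    x <- as.matrix(x)
    if (ncol(x) < 3L) stop("need at least 3 indicators")
    cor(x)
  }
  inv <- tryCatch(solve(r), error = function(e) {
    stop("adequacy undefined: correlation matrix is singular", call. = FALSE)
  })
  if (max(abs(inv)) > 1e10) {
    stop("adequacy undefined: correlation matrix is singular", call. = FALSE)
  }
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Principal-component decomposition of a correlation matrix
#'
#' Eigen-decomposition of the sample (n-1 denominator) correlation matrix.
#' Loadings are eigenvectors scaled by the square root of their eigenvalue,
#' so the retained loadings reconstruct the correlation matrix up to the
#' discarded components. Sign convention: each component is oriented so its
#' largest-magnitude loading is positive, removing eigenvector sign
#' ambiguity.
#'
#' @param x Data matrix/data frame, records by indicators (at least
#'   `ncol + 1` records), or a correlation matrix.
#' @return A `pca_result` list: `eigenvalues`, `variance_pct`,
#'   `cumulative_pct`, `loadings` (indicators by components).
#' @export
pca_eigen <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-8) &&
      isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    r <- x
  } else {
    if (ncol(x) < 2L) stop("need at least 2 indicators")
    if (nrow(x) < ncol(x) + 1L) stop("need at least indicators + 1 records")
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      stop("zero-variance indicator: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
    r <- cor(x)
  }
  e <- eigen(r, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  load <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  # orient each component so its largest-|.| loading is positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(r)
  pct <- 100 * lam / sum(lam)
  structure(list(
    eigenvalues = lam,
    variance_pct = pct,
    cumulative_pct = cumsum(pct),
    loadings = load
  ), class = "pca_result")
}

#' Number of components to retain
#'
#' Keeps the components whose eigenvalue exceeds `eigen_floor`; if their
#' cumulative explained variance falls short of `cum_threshold` percent, the
#' count is extended minimally to reach the threshold and the result is
#' flagged.
#'
#' @param p A `pca_result`, or a list with `eigenvalues` and
#'   `cumulative_pct`.
#' @param eigen_floor Minimum eigenvalue (default 1, the Kaiser rule).
#' @param cum_threshold Required cumulative variance percentage.
#' @return Integer count with attribute `extended` (TRUE when the Kaiser set
#'   alone missed the variance threshold).
#' @export
select_components <- function(p, eigen_floor = 1.0, cum_threshold = 80) {
  lam <- p$eigenvalues
  cum <- p$cumulative_pct
  k <- sum(lam > eigen_floor)
  k <- max(k, 1L)
  extended <- FALSE
  while (k < length(lam) && cum[k] < cum_threshold) {
    k <- k + 1L
    extended <- TRUE
  }
  structure(as.integer(k), extended = extended)
}

#' Component-score coefficients from loadings
#'
#' Divides each loading by the square root of its component's eigenvalue,
#' giving the coefficients of the indicators in each component's linear
#' combination.
#'
#' @param loadings Indicators-by-components loading matrix (retained
#'   components only).
#' @param eigenvalues Eigenvalues of the retained components (positive).
#' @export
loading_coefficients <- function(loadings, eigenvalues) {
  loadings <- as.matrix(loadings)
  if (length(eigenvalues) != ncol(loadings)) {
    stop("one eigenvalue per retained component required")
  }
  if (any(eigenvalues <= 0)) stop("eigenvalues of retained components must be positive")
  sweep(loadings, 2, sqrt(eigenvalues), "/")
}

#' Variance-weighted composite coefficients
#'
#' Averages each indicator's per-component coefficients, weighting by the
#' components' variance contribution rates:
#' `b_i = sum_j a_ij v_j / sum_j v_j`.
#'
#' @param coefficients Indicators-by-components coefficient matrix.
#' @param variance_pct Variance contribution (percent) of each retained
#'   component.
#' @export
composite_coefficients <- function(coefficients, variance_pct) {
  coefficients <- as.matrix(coefficients)
  if (length(variance_pct) != ncol(coefficients)) {
    stop("one variance share per component required")
  }
  if (sum(variance_pct) <= 0) stop("total variance contribution must be positive")
  b <- as.vector(coefficients %*% variance_pct) / sum(variance_pct)
  names(b) <- rownames(coefficients)
  b
}

#' Normalize composite coefficients to weights
#'
#' `w_i = b_i / sum(b)`. Negative coefficients make a weight
#' uninterpretable, so they abort by default; `negative = "absolute"`
#' normalizes absolute values instead (with a warning).
#'
#' @param b Composite coefficients.
#' @param negative `"error"` (default) or `"absolute"`.
#' @return Weights summing to exactly 1.
#' @export
normalize_to_weights <- function(b, negative = c("error", "absolute")) {
  negative <- match.arg(negative)
  if (any(b <= 0)) {
    if (negative == "error") {
      stop("non-positive composite coefficient; the weighting is ",
           "uninterpretable — reorient the indicator (score direction) or ",
           "use negative = \"absolute\"", call. = FALSE)
    }
    warning("normalizing absolute values of coefficients with mixed signs")
    b <- abs(b)
  }
  w <- b / sum(b)
  names(w) <- names(b)
  w
}

#' Principal-component indicator weights for one dimension
#'
#' Full chain on raw data: correlation PCA, component selection,
#' loading/sqrt(eigenvalue) coefficients, variance-weighted composite
#' coefficients, normalization.
#'
#' @param x Records-by-indicators data for one dimension.
#' @inheritParams select_components
#' @inheritParams normalize_to_weights
#' @return List with `pca`, `n_components`, `coefficients`,
#'   `composite_coefficients`, `weights`, `kmo`.
#' @export
pca_weights <- function(x, eigen_floor = 1.0, cum_threshold = 80,
                        negative = c("error", "absolute")) {
  p <- pca_eigen(x)
  k <- select_components(p, eigen_floor, cum_threshold)
  a <- loading_coefficients(p$loadings[, seq_len(k), drop = FALSE],
                            p$eigenvalues[seq_len(k)])
  b <- composite_coefficients(a, p$variance_pct[seq_len(k)])
  names(b) <- rownames(p$loadings)
  list(pca = p, n_components = as.integer(k), coefficients = a,
       composite_coefficients = b,
       weights = normalize_to_weights(b, negative = negative),
       kmo = kmo(x))
}

#' Coefficient-of-variation weights
#'
#' For dimensions with too few indicators for component analysis, weights
#' are proportional to each indicator's coefficient of variation
#' `cv_i = sd_i / mean_i` (sample SD): the more dispersed — hence more
#' discriminating — an indicator, the larger its weight.
#'
#' @param means,sds Named numeric vectors (means must be positive).
#' @return A data frame with `mean`, `sd`, `cv`, `weight` (weights sum to 1).
#' @export
cv_weights <- function(means, sds) {
  if (length(means) != length(sds)) stop("means and sds must have equal length")
  if (any(means <= 0)) {
    bad <- names(means)[means <= 0] %||% which(means <= 0)
    stop("non-positive mean for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cv <- sds / means
  data.frame(mean = means, sd = sds, cv = cv, weight = cv / sum(cv),
             row.names = names(means) %||% NULL)
}

#' Combine dimension and indicator weights into final weights
#'
#' The final weight of an indicator is its dimension's AHP weight times its
#' within-dimension weight. With both layers normalized the final weights
#' total one (published tables carry rounding, so totals within 0.002 are
#' accepted when validating shipped artifacts).
#'
#' @param dimension_weights Named vector of dimension weights (sums to 1).
#' @param indicator_weights Named list: per dimension, a named vector of
#'   within-dimension indicator weights (each sums to 1).
#' @return Data frame with `id`, `dimension`, `indicator_weight`,
#'   `final_weight`.
#' @export
final_weights <- function(dimension_weights, indicator_weights) {
  unknown <- setdiff(names(indicator_weights), names(dimension_weights))
  if (length(unknown)) {
    stop("indicator weights refer to unknown dimension: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(indicator_weights), function(dim) {
    w <- indicator_weights[[dim]]
    data.frame(id = names(w), dimension = dim, indicator_weight = as.numeric(w),
               final_weight = as.numeric(w) * dimension_weights[[dim]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen indicators on factor loadings
#'
#' Exploratory-factor-analysis retention rule: an indicator whose maximum
#' absolute loading falls below `retain_threshold` lacks convergent validity
#' and is dropped; an indicator whose top two absolute loadings differ by
#' less than `cross_gap` loads on two factors at once and is flagged.
#'
#' @param loadings Indicators-by-factors loading matrix (rownames are
#'   indicator ids).
#' @param retain_threshold Minimum acceptable maximum |loading|.
#' @param cross_gap Minimum separation between the top two |loadings|.
#' @return List with `retained`, `dropped`, `flagged` (cross-loading), and a
#'   `reasons` data frame.
#' @export
efa_screen <- function(loadings, retain_threshold = 0.5, cross_gap = 0.2) {
  loadings <- as.matrix(loadings)
  ids <- rownames(loadings) %||% paste0("item", seq_len(nrow(loadings)))
  absl <- abs(loadings)
  top <- apply(absl, 1, max)
  second <- if (ncol(loadings) >= 2) {
    apply(absl, 1, function(z) sort(z, decreasing = TRUE)[2])
  } else rep(0, nrow(loadings))
  dropped <- top < retain_threshold
  flagged <- !dropped & (top - second) < cross_gap & ncol(loadings) >= 2
  reasons <- data.frame(
    id = ids,
    max_loading = top,
    status = ifelse(dropped, "dropped", ifelse(flagged, "flagged", "retained")),
    reason = ifelse(dropped, "low-convergence",
                    ifelse(flagged, "cross-loading", "")),
    stringsAsFactors = FALSE
  )
  list(retained = ids[!dropped], dropped = ids[dropped], flagged = ids[flagged],
       reasons = reasons)
}

#' Load the published weight system
#'
#' Returns the published dimension weights and per-age-group indicator and
#' final weights as a long data frame.
#'
#' @param path Optional alternative JSON artifact.
#' @return Data frame `id`, `dimension`, `age_group`, `indicator_weight`,
#'   `final_weight`; attribute `dimension_weights`.
#' @export
load_weight_table <- function(path = NULL) {
  raw <- .read_json(path %||% .extdata("weights_table.json"))
  cat <- load_catalogue()
  rows <- lapply(c("group4", "group5"), function(g) {
    tab <- raw[[g]]
    data.frame(
      id = names(tab),
      dimension = cat$dimension[match(names(tab), cat$id)],
      age_group = g,
      indicator_weight = vapply(tab, function(x) x$indicator_weight, numeric(1)),
      final_weight = vapply(tab, function(x) x$final_weight, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dimension_weights") <- unlist(raw$dimension_weights)
  out
}
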