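#' Construct and validate an AHP judgment matrix
#'
#' A judgment matrix is a positive reciprocal pairwise-comparison matrix:
#' unit diagonal and `a_ji = 1/a_ij`. Published matrices typically carry
#' rounded decimal entries (0.33 for 1/3, 0.14 for 1/7), so reciprocity is
#' checked with a tolerance: `|a_ij * a_ji - 1| <= reciprocity_tolerance`.
#'
#' @param m Numeric square matrix (order 2--10).
#' @param criteria Optional criterion names (defaults to existing dimnames).
#' @param reciprocity_tolerance Allowed departure of `a_ij * a_ji` from 1.
#'   The default 0.02 accepts 2-decimal roundings; use 0 for strict mode.
#' @return The matrix with class `judgment_matrix`.
#' @export
judgment_matrix <- function(m, criteria = NULL, reciprocity_tolerance = 0.02) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || n < 2L || n > 10L) {
    stop("judgment matrix must be square of order 2-10")
  }
  if (any(!is.finite(m)) || any(m <= 0)) stop("entries must be positive")
  if (any(abs(diag(m) - 1) > 1e-12)) stop("diagonal entries must equal 1")
  dev <- abs(m * t(m) - 1)
  if (any(dev > reciprocity_tolerance + 1e-12)) {
    ij <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop(sprintf("reciprocity violated at (%d,%d): a_ij*a_ji = %.4f",
                 ij[1], ij[2], (m * t(m))[ij[1], ij[2]]))
  }
  if (!is.null(criteria)) dimnames(m) <- list(criteria, criteria)
  class(m) <- c("judgment_matrix", class(m))
  m
}

#' Read a judgment matrix from CSV
#'
#' @param path CSV file: n rows by n columns, header row of criterion names.
#' @param ... Passed to [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  judgment_matrix(as.matrix(df), criteria = names(df), ...)
}

#' The published dimension-level judgment matrix
#'
#' Pairwise comparisons of the six coordination dimensions (balance, spatial
#' orientation, rhythm, perceptual judgment, body coordination, limb range)
#' as printed, including the rounded decimal entries.
#'
#' @return A `judgment_matrix` of order 6.
#' @export
coordination_judgment_matrix <- function() {
  read_judgment_matrix(.extdata("judgment_matrix.csv"))
}

#' Column sums of a judgment matrix
#'
#' First step of the sum-method (approximate eigenvector) weighting.
#'
#' @param m Judgment matrix.
#' @return Numeric vector of column sums.
#' @export
ahp_column_sums <- function(m) colSums(unclass(m))

#' Column-normalize a judgment matrix
#'
#' Divides each entry by its column sum so every column of the result sums
#' to one.
#'
#' @param m Judgment matrix.
#' @export
ahp_normalize_columns <- function(m) {
  cs <- ahp_column_sums(m)
  if (any(cs <= 0)) stop("degenerate matrix: non-positive column sum")
  sweep(unclass(m), 2, cs, "/")
}

#' Sum-method priority weights
#'
#' The sum method approximates the principal eigenvector of a judgment
#' matrix: column-normalize, sum each row, and renormalize the row sums to
#' total one. For a perfectly consistent matrix (`a_ij = w_i/w_j`) this
#' recovers the weights exactly.
#'
#' @param m Judgment matrix.
#' @return Weight vector summing to 1.
#' @export
ahp_weights <- function(m) {
  d1 <- rowSums(ahp_normalize_columns(m))
  w <- d1 / sum(d1)
  names(w) <- rownames(m)
  w
}

#' Maximum-eigenvalue estimate
#'
#' `lambda_max = (1/n) * sum_i (M w)_i / w_i`, the Rayleigh-type estimate
#' used to test consistency. Equals the dominant eigenvalue exactly when `w`
#' is the true principal eigenvector, and equals `n` for consistent
#' matrices.
#'
#' @param m Judgment matrix.
#' @param w Positive weight vector summing to one (defaults to the
#'   sum-method weights).
#' @export
ahp_lambda_max <- function(m, w = ahp_weights(m)) {
  if (any(w <= 0)) stop("weights must be positive")
  mw <- as.vector(unclass(m) %*% w)
  mean(mw / w)
}

# Saaty random-index table; only the n = 6 entry (1.24) is identifiable from
# the published worked example, the rest are the standard constants.
.random_index <- c(`3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
                   `7` = 1.32, `8` = 1.41, `9` = 1.45)

#' Consistency index and ratio
#'
#' `C.I. = (lambda_max - n)/(n - 1)`; `C.R. = C.I./R.I.` with the Saaty
#' random index for the matrix order. A matrix is accepted as consistent
#' when `C.R. < 0.1`. Orders 1--2 are consistent by construction
#' (`C.R. = 0`).
#'
#' @param lambda_max Maximum-eigenvalue estimate.
#' @param n Matrix order.
#' @return List with `ci`, `ri`, `cr`, `consistent`.
#' @export
ahp_consistency <- function(lambda_max, n) {
  n <- as.integer(n)
  if (n < 2L) stop("order must be at least 2")
  if (n <= 2L) {
    return(list(ci = 0, ri = NA_real_, cr = 0, consistent = TRUE))
  }
  key <- as.character(n)
  if (!key %in% names(.random_index)) {
    stop(sprintf("no random-index constant for order %d", n))
  }
  ci <- (lambda_max - n) / (n - 1)
  ri <- .random_index[[key]]
  cr <- ci / ri
  list(ci = ci, ri = ri, cr = cr, consistent = cr < 0.1)
}

#' Full AHP analysis of a judgment matrix
#'
#' Runs the complete sum-method chain: column sums, column-normalized
#' matrix, row sums, priority weights, maximum-eigenvalue estimate and the
#' consistency test.
#'
#' @param m Judgment matrix (a `judgment_matrix`, or a plain matrix which is
#'   validated first).
#' @param ... Passed to [judgment_matrix()] when `m` is a plain matrix.
#' @return An `ahp_result` list: `weights`, `column_sums`, `normalized`,
#'   `row_sums`, `lambda_max`, `ci`, `ri`, `cr`, `consistent`, `n`.
#' @examples
#' res <- ahp(coordination_judgment_matrix())
#' round(res$weights, 2)
#' @export
ahp <- function(m, ...) {
  if (!inherits(m, "judgment_matrix")) m <- judgment_matrix(m, ...)
  n <- nrow(m)
  d <- ahp_normalize_columns(m)
  d1 <- rowSums(d)
  w <- d1 / sum(d1)
  names(w) <- rownames(m)
  lam <- ahp_lambda_max(m, w)
  cons <- ahp_consistency(lam, n)
  structure(list(
    n = n, weights = w, column_sums = ahp_column_sums(m), normalized = d,
    row_sums = d1, lambda_max = lam, ci = cons$ci, ri = cons$ri,
    cr = cons$cr, consistent = cons$consistent
  ), class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, digits = 3, ...) {
  cat(sprintf("<ahp_result> order %d\n", x$n))
  print(round(x$weights, digits))
  cat(sprintf("lambda_max = %.*f, C.I. = %.*f, C.R. = %.*f (%s)\n",
              digits, x$lambda_max, digits, x$ci, digits, x$cr,
              if (x$consistent) "consistent" else "NOT consistent"))
  invisible(x)
}
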