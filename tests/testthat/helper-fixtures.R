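# shared fixture builders (all generated in code, deterministic under the
# seeds set inside each test)

# exactly reciprocal random judgment matrix
random_reciprocal <- function(n, noise = 0.3) {
  w <- runif(n, 0.5, 3)
  m <- outer(w, w, "/") * exp(matrix(rnorm(n^2, 0, noise), n, n))
  m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

# perfectly consistent matrix from weights
consistent_matrix <- function(w) outer(w, w, "/")

# equicorrelated multivariate normal sample
equicorrelated <- function(n, p, rho) {
  f <- rnorm(n)
  sqrt(rho) * matrix(f, n, p) + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

# small cohort data frame in file layout (no generator involved)
manual_cohort_df <- function(n = 4) {
  vals <- lapply(indicator_ids(), function(id) round(runif(n, 5, 20), 2))
  names(vals) <- indicator_ids()
  cbind(data.frame(child_id = paste0("k", seq_len(n)),
                   sex = rep(c("female", "male"), length.out = n),
                   birth_date = rep("2014-03-10", n),
                   test_date = rep("2018-10-15", n),
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}
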