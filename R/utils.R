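`%||%` <- function(a, b) if (is.null(a)) b else a

.extdata <- function(file) {
  system.file("extdata", file, package = "coordeval", mustWork = TRUE)
}

.read_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is left untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
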