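#' Write a canonical fixture suite
#'
#' Emits, into `out_dir`: a small synthetic cohort CSV, the published
#' judgment matrix, copies of every shipped instrument artifact (catalogue,
#' weight system, norm tables, composite bands, moments, worked
#' principal-component example, sex effects), a synthetic expert-rating
#' table and a synthetic rater table, plus a `manifest.csv` listing every
#' emitted file with its MD5 checksum. Deterministic under `seed`.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Integer seed for the synthetic pieces.
#' @param n_per_cell Cohort cell size for the small fixture cohort.
#' @return Invisibly, the manifest data frame.
#' @export
write_fixture_suite <- function(out_dir, seed, n_per_cell = 15L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) files <<- c(files, name)

  # small cohort
  cfg <- generator_config(n = c(group4.female = n_per_cell,
                                group4.male = n_per_cell,
                                group5.female = n_per_cell,
                                group5.male = n_per_cell))
  cohort <- generate_cohort(cfg, seed = seed)
  write_cohort(cohort, file.path(out_dir, "cohort_small.csv"))
  emit("cohort_small.csv")

  # shipped instrument artifacts, copied verbatim
  shipped <- c("judgment_matrix.csv", "catalogue.json", "weights_table.json",
               "norms_group4.json", "norms_group5.json",
               "composite_bands.json", "indicator_moments.json",
               "pca_balance.json", "sex_effects.json")
  for (f in shipped) {
    file.copy(.extdata(f), file.path(out_dir, f), overwrite = TRUE)
    emit(f)
  }

  # synthetic expert ratings (16 experts x 6 dimensions, 1-5 scale) and a
  # synthetic rater table (30 subjects x 3 raters)
  with_seed(seed + 1L, {
    ratings <- matrix(pmin(pmax(round(rnorm(16 * 6, mean = 4, sd = 0.7)), 1), 5),
                      nrow = 16,
                      dimnames = list(paste0("expert", 1:16),
                                      c("balance", "rhythm",
                                        "spatial_orientation", "limb_range",
                                        "body_coordination",
                                        "perceptual_judgment")))
    write.csv(ratings, file.path(out_dir, "expert_ratings_synthetic.csv"))
    truth <- rnorm(30, 60, 10)
    raters <- sapply(1:3, function(j) truth + rnorm(30, 0, 3))
    colnames(raters) <- paste0("rater", 1:3)
    write.csv(raters, file.path(out_dir, "rater_table_synthetic.csv"),
              row.names = FALSE)
  })
  emit("expert_ratings_synthetic.csv")
  emit("rater_table_synthetic.csv")

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
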