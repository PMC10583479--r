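#' Stratified cohort split
#'
#' Assigns each slide to train/validation/test, stratified by tumor type.
#' Within each type, per-split counts are `floor(ratio * n)` and any
#' remainder goes to the training split, which reproduces the canonical
#' 245/35/70 split of a 350-slide cohort (and 35/5/10 per type) exactly.
#'
#' @param slides List of `slide_record`s.
#' @param ratios Length-3 numeric `(train, validation, test)` summing to 1.
#' @param seed Integer seed controlling the within-type shuffle.
#' @return The slide list with `split` set on every record.
#' @export
split_cohort <- function(slides, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(slides) == 0) stop("empty slide list")
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  types <- vapply(slides, function(s) s$true_tumor_type, character(1))
  for (ty in unique(types)) {
    idx <- which(types == ty)
    n <- length(idx)
    n_val <- floor(ratios[2] * n)
    n_test <- floor(ratios[3] * n)
    n_train <- n - n_val - n_test  # floor(r1*n) + remainder
    ord <- with_seed(derive_seed(seed, paste0("split/", ty)),
                     sample.int(n))
    shuffled <- idx[ord]
    lab <- rep(c("train", "validation", "test"),
               times = c(n_train, n_val, n_test))
    for (k in seq_len(n)) slides[[shuffled[k]]]$split <- lab[k]
  }
  slides
}

#' Generate a synthetic cohort
#'
#' Generates `n_slides_per_type` slides for each of the 7 tumor types and
#' assigns train/validation/test splits via [split_cohort()]. Per-slide
#' seeds derive from `config$seed` and the slide id, so the cohort is
#' reproducible and independent of generation order.
#'
#' @param config A [cohort_config()].
#' @param scheme A [class_scheme()].
#' @return List of `slide_record`s (length `7 * n_slides_per_type`).
#' @export
generate_cohort <- function(config, scheme = class_scheme()) {
  types <- tumor_type_labels(scheme)
  slides <- vector("list", length(types) * config$n_slides_per_type)
  k <- 0L
  for (ty in types) {
    for (i in seq_len(config$n_slides_per_type)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", ty, i)
      slides[[k]] <- generate_slide_raster(
        config, ty, sid, derive_seed(config$seed, paste0("slide/", sid)),
        scheme = scheme)
    }
  }
  split_cohort(slides, config$split_ratios, config$seed)
}

#' Cohort manifest
#'
#' @param slides List of `slide_record`s.
#' @return data.frame with columns `slide_id`, `tumor_type`, `split`.
#' @export
cohort_manifest <- function(slides) {
  data.frame(
    slide_id = vapply(slides, function(s) s$slide_id, character(1)),
    tumor_type = vapply(slides, function(s) s$true_tumor_type, character(1)),
    split = vapply(slides, function(s) s$split, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Subset a cohort by split
#'
#' @param slides List of `slide_record`s.
#' @param split One of `"train"`, `"validation"`, `"test"`, `"none"`.
#' @return The matching sub-list.
#' @export
cohort_split <- function(slides, split) {
  Filter(function(s) s$split == split, slides)
}
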