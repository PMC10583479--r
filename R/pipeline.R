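#' Run configuration
#'
#' Bundles everything one end-to-end study run needs: the cohort
#' parameters, the classifier confusion process, the segmenter error
#' rates, the rater panel, and the master seed.
#'
#' @param cohort A [cohort_config()].
#' @param confusion A [confusion_spec()]; default
#'   [reference_confusion_spec()].
#' @param segmenter_error Named per-class segmentation error rates
#'   (default: none, i.e. a perfect segmenter).
#' @param raters List of [rater_model()]s; default
#'   [default_rater_panel()].
#' @param seed Master seed (mandatory; flows into every stochastic stage).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(seed = seed),
                       confusion = reference_confusion_spec(),
                       segmenter_error = numeric(0),
                       raters = default_rater_panel(),
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(confusion, "confusion_spec"))
  structure(list(cohort = cohort, confusion = confusion,
                 segmenter_error = segmenter_error, raters = raters,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' End-to-end simulated study
#'
#' Runs the complete analysis on a synthetic cohort: cohort generation,
#' slide inference (segmentation, full-tumor tiling, patch classification,
#' majority vote) on the test split, a simulated pathologist panel with
#' per-slide consensus, and the evaluation suite (slide- and patch-level
#' confusion matrices, metrics, accumulated decimal consensus, PCA
#' features, confidence-versus-portion table).
#'
#' @param config A [run_config()].
#' @param split Which cohort split to diagnose (default `"test"`).
#' @param patch_size,factor Inference geometry (see
#'   [run_slide_pipeline()]).
#' @param scheme A [class_scheme()].
#' @return A list: `manifest`, `diagnoses`, `slide_cm`, `slide_metrics`,
#'   `slide_accuracy`, `patch_cm`, `patch_metrics`, `patch_mean_diagonal`,
#'   `panel`, `consensus`, `consensus_cm`, `consensus_accuracy`,
#'   `decimal_consensus_by_type`, `confidence_vs_portion`, `pca_panel`,
#'   `pca_algorithm`, `n_no_tumor`.
#' @export
run_study <- function(config, split = "test", patch_size = 1024,
                      factor = 16, scheme = class_scheme()) {
  slides <- generate_cohort(config$cohort, scheme)
  eval_slides <- cohort_split(slides, split)
  if (length(eval_slides) == 0) stop("no slides in split '", split, "'")
  segmenter <- if (length(config$segmenter_error) == 0) NULL else {
    make_oracle_segmenter(config$segmenter_error,
                          derive_seed(config$seed, "segmenter"), scheme)
  }
  classifier <- make_oracle_classifier(
    config$confusion, derive_seed(config$seed, "classifier"))

  diagnoses <- run_cohort_pipeline(eval_slides, segmenter, classifier,
                                   patch_size, factor, scheme)
  truths <- stats::setNames(
    vapply(eval_slides, function(s) s$true_tumor_type, character(1)),
    vapply(eval_slides, function(s) s$slide_id, character(1)))

  ok <- !vapply(diagnoses, function(d) d$status == "no_tumor", logical(1))
  slide_cm <- slide_confusion_matrix(
    truths[ok], vapply(diagnoses[ok], function(d) d$primary, character(1)),
    tumor_type_labels(scheme))

  # patch-level: pool retained predictions over all slides
  preds <- do.call(rbind, lapply(diagnoses, attr, "predictions"))
  retained <- preds[preds$emitted_class != "nonneoplastic" &
                      preds$true_class != "nonneoplastic", , drop = FALSE]
  patch_cm <- patch_confusion_matrix(retained$true_class,
                                     retained$emitted_class,
                                     tumor_type_labels(scheme))

  panel <- generate_pathologist_panel(eval_slides, config$raters,
                                      derive_seed(config$seed, "panel"),
                                      scheme)
  consensus <- consensus_for_panel(panel, scheme)
  consensus_cm <- slide_confusion_matrix(
    truths[consensus$slide_id], consensus$primary, tumor_type_labels(scheme))
  dc_by_type <- vapply(split(consensus$decimal_consensus,
                             truths[consensus$slide_id]),
                       decimal_consensus_accumulate, numeric(1))

  list(
    manifest = cohort_manifest(slides),
    diagnoses = diagnoses,
    slide_cm = slide_cm,
    slide_metrics = precision_recall_f1(slide_cm, "conventional"),
    slide_accuracy = accuracy_from_matrix(slide_cm),
    patch_cm = patch_cm,
    patch_metrics = precision_recall_f1(patch_cm, "paper"),
    patch_mean_diagonal = mean_diagonal(patch_cm),
    panel = panel,
    consensus = consensus,
    consensus_cm = consensus_cm,
    consensus_accuracy = accuracy_from_matrix(consensus_cm),
    decimal_consensus_by_type = dc_by_type,
    confidence_vs_portion = confidence_vs_portion_table(
      panel, truths, patch_cm, scheme),
    pca_panel = pca_project(build_pca_features("panel", panel, scheme)),
    pca_algorithm = pca_project(
      build_pca_features("algorithm", diagnoses, scheme)),
    n_no_tumor = sum(!ok)
  )
}

#' Write study artifacts to a directory
#'
#' Persists the tabular artifacts of a [run_study()] result (manifest,
#' predictions, panel, consensus, metrics) plus a `report.json` with the
#' headline numbers and the run seed.
#'
#' @param result A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @param seed The seed the run used (recorded in the report).
#' @return `out_dir`, invisibly.
#' @export
write_study_artifacts <- function(result, out_dir, seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$manifest[c("slide_id", "tumor_type", "split")] |>
                transform(raster_path = NA_character_),
              file.path(out_dir, "manifest.tsv"), "manifest")
  preds <- do.call(rbind, lapply(result$diagnoses, attr, "predictions"))
  write_table(preds, file.path(out_dir, "predictions.tsv"), "predictions")
  write_table(result$panel, file.path(out_dir, "panel.tsv"), "panel")
  write_table(result$consensus, file.path(out_dir, "consensus.tsv"),
              "consensus")
  write_table(result$patch_metrics, file.path(out_dir, "patch_metrics.tsv"),
              "metrics")
  report <- list(
    seed = seed,
    slide_accuracy = result$slide_accuracy,
    consensus_accuracy = result$consensus_accuracy,
    patch_mean_diagonal = result$patch_mean_diagonal,
    decimal_consensus_by_type = as.list(result$decimal_consensus_by_type),
    n_no_tumor = result$n_no_tumor)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
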