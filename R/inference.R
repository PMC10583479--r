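#' Six-class segmentation view of a label raster
#'
#' Collapses fine annotation labels to the segmentation task's classes:
#' background, epidermis, dermis, subcutis, inflammation/necrosis (codes
#' 0--4 map to themselves) and a single `tumor` class covering all seven
#' tumor-type codes. Optional bone/cartilage codes are folded into
#' `subcutis` (they are not part of the six-class task). Unknown codes
#' raise an error.
#'
#' @param raster A [label_raster()].
#' @param scheme A [class_scheme()].
#' @return An object of class `segmentation_map`: `grid` (integer matrix of
#'   segmentation codes 0--5), `resolution_um_per_px`, `slide_id`.
#' @export
derive_segmentation_view <- function(raster, scheme = class_scheme()) {
  g <- raster$grid
  seg <- scheme$segmentation_classes
  valid <- c(scheme$fine_codes, scheme$optional_codes,
             seg)  # already-collapsed maps pass through unchanged
  bad <- setdiff(unique(as.vector(g)), unname(valid))
  if (length(bad) > 0) {
    stop("unknown fine label code(s): ", paste(bad, collapse = ", "))
  }
  out <- g
  out[g >= 10L] <- seg[["tumor"]]
  out[g %in% scheme$optional_codes] <- seg[["subcutis"]]
  structure(list(grid = out,
                 resolution_um_per_px = raster$resolution_um_per_px,
                 slide_id = raster$slide_id),
            class = "segmentation_map")
}

#' Tumor mask from a segmentation map
#'
#' @param segmap A `segmentation_map`.
#' @param scheme A [class_scheme()].
#' @return Logical matrix, `TRUE` exactly where the class is `tumor`.
#' @export
extract_tumor_mask <- function(segmap, scheme = class_scheme()) {
  segmap$grid == scheme$segmentation_classes[["tumor"]]
}

#' Upscale a mask by block replication
#'
#' Nearest-neighbor upscaling from the segmentation resolution (4 um/px)
#' toward the classification resolution (0.25 um/px at the default factor
#' of 16): each source pixel becomes a `factor x factor` block.
#'
#' @param mask Logical (or integer) matrix.
#' @param factor Positive integer scale factor.
#' @return Matrix with dimensions `dim(mask) * factor`.
#' @export
upscale_mask <- function(mask, factor = 16) {
  if (factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  mask[rep(seq_len(nrow(mask)), each = factor),
       rep(seq_len(ncol(mask)), each = factor), drop = FALSE]
}

# Sums over non-overlapping size x size blocks of a numeric/logical matrix
# (partial edge blocks discarded). Returns a (nrow %/% size) x (ncol %/% size)
# matrix. Used for the full-tumor tile check.
block_sums <- function(m, size) {
  nbr <- nrow(m) %/% size
  nbc <- ncol(m) %/% size
  if (nbr == 0 || nbc == 0) return(matrix(numeric(0), nbr, nbc))
  m <- m[seq_len(nbr * size), seq_len(nbc * size), drop = FALSE]
  # collapse rows, then columns
  rs <- rowsum(m * 1, rep(seq_len(nbr), each = size))
  t(rowsum(t(rs), rep(seq_len(nbc), each = size)))
}

# Shared tiling core: grid origin (0,0), stride = patch size, partial edge
# tiles discarded; a tile is kept only if every pixel is TRUE.
tile_patch_frame <- function(full, patch_size, slide_id, resolution) {
  keep <- which(full, arr.ind = TRUE)
  data.frame(
    slide_id = rep(slide_id, nrow(keep)),
    row0 = (keep[, 1] - 1L) * patch_size,
    col0 = (keep[, 2] - 1L) * patch_size,
    size_px = rep(as.integer(patch_size), nrow(keep)),
    resolution_um_per_px = rep(resolution, nrow(keep)),
    stringsAsFactors = FALSE)
}

#' Tile a high-resolution mask into fully-tumor patches
#'
#' Divides a high-resolution tumor mask into non-overlapping
#' `patch_size x patch_size` tiles (grid origin `(0,0)`, stride
#' `patch_size`, partial edge tiles discarded) and keeps only tiles that
#' are 100% tumor -- the full-tumor rule gating which patches reach the
#' classifier.
#'
#' @param mask_hires Logical matrix at the classification resolution.
#' @param patch_size Tile side length in high-resolution pixels.
#' @param slide_id Identifier attached to the returned patches.
#' @param resolution_um_per_px Resolution recorded on the patches.
#' @return data.frame of patches: `slide_id`, `row0`, `col0` (0-based,
#'   high-resolution coordinates), `size_px`, `resolution_um_per_px`.
#'   Zero rows when no tile qualifies.
#' @export
tile_fully_tumor_patches <- function(mask_hires, patch_size = 1024,
                                     slide_id = "slide",
                                     resolution_um_per_px = 0.25) {
  bs <- block_sums(mask_hires, patch_size)
  tile_patch_frame(bs == patch_size^2, patch_size, slide_id,
                   resolution_um_per_px)
}

#' Tile a segmentation-resolution mask into fully-tumor patches
#'
#' Equivalent to upscaling the mask by `factor` and calling
#' [tile_fully_tumor_patches()] with `patch_size`, but computed directly on
#' the low-resolution mask by checking `patch_size / factor` blocks --
#' identical output (tested property) at a fraction of the memory.
#' Returned coordinates are high-resolution.
#'
#' @param mask_lowres Logical mask at the segmentation resolution.
#' @param patch_size Tile side at the high resolution (default 1024).
#' @param factor Upscale factor between the two resolutions (default 16).
#' @param slide_id,resolution_um_per_px Metadata for the returned patches;
#'   `resolution_um_per_px` is the high-resolution value.
#' @return As [tile_fully_tumor_patches()].
#' @export
tile_full_tumor_blocks <- function(mask_lowres, patch_size = 1024,
                                   factor = 16, slide_id = "slide",
                                   resolution_um_per_px = 0.25) {
  if (patch_size %% factor != 0) {
    stop("patch_size must be a multiple of factor")
  }
  block <- patch_size %/% factor
  bs <- block_sums(mask_lowres, block)
  tile_patch_frame(bs == block^2, patch_size, slide_id,
                   resolution_um_per_px)
}

# True classifier-level class under a patch: the dominant fine label within
# the patch footprint on the annotation raster, mapped to a tumor-type
# label or "nonneoplastic". Patch coordinates are high-resolution; `factor`
# converts them to the raster's grid.
patch_true_class <- function(patch_row0, patch_col0, patch_size, raster,
                             factor = 16, scheme = class_scheme()) {
  r0 <- patch_row0 %/% factor
  c0 <- patch_col0 %/% factor
  size <- patch_size %/% factor
  name <- dominant_class(raster$grid, r0, c0, size)
  if (name %in% names(scheme$tumor_types)) name else "nonneoplastic"
}

#' Classify tiled patches with a classifier contract
#'
#' Looks up each patch's true class (dominant fine annotation under its
#' footprint, mapped to a tumor type or `nonneoplastic`) and feeds it to
#' the classifier. Order is preserved; classifier errors are re-raised
#' with the offending patch's coordinates.
#'
#' @param patches data.frame as returned by the tiling functions
#'   (high-resolution coordinates).
#' @param classifier An `oracle_classifier` (or any object accepted by
#'   [classify_true_classes()]).
#' @param raster The slide's [label_raster()] (ground truth annotations).
#' @param factor Resolution factor between patch and raster coordinates.
#' @param scheme A [class_scheme()].
#' @return The `patches` data.frame with `true_class` and `emitted_class`
#'   columns appended.
#' @export
classify_patches <- function(patches, classifier, raster, factor = 16,
                             scheme = class_scheme()) {
  if (nrow(patches) == 0) {
    patches$true_class <- character(0)
    patches$emitted_class <- character(0)
    return(patches)
  }
  truths <- vapply(seq_len(nrow(patches)), function(i) {
    patch_true_class(patches$row0[i], patches$col0[i], patches$size_px[i],
                     raster, factor, scheme)
  }, character(1))
  emitted <- tryCatch(
    classify_true_classes(classifier, truths),
    error = function(e) {
      stop("classifier failed on patches of slide ", raster$slide_id,
           " (first patch at row0=", patches$row0[1], ", col0=",
           patches$col0[1], "): ", conditionMessage(e), call. = FALSE)
    })
  patches$true_class <- truths
  patches$emitted_class <- emitted
  patches
}

#' Majority-vote slide diagnosis from patch predictions
#'
#' Patches classified `nonneoplastic` are excluded and counted; the
#' remaining tumor-type counts are ranked in decreasing order (ties broken
#' by canonical tumor-type order with `tie_flag` set). The top class is the
#' primary diagnosis and the next two are the differentials. Fractions are
#' reported relative to retained (post-exclusion) patches. When every
#' patch is nonneoplastic (or there are no patches at all) the outcome has
#' status `"no_tumor"` rather than an error, so cohort-level evaluation
#' can count such slides.
#'
#' @param predictions data.frame with an `emitted_class` column (as from
#'   [classify_patches()]); may also carry `slide_id`.
#' @param slide_id Identifier (defaults to the predictions' slide id).
#' @param scheme A [class_scheme()].
#' @return An object of class `slide_diagnosis`: `slide_id`, `status`
#'   (`"ok"` or `"no_tumor"`), `ranked` (data.frame `tumor_type`,
#'   `patch_count`, `fraction`), `primary`, `differential1`,
#'   `differential2`, `n_patches_total`, `n_patches_excluded_nonneoplastic`,
#'   `tie_flag`.
#' @export
aggregate_slide_diagnosis <- function(predictions, slide_id = NULL,
                                      scheme = class_scheme()) {
  if (is.null(slide_id)) {
    slide_id <- if (nrow(predictions) > 0 && "slide_id" %in% names(predictions)) {
      predictions$slide_id[1]
    } else "slide"
  }
  emitted <- predictions$emitted_class
  bad <- setdiff(unique(emitted), scheme$classifier_classes)
  if (length(bad) > 0) {
    stop("emitted class outside classifier classes: ",
         paste(bad, collapse = ", "))
  }
  n_total <- length(emitted)
  n_excl <- sum(emitted == "nonneoplastic")
  retained <- emitted[emitted != "nonneoplastic"]
  if (length(retained) == 0) {
    return(structure(
      list(slide_id = slide_id, status = "no_tumor",
           ranked = data.frame(tumor_type = character(0),
                               patch_count = integer(0),
                               fraction = numeric(0)),
           primary = NA_character_, differential1 = NA_character_,
           differential2 = NA_character_, n_patches_total = n_total,
           n_patches_excluded_nonneoplastic = n_excl, tie_flag = FALSE),
      class = "slide_diagnosis"))
  }
  types <- tumor_type_labels(scheme)
  counts <- vapply(types, function(t) sum(retained == t), integer(1))
  counts <- counts[counts > 0]
  ord <- order(-counts, match(names(counts), types))
  ranked <- data.frame(
    tumor_type = names(counts)[ord],
    patch_count = unname(counts[ord]),
    fraction = unname(counts[ord]) / length(retained),
    stringsAsFactors = FALSE)
  tie <- length(counts) > 1 && sum(counts == max(counts)) > 1
  structure(
    list(slide_id = slide_id, status = "ok", ranked = ranked,
         primary = ranked$tumor_type[1],
         differential1 = if (nrow(ranked) >= 2) ranked$tumor_type[2] else NA_character_,
         differential2 = if (nrow(ranked) >= 3) ranked$tumor_type[3] else NA_character_,
         n_patches_total = n_total,
         n_patches_excluded_nonneoplastic = n_excl,
         tie_flag = tie),
    class = "slide_diagnosis")
}

#' @export
print.slide_diagnosis <- function(x, ...) {
  if (x$status == "no_tumor") {
    cat(sprintf("<slide_diagnosis> %s: no tumor diagnosis (%d patches, %d nonneoplastic)\n",
                x$slide_id, x$n_patches_total,
                x$n_patches_excluded_nonneoplastic))
  } else {
    cat(sprintf("<slide_diagnosis> %s: %s%s\n", x$slide_id, x$primary,
                if (x$tie_flag) " (tie broken by class order)" else ""))
    print(utils::head(x$ranked, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Full slide-inference pipeline
#'
#' Composes the whole-slide diagnosis chain on one slide: segmentation
#' (via the segmenter contract), tumor-mask extraction, full-tumor tiling
#' at the classification resolution (computed block-wise on the
#' segmentation grid; identical to upscale-then-tile), patch
#' classification, non-neoplastic exclusion, and majority voting.
#'
#' @param record A `slide_record`.
#' @param segmenter An `oracle_segmenter` (or `NULL` for a perfect
#'   segmenter, i.e. the ground-truth view).
#' @param classifier An `oracle_classifier`.
#' @param patch_size Classification patch side in high-resolution pixels.
#' @param factor Upscale factor between segmentation and classification
#'   resolutions.
#' @param scheme A [class_scheme()].
#' @return A `slide_diagnosis` (status `"no_tumor"` when no full-tumor
#'   tile exists), with the patch predictions attached as attribute
#'   `"predictions"`.
#' @export
run_slide_pipeline <- function(record, segmenter, classifier,
                               patch_size = 1024, factor = 16,
                               scheme = class_scheme()) {
  segmap <- if (is.null(segmenter)) {
    derive_segmentation_view(record$raster, scheme)
  } else {
    segment_raster(segmenter, record$raster)
  }
  mask <- extract_tumor_mask(segmap, scheme)
  patches <- tile_full_tumor_blocks(
    mask, patch_size, factor, slide_id = record$slide_id,
    resolution_um_per_px = record$raster$resolution_um_per_px / factor)
  preds <- classify_patches(patches, classifier, record$raster, factor,
                            scheme)
  dx <- aggregate_slide_diagnosis(preds, slide_id = record$slide_id,
                                  scheme = scheme)
  attr(dx, "predictions") <- preds
  dx
}

#' Run the pipeline over a cohort
#'
#' @param slides List of `slide_record`s.
#' @param segmenter,classifier,patch_size,factor,scheme As in
#'   [run_slide_pipeline()].
#' @return Named list of `slide_diagnosis` objects (by slide id).
#' @export
run_cohort_pipeline <- function(slides, segmenter, classifier,
                                patch_size = 1024, factor = 16,
                                scheme = class_scheme()) {
  out <- lapply(slides, run_slide_pipeline, segmenter = segmenter,
                classifier = classifier, patch_size = patch_size,
                factor = factor, scheme = scheme)
  names(out) <- vapply(slides, function(s) s$slide_id, character(1))
  out
}
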