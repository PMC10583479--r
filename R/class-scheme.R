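#' Tissue and tumor class scheme
#'
#' The fixed label scheme used throughout the pipeline. Slides are annotated
#' with *fine* labels: five non-tumor tissue classes (codes 0--4) and seven
#' tumor types (codes 10--16). The segmentation stage works on a coarser
#' six-class view in which every tumor type collapses to a single `tumor`
#' class; the patch classifier emits one of the seven tumor types or an
#' eighth `nonneoplastic` class.
#'
#' Bone and cartilage occur in real annotation schemes for skin but are not
#' part of the six-class segmentation task; they carry optional fine codes
#' (7, 8) and are folded into `subcutis` by [derive_segmentation_view()].
#'
#' @return An object of class `class_scheme`: a list with
#'   `segmentation_classes` (named integer codes 0--5),
#'   `tumor_types` (named integer fine codes 10--16, canonical order),
#'   `classifier_classes` (character: the 7 tumor types plus
#'   `"nonneoplastic"`), `fine_codes` (all valid fine codes, named),
#'   and `optional_codes` (bone, cartilage).
#' @examples
#' sc <- class_scheme()
#' sc$tumor_types
#' @export
class_scheme <- function() {
  segmentation_classes <- c(
    background = 0L, epidermis = 1L, dermis = 2L, subcutis = 3L,
    inflammation_necrosis = 4L, tumor = 5L
  )
  tumor_types <- c(
    trichoblastoma = 10L, SCC = 11L, PNST = 12L, melanoma = 13L,
    histiocytoma = 14L, MCT = 15L, plasmacytoma = 16L
  )
  optional_codes <- c(bone = 7L, cartilage = 8L)
  fine_codes <- c(segmentation_classes[1:5], tumor_types)
  structure(
    list(
      segmentation_classes = segmentation_classes,
      tumor_types = tumor_types,
      classifier_classes = c(names(tumor_types), "nonneoplastic"),
      fine_codes = fine_codes,
      optional_codes = optional_codes
    ),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme>\n")
  cat("  segmentation:", paste(names(x$segmentation_classes), collapse = ", "), "\n")
  cat("  tumor types :", paste(names(x$tumor_types), collapse = ", "), "\n")
  cat("  classifier  :", paste(x$classifier_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical tumor-type labels
#'
#' @param scheme A [class_scheme()].
#' @return Character vector of the 7 tumor-type labels in canonical order,
#'   used for deterministic tie-breaking.
#' @export
tumor_type_labels <- function(scheme = class_scheme()) {
  names(scheme$tumor_types)
}

# fine code -> class name (character), errors on unknown codes
fine_code_to_name <- function(codes, scheme = class_scheme(),
                              allow_optional = TRUE) {
  valid <- scheme$fine_codes
  if (allow_optional) valid <- c(valid, scheme$optional_codes)
  idx <- match(codes, valid)
  if (anyNA(idx)) {
    stop("unknown fine label code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  }
  names(valid)[idx]
}

# tumor type name -> fine code
tumor_type_code <- function(type, scheme = class_scheme()) {
  code <- scheme$tumor_types[type]
  if (anyNA(code)) stop("unknown tumor type: ", paste(type[is.na(code)], collapse = ", "))
  unname(code)
}
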