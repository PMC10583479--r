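#' Patch-classifier confusion specification
#'
#' Defines the error structure of a stochastic patch classifier: a
#' column-stochastic matrix (columns indexed by true class, rows by emitted
#' class) plus a probability that any tumor patch is emitted as
#' `nonneoplastic` before the confusion draw.
#'
#' @param labels Character vector of class labels (rows and columns).
#' @param column_stochastic_matrix Square numeric matrix; each column must
#'   sum to 1 within 1e-9 and all entries must be nonnegative.
#' @param nonneoplastic_rate Probability in `[0, 1)` of emitting
#'   `"nonneoplastic"` regardless of the confusion column.
#' @return An object of class `confusion_spec`.
#' @seealso [reference_confusion_spec()] for the bundled benchmark values.
#' @export
confusion_spec <- function(labels, column_stochastic_matrix,
                           nonneoplastic_rate = 0) {
  m <- as.matrix(column_stochastic_matrix)
  if (nrow(m) != ncol(m) || nrow(m) != length(labels)) {
    stop("matrix must be square with one row/column per label")
  }
  if (any(m < 0)) stop("confusion entries must be nonnegative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("each column must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  if (nonneoplastic_rate < 0 || nonneoplastic_rate >= 1) {
    stop("nonneoplastic_rate must lie in [0, 1)")
  }
  dimnames(m) <- list(emitted = labels, true = labels)
  structure(list(labels = labels, matrix = m,
                 nonneoplastic_rate = nonneoplastic_rate),
            class = "confusion_spec")
}

#' Stochastic patch-classifier oracle
#'
#' Stands in for a trained patch classification network. Each call takes
#' the true class of a patch and emits a class label: with probability
#' `nonneoplastic_rate` the label is `"nonneoplastic"`, otherwise it is
#' drawn from the confusion column of the true class. Draws are i.i.d.
#' on a private RNG stream, so calling the oracle does not disturb the
#' caller's RNG state and repeated runs from the same seed are identical.
#'
#' @param spec A [confusion_spec()].
#' @param seed Integer seed for the oracle's private stream.
#' @return An object of class `oracle_classifier`; call
#'   `classify_true_classes(oracle, true_classes)` or use it with
#'   [classify_patches()].
#' @examples
#' sp <- confusion_spec(c("a", "b"), diag(2))
#' oc <- make_oracle_classifier(sp, seed = 1)
#' classify_true_classes(oc, c("a", "b", "a"))
#' @export
make_oracle_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "confusion_spec"))
  structure(list(spec = spec, stream = new_rng_stream(seed)),
            class = "oracle_classifier")
}

#' Draw emitted classes from a classifier oracle
#'
#' @param oracle An `oracle_classifier`.
#' @param true_classes Character vector of true class labels; every label
#'   must be one of the spec's labels.
#' @return Character vector of emitted class labels, one per input.
#' @export
classify_true_classes <- function(oracle, true_classes) {
  spec <- oracle$spec
  bad <- setdiff(unique(true_classes), spec$labels)
  if (length(bad) > 0) {
    stop("true class not in confusion spec labels: ",
         paste(bad, collapse = ", "))
  }
  n <- length(true_classes)
  if (n == 0) return(character(0))
  stream_eval(oracle$stream, {
    out <- character(n)
    is_nn <- if (spec$nonneoplastic_rate > 0) {
      stats::runif(n) < spec$nonneoplastic_rate
    } else rep(FALSE, n)
    out[is_nn] <- "nonneoplastic"
    todo <- which(!is_nn)
    # one multinomial stream per true class keeps draws vectorized;
    # the grouping is deterministic for a given input vector
    for (tc in unique(true_classes[todo])) {
      idx <- todo[true_classes[todo] == tc]
      out[idx] <- sample(spec$labels, length(idx), replace = TRUE,
                         prob = spec$matrix[, tc])
    }
    out
  })
}

#' Stochastic segmenter oracle
#'
#' Stands in for a trained semantic segmentation network. Returns the
#' ground-truth six-class view of a label raster with each pixel
#' independently corrupted: a pixel of class `c` is replaced by a uniformly
#' random *other* segmentation class with probability `per_class_error[c]`.
#'
#' @param per_class_error Named numeric vector of error probabilities in
#'   `[0, 1]`, names drawn from the segmentation classes; classes not named
#'   default to 0.
#' @param seed Integer seed for the private stream.
#' @param scheme A [class_scheme()].
#' @return An object of class `oracle_segmenter`; apply it with
#'   [segment_raster()].
#' @export
make_oracle_segmenter <- function(per_class_error = numeric(0), seed = 1L,
                                  scheme = class_scheme()) {
  seg <- scheme$segmentation_classes
  err <- stats::setNames(rep(0, length(seg)), names(seg))
  if (length(per_class_error) > 0) {
    bad <- setdiff(names(per_class_error), names(seg))
    if (length(bad) > 0) stop("unknown segmentation class: ",
                              paste(bad, collapse = ", "))
    if (any(per_class_error < 0 | per_class_error > 1)) {
      stop("error rates must lie in [0, 1]")
    }
    err[names(per_class_error)] <- per_class_error
  }
  structure(list(per_class_error = err, stream = new_rng_stream(seed),
                 scheme = scheme),
            class = "oracle_segmenter")
}

#' Apply a segmenter oracle to a label raster
#'
#' @param segmenter An `oracle_segmenter`.
#' @param raster A [label_raster()].
#' @return A `segmentation_map` (see [derive_segmentation_view()]) with
#'   per-pixel corruption applied.
#' @export
segment_raster <- function(segmenter, raster) {
  view <- derive_segmentation_view(raster, scheme = segmenter$scheme)
  seg <- segmenter$scheme$segmentation_classes
  err <- segmenter$per_class_error
  if (all(err == 0)) return(view)
  g <- view$grid
  stream_eval(segmenter$stream, {
    for (cls in names(seg)) {
      e <- err[[cls]]
      if (e == 0) next
      idx <- which(g == seg[[cls]])
      if (length(idx) == 0) next
      flip <- idx[stats::runif(length(idx)) < e]
      if (length(flip) == 0) next
      others <- unname(seg[names(seg) != cls])
      g[flip] <- others[sample.int(length(others), length(flip),
                                   replace = TRUE)]
    }
  })
  view$grid <- g
  view
}
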