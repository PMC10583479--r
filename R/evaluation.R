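#' Labeled confusion matrix
#'
#' A square matrix of counts or column-normalized fractions with explicit
#' orientation metadata, so "rows = truth" (slide-level count tables) and
#' "rows = predicted, columns = truth" (patch-level fraction tables) are
#' never confused.
#'
#' @param cells Square numeric matrix.
#' @param labels Class labels (rows and columns).
#' @param orientation `"rows=truth"` or `"rows=predicted"`.
#' @param normalization `"counts"` or `"column_fractions"`.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(cells, labels,
                             orientation = c("rows=truth", "rows=predicted"),
                             normalization = c("counts", "column_fractions")) {
  orientation <- match.arg(orientation)
  normalization <- match.arg(normalization)
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells) || nrow(cells) != length(labels)) {
    stop("cells must be square with one row/column per label")
  }
  if (any(cells < 0, na.rm = TRUE)) stop("cells must be nonnegative")
  if (normalization == "counts") {
    if (any(abs(cells - round(cells)) > 1e-9, na.rm = TRUE)) {
      stop("count matrix must hold integers")
    }
  } else {
    cs <- colSums(cells)
    ok <- is.na(cs) | abs(cs - 1) <= 0.05  # 2-dp tables round; cells <0.01 print as 0
    if (!all(ok)) {
      stop("column fractions must sum to ~1 (worst column: ",
           format(max(abs(cs - 1), na.rm = TRUE)), ")")
    }
  }
  dimnames(cells) <- list(labels, labels)
  structure(list(cells = cells, labels = labels, orientation = orientation,
                 normalization = normalization),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s, %s\n", x$orientation, x$normalization))
  print(round(x$cells, 3))
  invisible(x)
}

#' Slide-level confusion matrix (counts, rows = truth)
#'
#' @param truths,predictions Equal-length character vectors of true and
#'   predicted labels per slide.
#' @param labels Class labels; defaults to the tumor types.
#' @return A `confusion_matrix` with `cells[i, j]` = number of slides of
#'   true class `i` predicted as class `j`.
#' @export
slide_confusion_matrix <- function(truths, predictions,
                                   labels = tumor_type_labels()) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions must have equal length")
  }
  bad <- setdiff(unique(c(truths, predictions)), labels)
  if (length(bad) > 0) stop("label outside scheme: ", paste(bad, collapse = ", "))
  tab <- table(factor(truths, levels = labels),
               factor(predictions, levels = labels))
  confusion_matrix(unclass(tab), labels, "rows=truth", "counts")
}

#' Patch-level confusion matrix (column fractions, rows = predicted)
#'
#' Cross-tabulates patch truths against predictions and normalizes each
#' column by its truth-class total, matching the orientation of the
#' reported patch table: columns indexed by ground truth, each summing
#' to 1; the diagonal is the fraction of each truth class predicted
#' correctly. Truth classes with zero patches yield `NA` columns with a
#' warning.
#'
#' @param truths,predictions Equal-length character vectors per patch
#'   (nonneoplastic predictions are expected to be excluded upstream).
#' @param labels Class labels; defaults to the tumor types.
#' @return A `confusion_matrix` (`column_fractions`, `rows=predicted`).
#' @export
patch_confusion_matrix <- function(truths, predictions,
                                   labels = tumor_type_labels()) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions must have equal length")
  }
  bad <- setdiff(unique(c(truths, predictions)), labels)
  if (length(bad) > 0) stop("label outside scheme: ", paste(bad, collapse = ", "))
  counts <- unclass(table(factor(predictions, levels = labels),
                          factor(truths, levels = labels)))
  tot <- colSums(counts)
  frac <- sweep(counts, 2, tot, "/")
  if (any(tot == 0)) {
    warning("truth class(es) with zero patches: ",
            paste(labels[tot == 0], collapse = ", "))
    frac[, tot == 0] <- NA_real_
  }
  confusion_matrix(frac, labels, "rows=predicted", "column_fractions")
}

# Harmonic mean, NA-propagating, 0 when both inputs are 0.
harmonic_mean <- function(p, r) {
  ifelse(is.na(p) | is.na(r), NA_real_,
         ifelse(p + r == 0, 0, 2 * p * r / (p + r)))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Two conventions are supported. `"conventional"` applies to count
#' matrices: `precision = TP / predicted total`, `recall = TP / truth
#' total` (orientation handled via the matrix metadata). `"paper"` applies
#' to column-normalized patch tables in rows = predicted orientation and
#' reproduces how the reported table's derived rows are computed: the
#' "precision" row is the column-normalized diagonal itself, and the
#' "recall" row is each diagonal entry divided by its *row* sum. Note the
#' printed labels of such tables are swapped relative to convention: the
#' column-normalized diagonal is conventionally a recall. Both variants
#' report `f1` as the harmonic mean of the paired values; division by zero
#' yields `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @param convention `"conventional"` or `"paper"`.
#' @return data.frame: `class`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm, convention = c("conventional", "paper")) {
  convention <- match.arg(convention)
  m <- cm$cells
  if (convention == "conventional") {
    if (cm$normalization != "counts") {
      stop("conventional metrics require a counts matrix")
    }
    if (cm$orientation == "rows=predicted") m <- t(m)
    tp <- diag(m)
    truth_tot <- rowSums(m)
    pred_tot <- colSums(m)
    precision <- ifelse(pred_tot == 0, NA_real_, tp / pred_tot)
    recall <- ifelse(truth_tot == 0, NA_real_, tp / truth_tot)
  } else {
    if (cm$normalization != "column_fractions" ||
        cm$orientation != "rows=predicted") {
      stop("'paper' convention requires a column-fraction matrix with rows=predicted")
    }
    precision <- diag(m)
    row_tot <- rowSums(m, na.rm = TRUE)
    recall <- ifelse(row_tot == 0, NA_real_, diag(m) / row_tot)
  }
  data.frame(class = cm$labels,
             precision = unname(precision),
             recall = unname(recall),
             f1 = unname(harmonic_mean(precision, recall)),
             stringsAsFactors = FALSE)
}

#' Overall accuracy from a count matrix
#'
#' @param cm A `confusion_matrix` with `normalization = "counts"`.
#' @return `trace / total`: the fraction of correctly classified items.
#' @export
accuracy_from_matrix <- function(cm) {
  if (cm$normalization != "counts") stop("accuracy requires a counts matrix")
  tot <- sum(cm$cells)
  if (tot == 0) stop("empty matrix")
  sum(diag(cm$cells)) / tot
}

#' Mean diagonal of a column-fraction matrix
#'
#' The unweighted mean over truth classes of the fraction correctly
#' predicted -- the "average over all tumor classes" summary of a
#' column-normalized patch table. Undefined (NA) columns are excluded with
#' a warning.
#'
#' @param cm A `confusion_matrix` with `normalization = "column_fractions"`.
#' @return Mean of the defined diagonal entries.
#' @export
mean_diagonal <- function(cm) {
  if (cm$normalization != "column_fractions") {
    stop("mean_diagonal requires a column-fraction matrix")
  }
  d <- diag(cm$cells)
  if (anyNA(d)) {
    warning("excluding ", sum(is.na(d)), " undefined column(s)")
    d <- d[!is.na(d)]
  }
  mean(d)
}

#' Per-slide feature matrices for PCA
#'
#' Builds the slides x tumor-types feature matrix underlying the biplot
#' analyses. For `source = "panel"`, the feature of (slide, type) is the
#' mean over raters of the confidence each rater assigned to that type
#' (0 when the type is not among a rater's three diagnoses); each row sums
#' to 1. For `source = "algorithm"`, it is the retained-patch fraction of
#' each of the slide's top-3 ranked classes (0 elsewhere); rows sum to at
#' most 1, with equality when at most 3 classes received patches.
#'
#' @param source `"panel"` or `"algorithm"`.
#' @param data For `"panel"`: a panel data.frame (see
#'   [generate_pathologist_panel()]). For `"algorithm"`: a list of
#'   `slide_diagnosis` objects.
#' @param scheme A [class_scheme()].
#' @return Numeric matrix, rows named by slide id, columns by tumor type.
#' @export
build_pca_features <- function(source = c("panel", "algorithm"), data,
                               scheme = class_scheme()) {
  source <- match.arg(source)
  types <- tumor_type_labels(scheme)
  if (source == "panel") {
    slide_ids <- unique(data$slide_id)
    feats <- matrix(0, length(slide_ids), length(types),
                    dimnames = list(slide_ids, types))
    for (sid in slide_ids) {
      df <- data[data$slide_id == sid, , drop = FALSE]
      acc <- stats::setNames(rep(0, length(types)), types)
      for (i in seq_len(nrow(df))) {
        for (k in 1:3) {
          dx <- df[[paste0("dx", k)]][i]
          acc[dx] <- acc[dx] + df[[paste0("conf", k)]][i]
        }
      }
      feats[sid, ] <- acc / nrow(df)
    }
  } else {
    diags <- data
    slide_ids <- vapply(diags, function(d) d$slide_id, character(1))
    feats <- matrix(0, length(diags), length(types),
                    dimnames = list(slide_ids, types))
    for (i in seq_along(diags)) {
      r <- diags[[i]]$ranked
      top <- utils::head(r, 3)
      feats[i, top$tumor_type] <- top$fraction
    }
  }
  feats
}

#' Principal component projection of a feature matrix
#'
#' Column-centers the features (optionally standardizing), decomposes them
#' into principal components, and fixes each component's sign so its
#' largest-magnitude loading is positive. A zero-variance matrix yields
#' all-zero scores with a warning.
#'
#' @param features Numeric matrix (slides x classes), >= 2 rows.
#' @param n_components Number of components to retain in `scores` and
#'   `loadings`.
#' @param standardize Scale columns to unit variance first (default FALSE:
#'   confidences and fractions already share a scale).
#' @return Object of class `pca_result`: `scores` (n x k, zero column
#'   means), `loadings` (p x k), `explained_variance` (fractions over all
#'   components, summing to 1), `center`.
#' @export
pca_project <- function(features, n_components = 2, standardize = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 rows")
  vars <- apply(features, 2, stats::var)
  if (all(vars < 1e-30)) {
    warning("zero-variance feature matrix; scores are all zero")
    k <- min(n_components, ncol(features))
    return(structure(
      list(scores = matrix(0, nrow(features), k),
           loadings = matrix(0, ncol(features), k,
                             dimnames = list(colnames(features), NULL)),
           explained_variance = rep(NA_real_, ncol(features)),
           center = colMeans(features)),
      class = "pca_result"))
  }
  if (standardize && any(vars < 1e-30)) {
    stop("cannot standardize zero-variance columns")
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = standardize)
  k <- min(n_components, ncol(pc$rotation))
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         explained_variance = ev / sum(ev),
         center = pc$center),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$scores), "scores,",
      ncol(x$scores), "component(s);",
      "explained:", paste0(round(100 * x$explained_variance[seq_len(
        min(3, length(x$explained_variance)))], 1), "%", collapse = ", "),
      "...\n")
  invisible(x)
}

#' Pathologist confidence versus correct-patch portion
#'
#' Per tumor type: the mean confidence that raters placed on their primary
#' diagnosis *when that primary was correct*, next to the algorithm's
#' fraction of correctly classified patches for that type (the patch
#' matrix diagonal). Types with no correct primaries get `NA` confidence.
#'
#' @param panel Panel data.frame (see [generate_pathologist_panel()]).
#' @param slide_truths Named character vector: true tumor type per slide id.
#' @param patch_cm A `confusion_matrix` of column fractions
#'   (rows = predicted).
#' @param scheme A [class_scheme()].
#' @return data.frame: `tumor_type`, `mean_confidence`, `patch_portion`.
#' @export
confidence_vs_portion_table <- function(panel, slide_truths, patch_cm,
                                        scheme = class_scheme()) {
  if (patch_cm$normalization != "column_fractions") {
    stop("patch_cm must hold column fractions")
  }
  types <- tumor_type_labels(scheme)
  if (!all(types %in% patch_cm$labels)) {
    stop("patch matrix must cover every tumor type")
  }
  truth <- slide_truths[panel$slide_id]
  correct <- panel$dx1 == truth
  conf <- vapply(types, function(t) {
    sel <- correct & truth == t
    if (!any(sel)) return(NA_real_)
    mean(panel$conf1[sel])
  }, numeric(1))
  data.frame(tumor_type = types,
             mean_confidence = unname(conf),
             patch_portion = unname(diag(patch_cm$cells)[types]),
             stringsAsFactors = FALSE)
}
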