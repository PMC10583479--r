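test_that("slide confusion matrix counts truth-by-prediction pairs", {
  types <- tumor_type_labels()
  # perfect predictions on 20 per type -> 20 * identity
  truths <- rep(types, each = 20)
  cm <- slide_confusion_matrix(truths, truths)
  expect_equal(unname(diag(cm$cells)), rep(20, 7))
  expect_equal(sum(cm$cells) - sum(diag(cm$cells)), 0)
  expect_equal(accuracy_from_matrix(cm), 1.0)
  # reference table round trip through paired lists
  ref <- reference_slide_confusion("algorithm")
  pairs <- slidedx:::matrix_to_pairs(ref)
  cm2 <- slide_confusion_matrix(pairs$truths, pairs$predictions, ref$labels)
  expect_equal(unname(cm2$cells), unname(ref$cells))
  expect_equal(sum(diag(cm2$cells)), 133)
  expect_equal(unname(rowSums(cm2$cells)), rep(20, 7))
  expect_error(slide_confusion_matrix("melanoma", "lipoma"), "outside")
  expect_error(slide_confusion_matrix(c("MCT", "SCC"), "MCT"), "equal length")
})

test_that("patch confusion matrix is column-normalized with rows=predicted", {
  types <- tumor_type_labels()
  # identity predictions -> identity matrix
  truths <- rep(types, each = 10)
  cm <- patch_confusion_matrix(truths, truths)
  expect_equal(unname(cm$cells), diag(7))
  expect_equal(cm$orientation, "rows=predicted")
  # column sums exactly 1 before rounding
  set.seed(3)
  preds <- sample(types, length(truths), replace = TRUE)
  cm2 <- patch_confusion_matrix(truths, preds)
  expect_equal(unname(colSums(cm2$cells)), rep(1, 7))
  # cell[i, j] = fraction of truth-j patches emitted as i
  expect_equal(cm2$cells["MCT", "SCC"],
               mean(preds[truths == "SCC"] == "MCT"))
  # zero-patch truth class yields an NA column with warning
  expect_warning(
    cm3 <- patch_confusion_matrix(rep("MCT", 5), rep("MCT", 5)),
    "zero patches")
  expect_true(all(is.na(cm3$cells[, "SCC"])))
  expect_equal(cm3$cells["MCT", "MCT"], 1)
})

test_that("generative recovery: oracle emissions reproduce the confusion columns", {
  sp <- reference_confusion_spec()
  oc <- make_oracle_classifier(sp, seed = 202)
  n <- 4000
  truths <- rep(sp$labels, each = n)
  emitted <- classify_true_classes(oc, truths)
  cm <- patch_confusion_matrix(truths, emitted, sp$labels)
  # simultaneous check over 49 cells: critical value 4 bounds the
  # family-wise false-alarm rate at ~0.3%
  for (tc in sp$labels) {
    p <- sp$matrix[, tc]
    sd4 <- 4 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(cm$cells[, tc] - p) <= pmax(sd4, 1e-12)),
                info = paste("column", tc))
  }
})

test_that("conventional metrics follow TP / predicted and TP / truth", {
  cells <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)  # rows = truth
  cm <- confusion_matrix(cells, c("A", "B"), "rows=truth", "counts")
  m <- precision_recall_f1(cm, "conventional")
  expect_equal(m$precision, c(8 / 9, 9 / 11))
  expect_equal(m$recall, c(8 / 10, 9 / 10))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # orientation metadata handled: transposed matrix gives identical metrics
  cmT <- confusion_matrix(t(cells), c("A", "B"), "rows=predicted", "counts")
  expect_equal(precision_recall_f1(cmT, "conventional"), m)
  # identity matrix -> all 1.0
  id <- confusion_matrix(diag(3) * 5, c("a", "b", "c"), "rows=truth", "counts")
  mid <- precision_recall_f1(id, "conventional")
  expect_true(all(mid$precision == 1 & mid$recall == 1 & mid$f1 == 1))
})

test_that("the reported-table convention reproduces the printed derived rows", {
  pcm <- reference_patch_confusion()
  m <- precision_recall_f1(pcm, "paper")
  printed <- reference_patch_metrics()
  expect_equal(m$class, printed$class)
  expect_true(all(abs(m$precision - printed$precision) <= 0.01 + 1e-9))
  expect_true(all(abs(m$recall - printed$recall) <= 0.01 + 1e-9))
  expect_true(all(abs(m$f1 - printed$f1) <= 0.01 + 1e-9))
  # headline harmonic means
  expect_equal(round(slidedx:::harmonic_mean(0.95, 0.66), 2), 0.78)
  expect_equal(round(slidedx:::harmonic_mean(0.75, 0.79), 2), 0.77)
  expect_equal(round(slidedx:::harmonic_mean(0.94, 0.94), 2), 0.94)
})

test_that("the two conventions coincide under equal truth-class totals", {
  # counts with equal column totals: column-normalizing divides by a constant,
  # so the paper "precision" equals conventional recall and vice versa
  set.seed(8)
  k <- 4
  counts <- matrix(0, k, k)
  for (j in 1:k) counts[, j] <- as.vector(stats::rmultinom(1, 500, runif(k) + 0.2))
  labels <- letters[1:k]
  cm_counts <- confusion_matrix(t(counts), labels, "rows=truth", "counts")
  conv <- precision_recall_f1(cm_counts, "conventional")
  frac <- sweep(counts, 2, colSums(counts), "/")
  cm_frac <- confusion_matrix(frac, labels, "rows=predicted",
                              "column_fractions")
  pap <- precision_recall_f1(cm_frac, "paper")
  expect_equal(pap$precision, conv$recall, tolerance = 1e-12)
})

test_that("accuracy equals count-weighted mean of conventional recall", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    cells <- matrix(rpois(k * k, 4), k, k)
    diag(cells) <- diag(cells) + rpois(k, 10)
    cm <- confusion_matrix(cells, paste0("c", 1:k), "rows=truth", "counts")
    m <- precision_recall_f1(cm, "conventional")
    w <- rowSums(cells) / sum(cells)
    expect_equal(accuracy_from_matrix(cm), sum(w * m$recall),
                 tolerance = 1e-12)
  }
  expect_error(
    accuracy_from_matrix(confusion_matrix(matrix(0, 2, 2), c("a", "b"),
                                          "rows=truth", "counts")),
    "empty")
})

test_that("mean diagonal averages defined columns only", {
  cells <- matrix(c(0.6, 0.4, 0.2, 0.8), 2)
  cm <- confusion_matrix(cells, c("A", "B"), "rows=predicted",
                         "column_fractions")
  expect_equal(mean_diagonal(cm), 0.7)
  expect_equal(mean_diagonal(reference_patch_confusion()), 0.85,
               tolerance = 0.005)
  cells_na <- cells; cells_na[, 2] <- NA
  cm_na <- confusion_matrix(cells_na, c("A", "B"), "rows=predicted",
                            "column_fractions")
  expect_warning(md <- mean_diagonal(cm_na), "undefined")
  expect_equal(md, 0.6)
})

test_that("panel PCA features average confidences and conserve mass", {
  panel <- data.frame(
    rater_id = c("r1", "r2"), slide_id = "s1",
    dx1 = c("MCT", "MCT"), conf1 = c(0.70, 0.60),
    dx2 = c("plasmacytoma", "histiocytoma"), conf2 = c(0.20, 0.30),
    dx3 = c("histiocytoma", "SCC"), conf3 = c(0.10, 0.10),
    stringsAsFactors = FALSE)
  f <- build_pca_features("panel", panel)
  expect_equal(unname(rowSums(f)), 1)
  expect_equal(f["s1", "MCT"], 0.65)
  expect_equal(f["s1", "histiocytoma"], 0.20)
  expect_equal(f["s1", "SCC"], 0.05)
  expect_equal(f["s1", "trichoblastoma"], 0)
  # single-rater panel reproduces that rater's confidence vector
  f1 <- build_pca_features("panel", panel[1, ])
  expect_equal(f1["s1", "MCT"], 0.70)
  expect_equal(unname(rowSums(f1)), 1)
})

test_that("algorithm PCA features hold top-3 retained fractions", {
  mk_dx <- function(id, classes) aggregate_slide_diagnosis(
    data.frame(slide_id = id, emitted_class = classes))
  d1 <- mk_dx("s1", rep(c("MCT", "SCC", "PNST", "melanoma"),
                        c(50, 30, 15, 5)))
  d2 <- mk_dx("s2", rep(c("histiocytoma", "nonneoplastic"), c(10, 40)))
  f <- build_pca_features("algorithm", list(d1, d2))
  # 4 classes on s1: row sums to top-3 mass < 1
  expect_equal(f["s1", "MCT"], 0.5)
  expect_equal(unname(rowSums(f)["s1"]), 0.95)
  # <= 3 classes on s2 (after exclusion): equality at 1
  expect_equal(unname(rowSums(f)["s2"]), 1)
})

test_that("PCA projection matches a brute-force eigendecomposition to 1e-8", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  res <- pca_project(X, n_components = 4)
  # independent oracle: eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  for (j in 1:4) {
    v <- eg$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v  # same sign convention
    expect_equal(unname(res$loadings[, j]), unname(v), tolerance = 1e-8)
    expect_equal(unname(res$scores[, j]), unname(as.vector(Xc %*% v)),
                 tolerance = 1e-8)
  }
  expect_equal(res$explained_variance,
               eg$values / sum(eg$values), tolerance = 1e-8)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(abs(colMeans(res$scores)) < 1e-10))
  # reconstruction with all components reproduces the centered features
  expect_equal(res$scores %*% t(res$loadings), unclass(Xc),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate PCA inputs are handled explicitly", {
  # identical rows -> zero variance, zero scores
  X <- matrix(1, 5, 3)
  expect_warning(res <- pca_project(X), "zero-variance")
  expect_true(all(res$scores == 0))
  # collinear 2-D toy set: first component explains everything
  Y <- cbind(x = c(0, 1, 2), y = c(0, 1, 2))
  res2 <- pca_project(Y)
  expect_equal(res2$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_project(matrix(1, 1, 3)), "2 rows")
})

test_that("confidence-versus-portion pairs panel confidence with the diagonal", {
  types <- tumor_type_labels()
  slides <- stub_slides(2)
  truth <- setNames(vapply(slides, function(s) s$true_tumor_type, character(1)),
                    vapply(slides, function(s) s$slide_id, character(1)))
  # all raters always correct at confidence 0.98
  panel <- do.call(rbind, lapply(names(truth), function(sid) {
    data.frame(rater_id = c("r1", "r2"), slide_id = sid,
               dx1 = unname(truth[sid]),
               conf1 = 0.98,
               dx2 = setdiff(types, truth[sid])[1], conf2 = 0.01,
               dx3 = setdiff(types, truth[sid])[2], conf3 = 0.01,
               stringsAsFactors = FALSE)
  }))
  idcm <- confusion_matrix(diag(7), types, "rows=predicted",
                           "column_fractions")
  tab <- confidence_vs_portion_table(panel, truth, idcm)
  expect_equal(tab$mean_confidence, rep(0.98, 7))
  expect_equal(tab$patch_portion, rep(1, 7))
  # a type with zero correct primaries gets NA confidence
  panel2 <- panel
  panel2$dx1[truth[panel2$slide_id] == "MCT"] <- "SCC"
  tab2 <- confidence_vs_portion_table(panel2, truth, idcm)
  expect_true(is.na(tab2$mean_confidence[tab2$tumor_type == "MCT"]))
})
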