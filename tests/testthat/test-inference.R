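test_that("segmentation view collapses tumor codes and conserves pixel counts", {
  g <- matrix(scheme$segmentation_classes[["dermis"]], 20, 20)
  g[5:12, 5:12] <- scheme$tumor_types[["melanoma"]]
  g[1, ] <- scheme$segmentation_classes[["epidermis"]]
  r <- label_raster(g, 4, "s")
  v <- derive_segmentation_view(r)
  tcode <- scheme$segmentation_classes[["tumor"]]
  expect_equal(sum(v$grid == tcode), 64)
  # non-tumor codes map to themselves; totals conserved
  for (cls in c("epidermis", "dermis")) {
    code <- scheme$segmentation_classes[[cls]]
    expect_equal(sum(v$grid == code), sum(g == code))
  }
  expect_equal(length(v$grid), length(g))
  # idempotent on an already-collapsed map
  v2 <- derive_segmentation_view(v)
  expect_identical(v2$grid, v$grid)
  # unknown codes rejected
  bad <- r; bad$grid[1, 1] <- 99L
  expect_error(derive_segmentation_view(bad), "unknown")
  # pure-tumor raster maps to all-tumor
  all_t <- label_raster(matrix(scheme$tumor_types[["MCT"]], 8, 8), 4, "t")
  expect_true(all(derive_segmentation_view(all_t)$grid == tcode))
})

test_that("tumor mask matches the tumor class exactly", {
  g <- matrix(scheme$segmentation_classes[["subcutis"]], 16, 16)
  g[3:6, 3:10] <- scheme$tumor_types[["PNST"]]
  v <- derive_segmentation_view(label_raster(g, 4, "s"))
  m <- extract_tumor_mask(v)
  expect_equal(sum(m), 32)
  expect_true(all(m == (g >= 10)))
})

test_that("mask upscaling replicates blocks and conserves counts", {
  m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  up <- upscale_mask(m, 16)
  expect_equal(dim(up), c(32, 32))
  expect_true(all(up[1:16, 1:16]))
  expect_true(all(!up[1:16, 17:32]))
  expect_equal(sum(up), sum(m) * 16^2)
  expect_identical(upscale_mask(m, 1), m)
  expect_error(upscale_mask(m, 2.5), "positive integer")
})

test_that("full-tumor tiling keeps only 100% tumor tiles on the aligned grid", {
  # all-tumor 2048^2 high-res mask -> 4 tiles of 1024
  mask <- matrix(TRUE, 128, 128)  # low-res 4 um, factor 16 -> 2048 hi-res
  hi <- upscale_mask(mask, 16)
  tiles <- tile_fully_tumor_patches(hi, 1024)
  expect_equal(nrow(tiles), 4)
  expect_setequal(tiles$row0, c(0, 1024))
  # one low-res dermis pixel inside the top-left tile removes exactly it
  mask2 <- mask; mask2[10, 10] <- FALSE
  tiles2 <- tile_fully_tumor_patches(upscale_mask(mask2, 16), 1024)
  expect_equal(nrow(tiles2), 3)
  expect_false(any(tiles2$row0 == 0 & tiles2$col0 == 0))
  # all-background -> no tiles
  expect_equal(nrow(tile_fully_tumor_patches(matrix(FALSE, 64, 64), 32)), 0)
})

test_that("block tiling on the 4um grid equals upscale-then-tile (random masks)", {
  set.seed(99)
  for (i in 1:20) {
    nr <- sample(4:13, 1) * 4
    mask <- matrix(runif(nr * nr) < runif(1, 0.3, 0.95), nr, nr)
    a <- tile_fully_tumor_patches(upscale_mask(mask, 16), 64 * 16)
    b <- tile_full_tumor_blocks(mask, 64 * 16, 16)
    expect_equal(a[c("row0", "col0", "size_px")], b[c("row0", "col0", "size_px")])
  }
})

test_that("patch classification preserves order and reports true classes", {
  g <- matrix(scheme$segmentation_classes[["dermis"]], 64, 64)
  g[1:32, ] <- scheme$tumor_types[["melanoma"]]
  r <- label_raster(g, 4, "s")
  mask <- extract_tumor_mask(derive_segmentation_view(r))
  patches <- tile_full_tumor_blocks(mask, 16 * 16, 16, slide_id = "s")
  expect_gt(nrow(patches), 0)
  oc <- identity_classifier()
  preds <- classify_patches(patches, oc, r, factor = 16)
  expect_equal(nrow(preds), nrow(patches))
  expect_true(all(preds$true_class == "melanoma"))
  expect_true(all(preds$emitted_class == "melanoma"))
  # empty input passes through
  empty <- classify_patches(patches[0, ], oc, r)
  expect_equal(nrow(empty), 0)
  # classifier failure carries patch context
  tiny_spec <- confusion_spec("SCC", matrix(1))
  bad <- make_oracle_classifier(tiny_spec, 1)
  expect_error(classify_patches(patches, bad, r), "classifier failed")
})

test_that("majority vote ranks counts, excludes nonneoplastic, breaks ties", {
  mk <- function(classes) data.frame(slide_id = "s", emitted_class = classes)
  # 780 histiocytoma vs 220 SCC -> fractions 0.78 / 0.22
  dx <- aggregate_slide_diagnosis(mk(rep(c("histiocytoma", "SCC"), c(780, 220))))
  expect_equal(dx$primary, "histiocytoma")
  expect_equal(dx$differential1, "SCC")
  expect_equal(dx$ranked$fraction, c(0.78, 0.22))
  expect_false(dx$tie_flag)
  # unanimous: no differentials
  dx2 <- aggregate_slide_diagnosis(mk(rep("MCT", 50)))
  expect_equal(dx2$primary, "MCT")
  expect_true(is.na(dx2$differential1) && is.na(dx2$differential2))
  # tie broken by canonical class order (PNST before melanoma), flagged
  dx3 <- aggregate_slide_diagnosis(mk(rep(c("PNST", "melanoma"), c(10, 10))))
  expect_equal(dx3$primary, "PNST")
  expect_true(dx3$tie_flag)
  # nonneoplastic exclusion and count conservation
  dx4 <- aggregate_slide_diagnosis(
    mk(rep(c("MCT", "nonneoplastic"), c(30, 20))))
  expect_equal(dx4$n_patches_total, 50)
  expect_equal(dx4$n_patches_excluded_nonneoplastic, 20)
  expect_equal(sum(dx4$ranked$patch_count),
               dx4$n_patches_total - dx4$n_patches_excluded_nonneoplastic)
  expect_equal(sum(dx4$ranked$fraction), 1)
  # all nonneoplastic -> distinct no-tumor status, not an error
  dx5 <- aggregate_slide_diagnosis(mk(rep("nonneoplastic", 5)))
  expect_equal(dx5$status, "no_tumor")
  expect_true(is.na(dx5$primary))
})

test_that("aggregation is invariant to prediction order", {
  set.seed(12)
  classes <- sample(c(tumor_type_labels(), "nonneoplastic"), 300,
                    replace = TRUE)
  d1 <- aggregate_slide_diagnosis(
    data.frame(slide_id = "s", emitted_class = classes))
  d2 <- aggregate_slide_diagnosis(
    data.frame(slide_id = "s", emitted_class = sample(classes)))
  expect_equal(d1$ranked, d2$ranked)
  expect_equal(d1$primary, d2$primary)
})

test_that("pipeline with perfect segmenter and identity classifier recovers truth", {
  cfg <- tiny_config(n = 1, px = 192, seed = 51, tumor_range = c(0.35, 0.5))
  for (ty in c("trichoblastoma", "plasmacytoma")) {
    rec <- generate_slide_raster(cfg, ty, paste0(ty, "_x"), 7)
    dx <- run_slide_pipeline(rec, NULL, identity_classifier(),
                             patch_size = 256, factor = 16)
    expect_equal(dx$status, "ok")
    expect_equal(dx$primary, ty)
    expect_equal(dx$n_patches_total,
                 sum(dx$ranked$patch_count) + dx$n_patches_excluded_nonneoplastic)
  }
})

test_that("a slide whose tumor yields no full tile gets no-tumor status", {
  g <- matrix(scheme$segmentation_classes[["dermis"]], 70, 70)
  g[1:10, 1:10] <- scheme$tumor_types[["SCC"]]  # smaller than one 64px block
  g[30:40, 30:40] <- scheme$tumor_types[["SCC"]]  # straddles block borders
  rec <- structure(list(slide_id = "tiny", raster = label_raster(g, 4, "tiny"),
                        true_tumor_type = "SCC", split = "none"),
                   class = "slide_record")
  dx <- run_slide_pipeline(rec, NULL, identity_classifier())
  expect_equal(dx$status, "no_tumor")
})

test_that("slide error rate from majority voting falls as patch count grows", {
  # draw patch votes directly from the weakest confusion column (SCC);
  # with a dominant diagonal, more patches must mean fewer slide errors
  sp <- reference_confusion_spec()
  oc <- make_oracle_classifier(sp, seed = 33)
  err <- vapply(c(3, 15, 75), function(n_patches) {
    wrong <- 0
    for (rep in 1:200) {
      emitted <- classify_true_classes(oc, rep("SCC", n_patches))
      counts <- table(factor(emitted, levels = sp$labels))
      top <- names(counts)[which.max(counts)]
      if (top != "SCC") wrong <- wrong + 1
    }
    wrong / 200
  }, numeric(1))
  expect_true(all(diff(err) <= 0.02))  # non-increasing up to MC noise
  expect_lt(err[3], err[1])
})
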