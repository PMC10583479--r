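#' Label raster
#'
#' A 2-D integer grid of fine label codes standing in for a fully annotated
#' whole-slide image at the segmentation resolution (default 4.0 um/pixel).
#' Coordinates are 0-based `(row, col)` with half-open patch extents.
#'
#' @param grid Integer matrix of fine label codes.
#' @param resolution_um_per_px Positive physical resolution.
#' @param slide_id Identifier string.
#' @param scheme A [class_scheme()] used to validate codes.
#' @return An object of class `label_raster`.
#' @export
label_raster <- function(grid, resolution_um_per_px = 4.0, slide_id = "slide",
                         scheme = class_scheme()) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  storage.mode(grid) <- "integer"
  valid <- c(scheme$fine_codes, scheme$optional_codes)
  bad <- setdiff(unique(as.vector(grid)), unname(valid))
  if (length(bad) > 0) {
    stop("grid contains codes outside the class scheme: ",
         paste(bad, collapse = ", "))
  }
  if (!is.numeric(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("resolution_um_per_px must be positive")
  }
  structure(
    list(grid = grid, resolution_um_per_px = as.numeric(resolution_um_per_px),
         slide_id = as.character(slide_id)),
    class = "label_raster"
  )
}

#' @export
print.label_raster <- function(x, ...) {
  counts <- table(factor(fine_code_to_name(as.vector(x$grid))))
  cat(sprintf("<label_raster> %s  %d x %d px @ %.2f um/px\n",
              x$slide_id, nrow(x$grid), ncol(x$grid), x$resolution_um_per_px))
  print(counts)
  invisible(x)
}

#' Cohort configuration
#'
#' Parameters of the synthetic cohort. Defaults mirror the study design the
#' pipeline was evaluated under: 50 slides per tumor type split 70/10/20
#' into train/validation/test. Raster geometry is a desk-scale choice: a
#' 768 x 768 grid at 4 um/pixel corresponds to a ~3 x 3 mm biopsy section.
#'
#' @param n_slides_per_type Slides generated per tumor type.
#' @param raster_size_px Integer `(rows, cols)`, each >= 64.
#' @param tumor_fraction_range Length-2 numeric in (0,1): the per-slide
#'   tumor pixel fraction is drawn uniformly from this interval.
#' @param inflammation_fraction Approximate fraction of slide area occupied
#'   by inflammation/necrosis pockets (0 disables them).
#' @param split_ratios Length-3 train/validation/test ratios summing to 1.
#' @param seed Master seed; all per-slide seeds derive from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_slides_per_type = 50,
                          raster_size_px = c(768L, 768L),
                          tumor_fraction_range = c(0.2, 0.5),
                          inflammation_fraction = 0.05,
                          split_ratios = c(train = 0.7, validation = 0.1, test = 0.2),
                          seed = 1L) {
  stopifnot(n_slides_per_type >= 1, length(raster_size_px) == 2)
  if (any(raster_size_px < 64)) stop("raster dimensions must be >= 64")
  stopifnot(length(tumor_fraction_range) == 2,
            tumor_fraction_range[1] <= tumor_fraction_range[2],
            all(tumor_fraction_range > 0), all(tumor_fraction_range < 1))
  stopifnot(length(split_ratios) == 3, all(split_ratios >= 0))
  if (abs(sum(split_ratios) - 1) > 1e-9) stop("split_ratios must sum to 1")
  if (inflammation_fraction < 0 || inflammation_fraction > 1) {
    stop("inflammation_fraction must lie in [0, 1]")
  }
  structure(
    list(n_slides_per_type = as.integer(n_slides_per_type),
         raster_size_px = as.integer(raster_size_px),
         tumor_fraction_range = as.numeric(tumor_fraction_range),
         inflammation_fraction = as.numeric(inflammation_fraction),
         split_ratios = stats::setNames(as.numeric(split_ratios),
                                        c("train", "validation", "test")),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Linear indices (column-major) of pixels inside a rotated ellipse, computed
# over the ellipse's bounding box only. Returns list(idx, q) with q the
# normalized squared radius, so callers can trim a blob from the outside in
# without paying for a sort on every ellipse.
ellipse_indices <- function(nr, nc, cr, cc, a, b, theta) {
  rad <- max(a, b)
  r0 <- max(1, floor(cr - rad)); r1 <- min(nr, ceiling(cr + rad))
  c0 <- max(1, floor(cc - rad)); c1 <- min(nc, ceiling(cc + rad))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), q = numeric(0)))
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - cr; dc <- cols - cc
  X <- matrix(dr, length(dr), length(dc))
  Y <- matrix(dc, length(dr), length(dc), byrow = TRUE)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  q <- (xr / a)^2 + (yr / b)^2
  inside <- which(q <= 1)
  ridx <- ((inside - 1L) %% length(rows)) + r0
  cidx <- ((inside - 1L) %/% length(rows)) + c0
  list(idx = (cidx - 1L) * nr + ridx, q = q[inside])
}

# Keep at most `keep` pixels of an ellipse, nearest the center first.
trim_ellipse <- function(e, keep) {
  if (length(e$idx) <= keep) return(e$idx)
  e$idx[order(e$q)[seq_len(keep)]]
}

#' Generate one synthetic slide
#'
#' Builds an annotated label raster with a background border, an epidermis
#' band, dermis and subcutis layers, optional inflammation/necrosis pockets,
#' and a connected tumor blob (a union of random ellipses grown to a target
#' pixel fraction drawn from `tumor_fraction_range`, trimmed outside-in so
#' the final fraction hits the target exactly up to rounding).
#'
#' @param config A [cohort_config()].
#' @param tumor_type One of the scheme's tumor-type labels.
#' @param slide_id Identifier.
#' @param seed Integer seed; the same config and seed reproduce the raster
#'   byte for byte.
#' @param scheme A [class_scheme()].
#' @return An object of class `slide_record`: `slide_id`, `raster`
#'   ([label_raster]), `true_tumor_type`, `split` (initially `"none"`).
#' @export
generate_slide_raster <- function(config, tumor_type, slide_id, seed,
                                  scheme = class_scheme()) {
  if (!tumor_type %in% names(scheme$tumor_types)) {
    stop("unknown tumor type: ", tumor_type)
  }
  nr <- config$raster_size_px[1]; nc <- config$raster_size_px[2]
  seg <- scheme$segmentation_classes
  tcode <- tumor_type_code(tumor_type, scheme)

  grid <- with_seed(seed, {
    g <- matrix(seg[["background"]], nr, nc)
    border <- max(2L, round(0.03 * min(nr, nc)))
    ir <- (border + 1L):(nr - border)
    ic <- (border + 1L):(nc - border)
    epi_h <- max(2L, round(0.05 * nr))
    epi_rows <- ir[seq_len(min(epi_h, length(ir)))]
    g[epi_rows, ic] <- seg[["epidermis"]]
    tissue_rows <- ir[ir > max(epi_rows)]
    dermis_n <- ceiling(length(tissue_rows) * 0.45)
    g[tissue_rows[seq_len(dermis_n)], ic] <- seg[["dermis"]]
    g[tissue_rows[(dermis_n + 1L):length(tissue_rows)], ic] <- seg[["subcutis"]]

    # inflammation/necrosis pockets inside dermis/subcutis
    if (config$inflammation_fraction > 0) {
      target_inf <- round(config$inflammation_fraction * nr * nc)
      placed <- 0L; tries <- 0L
      while (placed < target_inf && tries < 200L) {
        tries <- tries + 1L
        cr <- stats::runif(1, min(tissue_rows), max(tissue_rows))
        cc <- stats::runif(1, min(ic), max(ic))
        ax <- stats::runif(2, 0.02, 0.06) * min(nr, nc)
        e <- ellipse_indices(nr, nc, cr, cc, ax[1], ax[2], stats::runif(1, 0, pi))
        keep <- g[e$idx] %in% seg[c("dermis", "subcutis")]
        e <- list(idx = e$idx[keep], q = e$q[keep])
        idx <- trim_ellipse(e, target_inf - placed)
        g[idx] <- seg[["inflammation_necrosis"]]
        placed <- placed + length(idx)
      }
    }

    # tumor blob: union of ellipses grown to the target fraction
    target_frac <- stats::runif(1, config$tumor_fraction_range[1],
                                config$tumor_fraction_range[2])
    target_px <- round(target_frac * nr * nc)
    allowed <- seg[c("dermis", "subcutis", "inflammation_necrosis")]
    avail <- sum(g %in% allowed)
    if (avail < target_px) {
      stop(sprintf(
        "raster too small: %d tissue pixels available, %d tumor pixels required",
        avail, target_px))
    }
    tumor_px <- 0L
    tumor_cells <- integer(0)
    guard <- 0L
    while (tumor_px < target_px && guard < 500L) {
      guard <- guard + 1L
      if (tumor_px == 0L) {
        # first ellipse near the tissue center
        cr <- stats::runif(1, stats::quantile(tissue_rows, 0.3),
                           stats::quantile(tissue_rows, 0.7))
        cc <- stats::runif(1, stats::quantile(ic, 0.3), stats::quantile(ic, 0.7))
      } else {
        # subsequent ellipses seeded on existing tumor pixels -> connected blob
        pick <- tumor_cells[sample.int(length(tumor_cells), 1L)]
        cr <- ((pick - 1L) %% nr) + 1L
        cc <- ((pick - 1L) %/% nr) + 1L
      }
      ax <- stats::runif(2, 0.10, 0.28) * min(nr, nc)
      e <- ellipse_indices(nr, nc, cr, cc, ax[1], ax[2], stats::runif(1, 0, pi))
      keep <- g[e$idx] %in% allowed
      e <- list(idx = e$idx[keep], q = e$q[keep])
      if (length(e$idx) == 0) next
      idx <- trim_ellipse(e, target_px - tumor_px)
      g[idx] <- tcode
      tumor_cells <- c(tumor_cells, idx)
      tumor_px <- tumor_px + length(idx)
    }
    g
  })

  structure(
    list(slide_id = as.character(slide_id),
         raster = label_raster(grid, 4.0, slide_id, scheme),
         true_tumor_type = tumor_type,
         split = "none"),
    class = "slide_record"
  )
}

#' @export
print.slide_record <- function(x, ...) {
  frac <- mean(x$raster$grid >= 10L)
  cat(sprintf("<slide_record> %s  type=%s split=%s tumor_fraction=%.3f\n",
              x$slide_id, x$true_tumor_type, x$split, frac))
  invisible(x)
}
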