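#' Class sampling weights
#'
#' A normalized probability vector over annotation classes used when
#' drawing training patches. Every class keeps at least a floor of
#' probability so no class ever vanishes from the sampling pool.
#'
#' @param weights Named nonnegative numeric vector; normalized on
#'   construction.
#' @return Object of class `class_sampling_weights` (a named numeric
#'   vector summing to 1).
#' @export
class_sampling_weights <- function(weights) {
  if (length(weights) == 0 || is.null(names(weights))) {
    stop("weights must be a named vector")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(weights / s, class = "class_sampling_weights")
}

#' Adaptive class reweighting from validation scores
#'
#' Classes with low validation performance are up-sampled and
#' well-performing classes under-sampled: the new weight of class `c` is
#' proportional to `(1 - score_c) + epsilon`, normalized. The additive
#' floor `epsilon` keeps every class at nonzero probability even when its
#' score is perfect; weights are strictly decreasing in the score.
#'
#' @param per_class_score Named numeric vector of scores in `[0, 1]`
#'   (e.g. per-class validation F1).
#' @param epsilon Positive floor, default 0.05.
#' @return A [class_sampling_weights()] over the scored classes.
#' @examples
#' update_class_sampling_weights(c(A = 0.5, B = 1.0))  # A: 0.917, B: 0.083
#' @export
update_class_sampling_weights <- function(per_class_score, epsilon = 0.05) {
  if (length(per_class_score) == 0) stop("empty score map")
  if (is.null(names(per_class_score))) stop("scores must be named by class")
  if (any(per_class_score < 0 | per_class_score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  class_sampling_weights((1 - per_class_score) + epsilon)
}

# Uniform weights over a set of class names.
uniform_weights <- function(classes) {
  class_sampling_weights(stats::setNames(rep(1, length(classes)), classes))
}

# Clamp a patch top-left so the patch lies fully inside an nr x nc grid
# when centered on (r, c). 0-based output.
patch_origin <- function(r, c, size, nr, nc) {
  half <- size %/% 2L
  row0 <- min(max(r - half, 1L), nr - size + 1L) - 1L
  col0 <- min(max(c - half, 1L), nc - size + 1L) - 1L
  c(row0, col0)
}

# Most frequent fine class name within a patch footprint (1-based bounds).
# Fine codes are small integers, so tabulate() beats table() by a wide margin.
dominant_class <- function(grid, row0, col0, size) {
  sub <- grid[(row0 + 1L):(row0 + size), (col0 + 1L):(col0 + size)]
  counts <- tabulate(sub + 1L, nbins = 17L)
  fine_code_to_name(which.max(counts) - 1L)
}

#' Uniform per-slide training patch sampling
#'
#' Draws `n_per_slide` patches from each slide. For each draw a target
#' annotation class is sampled from `weights` restricted (and renormalized)
#' to the classes present on that slide; the patch is centered on a
#' uniformly chosen pixel of that class and clamped to the raster bounds.
#'
#' @param slides List of `slide_record`s; each raster must be larger than
#'   `patch_size`.
#' @param n_per_slide Patches per slide (default 10).
#' @param patch_size Side length in raster pixels (default 512).
#' @param weights A [class_sampling_weights()] over fine class names;
#'   `NULL` means uniform over the classes present per slide.
#' @param seed Integer seed (per-slide streams derive from it).
#' @param scheme A [class_scheme()].
#' @return data.frame with one row per patch: `slide_id`, `row0`, `col0`
#'   (0-based top-left), `size_px`, `target_class`, `dominant_class`.
#' @export
sample_training_patches_uniform <- function(slides, n_per_slide = 10,
                                            patch_size = 512, weights = NULL,
                                            seed = 1L,
                                            scheme = class_scheme()) {
  rows <- vector("list", length(slides))
  for (si in seq_along(slides)) {
    s <- slides[[si]]
    g <- s$raster$grid
    nr <- nrow(g); nc <- ncol(g)
    if (nr <= patch_size || nc <= patch_size) {
      stop("raster of slide ", s$slide_id, " not larger than patch_size")
    }
    by_class <- split(seq_along(g), fine_code_to_name(as.vector(g), scheme))
    present <- names(by_class)
    out <- with_seed(derive_seed(seed, paste0("unif/", s$slide_id)), {
      res <- vector("list", n_per_slide)
      for (k in seq_len(n_per_slide)) {
        if (is.null(weights)) {
          w <- stats::setNames(rep(1, length(present)), present)
        } else {
          w <- unclass(weights)[intersect(names(weights), present)]
          if (length(w) == 0 || sum(w) == 0) {
            # no weighted class present: redraw uniformly among present
            w <- stats::setNames(rep(1, length(present)), present)
          }
        }
        target <- sample(names(w), 1, prob = w)
        pix <- by_class[[target]]
        p <- pix[sample.int(length(pix), 1L)]
        r <- ((p - 1L) %% nr) + 1L
        cc <- ((p - 1L) %/% nr) + 1L
        o <- patch_origin(r, cc, patch_size, nr, nc)
        res[[k]] <- data.frame(
          slide_id = s$slide_id, row0 = o[1], col0 = o[2],
          size_px = patch_size, target_class = target,
          dominant_class = dominant_class(g, o[1], o[2], patch_size),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, res)
    })
    rows[[si]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Adaptive sampling loop
#'
#' Epoch 1 samples with uniform class weights; each later epoch reweights
#' classes by the previous epoch's per-class validation scores via
#' [update_class_sampling_weights()], so persistently hard classes are
#' sampled more often. No model is trained here: the evaluator contract
#' stands in for "train one epoch, score the validation patches".
#'
#' @param slides_train,slides_val Lists of `slide_record`s.
#' @param evaluator Function `(val_patches, weights) -> named scores in
#'   [0, 1]` over annotation classes.
#' @param epochs Number of epochs (>= 1).
#' @param n_per_slide,patch_size Passed to
#'   [sample_training_patches_uniform()].
#' @param seed Integer seed.
#' @param scheme A [class_scheme()].
#' @return List with `weights` (list of per-epoch
#'   [class_sampling_weights()] actually used), `scores` (list of per-epoch
#'   evaluator outputs), and `n_patches` (per-epoch training patch counts).
#' @export
run_adaptive_sampling_loop <- function(slides_train, slides_val, evaluator,
                                       epochs, n_per_slide = 10,
                                       patch_size = 512, seed = 1L,
                                       scheme = class_scheme()) {
  if (epochs < 1) stop("epochs must be >= 1")
  classes <- names(scheme$fine_codes)
  w <- uniform_weights(classes)
  weights_log <- vector("list", epochs)
  scores_log <- vector("list", epochs)
  n_patches <- integer(epochs)
  for (ep in seq_len(epochs)) {
    weights_log[[ep]] <- w
    train_patches <- sample_training_patches_uniform(
      slides_train, n_per_slide, patch_size, w,
      seed = derive_seed(seed, paste0("train-epoch/", ep)), scheme = scheme)
    val_patches <- sample_training_patches_uniform(
      slides_val, n_per_slide, patch_size, w,
      seed = derive_seed(seed, paste0("val-epoch/", ep)), scheme = scheme)
    n_patches[ep] <- nrow(train_patches)
    scores <- evaluator(val_patches, w)
    if (any(scores < 0 | scores > 1)) {
      stop("evaluator must return scores in [0, 1]")
    }
    scores_log[[ep]] <- scores
    w <- update_class_sampling_weights(scores)
  }
  list(weights = weights_log, scores = scores_log, n_patches = n_patches)
}

#' Sample high-purity patches for classifier training
#'
#' Rejection sampling of patches centered on pixels of `target_class`: a
#' patch is accepted only if at least `purity` of its pixels carry the
#' target class (the 90% purity rule, by default). Sampling stops after
#' `n` acceptances or `100 * n` attempts; if the cap is reached with zero
#' acceptances an empty result is returned with a warning.
#'
#' @param raster A [label_raster()].
#' @param target_class Fine class name to sample.
#' @param patch_size Side length in raster pixels.
#' @param purity Minimum in-class pixel fraction, in `(0, 1]`.
#' @param n Number of patches requested.
#' @param seed Integer seed.
#' @param scheme A [class_scheme()].
#' @return data.frame: `slide_id`, `row0`, `col0`, `size_px`,
#'   `target_class`, `purity_observed` (possibly zero rows).
#' @export
sample_pure_patches <- function(raster, target_class, patch_size = 1024,
                                purity = 0.9, n = 10, seed = 1L,
                                scheme = class_scheme()) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g)
  if (nr < patch_size || nc < patch_size) {
    stop("raster smaller than patch_size")
  }
  codes <- c(scheme$fine_codes, scheme$optional_codes)
  if (!target_class %in% names(codes)) {
    stop("unknown class: ", target_class)
  }
  tcode <- codes[[target_class]]
  pix <- which(g == tcode)
  empty <- data.frame(slide_id = character(0), row0 = integer(0),
                      col0 = integer(0), size_px = integer(0),
                      target_class = character(0),
                      purity_observed = numeric(0))
  if (length(pix) == 0) {
    warning("no pixels of class ", target_class, " on ", raster$slide_id)
    return(empty)
  }
  with_seed(seed, {
    accepted <- vector("list", n)
    n_acc <- 0L
    attempts <- 0L
    cap <- 100L * n
    while (n_acc < n && attempts < cap) {
      attempts <- attempts + 1L
      p <- pix[sample.int(length(pix), 1L)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      o <- patch_origin(r, cc, patch_size, nr, nc)
      sub <- g[(o[1] + 1L):(o[1] + patch_size),
               (o[2] + 1L):(o[2] + patch_size)]
      frac <- mean(sub == tcode)
      if (frac >= purity) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- data.frame(
          slide_id = raster$slide_id, row0 = o[1], col0 = o[2],
          size_px = patch_size, target_class = target_class,
          purity_observed = frac, stringsAsFactors = FALSE)
      }
    }
    if (n_acc == 0L) {
      warning("attempt cap reached with no patch meeting purity ",
              purity, " on ", raster$slide_id)
      return(empty)
    }
    res <- do.call(rbind, accepted[seq_len(n_acc)])
    rownames(res) <- NULL
    res
  })
}
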