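# Shared fixtures, built in code.

scheme <- class_scheme()

# A small deterministic cohort config for unit tests.
tiny_config <- function(n = 2, px = 128, seed = 11,
                        tumor_range = c(0.25, 0.4), infl = 0.03) {
  cohort_config(n_slides_per_type = n, raster_size_px = c(px, px),
                tumor_fraction_range = tumor_range,
                inflammation_fraction = infl, seed = seed)
}

# Slide stubs carrying only id/type/split: enough for panel generation and
# consensus tests, without paying for raster synthesis.
stub_slides <- function(n_per_type = 1, types = tumor_type_labels()) {
  out <- list()
  for (ty in types) {
    for (i in seq_len(n_per_type)) {
      out[[length(out) + 1L]] <- structure(
        list(slide_id = sprintf("%s_%03d", ty, i), raster = NULL,
             true_tumor_type = ty, split = "test"),
        class = "slide_record")
    }
  }
  out
}

# Identity classifier: always emits the true class.
identity_classifier <- function(seed = 1) {
  make_oracle_classifier(
    confusion_spec(tumor_type_labels(), diag(7)), seed)
}

# A hand-built valid response.
make_response <- function(rater = "r1", slide = "s1",
                          dx = c("MCT", "plasmacytoma", "histiocytoma"),
                          conf = c(0.70, 0.20, 0.10)) {
  pathologist_response(rater, slide, dx, conf)
}

# Brute-force purity of every possible patch placement (0-based origins).
enumerate_pure_positions <- function(grid, code, size, purity) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- NULL
  for (r0 in 0:(nr - size)) {
    for (c0 in 0:(nc - size)) {
      frac <- mean(grid[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size)] == code)
      if (frac >= purity) out <- rbind(out, c(r0, c0))
    }
  }
  out
}
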