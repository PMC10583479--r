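# On-disk formats: label rasters as 8-bit single-channel PNG (pixel value =
# fine label code) with a JSON sidecar carrying the code map, resolution and
# slide id; tabular artifacts as UTF-8 TSV with fixed schemas. Confidences
# travel as 2-digit decimal strings and are validated back onto the 0.01
# grid on read.

#' Write / read a label raster (PNG + JSON sidecar)
#'
#' @param raster A [label_raster()].
#' @param path PNG path; the sidecar is written at `<path>.json`.
#' @return `write_label_raster`: the path, invisibly.
#' @export
write_label_raster <- function(raster, path) {
  img <- raster$grid / 255
  png::writePNG(img, target = path)
  sidecar <- list(
    slide_id = raster$slide_id,
    resolution_um_per_px = raster$resolution_um_per_px,
    code_map = as.list(stats::setNames(
      fine_code_to_name(sort(unique(as.vector(raster$grid)))),
      sort(unique(as.vector(raster$grid)))))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path PNG path written by [write_label_raster()].
#' @param scheme A [class_scheme()].
#' @return `read_label_raster`: the round-tripped [label_raster()].
#' @rdname write_label_raster
#' @export
read_label_raster <- function(path, scheme = class_scheme()) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing JSON sidecar: ", sidecar_path)
  }
  sidecar <- tryCatch(jsonlite::read_json(sidecar_path),
                      error = function(e) stop("corrupt sidecar ",
                                               sidecar_path, ": ",
                                               conditionMessage(e)))
  for (f in c("slide_id", "resolution_um_per_px", "code_map")) {
    if (is.null(sidecar[[f]])) stop("corrupt sidecar: missing field ", f)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) != 2) stop("raster PNG must be single-channel")
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  known <- c(scheme$fine_codes, scheme$optional_codes)
  codes <- as.integer(names(sidecar$code_map))
  bad <- setdiff(unique(as.vector(grid)), codes)
  if (length(bad) > 0) {
    stop("pixel code(s) absent from sidecar code map: ",
         paste(bad, collapse = ", "))
  }
  declared <- unlist(sidecar$code_map)
  mismatch <- declared != names(known)[match(codes, known)]
  if (anyNA(match(codes, known)) || any(mismatch)) {
    stop("sidecar code map disagrees with the class scheme")
  }
  label_raster(grid, sidecar$resolution_um_per_px, sidecar$slide_id, scheme)
}

# Declared TSV schemas: column name -> type ("c" character, "i" integer,
# "d" double, "l" logical, "conf" confidence on the 0.01 grid).
tsv_schemas <- list(
  manifest = c(slide_id = "c", tumor_type = "c", split = "c",
               raster_path = "c"),
  patches = c(slide_id = "c", row0 = "i", col0 = "i", size_px = "i",
              target_class = "c", purity_observed = "d"),
  predictions = c(slide_id = "c", row0 = "i", col0 = "i",
                  emitted_class = "c"),
  panel = c(rater_id = "c", slide_id = "c", dx1 = "c", conf1 = "conf",
            dx2 = "c", conf2 = "conf", dx3 = "c", conf3 = "conf"),
  consensus = c(slide_id = "c", primary = "c", differential1 = "c",
                differential2 = "c", decimal_consensus = "d",
                draw_resolved = "l"),
  metrics = c(class = "c", precision = "d", recall = "d", f1 = "d")
)

#' Write / read schema-checked TSV tables
#'
#' Readers and writers for the pipeline's tabular artifacts (cohort
#' manifest, sampled patches, patch predictions, pathologist panel,
#' consensus, metrics). Files are UTF-8, LF, tab-separated with a header
#' that must match the declared schema. Confidence columns are written
#' with exactly 2 decimals and parsed back through integer hundredths;
#' an off-grid value is a named error.
#'
#' @param records data.frame matching the schema.
#' @param path File path.
#' @param schema One of `"manifest"`, `"patches"`, `"predictions"`,
#'   `"panel"`, `"consensus"`, `"metrics"`.
#' @return `write_table`: the path, invisibly. `read_table`: the typed
#'   data.frame.
#' @export
write_table <- function(records, path, schema) {
  sch <- tsv_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  missing <- setdiff(names(sch), names(records))
  if (length(missing) > 0) {
    stop("schema ", schema, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  out <- records[names(sch)]
  for (col in names(sch)) {
    if (sch[[col]] == "conf") {
      h <- out[[col]] * 100
      if (any(abs(h - round(h)) > 1e-6)) {
        stop("column ", col, ": confidence off the 0.01 grid")
      }
      out[[col]] <- sprintf("%.2f", out[[col]])
    }
  }
  con <- file(path, open = "wb")  # binary mode => LF endings everywhere
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  sch <- tsv_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!identical(names(df), names(sch))) {
    stop("schema mismatch in ", path, ": expected columns [",
         paste(names(sch), collapse = ", "), "], found [",
         paste(names(df), collapse = ", "), "]")
  }
  for (col in names(sch)) {
    df[[col]] <- switch(
      sch[[col]],
      c = df[[col]],
      i = as.integer(df[[col]]),
      d = as.numeric(df[[col]]),
      l = as.logical(df[[col]]),
      conf = {
        v <- as.numeric(df[[col]])
        h <- v * 100
        bad <- which(abs(h - round(h)) > 1e-6 | round(h) < 1 | round(h) > 98)
        if (length(bad) > 0) {
          stop("column ", col, ", row ", bad[1],
               ": malformed confidence grid value ", df[[col]][bad[1]])
        }
        round(h) / 100
      })
  }
  df
}
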