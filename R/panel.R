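#' Rater model
#'
#' Parameterizes one simulated pathologist: the probability that the
#' primary diagnosis is correct (per tumor type), similarity weights used
#' to sample wrong primaries and the two differential diagnoses, and the
#' concentration of the confidence triple.
#'
#' @param rater_id Identifier string.
#' @param primary_accuracy Either a single probability or a named vector
#'   over tumor types: the chance the rater's primary diagnosis equals the
#'   ground truth.
#' @param differential_similarity Square nonnegative matrix over tumor
#'   types; row `t` weights how plausible each other type is as a
#'   wrong/differential diagnosis when the truth is `t`. The diagonal is
#'   ignored. Default: [default_similarity()].
#' @param confidence_concentration Positive Dirichlet concentration of the
#'   raw confidence triple; smaller values give more peaked (confident)
#'   triples. The default 0.07 yields mean primary confidences near 0.9,
#'   matching the confidence levels experienced pathologists report for
#'   common tumor types.
#' @param scheme A [class_scheme()].
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(rater_id, primary_accuracy = 0.97,
                        differential_similarity = default_similarity(scheme),
                        confidence_concentration = 0.07,
                        scheme = class_scheme()) {
  types <- tumor_type_labels(scheme)
  if (length(primary_accuracy) == 1 && is.null(names(primary_accuracy))) {
    primary_accuracy <- stats::setNames(rep(primary_accuracy, length(types)),
                                        types)
  }
  if (!all(types %in% names(primary_accuracy))) {
    stop("primary_accuracy must cover every tumor type")
  }
  if (any(primary_accuracy < 0 | primary_accuracy > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  sim <- as.matrix(differential_similarity)
  if (!all(dim(sim) == length(types))) {
    stop("differential_similarity must be ", length(types), " x ",
         length(types))
  }
  if (any(sim < 0)) stop("similarity weights must be nonnegative")
  dimnames(sim) <- list(types, types)
  if (confidence_concentration <= 0) stop("concentration must be positive")
  structure(list(rater_id = as.character(rater_id),
                 primary_accuracy = primary_accuracy[types],
                 differential_similarity = sim,
                 confidence_concentration = confidence_concentration),
            class = "rater_model")
}

#' Default tumor-type similarity weights
#'
#' Histologic plausibility weights for wrong/differential diagnoses:
#' round cell tumors (histiocytoma, MCT, plasmacytoma) are mutually
#' similar, as are the epithelial tumors (SCC, trichoblastoma) and the
#' spindloid/melanocytic pair (PNST, melanoma); cross-group confusions get
#' low weight.
#'
#' @param scheme A [class_scheme()].
#' @return Square matrix over tumor types (diagonal zero).
#' @export
default_similarity <- function(scheme = class_scheme()) {
  types <- tumor_type_labels(scheme)
  groups <- list(round_cell = c("histiocytoma", "MCT", "plasmacytoma"),
                 epithelial = c("SCC", "trichoblastoma"),
                 spindloid = c("PNST", "melanoma"))
  sim <- matrix(1, length(types), length(types),
                dimnames = list(types, types))
  for (g in groups) sim[g, g] <- 3
  diag(sim) <- 0
  sim
}

#' Default panel of six raters
#'
#' @param n_raters Number of raters.
#' @param primary_accuracy Shared per-type accuracy (scalar or named).
#' @param confidence_concentration Shared concentration.
#' @param scheme A [class_scheme()].
#' @return List of [rater_model()]s with ids `rater1`, `rater2`, ...
#' @export
default_rater_panel <- function(n_raters = 6, primary_accuracy = 0.97,
                                confidence_concentration = 0.07,
                                scheme = class_scheme()) {
  lapply(seq_len(n_raters), function(i) {
    rater_model(sprintf("rater%d", i), primary_accuracy,
                confidence_concentration = confidence_concentration,
                scheme = scheme)
  })
}

#' Discretize a confidence triple to the reporting grid
#'
#' Maps three positive values summing to ~1 onto the 0.01 grid: sort
#' descending, largest-remainder rounding to integer hundredths summing to
#' exactly 100, then clip into `[1, 98]` hundredths with the residue
#' absorbed by the largest entry, and re-sort. The result always satisfies
#' the response constraints (grid values in `[0.01, 0.98]`, sum exactly
#' 1.00, non-increasing).
#'
#' @param x Numeric vector of length 3, positive, summing to ~1.
#' @return Integer vector of hundredths (length 3, decreasing, sum 100).
#' @export
discretize_confidence_triple <- function(x) {
  stopifnot(length(x) == 3, all(x >= 0))
  x <- sort(x / sum(x), decreasing = TRUE)
  raw <- x * 100
  lo <- floor(raw)
  short <- 100L - as.integer(sum(lo))
  if (short > 0) {
    rem_order <- order(raw - lo, decreasing = TRUE)
    lo[rem_order[seq_len(short)]] <- lo[rem_order[seq_len(short)]] + 1
  }
  h <- as.integer(lo)
  # clip into [1, 98]; push the imbalance onto the largest entry
  for (pass in 1:3) {
    clipped <- pmin(pmax(h, 1L), 98L)
    diff <- 100L - sum(clipped)
    if (diff != 0L) {
      j <- which.max(clipped)
      clipped[j] <- clipped[j] + diff
    }
    h <- clipped
    if (all(h >= 1L & h <= 98L) && sum(h) == 100L) break
  }
  sort(h, decreasing = TRUE)
}

# Sample one response for (rater, slide) under a fresh local seed.
sample_response <- function(rater, true_type, slide_id, seed,
                            scheme = class_scheme()) {
  types <- tumor_type_labels(scheme)
  with_seed(seed, {
    acc <- rater$primary_accuracy[[true_type]]
    correct <- stats::runif(1) < acc
    simrow <- rater$differential_similarity[true_type, ]
    if (correct) {
      primary <- true_type
    } else {
      w <- simrow
      w[true_type] <- 0
      primary <- sample(types, 1, prob = w)
    }
    # two distinct differentials drawn without replacement by similarity
    remaining <- setdiff(types, primary)
    w <- simrow[remaining]
    w[remaining == true_type] <- max(simrow)  # truth stays a likely differential
    if (all(w == 0)) w[] <- 1
    diffs <- sample(remaining, 2, prob = w)
    conc <- rater$confidence_concentration
    raw <- stats::rgamma(3, shape = conc)
    while (sum(raw) == 0) raw <- stats::rgamma(3, shape = conc)
    conf <- discretize_confidence_triple(raw / sum(raw))
    pathologist_response(rater$rater_id, slide_id,
                         c(primary, diffs), conf / 100, scheme = scheme)
  })
}

#' Generate a simulated pathologist panel
#'
#' For every (rater, slide) pair, draws a primary diagnosis (correct with
#' the rater's per-type probability, otherwise sampled by similarity to the
#' truth), two distinct differential diagnoses, and a confidence triple on
#' the 0.01 grid via [discretize_confidence_triple()]. Every emitted
#' response passes [validate_response()]. Per-(rater, slide) seeds derive
#' from `seed`, so output is independent of iteration order.
#'
#' @param slides List of `slide_record`s.
#' @param raters List of [rater_model()]s.
#' @param seed Integer master seed.
#' @param scheme A [class_scheme()].
#' @return data.frame with columns `rater_id`, `slide_id`, `dx1`, `conf1`,
#'   `dx2`, `conf2`, `dx3`, `conf3` (confidences numeric on the 0.01 grid).
#' @export
generate_pathologist_panel <- function(slides, raters, seed = 1L,
                                       scheme = class_scheme()) {
  if (length(raters) < 1) stop("need at least one rater")
  rows <- vector("list", length(slides) * length(raters))
  k <- 0L
  for (s in slides) {
    for (r in raters) {
      k <- k + 1L
      resp <- sample_response(
        r, s$true_tumor_type, s$slide_id,
        derive_seed(seed, paste0("panel/", r$rater_id, "/", s$slide_id)),
        scheme = scheme)
      rows[[k]] <- data.frame(
        rater_id = resp$rater_id, slide_id = resp$slide_id,
        dx1 = resp$diagnoses[1], conf1 = resp$confidences[1],
        dx2 = resp$diagnoses[2], conf2 = resp$confidences[2],
        dx3 = resp$diagnoses[3], conf3 = resp$confidences[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Convert a panel table to validated response objects
#'
#' @param panel data.frame as produced by [generate_pathologist_panel()]
#'   or read from a panel TSV.
#' @param scheme A [class_scheme()].
#' @return List of `pathologist_response` objects (each validated).
#' @export
panel_responses <- function(panel, scheme = class_scheme()) {
  lapply(seq_len(nrow(panel)), function(i) {
    pathologist_response(
      panel$rater_id[i], panel$slide_id[i],
      c(panel$dx1[i], panel$dx2[i], panel$dx3[i]),
      c(panel$conf1[i], panel$conf2[i], panel$conf3[i]),
      scheme = scheme)
  })
}
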