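#' Pathologist response
#'
#' One rater's ranked diagnoses for one slide: a primary diagnosis and two
#' differentials, each with a confidence value on the 0.01 grid in
#' `[0.01, 0.98]`. The three confidences must sum to exactly 1.00 and be
#' non-increasing (the primary carries the highest confidence).
#' Confidences are held internally as integer hundredths so the sum
#' constraint is exact, free of floating-point drift.
#'
#' @param rater_id,slide_id Identifiers.
#' @param diagnoses Character vector of 3 distinct tumor-type labels,
#'   primary first.
#' @param confidences Numeric vector of 3 grid values (e.g. `c(0.7, 0.2, 0.1)`).
#' @param scheme A [class_scheme()].
#' @return A validated object of class `pathologist_response` with fields
#'   `rater_id`, `slide_id`, `diagnoses`, `confidences` (numeric) and
#'   `confidences_hundredths` (integer).
#' @export
pathologist_response <- function(rater_id, slide_id, diagnoses, confidences,
                                 scheme = class_scheme()) {
  resp <- structure(
    list(rater_id = as.character(rater_id),
         slide_id = as.character(slide_id),
         diagnoses = as.character(diagnoses),
         confidences = as.numeric(confidences),
         confidences_hundredths = as.integer(round(confidences * 100))),
    class = "pathologist_response")
  validate_response(resp, scheme = scheme)
}

#' Validate a pathologist response
#'
#' Checks every response invariant and raises a specific error naming the
#' first violation: three distinct known tumor types; confidences on the
#' 0.01 grid; each in `[0.01, 0.98]`; sum exactly 1.00; primary confidence
#' maximal (non-increasing triple).
#'
#' @param response A `pathologist_response` (or a bare list with the same
#'   fields).
#' @param scheme A [class_scheme()].
#' @return The response, invisibly, if valid.
#' @export
validate_response <- function(response, scheme = class_scheme()) {
  d <- response$diagnoses
  cf <- response$confidences
  if (length(d) != 3) stop("response must carry exactly 3 diagnoses")
  if (anyDuplicated(d)) stop("duplicate diagnoses in response")
  bad <- setdiff(d, tumor_type_labels(scheme))
  if (length(bad) > 0) stop("unknown tumor type in response: ",
                            paste(bad, collapse = ", "))
  if (length(cf) != 3) stop("response must carry exactly 3 confidences")
  h <- cf * 100
  if (any(abs(h - round(h)) > 1e-6)) {
    stop("confidence off the 0.01 grid: ",
         paste(format(cf[abs(h - round(h)) > 1e-6]), collapse = ", "))
  }
  h <- as.integer(round(h))
  if (any(h < 1L | h > 98L)) {
    stop("confidence outside [0.01, 0.98]: ",
         paste(format(cf[h < 1L | h > 98L]), collapse = ", "))
  }
  if (sum(h) != 100L) {
    stop("confidences must sum to exactly 1.00 (got ",
         format(sum(h) / 100), ")")
  }
  if (is.unsorted(rev(h))) {
    stop("primary diagnosis must carry the highest confidence")
  }
  response$confidences_hundredths <- h
  invisible(response)
}

#' @export
print.pathologist_response <- function(x, ...) {
  cat(sprintf("<response> %s on %s: %s\n", x$rater_id, x$slide_id,
              paste(sprintf("%s (%.2f)", x$diagnoses, x$confidences),
                    collapse = ", ")))
  invisible(x)
}

#' Panel consensus for one slide
#'
#' Majority vote over the raters' primary diagnoses. The modal primary is
#' the consensus primary; a draw is broken by the higher mean confidence
#' among the raters who cast that label as their primary (a second-level
#' tie falls back to canonical tumor-type order), with `draw_resolved`
#' flagged. The first and second differential consensus are the next
#' labels by the same (vote count, mean confidence) ordering. The decimal
#' consensus is the number of raters whose primary equals the consensus
#' primary.
#'
#' @param responses List of validated `pathologist_response`s for one slide.
#' @param scheme A [class_scheme()].
#' @return An object of class `consensus_diagnosis`: `slide_id`, `primary`,
#'   `differential1`, `differential2` (may be `NA`), `vote_counts`,
#'   `mean_confidence` (both named over voted labels), `decimal_consensus`,
#'   `draw_resolved`.
#' @export
consensus_vote <- function(responses, scheme = class_scheme()) {
  if (length(responses) < 1) stop("need at least one response")
  for (r in responses) validate_response(r, scheme = scheme)
  slide_id <- unique(vapply(responses, function(r) r$slide_id, character(1)))
  if (length(slide_id) != 1) {
    stop("responses span multiple slides: ", paste(slide_id, collapse = ", "))
  }
  primaries <- vapply(responses, function(r) r$diagnoses[1], character(1))
  conf_h <- vapply(responses, function(r) r$confidences_hundredths[1],
                   integer(1))
  labels <- unique(primaries)
  votes <- vapply(labels, function(l) sum(primaries == l), integer(1))
  meanc <- vapply(labels, function(l) mean(conf_h[primaries == l]),
                  numeric(1))
  canon <- match(labels, tumor_type_labels(scheme))
  ord <- order(-votes, -meanc, canon)
  ranked <- labels[ord]
  top_votes <- votes[ord][1]
  draw <- sum(votes == top_votes) > 1
  structure(
    list(slide_id = slide_id,
         primary = ranked[1],
         differential1 = if (length(ranked) >= 2) ranked[2] else NA_character_,
         differential2 = if (length(ranked) >= 3) ranked[3] else NA_character_,
         vote_counts = stats::setNames(votes[ord], ranked),
         mean_confidence = stats::setNames(meanc[ord] / 100, ranked),
         decimal_consensus = as.numeric(top_votes),
         draw_resolved = draw),
    class = "consensus_diagnosis")
}

#' @export
print.consensus_diagnosis <- function(x, ...) {
  cat(sprintf("<consensus> %s: primary=%s (%g/%d votes%s), diff1=%s, diff2=%s\n",
              x$slide_id, x$primary, x$decimal_consensus,
              sum(x$vote_counts),
              if (x$draw_resolved) ", draw resolved by confidence" else "",
              x$differential1, x$differential2))
  invisible(x)
}

#' Accumulated decimal consensus
#'
#' The decimal consensus of a slide is the number of raters (0 to
#' `n_raters`) whose primary diagnosis matched the consensus primary. The
#' accumulated value for a tumor type is the arithmetic mean over its
#' slides; e.g. slides with 4/6 and 5/6 agreeing raters accumulate to
#' `(4 + 5) / 2 = 4.5`.
#'
#' @param values Numeric vector of per-slide decimal consensus values.
#' @return Their arithmetic mean.
#' @export
decimal_consensus_accumulate <- function(values) {
  if (length(values) == 0) stop("no decimal consensus values supplied")
  mean(values)
}

#' Consensus table for a whole panel
#'
#' Runs [consensus_vote()] per slide over a panel table.
#'
#' @param panel data.frame as from [generate_pathologist_panel()].
#' @param scheme A [class_scheme()].
#' @return data.frame: `slide_id`, `primary`, `differential1`,
#'   `differential2`, `decimal_consensus`, `draw_resolved`.
#' @export
consensus_for_panel <- function(panel, scheme = class_scheme()) {
  out <- lapply(split(panel, panel$slide_id), function(df) {
    cv <- consensus_vote(panel_responses(df, scheme), scheme)
    data.frame(slide_id = cv$slide_id, primary = cv$primary,
               differential1 = cv$differential1,
               differential2 = cv$differential2,
               decimal_consensus = cv$decimal_consensus,
               draw_resolved = cv$draw_resolved,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
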