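## Instrument scoring: PRHISM (13 principles, 0-4, NA allowed), DISCERN
## (15 items + overall, 1-5), expert accuracy/harm recoding, and the 0-100
## score conversions with their quality bands.

N_PRHISM_ITEMS <- 13L
N_DISCERN_ITEMS <- 15L

check_ordinal <- function(x, lo, hi, what, n_expected = NULL, na_ok = TRUE) {
  if (!is.null(n_expected) && length(x) != n_expected)
    stop(sprintf("expected exactly %d %s, got %d", n_expected, what, length(x)))
  v <- x[!is.na(x)]
  if (!na_ok && anyNA(x)) stop(what, " may not contain NA")
  if (length(v) && (any(v != round(v)) || any(v < lo) || any(v > hi)))
    stop(sprintf("%s values must be integers in %d..%d", what, lo, hi))
  invisible(x)
}

#' PRHISM score out of 100
#'
#' The 13 PRHISM principles are each rated 0-4; principles judged not
#' applicable are recorded `NA` and excluded. The score is the achieved
#' fraction of the maximum over applicable principles, on a 0-100 scale:
#' `100 * sum(non-NA scores) / (4 * n_applicable)`. The separate overall
#' 0-4 judgment (added for agreement analyses) never enters this score.
#'
#' @param principle_scores length-13 vector of integers 0-4 or `NA`.
#' @return list of class `scored_rating`: `score` (0-100), `n_applicable`,
#'   `category` (quality band, see [prhism_category()]), `instrument`.
#' @examples
#' prhism_score(rep(4, 13))$score  # 100
#' # 10 applicable principles summing to 25, 3 not applicable:
#' prhism_score(c(4, 4, 4, 4, 4, 2, 1, 1, 1, 0, NA, NA, NA))$score  # 62.5
#' @export
prhism_score <- function(principle_scores) {
  check_ordinal(principle_scores, 0L, 4L, "PRHISM principle scores",
                n_expected = N_PRHISM_ITEMS)
  n_app <- sum(!is.na(principle_scores))
  if (n_app == 0L)
    stop("no applicable items: all 13 PRHISM principles are NA")
  score <- 100 * sum(principle_scores, na.rm = TRUE) / (4 * n_app)
  structure(list(score = score, n_applicable = n_app,
                 category = prhism_category(score), instrument = "prhism"),
            class = "scored_rating")
}

#' Quality band of a 0-100 PRHISM-type score
#'
#' Printed band definitions are integer ranges: 0-25 poor, 26-50 mediocre,
#' 51-75 good, 76-100 excellent. Fractional scores are rounded half-up to the
#' nearest integer before banding, so 62.5 rounds to 63 and falls in `good`.
#' Bands carry ordinal codes 1 = poor ... 4 = excellent (used when the band
#' classification itself is analysed for agreement).
#'
#' @param score numeric vector in [0, 100].
#' @return factor with ordered levels `poor < mediocre < good < excellent`.
#' @examples
#' prhism_category(c(80, 25, 62.5))
#' @export
prhism_category <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 100))
    stop("score must be in [0, 100]")
  s <- round_half_up(score)
  factor(cut(s, breaks = c(-1, 25, 50, 75, 100),
             labels = c("poor", "mediocre", "good", "excellent")),
         levels = c("poor", "mediocre", "good", "excellent"), ordered = TRUE)
}

#' Total DISCERN score out of 80
#'
#' Sum of the 15 DISCERN items plus the overall quality rating, all on 1-5;
#' the total therefore ranges 16-80. `NA` items are not allowed here: when an
#' item was judged not applicable, use [modified_discern_score()], which
#' rescales over the applicable items.
#'
#' @param item_scores length-15 vector of integers 1-5 (no `NA`).
#' @param overall overall quality rating, integer 1-5.
#' @return integer total in 16..80.
#' @examples
#' discern_total(rep(5, 15), overall = 5)  # 80
#' @export
discern_total <- function(item_scores, overall) {
  if (anyNA(item_scores))
    stop("NA items present: use modified_discern_score(), ",
         "which rescales over the applicable items")
  check_ordinal(item_scores, 1L, 5L, "DISCERN item scores",
                n_expected = N_DISCERN_ITEMS, na_ok = FALSE)
  check_ordinal(overall, 1L, 5L, "DISCERN overall", n_expected = 1L,
                na_ok = FALSE)
  as.integer(sum(item_scores) + overall)
}

#' Modified DISCERN score out of 100
#'
#' The overall quality rating is removed from the DISCERN total and the
#' remaining 15 items are converted to a 0-100 scale over the applicable
#' (non-`NA`) items: `100 * sum(non-NA items) / (5 * n_applicable)`. Because
#' items floor at 1, the minimum attainable score is 20.
#'
#' The not-applicable rescaling mirrors the PRHISM rule (mean over applicable
#' items); a message flags when it is actually invoked.
#'
#' @param item_scores length-15 vector of integers 1-5 or `NA`.
#' @return list of class `scored_rating`: `score` (20-100), `n_applicable`,
#'   `category` (`NA`; no published banding for this score), `instrument`.
#' @examples
#' modified_discern_score(rep(1, 15))$score  # 20
#' @export
modified_discern_score <- function(item_scores) {
  check_ordinal(item_scores, 1L, 5L, "DISCERN item scores",
                n_expected = N_DISCERN_ITEMS)
  n_app <- sum(!is.na(item_scores))
  if (n_app == 0L)
    stop("no applicable items: all 15 DISCERN items are NA")
  if (n_app < N_DISCERN_ITEMS)
    message("DISCERN not-applicable rescaling in effect: ",
            N_DISCERN_ITEMS - n_app, " item(s) excluded from the denominator")
  score <- 100 * sum(item_scores, na.rm = TRUE) / (5 * n_app)
  structure(list(score = score, n_applicable = n_app,
                 category = NA, instrument = "discern"),
            class = "scored_rating")
}

#' Recode expert accuracy/harm ratings so 5 = accurate / nonharmful
#'
#' The expert assessment tool scores accuracy 5 = true ... 1 = false and harm
#' 5 = certainly not harmful ... 1 = certainly harmful, but its original
#' orientation rates accurate (or nonharmful) information as 1. To align with
#' the quality instruments (higher = better), values are reversed:
#' `value -> 6 - value`, so 5 means accurate / nonharmful. The map is an
#' involution (applying it twice returns the input).
#'
#' @param raw_accuracy,raw_harm integers 1-5 on the original orientation
#'   (1 = accurate / not harmful).
#' @param reason_text optional free-text justification, carried through.
#' @return list of class `expert_assessment`: `accuracy`, `harm` (both
#'   recoded, 5 = accurate / nonharmful), `reason_text`.
#' @examples
#' recode_expert(1, 5)  # accuracy 5, harm 1
#' @export
recode_expert <- function(raw_accuracy, raw_harm, reason_text = NULL) {
  check_ordinal(raw_accuracy, 1L, 5L, "accuracy", na_ok = FALSE)
  check_ordinal(raw_harm, 1L, 5L, "harm", na_ok = FALSE)
  structure(list(accuracy = 6L - as.integer(raw_accuracy),
                 harm = 6L - as.integer(raw_harm),
                 reason_text = reason_text),
            class = "expert_assessment")
}

#' @export
print.scored_rating <- function(x, ...) {
  cat(sprintf("%s score: %.1f / 100 (%d applicable item%s)",
              toupper(x$instrument), x$score, x$n_applicable,
              if (x$n_applicable == 1) "" else "s"))
  if (!is.na(x$category[1])) cat(sprintf("  [%s]", as.character(x$category)))
  cat("\n")
  invisible(x)
}

#' @export
print.expert_assessment <- function(x, ...) {
  cat(sprintf("Expert assessment (recoded, 5 = accurate/nonharmful): accuracy %d, harm %d\n",
              x$accuracy, x$harm))
  invisible(x)
}
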