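## Synthetic study-shaped data: video catalog with source categories and
## metadata, exclusion filtering, rater profiles in two experience strata,
## and full multi-instrument rating sets with a controllable pairwise kappa.

## Source-category proportions of the selected-video table: counts
## (6, 4, 9, 0, 15, 13, 12, 1) out of 60 across the eight uploader categories.
DEFAULT_SOURCE_PROBS <- c(6, 4, 9, 0, 15, 13, 12, 1) / 60

SOURCE_CATEGORY_LABELS <- c(
  "health profession schools / educational institutions",
  "health care facilities",
  "nonprofit health plans",
  "public health departments",
  "individual health care professionals",
  "entertainment, media, news",
  "personal blogs",
  "other")

EXCLUSION_CRITERIA <- c("other_language", "low_views", "too_short",
                        "irrelevant", "no_audio", "shorts_format",
                        "duplicate", "advertisement")

#' Generate a synthetic video catalog
#'
#' Emulates the selected-video table of a social-media quality study: source
#' categories are multinomial over the eight uploader categories (categories
#' 1-4 are the reliable sources), video length / view counts / months since
#' posting are long-tailed (log-normal) with parameters bracketing the
#' published ranges (length 1-126 min, views 3,921-978,676, months 7-123),
#' and each video carries a latent quality in [0, 1] with a positive shift
#' for reliable sources. Exclusion flag columns are all `FALSE`; set them (or
#' the views/length fields) to exercise [apply_exclusions()].
#'
#' @param n number of videos.
#' @param source_probs probabilities over the 8 source categories (default:
#'   the published study proportions).
#' @param reliable_shift upward shift (logit scale) of latent quality for
#'   reliable-source videos.
#' @param seed optional integer seed.
#' @return data frame of class `video_catalog`: `video_id, source_category,
#'   reliable, length_min, views, months_since_post, latent_quality` plus the
#'   exclusion flag columns.
#' @export
generate_catalog <- function(n, source_probs = DEFAULT_SOURCE_PROBS,
                             reliable_shift = 0.8, seed = NULL) {
  source_probs <- category_distribution(source_probs)
  if (length(source_probs) != 8L) stop("`source_probs` must have length 8")
  with_seed(seed, {
    if (n == 0L) {
      df <- data.frame(video_id = character(0), source_category = integer(0),
                       reliable = logical(0), length_min = numeric(0),
                       views = integer(0), months_since_post = integer(0),
                       latent_quality = numeric(0))
      for (fl in EXCLUSION_CRITERIA[-(2:3)]) df[[fl]] <- logical(0)
      class(df) <- c("video_catalog", "data.frame")
      return(df)
    }
    cat8 <- sample.int(8L, n, replace = TRUE, prob = source_probs)
    reliable <- cat8 <= 4L
    ## log-normal metadata spanning the printed ranges
    length_min <- pmin(pmax(stats::rlnorm(n, meanlog = log(8), sdlog = 1.1),
                            0.2), 300)
    views <- as.integer(pmin(stats::rlnorm(n, meanlog = log(30000), sdlog = 1.2),
                             2e6))
    months <- as.integer(pmax(round(stats::rlnorm(n, meanlog = log(29),
                                                  sdlog = 0.75)), 0))
    quality <- stats::plogis(stats::rnorm(n, mean = -0.2 + reliable_shift * reliable,
                                          sd = 1.0))
    df <- data.frame(
      video_id = sprintf("v%03d", seq_len(n)),
      source_category = cat8,
      reliable = reliable,
      length_min = round(length_min, 1),
      views = views,
      months_since_post = months,
      latent_quality = quality,
      stringsAsFactors = FALSE)
    for (fl in EXCLUSION_CRITERIA[-(2:3)]) df[[fl]] <- FALSE
    class(df) <- c("video_catalog", "data.frame")
    df
  })
}

#' Apply the study exclusion criteria to a candidate catalog
#'
#' Keeps records with views >= 3000, length >= 1 minute, and all exclusion
#' flags clean. The tally reports one count per criterion in the study's
#' numbered order -- (1) other language, (2) fewer than 3000 views,
#' (3) shorter than 60 seconds, (4) irrelevant, (5) no audio, (6) shorts,
#' (7) duplicate, (8) advertisement -- and a record failing several criteria
#' is counted once under the first.
#'
#' @param records catalog data frame carrying `views`, `length_min` and the
#'   boolean flag columns `other_language, irrelevant, no_audio,
#'   shorts_format, duplicate, advertisement`.
#' @return list: `kept` (filtered catalog), `excluded` (dropped records with
#'   an `exclusion_reason` column), `tally` (named integer vector in the
#'   criteria order).
#' @export
apply_exclusions <- function(records) {
  flags <- cbind(
    other_language = records$other_language,
    low_views      = records$views < 3000,
    too_short      = records$length_min < 1,
    irrelevant     = records$irrelevant,
    no_audio       = records$no_audio,
    shorts_format  = records$shorts_format,
    duplicate      = records$duplicate,
    advertisement  = records$advertisement)
  first_hit <- apply(flags, 1L, function(f) {
    i <- which(f)
    if (length(i)) i[1] else NA_integer_
  })
  excluded <- !is.na(first_hit)
  tally <- vapply(seq_along(EXCLUSION_CRITERIA),
                  function(i) sum(first_hit == i, na.rm = TRUE), integer(1))
  names(tally) <- EXCLUSION_CRITERIA
  out_excluded <- records[excluded, , drop = FALSE]
  if (nrow(out_excluded))
    out_excluded$exclusion_reason <- EXCLUSION_CRITERIA[first_hit[excluded]]
  list(kept = records[!excluded, , drop = FALSE],
       excluded = out_excluded,
       tally = tally)
}

#' Default rater panel: six physicians in two experience strata
#'
#' Three senior raters (more than 10 years as a physician) and three junior
#' raters, mirroring the study panel's years of experience. `severity_bias`
#' and `noise_sd` govern the item-level jitter in [generate_ratings()].
#'
#' @param physician_years integer vector of years of experience (one per
#'   rater); the stratum is senior iff years > 10.
#' @param expert_years years as a breast-cancer expert, same length.
#' @param severity_bias per-rater additive bias applied to item jitter.
#' @param noise_sd per-rater jitter standard deviation (> 0).
#' @return data frame of class `rater_panel`: `rater_id, physician_years,
#'   expert_years, stratum, severity_bias, noise_sd`.
#' @export
rater_panel <- function(physician_years = c(8, 9, 10, 16, 24, 37),
                        expert_years = c(1, 2, 2, 7, 15, 20),
                        severity_bias = rep(0, length(physician_years)),
                        noise_sd = rep(0.7, length(physician_years))) {
  n <- length(physician_years)
  stopifnot(length(expert_years) == n, length(severity_bias) == n,
            length(noise_sd) == n, all(noise_sd >= 0))
  df <- data.frame(
    rater_id = sprintf("r%d", seq_len(n)),
    physician_years = as.integer(physician_years),
    expert_years = as.integer(expert_years),
    stratum = ifelse(physician_years > 10, "senior", "junior"),
    severity_bias = severity_bias,
    noise_sd = noise_sd,
    stringsAsFactors = FALSE)
  class(df) <- c("rater_panel", "data.frame")
  df
}

## ordinal jitter: value + rounded gaussian noise + bias, clipped to support
jitter_ordinal <- function(center, noise_sd, bias, lo, hi) {
  v <- round(center + bias + stats::rnorm(length(center), sd = noise_sd))
  pmin(pmax(v, lo), hi)
}

#' Generate a full multi-instrument study dataset
#'
#' Builds the complete rating set a validation study produces, with a
#' controllable true pairwise agreement:
#' * per-video truth categories (0-4) derive from `latent_quality` through
#'   fixed quantile thresholds, so the truth marginal follows `marginal`
#'   independently of the agreement level;
#' * each rater's PRHISM and DISCERN overall-quality ratings come from the
#'   copy model calibrated so the population pairwise weighted kappa equals
#'   `agreement` (theta = sqrt(agreement));
#' * the 13 PRHISM items are the rater's overall plus per-item ordinal jitter
#'   clipped to 0-4, with independent per-item not-applicable probability;
#' * the 15 DISCERN items likewise on 1-5 around the DISCERN overall;
#' * expert accuracy/harm are a monotone map of latent quality plus rater
#'   noise on 1-5, already oriented so 5 = accurate / nonharmful.
#'
#' @param catalog a [generate_catalog()] data frame (or any data frame with
#'   `video_id` and `latent_quality`).
#' @param raters a [rater_panel()].
#' @param agreement target population pairwise weighted kappa in [0, 1].
#' @param marginal 5-category truth distribution (categories 0-4).
#' @param na_prob probability a PRHISM item is judged not applicable; a
#'   scalar or one probability per principle (length 13).
#' @param item_noise_sd NULL to use each rater's `noise_sd`, or a single
#'   override.
#' @param expert_noise_sd sd of the expert-rating noise.
#' @param seed optional integer seed.
#' @return list of class `study_dataset`: `catalog`, `raters`, `ratings`
#'   (long-format data frame), `truth` (per-video 0-4 truth category) and
#'   `provenance` (generator parameters).
#' @export
generate_ratings <- function(catalog, raters = rater_panel(),
                             agreement = 0.61,
                             marginal = pilot_marginal_synthetic(),
                             na_prob = 0.10,
                             item_noise_sd = NULL,
                             expert_noise_sd = 0.8,
                             seed = NULL) {
  marginal <- category_distribution(marginal)
  if (length(marginal) != 5L) stop("`marginal` must have 5 categories (0-4)")
  theta <- calibrate_theta(agreement, marginal, "quadratic")
  na_vec <- rep_len(na_prob, 13L)  # scalar or one probability per principle
  n <- nrow(catalog); R <- nrow(raters)
  if (n < 1L) stop("empty catalog")
  with_seed(seed, {
    ## fixed quantile thresholds on latent quality -> truth categories 0..4
    cum <- cumsum(marginal)[1:4]
    thresholds <- stats::quantile(catalog$latent_quality, probs = cum,
                                  type = 1, names = FALSE)
    truth <- findInterval(catalog$latent_quality, thresholds,
                          left.open = TRUE)   # 0..4
    model <- rater_model(theta, marginal)
    ## copy-model overall ratings, one independent draw per instrument
    overall_p <- simulate_ratings_from_truth(truth + 1L, R, model) - 1L  # 0..4
    overall_d <- simulate_ratings_from_truth(truth + 1L, R, model)       # 1..5
    sd_items <- if (is.null(item_noise_sd)) raters$noise_sd else
      rep_len(item_noise_sd, R)
    rows <- vector("list", R)
    for (j in seq_len(R)) {
      rid <- raters$rater_id[j]
      bias <- raters$severity_bias[j]
      ## PRHISM: 13 principles around this rater's overall, NA mechanism
      p_items <- vapply(1:13, function(it)
        jitter_ordinal(overall_p[, j], sd_items[j], bias, 0L, 4L),
        numeric(n))
      if (any(na_vec > 0)) {
        na_mask <- matrix(stats::runif(n * 13), n, 13) <
          matrix(na_vec, n, 13, byrow = TRUE)
        p_items[na_mask] <- NA
      }
      ## DISCERN: 15 items around the DISCERN overall (no NA by default:
      ## the study's not-applicable convention is a PRHISM feature)
      d_items <- vapply(1:15, function(it)
        jitter_ordinal(overall_d[, j], sd_items[j], bias, 1L, 5L),
        numeric(n))
      ## expert accuracy/harm: monotone in latent quality (through the truth
      ## category), rater noise, already on the recoded 5 = good orientation
      acc <- jitter_ordinal(truth + 1L, expert_noise_sd, bias, 1L, 5L)
      harm <- jitter_ordinal(truth + 1L, expert_noise_sd, bias, 1L, 5L)
      rows[[j]] <- data.frame(
        video_id = rep(catalog$video_id, times = 13 + 1 + 15 + 1 + 2),
        rater_id = rid,
        instrument = rep(c(rep("prhism", 14), rep("discern", 16),
                           "expert", "expert"), each = n),
        item = rep(c(paste0("p", 1:13), "overall",
                     paste0("d", 1:15), "overall",
                     "accuracy", "harm"), each = n),
        value = c(as.vector(p_items), overall_p[, j],
                  as.vector(d_items), overall_d[, j],
                  acc, harm),
        stringsAsFactors = FALSE)
    }
    ratings <- do.call(rbind, rows)
    ratings <- ratings[order(ratings$video_id, ratings$rater_id,
                             ratings$instrument, ratings$item), ]
    rownames(ratings) <- NULL
    structure(list(catalog = catalog, raters = raters, ratings = ratings,
                   truth = truth,
                   provenance = list(agreement = agreement, theta = theta,
                                     marginal = marginal, na_prob = na_prob,
                                     expert_noise_sd = expert_noise_sd,
                                     seed = seed)),
              class = "study_dataset")
  })
}

## copy-model ratings given fixed truth categories (codes 1..K)
simulate_ratings_from_truth <- function(truth, n_raters, model) {
  pi <- model$marginal
  K <- length(pi)
  n <- length(truth)
  th <- rep_len(model$theta, n_raters)
  copy <- matrix(stats::runif(n * n_raters), n, n_raters) <=
    matrix(th, n, n_raters, byrow = TRUE)
  noise <- matrix(sample.int(K, n * n_raters, replace = TRUE, prob = pi),
                  n, n_raters)
  out <- ifelse(copy, matrix(truth, n, n_raters), noise)
  storage.mode(out) <- "integer"
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Synthetic study dataset: %d videos x %d raters, %d rating rows\n",
              nrow(x$catalog), nrow(x$raters), nrow(x$ratings)))
  cat(sprintf("  target pairwise kappa %.2f (theta %.4f), PRHISM item NA prob %.2f\n",
              x$provenance$agreement, x$provenance$theta, x$provenance$na_prob))
  invisible(x)
}

#' Summarise a video catalog
#'
#' Median and range for length, views and months since posting, plus count
#' and percent per source category (the selected-video table shape).
#'
#' @param catalog a catalog data frame.
#' @return list with `continuous` (data frame: variable, median, min, max)
#'   and `sources` (data frame: category, label, n, percent).
#' @export
summarize_catalog <- function(catalog) {
  if (nrow(catalog) == 0L) stop("empty catalog")
  cont <- data.frame(
    variable = c("length_min", "views", "months_since_post"),
    median = c(stats::median(catalog$length_min), stats::median(catalog$views),
               stats::median(catalog$months_since_post)),
    min = c(min(catalog$length_min), min(catalog$views),
            min(catalog$months_since_post)),
    max = c(max(catalog$length_min), max(catalog$views),
            max(catalog$months_since_post)))
  counts <- vapply(1:8, function(k) sum(catalog$source_category == k),
                   integer(1))
  sources <- data.frame(category = 1:8, label = SOURCE_CATEGORY_LABELS,
                        n = counts,
                        percent = round_half_up(100 * counts / nrow(catalog)))
  list(continuous = cont, sources = sources)
}

#' Write a study dataset as CSV files plus a provenance JSON
#'
#' Writes `ratings.csv` (long format), `catalog.csv`, `raters.csv` and
#' `provenance.json` into `dir`. Byte-identical output for identical inputs.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings(dataset$ratings, file.path(dir, "ratings.csv"))
  write_catalog(dataset$catalog, file.path(dir, "catalog.csv"))
  utils::write.csv(dataset$raters, file.path(dir, "raters.csv"),
                   row.names = FALSE, quote = FALSE)
  prov <- dataset$provenance
  prov$marginal <- as.numeric(prov$marginal)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
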