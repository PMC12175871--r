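## Long-format ratings and catalog CSV dialects, strict validation, and the
## subjects x raters matrix extraction the agreement analyses consume.

RATINGS_COLUMNS <- c("video_id", "rater_id", "instrument", "item", "value")
INSTRUMENTS <- c("prhism", "discern", "expert")
PRHISM_ITEMS <- c(paste0("p", 1:13), "overall")
DISCERN_ITEMS <- c(paste0("d", 1:15), "overall")
EXPERT_ITEMS <- c("accuracy", "harm")

valid_items <- function(instrument) {
  switch(instrument,
         prhism = PRHISM_ITEMS,
         discern = DISCERN_ITEMS,
         expert = EXPERT_ITEMS,
         stop("unknown instrument: ", instrument))
}

#' Validate a long-format ratings table
#'
#' One row per (video, rater, instrument, item, value). Not-applicable values
#' are the literal token `NA`; empty value cells are rejected rather than
#' coerced. Item names must match the instrument (`p1`-`p13`/`overall`,
#' `d1`-`d15`/`overall`, `accuracy`/`harm`) and values the instrument's
#' support (PRHISM 0-4, DISCERN 1-5, expert 1-5); `overall`, `accuracy` and
#' `harm` may not be `NA`.
#'
#' @param ratings data frame with columns
#'   `video_id, rater_id, instrument, item, value`.
#' @return the validated data frame, invisibly, with `value` as integer.
#' @export
validate_ratings <- function(ratings) {
  missing_cols <- setdiff(RATINGS_COLUMNS, names(ratings))
  if (length(missing_cols))
    stop("ratings table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(ratings) == 0L) stop("ratings table has no rows")
  bad_instr <- setdiff(unique(ratings$instrument), INSTRUMENTS)
  if (length(bad_instr))
    stop("unknown instrument value(s): ", paste(bad_instr, collapse = ", "))
  if (is.character(ratings$value)) {
    v <- trimws(ratings$value)
    if (any(v == ""))
      stop("empty value cells are not allowed; use the literal token NA")
    out <- suppressWarnings(as.integer(v))
    if (any(is.na(out) & v != "NA"))
      stop("non-integer value cell(s); only integers or the token NA allowed")
    ratings$value <- out
  } else {
    ratings$value <- as.integer(ratings$value)
  }
  for (instr in unique(ratings$instrument)) {
    rows <- ratings$instrument == instr
    bad_item <- setdiff(unique(ratings$item[rows]), valid_items(instr))
    if (length(bad_item))
      stop("invalid item(s) for instrument ", instr, ": ",
           paste(bad_item, collapse = ", "))
    v <- ratings$value[rows]
    lo <- if (instr == "prhism") 0L else 1L
    hi <- if (instr == "prhism") 4L else 5L
    if (any(!is.na(v) & (v < lo | v > hi)))
      stop(sprintf("%s values must lie in %d..%d", instr, lo, hi))
    no_na_items <- if (instr == "expert") EXPERT_ITEMS else "overall"
    if (any(is.na(v) & ratings$item[rows] %in% no_na_items))
      stop(instr, ": ", paste(no_na_items, collapse = "/"),
           " ratings may not be NA")
  }
  invisible(ratings)
}

#' Read / write the long-format ratings CSV
#'
#' Strict header validation (exact column set) and the `NA`-token convention
#' of [validate_ratings()].
#'
#' @param path file path.
#' @return `read_ratings()`: validated data frame.
#' @export
read_ratings <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(sort(header), sort(RATINGS_COLUMNS)))
    stop("ratings CSV header must be exactly: ",
         paste(RATINGS_COLUMNS, collapse = ", "),
         " (got: ", paste(header, collapse = ", "), ")")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)  # keep the literal NA token
  validate_ratings(df)
}

#' @rdname read_ratings
#' @param ratings validated ratings data frame.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  out <- ratings[, RATINGS_COLUMNS]
  out$value <- ifelse(is.na(out$value), "NA", as.character(out$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the video catalog CSV
#'
#' @param path file path.
#' @return `read_catalog()`: data frame with at least `video_id`,
#'   `source_category` (1-8) and `reliable` (recomputed as category <= 4).
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("video_id", "source_category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("catalog CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!df$source_category %in% 1:8))
    stop("source_category must be an integer 1..8")
  df$reliable <- df$source_category <= 4L
  df
}

#' @rdname read_catalog
#' @param catalog catalog data frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a videos x raters matrix for one instrument item
#'
#' @param ratings validated long-format ratings.
#' @param instrument `"prhism"`, `"discern"` or `"expert"`.
#' @param item item name (e.g. `"overall"`, `"p3"`, `"accuracy"`).
#' @param video_ids,rater_ids optional subsets (and ordering) to extract.
#' @return numeric matrix, rows = videos, cols = raters, `NA` where absent.
#' @export
ratings_matrix <- function(ratings, instrument, item,
                           video_ids = NULL, rater_ids = NULL) {
  sub <- ratings[ratings$instrument == instrument & ratings$item == item, ]
  if (nrow(sub) == 0L)
    stop("no ratings found for ", instrument, " item ", item)
  if (is.null(video_ids)) video_ids <- sort(unique(sub$video_id))
  if (is.null(rater_ids)) rater_ids <- sort(unique(sub$rater_id))
  sub <- sub[sub$video_id %in% video_ids & sub$rater_id %in% rater_ids, ]
  if (anyDuplicated(sub[, c("video_id", "rater_id")]))
    stop("duplicate (video, rater) rating for ", instrument, " item ", item)
  m <- matrix(NA_real_, length(video_ids), length(rater_ids),
              dimnames = list(video_ids, rater_ids))
  m[cbind(match(sub$video_id, video_ids), match(sub$rater_id, rater_ids))] <-
    sub$value
  m
}

#' Score every (video, rater) sheet in a ratings table
#'
#' Applies [prhism_score()] and [modified_discern_score()] to each rater's
#' sheet for each video and returns one row per (video, rater, instrument).
#'
#' @param ratings validated long-format ratings.
#' @return data frame: `video_id, rater_id, instrument, score, n_applicable,
#'   category`.
#' @export
score_dataset <- function(ratings) {
  ratings <- validate_ratings(ratings)
  specs <- list(prhism = list(items = paste0("p", 1:13), item_max = 4),
                discern = list(items = paste0("d", 1:15), item_max = 5))
  out <- list()
  for (instr in names(specs)) {
    sub <- ratings[ratings$instrument == instr &
                     ratings$item %in% specs[[instr]]$items, ]
    if (nrow(sub) == 0L) next
    key <- interaction(sub$video_id, sub$rater_id, drop = TRUE, sep = "\r")
    total <- as.vector(tapply(sub$value, key, sum, na.rm = TRUE))
    n_app <- as.vector(tapply(!is.na(sub$value), key, sum))
    if (any(n_app == 0L))
      stop("no applicable items on some (video, rater) ", instr, " sheet")
    score <- 100 * total / (specs[[instr]]$item_max * n_app)
    parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
    out[[instr]] <- data.frame(
      video_id = parts[, 1], rater_id = parts[, 2], instrument = instr,
      score = score, n_applicable = as.integer(n_app),
      ## the PRHISM bands are reused for the modified DISCERN score (it has
      ## no published banding of its own)
      category = as.character(prhism_category(score)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$video_id, res$rater_id, res$instrument), ]
  rownames(res) <- NULL
  res
}
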