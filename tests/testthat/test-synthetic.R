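test_that("catalog generation is seed-reproducible and shape-correct", {
  c0 <- generate_catalog(0)
  expect_equal(nrow(c0), 0L)
  c1 <- generate_catalog(60, seed = 1)
  c2 <- generate_catalog(60, seed = 1)
  expect_identical(c1, c2)
  expect_equal(c1$reliable, c1$source_category <= 4)
  expect_true(all(c1$length_min > 0))
  expect_true(all(c1$views >= 0))
  expect_true(all(c1$latent_quality >= 0 & c1$latent_quality <= 1))
})

test_that("default source mix follows the study proportions", {
  cat600 <- generate_catalog(600, seed = 42)
  probs <- c(6, 4, 9, 0, 15, 13, 12, 1) / 60
  counts <- tabulate(cat600$source_category, 8)
  se <- sqrt(600 * probs * (1 - probs))
  expect_true(all(abs(counts - 600 * probs) <= 3 * se + 1e-9))
  expect_equal(counts[4], 0L)  # no public-health-department uploads
  all_cat2 <- generate_catalog(50, source_probs = c(0, 1, 0, 0, 0, 0, 0, 0),
                               seed = 3)
  expect_true(all(all_cat2$reliable))
})

test_that("exclusion filtering applies the numbered criteria in order", {
  base <- generate_catalog(65, seed = 8)
  base$views <- pmax(base$views, 3000)
  base$length_min <- pmax(base$length_min, 1)
  base$views[3] <- 2999              # criterion 2
  base$length_min[c(10, 20, 30, 40)] <- 0.5   # criterion 3
  res <- apply_exclusions(base)
  expect_equal(nrow(res$kept), 60L)
  expect_equal(unname(res$tally["low_views"]), 1L)
  expect_equal(unname(res$tally["too_short"]), 4L)
  expect_equal(sum(res$tally), 5L)
  # boundary reading: exactly 3000 views and exactly 60 seconds are kept
  base2 <- base[1:2, ]
  base2$views <- c(3000L, 5000L); base2$length_min <- c(1, 2)
  expect_equal(nrow(apply_exclusions(base2)$kept), 2L)
  # first matching criterion wins for multi-criteria records
  multi <- base[1, ]
  multi$other_language <- TRUE
  multi$views <- 100L
  t2 <- apply_exclusions(multi)$tally
  expect_equal(unname(t2["other_language"]), 1L)
  expect_equal(unname(t2["low_views"]), 0L)
})

test_that("rater panel strata split at more than 10 physician-years", {
  rp <- rater_panel()
  expect_equal(sum(rp$stratum == "senior"), 3L)
  expect_equal(sum(rp$stratum == "junior"), 3L)
  expect_equal(rp$stratum[rp$physician_years == 10], "junior")
})

test_that("generated ratings respect instrument supports and completeness", {
  cat_df <- generate_catalog(20, seed = 2)
  ds <- generate_ratings(cat_df, agreement = 0.61, seed = 11)
  r <- ds$ratings
  expect_s3_class(validate_ratings(r), "data.frame")
  p <- r$value[r$instrument == "prhism"]
  d <- r$value[r$instrument == "discern"]
  e <- r$value[r$instrument == "expert"]
  expect_true(all(is.na(p) | (p >= 0 & p <= 4)))
  expect_true(all(d >= 1 & d <= 5))
  expect_true(all(e >= 1 & e <= 5))
  # every (video, rater, instrument) combination appears exactly once
  combos <- unique(r[, c("video_id", "rater_id", "instrument")])
  expect_equal(nrow(combos), 20 * 6 * 3)
  # overall / accuracy / harm never NA
  expect_false(anyNA(r$value[r$item %in% c("overall", "accuracy", "harm")]))
  # byte-identical under the same seed
  ds2 <- generate_ratings(cat_df, agreement = 0.61, seed = 11)
  expect_identical(ds$ratings, ds2$ratings)
})

test_that("a per-principle NA probability of 1 fixes n_applicable at 10", {
  cat_df <- generate_catalog(10, seed = 4)
  na_vec <- c(rep(0, 10), rep(1, 3))
  ds <- generate_ratings(cat_df, agreement = 0.8, na_prob = na_vec, seed = 5)
  scored <- score_dataset(ds$ratings)
  p <- scored[scored$instrument == "prhism", ]
  expect_true(all(p$n_applicable == 10L))
})

test_that("a larger reliable-source quality shift widens the score gap", {
  gap <- function(shift) {
    cat_df <- generate_catalog(400, reliable_shift = shift, seed = 77)
    ds <- generate_ratings(cat_df, agreement = 0.9, na_prob = 0, seed = 78)
    scored <- score_dataset(ds$ratings)
    p <- merge(scored[scored$instrument == "prhism", ],
               cat_df[, c("video_id", "reliable")], by = "video_id")
    mean(p$score[p$reliable]) - mean(p$score[!p$reliable])
  }
  expect_gt(gap(2.0), gap(0.2))
})

test_that("catalog summaries report medians, ranges and a percent column", {
  one <- generate_catalog(1, seed = 1)
  s1 <- summarize_catalog(one)
  expect_equal(s1$continuous$median[1], one$length_min)
  expect_equal(s1$continuous$min, s1$continuous$max)

  three <- generate_catalog(3, seed = 2)
  three$length_min <- c(1, 8, 126)
  s3 <- summarize_catalog(three)
  expect_equal(s3$continuous$median[s3$continuous$variable == "length_min"], 8)
  expect_equal(s3$continuous$min[1], 1)
  expect_equal(s3$continuous$max[1], 126)

  s60 <- summarize_catalog(generate_catalog(60, seed = 3))
  expect_lt(abs(sum(s60$sources$percent) - 100), 8 / 2 + 1e-9)  # rounding only
  expect_error(summarize_catalog(generate_catalog(0)), "empty")
})

test_that("dataset files round-trip byte-identically under one seed", {
  cat_df <- generate_catalog(8, seed = 6)
  ds <- generate_ratings(cat_df, seed = 7)
  d1 <- file.path(tempdir(), "fixture_a")
  d2 <- file.path(tempdir(), "fixture_b")
  write_study_dataset(ds, d1)
  write_study_dataset(ds, d2)
  for (f in c("ratings.csv", "catalog.csv", "raters.csv", "provenance.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_ratings(file.path(d1, "ratings.csv"))
  expect_equal(nrow(back), nrow(ds$ratings))
  expect_equal(sum(is.na(back$value)), sum(is.na(ds$ratings$value)))
})
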