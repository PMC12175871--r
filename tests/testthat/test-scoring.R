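test_that("PRHISM score rescales over applicable principles", {
  expect_equal(prhism_score(rep(4, 13))$score, 100)
  expect_equal(prhism_score(rep(0, 13))$score, 0)
  # 10 applicable principles summing to 25, 3 not applicable
  r <- prhism_score(c(4, 4, 4, 4, 4, 2, 1, 1, 1, 0, NA, NA, NA))
  expect_equal(r$score, 62.5)
  expect_equal(r$n_applicable, 10L)
  expect_equal(as.character(r$category), "good")
})

test_that("PRHISM score errors are explicit, not silent zeros", {
  expect_error(prhism_score(rep(NA, 13)), "no applicable items")
  expect_error(prhism_score(rep(2, 12)), "exactly 13")
  expect_error(prhism_score(c(rep(2, 12), 5)), "0..4")
})

test_that("PRHISM score depends only on the applicable sum and count", {
  base <- c(3, 1, 4, 0, 2, 2, 3, 1, 4, 0, NA, NA, NA)
  for (i in 1:20) {
    perm <- sample(base)
    expect_equal(prhism_score(perm)$score, prhism_score(base)$score)
  }
  # adding an item equal to the current mean leaves the score unchanged
  v <- c(2, 2, 2, 4, 0, NA, NA, NA, NA, NA, NA, NA, NA)
  mean_item <- mean(v, na.rm = TRUE)
  v2 <- v; v2[6] <- mean_item
  expect_equal(prhism_score(v2)$score, prhism_score(v)$score,
               tolerance = 1e-12)
})

test_that("quality bands follow the printed integer ranges with half-up rounding", {
  expect_equal(as.character(prhism_category(80)), "excellent")
  expect_equal(as.character(prhism_category(25)), "poor")
  expect_equal(as.character(prhism_category(62.5)), "good")  # rounds to 63
  expect_equal(as.character(prhism_category(c(0, 26, 51, 76, 100))),
               c("poor", "mediocre", "good", "excellent", "excellent"))
  expect_equal(as.character(prhism_category(25.4)), "poor")   # rounds to 25
  expect_equal(as.character(prhism_category(25.5)), "mediocre") # half-up to 26
  expect_error(prhism_category(101), "0, 100")
  expect_error(prhism_category(-1), "0, 100")
})

test_that("an all-constant rating of value v lands in the band containing 25 v", {
  for (v in 0:4) {
    s <- prhism_score(rep(v, 13))
    expect_equal(s$score, 25 * v)
    expect_equal(s$category, prhism_category(25 * v))
  }
})

test_that("DISCERN total spans 16-80 and refuses NA items", {
  expect_equal(discern_total(rep(5, 15), 5), 80L)
  expect_equal(discern_total(rep(1, 15), 1), 16L)
  # alternating 1/5 among items (8 fives, 7 ones) plus matching overall
  items <- rep(c(5, 1), length.out = 15)
  expect_equal(discern_total(items, 1), sum(items) + 1L)
  expect_error(discern_total(c(rep(3, 14), NA), 3), "modified_discern_score")
})

test_that("modified DISCERN score excludes the overall and floors at 20", {
  expect_equal(modified_discern_score(rep(5, 15))$score, 100)
  expect_equal(modified_discern_score(rep(1, 15))$score, 20)
  expect_equal(modified_discern_score(rep(3, 15))$score, 60)  # sum 45
  expect_error(modified_discern_score(rep(NA, 15)), "no applicable items")
  expect_message(modified_discern_score(c(rep(3, 14), NA)), "not-applicable")
  r <- suppressMessages(modified_discern_score(c(rep(5, 10), rep(NA, 5))))
  expect_equal(r$score, 100)
  expect_equal(r$n_applicable, 10L)
})

test_that("expert recoding reverses the scale and is an involution", {
  e <- recode_expert(1, 5)
  expect_equal(e$accuracy, 5L)
  expect_equal(e$harm, 1L)
  expect_equal(recode_expert(3, 3)$accuracy, 3L)  # fixed point
  for (a in 1:5) for (h in 1:5) {
    once <- recode_expert(a, h)
    twice <- recode_expert(once$accuracy, once$harm)
    expect_equal(twice$accuracy, a)
    expect_equal(twice$harm, h)
  }
  expect_error(recode_expert(0, 3), "1..5")
  expect_error(recode_expert(3, 6), "1..5")
})

test_that("score_dataset emits one scored row per video, rater and instrument", {
  set.seed(42)
  overall_p <- matrix(sample(0:4, 12, TRUE), 4, 3)
  overall_d <- matrix(sample(1:5, 12, TRUE), 4, 3)
  ratings <- long_from_overalls(overall_p, overall_d)
  scored <- score_dataset(ratings)
  expect_equal(nrow(scored), 4 * 3 * 2)
  p <- scored[scored$instrument == "prhism", ]
  # items equal the overall, so score = 25 * overall
  expect_equal(p$score,
               25 * overall_p[cbind(match(p$video_id, sprintf("v%02d", 1:4)),
                                    match(p$rater_id, paste0("r", 1:3)))])
})
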