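## Simulation-based power and sample-size determination for multi-rater
## agreement studies: the latent copy-model rater, its closed-form population
## kappa, theta calibration, the Monte-Carlo power estimate for the kappa
## z-test, and the minimum-n search.

#' Validate a category distribution
#'
#' @param probs nonnegative vector summing to 1 over K ordered categories.
#' @return the normalised vector, invisibly.
#' @export
category_distribution <- function(probs) {
  if (any(probs < 0) || length(probs) < 2L)
    stop("`probs` must be a nonnegative vector over >= 2 categories")
  s <- sum(probs)
  if (abs(s - 1) > 1e-8) stop("`probs` must sum to 1")
  invisible(probs / s)
}

#' Synthetic stand-in for the pilot overall-quality distribution
#'
#' The validation study calibrated its simulation on the distribution of
#' overall-quality ratings (0-4) from a 50-video pilot, published only as a
#' histogram figure; the numeric values are unavailable. This constant is a
#' synthetic stand-in: a unimodal 5-category distribution centred between
#' categories 2 and 3, consistent with the reported mid-range mean quality of
#' the study's videos. Analyses that use it are conditional on this choice;
#' supply your own pilot distribution when one exists.
#'
#' @return named numeric vector of length 5 (categories 0-4) summing to 1.
#' @export
pilot_marginal_synthetic <- function() {
  c(`0` = 0.06, `1` = 0.20, `2` = 0.34, `3` = 0.30, `4` = 0.10)
}

#' Copy-model rater
#'
#' Simulation device for ordinal ratings with a controllable population
#' kappa: each video has a latent true category drawn from `marginal`; each
#' rater independently reports the truth with probability `theta` and
#' otherwise an independent draw from `marginal`. Under this model the
#' population weighted kappa between any two raters is `theta^2`, for every
#' weight scheme and marginal.
#'
#' @param theta copy probability in [0, 1].
#' @param marginal category distribution (see [category_distribution()]).
#' @return list of class `rater_model`.
#' @export
rater_model <- function(theta, marginal) {
  if (theta < 0 || theta > 1) stop("`theta` must be in [0, 1]")
  marginal <- category_distribution(marginal)
  structure(list(theta = theta, marginal = marginal), class = "rater_model")
}

#' @export
print.rater_model <- function(x, ...) {
  cat(sprintf("Copy-model rater: theta = %.4f over %d categories\n",
              x$theta, length(x$marginal)))
  invisible(x)
}

#' Population weighted kappa of a copy-model rater pair
#'
#' Computes the exact pairwise joint distribution
#' `P(X = a, Y = b) = sum_t pi_t (theta 1(a = t) + (1 - theta) pi_a)
#' (theta 1(b = t) + (1 - theta) pi_b)` and the population weighted kappa
#' from it. Strictly increasing in `theta` (it equals `theta^2`).
#'
#' @param model a [rater_model()].
#' @param scheme weight scheme.
#' @return population kappa in [0, 1].
#' @export
expected_kappa <- function(model, scheme = c("quadratic", "linear", "identity")) {
  scheme <- match.arg(scheme)
  pi <- model$marginal
  K <- length(pi)
  if (any(pi >= 1 - 1e-12))
    stop("degenerate marginal (one category has probability 1): kappa undefined")
  th <- model$theta
  ## response distribution of one rater given truth t: theta e_t + (1-theta) pi
  resp <- th * diag(K) + (1 - th) * matrix(pi, K, K, byrow = TRUE)
  joint <- t(resp) %*% (pi * resp)    # sum_t pi_t resp[t, a] resp[t, b]
  w <- kappa_weights(K, scheme)
  po <- sum(w * joint)
  pe <- sum(w * (pi %o% pi))
  (po - pe) / (1 - pe)
}

#' Calibrate the copy probability to a target population kappa
#'
#' Bisection solve of `expected_kappa(theta) = kappa_target` to an absolute
#' kappa tolerance of 1e-6 (the solution is `sqrt(kappa_target)` under the
#' copy model; the solver is kept generic so alternative rater models can
#' reuse it).
#'
#' @param kappa_target target population kappa in [0, 1].
#' @param marginal category distribution.
#' @param scheme weight scheme.
#' @return calibrated `theta` in [0, 1].
#' @export
calibrate_theta <- function(kappa_target, marginal = pilot_marginal_synthetic(),
                            scheme = c("quadratic", "linear", "identity")) {
  scheme <- match.arg(scheme)
  marginal <- category_distribution(marginal)
  if (kappa_target < 0 || kappa_target > 1)
    stop("`kappa_target` must be in [0, 1] (attainable range of the copy model)")
  if (kappa_target == 0) return(0)
  if (kappa_target == 1) return(1)
  f <- function(th) expected_kappa(rater_model(th, marginal), scheme) - kappa_target
  lo <- 0; hi <- 1
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
}

#' Simulation configuration for the power experiment
#'
#' Bundles the design of the agreement-study power simulation. The study
#' design values were: 6 raters, expected kappa 0.61, null kappa 0.53,
#' two-sided alpha 0.10, 10,000 replicates, and a pilot-derived 5-category
#' marginal.
#'
#' @param n_videos number of subjects (videos) per replicate (>= 2).
#' @param n_raters number of raters (>= 2).
#' @param kappa_true population kappa under which data are generated.
#' @param kappa_null null-hypothesis kappa of the z-test.
#' @param alpha two-sided significance level.
#' @param scheme weight scheme.
#' @param n_reps Monte-Carlo replicates.
#' @param seed integer seed (reproducible runs).
#' @param marginal 5-category (or K-category) truth distribution.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_videos = 55, n_raters = 6, kappa_true = 0.61,
                       kappa_null = 0.53, alpha = 0.10,
                       scheme = c("quadratic", "linear", "identity"),
                       n_reps = 10000, seed = 1,
                       marginal = pilot_marginal_synthetic()) {
  scheme <- match.arg(scheme)
  stopifnot(n_videos >= 2, n_raters >= 2, alpha > 0, alpha < 1, n_reps >= 1)
  marginal <- category_distribution(marginal)
  structure(list(n_videos = as.integer(n_videos),
                 n_raters = as.integer(n_raters),
                 kappa_true = kappa_true, kappa_null = kappa_null,
                 alpha = alpha, scheme = scheme,
                 n_reps = as.integer(n_reps), seed = seed,
                 marginal = marginal),
            class = "sim_config")
}

#' Simulate a subjects x raters ordinal rating matrix
#'
#' One replicate of the copy model: per video a latent truth is drawn from
#' the marginal; each rater independently reports the truth with probability
#' `theta`, otherwise an independent draw from the marginal.
#'
#' @param n_videos,n_raters dimensions.
#' @param model a [rater_model()]; `theta` may also be a vector of length
#'   `n_raters` for heterogeneous raters.
#' @param seed optional integer seed.
#' @return integer matrix of category indices `1..K` (n_videos x n_raters).
#' @export
simulate_ratings <- function(n_videos, n_raters, model, seed = NULL) {
  with_seed(seed, {
    pi <- model$marginal
    K <- length(pi)
    th <- rep_len(model$theta, n_raters)
    truth <- sample.int(K, n_videos, replace = TRUE, prob = pi)
    copy <- matrix(stats::runif(n_videos * n_raters), n_videos, n_raters) <=
      matrix(th, n_videos, n_raters, byrow = TRUE)
    noise <- matrix(sample.int(K, n_videos * n_raters, replace = TRUE, prob = pi),
                    n_videos, n_raters)
    out <- ifelse(copy, truth, noise)
    storage.mode(out) <- "integer"
    out
  })
}

#' Monte-Carlo power of the pairwise-mean-kappa z-test
#'
#' For each replicate: simulate a ratings matrix under the calibrated copy
#' model, compute the pairwise mean weighted kappa and its delete-one-video
#' jackknife SE (mirroring the reliability analysis), and apply the two-sided
#' kappa z-test against `kappa_null` at `alpha`. Power is the rejection
#' fraction. Replicates containing a degenerate rater pair are redrawn;
#' if more than 5% of replicates would need redrawing the run aborts.
#'
#' @param config a [sim_config()].
#' @param se_method `"jackknife"` (default; jackknife SE of the pooled mean)
#'   or `"pooled_pairs"` (per-pair large-sample variances averaged, treating
#'   pairs as independent), kept for comparison.
#' @return list of class `power_result`: `power`, `mc_se`, `n_rejections`,
#'   `n_valid_reps`, `n_redrawn`, `mean_kappa_hat`, `config`.
#' @export
estimate_power <- function(config, se_method = c("jackknife", "pooled_pairs")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(config, "sim_config"))
  theta <- calibrate_theta(config$kappa_true, config$marginal, config$scheme)
  model <- rater_model(theta, config$marginal)
  K <- length(config$marginal)
  w <- kappa_weights(K, config$scheme)
  max_redraws <- ceiling(0.05 * config$n_reps)
  with_seed(config$seed, {
    rejections <- 0L
    redrawn <- 0L
    kap_sum <- 0
    for (rep in seq_len(config$n_reps)) {
      repeat {
        M <- simulate_ratings(config$n_videos, config$n_raters, model)
        core <- pairwise_kappa_core(M, K, w,
                                    jackknife = (se_method == "jackknife"))
        if (!any(core$degenerate)) break
        redrawn <- redrawn + 1L
        if (redrawn > max_redraws)
          stop("more than 5% of replicates produced degenerate rater pairs; ",
               "the configuration is too close to a degenerate marginal")
      }
      se <- if (se_method == "jackknife") core$se else {
        kk <- core$pair_kappas
        stats::sd(kk) / sqrt(length(kk))
      }
      kap_sum <- kap_sum + core$mean_kappa
      tst <- kappa_z_test(core$mean_kappa, config$kappa_null, se, config$alpha)
      if (tst$reject) rejections <- rejections + 1L
    }
    power <- rejections / config$n_reps
    structure(list(power = power,
                   mc_se = sqrt(power * (1 - power) / config$n_reps),
                   n_rejections = rejections,
                   n_valid_reps = config$n_reps,
                   n_redrawn = redrawn,
                   mean_kappa_hat = kap_sum / config$n_reps,
                   theta = theta,
                   se_method = se_method,
                   config = config),
              class = "power_result")
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Simulated power: %.3f (MC se %.4f) from %d replicates\n",
              x$power, x$mc_se, x$n_valid_reps))
  cat(sprintf("  design: %d videos, %d raters, kappa %.2f vs null %.2f, alpha %.2f, %s weights\n",
              x$config$n_videos, x$config$n_raters, x$config$kappa_true,
              x$config$kappa_null, x$config$alpha, x$config$scheme))
  cat(sprintf("  mean estimated kappa %.4f; %d replicate(s) redrawn\n",
              x$mean_kappa_hat, x$n_redrawn))
  invisible(x)
}

#' Minimum number of videos reaching a target power
#'
#' Estimates power on a grid of video counts, smooths the curve with isotonic
#' regression (power is monotone in n up to Monte-Carlo noise), and returns
#' the smallest grid n whose smoothed power reaches the target. Each grid
#' point gets its own derived seed so the search is reproducible.
#'
#' @param target_power required power (e.g. 0.80).
#' @param grid increasing integer vector of candidate video counts.
#' @param config base [sim_config()]; its `n_videos` is overridden.
#' @return list of class `sample_size_result`: `n_min` (NA when no grid point
#'   reaches the target), `achieved_power`, `power_curve` data frame
#'   (`n`, `power`, `mc_se`, `smoothed_power`), `target_power`, `config`.
#' @export
find_min_n <- function(target_power, grid, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be a nonempty strictly increasing integer vector")
  res <- lapply(seq_along(grid), function(i) {
    cfg <- config
    cfg$n_videos <- as.integer(grid[i])
    cfg$seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    estimate_power(cfg)
  })
  pow <- vapply(res, function(r) r$power, numeric(1))
  mc <- vapply(res, function(r) r$mc_se, numeric(1))
  smoothed <- stats::isoreg(grid, pow)$yf
  hit <- which(smoothed >= target_power)
  n_min <- if (length(hit)) grid[hit[1]] else NA_integer_
  structure(list(n_min = n_min,
                 achieved_power = if (length(hit)) smoothed[hit[1]] else max(smoothed),
                 power_curve = data.frame(n = grid, power = pow, mc_se = mc,
                                          smoothed_power = smoothed),
                 target_power = target_power, config = config),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (is.na(x$n_min))
    cat(sprintf("No grid point reached power %.2f (max smoothed power %.3f)\n",
                x$target_power, x$achieved_power))
  else
    cat(sprintf("Minimum n = %d videos for power >= %.2f (smoothed power %.3f)\n",
                x$n_min, x$target_power, x$achieved_power))
  print(x$power_curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sample_size_result <- function(x, ...) {
  plot(x$power_curve$n, x$power_curve$power, type = "b", pch = 16,
       xlab = "number of videos", ylab = "estimated power", ylim = c(0, 1), ...)
  graphics::lines(x$power_curve$n, x$power_curve$smoothed_power, lty = 2)
  graphics::abline(h = x$target_power, col = "grey50")
  if (!is.na(x$n_min)) graphics::abline(v = x$n_min, col = "grey50", lty = 3)
  invisible(x)
}
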