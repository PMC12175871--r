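## Weighted Cohen kappa: contingency tables, point estimates, large-sample
## standard errors, normal-approximation CIs, the kappa z-test, and the
## Landis-Koch interpretation bands.

#' Agreement weight matrix for ordered categories
#'
#' Builds the K x K weight matrix used by [weighted_kappa()]. `identity`
#' weights (1 on the diagonal, 0 off) reproduce unweighted Cohen kappa;
#' `linear` weights are `1 - |i - j| / (K - 1)`; `quadratic` weights are
#' `1 - (i - j)^2 / (K - 1)^2`. Quadratic weights are the conventional choice
#' for Likert-type ordinal ratings and are the package default throughout.
#'
#' @param k number of ordered categories (>= 2).
#' @param scheme one of `"quadratic"`, `"linear"`, `"identity"`.
#' @return a `k` x `k` symmetric matrix with unit diagonal, entries in [0, 1].
#' @examples
#' kappa_weights(3, "quadratic")
#' @export
kappa_weights <- function(k, scheme = c("quadratic", "linear", "identity")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("`k` must be a single integer >= 2")
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
    identity  = (d == 0) + 0,
    linear    = 1 - d / (k - 1),
    quadratic = 1 - d^2 / (k - 1)^2
  )
}

#' Cross-classify two raters' ordinal ratings
#'
#' Builds the K x K contingency table underlying a two-rater kappa. Subjects
#' with `NA` in either vector are dropped pairwise.
#'
#' @param x,y equal-length rating vectors (values must be in `categories`
#'   or `NA`).
#' @param categories ordered vector of category labels shared by both raters.
#' @return an object of class `agreement_table`: a list with `counts`
#'   (K x K integer matrix, rows = `x`, cols = `y`), `categories`, and `n`.
#' @examples
#' build_table(c(1, 1, 2, 2), c(1, 2, 1, 2), categories = 1:2)
#' @export
build_table <- function(x, y, categories) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(categories) < 2L) stop("need at least 2 categories")
  if (anyDuplicated(categories)) stop("`categories` must be distinct")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stop("zero subjects retained after pairwise NA removal")
  i <- match(x, categories)
  j <- match(y, categories)
  if (anyNA(i) || anyNA(j))
    stop("rating value outside the declared category set")
  k <- length(categories)
  counts <- matrix(tabulate((j - 1L) * k + i, nbins = k * k), k, k,
                   dimnames = list(rater_a = categories, rater_b = categories))
  structure(list(counts = counts, categories = categories, n = length(x)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("Agreement table (", x$n, " subjects, ",
      length(x$categories), " categories)\n", sep = "")
  print(x$counts)
  invisible(x)
}

## Internal: kappa point estimate + Fleiss-Cohen-Everitt large-sample SE from
## a counts matrix and weight matrix. Returns list(kappa, po, pe, se) or a
## degenerate marker when pe == 1 (all mass in one identical category).
kappa_core <- function(counts, w) {
  n <- sum(counts)
  p <- counts / n
  r <- rowSums(p)
  c_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * (r %o% c_))
  if (1 - pe < .Machine$double.eps^0.5)
    return(list(degenerate = TRUE, po = po, pe = pe, n = n))
  kap <- (po - pe) / (1 - pe)
  ## non-null large-sample variance of weighted kappa
  ## (Fleiss, Cohen & Everitt form)
  wbar_i <- as.vector(w %*% c_)   # row-wise expected weight, Sum_j w_ij c_j
  wbar_j <- as.vector(t(w) %*% r) # col-wise, Sum_i w_ij r_i
  a <- outer(wbar_i, wbar_j, "+")
  term <- (w * (1 - pe) - a * (1 - po))^2
  v <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  list(degenerate = FALSE, kappa = kap, po = po, pe = pe,
       se = sqrt(max(v, 0)), n = n)
}

#' Weighted Cohen kappa with standard error and confidence interval
#'
#' Chance-corrected agreement for two raters on ordered categories,
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = sum(w * f) / n` and chance-expected agreement
#' `p_e = sum(w * r %o% c) / n^2`. The standard error is the non-null
#' large-sample (Fleiss-Cohen-Everitt) variance of weighted kappa; the CI is
#' the normal approximation `kappa +/- z * se` and is reported as computed
#' (not truncated to [-1, 1]; values outside are flagged on print).
#'
#' @param table an `agreement_table` from [build_table()], or a square counts
#'   matrix.
#' @param scheme weight scheme, see [kappa_weights()].
#' @param level confidence level in (0, 1); the validation-study convention is
#'   0.90 for primary reliability analyses and 0.95 elsewhere.
#' @return an object of class `kappa_estimate` with fields `kappa`, `po`,
#'   `pe`, `se`, `ci_low`, `ci_high`, `level`, `n`, `scheme`,
#'   `interpretation`.
#' @examples
#' tab <- build_table(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2), 1:2)
#' weighted_kappa(tab, scheme = "identity")  # kappa = 2/3
#' @export
weighted_kappa <- function(table, scheme = c("quadratic", "linear", "identity"),
                           level = 0.95) {
  scheme <- match.arg(scheme)
  counts <- if (inherits(table, "agreement_table")) table$counts else table
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("`table` must be a square counts matrix or an agreement_table")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n < 1) stop("empty table")
  w <- kappa_weights(nrow(counts), scheme)
  core <- kappa_core(counts, w)
  if (core$degenerate)
    stop("kappa undefined: expected agreement p_e = 1 ",
         "(both marginals concentrated in the same single category)")
  ci <- kappa_ci(core$kappa, core$se, level)
  structure(list(kappa = core$kappa, po = core$po, pe = core$pe,
                 se = core$se, ci_low = ci[[1]], ci_high = ci[[2]],
                 level = level, n = core$n, scheme = scheme,
                 interpretation = interpret_kappa(core$kappa)),
            class = "kappa_estimate")
}

#' Normal-approximation confidence interval for kappa
#'
#' `kappa +/- z_{(1 + level)/2} * se`. The interval is reported exactly as
#' computed; endpoints outside [-1, 1] are possible for small n and are left
#' untruncated so the user can see them.
#'
#' @param kappa point estimate.
#' @param se standard error (>= 0).
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
kappa_ci <- function(kappa, se, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  if (se < 0) stop("`se` must be >= 0")
  z <- stats::qnorm((1 + level) / 2)
  c(ci_low = kappa - z * se, ci_high = kappa + z * se)
}

#' z-test for a kappa coefficient against a null value
#'
#' Normal-approximation test `z = (kappa_hat - kappa0) / se`, two-sided
#' p-value `2 * (1 - Phi(|z|))`; the study convention is a two-sided
#' significance level of 10% against the null kappa 0.53.
#'
#' @param kappa_hat estimated kappa.
#' @param kappa0 null-hypothesis kappa.
#' @param se standard error of `kappa_hat` (> 0 unless
#'   `kappa_hat == kappa0`).
#' @param alpha significance level.
#' @return list with `z`, `p`, `reject`.
#' @export
kappa_z_test <- function(kappa_hat, kappa0, se, alpha = 0.10) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (se <= 0) {
    if (isTRUE(all.equal(kappa_hat, kappa0)))
      return(list(z = 0, p = 1, reject = FALSE))
    stop("`se` must be > 0")
  }
  z <- (kappa_hat - kappa0) / se
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, reject = p < alpha)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Verbal bands: below 0.00 no agreement; 0.00-0.20 slight; 0.21-0.40 fair;
#' 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#' Band edges follow the printed two-decimal ranges, so a value is banded
#' after round-half-up to two decimals. Kappa of 0.61 or higher is
#' conventionally read as sufficient agreement; [is_sufficient_kappa()]
#' exposes that flag.
#'
#' @param kappa numeric vector of kappa values (<= 1).
#' @return character vector of band labels.
#' @examples
#' interpret_kappa(c(0.52, 0.63, -0.05))
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa > 1 + 1e-12, na.rm = TRUE)) stop("kappa cannot exceed 1")
  k2 <- round_half_up(kappa, 2)
  cut(k2, breaks = c(-Inf, -1e-9, 0.205, 0.405, 0.605, 0.805, Inf),
      labels = c("no agreement", "slight", "fair", "moderate",
                 "substantial", "almost perfect")) |> as.character()
}

#' @rdname interpret_kappa
#' @export
is_sufficient_kappa <- function(kappa) kappa >= 0.61

#' @export
print.kappa_estimate <- function(x, ...) {
  cat(sprintf("Weighted Cohen kappa (%s weights, n = %d)\n", x$scheme, x$n))
  cat(sprintf("  kappa = %.4f (se %.4f), %d%% CI %.4f to %.4f  [%s]\n",
              x$kappa, x$se, round(100 * x$level), x$ci_low, x$ci_high,
              x$interpretation))
  cat(sprintf("  observed agreement %.4f, expected %.4f\n", x$po, x$pe))
  if (x$ci_low < -1 || x$ci_high > 1)
    cat("  note: normal-approximation CI extends beyond [-1, 1]\n")
  invisible(x)
}

#' @export
confint.kappa_estimate <- function(object, parm, level = NULL, ...) {
  lv <- if (is.null(level)) object$level else level
  ci <- kappa_ci(object$kappa, object$se, lv)
  m <- matrix(ci, 1, 2,
              dimnames = list("kappa", sprintf("%g %%", 100 * c((1 - lv) / 2, (1 + lv) / 2))))
  m
}

#' Weighted kappa between ratings on two different ordinal scales
#'
#' Agreement between two instruments whose rating scales differ (e.g. a 0-4
#' overall-quality judgment against a 1-5 expert accuracy rating). Each scale
#' is shifted by an integer so its declared support starts at 0, the two
#' shifted supports are merged into one ordered support, and
#' [weighted_kappa()] is applied on that common support. Distances between
#' categories are never rescaled; only the origin is aligned.
#'
#' @param a,b equal-length rating vectors.
#' @param scale_a,scale_b ordered integer supports for `a` and `b`
#'   (e.g. `0:4`, `1:5`).
#' @param scheme weight scheme.
#' @param level confidence level.
#' @return a `kappa_estimate`; its `categories` field records the common
#'   support used.
#' @examples
#' cross_instrument_kappa(c(0, 2, 4), c(1, 3, 5), scale_a = 0:4, scale_b = 1:5)
#' @export
cross_instrument_kappa <- function(a, b, scale_a, scale_b,
                                   scheme = c("quadratic", "linear", "identity"),
                                   level = 0.95) {
  scheme <- match.arg(scheme)
  if (!all(diff(scale_a) == 1) || !all(diff(scale_b) == 1))
    stop("scales must be consecutive integer supports")
  a0 <- a - min(scale_a)
  b0 <- b - min(scale_b)
  support <- 0:max(max(scale_a) - min(scale_a), max(scale_b) - min(scale_b))
  tab <- build_table(a0, b0, categories = support)
  est <- weighted_kappa(tab, scheme = scheme, level = level)
  est$categories <- support
  est
}
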