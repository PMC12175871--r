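## Pairwise-averaged multi-rater agreement: every unordered rater pair gets a
## weighted kappa; the study statistic is their mean, with a delete-one-video
## jackknife CI that respects the pairs sharing subjects.

## Internal fast path shared with the power simulation.
##
## M: n x R integer matrix of category indices in 1..K (NA allowed).
## Returns mean kappa over non-degenerate pairs, jackknife SE over subjects,
## per-pair kappas, and degeneracy flags. Leave-one-out kappas are computed in
## O(1) per subject via marginal updates:
##   removing a subject rated (a, b) turns (So, Se, r, c, n) into
##   So - w[a,b], Se - (Wc)[a] - (Wr)[b] + w[a,b], n - 1.
pairwise_kappa_core <- function(M, K, w, jackknife = TRUE) {
  n <- nrow(M); R <- ncol(M)
  pairs <- utils::combn(R, 2L)
  npair <- ncol(pairs)
  kap <- rep(NA_real_, npair)
  degenerate <- logical(npair)
  loo <- if (jackknife) matrix(NA_real_, n, npair) else NULL
  for (p in seq_len(npair)) {
    a <- M[, pairs[1L, p]]
    b <- M[, pairs[2L, p]]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    m <- length(a)
    if (m == 0L) { degenerate[p] <- TRUE; next }
    counts <- matrix(tabulate((b - 1L) * K + a, nbins = K * K), K, K)
    r <- rowSums(counts); cc <- colSums(counts)
    So <- sum(w * counts)
    Se <- sum(w * (r %o% cc))
    po <- So / m
    pe <- Se / m^2
    if (1 - pe < .Machine$double.eps^0.5) { degenerate[p] <- TRUE; next }
    kap[p] <- (po - pe) / (1 - pe)
    if (jackknife) {
      ## removing a subject not rated by this pair leaves its kappa unchanged
      loo[, p] <- kap[p]
    }
    if (jackknife && m > 1L) {
      Wc <- as.vector(w %*% cc)
      Wr <- as.vector(w %*% r)   # w symmetric
      wab <- w[cbind(a, b)]
      po_i <- (So - wab) / (m - 1)
      pe_i <- (Se - Wc[a] - Wr[b] + wab) / (m - 1)^2
      ki <- ifelse(1 - pe_i < .Machine$double.eps^0.5, NA_real_,
                   (po_i - pe_i) / (1 - pe_i))
      loo[keep, p] <- ki
    }
  }
  use <- !degenerate
  mean_kappa <- mean(kap[use])
  se <- NA_real_
  if (jackknife) {
    ## jackknife over subjects of the mean-of-pairs statistic
    th <- rowMeans(loo[, use, drop = FALSE])
    ok <- !is.na(th)
    m_eff <- sum(ok)
    if (m_eff > 1L) {
      th <- th[ok]
      se <- sqrt((m_eff - 1) / m_eff * sum((th - mean(th))^2))
    }
  }
  list(mean_kappa = mean_kappa, se = se, pair_kappas = kap,
       degenerate = degenerate, pairs = pairs, n = n)
}

## Coerce a subjects x raters matrix of ratings on `categories` to integer
## codes 1..K, validating the support.
code_matrix <- function(ratings, categories) {
  if (!is.matrix(ratings)) ratings <- as.matrix(ratings)
  codes <- match(ratings, categories)
  bad <- is.na(codes) & !is.na(ratings)
  if (any(bad)) stop("rating value outside the declared category set")
  matrix(codes, nrow(ratings), ncol(ratings),
         dimnames = dimnames(ratings))
}

#' Pairwise-averaged weighted kappa for several raters
#'
#' With R raters every unordered pair (C(R, 2) pairs; 15 for 6 raters) gets a
#' two-rater weighted kappa, and agreement is summarised by the mean of those
#' pairwise kappas. Because all pairs share the same subjects they are not
#' independent; the default CI is a delete-one-subject jackknife of the
#' mean-of-pairs statistic, which accounts for that sharing. A naive CI that
#' treats the pairs as independent (`ci_method = "independent"`) is available
#' for comparison only.
#'
#' Pairs whose table is degenerate (expected agreement 1) are excluded from
#' the mean with a warning. Subjects with `NA` are dropped pairwise within
#' each pair.
#'
#' @param ratings subjects x raters matrix of ordinal ratings.
#' @param categories ordered category support (default: sorted unique values).
#' @param scheme weight scheme, see [kappa_weights()].
#' @param level confidence level (0.90 in the primary reliability analyses).
#' @param ci_method `"jackknife"` (default) or `"independent"`.
#' @return object of class `pairwise_kappa`: `mean_kappa`, `se`, `ci_low`,
#'   `ci_high`, `level`, `pair_estimates` (data frame of per-pair results),
#'   `n_subjects`, `n_raters`, `scheme`, `interpretation`.
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 2), r2 = c(1, 2, 3, 3), r3 = c(1, 1, 3, 2))
#' pairwise_mean_kappa(m, categories = 1:3, level = 0.90)
#' @export
pairwise_mean_kappa <- function(ratings, categories = NULL,
                                scheme = c("quadratic", "linear", "identity"),
                                level = 0.90,
                                ci_method = c("jackknife", "independent")) {
  scheme <- match.arg(scheme)
  ci_method <- match.arg(ci_method)
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("need at least 2 raters")
  if (nrow(ratings) < 2L) stop("need at least 2 subjects")
  if (is.null(categories))
    categories <- sort(unique(as.vector(ratings[!is.na(ratings)])))
  if (length(categories) < 2L)
    stop("fewer than 2 distinct categories observed; kappa undefined")
  M <- code_matrix(ratings, categories)
  K <- length(categories)
  w <- kappa_weights(K, scheme)
  core <- pairwise_kappa_core(M, K, w, jackknife = (ci_method == "jackknife"))
  if (any(core$degenerate))
    warning(sum(core$degenerate),
            " degenerate rater pair(s) (p_e = 1) excluded from the mean")
  if (all(core$degenerate)) stop("all rater pairs degenerate; kappa undefined")
  rn <- colnames(ratings)
  if (is.null(rn)) rn <- paste0("R", seq_len(ncol(ratings)))
  pair_df <- data.frame(
    rater_a = rn[core$pairs[1L, ]],
    rater_b = rn[core$pairs[2L, ]],
    kappa = core$pair_kappas,
    degenerate = core$degenerate,
    stringsAsFactors = FALSE
  )
  se <- core$se
  if (ci_method == "independent") {
    k_ok <- core$pair_kappas[!core$degenerate]
    se <- stats::sd(k_ok) / sqrt(length(k_ok))
  }
  ci <- kappa_ci(core$mean_kappa, se, level)
  structure(list(mean_kappa = core$mean_kappa, se = se,
                 ci_low = ci[[1]], ci_high = ci[[2]], level = level,
                 pair_estimates = pair_df,
                 n_subjects = nrow(ratings), n_raters = ncol(ratings),
                 n_pairs_used = sum(!core$degenerate),
                 scheme = scheme, ci_method = ci_method,
                 interpretation = interpret_kappa(core$mean_kappa)),
            class = "pairwise_kappa")
}

#' @export
print.pairwise_kappa <- function(x, ...) {
  cat(sprintf("Pairwise mean weighted kappa (%d raters, %d pairs used, %d subjects)\n",
              x$n_raters, x$n_pairs_used, x$n_subjects))
  cat(sprintf("  mean kappa = %.4f (se %.4f, %s), %d%% CI %.4f to %.4f  [%s]\n",
              x$mean_kappa, x$se, x$ci_method, round(100 * x$level),
              x$ci_low, x$ci_high, x$interpretation))
  cat(sprintf("  weights: %s\n", x$scheme))
  invisible(x)
}

#' @export
summary.pairwise_kappa <- function(object, ...) {
  print(object)
  cat("\nPer-pair kappas:\n")
  print(object$pair_estimates, row.names = FALSE)
  invisible(object)
}

#' @export
confint.pairwise_kappa <- function(object, parm, level = NULL, ...) {
  lv <- if (is.null(level)) object$level else level
  ci <- kappa_ci(object$mean_kappa, object$se, lv)
  matrix(ci, 1, 2, dimnames = list(
    "mean kappa", sprintf("%g %%", 100 * c((1 - lv) / 2, (1 + lv) / 2))))
}
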