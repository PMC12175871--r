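## Two-way random-effects intraclass correlation for continuous scores
## (absolute agreement, single rater) with the standard F-based interval.

#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the mean
#' squares of the subjects x raters layout:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`
#' with MSR the between-subject, MSC the between-rater and MSE the residual
#' mean square. The confidence interval is the McGraw-Wong F-based interval.
#' Rows (subjects) containing any missing value are deleted listwise.
#'
#' @param scores subjects x raters numeric matrix of continuous scores.
#' @param level confidence level.
#' @return object of class `icc_estimate`: `icc`, `ci_low`, `ci_high`,
#'   `level`, `n_subjects`, `n_raters`, `model` label, and the mean squares.
#' @examples
#' m <- cbind(a = c(10, 20, 30, 40), b = c(11, 19, 33, 38))
#' icc(m)
#' @export
icc <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  keep <- stats::complete.cases(scores)
  scores <- scores[keep, , drop = FALSE]
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("need >= 2 complete subjects and >= 2 raters")
  grand <- mean(scores)
  row_m <- rowMeans(scores)
  col_m <- colMeans(scores)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((scores - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  flagged <- FALSE
  if (denom <= 0 || MSR <= MSE) {
    ## no between-subject variance beyond noise: boundary
    r <- max(0, (MSR - MSE) / denom)
    if (r == 0) flagged <- TRUE
  } else {
    r <- (MSR - MSE) / denom
  }
  alpha <- 1 - level
  ## McGraw & Wong interval for ICC(A,1)
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  if (!is.finite(a) || !is.finite(b)) { a <- k / n; b <- n }  # r -> 1 limit
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = r, ci_low = min(lo, r), ci_high = max(hi, r),
                 level = level, n_subjects = n, n_raters = k,
                 model = "two-way random effects, absolute agreement, single rater",
                 MSR = MSR, MSC = MSC, MSE = MSE,
                 boundary = flagged),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat("Intraclass correlation (", x$model, ")\n", sep = "")
  cat(sprintf("  ICC = %.4f, %d%% CI %.4f to %.4f  (n = %d subjects, %d raters)\n",
              x$icc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  if (x$boundary)
    cat("  note: no between-subject variance beyond noise; ICC at 0 boundary\n")
  invisible(x)
}

#' @export
confint.icc_estimate <- function(object, parm, level = NULL, ...) {
  matrix(c(object$ci_low, object$ci_high), 1, 2,
         dimnames = list("ICC", c("lower", "upper")))
}
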