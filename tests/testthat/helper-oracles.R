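# Independent oracles used across tests. Deliberately naive, loop-based
# implementations so they share no code path with the package internals.

# textbook unweighted Cohen kappa straight from the counts, cell by cell
oracle_unweighted_kappa <- function(counts) {
  n <- sum(counts)
  K <- nrow(counts)
  po <- 0
  for (i in seq_len(K)) po <- po + counts[i, i] / n
  pe <- 0
  for (i in seq_len(K)) pe <- pe + sum(counts[i, ]) * sum(counts[, i]) / n^2
  if (1 - pe < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# weighted kappa from raw rating vectors by explicit pair enumeration
oracle_weighted_kappa <- function(x, y, categories, w) {
  n <- length(x)
  po <- 0
  for (s in seq_len(n))
    po <- po + w[match(x[s], categories), match(y[s], categories)]
  po <- po / n
  pe <- 0
  for (s in seq_len(n)) for (t in seq_len(n))
    pe <- pe + w[match(x[s], categories), match(y[t], categories)]
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

random_table <- function(k, n) {
  counts <- matrix(0L, k, k)
  cells <- sample.int(k * k, n, replace = TRUE)
  for (c_ in cells) counts[c_] <- counts[c_] + 1L
  counts
}

# enumerate every k x k nonnegative integer table with total exactly n
all_tables <- function(k, n) {
  cells <- k * k
  out <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 1L) {
      out[[length(out) + 1L]] <<- c(prefix, remaining)
      return(invisible())
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v, slots - 1L)
  }
  rec(integer(0), n, cells)
  lapply(out, function(v) matrix(v, k, k))
}

# tiny deterministic ratings fixture: 3 raters x 8 videos on 1..4
hand_ratings_matrix <- function() {
  cbind(r1 = c(1, 2, 3, 4, 2, 3, 1, 4),
        r2 = c(1, 2, 3, 3, 2, 4, 2, 4),
        r3 = c(2, 2, 3, 4, 1, 3, 1, 3))
}

# build a full long-format ratings table from per-rater overall vectors,
# with items exactly equal to the overall (no jitter, no NA)
long_from_overalls <- function(overall_p, overall_d, accuracy = NULL) {
  n <- nrow(overall_p); R <- ncol(overall_p)
  if (is.null(accuracy)) accuracy <- overall_d
  rows <- list()
  for (j in seq_len(R)) {
    rows[[j]] <- data.frame(
      video_id = rep(sprintf("v%02d", seq_len(n)), times = 14 + 16 + 2),
      rater_id = sprintf("r%d", j),
      instrument = rep(c(rep("prhism", 14), rep("discern", 16), "expert",
                         "expert"), each = n),
      item = rep(c(paste0("p", 1:13), "overall", paste0("d", 1:15), "overall",
                   "accuracy", "harm"), each = n),
      value = c(rep(overall_p[, j], 13), overall_p[, j],
                rep(overall_d[, j], 15), overall_d[, j],
                accuracy[, j], accuracy[, j]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
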