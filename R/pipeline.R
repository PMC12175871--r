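## The full analysis suite over a ratings dataset: primary reliability with
## subgroups, validity against the expert standard, per-item agreement,
## score-level agreement, and the orchestrating run_all() report bundle.

#' Analysis configuration
#'
#' The study conventions: 90% CIs for the primary reliability analyses, 95%
#' elsewhere, quadratic weights, success threshold 0.53 on the lower CI limit
#' of the primary kappa.
#'
#' @param ci_level_reliability CI level for the primary (reliability)
#'   pairwise-mean-kappa analyses.
#' @param ci_level_secondary CI level for all secondary analyses.
#' @param scheme weight scheme for ordinal kappas.
#' @param success_threshold the primary analysis succeeds when the lower CI
#'   limit of the inter-rater kappa exceeds this value.
#' @param seed integer seed recorded in provenance.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(ci_level_reliability = 0.90,
                            ci_level_secondary = 0.95,
                            scheme = c("quadratic", "linear", "identity"),
                            success_threshold = 0.53,
                            seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(ci_level_reliability > 0, ci_level_reliability < 1,
            ci_level_secondary > 0, ci_level_secondary < 1)
  structure(list(ci_level_reliability = ci_level_reliability,
                 ci_level_secondary = ci_level_secondary,
                 scheme = scheme, success_threshold = success_threshold,
                 seed = seed),
            class = "analysis_config")
}

results_row <- function(analysis_id, subgroup, instrument, statistic,
                        estimate, se, ci_low, ci_high, level,
                        interpretation, n_subjects, n_raters_or_pairs,
                        scheme) {
  data.frame(analysis_id = analysis_id, subgroup = subgroup,
             instrument = instrument, statistic = statistic,
             estimate = estimate, se = se, ci_low = ci_low,
             ci_high = ci_high, level = level,
             interpretation = interpretation,
             n_subjects = n_subjects,
             n_raters_or_pairs = n_raters_or_pairs,
             scheme = scheme, stringsAsFactors = FALSE)
}

not_estimable_row <- function(analysis_id, subgroup, instrument, statistic,
                              level, scheme, n_subjects = 0) {
  results_row(analysis_id, subgroup, instrument, statistic,
              NA_real_, NA_real_, NA_real_, NA_real_, level,
              "not estimable", n_subjects, NA_integer_, scheme)
}

row_from_pairwise <- function(pk, analysis_id, subgroup, instrument) {
  results_row(analysis_id, subgroup, instrument, "kappa",
              pk$mean_kappa, pk$se, pk$ci_low, pk$ci_high, pk$level,
              pk$interpretation, pk$n_subjects, pk$n_pairs_used, pk$scheme)
}

## pairwise mean kappa over a (possibly subgrouped) ratings matrix; emits a
## not-estimable row rather than failing when the subgroup is too small
pairwise_row <- function(m, analysis_id, subgroup, instrument, categories,
                         scheme, level) {
  if (is.null(m) || nrow(m) < 2L)
    return(not_estimable_row(analysis_id, subgroup, instrument, "kappa",
                             level, scheme, n_subjects = NROW(m)))
  pk <- tryCatch(
    suppressWarnings(pairwise_mean_kappa(m, categories = categories,
                                         scheme = scheme, level = level)),
    error = function(e) NULL)
  if (is.null(pk))
    return(not_estimable_row(analysis_id, subgroup, instrument, "kappa",
                             level, scheme, n_subjects = nrow(m)))
  row_from_pairwise(pk, analysis_id, subgroup, instrument)
}

dataset_parts <- function(dataset) {
  if (inherits(dataset, "study_dataset"))
    list(ratings = validate_ratings(dataset$ratings),
         catalog = dataset$catalog, raters = dataset$raters)
  else if (is.list(dataset) && !is.null(dataset$ratings))
    list(ratings = validate_ratings(dataset$ratings),
         catalog = dataset$catalog, raters = dataset$raters)
  else stop("`dataset` must be a study_dataset or a list with $ratings")
}

#' Primary reliability analysis: inter-rater agreement of overall quality
#'
#' Pairwise mean weighted kappa (90% CI by default) for the PRHISM overall
#' quality (0-4) and the DISCERN overall quality (1-5), over all videos and
#' within the subgroups reliable sources (categories 1-4) vs other sources
#' (5-8) and senior (> 10 years as a physician) vs junior raters. Each
#' primary row carries a success flag: lower CI limit above the configured
#' threshold (0.53).
#'
#' @param dataset a `study_dataset` (or list with `ratings`, `catalog`,
#'   `raters`).
#' @param config an [analysis_config()].
#' @return data frame of results rows with an extra `success` column on the
#'   all-videos rows.
#' @export
run_reliability <- function(dataset, config = analysis_config()) {
  parts <- dataset_parts(dataset)
  lev <- config$ci_level_reliability
  rows <- list()
  specs <- list(prhism = list(cats = 0:4), discern = list(cats = 1:5))
  for (instr in names(specs)) {
    cats <- specs[[instr]]$cats
    m <- ratings_matrix(parts$ratings, instr, "overall")
    rows[[length(rows) + 1L]] <- pairwise_row(
      m, paste0("reliability_", instr, "_overall"), "all videos", instr,
      cats, config$scheme, lev)
    if (!is.null(parts$catalog)) {
      for (sg in c("reliable", "other")) {
        ids <- parts$catalog$video_id[
          if (sg == "reliable") parts$catalog$reliable
          else !parts$catalog$reliable]
        msub <- m[rownames(m) %in% ids, , drop = FALSE]
        rows[[length(rows) + 1L]] <- pairwise_row(
          msub, paste0("reliability_", instr, "_overall"),
          paste0(sg, " sources"), instr, cats, config$scheme, lev)
      }
    }
    if (!is.null(parts$raters)) {
      for (sg in c("senior", "junior")) {
        rid <- parts$raters$rater_id[parts$raters$stratum == sg]
        msub <- m[, colnames(m) %in% rid, drop = FALSE]
        if (ncol(msub) < 2L) {
          rows[[length(rows) + 1L]] <- not_estimable_row(
            paste0("reliability_", instr, "_overall"),
            paste0(sg, " raters"), instr, "kappa", lev, config$scheme,
            nrow(msub))
        } else {
          rows[[length(rows) + 1L]] <- pairwise_row(
            msub, paste0("reliability_", instr, "_overall"),
            paste0(sg, " raters"), instr, cats, config$scheme, lev)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$success <- ifelse(out$subgroup == "all videos",
                        out$ci_low > config$success_threshold, NA)
  out
}

## per-rater intra-rater kappa rows + pooled mean across raters (normal CI on
## the mean of the per-rater kappas, se = sd / sqrt(R))
intra_rater_rows <- function(ratings, raters, analysis_id, instrument,
                             get_ab, scale_a, scale_b, scheme, level) {
  per <- list()
  kaps <- c()
  for (rid in raters) {
    ab <- get_ab(rid)
    est <- tryCatch(
      cross_instrument_kappa(ab$a, ab$b, scale_a, scale_b,
                             scheme = scheme, level = level),
      error = function(e) NULL)
    if (is.null(est)) {
      per[[length(per) + 1L]] <- not_estimable_row(
        analysis_id, paste0("rater ", rid), instrument, "kappa",
        level, scheme)
    } else {
      per[[length(per) + 1L]] <- results_row(
        analysis_id, paste0("rater ", rid), instrument, "kappa",
        est$kappa, est$se, est$ci_low, est$ci_high, level,
        est$interpretation, est$n, 1L, scheme)
      kaps <- c(kaps, est$kappa)
    }
  }
  pooled <- if (length(kaps) >= 2) {
    mk <- mean(kaps); se <- stats::sd(kaps) / sqrt(length(kaps))
    ci <- kappa_ci(mk, se, level)
    results_row(analysis_id, "pooled across raters", instrument, "kappa",
                mk, se, ci[[1]], ci[[2]], level, interpret_kappa(mk),
                per[[1]]$n_subjects, length(kaps), scheme)
  } else {
    not_estimable_row(analysis_id, "pooled across raters", instrument,
                      "kappa", level, scheme)
  }
  do.call(rbind, c(per, list(pooled)))
}

#' Validity analysis: agreement with the expert subjective standard
#'
#' Per rater (intra-rater, 95% CI by default): PRHISM overall vs the rater's
#' own recoded expert accuracy rating (the validity standard), DISCERN
#' overall vs accuracy, and PRHISM overall vs DISCERN overall; each with a
#' pooled mean-across-raters row. The expert accuracy item operationalises
#' the subjective quality standard; the harm item is analysed as a parallel
#' optional row. Also emits the expert-vs-expert inter-rater row (pairwise
#' mean kappa on the accuracy ratings).
#'
#' @inheritParams run_reliability
#' @return data frame of results rows.
#' @export
run_validity <- function(dataset, config = analysis_config()) {
  parts <- dataset_parts(dataset)
  lev <- config$ci_level_secondary
  r <- parts$ratings
  mp <- ratings_matrix(r, "prhism", "overall")
  md <- ratings_matrix(r, "discern", "overall")
  ma <- ratings_matrix(r, "expert", "accuracy")
  mh <- ratings_matrix(r, "expert", "harm")
  raters <- colnames(mp)
  rows <- list(
    intra_rater_rows(r, raters, "validity_prhism_vs_expert", "prhism",
                     function(rid) list(a = mp[, rid], b = ma[, rid]),
                     0:4, 1:5, config$scheme, lev),
    intra_rater_rows(r, raters, "validity_discern_vs_expert", "discern",
                     function(rid) list(a = md[, rid], b = ma[, rid]),
                     1:5, 1:5, config$scheme, lev),
    intra_rater_rows(r, raters, "intrarater_prhism_vs_discern", "both",
                     function(rid) list(a = mp[, rid], b = md[, rid]),
                     0:4, 1:5, config$scheme, lev),
    intra_rater_rows(r, raters, "validity_prhism_vs_harm", "prhism",
                     function(rid) list(a = mp[, rid], b = mh[, rid]),
                     0:4, 1:5, config$scheme, lev),
    pairwise_row(ma, "expert_interrater_accuracy", "all videos", "expert",
                 1:5, config$scheme, lev)
  )
  do.call(rbind, rows)
}

#' Per-item agreement analysis
#'
#' Pairwise mean kappa for each of the 13 PRHISM principles and 15 DISCERN
#' items. Items where any rating is not applicable (`NA`) are assessed with
#' unweighted (identity) kappa on the pairwise-complete subset, mirroring the
#' study's handling; complete items use the configured weighted scheme. The
#' scheme actually used is recorded per row.
#'
#' @inheritParams run_reliability
#' @return data frame of results rows (one per item).
#' @export
run_item_agreement <- function(dataset, config = analysis_config()) {
  parts <- dataset_parts(dataset)
  lev <- config$ci_level_secondary
  rows <- list()
  item_sets <- list(prhism = list(items = paste0("p", 1:13), cats = 0:4),
                    discern = list(items = paste0("d", 1:15), cats = 1:5))
  for (instr in names(item_sets)) {
    for (it in item_sets[[instr]]$items) {
      m <- ratings_matrix(parts$ratings, instr, it)
      scheme <- if (anyNA(m)) "identity" else config$scheme
      rows[[length(rows) + 1L]] <- pairwise_row(
        m, paste0("item_agreement_", it), "all videos", instr,
        item_sets[[instr]]$cats, scheme, lev)
    }
  }
  do.call(rbind, rows)
}

#' Score-level agreement analysis
#'
#' On the 0-100 PRHISM score and modified DISCERN score: (a) pairwise mean
#' weighted kappa of the 4-band quality classifications (the PRHISM bands are
#' reused for the modified DISCERN score, which has no published banding --
#' flagged in the `subgroup` column); (b) two-way random-effects ICC on the
#' raw scores; (c) dataset-level mean (SD) of each score.
#'
#' @inheritParams run_reliability
#' @return data frame of results rows.
#' @export
run_score_agreement <- function(dataset, config = analysis_config()) {
  parts <- dataset_parts(dataset)
  lev <- config$ci_level_secondary
  scored <- score_dataset(parts$ratings)
  rows <- list()
  for (instr in c("prhism", "discern")) {
    sub <- scored[scored$instrument == instr, ]
    vids <- sort(unique(sub$video_id)); rids <- sort(unique(sub$rater_id))
    smat <- matrix(NA_real_, length(vids), length(rids),
                   dimnames = list(vids, rids))
    smat[cbind(match(sub$video_id, vids), match(sub$rater_id, rids))] <-
      sub$score
    cmat <- matrix(as.integer(prhism_category(as.vector(smat))),
                   nrow(smat), dimnames = dimnames(smat))
    flag <- if (instr == "discern") " (PRHISM bands reused)" else ""
    rows[[length(rows) + 1L]] <- pairwise_row(
      cmat, paste0("score_classification_", instr),
      paste0("all videos", flag), instr, 1:4, config$scheme, lev)
    ic <- icc(smat, level = lev)
    rows[[length(rows) + 1L]] <- results_row(
      paste0("score_icc_", instr), "all videos", instr, "icc",
      ic$icc, NA_real_, ic$ci_low, ic$ci_high, lev, NA_character_,
      ic$n_subjects, ic$n_raters, NA_character_)
    rows[[length(rows) + 1L]] <- results_row(
      paste0("score_mean_", instr), "all videos", instr, "score-mean",
      mean(smat), stats::sd(smat), NA_real_, NA_real_, NA_real_,
      NA_character_, nrow(smat), ncol(smat), NA_character_)
  }
  do.call(rbind, rows)
}

#' Run the complete analysis suite
#'
#' Runs [run_reliability()], [run_validity()], [run_item_agreement()] and
#' [run_score_agreement()], assembles one results table, and (optionally)
#' writes `results.csv`, `catalog_summary.csv`, a plain-text report with
#' interpretation sentences, and a provenance JSON into `out_dir`. Outputs
#' are byte-identical for identical inputs and config.
#'
#' @inheritParams run_reliability
#' @param out_dir optional output directory.
#' @return object of class `study_results`: `results` (data frame),
#'   `catalog_summary`, `config`, `n_videos`, `n_raters`.
#' @export
run_all <- function(dataset, config = analysis_config(), out_dir = NULL) {
  parts <- dataset_parts(dataset)
  rel <- run_reliability(dataset, config)
  rel_rows <- rel
  rel_rows$success <- NULL
  res <- list(rel_rows,
              run_validity(dataset, config),
              run_item_agreement(dataset, config),
              run_score_agreement(dataset, config))
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  summary_cat <- if (!is.null(parts$catalog)) summarize_catalog(parts$catalog)
  out <- structure(list(results = results,
                        reliability = rel,
                        catalog_summary = summary_cat,
                        config = config,
                        n_videos = length(unique(parts$ratings$video_id)),
                        n_raters = length(unique(parts$ratings$rater_id))),
                   class = "study_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format_results_csv(results),
                     file.path(out_dir, "results.csv"), row.names = FALSE)
    if (!is.null(summary_cat)) {
      utils::write.csv(summary_cat$sources,
                       file.path(out_dir, "catalog_summary.csv"),
                       row.names = FALSE)
    }
    writeLines(report_text(out), file.path(out_dir, "report.txt"))
    prov <- list(config = unclass(config), n_videos = out$n_videos,
                 n_raters = out$n_raters)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

format_results_csv <- function(results) {
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) round(x, 6))
  results
}

report_text <- function(x) {
  rel <- x$reliability
  lines <- c("Agreement study report",
             sprintf("%d videos, %d raters", x$n_videos, x$n_raters),
             sprintf("weights: %s; reliability CI %d%%; secondary CI %d%%",
                     x$config$scheme,
                     round(100 * x$config$ci_level_reliability),
                     round(100 * x$config$ci_level_secondary)),
             "",
             "Primary reliability (pairwise mean weighted kappa):")
  for (i in which(rel$subgroup == "all videos")) {
    lines <- c(lines, sprintf(
      "  %s overall quality: kappa %.2f (%d%% CI %.2f-%.2f), %s agreement; primary success (lower limit > %.2f): %s",
      toupper(rel$instrument[i]), rel$estimate[i],
      round(100 * rel$level[i]), rel$ci_low[i], rel$ci_high[i],
      rel$interpretation[i], x$config$success_threshold,
      ifelse(isTRUE(rel$success[i]), "yes", "no")))
  }
  lines <- c(lines, "",
             "Note: rater strata use physician-years > 10 as senior;",
             "the boundary case (exactly 10 years) is classified junior.",
             sprintf("Total result rows: %d", nrow(x$results)))
  lines
}

#' @export
print.study_results <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}
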