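#' @include comparison.R
NULL

#' Unpaired one-sided Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties:
#' `U = sum(rank(x in pooled)) - n_x (n_x + 1) / 2`. The p-value is exact (by
#' enumeration of rank arrangements) when `n_x + n_y <= 12` and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections; both via [stats::wilcox.test()], whose W statistic is this U.
#' `alternative = "greater"` tests whether `x` is stochastically greater than
#' `y`.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"greater"` or `"less"` (one-sided, as the synthesis
#'   stage uses it); `"two.sided"` is accepted for completeness.
#' @return List with `U`, `p`, `n_x`, `n_y`, `alternative` and `exact`.
#' @export
mannWhitneyU <- function(x, y, alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    .mmiStop("invalidArgumentError", "both samples must be non-empty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny) <= 12 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
  list(U = U, p = p, n_x = nx, n_y = ny, alternative = alternative,
       exact = exact)
}

.ADJ_COLS <- setNames(paste0("adj_r2_", .labelKey(.SET_ORDER)), .SET_ORDER)

## Default between-set comparisons: environment beats microbial-only models,
## and the combined set beats environment alone.
.DEFAULT_MW <- list(c("E", "M", "greater"), c("E+M", "E", "greater"))

#' Summarize comparison results within one subset of datasets
#'
#' Computes the subset-level effect sizes: mean and standard error of the
#' averaged-model adjusted R-squared per predictor set, the percentage of
#' datasets improved for each comparison pair, the mean adjusted-R-squared
#' increase (averaged over every dataset in the subset, improved or not), and
#' one-sided Mann-Whitney comparisons of the adjusted-R-squared distributions
#' between predictor sets. Subsets smaller than `min_n` (default 12, the
#' replication floor for synthesis) are suppressed: a summary is still
#' returned but carries `suppressed = TRUE` and no statistics.
#'
#' @param results results table from [resultsTable()] / [runPipeline()].
#' @param subset_label name for the subset.
#' @param filter named list of metadata values to keep (e.g.
#'   `list(process_type = "nitrification")`); `NULL` keeps everything.
#' @param min_n replication floor.
#' @param mw_comparisons list of `c(set_a, set_b, alternative)` triples.
#' @return A `SynthesisSummary` (list).
#' @export
summarizeSubset <- function(results, subset_label = "all", filter = NULL,
                            min_n = 12L, mw_comparisons = .DEFAULT_MW) {
  keep <- rep(TRUE, nrow(results))
  for (f in names(filter))
    keep <- keep & results[[f]] %in% filter[[f]]
  sub <- results[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n < min_n) {
    return(structure(list(subset_label = subset_label, n_datasets = n,
                          suppressed = TRUE,
                          reason = sprintf("n = %d below replication floor %d",
                                           n, min_n)),
                     class = "SynthesisSummary"))
  }
  mean_adj <- list(); se_adj <- list(); n_adj <- list()
  for (lab in names(.ADJ_COLS)) {
    col <- .ADJ_COLS[[lab]]
    if (!col %in% names(sub)) next
    v <- sub[[col]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    mean_adj[[lab]] <- mean(v)
    se_adj[[lab]] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    n_adj[[lab]] <- length(v)
  }
  pct_improved <- list(); mean_delta <- list()
  imp_cols <- grep("^improved_", names(sub), value = TRUE)
  for (col in imp_cols) {
    pair <- sub("^improved_", "", col)
    v <- sub[[col]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    pct_improved[[pair]] <- 100 * mean(v)
    dcol <- paste0("delta_adj_r2_", pair)
    if (dcol %in% names(sub))
      mean_delta[[pair]] <- mean(sub[[dcol]], na.rm = TRUE)
  }
  mw <- list()
  for (cmp in mw_comparisons) {
    a <- cmp[1L]; b <- cmp[2L]; alt <- cmp[3L]
    ca <- .ADJ_COLS[[a]]; cb <- .ADJ_COLS[[b]]
    if (is.null(ca) || is.null(cb) || !ca %in% names(sub) ||
        !cb %in% names(sub)) next
    va <- sub[[ca]][!is.na(sub[[ca]])]
    vb <- sub[[cb]][!is.na(sub[[cb]])]
    if (length(va) < min_n || length(vb) < min_n) next
    t <- mannWhitneyU(va, vb, alternative = alt)
    mw[[paste0(.labelKey(a), "_vs_", .labelKey(b))]] <-
      list(set_a = a, set_b = b, alternative = alt,
           U = t$U, p = t$p, n_a = t$n_x, n_b = t$n_y)
  }
  structure(list(subset_label = subset_label, n_datasets = n,
                 suppressed = FALSE,
                 mean_adj_r2 = mean_adj, se_adj_r2 = se_adj,
                 n_per_set = n_adj,
                 pct_improved = pct_improved,
                 mean_delta_adj_r2 = mean_delta,
                 mw_tests = mw),
            class = "SynthesisSummary")
}

#' @export
print.SynthesisSummary <- function(x, ...) {
  cat("SynthesisSummary [", x$subset_label, "] n =", x$n_datasets, "\n")
  if (isTRUE(x$suppressed)) {
    cat("  suppressed:", x$reason, "\n")
    return(invisible(x))
  }
  for (lab in names(x$mean_adj_r2))
    cat(sprintf("  %-6s mean adjR2 = %6.3f (se %.3f, n %d)\n", lab,
                x$mean_adj_r2[[lab]], x$se_adj_r2[[lab]], x$n_per_set[[lab]]))
  for (pair in names(x$pct_improved))
    cat(sprintf("  %s: %.1f%% improved, mean dAdjR2 = %.3f\n", pair,
                x$pct_improved[[pair]],
                x$mean_delta_adj_r2[[pair]] %||% NA))
  for (nm in names(x$mw_tests)) {
    t <- x$mw_tests[[nm]]
    cat(sprintf("  MW %s > %s: U = %.1f, p = %.4g\n", t$set_a, t$set_b,
                t$U, t$p))
  }
  invisible(x)
}

#' Compare adjusted-R-squared distributions of two predictor sets
#'
#' Unpaired one-sided Mann-Whitney test on the per-dataset adjusted
#' R-squared values of two predictor sets across a results table. Requires
#' both sets present in at least `min_n` datasets; otherwise the record is
#' suppressed with a reason.
#'
#' @param results results table.
#' @param set_a,set_b predictor-set labels (`"E"`, `"M"`, `"E+M"`, ...).
#' @param alternative one-sided direction (`set_a` vs `set_b`).
#' @param min_n replication floor per group.
#' @return List with the test record or a suppression marker.
#' @export
comparePredictorDistributions <- function(results, set_a, set_b,
                                          alternative = "greater",
                                          min_n = 12L) {
  ca <- .ADJ_COLS[[set_a]]; cb <- .ADJ_COLS[[set_b]]
  if (is.null(ca) || is.null(cb))
    .mmiStop("invalidArgumentError", "unknown predictor-set label")
  va <- results[[ca]]; vb <- results[[cb]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < min_n || length(vb) < min_n)
    return(list(set_a = set_a, set_b = set_b, suppressed = TRUE,
                reason = sprintf("group sizes %d/%d below floor %d",
                                 length(va), length(vb), min_n)))
  t <- mannWhitneyU(va, vb, alternative = alternative)
  list(set_a = set_a, set_b = set_b, alternative = alternative,
       U = t$U, p = t$p, n_a = t$n_x, n_b = t$n_y, suppressed = FALSE)
}

#' Synthesize comparison results across a collection
#'
#' Emits the full-collection summary plus one summary per process-type,
#' environment-type and microbial-data-type stratum that reaches the
#' replication floor, mirroring how the framework reports effect sizes
#' across ecologically relevant subsets.
#'
#' @param results results table from [runPipeline()] / [resultsTable()].
#' @param manifest collection manifest (used for stratum levels).
#' @param min_n replication floor (subsets below it are suppressed).
#' @param mw_comparisons between-set Mann-Whitney comparisons to run.
#' @return List with `summaries` (named list of `SynthesisSummary`) and
#'   `table` (one row per stratum x predictor set).
#' @export
synthesizeCollection <- function(results, manifest, min_n = 12L,
                                 mw_comparisons = .DEFAULT_MW) {
  summaries <- list(
    all = summarizeSubset(results, "all", NULL, min_n = min_n,
                          mw_comparisons = mw_comparisons)
  )
  strata <- list(process_type = unique(manifest$process_type),
                 environment_type = unique(manifest$environment_type),
                 microbial_data_type = unique(manifest$microbial_data_type))
  for (field in names(strata)) {
    for (level in sort(strata[[field]])) {
      lab <- paste0(field, ":", level)
      summaries[[lab]] <- summarizeSubset(
        results, lab, setNames(list(level), field), min_n = min_n,
        mw_comparisons = mw_comparisons)
    }
  }
  rows <- list()
  for (s in summaries) {
    if (isTRUE(s$suppressed)) next
    for (lab in names(s$mean_adj_r2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s$subset_label,
        n_datasets = s$n_datasets,
        predictor_set = lab,
        n_set = s$n_per_set[[lab]],
        mean_adj_r2 = s$mean_adj_r2[[lab]],
        se_adj_r2 = s$se_adj_r2[[lab]],
        pct_improved_E_vs_E_M = s$pct_improved[["E_vs_E_M"]] %||% NA_real_,
        mean_delta_adj_r2_E_vs_E_M =
          s$mean_delta_adj_r2[["E_vs_E_M"]] %||% NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0))
  list(summaries = summaries, table = table)
}

#' Render a plain-text synthesis report
#'
#' @param synthesis output of [synthesizeCollection()].
#' @return Character vector of report lines (also printable via `cat`).
#' @export
renderReport <- function(synthesis) {
  lines <- c("# Synthesis report", "")
  for (s in synthesis$summaries) {
    lines <- c(lines, sprintf("## %s (n = %d)", s$subset_label, s$n_datasets))
    if (isTRUE(s$suppressed)) {
      lines <- c(lines, paste0("suppressed: ", s$reason), "")
      next
    }
    for (lab in names(s$mean_adj_r2))
      lines <- c(lines, sprintf("- %s: mean adjR2 %.3f (se %.3f, n %d)",
                                lab, s$mean_adj_r2[[lab]],
                                s$se_adj_r2[[lab]], s$n_per_set[[lab]]))
    for (pair in names(s$pct_improved))
      lines <- c(lines,
                 sprintf("- %s: %.1f%% improved; mean adjR2 increase %.3f",
                         pair, s$pct_improved[[pair]],
                         s$mean_delta_adj_r2[[pair]] %||% NA_real_))
    for (nm in names(s$mw_tests)) {
      t <- s$mw_tests[[nm]]
      lines <- c(lines,
                 sprintf("- Mann-Whitney %s vs %s (%s): U = %.1f, p = %.4g",
                         t$set_a, t$set_b, t$alternative, t$U, t$p))
    }
    lines <- c(lines, "")
  }
  lines
}
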