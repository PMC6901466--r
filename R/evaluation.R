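#' Evaluate consensus calls against clinical labels
#'
#' Cross-tabulates consensus (or single-predictor) calls with the clinical
#' classes and derives the headline quantities of the calibration:
#'
#' * `n_pass_spec` — variants passing the pathogenic gate (the 95 percent
#'   specificity threshold), split into DAVs and NPAVs; the DAV share is
#'   the pathogenic precision;
#' * `n_pass_sens` — variants passing the benign gate (the 95 percent
#'   sensitivity threshold), split likewise; the NPAV share is the benign
#'   precision;
#' * `sensitivity` / `specificity` — per-class recall: the fraction of
#'   DAVs called pathogenic and of NPAVs called benign;
#' * `predictable_fraction` — `(n_pass_spec + n_pass_sens) / n_evaluated`;
#' * a breakdown of the remaining categories (contradictory,
#'   unresolved_partial, unresolved_all, conflicting).
#'
#' The denominator `n_evaluated` counts DAVs and NPAVs only: `PART` and
#' `EXCL` records are excluded before any percentage is formed.
#' Percentages are stored at full precision and rounded (half away from
#' zero, one decimal) only when printed.
#'
#' @param calls factor/character of calls: consensus values from
#'   [combine_calls()] or per-predictor values from [classify_dual()]
#'   (`pathogenic` / `benign` count as passing the respective gate).
#' @param class clinical classes aligned with `calls` (`DIS`/`DAV`,
#'   `NO_PHEN`/`NPAV`, `PART`, `EXCL`).
#' @return an object of class `vthresh_eval` (a list of counts and
#'   percentages as described above).
#' @export
evaluate_calls <- function(calls, class) {
  stopifnot(length(calls) == length(class))
  calls <- as.character(calls)
  pool <- norm_class_pool(class)
  keep <- pool %in% c("DAV", "NPAV") & !is.na(calls)
  calls <- calls[keep]
  pool <- pool[keep]
  n <- length(calls)
  if (n == 0L) stop("no evaluable (DAV or NPAV) records", call. = FALSE)

  is_dav <- pool == "DAV"
  pass_spec <- calls == "pathogenic"
  pass_sens <- calls == "benign"
  n_pass_spec <- sum(pass_spec)
  n_pass_sens <- sum(pass_sens)
  n_pass_spec_dav <- sum(pass_spec & is_dav)
  n_pass_sens_npav <- sum(pass_sens & !is_dav)

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    n_evaluated = n,
    n_dav = sum(is_dav), n_npav = sum(!is_dav),
    n_pass_spec = n_pass_spec,
    n_pass_spec_dav = n_pass_spec_dav,
    n_pass_spec_npav = n_pass_spec - n_pass_spec_dav,
    n_pass_sens = n_pass_sens,
    n_pass_sens_dav = n_pass_sens - n_pass_sens_npav,
    n_pass_sens_npav = n_pass_sens_npav,
    precision_pathogenic = pct(n_pass_spec_dav, n_pass_spec),
    precision_benign = pct(n_pass_sens_npav, n_pass_sens),
    sensitivity = pct(n_pass_spec_dav, sum(is_dav)),
    specificity = pct(n_pass_sens_npav, sum(!is_dav)),
    predictable_fraction = pct(n_pass_spec + n_pass_sens, n),
    category_breakdown = c(
      contradictory = sum(calls == "contradictory"),
      unresolved_partial = sum(calls == "unresolved_partial"),
      unresolved_all = sum(calls %in% c("unresolved_all", "unresolved")),
      conflicting = sum(calls == "conflicting"))),
    class = "vthresh_eval")
}

#' @export
print.vthresh_eval <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "n/a", round_half_up(v, 1))
  cat("Call evaluation against clinical labels\n")
  cat(sprintf("  evaluated: %d (%d DAV, %d NPAV)\n",
              x$n_evaluated, x$n_dav, x$n_npav))
  cat(sprintf("  pathogenic gate: %d passed (%d DAV, %d NPAV) | precision %s%%\n",
              x$n_pass_spec, x$n_pass_spec_dav, x$n_pass_spec_npav,
              fmt(x$precision_pathogenic)))
  cat(sprintf("  benign gate:     %d passed (%d DAV, %d NPAV) | precision %s%%\n",
              x$n_pass_sens, x$n_pass_sens_dav, x$n_pass_sens_npav,
              fmt(x$precision_benign)))
  cat(sprintf("  sensitivity %s%% | specificity %s%% | predictable %s%%\n",
              fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$predictable_fraction)))
  bd <- x$category_breakdown
  cat("  other categories:",
      paste(sprintf("%s %d", names(bd), bd), collapse = ", "), "\n")
  invisible(x)
}

#' Per-class accuracy of a single fixed threshold
#'
#' For one predictor and one cutoff, the fraction of each clinical class
#' on its "correct" side: DAV-like classes (`DAV`, `PART`) are correct on
#' the deleterious side of the threshold (strictly beyond it, per the
#' predictor's orientation), NPAVs on the other side.  Used to assess
#' shipped arbitrary cutoffs and single evidence-based cutoffs.
#'
#' @param score numeric raw scores.
#' @param class aligned clinical classes.
#' @param threshold the raw-scale cutoff.
#' @param config the predictor's [predictor_config()].
#' @return named numeric vector of percentages (`NA` for empty classes)
#'   with one element per class present in `DAV`, `PART`, `NPAV`.
#' @export
evaluate_fixed_threshold <- function(score, class, threshold, config) {
  stopifnot(inherits(config, "predictor_config"),
            length(score) == length(class))
  pool <- norm_class_pool(class)
  u <- config$orientation * score
  tau <- config$orientation * threshold
  deleterious <- u > tau
  out <- c(DAV = NA_real_, PART = NA_real_, NPAV = NA_real_)
  for (cl in names(out)) {
    sel <- pool == cl
    if (!any(sel)) next
    correct <- if (cl == "NPAV") !deleterious[sel] else deleterious[sel]
    out[cl] <- 100 * mean(correct)
  }
  out
}

#' Compare score distributions of two groups
#'
#' Thin wrapper over the standard two-sample tests used when contrasting
#' labelled score pools (e.g. VUS vs benign, domain vs non-domain):
#' Welch t-test (optionally one-tailed), Kruskal-Wallis rank test, or a
#' chi-square test on a counts table.
#'
#' @param a,b numeric score vectors, or for `"chi_square"` a single counts
#'   matrix passed as `a` (with `b` missing).
#' @param test one of `"t_test"`, `"kruskal_wallis"`, `"chi_square"`.
#' @param alternative for the t-test, as in [stats::t.test()]; the
#'   one-tailed direction is the hypothesized one (first group more
#'   extreme).
#' @return an object of class `vthresh_gcmp`: group summaries, the test
#'   statistic, `p_value` and the effect direction (`sign(mean(a) -
#'   mean(b))`).
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("t_test", "kruskal_wallis",
                                    "chi_square"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  if (test == "chi_square") {
    counts <- as.matrix(a)
    ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
    res <- list(test = test, statistic = unname(ht$statistic),
                p_value = ht$p.value, counts = counts, direction = NA_real_)
  } else {
    stopifnot(is.numeric(a), is.numeric(b))
    if (test == "t_test") {
      if (length(a) < 2L || length(b) < 2L) {
        stop("t-test needs at least 2 observations per group", call. = FALSE)
      }
      if (sd(a) == 0 && sd(b) == 0) {
        stop("both groups have zero variance; t statistic undefined",
             call. = FALSE)
      }
      ht <- t.test(a, b, alternative = alternative)
    } else {
      ht <- kruskal.test(list(a, b))
    }
    res <- list(test = test, statistic = unname(ht$statistic),
                p_value = ht$p.value,
                group_a = c(mean = mean(a), sd = sd(a), n = length(a)),
                group_b = c(mean = mean(b), sd = sd(b), n = length(b)),
                direction = sign(mean(a) - mean(b)))
  }
  structure(res, class = "vthresh_gcmp")
}

#' @export
print.vthresh_gcmp <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$group_a)) {
    cat(sprintf("  group a: mean %.4g (sd %.4g, n %d) | group b: mean %.4g (sd %.4g, n %d)\n",
                x$group_a["mean"], x$group_a["sd"], x$group_a["n"],
                x$group_b["mean"], x$group_b["sd"], x$group_b["n"]))
  }
  invisible(x)
}

#' Stratified evaluation report
#'
#' Splits calls by a stratum label (domain membership, enzyme class,
#' possible/impossible, ACMG label, ...), evaluates each stratum with
#' [evaluate_calls()], and, when scores are supplied, compares the score
#' distributions of stratum pairs with Bonferroni-corrected t-tests.
#' Strata with fewer than `min_n` records are flagged and excluded from
#' the between-stratum comparisons.
#'
#' @param calls calls as in [evaluate_calls()].
#' @param class aligned clinical classes.
#' @param strata aligned stratum labels.
#' @param score optional aligned numeric scores for between-stratum
#'   comparisons.
#' @param min_n minimum records per stratum (default 5).
#' @return list with `reports` (named list of `vthresh_eval`, `NULL` where
#'   a stratum could not be evaluated), `flagged` (strata under `min_n`),
#'   and `comparisons` (data.frame of pairwise t-tests with raw and
#'   Bonferroni-adjusted p-values; empty without scores).
#' @export
stratified_report <- function(calls, class, strata, score = NULL,
                              min_n = 5) {
  stopifnot(length(calls) == length(class),
            length(strata) == length(class))
  strata <- as.character(strata)
  levels <- unique(strata)
  counts <- table(factor(strata, levels = levels))
  flagged <- names(counts)[counts < min_n]
  reports <- setNames(vector("list", length(levels)), levels)
  for (s in levels) {
    sel <- strata == s
    reports[[s]] <- tryCatch(evaluate_calls(calls[sel], class[sel]),
                             error = function(e) NULL)
  }
  comparisons <- data.frame(stratum_a = character(0),
                            stratum_b = character(0),
                            statistic = numeric(0), p_value = numeric(0),
                            p_adjusted = numeric(0))
  if (!is.null(score)) {
    eligible <- setdiff(levels, flagged)
    if (length(eligible) >= 2L) {
      prs <- combn(eligible, 2)
      rows <- lapply(seq_len(ncol(prs)), function(k) {
        sa <- score[strata == prs[1, k]]
        sb <- score[strata == prs[2, k]]
        cmp <- compare_groups(sa, sb, test = "t_test")
        data.frame(stratum_a = prs[1, k], stratum_b = prs[2, k],
                   statistic = cmp$statistic, p_value = cmp$p_value,
                   stringsAsFactors = FALSE)
      })
      comparisons <- do.call(rbind, rows)
      comparisons$p_adjusted <- pmin(1, comparisons$p_value *
                                       nrow(comparisons))
    }
  }
  list(reports = reports, flagged = flagged, comparisons = comparisons)
}
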