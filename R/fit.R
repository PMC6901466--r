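#' Evidence-based threshold from summary statistics
#'
#' The calibration places one cutoff 2 SD from the DAV median toward the
#' benign direction (the 95 percent *sensitivity* threshold) and one 2 SD
#' from the NPAV median toward the deleterious direction (the 95 percent
#' *specificity* threshold).  On the raw score scale, with orientation `o`
#' (+1 when larger scores are more deleterious):
#' \deqn{t_{sens} = median_{DAV} - o \cdot 2\,SD_{DAV}, \qquad
#'       t_{spec} = median_{NPAV} + o \cdot 2\,SD_{NPAV}.}
#'
#' @param center pool median.
#' @param spread pool standard deviation.
#' @param orientation +1 or -1 (see [predictor_config()]).
#' @param kind `"sensitivity"` (DAV pool) or `"specificity"` (NPAV pool).
#' @return the raw-scale threshold.
#' @examples
#' threshold_from_stats(61, 46.51, +1, "sensitivity")    # -32.02
#' threshold_from_stats(-6.57, 2.22, -1, "sensitivity")  # -2.13
#' @export
threshold_from_stats <- function(center, spread,
                                 orientation,
                                 kind = c("sensitivity", "specificity")) {
  kind <- match.arg(kind)
  stopifnot(orientation %in% c(-1, 1), is.finite(center), spread >= 0)
  if (kind == "sensitivity") center - orientation * 2 * spread
  else center + orientation * 2 * spread
}

#' Compute an evidence-based threshold from a score pool
#'
#' Computes the median and sample standard deviation (n-1 denominator) of a
#' labelled score pool and derives the threshold via
#' [threshold_from_stats()].  Sensitivity thresholds come from DAV pools,
#' specificity thresholds from NPAV pools.
#'
#' @param scores numeric vector of raw predictor scores (>= 2 values).
#' @param kind `"sensitivity"` or `"specificity"`.
#' @param config the predictor's [predictor_config()].
#' @return list with `threshold`, `center` (median), `spread` (SD), `n`,
#'   `kind` and `predictor`.
#' @export
compute_threshold <- function(scores,
                              kind = c("sensitivity", "specificity"),
                              config) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "predictor_config"))
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L) {
    stop("need at least 2 scores to compute a threshold (got ",
         length(scores), ")", call. = FALSE)
  }
  ctr <- median(scores)
  spr <- sd(scores)
  if (!is.finite(spr)) stop("standard deviation is undefined", call. = FALSE)
  list(threshold = threshold_from_stats(ctr, spr, config$orientation, kind),
       center = ctr, spread = spr, n = length(scores),
       kind = kind, predictor = config$name)
}

norm_class_pool <- function(class) {
  x <- as.character(class)
  x[x %in% c("DIS", "DAV")] <- "DAV"
  x[x %in% c("NO_PHEN", "NPAV")] <- "NPAV"
  x[x %in% c("PART", "partial")] <- "PART"
  bad <- !(x %in% c("DAV", "NPAV", "PART", "EXCL"))
  if (any(bad)) {
    stop("unrecognized clinical class value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Fit gene-specific (or general) evidence-based dual thresholds
#'
#' The central model fit.  For every (gene, predictor) pair with enough
#' labelled scores it computes the dual evidence-based thresholds: the
#' 95 percent sensitivity threshold from the DAV score pool and the
#' 95 percent specificity threshold from the NPAV pool, each placed 2
#' sample standard deviations from the pool median (see
#' [threshold_from_stats()]).  With `scope = "general"` all genes are
#' pooled and a single threshold pair per predictor is fitted.
#'
#' Partial-phenotype (`PART`) records are excluded from both pools by
#' default: the sensitivity/specificity construction is defined on DAVs
#' and NPAVs only.  Genes whose pools are smaller than the minimum counts
#' are skipped and listed in the returned object's `skipped` table; the
#' defaults (9 DAVs, 6 NPAVs) mirror the gene-selection floor of the
#' reference dataset.
#'
#' @param data data.frame with columns `gene`, `predictor`, `score` and
#'   `class` (values `DIS`/`DAV`, `NO_PHEN`/`NPAV`, `PART`, `EXCL`).
#'   `EXCL` records are always ignored.
#' @param predictors list of [predictor_config()] objects covering every
#'   predictor present in `data`.
#' @param scope `"gene"` for gene-specific thresholds, `"general"` for one
#'   pooled threshold pair per predictor.
#' @param min_dav,min_npav minimum pool sizes per (gene, predictor).
#' @param include_partial count `PART` records into the DAV pool (off by
#'   default).
#' @return an object of class `vthresh` with components `thresholds` (one
#'   row per (gene, predictor): `t_sens`, `t_spec`, pool medians, SDs and
#'   sizes), `skipped`, `predictors`, `scope` and `call`.  Supports
#'   `print()`, `summary()`, `coef()`, `predict()`, `plot()` and
#'   `simulate()`.
#' @examples
#' d <- gen_scores(default_score_spec("G1"), seed = 1)
#' fit <- fit_thresholds(d, default_predictors())
#' coef(fit)
#' @export
fit_thresholds <- function(data,
                           predictors = default_predictors(),
                           scope = c("gene", "general"),
                           min_dav = 9, min_npav = 6,
                           include_partial = FALSE) {
  scope <- match.arg(scope)
  predictors <- as_predictor_list(predictors)
  required <- c("gene", "predictor", "score", "class")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(data$predictor), names(predictors))
  if (length(unknown)) {
    stop("no predictor_config for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pool <- norm_class_pool(data$class)
  dav_pool <- pool == "DAV" | (include_partial & pool == "PART")
  npav_pool <- pool == "NPAV"
  gene_key <- if (scope == "general") rep("(all)", nrow(data)) else
    as.character(data$gene)

  rows <- list()
  skipped <- list()
  for (pred in intersect(names(predictors), unique(data$predictor))) {
    cfg <- predictors[[pred]]
    sel <- data$predictor == pred
    for (g in unique(gene_key[sel])) {
      in_cell <- sel & gene_key == g
      dav <- data$score[in_cell & dav_pool]
      npav <- data$score[in_cell & npav_pool]
      if (length(dav) < min_dav || length(npav) < min_npav) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = g, predictor = pred,
          reason = sprintf("pool too small (%d DAV, %d NPAV; need %d/%d)",
                           length(dav), length(npav), min_dav, min_npav),
          stringsAsFactors = FALSE)
        next
      }
      ts <- compute_threshold(dav, "sensitivity", cfg)
      tp <- compute_threshold(npav, "specificity", cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, predictor = pred,
        t_sens = ts$threshold, t_spec = tp$threshold,
        median_dav = ts$center, sd_dav = ts$spread, n_dav = ts$n,
        median_npav = tp$center, sd_npav = tp$spread, n_npav = tp$n,
        stringsAsFactors = FALSE)
    }
  }
  thresholds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), predictor = character(0),
               t_sens = numeric(0), t_spec = numeric(0),
               median_dav = numeric(0), sd_dav = numeric(0),
               n_dav = integer(0), median_npav = numeric(0),
               sd_npav = numeric(0), n_npav = integer(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(0), predictor = character(0),
               reason = character(0))
  structure(list(thresholds = thresholds, skipped = skipped,
                 predictors = predictors, scope = scope,
                 min_dav = min_dav, min_npav = min_npav,
                 include_partial = include_partial,
                 call = match.call()),
            class = "vthresh")
}

#' @export
print.vthresh <- function(x, ...) {
  cat("Evidence-based dual-threshold fit (median +/- 2 SD)\n")
  cat("  scope:", x$scope, "\n")
  cat("  predictors:", paste(names(x$predictors), collapse = ", "), "\n")
  cat(sprintf("  %d (gene, predictor) threshold pairs fitted, %d skipped\n",
              nrow(x$thresholds), nrow(x$skipped)))
  invisible(x)
}

#' @export
summary.vthresh <- function(object, ...) {
  out <- object$thresholds
  out$separation <- with(out, abs(median_dav - median_npav) /
                           sqrt((sd_dav^2 + sd_npav^2) / 2))
  structure(list(scope = object$scope, table = out,
                 skipped = object$skipped), class = "summary.vthresh")
}

#' @export
print.summary.vthresh <- function(x, ...) {
  cat("Dual evidence-based thresholds (", x$scope, " scope)\n\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 5))
  print(tab, row.names = FALSE)
  if (nrow(x$skipped)) {
    cat("\nSkipped:\n")
    print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted thresholds
#' @param object a `vthresh` fit.
#' @param ... unused.
#' @return data.frame with `gene`, `predictor`, `t_sens`, `t_spec`.
#' @export
coef.vthresh <- function(object, ...) {
  object$thresholds[c("gene", "predictor", "t_sens", "t_spec")]
}

#' Classify one score against a dual threshold pair
#'
#' On the orientation-harmonized scale (`u = orientation * score`, so
#' larger `u` is always more deleterious), a score is called *pathogenic*
#' when it lies strictly beyond the specificity threshold and not on the
#' benign side of the sensitivity threshold, *benign* in the mirror case,
#' *conflicting* when the two zones overlap (possible when a poorly
#' separated gene yields crossed thresholds) and the score falls in both,
#' and *unresolved* otherwise.  Exact ties with either threshold are
#' unresolved: the inequalities are strict.
#'
#' @param score numeric vector of raw scores.
#' @param t_sens,t_spec sensitivity / specificity thresholds (raw scale).
#' @param config the predictor's [predictor_config()].
#' @return factor with levels `pathogenic`, `benign`, `unresolved`,
#'   `conflicting`.
#' @export
classify_dual <- function(score, t_sens, t_spec, config) {
  stopifnot(inherits(config, "predictor_config"))
  o <- config$orientation
  u <- o * score
  tau_s <- o * t_sens
  tau_p <- o * t_spec
  path <- u > tau_p
  ben <- u < tau_s
  out <- rep("unresolved", length(score))
  out[path & !ben] <- "pathogenic"
  out[ben & !path] <- "benign"
  out[path & ben] <- "conflicting"
  factor(out, levels = CALL_LEVELS)
}

CALL_LEVELS <- c("pathogenic", "benign", "unresolved", "conflicting")
COMBINED_LEVELS <- c("pathogenic", "benign", "contradictory",
                     "unresolved_partial", "unresolved_all")

#' Combine per-predictor calls into a consensus call
#'
#' The consensus is `pathogenic` only when every predictor calls
#' pathogenic, `benign` only when every predictor calls benign,
#' `contradictory` when both pathogenic and benign evidence occur (a
#' single-predictor `conflicting` call counts as both), `unresolved_all`
#' when no predictor resolves, and `unresolved_partial` when some but not
#' all resolve without contradiction.
#'
#' @param calls character vector or factor of per-predictor calls for one
#'   variant (values from [classify_dual()]).
#' @return single factor value with levels `pathogenic`, `benign`,
#'   `contradictory`, `unresolved_partial`, `unresolved_all`.
#' @export
combine_calls <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) == 0L) stop("no per-predictor calls given", call. = FALSE)
  bad <- setdiff(calls, CALL_LEVELS)
  if (length(bad)) stop("invalid call value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  has_path <- any(calls %in% c("pathogenic", "conflicting"))
  has_ben <- any(calls %in% c("benign", "conflicting"))
  out <-
    if (has_path && has_ben) "contradictory"
    else if (all(calls == "pathogenic")) "pathogenic"
    else if (all(calls == "benign")) "benign"
    else if (all(calls == "unresolved")) "unresolved_all"
    else "unresolved_partial"
  factor(out, levels = COMBINED_LEVELS)
}

lookup_thresholds <- function(fit, gene, predictor) {
  th <- fit$thresholds
  key_gene <- if (fit$scope == "general") rep("(all)", length(gene)) else
    as.character(gene)
  idx <- match(paste(key_gene, predictor), paste(th$gene, th$predictor))
  idx
}

#' Predict calls for new scores from a fitted threshold model
#'
#' Classifies each row of `newdata` against its (gene, predictor)
#' threshold pair with [classify_dual()]; with `type = "combined"` the
#' per-predictor calls of each variant (identified by `gene` plus the
#' `id` column, `hgvs_p` by default) are merged by [combine_calls()].
#' Rows whose (gene, predictor) pair has no fitted thresholds get an `NA`
#' call.
#'
#' @param object a `vthresh` fit.
#' @param newdata data.frame with columns `gene`, `predictor`, `score`
#'   and, for combining, the variant identifier column.
#' @param type `"call"` for per-row calls, `"combined"` for one consensus
#'   row per variant.
#' @param id name of the variant identifier column (default `"hgvs_p"`).
#' @param ... unused.
#' @return for `"call"`: `newdata` with `t_sens`, `t_spec` and `call`
#'   columns appended.  For `"combined"`: one row per (gene, id) with the
#'   consensus `combined` call and `n_predictors`.
#' @export
predict.vthresh <- function(object, newdata, type = c("call", "combined"),
                            id = "hgvs_p", ...) {
  type <- match.arg(type)
  stopifnot(all(c("gene", "predictor", "score") %in% names(newdata)))
  idx <- lookup_thresholds(object, newdata$gene, newdata$predictor)
  th <- object$thresholds
  newdata$t_sens <- th$t_sens[idx]
  newdata$t_spec <- th$t_spec[idx]
  call <- rep(NA_character_, nrow(newdata))
  for (pred in unique(newdata$predictor)) {
    cfg <- object$predictors[[pred]]
    if (is.null(cfg)) next
    sel <- which(newdata$predictor == pred & !is.na(idx))
    if (!length(sel)) next
    call[sel] <- as.character(classify_dual(
      newdata$score[sel], newdata$t_sens[sel], newdata$t_spec[sel], cfg))
  }
  newdata$call <- factor(call, levels = CALL_LEVELS)
  if (type == "call") return(newdata)

  if (!id %in% names(newdata)) {
    stop("newdata needs an '", id, "' column to combine per-predictor calls",
         call. = FALSE)
  }
  keep <- !is.na(newdata$call)
  key <- paste(newdata$gene, newdata[[id]], sep = "\r")
  split_calls <- split(as.character(newdata$call)[keep], key[keep])
  first <- !duplicated(key) & keep
  res <- data.frame(gene = newdata$gene[first],
                    id = newdata[[id]][first],
                    stringsAsFactors = FALSE)
  names(res)[2] <- id
  key_first <- key[first]
  res$n_predictors <- lengths(split_calls)[key_first]
  res$combined <- factor(
    vapply(split_calls[key_first],
           function(cl) as.character(combine_calls(cl)), character(1)),
    levels = COMBINED_LEVELS)
  rownames(res) <- NULL
  res
}

#' Plot labelled score distributions with fitted thresholds
#'
#' Draws kernel density estimates of the DAV and NPAV score pools for one
#' (gene, predictor) cell of the training data, with the fitted
#' sensitivity and specificity thresholds as vertical lines.
#'
#' @param x a `vthresh` fit.
#' @param data the training data (same layout as in [fit_thresholds()]).
#' @param gene,predictor which cell to plot; defaults to the first fitted
#'   pair.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the thresholds row plotted.
#' @export
plot.vthresh <- function(x, data, gene = NULL, predictor = NULL, ...) {
  th <- x$thresholds
  if (!nrow(th)) stop("no fitted thresholds to plot", call. = FALSE)
  if (is.null(gene)) gene <- th$gene[1L]
  if (is.null(predictor)) predictor <- th$predictor[1L]
  row <- th[th$gene == gene & th$predictor == predictor, ]
  if (!nrow(row)) stop("no thresholds fitted for ", gene, "/", predictor,
                       call. = FALSE)
  gsel <- if (x$scope == "general") rep(TRUE, nrow(data)) else
    data$gene == gene
  sel <- gsel & data$predictor == predictor
  pool <- norm_class_pool(data$class[sel])
  dav <- data$score[sel][pool == "DAV"]
  npav <- data$score[sel][pool == "NPAV"]
  dd <- density(dav)
  dn <- density(npav)
  plot(dd, col = "firebrick", lwd = 2,
       main = sprintf("%s / %s", gene, predictor),
       xlab = sprintf("%s score", predictor),
       xlim = range(dd$x, dn$x), ylim = c(0, max(dd$y, dn$y)), ...)
  lines(dn, col = "steelblue", lwd = 2)
  abline(v = row$t_sens, lty = 2)
  abline(v = row$t_spec, lty = 3)
  legend("topright", bty = "n", lwd = c(2, 2, 1, 1),
         lty = c(1, 1, 2, 3),
         col = c("firebrick", "steelblue", "black", "black"),
         legend = c("DAV", "NPAV", "t_sens", "t_spec"))
  invisible(row)
}

#' Simulate score tables from a fitted threshold model
#'
#' Draws new labelled score tables from normal pools parameterized by the
#' fitted medians and SDs, with the fitted pool sizes — a parametric
#' bootstrap of the training data under the model's own summary.
#'
#' @param object a `vthresh` fit.
#' @param nsim number of tables.
#' @param seed RNG seed (restores the caller's RNG state).
#' @param ... unused.
#' @return list of `nsim` data.frames with columns `gene`, `predictor`,
#'   `score`, `class`.
#' @export
simulate.vthresh <- function(object, nsim = 1, seed = NULL, ...) {
  th <- object$thresholds
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      do.call(rbind, lapply(seq_len(nrow(th)), function(j) {
        r <- th[j, ]
        data.frame(
          gene = r$gene, predictor = r$predictor,
          score = c(rnorm(r$n_dav, r$median_dav, r$sd_dav),
                    rnorm(r$n_npav, r$median_npav, r$sd_npav)),
          class = rep(c("DAV", "NPAV"), c(r$n_dav, r$n_npav)),
          stringsAsFactors = FALSE)
      }))
    })
  })
}

#' Rescale a raw score to a weight in [-100, 100]
#'
#' Two-sided piecewise-linear map sending the threshold to 0 and the two
#' ends of the observed range to +/-100.  In `"literal"` mode the observed
#' maximum maps to +100 regardless of orientation; in the default
#' `"harmonized"` mode the *deleterious* extreme (per the predictor's
#' orientation) maps to +100, so weights from different predictors share a
#' direction before averaging.  Scores outside the observed range are
#' clamped with a warning.
#'
#' @param score numeric vector of raw scores.
#' @param threshold raw-scale threshold mapped to weight 0; must lie
#'   strictly inside the observed range.
#' @param config the predictor's [predictor_config()].
#' @param mode `"harmonized"` or `"literal"`.
#' @return numeric vector of weights in `[-100, 100]`.
#' @export
rescale_to_weight <- function(score, threshold, config,
                              mode = c("harmonized", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "predictor_config"))
  lo <- config$observed_min
  hi <- config$observed_max
  if (threshold <= lo || threshold >= hi) {
    stop("threshold must lie strictly inside the observed range [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  out_of_range <- score < lo | score > hi
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " score(s) outside the observed range were clamped")
    score <- pmin(pmax(score, lo), hi)
  }
  w <- ifelse(score >= threshold,
              100 * (score - threshold) / (hi - threshold),
              -100 * (threshold - score) / (threshold - lo))
  if (mode == "harmonized" && config$orientation == -1) w <- -w
  w
}

#' Average per-predictor weights
#'
#' Arithmetic mean of the rescaled weights of the predictors applied to
#' one variant.
#'
#' @param weights named numeric vector (predictor -> weight).
#' @return the mean weight.
#' @export
weighted_mean_score <- function(weights) {
  if (length(weights) == 0L) stop("no weights given", call. = FALSE)
  mean(as.numeric(weights))
}
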