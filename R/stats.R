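#' @include utils.R
NULL

#' Nonparametric comparison of two event-measure samples
#'
#' Runs the two-sample Kolmogorov-Smirnov test on the cumulative
#' distributions plus, for unpaired samples, the Mann-Whitney test for
#' central tendency, or, for paired samples, the Wilcoxon signed-rank test.
#' Small tie-free samples use the exact Mann-Whitney/Wilcoxon null
#' distribution (the `stats::wilcox.test` default); otherwise the normal
#' approximation with tie correction is used. Significance levels follow
#' the convention for spontaneous-current analysis: 0.01 for the KS
#' distribution comparison, 0.05 otherwise. Paired samples whose
#' differences are all zero are degenerate: p = 1, flagged in `note`.
#'
#' @param a,b Numeric samples.
#' @param paired Paired comparison (requires equal lengths).
#' @param alphaKs,alphaRank Significance levels.
#' @return `data.frame(test, statistic, p_value, n_a, n_b, alpha_used,
#'   significant, note)` with one row per test.
#' @export
compareDistributions <- function(a, b, paired = FALSE, alphaKs = 0.01,
                                 alphaRank = 0.05) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (paired && length(a) != length(b))
    stopf("paired comparison requires equal sample sizes")
  ks <- suppressWarnings(stats::ks.test(a, b))
  rows <- data.frame(test = "ks", statistic = unname(ks$statistic),
                     p_value = ks$p.value, n_a = length(a), n_b = length(b),
                     alpha_used = alphaKs,
                     significant = ks$p.value < alphaKs, note = "",
                     stringsAsFactors = FALSE)
  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      rows <- rbind(rows, data.frame(
        test = "wilcoxon", statistic = 0, p_value = 1, n_a = length(a),
        n_b = length(b), alpha_used = alphaRank, significant = FALSE,
        note = "degenerate: all paired differences zero",
        stringsAsFactors = FALSE))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
      rows <- rbind(rows, data.frame(
        test = "wilcoxon", statistic = unname(wt$statistic),
        p_value = wt$p.value, n_a = length(a), n_b = length(b),
        alpha_used = alphaRank, significant = wt$p.value < alphaRank,
        note = "", stringsAsFactors = FALSE))
    }
  } else {
    mw <- suppressWarnings(stats::wilcox.test(a, b))
    rows <- rbind(rows, data.frame(
      test = "mann_whitney", statistic = unname(mw$statistic),
      p_value = mw$p.value, n_a = length(a), n_b = length(b),
      alpha_used = alphaRank, significant = mw$p.value < alphaRank,
      note = "", stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

#' Fisher's exact test for two proportions
#'
#' Two-sided exact test on the 2 x 2 table `(k1, n1 - k1; k2, n2 - k2)`.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @param alpha Significance level.
#' @return One-row `data.frame` in the [compareDistributions()] layout.
#' @export
fisherProportions <- function(k1, n1, k2, n2, alpha = 0.05) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                                  byrow = TRUE))
  data.frame(test = "fisher", statistic = unname(ft$estimate),
             p_value = ft$p.value, n_a = n1, n_b = n2, alpha_used = alpha,
             significant = ft$p.value < alpha, note = "",
             stringsAsFactors = FALSE)
}

#' Single-outlier screen (Grubbs test)
#'
#' One-pass Grubbs test: flags the most extreme value if
#' `G = max|x - mean| / sd` exceeds the critical value at level `alpha`.
#' At most one value is flagged.
#'
#' @param x Numeric values (n >= 3).
#' @param alpha Significance level.
#' @return `list(outlier_index, g_statistic, g_critical)`;
#'   `outlier_index` is `integer(0)` when nothing is flagged.
#' @export
outlierScreen <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stopf("outlier screen needs at least 3 values (got %d)", n)
  s <- stats::sd(x)
  if (s == 0) return(list(outlier_index = integer(0), g_statistic = 0,
                          g_critical = NA_real_))
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- if (g > gcrit) which.max(dev) else integer(0)
  list(outlier_index = idx, g_statistic = g, g_critical = gcrit)
}

#' Marker percentages from count fields
#'
#' Per visual field, the marker-positive percentage of MAP2+ neurons; per
#' time point, the mean +/- SEM across fields; per marker, the unweighted
#' mean of the time-point means (see [averageAcrossTimepoints()]). Markers
#' counted on fewer than `minCells` neurons at a time point are flagged
#' (not fatal).
#'
#' @param counts `data.frame(marker, timepoint, field, n_marker, n_map2)`
#'   as produced by [simulateCountFields()].
#' @param minCells Minimum neurons per marker and time point.
#' @return `list(per_timepoint, combined)` data.frames; percentages in %.
#' @export
markerPercentages <- function(counts, minCells = 600) {
  need <- c("marker", "timepoint", "field", "n_marker", "n_map2")
  if (!all(need %in% names(counts)))
    stopf("count table must have columns: %s", paste(need, collapse = ", "))
  counts$pct <- 100 * counts$n_marker / counts$n_map2
  sp <- split(counts, list(counts$marker, counts$timepoint), drop = TRUE)
  per <- do.call(rbind, lapply(sp, function(d) data.frame(
    marker = d$marker[1], timepoint = d$timepoint[1],
    mean_pct = mean(d$pct),
    sem_pct = stats::sd(d$pct) / sqrt(nrow(d)),
    total_cells = sum(d$n_map2), n_fields = nrow(d),
    low_count = sum(d$n_map2) < minCells,
    stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  comb <- do.call(rbind, lapply(split(per, per$marker), function(d)
    data.frame(marker = d$marker[1],
               combined_pct = averageAcrossTimepoints(d$mean_pct),
               total_cells = sum(d$total_cells),
               low_count = any(d$low_count), stringsAsFactors = FALSE)))
  rownames(comb) <- NULL
  list(per_timepoint = per, combined = comb)
}

#' Combine time-point means into a single marker percentage
#'
#' The combined value is the unweighted mean of the per-time-point means
#' (each time point contributes equally regardless of cell counts).
#'
#' @param means Numeric vector of per-time-point mean percentages.
#' @return Combined percentage.
#' @export
averageAcrossTimepoints <- function(means) mean(means)

#' Infer a total cell fraction from a labelled fraction
#'
#' When only a fraction `labelingEfficiency` of a population carries a
#' reporter, the total population fraction is the observed labelled
#' fraction divided by the efficiency; the unlabelled remainder is the
#' difference. Values are percentages.
#'
#' @param observedLabeledPct Observed labelled-cell percentage.
#' @param labelingEfficiency Labelled fraction of the population, in
#'   (0, 1].
#' @return `list(total_pct, unlabeled_pct)` (full precision; display
#'   convention is two decimals).
#' @export
inferTotalFraction <- function(observedLabeledPct, labelingEfficiency) {
  checkScalar(labelingEfficiency, "labelingEfficiency", 0, 1,
              strict_lower = TRUE)
  total <- observedLabeledPct / labelingEfficiency
  list(total_pct = total, unlabeled_pct = total - observedLabeledPct)
}

#' Relative expression by the delta-Ct method
#'
#' Per gene (and time point), technical triplicates are averaged;
#' `delta_ct = Ct_gene - mean(Ct_hk1, Ct_hk2)` against the two housekeeping
#' genes, and relative expression is `2^-delta_ct`. A gene with any missing
#' triplicate set is reported as not detected; a missing housekeeping gene
#' is fatal for that sample.
#'
#' @param ctTable `data.frame(timepoint, gene, replicate, ct)` (the
#'   `timepoint` column is optional).
#' @param hkGenes The two housekeeping genes.
#' @return `data.frame(timepoint, gene, mean_ct, delta_ct, rel_expression,
#'   detected)`.
#' @export
deltaCt <- function(ctTable, hkGenes = c("ACTB", "GAPDH")) {
  if (!all(c("gene", "ct") %in% names(ctTable)))
    stopf("Ct table must have 'gene' and 'ct' columns")
  if (is.null(ctTable$timepoint)) ctTable$timepoint <- NA
  out <- do.call(rbind, lapply(split(ctTable, ctTable$timepoint),
                               function(d) {
    means <- vapply(split(d$ct, d$gene),
                    function(v) if (anyNA(v)) NA_real_ else mean(v),
                    numeric(1))
    missingHk <- hkGenes[!hkGenes %in% names(means) |
                           is.na(means[hkGenes])]
    if (length(missingHk))
      stopf("housekeeping gene(s) not detected: %s",
            paste(missingHk, collapse = ", "))
    hk <- mean(means[hkGenes])
    genes <- setdiff(names(means), hkGenes)
    data.frame(timepoint = d$timepoint[1], gene = genes,
               mean_ct = unname(means[genes]),
               delta_ct = unname(means[genes] - hk),
               rel_expression = unname(2^(-(means[genes] - hk))),
               detected = !is.na(means[genes]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
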