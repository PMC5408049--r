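#' Contingency table of a diagnostic classification
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  stop_if_not(sum(counts) > 0, "the table must contain at least one case")
  structure(as.list(counts), class = "contingency_table")
}

#' Build a contingency table from classified territories
#'
#' @param records output of [classify_territory()].
#' @param test name of the logical test column (e.g. `"mbf_positive"`).
#' @param truth name of the logical reference column (default `"ischaemic"`).
#' @return a [contingency_table()].
#' @export
contingency_from_records <- function(records, test, truth = "ischaemic") {
  p <- records[[test]]; d <- records[[truth]]
  contingency_table(tp = sum(p & d), fp = sum(p & !d),
                    tn = sum(!p & !d), fn = sum(!p & d))
}

#' Diagnostic performance metrics
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from a contingency table, as percentages.  Full precision is
#' retained in `percent`; `display` rounds half away from zero to integers
#' as printed in clinical tables.  A metric with a zero denominator is
#' returned as `NA` and flagged.
#'
#' @param t a [contingency_table()].
#' @return data.frame with columns `metric`, `percent`, `display`,
#'   `defined`.
#' @export
#' @examples
#' contingency_metrics(contingency_table(36, 10, 36, 12))
contingency_metrics <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  num <- c(sensitivity = t$tp, specificity = t$tn, ppv = t$tp, npv = t$tn,
           accuracy = t$tp + t$tn)
  den <- c(sensitivity = t$tp + t$fn, specificity = t$tn + t$fp,
           ppv = t$tp + t$fp, npv = t$tn + t$fn,
           accuracy = t$tp + t$fp + t$tn + t$fn)
  pct <- ifelse(den > 0, 100 * num / den, NA_real_)
  data.frame(
    metric = names(num),
    percent = as.numeric(pct),
    display = round_half_up(as.numeric(pct)),
    defined = den > 0,
    row.names = NULL
  )
}

#' Cluster-adjusted confidence interval for a proportion
#'
#' Wald-type 95 % interval for a territory-level proportion whose variance
#' is corrected for within-patient clustering by the ratio-estimator
#' (cluster-summed) variance: with cluster successes \eqn{x_i}, sizes
#' \eqn{n_i} and \eqn{\hat p = \sum x_i / \sum n_i},
#' \deqn{\widehat{var}(\hat p) = \sum_i (x_i - \hat p n_i)^2 / (\sum_i n_i)^2.}
#' With one territory per cluster this reduces exactly to the binomial Wald
#' variance \eqn{\hat p (1-\hat p)/n}.  Bounds are clipped to [0, 100] %.
#'
#' @param outcome logical (or 0/1) territory-level outcomes.
#' @param cluster patient identifier per territory; >= 2 distinct clusters.
#' @param conf confidence level, default 0.95.
#' @param adjust set `FALSE` for the unadjusted binomial Wald interval.
#' @return object of class `metric_ci`: `estimate`, `ci_low`, `ci_high`
#'   (percent), `cluster_adjusted`, `design_effect`.
#' @export
cluster_adjusted_ci <- function(outcome, cluster, conf = 0.95,
                                adjust = TRUE) {
  outcome <- as.numeric(outcome)
  stop_if_not(length(outcome) == length(cluster),
              "`outcome` and `cluster` must have equal length")
  stop_if_not(all(outcome %in% c(0, 1)), "`outcome` must be binary")
  m <- length(unique(cluster))
  stop_if_not(m >= 2, "at least 2 clusters are required")
  n <- length(outcome)
  p <- mean(outcome)
  v_unadj <- p * (1 - p) / n
  if (adjust) {
    xi <- tapply(outcome, cluster, sum)
    ni <- tapply(outcome, cluster, length)
    v <- sum((xi - p * ni)^2) / n^2
  } else {
    v <- v_unadj
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(estimate = 100 * p,
         ci_low = max(0, 100 * (p - z * sqrt(v))),
         ci_high = min(100, 100 * (p + z * sqrt(v))),
         cluster_adjusted = adjust,
         design_effect = if (v_unadj > 0) v / v_unadj else NA_real_),
    class = "metric_ci"
  )
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.1f %% (95 %% CI %.1f - %.1f %%)%s\n", x$estimate, x$ci_low,
              x$ci_high,
              if (x$cluster_adjusted) ", cluster-adjusted" else ""))
  invisible(x)
}

# Orient scores so that HIGHER oriented score indicates disease.
orient_scores <- function(scores, orientation) {
  if (orientation == "lower") -scores else scores
}

#' ROC curve and area under the curve
#'
#' AUC by the Mann--Whitney construction with tie correction (ties count
#' one half).  The default orientation treats lower scores as indicating
#' disease, matching perfusion indices where ischaemia lowers MBF and TPR.
#' The variance (and normal-approximation CI) comes from the DeLong
#' placement-value decomposition.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) disease reference.
#' @param orientation `"lower"` (lower score indicates disease) or
#'   `"higher"`.
#' @param conf confidence level for the AUC interval.
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `var_auc`, `orientation` and a data.frame `operating_points` of
#'   threshold / sensitivity / specificity (inclusive thresholds at the
#'   observed score values).
#' @export
roc_auc <- function(scores, labels, orientation = c("lower", "higher"),
                    conf = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stop_if_not(length(scores) == length(labels) && !anyNA(scores) &&
                !anyNA(labels), "scores and labels must be complete and paired")
  stop_if_not(any(labels) && any(!labels),
              "both diseased and normal cases are required")
  s <- orient_scores(scores, orientation)
  n1 <- sum(labels); n0 <- sum(!labels)
  rk <- rank(s, ties.method = "average")
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  v <- delong_variance(scores, labels, orientation)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(v)
  thr <- sort(unique(scores))
  op <- do.call(rbind, lapply(thr, function(cut) {
    pos <- if (orientation == "lower") scores <= cut else scores >= cut
    data.frame(threshold = cut,
               sensitivity = sum(pos & labels) / n1,
               specificity = sum(!pos & !labels) / n0)
  }))
  structure(
    list(auc = auc, ci_low = max(0, auc - half), ci_high = min(1, auc + half),
         var_auc = v, orientation = orientation, operating_points = op,
         n_diseased = n1, n_normal = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95 %% CI %.3f - %.3f), %d diseased vs %d normal, %s-score-indicates-disease\n",
              x$auc, x$ci_low, x$ci_high, x$n_diseased, x$n_normal,
              x$orientation))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  op <- x$operating_points[order(1 - x$operating_points$specificity,
                                 x$operating_points$sensitivity), ]
  plot(c(0, 1 - op$specificity, 1), c(0, op$sensitivity, 1), type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong placement values for one score vector: list with V10 (per diseased
# case) and V01 (per normal case); psi = 1 when the diseased case is more
# disease-like, 0.5 on ties.
delong_placements <- function(scores, labels, orientation = "lower") {
  s <- orient_scores(scores, orientation)
  x <- s[labels]; y <- s[!labels]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong variance of a single AUC
#'
#' Nonparametric variance of the Mann--Whitney AUC from the placement-value
#' decomposition: `var = S10/m + S01/n` with `m` diseased and `n` normal
#' cases.
#'
#' @inheritParams roc_auc
#' @return variance of the AUC estimate.
#' @export
delong_variance <- function(scores, labels, orientation = "lower") {
  labels <- as.logical(labels)
  pl <- delong_placements(scores, labels, orientation)
  m <- length(pl$v10); n <- length(pl$v01)
  if (m < 2 || n < 2) return(NA_real_)
  stats::var(pl$v10) / m + stats::var(pl$v01) / n
}

#' Compare two correlated AUCs by the DeLong method
#'
#' Both score sets must be measured on the same subjects.  The covariance
#' of the paired AUCs is estimated from the placement values and the
#' difference tested with a two-sided normal test.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels logical disease reference.
#' @param orientation as in [roc_auc()].
#' @return list with `auc_a`, `auc_b`, `diff`, `var_diff`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           orientation = "lower") {
  labels <- as.logical(labels)
  stop_if_not(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "scores must be paired on identical subjects")
  stop_if_not(any(labels) && any(!labels),
              "both diseased and normal cases are required")
  pa <- delong_placements(scores_a, labels, orientation)
  pb <- delong_placements(scores_b, labels, orientation)
  m <- length(pa$v10); n <- length(pa$v01)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc_a, auc_b = auc_b, diff = d, var_diff = var_diff, z = z,
       p_value = p)
}

#' Optimal diagnostic threshold by the Youden index
#'
#' Maximises `J = sensitivity + specificity - 1` over inclusive cut-points
#' at the observed score values.  Ties in J are broken toward higher
#' sensitivity, then toward the lower threshold.  When the classes are
#' perfectly separated the midpoint of the separating interval is returned
#' (documented convention), with `J = 1`.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels,
                             orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stop_if_not(any(labels) && any(!labels),
              "both diseased and normal cases are required")
  n1 <- sum(labels); n0 <- sum(!labels)
  cand <- sort(unique(scores))
  stats_at <- function(cut) {
    pos <- if (orientation == "lower") scores <= cut else scores >= cut
    sens <- sum(pos & labels) / n1
    spec <- sum(!pos & !labels) / n0
    c(J = sens + spec - 1, sens = sens, spec = spec)
  }
  res <- t(vapply(cand, stats_at, c(J = 0, sens = 0, spec = 0)))
  ord <- order(-res[, "J"], -res[, "sens"], cand)
  best <- ord[1]
  thr <- cand[best]
  if (res[best, "J"] >= 1 - 1e-12) {
    dis <- scores[labels]; nor <- scores[!labels]
    thr <- if (orientation == "lower") {
      (max(dis) + min(nor)) / 2
    } else {
      (min(dis) + max(nor)) / 2
    }
  }
  list(threshold = thr, J = unname(res[best, "J"]),
       sensitivity = unname(res[best, "sens"]),
       specificity = unname(res[best, "spec"]))
}

#' Combined MBF-by-TPR score
#'
#' Product variable combining absolute flow and the transmural ratio into a
#' single index, scored with the same lower-indicates-disease orientation.
#'
#' @param mbf MBF (ml/100 ml/min).
#' @param tpr transmural perfusion ratio.
#' @return `mbf * tpr`.
#' @export
combined_score <- function(mbf, tpr) {
  stop_if_not(all(is.finite(mbf)) && all(is.finite(tpr)),
              "inputs must be finite")
  mbf * tpr
}

#' Pearson correlation
#'
#' Product-moment correlation via [stats::cor.test()].
#'
#' @param x,y paired numeric vectors, `n >= 3`, non-degenerate.
#' @return list with `r` and `p_value`.
#' @export
pearson_r <- function(x, y) {
  stop_if_not(length(x) == length(y), "`x` and `y` must be paired")
  stop_if_not(length(x) >= 3, "at least 3 pairs are required")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in `x` or `y`")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Intraclass correlation between two readers
#'
#' Single-measure two-way ICC from the mean squares of the
#' subject-by-reader decomposition.  The default `"agreement"` convention
#' (two-way, absolute agreement, single measure — ICC(A,1)) penalises a
#' systematic offset between readers; `"consistency"` (ICC(C,1)) does not.
#'
#' @param reader1,reader2 paired measurements, `n >= 3`.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return the ICC (in [-1, 1]).
#' @export
icc_two_readers <- function(reader1, reader2,
                            type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stop_if_not(length(reader1) == length(reader2),
              "reader measurements must be paired")
  n <- length(reader1)
  stop_if_not(n >= 3, "at least 3 paired measurements are required")
  k <- 2
  Y <- cbind(reader1, reader2)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)`.  Returns `NA` with a
#' warning when expected agreement is 1 (both raters constant).
#'
#' @param labels1,labels2 paired classifications (logical or factor-like).
#' @return kappa in [-1, 1], or `NA` if undefined.
#' @export
cohen_kappa <- function(labels1, labels2) {
  stop_if_not(length(labels1) == length(labels2),
              "labelings must be paired")
  l1 <- as.character(labels1); l2 <- as.character(labels2)
  cats <- union(unique(l1), unique(l2))
  po <- mean(l1 == l2)
  pe <- sum(vapply(cats, function(cc) mean(l1 == cc) * mean(l2 == cc), 0))
  if (abs(1 - pe) < .Machine$double.eps) {
    warning("expected agreement is 1; kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Effective radiation dose from the dose-length product
#'
#' @param dlp dose-length product (mGy cm), >= 0.
#' @param k conversion factor (mSv per mGy cm), default 0.014.
#' @param digits decimals for the displayed dose (half-up); `NULL` returns
#'   full precision.
#' @return effective dose (mSv).
#' @export
#' @examples
#' effective_dose(640)  # 9.0 mSv
effective_dose <- function(dlp, k = 0.014, digits = 1) {
  stop_if_not(all(dlp >= 0), "`dlp` must be non-negative")
  dose <- dlp * k
  if (is.null(digits)) dose else round_half_up(dose, digits)
}

#' Group means with an unpaired two-sided t-test
#'
#' @param values numeric measurements.
#' @param group two-level grouping.
#' @param var_equal pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return list with per-group `n`, `mean`, `sd` and the two-sided
#'   `p_value`.
#' @export
group_summary <- function(values, group, var_equal = TRUE) {
  group <- factor(group)
  stop_if_not(nlevels(group) == 2, "exactly two groups are required")
  stop_if_not(all(table(group) >= 2), "both groups need n >= 2")
  tt <- stats::t.test(values ~ group, var.equal = var_equal)
  list(
    groups = levels(group),
    n = as.numeric(table(group)),
    mean = as.numeric(tapply(values, group, mean)),
    sd = as.numeric(tapply(values, group, stats::sd)),
    p_value = tt$p.value
  )
}

#' Full diagnostic evaluation of a territory table
#'
#' Runs the complete statistical battery on classified territories:
#' contingency metrics with cluster-adjusted confidence intervals for MBF
#' and TPR (and the 50--100 ml/100 ml/min intermediate-MBF sub-analysis),
#' ROC/AUC for MBF, TPR and the combined MBF-by-TPR score, pairwise DeLong
#' AUC comparisons, Youden-optimal thresholds, Pearson correlations against
#' FFR, group summaries, and the quadrant counts of the joint MBF/TPR
#' classification (no single combined verdict is asserted).
#'
#' @param records territory data.frame (see [classify_territory()]).
#' @inheritParams classify_territory
#' @param subrange intermediate-MBF sub-analysis range (inclusive),
#'   default `c(50, 100)`.
#' @return object of class `ctmpi_diag`.
#' @export
diagnostic_report <- function(records, mbf_threshold = 76,
                              tpr_threshold = 0.82, ffr_threshold = 0.80,
                              subrange = c(50, 100)) {
  rec <- classify_territory(records, mbf_threshold, tpr_threshold,
                            ffr_threshold)
  one_classifier <- function(rec, test) {
    tab <- contingency_from_records(rec, test)
    metrics <- contingency_metrics(tab)
    correct <- rec[[test]] == rec$ischaemic
    ci <- if (length(unique(rec$patient_id)) >= 2) {
      cluster_adjusted_ci(correct, rec$patient_id)
    } else {
      NULL
    }
    list(table = tab, metrics = metrics, accuracy_ci = ci)
  }
  sub <- rec[rec$mbf >= subrange[1] & rec$mbf <= subrange[2], , drop = FALSE]

  combined <- combined_score(rec$mbf, rec$tpr)
  two_class <- any(rec$ischaemic) && any(!rec$ischaemic)
  roc_mbf <- if (two_class) roc_auc(rec$mbf, rec$ischaemic) else NULL
  roc_tpr <- if (two_class) roc_auc(rec$tpr, rec$ischaemic) else NULL
  roc_comb <- if (two_class) roc_auc(combined, rec$ischaemic) else NULL

  quadrants <- c(
    both_positive = sum(rec$mbf_positive & rec$tpr_positive),
    mbf_only = sum(rec$mbf_positive & !rec$tpr_positive),
    tpr_only = sum(!rec$mbf_positive & rec$tpr_positive),
    both_negative = sum(!rec$mbf_positive & !rec$tpr_positive)
  )

  structure(list(
    records = rec,
    n_territories = nrow(rec),
    n_patients = length(unique(rec$patient_id)),
    n_ischaemic = sum(rec$ischaemic),
    thresholds = c(mbf = mbf_threshold, tpr = tpr_threshold,
                   ffr = ffr_threshold),
    mbf = one_classifier(rec, "mbf_positive"),
    tpr = one_classifier(rec, "tpr_positive"),
    sub_mbf = if (nrow(sub) > 0 && any(sub$ischaemic) && any(!sub$ischaemic))
      one_classifier(sub, "mbf_positive") else NULL,
    sub_tpr = if (nrow(sub) > 0 && any(sub$ischaemic) && any(!sub$ischaemic))
      one_classifier(sub, "tpr_positive") else NULL,
    n_sub = nrow(sub),
    roc = list(mbf = roc_mbf, tpr = roc_tpr, combined = roc_comb),
    delong = if (two_class) list(
      mbf_vs_tpr = delong_compare(rec$mbf, rec$tpr, rec$ischaemic),
      combined_vs_tpr = delong_compare(combined, rec$tpr, rec$ischaemic),
      combined_vs_mbf = delong_compare(combined, rec$mbf, rec$ischaemic)
    ) else NULL,
    youden = if (two_class) list(
      mbf = youden_threshold(rec$mbf, rec$ischaemic),
      tpr = youden_threshold(rec$tpr, rec$ischaemic)
    ) else NULL,
    correlation = list(
      mbf_ffr = pearson_r(rec$mbf, rec$ffr),
      tpr_ffr = pearson_r(rec$tpr, rec$ffr)
    ),
    group_means = if (two_class) list(
      mbf = group_summary(rec$mbf, rec$ischaemic),
      tpr = group_summary(rec$tpr, rec$ischaemic)
    ) else NULL,
    quadrants = quadrants,
    concordance = mean(rec$concordant)
  ), class = "ctmpi_diag")
}

#' @export
print.ctmpi_diag <- function(x, ...) {
  cat(sprintf("Diagnostic evaluation: %d territories in %d patients (%d ischaemic by FFR <= %.2f)\n",
              x$n_territories, x$n_patients, x$n_ischaemic,
              x$thresholds["ffr"]))
  fmt_row <- function(name, cl) {
    t <- cl$table; m <- cl$metrics
    ci_txt <- if (!is.null(cl$accuracy_ci)) {
      sprintf(" (%.0f-%.0f %%)", cl$accuracy_ci$ci_low, cl$accuracy_ci$ci_high)
    } else ""
    cat(sprintf("  %-10s TP %2d FP %2d TN %2d FN %2d | sens %.0f %% spec %.0f %% ppv %.0f %% npv %.0f %% acc %.0f %%%s\n",
                name, t$tp, t$fp, t$tn, t$fn, m$display[1], m$display[2],
                m$display[3], m$display[4], m$display[5], ci_txt))
  }
  fmt_row(sprintf("MBF<=%g", x$thresholds["mbf"]), x$mbf)
  fmt_row(sprintf("TPR<=%g", x$thresholds["tpr"]), x$tpr)
  if (!is.null(x$sub_mbf)) {
    cat(sprintf("  intermediate-MBF sub-analysis (n = %d):\n", x$n_sub))
    fmt_row("  MBF", x$sub_mbf); fmt_row("  TPR", x$sub_tpr)
  }
  if (!is.null(x$roc$mbf)) {
    cat(sprintf("  AUC: MBF %.2f, TPR %.2f, MBF x TPR %.2f; DeLong MBF vs TPR p = %.3f\n",
                x$roc$mbf$auc, x$roc$tpr$auc, x$roc$combined$auc,
                x$delong$mbf_vs_tpr$p_value))
    cat(sprintf("  Youden thresholds: MBF %.1f, TPR %.2f\n",
                x$youden$mbf$threshold, x$youden$tpr$threshold))
  }
  cat(sprintf("  Pearson vs FFR: MBF r = %.2f, TPR r = %.2f\n",
              x$correlation$mbf_ffr$r, x$correlation$tpr_ffr$r))
  cat(sprintf("  MBF/TPR concordance %.0f %%; quadrants (+/+ %d, +/- %d, -/+ %d, -/- %d)\n",
              100 * x$concordance, x$quadrants[1], x$quadrants[2],
              x$quadrants[3], x$quadrants[4]))
  invisible(x)
}
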