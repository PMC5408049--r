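test_that("contingency metrics reproduce the printed diagnostic table rows", {
  # all-vessel rows
  mbf <- contingency_metrics(contingency_table(36, 10, 36, 12))
  expect_equal(mbf$display, c(75, 78, 78, 75, 77))
  tpr <- contingency_metrics(contingency_table(31, 11, 35, 17))
  expect_equal(tpr$display, c(65, 76, 74, 67, 70))
  # intermediate-flow sub-analysis rows
  sub_mbf <- contingency_metrics(contingency_table(29, 10, 22, 4))
  expect_equal(sub_mbf$display, c(88, 69, 74, 85, 78))
  sub_tpr <- contingency_metrics(contingency_table(24, 8, 24, 9))
  expect_equal(sub_tpr$display, c(73, 75, 75, 73, 74))
  # perfect classifier
  perfect <- contingency_metrics(contingency_table(1, 0, 1, 0))
  expect_equal(perfect$percent, rep(100, 5))
  # undefined metric flagged on zero denominator
  no_pos <- contingency_metrics(contingency_table(0, 0, 5, 0))
  expect_false(no_pos$defined[no_pos$metric == "ppv"])
  expect_true(is.na(no_pos$percent[no_pos$metric == "ppv"]))
})

test_that("displayed percentages round half away from zero", {
  expect_equal(round_half_up(76.5), 77)
  expect_equal(round_half_up(68.75, 0), 69)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(8.96, 1), 9.0)
  expect_equal(round_half_up(2.5), 3)  # differs from banker's rounding
})

test_that("cluster-adjusted CI reduces to the Wald interval for singleton clusters", {
  outcome <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  singletons <- paste0("P", 1:10)
  adj <- cluster_adjusted_ci(outcome, singletons)
  unadj <- cluster_adjusted_ci(outcome, singletons, adjust = FALSE)
  expect_equal(adj$ci_low, unadj$ci_low, tolerance = 1e-12)
  expect_equal(adj$ci_high, unadj$ci_high, tolerance = 1e-12)
  expect_equal(adj$design_effect, 1, tolerance = 1e-12)
  expect_error(cluster_adjusted_ci(outcome, rep("P1", 10)), "2 clusters")
})

test_that("within-patient concordance widens the adjusted interval", {
  # outcomes perfectly concordant within patients -> design effect > 1
  outcome <- rep(c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0), each = 3)
  cluster <- rep(paste0("P", 1:10), each = 3)
  adj <- cluster_adjusted_ci(outcome, cluster)
  unadj <- cluster_adjusted_ci(outcome, cluster, adjust = FALSE)
  expect_gt(adj$design_effect, 1)
  expect_lt(adj$ci_low, unadj$ci_low)
  expect_gt(adj$ci_high, unadj$ci_high)
  # boundary estimates clip to [0, 100]
  all_one <- cluster_adjusted_ci(rep(1, 6), rep(c("a", "b", "c"), 2))
  expect_equal(all_one$estimate, 100)
  expect_lte(all_one$ci_high, 100)
  expect_gte(all_one$ci_low, 0)
})

test_that("AUC matches exhaustive pair counting and handles ties", {
  # perfect separation, lower score indicates disease
  perfect <- roc_auc(c(1, 2, 3, 4, 5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                            FALSE))
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(ties$auc, 0.5)

  pair_count_auc <- function(scores, labels) {
    d <- scores[labels]; n <- scores[!labels]
    tot <- 0
    for (x in d) for (y in n) {
      tot <- tot + (x < y) + 0.5 * (x == y)  # lower indicates disease
    }
    tot / (length(d) * length(n))
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    scores <- round(rnorm(n, 80, 20))       # rounding forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels))
  }
  # orientation flip maps AUC to 1 - AUC
  set.seed(7)
  scores <- rnorm(40); labels <- runif(40) < 0.4
  expect_equal(roc_auc(scores, labels, "higher")$auc,
               1 - roc_auc(scores, labels, "lower")$auc)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both")
})

test_that("AUC and DeLong comparison agree with the pROC reference", {
  set.seed(3)
  n <- 60
  labels <- runif(n) < 0.5
  a <- rnorm(n, ifelse(labels, 70, 90), 20)
  b <- rnorm(n, ifelse(labels, 0.85, 1.0), 0.3)
  r <- roc_auc(a, labels)
  pr <- pROC::roc(labels, a, direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ours <- delong_compare(a, b, labels)
  prb <- pROC::roc(labels, b, direction = ">", quiet = TRUE)
  ref <- pROC::roc.test(pr, prb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$auc_b, as.numeric(pROC::auc(prb)))
})

test_that("identical classifiers give zero AUC difference and p = 1", {
  set.seed(11)
  s <- rnorm(30); l <- runif(30) < 0.5
  cmp <- delong_compare(s, s, l)
  expect_equal(cmp$diff, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("DeLong variance matches the bootstrap on a synthetic cohort", {
  set.seed(19)
  n <- 40
  labels <- c(rep(TRUE, 18), rep(FALSE, 22))
  scores <- rnorm(n, ifelse(labels, 70, 92), 22)
  v_delong <- delong_variance(scores, labels)
  boot <- replicate(2000, {
    i <- sample.int(n, replace = TRUE)
    if (!any(labels[i]) || all(labels[i])) return(NA_real_)
    roc_auc(scores[i], labels[i])$auc
  })
  v_boot <- var(boot, na.rm = TRUE)
  expect_equal(v_delong, v_boot, tolerance = 0.25)
})

test_that("a study-sized cohort separates MBF from TPR in the DeLong test", {
  # cohorts drawn at the study's measurement distributions; the MBF-TPR AUC
  # gap (~0.74 vs ~0.65 in expectation) should register as real signal far
  # beyond the nominal 5 % false-positive rate
  pvals <- vapply(1:30, function(s) {
    coh <- simulate_cohort(seed = 500 + s)
    delong_compare(coh$mbf, coh$tpr, coh$ffr <= 0.80)$p_value
  }, 0)
  aucs <- vapply(1:30, function(s) {
    coh <- simulate_cohort(seed = 500 + s)
    c(roc_auc(coh$mbf, coh$ffr <= 0.80)$auc)
  }, 0)
  expect_gt(mean(aucs), 0.65)
  expect_gt(mean(pvals < 0.05), 0.25)
  expect_lt(median(pvals), 0.25)
})

test_that("Youden threshold equals the exhaustive cut-point scan", {
  scan_oracle <- function(scores, labels) {
    best <- -Inf
    for (cut in sort(unique(scores))) {
      pos <- scores <= cut
      J <- sum(pos & labels) / sum(labels) +
        sum(!pos & !labels) / sum(!labels) - 1
      best <- max(best, J)
    }
    best
  }
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n, 80, 15))
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    got <- youden_threshold(scores, labels)
    expect_equal(got$J, scan_oracle(scores, labels))
  }
})

test_that("Youden threshold is translation-equivariant and gap-centred", {
  scores <- c(55, 60, 65, 90, 95, 100)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- youden_threshold(scores, labels)
  expect_equal(got$J, 1)
  expect_equal(got$threshold, (65 + 90) / 2)  # midpoint of the gap
  shifted <- youden_threshold(scores + 13, labels)
  expect_equal(shifted$threshold, got$threshold + 13)

  set.seed(31)
  s2 <- rnorm(30, 80, 15); l2 <- runif(30) < 0.5
  t1 <- youden_threshold(s2, l2)$threshold
  t2 <- youden_threshold(s2 + 7, l2)$threshold
  expect_equal(t2, t1 + 7)
})

test_that("the combined flow-ratio product behaves as a plain product", {
  expect_equal(combined_score(76, 0.82), 62.32)
  expect_equal(combined_score(88, 1), 88)
  expect_equal(combined_score(0, 0.5), 0)
  expect_error(combined_score(Inf, 1), "finite")
})

test_that("Pearson correlation matches the closed-form product-moment formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, direct)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("ICC conventions are ordered and match the ANOVA decomposition", {
  set.seed(13)
  r1 <- rnorm(12, 80, 15)
  expect_equal(icc_two_readers(r1, r1), 1)
  # a systematic offset hurts absolute agreement but not consistency
  r2 <- r1 + 30 + rnorm(12, 0, 2)
  expect_lt(icc_two_readers(r1, r2, "agreement"),
            icc_two_readers(r1, r2, "consistency"))
  # oracle: mean squares from a two-way aov decomposition
  r3 <- r1 + rnorm(12, 0, 6)
  n <- 12; k <- 2
  long <- data.frame(y = c(r1, r3),
                     subj = factor(rep(1:n, 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- anova(aov(y ~ subj + rater, data = long))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_two_readers(r1, r3, "agreement"), icc_a1)
  icc_c1 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc_two_readers(r1, r3, "consistency"), icc_c1)
})

test_that("kappa spans perfect agreement, perfect disagreement and chance", {
  l1 <- rep(c(TRUE, FALSE), 8)
  expect_equal(cohen_kappa(l1, l1), 1)
  expect_equal(cohen_kappa(l1, !l1), -1)  # balanced complement
  set.seed(17)
  a <- runif(1e4) < 0.5
  b <- runif(1e4) < 0.5
  expect_lt(abs(cohen_kappa(a, b)), 0.03)
  expect_warning(k <- cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), "undefined")
  expect_true(is.na(k))
})

test_that("effective dose applies the 0.014 conversion factor", {
  expect_equal(effective_dose(640), 9.0)
  expect_equal(effective_dose(0), 0.0)
  expect_equal(effective_dose(1000), 14.0)
  expect_equal(effective_dose(640, digits = NULL), 8.96)
  expect_error(effective_dose(-10), "non-negative")
})

test_that("group summary matches a hand-computed pooled t-test", {
  g1 <- c(71, 68, 75, 80, 64)
  g2 <- c(90, 95, 88, 92, 99)
  out <- group_summary(c(g1, g2), rep(c("isch", "norm"), each = 5))
  expect_equal(out$mean, c(mean(g1), mean(g2)))
  expect_equal(out$sd, c(sd(g1), sd(g2)))
  sp2 <- ((5 - 1) * var(g1) + (5 - 1) * var(g2)) / 8
  t_stat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_stat), df = 8)
  expect_equal(out$p_value, p_hand)
  # identical groups -> p = 1
  same <- group_summary(c(g1, g1), rep(c("a", "b"), each = 5))
  expect_equal(same$p_value, 1)
})

test_that("the full diagnostic report assembles coherently on a cohort", {
  coh <- simulate_cohort(seed = 77)
  rep <- diagnostic_report(coh)
  expect_s3_class(rep, "ctmpi_diag")
  expect_equal(rep$n_territories, 94)
  expect_equal(rep$n_patients, 43)
  tab <- rep$mbf$table
  expect_equal(tab$tp + tab$fp + tab$tn + tab$fn, 94)
  expect_equal(sum(rep$quadrants), 94)
  expect_true(rep$roc$mbf$auc > 0.5 && rep$roc$mbf$auc <= 1)
  expect_output(print(rep), "Diagnostic evaluation")
})
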