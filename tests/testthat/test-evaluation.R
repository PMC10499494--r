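mk_pairs <- function(tp, fp, tn, fn) {
  calls <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, tn), rep(FALSE, fn))
  labels <- c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn), rep(TRUE, fn))
  list(calls = calls, labels = labels)
}

test_that("confusion metrics reproduce the definitional ratios", {
  p <- mk_pairs(30, 34, 66, 70)
  cm <- confusion_metrics(p$calls, p$labels)
  expect_equal(cm$sensitivity, 0.30)
  expect_equal(cm$specificity, 0.66)
  expect_equal(cm$n, 200)
  expect_equal(cm$accuracy, 96 / 200)
  expect_false(cm$or_corrected)
  expect_equal(cm$odds_ratio, (30 * 66) / (34 * 70))
  # perfect and inverted calls
  expect_equal(confusion_metrics(p$labels, p$labels)$accuracy, 1.0)
  expect_equal(confusion_metrics(!p$labels, p$labels)$accuracy, 0.0)
  # counts are permutation invariant and sum to n
  set.seed(1)
  o <- sample(200)
  cm2 <- confusion_metrics(p$calls[o], p$labels[o])
  expect_equal(cm2[c("tp", "fp", "tn", "fn")], cm[c("tp", "fp", "tn", "fn")])
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, cm$n)
})

test_that("a zero cell triggers the Haldane-Anscombe correction, flagged", {
  p <- mk_pairs(2, 0, 2, 0)
  cm <- confusion_metrics(p$calls, p$labels)
  expect_true(cm$or_corrected)
  expect_equal(cm$odds_ratio, (2.5 * 2.5) / (0.5 * 0.5))
  expect_equal(cm$odds_ratio, 25)
})

test_that("McNemar handles asymptotic, exact and degenerate regimes", {
  # b = 30, c = 10 -> chi2 = 400/40 = 10, asymptotic
  p <- mk_pairs(5, 30, 5, 10)
  mc <- mcnemar_agreement(p$calls, p$labels)
  expect_equal(mc$b, 30)
  expect_equal(mc$c, 10)
  expect_equal(mc$chi2, 10)
  expect_equal(mc$method, "chi-square")
  expect_equal(mc$p, stats::pchisq(10, 1, lower.tail = FALSE))
  # b = c large -> chi2 0, p 1
  p2 <- mk_pairs(3, 15, 3, 15)
  mc2 <- mcnemar_agreement(p2$calls, p2$labels)
  expect_equal(mc2$chi2, 0)
  expect_equal(mc2$p, 1)
  # small discordance -> exact binomial
  p3 <- mk_pairs(10, 3, 10, 1)
  mc3 <- mcnemar_agreement(p3$calls, p3$labels)
  expect_equal(mc3$method, "exact-binomial")
  expect_equal(mc3$p, stats::binom.test(3, 4, 0.5)$p.value)
  # fully concordant -> degenerate, no error
  p4 <- mk_pairs(5, 0, 5, 0)
  mc4 <- mcnemar_agreement(p4$calls, p4$labels)
  expect_equal(mc4$method, "degenerate")
  expect_equal(mc4$chi2, 0)
  expect_equal(mc4$p, 1)
})

test_that("ROC endpoints, monotonicity and textbook cases hold", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auroc(rep(1.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(auroc(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  rc <- roc_curve(c(3, 2, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "negative")
  expect_error(roc_curve(1:4, rep(FALSE, 4)), "positive")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(7)
  s <- stats::rnorm(60)
  l <- stats::runif(60) < 0.4
  expect_equal(auroc(exp(s), l), auroc(s, l))
  expect_equal(auroc(2 * s + 5, l), auroc(s, l))
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(21)
  for (i in 1:5) {
    s <- round(stats::rnorm(40), 1)  # rounding forces ties
    l <- stats::runif(40) < 0.5
    if (!any(l) || all(l)) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auroc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("Pearson correlation validates its inputs", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_error(pearson_r(rep(1, 4), x), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "length")
})

test_that("null calls and labels keep McNemar and AUROC calibrated", {
  # 200 replicates of independent Bernoulli(0.4) calls and labels, n = 200:
  # the rejection rate at alpha = 0.05 stays near nominal and AUROC of an
  # uninformative score stays near one half
  set.seed(1234)
  rej <- 0
  aucs <- numeric(200)
  for (i in 1:200) {
    labels <- stats::runif(200) < 0.4
    calls <- stats::runif(200) < 0.4
    if (mcnemar_agreement(calls, labels)$p < 0.05) rej <- rej + 1
    aucs[i] <- auroc(stats::rnorm(200), labels)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.12)
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("evaluation reports bundle and serialize their statistics", {
  set.seed(5)
  labels <- stats::runif(50) < 0.5
  scores <- stats::rnorm(50) + labels
  lvmi <- 80 + 40 * labels + stats::rnorm(50, 0, 5)
  rep_ <- eval_report(scores > 0.5, scores, labels, lvmi)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$auroc, auroc(scores, labels))
  p <- withr::local_tempfile(fileext = ".json")
  write_eval_json(rep_, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$auroc, rep_$auroc)
  expect_equal(back$n, 50)
  ci <- auroc_ci(scores, labels, n_boot = 100, seed = 3)
  expect_lte(ci$lower, ci$auroc)
  expect_gte(ci$upper, ci$auroc)
})
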