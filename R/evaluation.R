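# Evaluation of criterion calls against the echocardiographic reference:
# confusion metrics, McNemar agreement, ROC/AUROC on the MMCV score, and
# Pearson correlation with LVMI.

#' Confusion-matrix metrics
#'
#' Counts and the derived rates; the odds ratio uses the Haldane-Anscombe 0.5
#' correction when any cell is zero (the result is then flagged via
#' `or_corrected`).
#'
#' @param calls logical vector of criterion calls.
#' @param labels logical vector of reference labels, same length.
#' @return a list of class `confusion_metrics`: n, tp, fp, tn, fn, accuracy,
#'   sensitivity, specificity, ppv, npv, odds_ratio, or_corrected.
#' @export
confusion_metrics <- function(calls, labels) {
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  if (length(calls) != length(labels)) stop("calls and labels differ in length")
  if (length(calls) < 1) stop("need at least one observation")
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  tn <- sum(!calls & !labels)
  fn <- sum(!calls & labels)
  corrected <- any(c(tp, fp, tn, fn) == 0)
  k <- if (corrected) 0.5 else 0
  structure(list(
    n = length(calls), tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(calls),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    odds_ratio = ((tp + k) * (tn + k)) / ((fp + k) * (fn + k)),
    or_corrected = corrected
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("<confusion_metrics> n=%d tp=%d fp=%d tn=%d fn=%d | ",
                     "acc %.3f sens %.3f spec %.3f ppv %.3f npv %.3f OR %.2f%s\n"),
              x$n, x$tp, x$fp, x$tn, x$fn, x$accuracy, x$sensitivity,
              x$specificity, x$ppv, x$npv, x$odds_ratio,
              if (x$or_corrected) " (0.5-corrected)" else ""))
  invisible(x)
}

#' McNemar test of paired disagreement
#'
#' With discordant counts b (call positive, label negative) and c (call
#' negative, label positive): chi2 = (b - c)^2 / (b + c), without continuity
#' correction, with the p-value from chi-square on 1 df (via
#' [stats::mcnemar.test()]). When b + c < 25 the p-value comes from the exact
#' binomial test instead; b + c = 0 returns chi2 = 0, p = 1, flagged
#' degenerate.
#'
#' @param calls,labels logical vectors of equal length.
#' @return list of class `mcnemar_result`: b, c, chi2, p, method.
#' @export
mcnemar_agreement <- function(calls, labels) {
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  if (length(calls) != length(labels)) stop("calls and labels differ in length")
  b <- sum(calls & !labels)
  cc <- sum(!calls & labels)
  if (b + cc == 0) {
    out <- list(b = b, c = cc, chi2 = 0, p = 1, method = "degenerate")
  } else if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    out <- list(b = b, c = cc, chi2 = (b - cc)^2 / (b + cc), p = p,
                method = "exact-binomial")
  } else {
    tab <- matrix(c(sum(calls & labels), cc, b, sum(!calls & !labels)), 2)
    mt <- stats::mcnemar.test(tab, correct = FALSE)
    out <- list(b = b, c = cc, chi2 = unname(mt$statistic), p = mt$p.value,
                method = "chi-square")
  }
  structure(out, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b=%d c=%d chi2=%.3f p=%.4g (%s)\n",
              x$b, x$c, x$chi2, x$p, x$method))
  invisible(x)
}

#' ROC curve by descending-score threshold sweep
#'
#' Thresholds are the observed unique scores plus +/-Inf endpoints; tied
#' scores are grouped at one threshold step, so the curve is deterministic and
#' finite and its trapezoidal area equals the Mann-Whitney statistic
#' P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores numeric scores (higher = more LVH-like), e.g. MMCV values.
#' @param labels logical reference labels; both classes must be present.
#' @return data frame with columns threshold, fpr, tpr, from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!any(labels)) stop("no positive labels: ROC undefined")
  if (all(labels)) stop("no negative labels: ROC undefined")
  np <- sum(labels)
  nn <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  ctp <- cumsum(l)[grp_end]
  cfp <- cumsum(!l)[grp_end]
  data.frame(threshold = c(Inf, s[grp_end], -Inf),
             fpr = c(0, cfp / nn, 1),
             tpr = c(0, ctp / np, 1))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of [roc_curve()], equal to the probability a positive
#' case's score exceeds a negative case's, with ties credited one half.
#'
#' @inheritParams roc_curve
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Seeded bootstrap confidence interval for AUROC
#'
#' @inheritParams roc_curve
#' @param n_boot number of resamples (default 1000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with auroc, lower, upper, n_boot.
#' @export
auroc_ci <- function(scores, labels, n_boot = 1000, conf = 0.95, seed = 1) {
  labels <- as.logical(labels)
  set.seed(as.integer(seed))
  n <- length(scores)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    if (!any(labels[idx]) || all(labels[idx])) return(NA_real_)
    auroc(scores[idx], labels[idx])
  }, 0)
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(auroc = auroc(scores, labels), lower = unname(q[1]),
       upper = unname(q[2]), n_boot = n_boot)
}

#' Pearson correlation between criterion scores and a reference
#'
#' @param scores numeric vector (e.g. per-ECG MMCV values).
#' @param reference numeric vector (e.g. LVMI), same length, >= 3 values,
#'   both non-constant.
#' @return sample Pearson r.
#' @export
pearson_r <- function(scores, reference) {
  if (length(scores) != length(reference)) stop("vectors differ in length")
  if (length(scores) < 3) stop("need at least 3 observations")
  if (stats::sd(scores) == 0 || stats::sd(reference) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(scores, reference, method = "pearson")
}

#' Score one criterion against the reference labels
#'
#' @param calls logical criterion calls, one per record.
#' @param scores numeric MMCV values, one per record (ROC score).
#' @param labels logical reference LVH labels.
#' @param lvmi optional numeric LVMI per record for the Pearson correlation.
#' @return a list of class `eval_report`: confusion metrics, mcnemar, roc
#'   points, auroc, pearson_r (NA when lvmi absent).
#' @export
eval_report <- function(calls, scores, labels, lvmi = NULL) {
  cm <- confusion_metrics(calls, labels)
  mc <- mcnemar_agreement(calls, labels)
  rc <- roc_curve(scores, labels)
  au <- auroc(scores, labels)
  pr <- if (!is.null(lvmi)) pearson_r(scores, lvmi) else NA_real_
  structure(list(confusion = cm, mcnemar = mc, roc_points = rc, auroc = au,
                 pearson_r = pr), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$confusion)
  print(x$mcnemar)
  cat(sprintf("AUROC %.3f; Pearson r vs LVMI %s\n", x$auroc,
              if (is.na(x$pearson_r)) "n/a" else sprintf("%.3f", x$pearson_r)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  out <- list(
    n = report$confusion$n, tp = report$confusion$tp, fp = report$confusion$fp,
    tn = report$confusion$tn, fn = report$confusion$fn,
    accuracy = report$confusion$accuracy,
    sensitivity = report$confusion$sensitivity,
    specificity = report$confusion$specificity,
    ppv = report$confusion$ppv, npv = report$confusion$npv,
    odds_ratio = report$confusion$odds_ratio,
    mcnemar_chi2 = report$mcnemar$chi2, mcnemar_p = report$mcnemar$p,
    auroc = report$auroc, pearson_r = report$pearson_r,
    roc_points = report$roc_points
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
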