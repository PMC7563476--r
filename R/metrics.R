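as_binary_truth <- function(truth) {
  if (is.factor(truth)) truth <- as.character(truth)
  if (is.character(truth)) {
    stop("`truth` must be logical or 0/1 numeric", call. = FALSE)
  }
  out <- as.logical(truth)
  if (anyNA(out)) stop("`truth` contains missing values", call. = FALSE)
  out
}

#' Confusion-matrix metrics
#'
#' Standard binary-classification metrics from aligned calls and truth:
#' sensitivity, specificity, PPV, NPV, F1 (`2 * PPV * sens / (PPV + sens)`)
#' and accuracy. Quotients with zero denominators are reported as `NA`, not
#' 0.
#'
#' @param pred Logical (or 0/1) vector of positive calls.
#' @param truth Logical (or 0/1) vector of ground truth, same length.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`, `accuracy`.
#' @export
confusion_metrics <- function(pred, truth) {
  truth <- as_binary_truth(truth)
  pred <- as_binary_truth(pred)
  if (!length(truth) || length(pred) != length(truth)) {
    stop("`pred` and `truth` must be non-empty and aligned", call. = FALSE)
  }
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else 2 * ppv * sens / (ppv + sens)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    f1 = f1, accuracy = (tp + tn) / length(truth)
  )
}

# DeLong structural components via midranks. v10: one pseudo-value per
# positive, v01: one per negative; AUC is the Mann-Whitney statistic with
# half-credit for ties.
delong_components <- function(scores, truth) {
  truth <- as_binary_truth(truth)
  if (length(scores) != length(truth)) stop("`scores` and `truth` must be aligned", call. = FALSE)
  pos <- scores[truth]
  neg <- scores[!truth]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  tx <- rank(pos, ties.method = "average")
  ty <- rank(neg, ties.method = "average")
  tz <- rank(c(pos, neg), ties.method = "average")
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

curve_result <- function(kind, points, auc, ci, method) {
  structure(
    list(
      kind = kind, points = points, auc = auc,
      ci_low = ci[1], ci_high = ci[2], ci_method = method
    ),
    class = "curve_result"
  )
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf(
    "<curve_result> %s: AUC %.4f [%.4f-%.4f] (%s)\n",
    x$kind, x$auc, x$ci_low, x$ci_high, x$ci_method
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.curve_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, auc = x$auc, ci_low = x$ci_low,
    ci_high = x$ci_high, ci_method = x$ci_method
  )
}

#' @importFrom generics tidy
#' @export
tidy.curve_result <- function(x, ...) x$points

#' AUROC with DeLong confidence interval
#'
#' Area under the ROC curve via the Mann-Whitney formulation (ties receive
#' half credit), with a 95% (by default) confidence interval from the DeLong
#' structural-components variance estimator.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param truth Logical/0-1 ground truth.
#' @param conf_level Confidence level.
#' @return A `curve_result` with ROC points (`fpr`, `tpr`, `threshold`).
#' @export
auroc_with_ci <- function(scores, truth, conf_level = 0.95) {
  truth <- as_binary_truth(truth)
  comp <- delong_components(scores, truth)
  v <- stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n
  if (comp$m == 1) v <- stats::var(comp$v01) / comp$n
  if (comp$n == 1) v <- stats::var(comp$v10) / comp$m
  if (is.na(v)) v <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(comp$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE) # last row of each tied block
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(!y)
  pts <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cum_tp[keep] / comp$m),
    fpr = c(0, cum_fp[keep] / comp$n)
  )
  curve_result("ROC", pts, comp$auc, ci, "delong")
}

# interpolation-free step-area under the precision-recall curve,
# tie-grouped; returns area only (fast path for bootstrapping)
aucpr_step <- function(scores, truth) {
  p_tot <- sum(truth)
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  recall <- tp / p_tot
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' AUCPR with bootstrap confidence interval
#'
#' Area under the precision-recall curve by interpolation-free step
#' integration over tie-grouped thresholds, with a percentile confidence
#' interval from a stratified bootstrap (positives and negatives resampled
#' separately).
#'
#' @inheritParams auroc_with_ci
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @return A `curve_result` with PR points (`recall`, `precision`,
#'   `threshold`).
#' @export
aucpr_with_ci <- function(scores, truth, conf_level = 0.95, n_boot = 2000, seed = 1L) {
  truth <- as_binary_truth(truth)
  if (sum(truth) == 0) stop("at least one positive is required for a PR curve", call. = FALSE)
  area <- aucpr_step(scores, truth)
  pos <- scores[truth]
  neg <- scores[!truth]
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(neg) > 0) {
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(n_boot), function(i) {
      sp <- sample(pos, length(pos), replace = TRUE)
      sn <- sample(neg, length(neg), replace = TRUE)
      aucpr_step(c(sp, sn), c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
    }, numeric(1))
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
    ci[1] <- min(ci[1], area)
    ci[2] <- max(ci[2], area)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  pts <- tibble::tibble(
    threshold = s[keep], recall = tp / sum(truth),
    precision = tp / (tp + fp)
  )
  curve_result("PR", pts, area, ci, sprintf("stratified bootstrap (%d)", n_boot))
}

#' DeLong test for two correlated AUROCs
#'
#' Nonparametric comparison of two classifiers scored on the same patients:
#' the paired difference of the Mann-Whitney AUCs divided by its
#' structural-components standard error, with a two-sided normal p-value.
#' Swapping the classifiers negates `z` and leaves `p_value` unchanged.
#'
#' @param scores_a,scores_b Score vectors on identical patients, same order.
#' @param truth Logical/0-1 ground truth.
#' @return Tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- as_binary_truth(truth)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(truth)) {
    stop("scores must be paired on identical patients", call. = FALSE)
  }
  ca <- delong_components(scores_a, truth)
  cb <- delong_components(scores_b, truth)
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  v <- (if (ca$m > 1) stats::var(d10) / ca$m else 0) +
    (if (ca$n > 1) stats::var(d01) / ca$n else 0)
  diff_auc <- ca$auc - cb$auc
  if (v <= 0) {
    z <- 0
    p <- 1
    if (abs(diff_auc) > 1e-12) {
      z <- sign(diff_auc) * Inf
      p <- 0
    }
  } else {
    z <- diff_auc / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, z = z, p_value = p)
}

#' Multiple DeLong comparisons against a common reference
#'
#' @param score_list Named list of score vectors (paired on the same
#'   patients).
#' @param reference Name of the reference classifier in `score_list`.
#' @param truth Ground truth.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Tibble with one row per non-reference classifier.
#' @export
delong_tests <- function(score_list, reference, truth, adjust = "none") {
  stopifnot(reference %in% names(score_list))
  others <- setdiff(names(score_list), reference)
  out <- purrr::map_dfr(others, function(nm) {
    res <- delong_test(score_list[[nm]], score_list[[reference]], truth)
    tibble::tibble(classifier = nm, reference = reference, res)
  })
  if (adjust != "none" && nrow(out) > 1) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  out
}

#' Plot a ROC or PR curve
#'
#' @param object A `curve_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.curve_result <- function(object, ...) {
  lab <- sprintf(
    "%s: AUC %.3f [%.3f-%.3f]", object$kind, object$auc,
    object$ci_low, object$ci_high
  )
  if (object$kind == "ROC") {
    ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = lab
      ) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$points, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision", title = lab) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}
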