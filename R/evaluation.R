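#' @title Discrimination analysis
#' @description ROC-based evaluation of survival-probability scores:
#'   Mann-Whitney AUC with ties counted one half, the empirical ROC
#'   staircase, DeLong and stratified-bootstrap confidence intervals, and a
#'   Youden-index cutoff. Scores are survival probabilities and the positive
#'   class is "survived"; predicting death instead is a pure relabelling
#'   (flip the outcome, the AUC complements).
#' @name evaluation
NULL

check_two_classes <- function(outcome) {
  outcome <- as.numeric(outcome)
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    stop_ntriss("outcome must be 0/1 with no missing values",
                class = "ntriss_validation_error")
  }
  if (length(unique(outcome)) < 2L) {
    stop_ntriss("both outcome classes must be present; AUC is undefined",
                class = "ntriss_validation_error")
  }
  outcome
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen survivor receives a higher score than a
#' randomly chosen non-survivor, ties counted one half (the rank /
#' Mann-Whitney formulation). Equal to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param outcome 0/1 class labels (1 = positive, survived).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, outcome) {
  outcome <- check_two_classes(outcome)
  if (anyNA(scores)) {
    stop_ntriss("scores must not be missing", class = "ntriss_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  (sum(r[outcome == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' Thresholds run from above the maximum score (sensitivity 0, specificity 1)
#' down through every unique score; a case is called positive when its score
#' is >= the threshold. The trapezoidal area of the staircase equals [auc()].
#'
#' @inheritParams auc
#' @return object of class `roc_result`: `thresholds` (descending, `Inf`
#'   sentinel first), `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, outcome) {
  outcome <- check_two_classes(outcome)
  if (anyNA(scores)) {
    stop_ntriss("scores must not be missing", class = "ntriss_validation_error")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  # cumulative counts of cases at each unique score, high to low
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- outcome[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp_by_grp <- tapply(y_sorted, grp, sum)
  fp_by_grp <- tapply(1 - y_sorted, grp, sum)
  sens <- c(0, cumsum(tp_by_grp) / n_pos)
  spec <- c(1, 1 - cumsum(fp_by_grp) / n_neg)
  structure(list(thresholds = thr, sensitivity = unname(sens),
                 specificity = unname(spec),
                 auc = auc(scores, outcome), n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d positives / %d negatives, %d thresholds, AUC = %.4f\n",
              x$n_pos, x$n_neg, length(x$thresholds), x$auc))
  invisible(x)
}

# DeLong placement-value variance of the Mann-Whitney AUC
delong_variance <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  m <- length(pos)
  n <- length(neg)
  # placements via mid-ranks: V10_i = mean_j [pos_i > neg_j] + [==]/2
  all_r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  a <- mean(v10)
  s10 <- stats::var(v10)
  s01 <- stats::var(v01)
  list(auc = a, var = s10 / m + s01 / n)
}

#' Confidence interval for the AUC
#'
#' `method = "delong"` uses the closed-form placement-value variance of the
#' Mann-Whitney statistic with a normal interval (deterministic);
#' `method = "bootstrap"` uses the percentile interval over stratified
#' resamples (cases and non-cases resampled separately), seeded.
#'
#' @inheritParams auc
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates (default 2000; at least 200).
#' @param seed RNG seed for the bootstrap.
#' @return list: `ci_low`, `ci_high`, `auc`, `method`, `level`.
#' @export
auc_ci <- function(scores, outcome, method = c("delong", "bootstrap"),
                   level = 0.95, reps = 2000, seed = 1) {
  method <- match.arg(method)
  outcome <- check_two_classes(outcome)
  a <- auc(scores, outcome)
  alpha <- (1 - level) / 2
  if (method == "delong") {
    v <- delong_variance(scores, outcome)
    if (v$var <= 0) {
      warning("degenerate AUC variance; interval collapsed at the estimate")
      ci <- c(a, a)
    } else {
      z <- stats::qnorm(1 - alpha)
      ci <- pmin(1, pmax(0, a + c(-1, 1) * z * sqrt(v$var)))
    }
  } else {
    if (reps < 200) {
      stop_ntriss("bootstrap requires at least 200 replicates",
                  class = "ntriss_config_error")
    }
    ipos <- which(outcome == 1)
    ineg <- which(outcome == 0)
    stats_boot <- with_seed(seed, {
      vapply(seq_len(reps), function(r) {
        bp <- sample(ipos, length(ipos), replace = TRUE)
        bn <- sample(ineg, length(ineg), replace = TRUE)
        idx <- c(bp, bn)
        auc(scores[idx], outcome[idx])
      }, numeric(1))
    })
    ci <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
    if (ci[1] == ci[2]) {
      warning("degenerate bootstrap distribution; interval collapsed")
    }
  }
  list(ci_low = ci[1], ci_high = ci[2], auc = a, method = method,
       level = level)
}

#' Optimal score cutoff
#'
#' Youden's index: the threshold maximising sensitivity + specificity - 1.
#' Ties are broken toward the higher threshold (the more specific rule when
#' the clinical question is flagging probable deaths). The `Inf` sentinel is
#' never returned; a tie at the top yields the highest finite threshold.
#'
#' @param roc a [roc_curve()] result.
#' @param method currently only `"youden"`.
#' @return list: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(roc, method = "youden") {
  stopifnot(inherits(roc, "roc_result"))
  if (!identical(method, "youden")) {
    stop_ntriss("unknown cutoff method: ", method,
                class = "ntriss_config_error")
  }
  j <- roc$sensitivity + roc$specificity - 1
  finite <- is.finite(roc$thresholds)
  jf <- j[finite]
  # which.max returns the first (highest-threshold) maximiser: thresholds
  # are stored in descending order
  k <- which.max(jf)
  idx <- which(finite)[k]
  list(cutoff = roc$thresholds[idx],
       sensitivity = roc$sensitivity[idx],
       specificity = roc$specificity[idx],
       youden = j[idx])
}

#' Full discrimination report for a score vector
#'
#' Bundles AUC, its confidence interval, and the Youden cutoff with its
#' sensitivity and specificity, mirroring the usual reporting layout for
#' survival-probability models (sens %, spec %, cutoff, CI, AUC).
#'
#' @inheritParams auc_ci
#' @return list of class `ntriss_evaluation` with `auc`, `ci_low`, `ci_high`,
#'   `ci_method`, `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, outcome, method = c("delong", "bootstrap"),
                            level = 0.95, reps = 2000, seed = 1) {
  method <- match.arg(method)
  keep <- !is.na(scores)
  scores <- scores[keep]
  outcome <- as.numeric(outcome)[keep]
  roc <- roc_curve(scores, outcome)
  ci <- auc_ci(scores, outcome, method = method, level = level, reps = reps,
               seed = seed)
  cut <- optimal_cutoff(roc)
  structure(list(auc = roc$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 ci_method = method, level = level, cutoff = cut$cutoff,
                 sensitivity = cut$sensitivity,
                 specificity = cut$specificity,
                 n_pos = roc$n_pos, n_neg = roc$n_neg),
            class = "ntriss_evaluation")
}

#' @export
print.ntriss_evaluation <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f (%s %.0f%% CI %.3f-%.3f), cutoff %.3f: sens %.1f%%, spec %.1f%%\n",
    x$auc, x$ci_method, 100 * x$level, x$ci_low, x$ci_high, x$cutoff,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
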