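#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth equal-length binary label vectors (logical, 0/1,
#'   or two-level character/factor).
#' @param positive label counted as the positive (case) class; defaults to
#'   `TRUE`, `1`, or the last sorted level.
#' @return An object of class `"confusion_matrix"`: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(predicted, truth, positive = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  to_bin <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    ux <- sort(unique(as.character(x)))
    if (is.null(positive)) positive <<- ux[length(ux)]
    as.character(x) == positive
  }
  if (!is.null(positive) && !is.logical(predicted) &&
      !is.numeric(predicted)) {
    p <- as.character(predicted) == positive
    t <- as.character(truth) == positive
  } else {
    p <- to_bin(predicted); t <- to_bin(truth)
  }
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("+", "-"),
                              truth = c("+", "-")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A metric whose denominator
#' is zero is reported as `NA` (not available), never as 0.
#'
#' @param cm a [confusion()] result, or a list with `TP`, `FP`, `FN`, `TN`.
#' @return list of class `"metric_set"` with the four metrics.
#' @export
metrics <- function(cm) {
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = (tp + tn) / total,
                 precision = ratio(tp, tp + fp),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  precision %.4f  sensitivity %.4f  specificity %.4f\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity))
  invisible(x)
}

#' ROC curve and AUC with confidence interval
#'
#' Sweeps the decision threshold over the unique scores to trace the ROC
#' curve. The AUC is the rank (Mann-Whitney U) form, which handles ties
#' exactly and equals the trapezoidal area under the swept curve. The 95%
#' interval uses the Hanley-McNeil standard error by default, or a seeded
#' stratified bootstrap.
#'
#' @param scores numeric scores (higher = more case-like), e.g. disease
#'   posteriors.
#' @param truth binary truth vector (see [confusion()]).
#' @param level confidence level (default 0.95).
#' @param ci_method `"hanley"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param positive positive-class label for non-logical `truth`.
#' @return list of class `"roc_result"`: `points` (data.frame fpr/tpr from
#'   (0,0) to (1,1)), `auc`, `ci` (lower, upper), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, level = 0.95, ci_method = c("hanley",
                    "bootstrap"), boot_n = 2000L, seed = 1L,
                    positive = NULL) {
  ci_method <- match.arg(ci_method)
  scores <- as.numeric(scores)
  if (is.logical(truth)) y <- truth
  else if (is.numeric(truth)) y <- truth != 0
  else {
    ux <- sort(unique(as.character(truth)))
    if (is.null(positive)) positive <- ux[length(ux)]
    y <- as.character(truth) == positive
  }
  if (length(scores) != length(y)) stop("scores and truth differ in length")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one positive and one negative")
  auc_of <- function(s, yy) {
    r <- rank(s)
    (sum(r[yy]) - sum(yy) * (sum(yy) + 1) / 2) / (sum(yy) * sum(!yy))
  }
  auc <- auc_of(scores, y)
  # threshold sweep (descending unique scores)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)  # last index of each tie block
  points <- data.frame(fpr = c(0, fp[keep] / n0),
                       tpr = c(0, tp[keep] / n1))
  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    set.seed(as.integer(seed) %% 2147483647L)
    ip <- which(y); ineg <- which(!y)
    boots <- vapply(seq_len(boot_n), function(i) {
      bi <- c(sample(ip, n1, replace = TRUE),
              sample(ineg, n0, replace = TRUE))
      auc_of(scores[bi], y[bi])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c((1 - level) / 2,
                                          1 - (1 - level) / 2)))
  }
  structure(list(points = points, auc = auc, ci = ci,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (95%% CI %.4f - %.4f), %d+/%d-\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Hold-out validation of a fitted network
#'
#' Scores every test record by its exact disease posterior (any variables
#' missing from a record are marginalized out), classifies at the given
#' threshold, and reports the confusion matrix, the four classification
#' metrics and the ROC/AUC.
#'
#' @param net a [bayes_net()] containing a binary `disease` node.
#' @param test discrete data.frame holding the network's variables,
#'   including the true disease column.
#' @param disease disease node name.
#' @param threshold classification cut-off (default 0.5).
#' @param yes_state disease-present state (default: the node's second
#'   state).
#' @return list of class `"bn_evaluation"`: `scores`, `truth`,
#'   `confusion`, `metrics`, `roc`.
#' @export
evaluate_bn <- function(net, test, disease, threshold = 0.5,
                        yes_state = NULL) {
  stopifnot(inherits(net, "bayes_net"), is.data.frame(test))
  states <- net$nodes[[disease]]$states
  if (is.null(yes_state)) yes_state <- states[2L]
  if (!disease %in% names(test)) stop("test set lacks the disease column")
  predictors <- intersect(setdiff(names(net$nodes), disease), names(test))
  scores <- vapply(seq_len(nrow(test)), function(i) {
    ev <- lapply(test[i, predictors, drop = FALSE], as.character)
    predictive_probability(net, disease, ev, yes_state)
  }, numeric(1))
  truth <- as.character(test[[disease]]) == yes_state
  cm <- confusion(scores > threshold, truth)
  structure(list(scores = scores, truth = truth, confusion = cm,
                 metrics = metrics(cm),
                 roc = roc_auc(scores, truth)),
            class = "bn_evaluation")
}

#' @export
print.bn_evaluation <- function(x, ...) {
  print(x$confusion)
  print(x$metrics)
  print(x$roc)
  invisible(x)
}
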