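#' ROC and precision-recall curves for scored pair sets
#'
#' Sweeps thresholds over the unique scores of a scored pair set (lower
#' score = stronger call, e.g. adjusted p or FDR q), grouping ties at one
#' threshold, and returns the ROC curve with trapezoidal AUC and the
#' precision-recall curve with step-weighted average precision
#' (AP = sum over thresholds of precision x recall increment).
#'
#' @param score Numeric vector; lower is better.
#' @param label Logical vector: TRUE = pair in ground truth.
#' @return list(roc = data.frame(fpr, tpr), auc, pr = data.frame(recall,
#'   precision), average_precision).
#' @examples
#' roc_pr_eval(c(.01, .02, .03, .04), c(TRUE, FALSE, TRUE, FALSE))$auc
#' @export
roc_pr_eval <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  if (!any(label)) stop("no positive labels")
  if (all(label)) stop("no negative labels")
  np <- sum(label); nn <- sum(!label)
  ord <- order(score)
  s <- score[ord]; l <- label[ord]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / np
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = recall, precision = precision),
       average_precision = ap)
}

#' Fold enrichment of significant discoveries over random selection
#'
#' fold = (|significant & known| / |significant|) /
#' (|known| / |universe|): how much more often significant nominations hit
#' known physical relationships than a random draw of the same size
#' would.
#'
#' @param significant_pairs,known_pairs,universe_pairs Character vectors
#'   of pair keys; `known_pairs` must be a subset of the universe.
#' @return The fold (NaN with a warning when no pair is significant).
#' @export
enrichment_over_random <- function(significant_pairs, known_pairs,
                                   universe_pairs) {
  universe_pairs <- unique(universe_pairs)
  significant_pairs <- unique(significant_pairs)
  known_pairs <- unique(known_pairs)
  if (length(setdiff(known_pairs, universe_pairs)))
    stop("known pairs must be a subset of the universe")
  if (!length(significant_pairs)) {
    warning("no significant pairs; fold undefined")
    return(NaN)
  }
  hit <- mean(significant_pairs %in% known_pairs)
  base <- length(known_pairs) / length(universe_pairs)
  hit / base
}

#' Head-to-head comparison of pairwise and LASSO discovery
#'
#' Computes ROC/PR curves for two scorings of one pair universe (e.g.
#' adjusted pairwise-correlation p vs LASSO FDR q), their AUC and average
#' -precision deltas (LASSO minus pairwise), and a bootstrap percentile
#' confidence interval for the AUC delta obtained by resampling pairs.
#' Pairs a method never scores should carry the worst (largest) score so
#' both methods are compared on the same universe.
#'
#' @param pairwise_scored,lasso_scored data.frames with columns
#'   `pair_id`, `score`, `label` over the same universe.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return list(pairwise, lasso — [roc_pr_eval()] results, delta_auc,
#'   delta_ap, ci_delta_auc — 95% percentile interval).
#' @export
compare_methods <- function(pairwise_scored, lasso_scored, n_boot = 1000,
                            seed = 1) {
  if (!setequal(pairwise_scored$pair_id, lasso_scored$pair_id) ||
      nrow(pairwise_scored) != nrow(lasso_scored)) {
    nd <- length(union(setdiff(pairwise_scored$pair_id, lasso_scored$pair_id),
                       setdiff(lasso_scored$pair_id, pairwise_scored$pair_id)))
    stop("score sets cover different universes (symmetric difference: ",
         nd, " pairs)")
  }
  l <- lasso_scored[match(pairwise_scored$pair_id, lasso_scored$pair_id), ]
  if (!identical(as.logical(pairwise_scored$label), as.logical(l$label)))
    stop("labels disagree between the two score sets")
  pw <- roc_pr_eval(pairwise_scored$score, pairwise_scored$label)
  la <- roc_pr_eval(l$score, l$label)
  set.seed(seed)
  n <- nrow(pairwise_scored)
  deltas <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(pairwise_scored$label[i])) < 2) return(NA_real_)
    roc_pr_eval(l$score[i], l$label[i])$auc -
      roc_pr_eval(pairwise_scored$score[i], pairwise_scored$label[i])$auc
  })
  list(pairwise = pw, lasso = la,
       delta_auc = la$auc - pw$auc,
       delta_ap = la$average_precision - pw$average_precision,
       ci_delta_auc = unname(stats::quantile(deltas, c(0.025, 0.975),
                                             na.rm = TRUE, type = 7)))
}
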