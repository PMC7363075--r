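# Score aggregation and evaluation statistics: bag-of-local-features
# lesion/subject scores, ROC/AUC, bootstrap confidence intervals,
# stratified test sets, confusion matrices.

#' Lesion score from patch probabilities
#'
#' The arithmetic mean of the patch probabilities on one lesion
#' (bag-of-local-features aggregation).
#'
#' @param probs Non-empty numeric vector of patch probabilities.
#' @return Scalar in `[0, 1]`.
#' @export
lesion_score <- function(probs) {
  if (length(probs) == 0) stop("no patch probabilities")
  mean(probs)
}

#' Subject score from lesion scores
#'
#' The maximum of the lesion scores; a subject with no proposed lesions
#' scores 0 (predicted healthy).
#'
#' @param lesion_scores Numeric vector (possibly empty).
#' @return Scalar in `[0, 1]`.
#' @export
subject_score <- function(lesion_scores) {
  if (length(lesion_scores) == 0) return(0)
  max(lesion_scores)
}

#' ROC curve and AUC
#'
#' The AUC equals the probability that a random positive outscores a random
#' negative, with ties counted one half (rank/Mann-Whitney formulation).
#' ROC points are computed at every distinct score threshold.
#'
#' @param scores Numeric scores, higher = more stroke-like.
#' @param labels Binary labels (1 = stroke).
#' @return An `eval_result` list: `roc` (data.frame with threshold, fpr,
#'   tpr), `auc`, `n`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(threshold = th,
                    fpr = vapply(th, function(t)
                      sum(scores >= t & labels == 0) / nn, numeric(1)),
                    tpr = vapply(th, function(t)
                      sum(scores >= t & labels == 1) / np, numeric(1)))
  structure(list(roc = roc, auc = auc, n = length(scores)),
            class = "eval_result")
}

#' Bootstrap confidence interval for the AUC
#'
#' Repeats `reps` times: draw `m` samples with replacement from the test
#' set, compute the AUC; report the nearest-rank 2.5th and 97.5th
#' percentiles of the sorted AUCs.  Resamples containing a single class are
#' redrawn (up to `max_retry` times each).
#'
#' @param scores,labels Test-set scores and binary labels.
#' @param reps Bootstrap repetitions.
#' @param m Resample size.
#' @param seed Integer seed.
#' @param max_retry Retry cap for degenerate resamples.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, reps = 1000, m = 100,
                             seed = 1L, max_retry = 1000) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n <- length(scores)
  with_seed(seed, {
    aucs <- numeric(reps)
    for (i in seq_len(reps)) {
      for (try in seq_len(max_retry)) {
        idx <- sample(n, m, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        if (try == max_retry) stop("could not draw a two-class resample")
      }
      aucs[i] <- roc_auc(scores[idx], labels[idx])$auc
    }
    s <- sort(aucs)
    lo <- s[max(1, ceiling(0.025 * reps))]
    hi <- s[ceiling(0.975 * reps)]
    structure(c(low = lo, high = hi), aucs = aucs)
  })
}

#' Stratified balanced test-set selection
#'
#' Within every stratum (scanner model or age decade), selects equal
#' numbers of stroke and healthy subjects -- `min(n_stroke, n_healthy)` of
#' each, sampled without replacement.  Strata missing a class contribute
#' nothing.
#'
#' @param records Data.frame with columns `subject_id`, `label`, and the
#'   stratification variable (`scanner_model` or `age`).
#' @param key `"scanner"` or `"age_decade"`.
#' @param seed Integer seed.
#' @return The selected subset of `records` (with an `age_decade` column
#'   when stratifying by age).
#' @export
stratify_test_set <- function(records, key = c("scanner", "age_decade"),
                              seed = 1L) {
  key <- match.arg(key)
  if (key == "age_decade") records$age_decade <- floor(records$age / 10)
  kv <- if (key == "scanner") records$scanner_model else records$age_decade
  with_seed(seed, {
    out <- NULL
    for (s in unique(kv)) {
      sub <- records[kv == s, , drop = FALSE]
      ns <- sum(sub$label == 1); nh <- sum(sub$label == 0)
      k <- min(ns, nh)
      if (k == 0) next
      pick <- c(sample(which(sub$label == 1), k),
                sample(which(sub$label == 0), k))
      out <- rbind(out, sub[pick, , drop = FALSE])
    }
    if (is.null(out)) stop("every stratum is degenerate (missing a class)")
    out
  })
}

#' Confusion matrix at a score threshold
#'
#' Predicted positive iff `score >= t`.
#'
#' @param scores Numeric subject scores.
#' @param labels Binary labels (1 = stroke).
#' @param t Threshold (reference operating point 0.3).
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_at_threshold <- function(scores, labels, t = 0.3) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= t)
  c(TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    FN = sum(pred == 0 & labels == 1),
    TN = sum(pred == 0 & labels == 0))
}

#' Recompute headline statistics from deposited classification datapoints
#'
#' Given a CSV of per-subject prediction/ground-truth datapoints (columns
#' `score`, `label`, `test_set` with values `unstratified`, `scanner`,
#' `age`; optionally per-volume `dice` columns tagged `masking` =
#' enabled/disabled), recomputes the test-set sizes, the confusion counts
#' at threshold 0.3 on the unstratified set, per-set AUCs, and the mean
#' per-volume proposal Dice per masking condition.
#'
#' @param path CSV file path.
#' @return List with `sizes`, `confusion`, `aucs`, `mean_dice`.
#' @export
deposited_datapoint_stats <- function(path) {
  if (!file.exists(path))
    stop("deposited datapoints file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- d[!is.na(d$score), , drop = FALSE]
  sizes <- table(cls$test_set)
  un <- cls[cls$test_set == "unstratified", , drop = FALSE]
  conf <- confusion_at_threshold(un$score, un$label, 0.3)
  aucs <- vapply(split(cls, cls$test_set),
                 function(s) roc_auc(s$score, s$label)$auc, numeric(1))
  mean_dice <- if ("dice" %in% names(d)) {
    dd <- d[!is.na(d$dice), , drop = FALSE]
    tapply(dd$dice, dd$masking, mean)
  } else NULL
  list(sizes = sizes, confusion = conf, aucs = aucs, mean_dice = mean_dice)
}

#' Write a predictions CSV
#'
#' @param scores Data.frame with columns subject_id, score, label.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
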