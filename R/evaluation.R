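#' Construct a ground-truth list explicitly
#'
#' @param positives,negatives disjoint character vectors of instance ids.
#' @param sampling_seed,replicate_index bookkeeping metadata.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(positives, negatives, sampling_seed = NA_integer_,
                         replicate_index = 1L) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(intersect(positives, negatives)) > 0L)
    stop("positives and negatives overlap")
  structure(list(positives = positives, negatives = negatives,
                 sampling_seed = as.integer(sampling_seed),
                 replicate_index = as.integer(replicate_index)),
            class = "ground_truth")
}

#' Sample a balanced negative set for one ground-truth replicate
#'
#' Negatives are drawn uniformly without replacement from the candidate
#' pool minus the positives, matching the number of positives (no public
#' negative drug-disease relations exist, so tissue-matched random
#' instances stand in). Deterministic under `seed`.
#'
#' @param positives character vector of positive instance ids.
#' @param pool character vector of candidate instance ids.
#' @param seed integer seed.
#' @param replicate_index bookkeeping index; default 1.
#' @return object of class `"ground_truth"`: list with `positives`,
#'   `negatives`, `sampling_seed`, `replicate_index`.
#' @export
sample_negatives <- function(positives, pool, seed = 1L,
                             replicate_index = 1L) {
  positives <- unique(as.character(positives))
  candidates <- setdiff(unique(as.character(pool)), positives)
  if (length(candidates) < length(positives))
    stop("candidate pool too small for balanced negative sampling")
  set.seed(as.integer(seed))
  negatives <- sample(candidates, length(positives))
  structure(list(positives = positives, negatives = negatives,
                 sampling_seed = as.integer(seed),
                 replicate_index = as.integer(replicate_index)),
            class = "ground_truth")
}

#' Build the replicated ground-truth lists
#'
#' `n` independent balanced samplings with derived seeds
#' `master_seed + 1 .. master_seed + n`; replicates may overlap in their
#' negatives.
#'
#' @inheritParams sample_negatives
#' @param n number of samplings; default 10.
#' @param master_seed integer master seed.
#' @return list of `n` [sample_negatives()] results.
#' @export
build_ground_truths <- function(positives, pool, n = 10L,
                                master_seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i)
    sample_negatives(positives, pool, seed = as.integer(master_seed) + i,
                     replicate_index = i))
}

# named score lookup restricted to a ground truth's instances
truth_scores <- function(scores, truth) {
  ids <- c(truth$positives, truth$negatives)
  miss <- setdiff(ids, names(scores))
  if (length(miss) > 0L)
    stop("scores missing for instances: ", paste(head(miss, 5L),
                                                 collapse = ", "))
  list(s = unname(scores[ids]),
       y = c(rep(1L, length(truth$positives)),
             rep(0L, length(truth$negatives))),
       ids = ids)
}

#' Area under the ROC curve
#'
#' Mann-Whitney pair statistic: the fraction of (positive, negative) pairs
#' where the positive scores higher, ties counting 0.5.
#'
#' @param scores named numeric vector (instance id -> score, higher =
#'   more drug-like for the indication).
#' @param truth a [sample_negatives()] ground truth.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
  ts <- truth_scores(scores, truth)
  r <- rank(ts$s)                      # average ranks = 0.5 per tied pair
  P <- sum(ts$y == 1L); N <- sum(ts$y == 0L)
  (sum(r[ts$y == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration down the ranked list with tied scores grouped:
#' each tied block contributes its recall increment times the precision at
#' the block's end. A fully tied list therefore scores the prevalence;
#' a single positive ranked last of n scores 1/n.
#'
#' @inheritParams auroc
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, truth) {
  ts <- truth_scores(scores, truth)
  o <- order(-ts$s)
  s <- ts$s[o]; y <- ts$y[o]
  P <- sum(y == 1L)
  blocks <- split(seq_along(s), match(s, unique(s)))
  tp <- 0; n_seen <- 0; area <- 0
  for (b in blocks) {
    tp_new <- tp + sum(y[b] == 1L)
    n_new <- n_seen + length(b)
    area <- area + (tp_new - tp) / P * (tp_new / n_new)
    tp <- tp_new; n_seen <- n_new
  }
  area
}

#' Binarize a ranking into predicted labels
#'
#' Predicts positive for the top `m` instances of the ground truth by
#' score, with ties broken by instance id; `m` defaults to the number of
#' positives (balanced lists make this a median split). A fixed score
#' `threshold` may be used instead.
#'
#' @inheritParams auroc
#' @param m number of predicted positives; default `|positives|`.
#' @param threshold optional score cutoff overriding the top-m rule
#'   (predict positive where score >= threshold).
#' @return named integer vector of predicted labels over the truth's
#'   instances.
#' @export
binarize <- function(scores, truth, m = length(truth$positives),
                     threshold = NULL) {
  ts <- truth_scores(scores, truth)
  pred <- if (is.null(threshold)) {
    o <- order(-ts$s, ts$ids, method = "radix")
    p <- integer(length(ts$s)); p[o[seq_len(m)]] <- 1L; p
  } else as.integer(ts$s >= threshold)
  structure(pred, names = ts$ids)
}

# confusion counts of predicted vs true labels over a ground truth
confusion <- function(pred, truth) {
  y <- structure(c(rep(1L, length(truth$positives)),
                   rep(0L, length(truth$negatives))),
                 names = c(truth$positives, truth$negatives))
  pred <- pred[names(y)]
  c(tp = sum(pred == 1L & y == 1L), fp = sum(pred == 1L & y == 0L),
    fn = sum(pred == 0L & y == 1L), tn = sum(pred == 0L & y == 0L))
}

#' F1 score of predicted labels
#'
#' Harmonic mean of precision and recall, `2TP / (2TP + FP + FN)`.
#'
#' @param pred named 0/1 predictions from [binarize()].
#' @param truth the ground truth.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(pred, truth) {
  cm <- confusion(pred, truth)
  denom <- 2 * cm["tp"] + cm["fp"] + cm["fn"]
  if (denom == 0) return(0)
  unname(2 * cm["tp"] / denom)
}

#' Accuracy of predicted labels
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams f1_score
#' @return accuracy in [0, 1].
#' @export
accuracy_score <- function(pred, truth) {
  cm <- confusion(pred, truth)
  unname((cm["tp"] + cm["tn"]) / sum(cm))
}

#' Evaluate a drug ranking over replicated ground truths
#'
#' Computes AUROC, AUPR, F1 and accuracy per replicate (F1/accuracy via
#' the top-m binarisation) and aggregates them.
#'
#' @param scores named numeric score vector (e.g. `coef()` of a
#'   [drugresc()] fit).
#' @param truths list of ground truths from [build_ground_truths()].
#' @return object of class `"metric_report"`: list with `per_replicate`
#'   (data.frame) and `aggregate` (mean and sd per metric).
#' @export
evaluate_scores <- function(scores, truths) {
  rows <- lapply(truths, function(tr) {
    pred <- binarize(scores, tr)
    data.frame(replicate = tr$replicate_index,
               auroc = auroc(scores, tr), aupr = aupr(scores, tr),
               f1 = f1_score(pred, tr),
               accuracy = accuracy_score(pred, tr))
  })
  aggregate_metrics(do.call(rbind, rows))
}

#' Aggregate per-replicate metrics
#'
#' Mean and sample standard deviation per metric. With a single replicate
#' the sd is reported as 0 and flagged.
#'
#' @param per_replicate data.frame with columns `replicate, auroc, aupr,
#'   f1, accuracy`.
#' @return a `"metric_report"` object.
#' @export
aggregate_metrics <- function(per_replicate) {
  metrics <- c("auroc", "aupr", "f1", "accuracy")
  single <- nrow(per_replicate) == 1L
  agg <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m)
                      mean(per_replicate[[m]]), numeric(1L)),
                    sd = vapply(metrics, function(m)
                      if (single) 0 else sd(per_replicate[[m]]),
                      numeric(1L)))
  structure(list(per_replicate = per_replicate, aggregate = agg,
                 sd_degenerate = single),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report over %d replicate(s)%s\n",
              nrow(x$per_replicate),
              if (x$sd_degenerate) " (single replicate: sd set to 0)"
              else ""))
  print.data.frame(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}
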