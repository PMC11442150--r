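#' Fit the cell-phenotype random forest on a D2C matrix
#'
#' Observations are cells, features are drug instances. `ntree`
#' classification trees (Gini impurity, unlimited depth, minimum node size
#' 1) are grown on bootstrap resamples of the cells; the bootstrap draw of
#' every tree is recorded so its out-of-bag (OOB) set is available for
#' permutation importance. Deterministic under `seed`. If a bootstrap draw
#' leaves some tree with an empty OOB set (essentially impossible beyond
#' toy sizes) the forest is refit with a shifted seed.
#'
#' @param d2c a [d2c_matrix()].
#' @param labels a [cell_labels()] vector covering exactly the matrix's
#'   cells; both classes must be present with >= 2 cells each.
#' @param ntree number of trees; default 100.
#' @param mtry number of candidate split variables; default
#'   `floor(sqrt(D))`.
#' @param seed integer seed.
#' @return object of class `"drugresc_forest"`: list with the fitted
#'   `randomForest` object `rf`, `inbag` (cells x trees bootstrap counts),
#'   `oob` (list of OOB cell indices per tree), `ntree`, `mtry`, `seed`.
#' @export
fit_forest <- function(d2c, labels, ntree = 100L, mtry = NULL, seed = 1L) {
  xy <- d2c_design(d2c, labels)
  if (min(table(xy$y)) < 2L) stop("need at least 2 cells in each class")
  D <- ncol(xy$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(D)))
  if (mtry < 1L || mtry > D) stop("mtry outside [1, D]")
  for (attempt in 0:9) {
    set.seed(as.integer(seed) + attempt)
    rf <- randomForest::randomForest(x = xy$x, y = xy$y,
                                     ntree = as.integer(ntree),
                                     mtry = as.integer(mtry),
                                     keep.inbag = TRUE, keep.forest = TRUE)
    oob <- lapply(seq_len(ntree), function(t) which(rf$inbag[, t] == 0L))
    if (all(lengths(oob) > 0L)) break
  }
  if (any(lengths(oob) == 0L)) stop("a tree has an empty out-of-bag set")
  structure(list(rf = rf, inbag = rf$inbag, oob = oob,
                 ntree = as.integer(ntree), mtry = as.integer(mtry),
                 seed = as.integer(seed), x = xy$x, y = xy$y),
            class = "drugresc_forest")
}

#' @export
print.drugresc_forest <- function(x, ...) {
  cat(sprintf(paste0("drugresc_forest: %d trees, mtry = %d, %d cells x %d",
                     " instances, OOB error %.3f\n"),
              x$ntree, x$mtry, nrow(x$x), ncol(x$x),
              x$rf$err.rate[x$ntree, "OOB"]))
  invisible(x)
}

# cells x instances design matrix + factor response, labels exact-matched
d2c_design <- function(d2c, labels) {
  stopifnot(inherits(d2c, "d2c_matrix"))
  y <- align_labels(labels, d2c$cells)
  if (length(unique(y)) < 2L)
    stop("both phenotype classes must be present")
  list(x = t(d2c$scores), y = factor(y, levels = c(0L, 1L)))
}

#' Select mtry by minimum out-of-bag error over a grid
#'
#' One forest is fit per candidate value; the candidate with the smallest
#' OOB error rate wins, ties going to the smallest mtry.
#'
#' @param d2c a [d2c_matrix()].
#' @param labels a [cell_labels()] vector.
#' @param grid integer candidates in `[1, D]`; default
#'   [default_mtry_grid()] of the instance count.
#' @param ntree trees per candidate forest; default 100.
#' @param seed integer seed (same seed for every candidate).
#' @return the selected mtry (integer).
#' @export
select_mtry <- function(d2c, labels, grid = NULL, ntree = 100L, seed = 1L) {
  D <- length(d2c$instances)
  if (is.null(grid)) grid <- default_mtry_grid(D)
  grid <- as.integer(grid)
  if (any(grid < 1L | grid > D)) stop("mtry grid values outside [1, D]")
  grid <- sort(unique(grid))
  err <- vapply(grid, function(m) {
    fm <- fit_forest(d2c, labels, ntree = ntree, mtry = m, seed = seed)
    fm$rf$err.rate[ntree, "OOB"]
  }, numeric(1L))
  grid[which.min(err)]   # first minimum = smallest mtry on ties
}

#' Raw drug score from per-tree correct-vote counts
#'
#' The permutation importance of one drug instance is the mean over trees
#' of the drop in correct out-of-bag votes caused by permuting that
#' instance's D2C values:
#' \deqn{score_d = \frac{1}{ntree}\sum_t (C_{td} - CP_{td}),}
#' where \eqn{C_{td}} and \eqn{CP_{td}} count correct OOB class votes of
#' tree t before and after the permutation. Counts are used as-is, not
#' divided by the OOB size.
#'
#' @param correct vector of per-tree correct-vote counts before
#'   permutation.
#' @param permuted matching counts after permutation.
#' @return single numeric raw score.
#' @export
#' @examples
#' drug_score_from_votes(c(10, 8), c(6, 8))  # 2
drug_score_from_votes <- function(correct, permuted) {
  stopifnot(length(correct) == length(permuted), length(correct) >= 1L)
  mean(correct - permuted)
}

#' Out-of-bag permutation importance of every drug instance
#'
#' For each tree t, the correct-vote count \eqn{C_{td}} over its OOB cells
#' is computed from the tree's own predictions; then instance d's D2C
#' values are permuted within the OOB set (one fresh permutation per
#' (d, t) pair, streamed from a seeded generator), the OOB cells are passed
#' back through tree t, and the permuted count \eqn{CP_{td}} is taken. The
#' raw score is [drug_score_from_votes()] over trees. An instance whose
#' column is constant has raw score exactly 0.
#'
#' @param model a [fit_forest()] result.
#' @param seed integer seed for the permutation stream.
#' @param scale `"count"` (default): the raw-count form above;
#'   `"rate"`: each per-tree difference divided by that tree's OOB size
#'   (the conventional mean-decrease-accuracy).
#' @param n_permutations inner permutations averaged per (d, t); default 1.
#' @return a drug score table (data.frame with columns `instance_id,
#'   drug_name, method, raw_score, standardized_score, rank`).
#' @export
oob_permutation_importance <- function(model, seed = 1L,
                                       scale = c("count", "rate"),
                                       n_permutations = 1L) {
  stopifnot(inherits(model, "drugresc_forest"))
  scale <- match.arg(scale)
  rf <- model$rf; x <- model$x; y <- model$y
  ntree <- model$ntree; D <- ncol(x)
  oob <- model$oob
  oob_sizes <- lengths(oob)

  base <- predict(rf, x, predict.all = TRUE)$individual
  C_t <- vapply(seq_len(ntree), function(t)
    sum(base[oob[[t]], t] == y[oob[[t]]]), numeric(1L))

  block_end <- cumsum(oob_sizes * n_permutations)
  block_start <- c(1L, head(block_end, -1L) + 1L)

  set.seed(as.integer(seed))
  raw <- numeric(D)
  for (d in seq_len(D)) {
    stacked <- matrix(0, nrow = sum(oob_sizes) * n_permutations, ncol = D,
                      dimnames = list(NULL, colnames(x)))
    pos <- 1L
    for (t in seq_len(ntree)) {
      idx <- oob[[t]]
      for (r in seq_len(n_permutations)) {
        blk <- x[idx, , drop = FALSE]
        blk[, d] <- blk[sample.int(length(idx)), d]
        stacked[pos:(pos + length(idx) - 1L), ] <- blk
        pos <- pos + length(idx)
      }
    }
    pred <- predict(rf, stacked, predict.all = TRUE)$individual
    diff_t <- numeric(ntree)
    for (t in seq_len(ntree)) {
      rows <- block_start[t]:block_end[t]
      truth <- rep(as.character(y[oob[[t]]]), n_permutations)
      cp <- sum(pred[rows, t] == truth) / n_permutations
      diff_t[t] <- C_t[t] - cp
    }
    if (scale == "rate") diff_t <- diff_t / oob_sizes
    raw[d] <- mean(diff_t)
  }
  new_score_table(colnames(x), model$drug_names, "random_forest", raw)
}

#' Min-max standardise raw drug scores to [0, 1]
#'
#' `(s - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#' If all scores are equal the standardised score is defined as 0.5 for
#' every instance, with a warning.
#'
#' @param raw numeric vector, length >= 2.
#' @return numeric vector in [0, 1].
#' @export
standardize_scores <- function(raw) {
  stopifnot(length(raw) >= 2L)
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    warning("all raw scores equal; standardized scores set to 0.5")
    return(rep(0.5, length(raw)))
  }
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

# assemble a DrugScoreTable: standardized scores and gapless ranks,
# ties broken by (-score, instance_id)
new_score_table <- function(instance_ids, drug_names, method, raw,
                            votes = NULL) {
  if (is.null(drug_names)) drug_names <- instance_ids
  std <- suppressWarnings(standardize_scores(raw))
  ord <- order(-raw, instance_ids, method = "radix")
  rank <- integer(length(raw)); rank[ord] <- seq_along(raw)
  out <- data.frame(instance_id = instance_ids, drug_name = drug_names,
                    method = method, raw_score = raw,
                    standardized_score = std, rank = rank,
                    stringsAsFactors = FALSE)
  if (!is.null(votes)) out$votes <- votes
  class(out) <- c("drug_score_table", "data.frame")
  out
}

#' @export
print.drug_score_table <- function(x, n = 10L, ...) {
  cat(sprintf("drug_score_table (%s): %d instances\n",
              x$method[1L], nrow(x)))
  print.data.frame(head(x[order(x$rank), ], n), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}
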