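#' Wilcoxon rank-sum importance
#'
#' Per instance: two-sided rank-sum test of the D2C values between the two
#' phenotype groups; importance is `-log10(p)`. Exact p-values are used
#' when sample sizes permit and there are no ties; a constant column (or
#' identical group multisets) yields p = 1 and importance 0.
#'
#' @param d2c a [d2c_matrix()].
#' @param labels a [cell_labels()] vector.
#' @param drug_names optional instance -> drug-name vector.
#' @return a drug score table.
#' @export
wilcoxon_importance <- function(d2c, labels, drug_names = NULL) {
  xy <- d2c_design(d2c, labels)
  g1 <- xy$y == "1"
  raw <- apply(xy$x, 2L, function(v) {
    if (max(v) == min(v)) return(0)
    p <- suppressWarnings(
      wilcox.test(v[g1], v[!g1], alternative = "two.sided",
                  correct = FALSE)$p.value)
    if (!is.finite(p)) p <- 1
    -log10(max(p, .Machine$double.xmin))
  })
  new_score_table(colnames(xy$x), drug_names, "wilcoxon", unname(raw))
}

#' ANOVA / Welch F importance with a variance-homogeneity gate
#'
#' Per instance: Bartlett's test compares group variances at level 0.05.
#' Homogeneous variances route to the one-way ANOVA F statistic
#' (`oneway.test`, `var.equal = TRUE`); heterogeneous to the Welch F
#' (`var.equal = FALSE`). Importance is the F statistic. A constant column
#' scores 0.
#'
#' @inheritParams wilcoxon_importance
#' @param gate_level Bartlett test level; default 0.05.
#' @return a drug score table with attribute `"branch"` recording
#'   `"anova"` or `"welch"` per instance.
#' @export
anova_importance <- function(d2c, labels, gate_level = 0.05,
                             drug_names = NULL) {
  xy <- d2c_design(d2c, labels)
  grp <- xy$y
  branch <- character(ncol(xy$x))
  raw <- numeric(ncol(xy$x))
  for (j in seq_len(ncol(xy$x))) {
    v <- xy$x[, j]
    if (max(v) == min(v)) { raw[j] <- 0; branch[j] <- "degenerate"; next }
    bp <- tryCatch(bartlett.test(v, grp)$p.value, error = function(e) NA)
    homogeneous <- is.finite(bp) && bp >= gate_level
    branch[j] <- if (homogeneous) "anova" else "welch"
    f <- tryCatch(oneway.test(v ~ grp, var.equal = homogeneous)$statistic,
                  error = function(e) NA_real_)
    raw[j] <- if (is.finite(f)) unname(f) else 0
  }
  out <- new_score_table(colnames(xy$x), drug_names, "anova", raw)
  attr(out, "branch") <- structure(branch, names = colnames(xy$x))
  out
}

#' L1-penalised logistic regression importance
#'
#' Lasso logistic regression of phenotype on the (internally standardised)
#' D2C columns; the penalty is chosen by 5-fold cross-validation and the
#' importance of an instance is the absolute value of its coefficient on
#' the standardised scale (|coefficient| x feature sd). Fold assignment and
#' hence coefficients are deterministic under `seed`.
#'
#' @inheritParams wilcoxon_importance
#' @param seed integer seed controlling the CV folds.
#' @param nfolds CV folds; default 5.
#' @return a drug score table.
#' @export
logistic_l1_importance <- function(d2c, labels, seed = 1L, nfolds = 5L,
                                   drug_names = NULL) {
  xy <- d2c_design(d2c, labels)
  set.seed(as.integer(seed))
  cv <- glmnet::cv.glmnet(xy$x, xy$y, family = "binomial", alpha = 1,
                          nfolds = nfolds, standardize = TRUE)
  beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  sds <- apply(xy$x, 2L, sd)
  new_score_table(colnames(xy$x), drug_names, "logistic_l1",
                  abs(beta) * sds)
}

#' SVM (RBF) one-dimensional sensitivity importance
#'
#' Optional adapter over the e1071 learner. An RBF-kernel SVM is fit on
#' the D2C matrix; the importance of an instance is the range of the
#' model's decision value as that instance's column is swept over its
#' observed range while all other columns are held at their medians
#' (one-dimensional sensitivity analysis).
#'
#' @inheritParams logistic_l1_importance
#' @param n_grid sweep resolution; default 25.
#' @return a drug score table.
#' @export
svm_sensitivity_importance <- function(d2c, labels, seed = 1L,
                                       n_grid = 25L, drug_names = NULL) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the e1071 package is required for the SVM backend")
  xy <- d2c_design(d2c, labels)
  set.seed(as.integer(seed))
  fit <- e1071::svm(xy$x, xy$y, kernel = "radial", probability = FALSE)
  med <- apply(xy$x, 2L, median)
  raw <- vapply(seq_len(ncol(xy$x)), function(j) {
    grid <- seq(min(xy$x[, j]), max(xy$x[, j]), length.out = n_grid)
    nd <- matrix(rep(med, each = n_grid), nrow = n_grid,
                 dimnames = list(NULL, colnames(xy$x)))
    nd[, j] <- grid
    dv <- attr(predict(fit, nd, decision.values = TRUE),
               "decision.values")
    diff(range(dv))
  }, numeric(1L))
  new_score_table(colnames(xy$x), drug_names, "svm_sensitivity", raw)
}

#' Gradient-boosting gain importance
#'
#' Optional adapter over the xgboost learner: total split gain per
#' instance in a boosted-tree classifier of the phenotype.
#'
#' @inheritParams logistic_l1_importance
#' @param nrounds maximum boosting iterations; default 500.
#' @return a drug score table.
#' @export
gboost_gain_importance <- function(d2c, labels, seed = 1L, nrounds = 500L,
                                   drug_names = NULL) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the xgboost package is required for the boosting backend")
  xy <- d2c_design(d2c, labels)
  set.seed(as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(xy$x,
                                 label = as.integer(as.character(xy$y)),
                                 nthread = 1L)
  bst <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          nthread = 1L),
                            data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  raw <- structure(numeric(ncol(xy$x)), names = colnames(xy$x))
  raw[imp$Feature] <- imp$Gain
  new_score_table(colnames(xy$x), drug_names, "gboost_gain", unname(raw))
}

#' Cross-method candidate vote
#'
#' A method "votes" for an instance when the instance falls in that
#' method's predicted-positive set, defined as the top half of its ranking
#' (rank <= floor(D/2)). Instances with at least `k` votes are ensemble
#' candidates.
#'
#' @param tables list of >= `k` drug score tables over the same instances.
#' @param k minimum votes to become a candidate; default 3.
#' @return a drug score table with `raw_score` = votes, plus `votes` and
#'   `candidate` columns.
#' @export
ensemble_vote <- function(tables, k = 3L) {
  if (length(tables) < k)
    stop("k exceeds the number of method tables")
  ids <- sort(tables[[1L]]$instance_id)
  for (tb in tables)
    if (!setequal(tb$instance_id, ids))
      stop("method tables cover different instances")
  m <- floor(length(ids) / 2)
  votes <- structure(integer(length(ids)), names = ids)
  for (tb in tables) {
    pos <- tb$instance_id[tb$rank <= m]
    votes[pos] <- votes[pos] + 1L
  }
  dn <- tables[[1L]]$drug_name[match(ids, tables[[1L]]$instance_id)]
  out <- new_score_table(ids, dn, "vote", as.numeric(votes),
                         votes = as.integer(votes))
  out$candidate <- out$votes >= k
  out
}
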