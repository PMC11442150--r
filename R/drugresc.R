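#' Fit the DrugReSC drug-ranking model
#'
#' The full pipeline in one call: (1) the gene-by-cell matrix is
#' transformed into a drug-by-cell matrix of D2C reversal scores via the
#' rank-weighted enrichment walk; (2) each drug instance is scored by its
#' contribution to classifying disease-associated (label 1) versus other
#' cells, by default via random-forest out-of-bag permutation importance
#' (with mtry chosen by minimum OOB error over a grid), optionally via the
#' Wilcoxon, ANOVA/Welch, L1-logistic, SVM-sensitivity, boosting-gain or
#' vote backends; (3) raw scores are min-max standardised to [0, 1] and
#' the instances ranked.
#'
#' @param expr an [expression_matrix()] (log scale, genes x cells).
#' @param labels a [cell_labels()] vector over exactly the same cells
#'   (1 = disease-associated).
#' @param signatures list of [drug_signature()] objects.
#' @param config a [drugresc_config()]; its `alpha`, `ntree`, `mtry_grid`,
#'   `master_seed` and `importance_method` drive the run.
#' @param mtry fixed mtry, skipping grid selection; default `NULL`.
#' @param d2c a precomputed [d2c_matrix()] to reuse; default `NULL`
#'   (computed from `expr` and `signatures`).
#' @param verbose message progress; default FALSE.
#' @return object of class `"drugresc"`: list with `d2c`, `scores` (the
#'   drug score table), `forest` (for the random-forest method), `mtry`,
#'   `config`, `labels`, `signatures`, `call`.
#' @export
#' @examples
#' fx <- make_worked_example()
#' d2c <- build_d2c_matrix(fx$expression, fx$signatures)
#' d2c$scores["reversal", ]  # 2 in the disease-like cell
drugresc <- function(expr = NULL, labels, signatures = NULL,
                     config = drugresc_config(), mtry = NULL, d2c = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(config, "drugresc_config"))
  if (is.null(d2c)) {
    if (is.null(expr) || is.null(signatures))
      stop("either d2c or both expr and signatures must be given")
    d2c <- build_d2c_matrix(expr, signatures, alpha = config$alpha,
                            verbose = verbose)
  }
  drug_names <- NULL
  if (!is.null(signatures)) {
    map <- vapply(signatures, `[[`, "", "drug_name")
    names(map) <- vapply(signatures, `[[`, "", "instance_id")
    drug_names <- unname(map[d2c$instances])
  }
  labels <- align_labels(labels, d2c$cells)
  seed <- config$master_seed
  method <- config$importance_method

  forest <- NULL
  if (method == "random_forest") {
    if (is.null(mtry))
      mtry <- select_mtry(d2c, labels, grid = config$mtry_grid,
                          ntree = config$ntree, seed = seed)
    if (verbose) message("mtry = ", mtry)
    forest <- fit_forest(d2c, labels, ntree = config$ntree, mtry = mtry,
                         seed = seed + 1L)
    forest$drug_names <- drug_names
    scores <- oob_permutation_importance(forest, seed = seed + 2L)
  } else if (method == "wilcoxon") {
    scores <- wilcoxon_importance(d2c, labels, drug_names)
  } else if (method == "anova") {
    scores <- anova_importance(d2c, labels, drug_names = drug_names)
  } else if (method == "logistic_l1") {
    scores <- logistic_l1_importance(d2c, labels, seed = seed,
                                     drug_names = drug_names)
  } else if (method == "svm_sensitivity") {
    scores <- svm_sensitivity_importance(d2c, labels, seed = seed,
                                         drug_names = drug_names)
  } else if (method == "gboost_gain") {
    scores <- gboost_gain_importance(d2c, labels, seed = seed,
                                     drug_names = drug_names)
  } else { # vote over the four always-available backends
    f <- fit_forest(d2c, labels, ntree = config$ntree,
                    mtry = mtry %||% max(1L, floor(sqrt(nrow(d2c$scores)))),
                    seed = seed + 1L)
    f$drug_names <- drug_names
    tables <- list(oob_permutation_importance(f, seed = seed + 2L),
                   wilcoxon_importance(d2c, labels, drug_names),
                   anova_importance(d2c, labels, drug_names = drug_names),
                   logistic_l1_importance(d2c, labels, seed = seed,
                                          drug_names = drug_names))
    scores <- ensemble_vote(tables, k = 3L)
    forest <- f
  }
  structure(list(d2c = d2c, scores = scores, forest = forest,
                 mtry = if (method %in% c("random_forest", "vote"))
                   forest$mtry else NA_integer_,
                 config = config, labels = labels,
                 signatures = signatures, call = match.call()),
            class = "drugresc")
}

#' @export
print.drugresc <- function(x, ...) {
  cat("DrugReSC fit\n")
  cat(sprintf("  method: %s | %d drug instances x %d cells (%d disease)\n",
              x$config$importance_method, length(x$d2c$instances),
              length(x$d2c$cells), sum(x$labels == 1L)))
  cat("  top instances:\n")
  top <- x$scores[order(x$scores$rank), ][seq_len(min(5L, nrow(x$scores))), ]
  print.data.frame(top[, c("rank", "instance_id", "drug_name",
                           "raw_score", "standardized_score")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.drugresc <- function(object, ...) {
  s <- list(n_instances = length(object$d2c$instances),
            n_cells = length(object$d2c$cells),
            n_disease = sum(object$labels == 1L),
            method = object$config$importance_method,
            mtry = object$mtry,
            oob_error = if (!is.null(object$forest))
              unname(object$forest$rf$err.rate[object$forest$ntree, "OOB"])
            else NA_real_,
            d2c_range = range(object$d2c$scores),
            scores = object$scores[order(object$scores$rank), ])
  class(s) <- "summary.drugresc"
  s
}

#' @export
print.summary.drugresc <- function(x, ...) {
  cat(sprintf("DrugReSC: %d instances x %d cells (%d disease-associated)\n",
              x$n_instances, x$n_cells, x$n_disease))
  cat(sprintf("  importance method: %s", x$method))
  if (!is.na(x$mtry)) cat(sprintf(" (mtry = %d, OOB error %.3f)",
                                  x$mtry, x$oob_error))
  cat("\n")
  cat(sprintf("  D2C range: [%.3f, %.3f]\n", x$d2c_range[1], x$d2c_range[2]))
  cat("  ranked drug instances:\n")
  print.data.frame(x$scores, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn drugresc standardized drug scores as a named vector
#'   (or raw scores with `type = "raw"`).
#' @param object,x a fitted `"drugresc"` object.
#' @param type `"standardized"` or `"raw"`.
#' @param ... ignored.
#' @export
coef.drugresc <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  col <- if (type == "raw") "raw_score" else "standardized_score"
  structure(object$scores[[col]], names = object$scores$instance_id)
}

#' @describeIn drugresc D2C scores for new cells: `newdata` is an
#'   [expression_matrix()] over new cells; returns their drug-by-cell
#'   matrix under the fitted signatures, or (with
#'   `type = "class"`, random-forest fit only) the forest's predicted
#'   phenotype for the new cells.
#' @param newdata an [expression_matrix()] of new cells.
#' @export
predict.drugresc <- function(object, newdata,
                             type = c("d2c", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$signatures))
    stop("the fit holds no signatures; predict needs them")
  nd <- build_d2c_matrix(newdata, object$signatures,
                         alpha = object$config$alpha, verbose = FALSE)
  if (type == "d2c") return(nd)
  if (is.null(object$forest)) stop("no forest in this fit")
  predict(object$forest$rf, t(nd$scores))
}

#' @describeIn drugresc barplot of the top `n` standardized drug scores.
#' @param n number of instances plotted.
#' @export
plot.drugresc <- function(x, n = 15L, ...) {
  tb <- x$scores[order(x$scores$rank), ]
  tb <- tb[seq_len(min(n, nrow(tb))), ]
  op <- par(mar = c(4, 9, 2, 1)); on.exit(par(op))
  barplot(rev(tb$standardized_score), names.arg = rev(tb$instance_id),
          horiz = TRUE, las = 1, col = "steelblue",
          xlab = "standardized drug score",
          main = sprintf("Top drug instances (%s)", tb$method[1L]), ...)
  invisible(x)
}
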