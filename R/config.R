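#' Run configuration for the DrugReSC pipeline
#'
#' Collects the tunable parameters of the pipeline in one validated object.
#' Every parameter has the pipeline's default; `drugresc()` and the
#' command-line wrapper accept a config built here.
#'
#' @param alpha exponent of the rank weight in the enrichment walk
#'   (must be > 0). Default 0.25.
#' @param de_p_threshold p-value cutoff for including a gene in a drug
#'   instance's up/down signature (strict `<`). Default 0.01.
#' @param ntree number of trees in the random forest. Default 100.
#' @param mtry_grid candidate numbers of split variables tried when `mtry`
#'   is not fixed; `NULL` means the default grid
#'   `{floor(sqrt(D)/2), floor(sqrt(D)), floor(2*sqrt(D)), floor(D/3)}`
#'   clipped to `[1, D]` for D instances.
#' @param n_negative_samplings number of balanced negative samplings used in
#'   evaluation. Default 10.
#' @param master_seed integer master seed; every stochastic step derives its
#'   seed from it.
#' @param importance_method one of `"random_forest"`, `"wilcoxon"`,
#'   `"anova"`, `"logistic_l1"`, `"svm_sensitivity"`, `"gboost_gain"`,
#'   `"vote"`.
#' @param pseudocount pseudocount added before the log2 transform in
#'   [log_normalize()]. Default 1.
#'
#' @return an object of class `"drugresc_config"` (a named list).
#' @export
#' @examples
#' cfg <- drugresc_config(alpha = 0.25, ntree = 100)
#' cfg$de_p_threshold
drugresc_config <- function(alpha = 0.25,
                            de_p_threshold = 0.01,
                            ntree = 100L,
                            mtry_grid = NULL,
                            n_negative_samplings = 10L,
                            master_seed = 1L,
                            importance_method = c("random_forest", "wilcoxon",
                                                  "anova", "logistic_l1",
                                                  "svm_sensitivity",
                                                  "gboost_gain", "vote"),
                            pseudocount = 1) {
  importance_method <- match.arg(importance_method)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(de_p_threshold), length(de_p_threshold) == 1L,
            de_p_threshold > 0, de_p_threshold < 1,
            is.numeric(ntree), length(ntree) == 1L, ntree >= 1,
            is.numeric(n_negative_samplings), n_negative_samplings >= 1,
            is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(pseudocount), pseudocount >= 0)
  if (!is.null(mtry_grid)) {
    stopifnot(is.numeric(mtry_grid), length(mtry_grid) >= 1L,
              all(mtry_grid >= 1))
    mtry_grid <- as.integer(mtry_grid)
  }
  structure(list(alpha = alpha,
                 de_p_threshold = de_p_threshold,
                 ntree = as.integer(ntree),
                 mtry_grid = mtry_grid,
                 n_negative_samplings = as.integer(n_negative_samplings),
                 master_seed = as.integer(master_seed),
                 importance_method = importance_method,
                 pseudocount = pseudocount),
            class = "drugresc_config")
}

#' @export
print.drugresc_config <- function(x, ...) {
  cat("DrugReSC run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "<default grid>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

# default mtry grid for D features, bracketing the conventional sqrt(D)
default_mtry_grid <- function(D) {
  g <- unique(pmin(pmax(c(floor(sqrt(D) / 2), floor(sqrt(D)),
                          floor(2 * sqrt(D)), floor(D / 3)), 1L), D))
  sort(as.integer(g))
}
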