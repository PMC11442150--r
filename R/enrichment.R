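#' Rank one cell's genes by absolute expression
#'
#' Genes are sorted by absolute expression, descending: the gene with the
#' largest |expression| receives rank N, the smallest rank 1. Ties in
#' |expression| are broken by lexicographic gene symbol, so the ordering is
#' a deterministic total order.
#'
#' @param expr named numeric vector: one cell's (log-scale) expression over
#'   genes; length >= 2, finite.
#' @param cell_id optional identifier carried along.
#' @return object of class `"cell_ranking"`: list with `cell_id`, `ord`
#'   (gene symbols in rank-descending order, i.e. position 1 = rank N) and
#'   `ranks` (named integer vector, N..1).
#' @export
#' @examples
#' r <- rank_cell(c(a = 3, b = 1, c = 2))
#' r$ranks  # a = 3, c = 2, b = 1
rank_cell <- function(expr, cell_id = NA_character_) {
  genes <- names(expr)
  if (is.null(genes)) stop("expression vector must be named by gene")
  N <- length(expr)
  if (N < 2L) stop("need at least 2 genes to rank")
  if (!all(is.finite(expr))) stop("non-finite expression values")
  o <- order(-abs(expr), genes, method = "radix")
  ord <- genes[o]
  ranks <- structure(integer(N), names = ord)
  ranks[] <- N:1L
  structure(list(cell_id = cell_id, ord = ord, ranks = ranks),
            class = "cell_ranking")
}

#' Single-sample enrichment score of a gene set in a ranked cell
#'
#' Walks the cell's genes in rank-descending order. At position i the hit
#' curve is the rank-weighted fraction of signature genes seen so far,
#' \deqn{P_{hit}(G,i) = \sum_{j \in G, j \le i} |r_j|^\alpha /
#'       \sum_{j \in G} |r_j|^\alpha,}
#' and the miss curve is the uniform fraction of non-signature genes,
#' \deqn{P_{miss}(G,i) = \#\{j \notin G, j \le i\} / (N - N_G).}
#' The enrichment score is the signed value of \eqn{P_{hit} - P_{miss}} at
#' the position of its maximal absolute value (ties resolve to the earliest
#' position). ES lies in [-1, 1]; it depends only on the rank order, so it
#' is invariant to strictly monotone transforms of |expression|.
#'
#' @param ranking a [rank_cell()] result.
#' @param signature_genes character vector G; genes absent from the ranking
#'   are dropped before the walk.
#' @param alpha rank-weight exponent (> 0); default 0.25.
#' @return single numeric ES.
#' @export
enrichment_score <- function(ranking, signature_genes, alpha = 0.25) {
  stopifnot(inherits(ranking, "cell_ranking"), alpha > 0)
  N <- length(ranking$ord)
  hit <- ranking$ord %in% signature_genes
  NG <- sum(hit)
  if (NG == 0L)
    stop("signature has no genes in the ranking")
  if (NG == N)
    stop("signature covers every ranked gene; miss fraction undefined")
  w <- (N:1)^alpha            # |r_j|^alpha at positions 1..N
  hw <- w * hit
  p_hit <- cumsum(hw) / sum(hw)
  p_miss <- cumsum(!hit) / (N - NG)
  d <- p_hit - p_miss
  d[which.max(abs(d))]
}

#' D2C reversal score of one drug instance in one cell
#'
#' `ES(up) - ES(down)`. A side whose genes are all absent from the ranking
#' contributes 0 (with a warning); both sides absent is an error. The score
#' lies in [-2, 2] and is antisymmetric under swapping the up and down
#' sets.
#'
#' @param ranking a [rank_cell()] result.
#' @param signature a [drug_signature()].
#' @param alpha rank-weight exponent; default 0.25.
#' @return single numeric D2C score.
#' @export
d2c_score <- function(ranking, signature, alpha = 0.25) {
  up <- intersect(signature$up, ranking$ord)
  dn <- intersect(signature$down, ranking$ord)
  if (length(up) == 0L && length(dn) == 0L)
    stop("instance ", signature$instance_id,
         ": no signature gene present in the ranking")
  es_up <- if (length(up)) enrichment_score(ranking, up, alpha) else {
    warning("instance ", signature$instance_id,
            ": empty up-side after intersection; contributes 0")
    0
  }
  es_dn <- if (length(dn)) enrichment_score(ranking, dn, alpha) else {
    warning("instance ", signature$instance_id,
            ": empty down-side after intersection; contributes 0")
    0
  }
  es_up - es_dn
}

#' Construct / validate a drug-by-cell score matrix
#'
#' @param scores numeric matrix, instances x cells, values in [-2, 2].
#' @param instances,cells identifiers.
#' @return object of class `"d2c_matrix"`: list with `instances`, `cells`,
#'   `scores`.
#' @export
d2c_matrix <- function(scores, instances = rownames(scores),
                       cells = colnames(scores)) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(instances) || ncol(scores) != length(cells))
    stop("dimension mismatch")
  if (!all(is.finite(scores))) stop("non-finite D2C scores")
  if (any(scores < -2 - 1e-9 | scores > 2 + 1e-9))
    stop("D2C scores outside [-2, 2]")
  dimnames(scores) <- list(instances, cells)
  structure(list(instances = as.character(instances),
                 cells = as.character(cells), scores = scores),
            class = "d2c_matrix")
}

#' @export
print.d2c_matrix <- function(x, ...) {
  cat(sprintf("d2c_matrix: %d drug instances x %d cells, range [%.3f, %.3f]\n",
              length(x$instances), length(x$cells),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Transform a gene-by-cell matrix into a drug-by-cell matrix
#'
#' For every (instance, cell) pair computes the D2C score under the given
#' rank-weight exponent. Cells are processed one at a time (one ranking per
#' cell, shared across instances). Instances with no usable gene on either
#' side, or flagged empty, are dropped with a message.
#'
#' @param expr an [expression_matrix()], >= 2 cells.
#' @param signatures list of [drug_signature()] objects.
#' @param alpha rank-weight exponent; default 0.25.
#' @param verbose message dropped instances; default TRUE.
#' @return a [d2c_matrix()].
#' @export
build_d2c_matrix <- function(expr, signatures, alpha = 0.25,
                             verbose = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr) < 2L) stop("need at least 2 cells")
  genes <- rownames(expr)
  N <- nrow(expr)

  keep <- vapply(signatures, function(s) {
    if (flag_empty(s)) return(FALSE)
    nu <- sum(s$up %in% genes); nd <- sum(s$down %in% genes)
    (nu > 0L || nd > 0L) && nu < N && nd < N
  }, logical(1L))
  if (any(!keep) && verbose) {
    bad <- vapply(signatures[!keep], `[[`, "", "instance_id")
    message("dropping ", sum(!keep), " unusable instance(s): ",
            paste(bad, collapse = ", "))
  }
  signatures <- signatures[keep]
  if (length(signatures) == 0L) stop("no usable drug signature")

  gidx <- seq_len(N); names(gidx) <- genes
  up_members <- lapply(signatures, function(s) {
    v <- logical(N); v[gidx[intersect(s$up, genes)]] <- TRUE; v
  })
  dn_members <- lapply(signatures, function(s) {
    v <- logical(N); v[gidx[intersect(s$down, genes)]] <- TRUE; v
  })
  has_up <- vapply(up_members, any, logical(1L))
  has_dn <- vapply(dn_members, any, logical(1L))

  D <- length(signatures)
  w <- (N:1)^alpha
  scores <- matrix(0, nrow = D, ncol = ncol(expr))
  for (ci in seq_len(ncol(expr))) {
    x <- expr[, ci]
    o <- order(-abs(x), genes, method = "radix")
    for (di in seq_len(D)) {
      es_up <- if (has_up[di]) walk_es(up_members[[di]][o], w, N) else 0
      es_dn <- if (has_dn[di]) walk_es(dn_members[[di]][o], w, N) else 0
      scores[di, ci] <- es_up - es_dn
    }
  }
  d2c_matrix(scores,
             instances = vapply(signatures, `[[`, "", "instance_id"),
             cells = colnames(expr))
}

# core running-sum walk on an already-ordered hit indicator
walk_es <- function(hit, w, N) {
  NG <- sum(hit)
  hw <- w * hit
  d <- cumsum(hw) / sum(hw) - cumsum(!hit) / (N - NG)
  d[which.max(abs(d))]
}
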