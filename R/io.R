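#' Construct an expression matrix object
#'
#' A thin validated container: a dense numeric matrix of log-scale
#' expression with genes as rows and cells as columns. Gene symbols and
#' cell identifiers must be unique, all values finite.
#'
#' @param values numeric matrix, genes x cells, log2 scale.
#' @param genes character vector of gene symbols (rows).
#' @param cells character vector of cell identifiers (columns).
#' @return object of class `"expression_matrix"`: the matrix with dimnames
#'   set and the class attribute.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              cells = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(genes) || is.null(cells))
    stop("gene and cell identifiers are required")
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(values) != length(genes) || ncol(values) != length(cells))
    stop("dimension mismatch between values and gene/cell identifiers")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols; collapse them first (collapse_duplicate_genes)")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  if (!all(is.finite(values))) stop("non-finite expression values")
  dimnames(values) <- list(genes, cells)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (log scale)\n",
              nrow(x), ncol(x)))
  cat("  genes:", paste(head(rownames(x), 4L), collapse = ", "),
      if (nrow(x) > 4L) "..." else "", "\n")
  cat("  cells:", paste(head(colnames(x), 4L), collapse = ", "),
      if (ncol(x) > 4L) "..." else "", "\n")
  invisible(x)
}

#' Read a gene-by-cell expression matrix
#'
#' Two on-disk layouts are supported. `dense_table`: a TSV/CSV with gene
#' symbols in the first column and one named column per cell.
#' `mtx_triplet`: a MatrixMarket file plus companion one-identifier-per-line
#' text files for rows (genes) and columns (cells).
#'
#' Duplicate gene symbols are collapsed to their per-cell mean before the
#' matrix is returned.
#'
#' @param path matrix file.
#' @param format `"dense_table"` or `"mtx_triplet"`.
#' @param genes_path,cells_path companion identifier files
#'   (`mtx_triplet` only).
#' @param sep field separator for `dense_table`; default tab.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("dense_table", "mtx_triplet"),
                            genes_path = NULL, cells_path = NULL,
                            sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_table") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("dense table needs a gene column and >=1 cell")
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression entries")
    rownames(vals) <- genes
    collapse_duplicate_genes(vals, cells = colnames(vals))
  } else {
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx_triplet format requires genes_path and cells_path")
    if (!file.exists(genes_path)) stop("file not found: ", genes_path)
    if (!file.exists(cells_path)) stop("file not found: ", cells_path)
    m <- withCallingHandlers(
      as.matrix(Matrix::readMM(path)),
      warning = function(w)
        stop("malformed MTX file (dimension/entry mismatch): ",
             conditionMessage(w), call. = FALSE))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("dimension mismatch between MTX matrix and identifier lists")
    rownames(m) <- genes
    collapse_duplicate_genes(m, cells = cells)
  }
}

#' Collapse duplicate gene symbols to their mean
#'
#' Rows sharing a gene symbol are replaced by one row holding the
#' arithmetic mean of their values, per cell. First-appearance order of
#' symbols is preserved. Idempotent.
#'
#' @param values numeric matrix with gene symbols as rownames.
#' @param cells cell identifiers; default taken from colnames.
#' @return an [expression_matrix()] with unique gene symbols.
#' @export
collapse_duplicate_genes <- function(values, cells = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("empty table")
  genes <- rownames(values)
  if (is.null(genes)) stop("gene symbols (rownames) are required")
  if (anyDuplicated(genes)) {
    grp <- factor(genes, levels = unique(genes))
    sums <- rowsum(values, grp)                 # keeps level order
    counts <- as.vector(table(grp))
    values <- sums / counts
    genes <- levels(grp)
  }
  expression_matrix(values, genes = genes, cells = cells)
}

#' Library-size normalise counts and log2-transform
#'
#' Each cell is scaled to a fixed total of 1e6 (a length-agnostic TPM-like
#' normalisation), then `log2(x + pseudocount)` is applied. Matrices that
#' are already normalised can be wrapped directly with
#' [expression_matrix()] instead.
#'
#' @param counts nonnegative numeric gene x cell matrix with dimnames.
#' @param pseudocount added before the log; default 1.
#' @return an [expression_matrix()] (log2 scale).
#' @export
log_normalize <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total count: ",
         paste(head(colnames(counts)[tot == 0], 5L), collapse = ", "))
  scaled <- sweep(counts, 2L, 1e6 / tot, `*`)
  expression_matrix(log2(scaled + pseudocount))
}

#' Read binary cell phenotype labels
#'
#' Expects a tab-separated file with header columns `cell_id` and
#' `phenotype`; phenotype must be 0 (other) or 1 (disease-associated).
#'
#' @param path label file.
#' @return object of class `"cell_labels"`: a named integer vector
#'   (names = cell ids, values in {0,1}).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "phenotype") %in% names(tab)))
    stop("label file needs columns cell_id, phenotype")
  cell_labels(tab$phenotype, tab$cell_id)
}

#' Construct a validated cell-label vector
#'
#' @param phenotype vector of 0/1 values (1 = disease-associated).
#' @param cells cell identifiers aligned to `phenotype`.
#' @return named integer vector of class `"cell_labels"`.
#' @export
cell_labels <- function(phenotype, cells) {
  if (length(phenotype) != length(cells))
    stop("phenotype and cells differ in length")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers in labels")
  if (!all(phenotype %in% c(0, 1)))
    stop("phenotype values must be 0 or 1")
  structure(as.integer(phenotype), names = as.character(cells),
            class = "cell_labels")
}

#' Write cell labels
#' @param labels a [cell_labels()] vector.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(cell_id = names(labels), phenotype = as.integer(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align labels to an expression or D2C matrix's cells; exact-match contract:
# any cell present on one side only is an error, never silently dropped
align_labels <- function(labels, cells) {
  if (!setequal(names(labels), cells))
    stop("cell identifiers of labels and matrix do not match exactly; ",
         "missing on one side: ",
         paste(head(c(setdiff(cells, names(labels)),
                      setdiff(names(labels), cells)), 5L), collapse = ", "))
  labels[cells]
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated dialect: set name, description, then one gene per
#' remaining field.
#'
#' @param path GMT file.
#' @return named list of character vectors; each has attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", l)
    structure(f[-(1:2)], description = f[2L], set_name = f[1L])
  })
  names(sets) <- vapply(sets, attr, "", "set_name")
  sets
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors; an optional
#'   `"description"` attribute per set becomes the second field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a drug score table to CSV
#'
#' Columns: `instance_id, drug_name, method, raw_score,
#' standardized_score, rank` (plus `votes` when present).
#'
#' @param table a data.frame as returned by the importance backends.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  need <- c("instance_id", "drug_name", "method", "raw_score",
            "standardized_score", "rank")
  if (!all(need %in% names(table)))
    stop("score table missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  keep <- c(need, intersect("votes", names(table)))
  utils::write.csv(table[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug score table written by [write_score_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a D2C matrix as CSV (instances x cells)
#' @param d2c a `d2c_matrix` object.
#' @param path CSV path.
#' @return `path` (writer) / `d2c_matrix` (reader).
#' @export
write_d2c <- function(d2c, path) {
  df <- data.frame(instance_id = d2c$instances,
                   as.data.frame(d2c$scores), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_d2c
#' @export
read_d2c <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  d2c_matrix(m, instances = df[[1L]], cells = colnames(m))
}
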