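#' Differential-expression profile of one drug instance
#'
#' One instance = one replicate of a drug treatment condition (dose, cell
#' line, duration). Holds the log-scale differential expression vector c
#' and its p-values p over the assayed genes.
#'
#' @param instance_id,drug_name identifiers.
#' @param genes gene symbols (unique).
#' @param logfc log-scale differential expression, aligned to `genes`.
#' @param pvalues p-values in [0, 1], aligned to `genes`.
#' @param dose_value,dose_unit,tissue optional treatment metadata.
#' @return object of class `"de_profile"`.
#' @export
de_profile <- function(instance_id, drug_name, genes, logfc, pvalues,
                       dose_value = NA_real_, dose_unit = NA_character_,
                       tissue = NA_character_) {
  genes <- as.character(genes)
  if (length(genes) != length(logfc) || length(genes) != length(pvalues))
    stop("genes, logfc and pvalues must be aligned")
  if (anyDuplicated(genes)) stop("duplicate genes in DE profile")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  structure(list(instance_id = as.character(instance_id),
                 drug_name = as.character(drug_name),
                 genes = genes,
                 logfc = as.numeric(logfc),
                 pvalues = as.numeric(pvalues),
                 dose_value = as.numeric(dose_value),
                 dose_unit = as.character(dose_unit),
                 tissue = as.character(tissue)),
            class = "de_profile")
}

#' @export
print.de_profile <- function(x, ...) {
  cat(sprintf("de_profile %s (%s), %d genes, dose %s %s\n",
              x$instance_id, x$drug_name, length(x$genes),
              format(x$dose_value), x$dose_unit))
  invisible(x)
}

#' Up/down gene signature of a drug instance
#'
#' @param instance_id,drug_name identifiers.
#' @param up,down character vectors of up-/down-regulated genes;
#'   must be disjoint.
#' @param metadata optional named list (dose, tissue, ...).
#' @return object of class `"drug_signature"`.
#' @export
drug_signature <- function(instance_id, drug_name, up, down,
                           metadata = list()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L)
    stop("up and down signatures overlap")
  structure(list(instance_id = as.character(instance_id),
                 drug_name = as.character(drug_name),
                 up = up, down = down, metadata = metadata),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("drug_signature %s (%s): %d up, %d down\n",
              x$instance_id, x$drug_name, length(x$up), length(x$down)))
  invisible(x)
}

#' Build an up/down signature from a DE profile
#'
#' Genes with log-scale differential expression strictly greater than 0 and
#' p strictly below the threshold form the up-signature; those with
#' strictly negative differential expression and p below the threshold form
#' the down-signature. Genes with zero differential expression enter
#' neither set. No multiple-testing correction is applied to the drug
#' p-values.
#'
#' @param profile a [de_profile()].
#' @param p_threshold strict p cutoff in (0, 1); default 0.01.
#' @return a [drug_signature()] (possibly with empty sets; see
#'   [flag_empty()]).
#' @export
#' @examples
#' p <- de_profile("i1", "drugA", c("g1", "g2", "g3"),
#'                 logfc = c(1.2, -0.5, 0.3),
#'                 pvalues = c(0.005, 0.002, 0.2))
#' sig <- build_signature(p, 0.01)
#' sig$up    # "g1"
#' sig$down  # "g2"
build_signature <- function(profile, p_threshold = 0.01) {
  stopifnot(inherits(profile, "de_profile"),
            p_threshold > 0, p_threshold < 1)
  sig <- profile$pvalues < p_threshold
  drug_signature(profile$instance_id, profile$drug_name,
                 up = profile$genes[sig & profile$logfc > 0],
                 down = profile$genes[sig & profile$logfc < 0],
                 metadata = list(dose_value = profile$dose_value,
                                 dose_unit = profile$dose_unit,
                                 tissue = profile$tissue))
}

#' Keep only instances measured at a given dose
#'
#' @param profiles list of [de_profile()] objects.
#' @param dose_value,dose_unit required treatment dose (default 10 uM, the
#'   most common assay concentration in large perturbation screens).
#'   Unit matching is case-insensitive and treats the micro sign and "u"
#'   as equivalent.
#' @return the retained profiles, input order preserved; warns when no
#'   instance matches.
#' @export
filter_instances <- function(profiles, dose_value = 10, dose_unit = "uM") {
  norm_unit <- function(u) gsub("µ|μ", "u", tolower(trimws(u)))
  keep <- vapply(profiles, function(p) {
    isTRUE(p$dose_value == dose_value) &&
      isTRUE(norm_unit(p$dose_unit) == norm_unit(dose_unit))
  }, logical(1L))
  out <- profiles[keep]
  if (length(profiles) > 0L && length(out) == 0L)
    warning("no instance at dose ", dose_value, " ", dose_unit)
  out
}

#' Is a signature empty on both sides?
#'
#' Instances whose up- and down-signatures are both empty carry no usable
#' information and must be excluded from the drug-by-cell matrix; callers
#' log the exclusion.
#'
#' @param signature a [drug_signature()].
#' @return `TRUE` iff both sets are empty.
#' @export
flag_empty <- function(signature) {
  length(signature$up) == 0L && length(signature$down) == 0L
}

#' Read per-gene drug DE tables
#'
#' Long-format TSV with columns `instance_id, drug_name, dose, tissue,
#' gene, logfc, pvalue`; `dose` is `"<value><unit>"` (e.g. `10uM`) or
#' `"<value> <unit>"`. One [de_profile()] per instance is returned, in
#' first-appearance order.
#'
#' @param path TSV path.
#' @return list of [de_profile()] objects.
#' @export
read_de_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "drug_name", "dose", "tissue", "gene",
            "logfc", "pvalue")
  if (!all(need %in% names(tab)))
    stop("DE table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  ids <- unique(tab$instance_id)
  lapply(ids, function(id) {
    sub <- tab[tab$instance_id == id, ]
    d <- parse_dose(sub$dose[1L])
    de_profile(id, sub$drug_name[1L], sub$gene, sub$logfc, sub$pvalue,
               dose_value = d$value, dose_unit = d$unit,
               tissue = sub$tissue[1L])
  })
}

#' Write DE profiles to the long TSV format read by [read_de_profiles()]
#' @param profiles list of [de_profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_profiles <- function(profiles, path) {
  dfs <- lapply(profiles, function(p)
    data.frame(instance_id = p$instance_id, drug_name = p$drug_name,
               dose = paste0(format(p$dose_value, trim = TRUE), p$dose_unit),
               tissue = p$tissue, gene = p$genes, logfc = p$logfc,
               pvalue = p$pvalues))
  utils::write.table(do.call(rbind, dfs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

parse_dose <- function(s) {
  s <- trimws(as.character(s))
  m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(.*)$", s))[[1L]]
  if (length(m) < 3L || is.na(suppressWarnings(as.numeric(m[2L]))))
    return(list(value = NA_real_, unit = s))
  list(value = as.numeric(m[2L]), unit = m[3L])
}

#' Export signatures as GMT (two records per instance)
#'
#' Record names are `<instance_id>__UP` and `<instance_id>__DOWN`; the
#' description field carries the drug name.
#'
#' @param signatures list of [drug_signature()] objects.
#' @param path output GMT path.
#' @return `path`, invisibly.
#' @export
signatures_to_gmt <- function(signatures, path) {
  sets <- list()
  for (s in signatures) {
    sets[[paste0(s$instance_id, "__UP")]] <-
      structure(s$up, description = s$drug_name)
    sets[[paste0(s$instance_id, "__DOWN")]] <-
      structure(s$down, description = s$drug_name)
  }
  write_gmt(sets, path)
}

#' Rebuild signatures from a GMT written by [signatures_to_gmt()]
#' @param path GMT path.
#' @return list of [drug_signature()] objects.
#' @export
signatures_from_gmt <- function(path) {
  sets <- read_gmt(path)
  ids <- unique(sub("__(UP|DOWN)$", "", names(sets)))
  lapply(ids, function(id) {
    up <- sets[[paste0(id, "__UP")]]
    dn <- sets[[paste0(id, "__DOWN")]]
    drug_signature(id,
                   drug_name = attr(up %||% dn, "description") %||% id,
                   up = up %||% character(), down = dn %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
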