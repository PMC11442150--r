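#' Configuration of the synthetic cohort generator
#'
#' The generator plants a disease expression program and a set of
#' "positive" drugs whose signatures reverse it, so every pipeline stage
#' and the end-to-end benchmark run self-contained.
#'
#' @param n_genes genes simulated; default 2000.
#' @param n_cells cells simulated; default 300.
#' @param frac_disease_cells fraction labelled disease-associated
#'   (phenotype 1); default 0.1.
#' @param program_size disease-program genes, split into an up- and a
#'   down-half; default 100.
#' @param effect_size mean log2 shift of program genes in disease cells
#'   (>= 0); default 2.
#' @param noise_sd per-gene Gaussian noise sd on the log2 scale;
#'   default 1.
#' @param n_positive_drugs planted reversal drugs; default 5.
#' @param n_negative_drugs non-indicated drugs with random signatures;
#'   default 15.
#' @param reversal_strength fraction of each program half covered by a
#'   positive drug's opposing signature, in (0, 1]; default 1.
#' @param seed integer seed; the fixture is byte-reproducible under it.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L, n_cells = 300L,
                       frac_disease_cells = 0.1, program_size = 100L,
                       effect_size = 2, noise_sd = 1,
                       n_positive_drugs = 5L, n_negative_drugs = 15L,
                       reversal_strength = 1, seed = 1L) {
  stopifnot(frac_disease_cells > 0, frac_disease_cells < 1,
            program_size < n_genes, program_size >= 2,
            reversal_strength > 0, reversal_strength <= 1,
            effect_size >= 0, noise_sd > 0,
            n_positive_drugs >= 1, n_negative_drugs >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 frac_disease_cells = frac_disease_cells,
                 program_size = as.integer(program_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_positive_drugs = as.integer(n_positive_drugs),
                 n_negative_drugs = as.integer(n_negative_drugs),
                 reversal_strength = reversal_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a single-cell cohort with planted reversal drugs
#'
#' Baseline log2 expression of gene g in every cell is
#' `Normal(mu_g, noise_sd)` clipped at 0, with per-gene means `mu_g ~
#' Uniform(1, 8)`. A randomly chosen disease program of `program_size`
#' genes is split in half: in disease cells the up-half is shifted by
#' `+effect_size` and the down-half by `-effect_size`. Each positive drug's
#' DE profile *reverses* the program: its down-signature covers a
#' `reversal_strength` fraction of the program's up-half (negative log-fold
#' changes) and its up-signature the matching fraction of the down-half
#' (positive log-fold changes); signature-gene |logfc| ~
#' `|Normal(effect_size, 0.2)|` with p ~ `Uniform(1e-6, 0.009)` (strictly
#' below the 0.01 signature cutoff), all other genes get null logfc with
#' p ~ `Uniform(0.2, 1)`. Negative drugs receive signatures of matched
#' sizes over random non-program genes, organised in blocks of
#' `n_positive_drugs` instances that share a random "decoy program": the
#' negative group then mirrors the positive group's within-group signature
#' correlation, so at `effect_size = 0` the two groups are exchangeable
#' and drug-level rankings are calibrated at chance. All instances carry a
#' 10 uM dose so they survive the default dose filter.
#'
#' @param config a [sim_config()].
#' @return list with `expression` ([expression_matrix()]), `labels`
#'   ([cell_labels()]), `profiles` (list of [de_profile()]), `positives`
#'   (character vector of positive instance ids), `program` (list with
#'   `up`, `down` gene vectors), and `config`.
#' @export
#' @examples
#' fx <- simulate_cohort(sim_config(n_genes = 200, n_cells = 40,
#'                                  program_size = 20, seed = 7))
#' dim(fx$expression)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; C <- config$n_cells
  genes <- sprintf("g%04d", seq_len(G))
  cells <- sprintf("cell%04d", seq_len(C))

  mu <- runif(G, 1, 8)
  vals <- matrix(rnorm(G * C, mean = mu, sd = config$noise_sd),
                 nrow = G, ncol = C)

  n_dis <- max(2L, round(config$frac_disease_cells * C))
  dis_cells <- sort(sample.int(C, n_dis))
  phenotype <- integer(C); phenotype[dis_cells] <- 1L

  prog <- sample.int(G, config$program_size)
  half <- floor(config$program_size / 2)
  prog_up <- prog[seq_len(half)]            # high in disease cells
  prog_dn <- prog[(half + 1L):config$program_size]
  vals[prog_up, dis_cells] <- vals[prog_up, dis_cells] + config$effect_size
  vals[prog_dn, dis_cells] <- vals[prog_dn, dis_cells] - config$effect_size
  vals[vals < 0] <- 0
  dimnames(vals) <- list(genes, cells)

  n_sig <- max(1L, round(config$reversal_strength * half))
  sig_profile <- function(id, drug, up_idx, dn_idx) {
    lfc <- rnorm(G, 0, 0.05)
    pv <- runif(G, 0.2, 1)
    lfc[up_idx] <- abs(rnorm(length(up_idx), config$effect_size, 0.2))
    lfc[dn_idx] <- -abs(rnorm(length(dn_idx), config$effect_size, 0.2))
    pv[c(up_idx, dn_idx)] <- runif(length(up_idx) + length(dn_idx),
                                   1e-6, 0.009)
    de_profile(id, drug, genes, lfc, pv,
               dose_value = 10, dose_unit = "uM", tissue = "synthetic")
  }

  profiles <- vector("list", config$n_positive_drugs +
                       config$n_negative_drugs)
  positives <- character(config$n_positive_drugs)
  for (i in seq_len(config$n_positive_drugs)) {
    id <- sprintf("pos_%02d", i)
    positives[i] <- id
    # reversal: drug down-signature on the program's up-half and vice versa
    profiles[[i]] <- sig_profile(id, sprintf("posdrug%02d", i),
                                 up_idx = sample(prog_dn, n_sig),
                                 dn_idx = sample(prog_up, n_sig))
  }
  # negatives mirror the positives' correlation structure: blocks of
  # n_positive_drugs instances share a random non-program "decoy program"
  # each member partially reverses. Under effect_size = 0 the positive and
  # negative instance groups are then exchangeable, so drug-level rankings
  # are calibrated at chance; decoy programs carry no phenotype signal at
  # any effect size.
  nonprog <- setdiff(seq_len(G), prog)
  decoys <- list()
  for (i in seq_len(config$n_negative_drugs)) {
    id <- sprintf("neg_%02d", i)
    b <- ceiling(i / config$n_positive_drugs)
    if (length(decoys) < b) {
      dp <- sample(nonprog, config$program_size)
      decoys[[b]] <- list(up = dp[seq_len(half)],
                          dn = dp[(half + 1L):config$program_size])
    }
    profiles[[config$n_positive_drugs + i]] <-
      sig_profile(id, sprintf("negdrug%02d", i),
                  up_idx = sample(decoys[[b]]$dn, n_sig),
                  dn_idx = sample(decoys[[b]]$up, n_sig))
  }

  list(expression = expression_matrix(vals),
       labels = cell_labels(phenotype, cells),
       profiles = profiles, positives = positives,
       program = list(up = genes[prog_up], down = genes[prog_dn]),
       config = config)
}

#' Write a simulated cohort to a directory of plain-text fixtures
#'
#' Emits `expression.tsv` (dense), `labels.tsv`, `de_profiles.tsv`,
#' `signatures.gmt` (built at the 0.01 cutoff) and `positives.txt`.
#'
#' @param fixture a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene = rownames(fixture$expression),
                        as.data.frame(unclass(fixture$expression)),
                        check.names = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_labels(fixture$labels, file.path(dir, "labels.tsv"))
  write_de_profiles(fixture$profiles, file.path(dir, "de_profiles.tsv"))
  sigs <- lapply(fixture$profiles, build_signature)
  signatures_to_gmt(sigs, file.path(dir, "signatures.gmt"))
  writeLines(fixture$positives, file.path(dir, "positives.txt"))
  invisible(dir)
}

#' Hand-evaluable worked example
#'
#' Three genes, two cells. In the first cell the expression values give
#' ranks 3, 2, 1 to genes g1, g2, g3. The `"reversal"` drug signature
#' (up = top gene g1, down = bottom gene g3) has enrichment walks
#' ES_up = 1 and ES_down = -1, hence D2C = 2 in cell 1. The symmetry case
#' "same set on both sides scores 0" cannot be built as a
#' [drug_signature()] (up and down must be disjoint), so it is exposed as
#' the helper `d2c_self(ranking, G) = ES(G) - ES(G)`, identically 0.
#'
#' @return list with `expression` (3 x 2 [expression_matrix()]), `labels`,
#'   `signatures` (list with the `"reversal"` instance), and `d2c_self`
#'   as above.
#' @export
#' @examples
#' fx <- make_worked_example()
#' r <- rank_cell(fx$expression[, 1])
#' enrichment_score(r, "g1")   #  1
#' enrichment_score(r, "g3")   # -1
make_worked_example <- function() {
  vals <- matrix(c(4, 2, 1,    # cell 1: |expr| ranks g1=3, g2=2, g3=1
                   1, 2, 4),   # cell 2: reversed
                 nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  sigs <- list(reversal = drug_signature("reversal", "reversal_drug",
                                         up = "g1", down = "g3"))
  list(expression = expression_matrix(vals),
       labels = cell_labels(c(1L, 0L), c("c1", "c2")),
       signatures = sigs,
       d2c_self = function(ranking, genes_set)
         enrichment_score(ranking, genes_set) -
           enrichment_score(ranking, genes_set))
}
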