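# a small D2C matrix with one planted discriminative instance
planted_d2c <- function(n_cells = 60L, n_inst = 8L, gap = 1, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_cells / 2)
  m <- matrix(rnorm(n_inst * n_cells, sd = 0.3), nrow = n_inst)
  m[1, ] <- m[1, ] + gap * y
  m <- pmin(pmax(m, -2), 2)
  rownames(m) <- sprintf("i%02d", seq_len(n_inst))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  list(d2c = d2c_matrix(m),
       labels = cell_labels(y, colnames(m)))
}

test_that("raw drug score is the mean per-tree vote drop", {
  expect_identical(drug_score_from_votes(c(10, 8), c(6, 8)), 2)
  expect_identical(drug_score_from_votes(5, 5), 0)
  expect_identical(drug_score_from_votes(c(3, 3, 3), c(4, 3, 2)), 0)
})

test_that("forest bookkeeping: bootstrap coverage, OOB sets, determinism", {
  px <- planted_d2c()
  f1 <- fit_forest(px$d2c, px$labels, ntree = 50, seed = 3)
  expect_equal(f1$ntree, 50L)
  expect_true(all(lengths(f1$oob) > 0))
  # in-bag plus out-of-bag covers every cell, per tree
  for (t in c(1L, 25L, 50L)) {
    inb <- which(f1$inbag[, t] > 0)
    expect_setequal(c(inb, f1$oob[[t]]), seq_len(60))
  }
  f2 <- fit_forest(px$d2c, px$labels, ntree = 50, seed = 3)
  expect_identical(f1$inbag, f2$inbag)

  all1 <- cell_labels(rep(1L, 60), px$d2c$cells)
  expect_error(fit_forest(px$d2c, all1), "both phenotype classes")
})

test_that("mtry selection is an argmin over the grid", {
  px <- planted_d2c()
  expect_equal(select_mtry(px$d2c, px$labels, grid = 3L, ntree = 30), 3L)
  m <- select_mtry(px$d2c, px$labels, grid = c(1L, 2L, 8L), ntree = 30,
                   seed = 2)
  expect_true(m %in% c(1L, 2L, 8L))
  expect_error(select_mtry(px$d2c, px$labels, grid = c(1L, 9L)),
               "outside")
})

test_that("permutation importance: constant column scores exactly zero", {
  px <- planted_d2c()
  m <- px$d2c$scores
  m[3, ] <- 0.7
  d2c <- d2c_matrix(m)
  fit <- fit_forest(d2c, px$labels, ntree = 40, seed = 5)
  tb <- oob_permutation_importance(fit, seed = 6)
  expect_identical(tb$raw_score[tb$instance_id == "i03"], 0)
})

test_that("planted instance dominates the importance ranking", {
  hits <- 0L
  for (s in 1:5) {
    px <- planted_d2c(gap = 1.5, seed = 100 + s)
    fit <- fit_forest(px$d2c, px$labels, ntree = 100, seed = 200 + s)
    tb <- oob_permutation_importance(fit, seed = 300 + s)
    expect_gt(tb$raw_score[tb$instance_id == "i01"], 0)
    hits <- hits + (tb$rank[tb$instance_id == "i01"] == 1L)
  }
  expect_gte(hits, 4L)
})

test_that("importance run is reproducible under a fixed seed", {
  px <- planted_d2c()
  run <- function() {
    fit <- fit_forest(px$d2c, px$labels, ntree = 30, seed = 11)
    oob_permutation_importance(fit, seed = 12)$raw_score
  }
  expect_identical(run(), run())
})

test_that("standardisation maps to [0,1] and is affine-invariant", {
  expect_equal(standardize_scores(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(standardize_scores(c(0, 1)), c(0, 1))
  expect_warning(s <- standardize_scores(c(2, 2, 2)), "all raw scores")
  expect_equal(s, rep(0.5, 3))

  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(12)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(standardize_scores(a * v + b), standardize_scores(v),
                 tolerance = 1e-12)
  }
})

test_that("rate-normalised variant divides by per-tree OOB size", {
  px <- planted_d2c(gap = 2)
  fit <- fit_forest(px$d2c, px$labels, ntree = 30, seed = 21)
  cnt <- oob_permutation_importance(fit, seed = 22, scale = "count")
  rate <- oob_permutation_importance(fit, seed = 22, scale = "rate")
  # same permutation stream, so the planted signal survives both scalings
  expect_equal(which.max(cnt$raw_score), which.max(rate$raw_score))
  expect_lt(max(abs(rate$raw_score)), max(abs(cnt$raw_score)))
})

test_that("wilcoxon importance follows the rank-sum test", {
  px <- planted_d2c()
  m <- px$d2c$scores

  # identical group multisets -> p = 1 -> importance 0
  m[2, ] <- rep(seq(-1, 1, length.out = 30), 2)
  # constant column -> importance 0
  m[3, ] <- 0.4
  # full separation at 30 vs 30 -> exact-test minimum unreachable (ties
  # are absent); compare against the enumerated minimal p at n=10 per
  # group on a small case below
  d2c <- d2c_matrix(m)
  tb <- wilcoxon_importance(d2c, px$labels)
  expect_equal(tb$raw_score[tb$instance_id == "i02"], 0)
  expect_equal(tb$raw_score[tb$instance_id == "i03"], 0)
  expect_gt(tb$raw_score[tb$instance_id == "i01"], 0)

  # exact minimal p for full separation, n = 10 per group
  sep <- matrix(c(seq_len(20) / 10, rnorm(20)), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), sprintf("c%02d", 1:20)))
  lab <- cell_labels(rep(c(0L, 1L), each = 10), colnames(sep))
  tb2 <- wilcoxon_importance(d2c_matrix(pmin(pmax(sep, -2), 2)), lab)
  p_min <- 2 / choose(20, 10)   # exhaustive rank-sum enumeration
  expect_equal(tb2$raw_score[tb2$instance_id == "s1"], -log10(p_min),
               tolerance = 1e-10)
})

test_that("ANOVA importance gates on Bartlett and matches t^2 for 2 groups", {
  set.seed(31)
  n <- 50
  y <- rep(c(0L, 1L), each = n)
  v_equal <- c(rnorm(n, 0, 1), rnorm(n, 5, 1))        # homogeneous
  v_heter <- c(rnorm(n, 0, 0.2), rnorm(n, 1, 3))      # heteroskedastic
  v_null <- rnorm(2 * n)
  m <- rbind(i1 = v_equal / 4, i2 = v_heter / 3, i3 = v_null / 4)
  m <- pmin(pmax(m, -2), 2)
  colnames(m) <- sprintf("c%03d", seq_len(2 * n))
  lab <- cell_labels(y, colnames(m))
  tb <- anova_importance(d2c_matrix(m), lab)
  br <- attr(tb, "branch")
  expect_equal(unname(br["i1"]), "anova")
  expect_equal(unname(br["i2"]), "welch")

  # two-group classic ANOVA F equals the squared pooled t statistic
  tstat <- t.test(m["i1", y == 1], m["i1", y == 0],
                  var.equal = TRUE)$statistic
  expect_equal(tb$raw_score[tb$instance_id == "i1"], unname(tstat^2),
               tolerance = 1e-10)
  # equal means and variances -> small F
  expect_lt(tb$raw_score[tb$instance_id == "i3"],
            tb$raw_score[tb$instance_id == "i1"] / 10)
})

test_that("L1 logistic importance finds the informative feature", {
  px <- planted_d2c(gap = 2, n_cells = 80)
  tb1 <- logistic_l1_importance(px$d2c, px$labels, seed = 41)
  expect_equal(tb1$instance_id[tb1$rank == 1L], "i01")
  tb2 <- logistic_l1_importance(px$d2c, px$labels, seed = 41)
  expect_identical(tb1$raw_score, tb2$raw_score)   # same folds, same fit
})

test_that("ensemble vote counts top-half membership across methods", {
  ids <- sprintf("i%02d", 1:6)
  mk <- function(raw) DrugReSC:::new_score_table(ids, ids, "m", raw)
  t1 <- mk(c(6, 5, 4, 3, 2, 1))   # top half: i01 i02 i03
  t2 <- mk(c(6, 5, 4, 3, 2, 1))
  t3 <- mk(c(1, 6, 5, 4, 3, 2))   # top half: i02 i03 i04
  t4 <- mk(c(1, 2, 3, 4, 5, 6))   # top half: i04 i05 i06
  out <- ensemble_vote(list(t1, t2, t3, t4), k = 3)
  v <- structure(out$votes, names = out$instance_id)
  expect_equal(unname(v[c("i01", "i02", "i03", "i04")]), c(2L, 3L, 3L, 2L))
  expect_setequal(out$instance_id[out$candidate], c("i02", "i03"))
  expect_error(ensemble_vote(list(t1, t2), k = 3), "exceeds")
})

test_that("optional SVM and boosting adapters rank the planted instance", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("xgboost")
  px <- planted_d2c(gap = 2)
  tb_svm <- svm_sensitivity_importance(px$d2c, px$labels, seed = 51)
  expect_equal(tb_svm$instance_id[tb_svm$rank == 1L], "i01")
  tb_xgb <- gboost_gain_importance(px$d2c, px$labels, seed = 52,
                                   nrounds = 50)
  expect_equal(tb_xgb$instance_id[tb_xgb$rank == 1L], "i01")
})
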