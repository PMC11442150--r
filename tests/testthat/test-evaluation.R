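truth_of <- function(pos, neg) {
  structure(list(positives = pos, negatives = neg, sampling_seed = 0L,
                 replicate_index = 1L), class = "ground_truth")
}

test_that("negative sampling is balanced, disjoint and seed-stable", {
  pos <- c("p1", "p2", "p3")
  pool <- c(pos, sprintf("n%02d", 1:10))
  gt <- sample_negatives(pos, pool, seed = 7)
  expect_length(gt$negatives, 3)
  expect_length(intersect(gt$negatives, pos), 0)
  expect_true(all(gt$negatives %in% pool))
  expect_identical(gt$negatives, sample_negatives(pos, pool, seed = 7)$negatives)
  expect_error(sample_negatives(pos, c(pos, "n1")), "too small")
})

test_that("ground-truth replication derives one seed per replicate", {
  pos <- c("p1", "p2")
  pool <- c(pos, sprintf("n%02d", 1:8))
  gts <- build_ground_truths(pos, pool, n = 10, master_seed = 3)
  expect_length(gts, 10)
  expect_equal(vapply(gts, `[[`, 0L, "replicate_index"), 1:10)
  expect_equal(vapply(gts, `[[`, 0L, "sampling_seed"), 3L + 1:10)
  # reproducible family; a different master seed changes it
  gts2 <- build_ground_truths(pos, pool, n = 10, master_seed = 3)
  expect_identical(lapply(gts, `[[`, "negatives"),
                   lapply(gts2, `[[`, "negatives"))
  gts3 <- build_ground_truths(pos, pool, n = 10, master_seed = 4)
  expect_false(identical(lapply(gts, `[[`, "negatives"),
                         lapply(gts3, `[[`, "negatives")))
  expect_length(build_ground_truths(pos, pool, n = 1, master_seed = 1), 1)
})

test_that("auroc equals exhaustive pair counting", {
  # the spec-style worked case
  s <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.6)
  gt <- truth_of(c("a", "c"), c("b", "d"))
  expect_equal(auroc(s, gt), 0.75)

  # perfect separation and all-tied scores
  expect_equal(auroc(c(a = 2, b = 1, c = 0.9), truth_of("a", c("b", "c"))), 1)
  expect_equal(auroc(c(a = 1, b = 1, c = 1, d = 1),
                     truth_of(c("a", "b"), c("c", "d"))), 0.5)

  # randomised equivalence with the pair oracle, including ties,
  # across many labelings of up to 12 instances
  set.seed(55)
  for (case in 1:40) {
    n <- sample(4:12, 1)
    sc <- round(rnorm(n), 1)            # rounding induces ties
    names(sc) <- paste0("x", seq_len(n))
    P <- sample(seq_len(n - 1), 1)
    pos <- names(sc)[sample.int(n, P)]
    gt <- truth_of(pos, setdiff(names(sc), pos))
    expect_equal(auroc(sc, gt),
                 auroc_pairs(sc[pos], sc[setdiff(names(sc), pos)]),
                 tolerance = 1e-12)
    # complement identity in the absence of ties
    sc2 <- structure(sample(seq_len(n)) + 0, names = names(sc))
    expect_equal(auroc(sc2, gt) + auroc(-sc2, gt), 1, tolerance = 1e-12)
  }
})

test_that("aupr handles perfect, worst-single-positive and tied lists", {
  gt <- truth_of(c("a", "b"), c("c", "d"))
  expect_equal(aupr(c(a = 4, b = 3, c = 2, d = 1), gt), 1)

  # single positive ranked last of n -> 1/n
  for (n in c(4, 7, 10)) {
    sc <- structure(seq(n, 1), names = paste0("x", 1:n))
    gt1 <- truth_of(paste0("x", n), paste0("x", 1:(n - 1)))
    expect_equal(aupr(sc, gt1), 1 / n, tolerance = 1e-12)
  }

  # all tied -> prevalence
  sc <- structure(rep(1, 6), names = paste0("x", 1:6))
  gt2 <- truth_of(paste0("x", 1:2), paste0("x", 3:6))
  expect_equal(aupr(sc, gt2), 2 / 6, tolerance = 1e-12)
})

test_that("metrics are invariant to strictly increasing score transforms", {
  set.seed(66)
  sc <- structure(runif(10), names = paste0("x", 1:10))
  gt <- truth_of(paste0("x", 1:4), paste0("x", 5:10))
  f <- function(v) exp(3 * v) + 1
  expect_equal(auroc(sc, gt), auroc(f(sc), gt), tolerance = 1e-12)
  expect_equal(aupr(sc, gt), aupr(f(sc), gt), tolerance = 1e-12)
  expect_equal(f1_score(binarize(sc, gt), gt),
               f1_score(binarize(f(sc), gt), gt))
})

test_that("binarize, F1 and accuracy reproduce the worked confusion", {
  # perfect and inverted rankings on a balanced truth
  gt <- truth_of(c("a", "b"), c("c", "d"))
  perf <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(f1_score(binarize(perf, gt), gt), 1)
  expect_equal(accuracy_score(binarize(perf, gt), gt), 1)
  inv <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(f1_score(binarize(inv, gt), gt), 0)
  expect_equal(accuracy_score(binarize(inv, gt), gt), 0)

  # TP=2 FP=1 FN=1 TN=2
  gt6 <- truth_of(c("p1", "p2", "p3"), c("n1", "n2", "n3"))
  pred <- structure(c(1L, 1L, 0L, 1L, 0L, 0L),
                    names = c("p1", "p2", "p3", "n1", "n2", "n3"))
  expect_equal(f1_score(pred, gt6), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(accuracy_score(pred, gt6), 4 / 6)

  # top-m rule with tied scores falls back to instance-id order
  tied <- structure(rep(0.5, 4), names = c("a", "b", "c", "d"))
  pr <- binarize(tied, gt)
  expect_equal(sum(pr), 2L)
  expect_equal(names(pr)[pr == 1L], c("a", "b"))

  # fixed-threshold option
  thr <- binarize(perf, gt, threshold = 2.5)
  expect_equal(unname(thr[c("a", "b", "c", "d")]), c(1L, 1L, 0L, 0L))
})

test_that("replicate aggregation reports mean and sample sd", {
  rows <- data.frame(replicate = 1:2, auroc = c(0.6, 0.8),
                     aupr = c(0.5, 0.5), f1 = c(1, 1),
                     accuracy = c(0.9, 0.7))
  rep2 <- aggregate_metrics(rows)
  agg <- rep2$aggregate
  expect_equal(agg$mean[agg$metric == "auroc"], 0.7)
  expect_equal(agg$sd[agg$metric == "auroc"], sd(c(0.6, 0.8)))
  expect_equal(agg$sd[agg$metric == "aupr"], 0)
  # single replicate: sd reported as 0 and flagged
  rep1 <- aggregate_metrics(rows[1, ])
  expect_true(rep1$sd_degenerate)
  expect_true(all(rep1$aggregate$sd == 0))

  # end-to-end evaluate_scores over replicated truths
  pos <- c("p1", "p2"); pool <- c(pos, sprintf("n%02d", 1:8))
  sc <- structure(c(10, 9, rnorm(8)), names = pool)
  rep <- evaluate_scores(sc, build_ground_truths(pos, pool, n = 5,
                                                 master_seed = 2))
  expect_equal(nrow(rep$per_replicate), 5)
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "auroc"], 1)
})
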