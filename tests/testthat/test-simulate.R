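test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_disease_cells = 0))
  expect_error(sim_config(program_size = 2000, n_genes = 2000))
  expect_error(sim_config(reversal_strength = 0))
  expect_error(sim_config(effect_size = -1))
})

test_that("simulated cohort has the configured shape and structure", {
  cfg <- sim_config(n_genes = 400, n_cells = 80, program_size = 40,
                    n_positive_drugs = 3, n_negative_drugs = 5, seed = 2)
  fx <- simulate_cohort(cfg)
  expect_equal(dim(fx$expression), c(400L, 80L))
  expect_length(fx$labels, 80)
  expect_equal(sum(fx$labels), 8L)              # 10% disease cells
  expect_length(fx$profiles, 8)
  expect_length(fx$positives, 3)
  expect_length(fx$program$up, 20)
  expect_true(all(fx$expression >= 0))          # clipped log scale

  # every instance is at 10 uM, so the default dose filter keeps all
  expect_length(filter_instances(fx$profiles), 8)

  # positive drugs reverse the program; negatives avoid it entirely
  sig <- build_signature(fx$profiles[[1]])
  expect_true(all(sig$down %in% fx$program$up))
  expect_true(all(sig$up %in% fx$program$down))
  sig_neg <- build_signature(fx$profiles[[4]])
  expect_length(intersect(c(sig_neg$up, sig_neg$down),
                          c(fx$program$up, fx$program$down)), 0)
  # matched signature sizes
  expect_length(sig_neg$up, length(sig$up))
})

test_that("identical seeds give byte-identical fixture files", {
  cfg <- sim_config(n_genes = 150, n_cells = 30, program_size = 20,
                    n_positive_drugs = 2, n_negative_drugs = 3, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the fixture
  cfg2 <- sim_config(n_genes = 150, n_cells = 30, program_size = 20,
                     n_positive_drugs = 2, n_negative_drugs = 3, seed = 100)
  d3 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "expression.tsv")),
                         readLines(file.path(d3, "expression.tsv"))))
})

test_that("written fixtures reload through the io layer", {
  cfg <- sim_config(n_genes = 120, n_cells = 25, program_size = 16,
                    n_positive_drugs = 2, n_negative_drugs = 3, seed = 17)
  fx <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(fx, d)
  em <- read_expression(file.path(d, "expression.tsv"), "dense_table")
  expect_equal(dim(em), dim(fx$expression))
  expect_equal(unclass(em), unclass(fx$expression), tolerance = 1e-6)
  lab <- read_labels(file.path(d, "labels.tsv"))
  expect_equal(lab, fx$labels)
  profs <- read_de_profiles(file.path(d, "de_profiles.tsv"))
  expect_length(profs, 5)
  sigs <- signatures_from_gmt(file.path(d, "signatures.gmt"))
  expect_length(sigs, 5)
  expect_equal(readLines(file.path(d, "positives.txt")), fx$positives)
})

test_that("zero effect size leaves the two cell groups exchangeable", {
  fx <- tiny_cohort(seed = 31, effect_size = 0)
  em <- fx$expression
  # group-mean difference of program genes is at noise scale
  dis <- names(fx$labels)[fx$labels == 1L]
  oth <- names(fx$labels)[fx$labels == 0L]
  gap <- rowMeans(em[fx$program$up, dis, drop = FALSE]) -
    rowMeans(em[fx$program$up, oth, drop = FALSE])
  expect_lt(abs(mean(gap)), 0.5)
})

test_that("strong planted reversal separates group-mean D2C per positive", {
  gaps_ok <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    fx <- simulate_cohort(sim_config(n_genes = 500, n_cells = 80,
                                     program_size = 40, effect_size = 3,
                                     reversal_strength = 1,
                                     n_positive_drugs = 2,
                                     n_negative_drugs = 4,
                                     seed = 700 + s))
    sigs <- lapply(fx$profiles, build_signature)
    d2c <- build_d2c_matrix(fx$expression, sigs)
    dis <- fx$labels[d2c$cells] == 1L
    gap <- abs(rowMeans(d2c$scores[fx$positives, dis, drop = FALSE]) -
                 rowMeans(d2c$scores[fx$positives, !dis, drop = FALSE]))
    gaps_ok <- gaps_ok + all(gap > 0)
  }
  expect_equal(gaps_ok, n_seeds)
})

test_that("worked example matches its hand evaluation", {
  fx <- make_worked_example()
  r1 <- rank_cell(fx$expression[, 1])
  expect_identical(enrichment_score(r1, "g1"), 1)
  expect_identical(enrichment_score(r1, "g3"), -1)
  expect_identical(d2c_score(r1, fx$signatures$reversal), 2)
  expect_identical(fx$d2c_self(r1, c("g1", "g2")), 0)
  # the second cell reverses the ranking, hence the sign
  r2 <- rank_cell(fx$expression[, 2])
  expect_identical(d2c_score(r2, fx$signatures$reversal), -2)
})
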