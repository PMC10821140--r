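test_that("validity, uniqueness and novelty follow their definitions and edge rules", {
  expect_equal(validity(c("CCO", "c1ccccc1", "C1CC")), 2 / 3)
  expect_equal(validity(c("CCO", "CCN")), 1)
  expect_equal(validity(c("xx", "yy")), 0)
  expect_error(validity(character(0)), "empty")

  # one rewriting among five valid strings -> 4/5 distinct
  gen <- c("CCO", "OCC", "CCN", "CCS", "CCC")
  expect_equal(unique_at_k(gen, k = 5), 4 / 5)
  expect_equal(unique_at_k(rep("CCO", 10), k = 10), 1 / 10)
  # fewer than k valid: denominator falls back to the number of valid ones
  expect_equal(unique_at_k(c("CCO", "bad", "CCN"), k = 10), 1)
  expect_error(unique_at_k(c("bad", "worse"), k = 5), "no valid")

  expect_equal(novelty(c("A", "B", "C"), "A"), 2 / 3)
  expect_equal(novelty(c("A", "B"), c("X", "Y")), 1)
  expect_equal(novelty(c("A", "B"), c("A", "B", "C")), 0)
  expect_error(novelty(character(0), "A"), "empty")
})

test_that("success rate is the exact product and reproduces the benchmark panel", {
  expect_equal(success_rate(1, 1, 1), 1)
  expect_error(success_rate(1.2, 1, 1), "0, 1|\\[0, 1\\]")

  panel <- load_benchmark_panel()
  expect_identical(nrow(panel), 14L)
  for (i in seq_len(nrow(panel))) {
    prod <- success_rate(panel$validity[i], panel$uniqueness[i], panel$novelty[i])
    expect_equal(round(prod, 3), panel$success_rate[i],
                 label = sprintf("%s/%s product", panel$dataset[i], panel$model[i]))
  }
})

test_that("Tanimoto is reflexive, symmetric and matches the RDKit oracle", {
  cs <- load_case_study_pairs()
  expect_equal(tanimoto(cs$generated[1], cs$generated[1]), 1)
  expect_equal(tanimoto(cs$generated[1], cs$reference[1]),
               tanimoto(cs$reference[1], cs$generated[1]))
  expect_error(tanimoto("C1CC", "CCO"), "invalid")

  # dual route: R sparse-count computation vs RDKit's own similarity
  for (fp in list(fingerprint_spec("morgan_count"), fingerprint_spec("morgan_bits"))) {
    M <- tanimoto_matrix(cs$generated, fp)
    Mo <- chem_tanimoto_oracle(cs$generated, fp)
    expect_lt(max(abs(M - Mo)), 1e-12)
    expect_equal(M, t(M))
  }
})

test_that("internal diversity matches a naive double-loop oracle and is order-invariant", {
  expect_equal(internal_diversity(rep("CCO", 4)), 0)
  expect_equal(internal_diversity("CCO"), 0)

  smiles <- toy_corpus_100()$canonical[1:10]
  M <- tanimoto_matrix(smiles)
  for (p in c(1L, 2L)) {
    naive <- 0
    for (i in 1:10) for (j in 1:10) naive <- naive + M[i, j]^p
    naive <- 1 - (naive / 100)^(1 / p)
    expect_equal(internal_diversity(smiles, p = p), naive, tolerance = 1e-9)
  }
  set.seed(5)
  expect_equal(internal_diversity(sample(smiles), p = 1),
               internal_diversity(smiles, p = 1), tolerance = 1e-12)
  expect_error(internal_diversity(character(0)), "empty")
})

test_that("property profiling reproduces reference descriptor values", {
  # methane: molecular weight from atomic masses, zero polar surface area
  ch4 <- property_profile("C")
  expect_equal(ch4$mw, 16.043, tolerance = 0.01)
  expect_identical(ch4$tpsa, 0)
  expect_true(ch4$sascore >= 1 && ch4$sascore <= 10)

  cs <- load_case_study_pairs()
  pp <- property_profile(cs$generated)
  expect_true(all(pp$qed > 0 & pp$qed < 1))
  # row 1 reference values
  expect_close(pp$qed[1], 0.916, 0.005)
  expect_close(pp$sascore[1], 1.839, 0.005)
  expect_close(pp$logp[1], 2.952, 0.005)
  expect_error(property_profile("C1CC"), "invalid")
})

test_that("classification metrics implement the formulas and flag undefined cases", {
  m <- classification_metrics(tp = 1, fp = 0, fn = 0)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  m <- classification_metrics(tp = 50, fp = 50, fn = 0)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 2 / 3)

  m <- classification_metrics(tp = 0, fp = 0, fn = 5)
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 0)
  expect_true(all(c("precision", "f1") %in% m$undefined))
  expect_error(classification_metrics(0, 0, 0, 0), "all-zero")
  expect_error(classification_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("generation report combines the five metrics coherently", {
  train <- toy_corpus_100()$canonical
  gen <- c(train[1:5], enumerate_smiles(train[6], 2, seed = 1), "C1CC",
           "CCOCCN", "CCNC(=O)CF")
  rep <- generation_report(gen, train, k = 100, p = 1)
  m <- rep$metrics
  expect_equal(m$validity, 9 / 10)
  expect_equal(m$success_rate, m$validity * m$unique_at_k * m$novelty,
               tolerance = 1e-12)
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  # 8 distinct canonical forms among 9 valid (one enumerated duplicate)
  expect_equal(m$unique_at_k, 8 / 9)
  # 2 of the 8 distinct molecules are outside the training set
  expect_equal(m$novelty, 2 / 8)

  path <- withr::local_tempfile(fileext = ".json")
  write_generation_report(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$metrics$validity, 0.9)
})

test_that("property distribution comparison aligns bins and detects shifts", {
  cs <- load_case_study_pairs()
  pp <- property_profile(cs$generated)
  cmp0 <- compare_property_distributions(pp, pp)
  for (p in names(cmp0)) {
    expect_identical(cmp0[[p]]$gen_counts, cmp0[[p]]$ref_counts)
    expect_equal(cmp0[[p]]$mean_difference, 0)
  }
  shifted <- pp
  shifted$logp <- shifted$logp + 1
  cmp1 <- compare_property_distributions(shifted, pp)
  expect_equal(cmp1$logp$mean_difference, 1, tolerance = 1e-12)
  expect_error(compare_property_distributions(pp[0, ], pp), "empty")
})
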