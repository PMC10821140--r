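test_that("validation accepts parseable SMILES and rejects garbage quietly", {
  expect_identical(validate_smiles(c("CCO", "c1ccccc1", "C1CC", "xyz", "")),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(validate_smiles(character(0)), logical(0))
})

test_that("canonicalization is idempotent and writing-invariant", {
  forms <- c("OCC", "CCO", "C(C)O")
  canon <- canonicalize_smiles(forms)
  expect_length(unique(canon), 1L)
  expect_identical(canonicalize_smiles(canon), canon)
  expect_error(canonicalize_smiles("C1CC"), "invalid")
})

test_that("enumeration is seeded, valid and canonical-form preserving", {
  apap <- "CC(=O)Nc1ccc(O)cc1"
  e1 <- enumerate_smiles(apap, 10, seed = 3)
  expect_length(e1, 10L)
  expect_true(all(validate_smiles(e1)))
  expect_true(all(canonicalize_smiles(e1) == canonicalize_smiles(apap)))
  expect_identical(enumerate_smiles(apap, 10, seed = 3), e1)
  expect_false(identical(enumerate_smiles(apap, 10, seed = 4), e1))
  expect_identical(enumerate_smiles("C", 1, seed = 0), "C")
  expect_error(enumerate_smiles("notsmiles", 2, seed = 0), "invalid")
})

test_that("view pairs share the canonical form and rarely coincide for big molecules", {
  vp <- sample_view_pair("C", seed = 0)
  expect_identical(vp$x1, "C")
  expect_identical(vp$x2, "C")

  apap <- sample_view_pair("CC(=O)Nc1ccc(O)cc1", seed = 0)
  expect_identical(canonicalize_smiles(apap$x1), apap$source_canonical)
  expect_identical(canonicalize_smiles(apap$x2), apap$source_canonical)

  # Monte-Carlo coincidence rate on a ~20-heavy-atom molecule
  big <- "COc1ccc(NC(=O)N2CCN(C(=O)C3CCCCC3)CC2)cc1"
  pairs <- sample_view_pairs(rep(big, 1000), seed = 42)
  coincide <- mean(vapply(pairs, function(p) p$x1 == p$x2, logical(1)))
  expect_lt(coincide, 0.05)
})

test_that("vocabulary has dense ids, reserved specials and scheme-aware tokens", {
  v <- build_vocab("CCO")
  expect_s3_class(v, "token_vocabulary")
  expect_identical(v$size, 6L)
  expect_identical(v$tokens[1:4], c("<pad>", "<bos>", "<eos>", "<unk>"))

  v2 <- build_vocab(c("CCl", "C[NH3+]C", "C%11CC%11"))
  expect_true(all(c("Cl", "[NH3+]", "%11") %in% v2$tokens))
  # bijective map over non-specials
  body <- v2$tokens[-(1:4)]
  expect_identical(v2$tokens[vocab_id(v2, body) + 1L], body)
  expect_error(build_vocab(character(0)), "empty")
})

test_that("tokenize/detokenize round-trips and handles specials", {
  v <- build_vocab("CCO")
  t1 <- tokenize("CCO", v)
  expect_identical(t1$ids, c(1L, 4L, 4L, 5L, 2L))
  expect_identical(t1$length, 5L)
  expect_identical(detokenize(t1, v), "CCO")

  # round-trip identity over a generated corpus
  corpus <- toy_corpus_100()$canonical
  vc <- build_vocab(corpus)
  for (s in corpus[seq(1, 100, 7)]) {
    expect_identical(detokenize(tokenize(s, vc), vc), s)
  }

  expect_true(build_vocab("CCO")$unk %in% tokenize("CBr", v)$ids)
  expect_error(tokenize(strrep("C", 200), v, max_len = 100), "exceeds")

  expect_identical(detokenize(c(1L, 2L), v), "")
  expect_identical(detokenize(c(1L, 4L, 2L, 5L, 5L), v), "C")  # after-eos dropped
  expect_error(detokenize(c(1L, 99L), v), "out of range")
})

test_that("smi/csv/vocab readers and writers round-trip and strip whitespace", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "c1ccccc1"), tmp)
  expect_identical(read_smi(tmp), c("CCO", "c1ccccc1"))
  writeLines(c("CCO mol1", "", "  c1ccccc1  name two"), tmp)
  expect_identical(read_smi(tmp), c("CCO", "c1ccccc1"))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "1,COc1ccc(NC(=O)N2CCN(C(=O)C3 CCCCC3)CC2)cc1"), csv)
  expect_identical(read_smiles_csv(csv),
                   "COc1ccc(NC(=O)N2CCN(C(=O)C3CCCCC3)CC2)cc1")
  expect_error(read_smiles_csv(csv, column = "nope"), "no column")

  vf <- withr::local_tempfile(fileext = ".vocab")
  v <- build_vocab(c("CCl", "C[NH3+]C"))
  write_vocab(v, vf)
  expect_identical(read_vocab(vf), v)
})

test_that("molecule records keep invalid strings with a flag", {
  rec <- molecule_records(c("CCO", "C1CC"))
  expect_identical(rec$is_valid, c(TRUE, FALSE))
  expect_true(is.na(rec$canonical[2]))
  expect_identical(rec$canonical[1], "CCO")
})
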