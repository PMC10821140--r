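# brute-force NT-Xent oracle: explicit double loop over anchors and
# negatives, independent of the vectorized implementation
ntxent_oracle <- function(Z, tau) {
  n2 <- nrow(Z)
  sim <- function(i, j) sum(Z[i, ] * Z[j, ]) / sqrt(sum(Z[i, ]^2) * sum(Z[j, ]^2))
  total <- 0
  for (i in seq_len(n2)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    denom <- 0
    for (k in seq_len(n2)) if (k != i) denom <- denom + exp(sim(i, k) / tau)
    total <- total - log(exp(sim(i, j) / tau) / denom)
  }
  total / n2
}

test_that("configuration invariants are enforced", {
  expect_error(contrastive_config(temperature = 0), "temperature")
  expect_error(contrastive_config(embed_dim = 10, attention_heads = 3))
  expect_error(contrastive_config(patience = 200, max_epochs = 100))
  cfg <- contrastive_config()
  expect_identical(cfg$batch_molecules, 16L)
  expect_identical(cfg$embed_dim, 256L)
  expect_equal(cfg$temperature, 0.1)
  expect_equal(range(cfg$learning_rate), c(1e-4, 1e-2))
})

test_that("cosine similarity behaves on axes and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(-1, -1)), -1)
  expect_equal(cosine_similarity(c(2, 3), c(4, 6)), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("NT-Xent equals the hand value and the double-loop oracle", {
  # N=1: the denominator holds only the positive -> exactly 0
  expect_identical(nt_xent_loss(rbind(c(1, 2), c(-3, 1)), tau = 0.7), 0)

  # N=2 axis-aligned hand value: -log(e / (e + 2))
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(nt_xent_loss(Z, tau = 1), -log(exp(1) / (exp(1) + 2)), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    N <- sample(2:4, 1)
    d <- sample(2:8, 1)
    Z <- matrix(rnorm(2 * N * d), 2 * N, d)
    tau <- runif(1, 0.05, 1)
    expect_equal(nt_xent_loss(Z, tau), ntxent_oracle(Z, tau), tolerance = 1e-6)
  }

  expect_error(nt_xent_loss(Z, tau = -1), "positive")
  expect_error(nt_xent_loss(matrix(rnorm(9), 3, 3), tau = 1), "2N")
})

test_that("NT-Xent is batch-permutation invariant and rewards positive similarity", {
  set.seed(37)
  N <- 4; d <- 6
  Z <- matrix(rnorm(2 * N * d), 2 * N, d)
  base <- nt_xent_loss(Z, 0.2)
  perm <- sample(N)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  expect_equal(nt_xent_loss(Z[rows, ], 0.2), base, tolerance = 1e-6)

  # pulling one positive pair together (all else fixed) lowers the loss
  Z2 <- Z
  Z2[2, ] <- Z2[1, ] + 0.01 * (Z2[2, ] - Z2[1, ])
  expect_lt(nt_xent_loss(Z2, 0.2), base)

  # analytic gradient agrees with finite differences
  fb <- nt_xent_fwd_bwd(Z, 0.2)
  for (i in c(1L, 9L, 30L)) {
    Zp <- Z; Zp[i] <- Zp[i] + 1e-6
    Zm <- Z; Zm[i] <- Zm[i] - 1e-6
    nu <- (nt_xent_loss(Zp, 0.2) - nt_xent_loss(Zm, 0.2)) / 2e-6
    expect_equal(fb$dZ[i], nu, tolerance = 1e-5)
  }
})

test_that("pre-training learns, early-stops and is seed-reproducible", {
  ck <- tiny_contrastive_ckpt()
  expect_s3_class(ck, "model_checkpoint")
  h <- ck$metadata$history
  expect_true(all(is.finite(h$train_loss)))
  expect_lte(ck$metadata$best_val_loss, h$val_loss[1])

  ck2 <- pretrain_contrastive(toy_corpus_60(), tiny_contrastive_config(),
                              seed = 7, verbose = FALSE)
  expect_identical(ck2$metadata$best_val_loss, ck$metadata$best_val_loss)
  expect_identical(ck2$params$tok_emb, ck$params$tok_emb)
})

test_that("encode_views/project run off a checkpoint and the embedding transfers", {
  ck <- tiny_contrastive_ckpt()
  R <- encode_views(ck, c("CCO", "CCO", "c1ccccc1"))
  expect_identical(dim(R), c(3L, ck$config$embed_dim))
  expect_equal(R[1, ], R[2, ], tolerance = 1e-12)
  Zp <- project(ck, R)
  expect_identical(ncol(Zp), ck$config$proj_out_dim)

  emb <- extract_embedding(ck)
  expect_identical(nrow(emb$embedding), ck$vocab$size)

  # re-insert into a fresh model of the same shape: encoder outputs identical
  ck_fresh <- ck
  ck_fresh$params$tok_emb <- matrix(0, ck$vocab$size, ck$config$embed_dim)
  ck_restored <- ck_fresh
  ck_restored$params$tok_emb <- emb$embedding
  expect_equal(encode_views(ck_restored, "CCO"), encode_views(ck, "CCO"),
               tolerance = 1e-12)

  # transfer guard: different vocabulary is rejected, model unmodified
  other <- list(params = list(tok_emb = matrix(0, 5, ck$config$embed_dim)),
                vocab = build_vocab("CCO"))
  expect_error(load_pretrained_embedding(other, ck), "mismatch")
})

test_that("checkpoints round-trip through disk bit-identically", {
  ck <- tiny_contrastive_ckpt()
  f1 <- withr::local_tempfile(fileext = ".rds")
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f1)
  re <- load_checkpoint(f1)
  expect_identical(re$params, ck$params)
  save_checkpoint(re, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  expect_error(suppressWarnings(load_checkpoint(withr::local_tempfile(fileext = ".rds"))))
})
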