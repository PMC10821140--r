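# The transformer stack's hand-derived backpropagation is validated against
# central finite differences: the strongest available oracle for the
# network code, covering every layer type in one sweep.

numeric_grad <- function(f, params, path, i, eps = 1e-5) {
  perturb <- function(delta) {
    p <- params
    if (length(path) == 1) {
      p[[path[[1]]]][i] <- p[[path[[1]]]][i] + delta
    } else {
      p[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] <-
        p[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] + delta
    }
    p
  }
  (f(perturb(eps)) - f(perturb(-eps))) / (2 * eps)
}

pick_grad <- function(grads, path, i) {
  g <- grads[[path[[1]]]]
  if (length(path) > 1) g <- g[[path[[2]]]][[path[[3]]]]
  g[i]
}

check_paths <- function(f, params, grads, paths) {
  for (p in paths) {
    target <- params[[p[[1]]]]
    if (length(p) > 1) target <- target[[p[[2]]]][[p[[3]]]]
    set.seed(length(target))
    for (i in sample(length(target), min(3, length(target)))) {
      an <- pick_grad(grads, p, i)
      nu <- numeric_grad(f, params, p, i)
      expect_true(abs(an - nu) <= 1e-6 + 1e-4 * max(abs(an), abs(nu)),
                  label = sprintf("grad %s[%d]: analytic %g vs numeric %g",
                                  paste(unlist(p), collapse = "$"), i, an, nu))
    }
  }
}

all_block_paths <- function(top, blocks = 1) {
  unlist(lapply(blocks, function(b) {
    lapply(c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
             "ln2_g", "ln2_b", "W1", "b1", "W2", "b2"),
           function(nm) list(top, b, nm))
  }), recursive = FALSE)
}

test_that("gelu matches the exact normal-CDF form", {
  expect_identical(gelu(0), 0)
  expect_equal(gelu(1), pnorm(1), tolerance = 1e-12)
  expect_equal(gelu(-1), -pnorm(-1), tolerance = 1e-12)
  expect_equal(gelu(c(-2, 0.5, 3)), c(-2, 0.5, 3) * pnorm(c(-2, 0.5, 3)),
               tolerance = 1e-12)
})

test_that("decoder LM gradients match finite differences everywhere", {
  set.seed(11)
  cfg <- decoder_config(n_blocks = 2, d_model = 8, d_ff = 12, attention_heads = 2,
                        max_len = 12, batch_size = 2)
  params <- generator_init(7L, cfg)
  batch <- pad_batch(list(c(1L, 4L, 5L, 6L, 4L, 2L), c(1L, 5L, 6L, 2L)))
  f <- function(p) lm_batch(p, cfg, batch, want_grad = FALSE)$loss
  grads <- lm_batch(params, cfg, batch, want_grad = TRUE)$grads
  paths <- c(list(list("tok_emb"), list("pos_emb"), list("out_W"), list("out_b"),
                  list("lnf_g"), list("lnf_b")),
             all_block_paths("blocks", 1:2))
  check_paths(f, params, grads, paths)
})

test_that("contrastive chain gradients (encoder+pool+projection+NT-Xent) are exact", {
  set.seed(13)
  cfg <- contrastive_config(embed_dim = 8, encoder_layers = 1, attention_heads = 2,
                            d_ff = 12, proj_hidden_dim = 6, proj_out_dim = 4,
                            batch_molecules = 3, temperature = 0.3,
                            learning_rate = 1e-3)
  params <- contrastive_init(9L, cfg)
  # scale the projection head away from the near-zero init so the projected
  # norms are O(1): keeps the finite-difference check well conditioned
  params$proj$W1 <- params$proj$W1 * 20
  params$proj$W2 <- params$proj$W2 * 20
  params$proj$b1 <- rnorm(length(params$proj$b1), sd = 0.2)
  params$proj$b2 <- rnorm(length(params$proj$b2), sd = 0.2)
  ids <- list(c(1L, 4L, 5L, 2L), c(1L, 5L, 4L, 6L, 2L),
              c(1L, 6L, 2L), c(1L, 6L, 6L, 2L),
              c(1L, 4L, 4L, 4L, 2L), c(1L, 5L, 2L))
  f <- function(p) contrastive_batch_loss(p, cfg, ids, want_grad = FALSE)$loss
  grads <- contrastive_batch_loss(params, cfg, ids, want_grad = TRUE)$grads
  check_paths(f, params, grads,
              c(list(list("tok_emb"), list("pos_emb")), all_block_paths("blocks", 1)))
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (i in c(1L, 4L)) {
      an <- grads$proj[[nm]][i]
      pert <- function(delta) { p <- params; p$proj[[nm]][i] <- p$proj[[nm]][i] + delta; p }
      nu <- (f(pert(1e-5)) - f(pert(-1e-5))) / 2e-5
      expect_true(abs(an - nu) <= 1e-6 + 1e-4 * max(abs(an), abs(nu)),
                  label = sprintf("proj %s[%d]: %g vs %g", nm, i, an, nu))
    }
  }
})

test_that("CPI dual-encoder gradients are exact", {
  set.seed(17)
  cfg <- cpi_config(n_layers = 1, d_model = 8, d_ff = 12, attention_heads = 2,
                    max_len = 12, protein_max_len = 12, batch_size = 4)
  params <- cpi_init(7L, 9L, cfg)
  mol_ids <- list(c(1L, 4L, 5L, 2L), c(1L, 5L, 2L), c(1L, 6L, 4L, 2L))
  prot_ids <- list(c(1L, 4L, 7L, 8L, 2L), c(1L, 8L, 2L), c(1L, 5L, 5L, 2L))
  labels <- c(1L, 0L, 1L)
  f <- function(p) cpi_batch(p, cfg, mol_ids, prot_ids, labels, want_grad = FALSE)$loss
  grads <- cpi_batch(params, cfg, mol_ids, prot_ids, labels, want_grad = TRUE)$grads
  check_paths(f, params, grads, list(list("cls_W"), list("cls_b")))
  for (enc in c("mol", "prot")) {
    for (i in c(3L, 10L)) {
      an <- grads[[enc]]$tok_emb[i]
      pert <- function(delta) { p <- params; p[[enc]]$tok_emb[i] <- p[[enc]]$tok_emb[i] + delta; p }
      nu <- (f(pert(1e-5)) - f(pert(-1e-5))) / 2e-5
      expect_true(abs(an - nu) <= 1e-6 + 1e-4 * max(abs(an), abs(nu)),
                  label = sprintf("%s tok_emb[%d]", enc, i))
    }
    for (nm in c("Wq", "W1", "ln2_g", "bo")) {
      an <- grads[[enc]]$blocks[[1]][[nm]][2]
      pert <- function(delta) {
        p <- params; p[[enc]]$blocks[[1]][[nm]][2] <- p[[enc]]$blocks[[1]][[nm]][2] + delta; p
      }
      nu <- (f(pert(1e-5)) - f(pert(-1e-5))) / 2e-5
      expect_true(abs(an - nu) <= 1e-6 + 1e-4 * max(abs(an), abs(nu)),
                  label = sprintf("%s %s", enc, nm))
    }
  }
})

test_that("encoder pooling is padding-invariant and permutation-equivariant", {
  set.seed(19)
  cfg <- contrastive_config(embed_dim = 8, encoder_layers = 2, attention_heads = 2,
                            d_ff = 16, proj_hidden_dim = 8, proj_out_dim = 4,
                            learning_rate = 1e-3)
  params <- contrastive_init(9L, cfg)
  seqs <- list(c(1L, 4L, 5L, 2L), c(1L, 5L, 6L, 6L, 4L, 2L), c(1L, 6L, 2L))

  enc <- function(id_list) {
    b <- pad_batch(id_list)
    mean_pool(transformer_fwd(encoder_params(params), b$ids, b$mask,
                              cfg$attention_heads, causal = FALSE,
                              keep_cache = FALSE)$h, b$mask)
  }
  # extra padding (forcing a wider batch) leaves each row unchanged
  r_alone <- enc(seqs[1])
  r_padded <- enc(seqs)[1, , drop = FALSE]
  expect_equal(r_alone, r_padded, tolerance = 1e-10)

  # permuting sequences permutes rows correspondingly
  r <- enc(seqs)
  r_perm <- enc(seqs[c(3, 1, 2)])
  expect_equal(r_perm, r[c(3, 1, 2), ], tolerance = 1e-10)

  # identical views give identical vectors
  expect_equal(enc(seqs[c(2, 2)])[1, ], enc(seqs[c(2, 2)])[2, ], tolerance = 1e-12)
})

test_that("AdamW freeze skips listed parameters entirely", {
  set.seed(23)
  params <- list(a = matrix(rnorm(4), 2), b = matrix(rnorm(4), 2))
  grads <- list(a = matrix(1, 2, 2), b = matrix(1, 2, 2))
  opt <- adamw_init(params)
  st <- adamw_step(params, grads, opt, lr = 0.1, frozen = "a")
  expect_identical(st$params$a, params$a)
  expect_false(identical(st$params$b, params$b))
})
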