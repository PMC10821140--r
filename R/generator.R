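# Autoregressive SMILES decoder (GPT-style) with optional transfer of the
# contrastively pre-trained token embedding, frozen or unfrozen.

#' Configuration for the generative decoder
#'
#' @param n_blocks decoder blocks (default 8, mirroring comparable GPT-style
#'   SMILES generators; tests use 2).
#' @param d_model model width (default 256).
#' @param d_ff feed-forward hidden width (default 1024).
#' @param attention_heads heads; must divide `d_model`.
#' @param max_len maximum token-sequence length incl. bos/eos.
#' @param dropout dropout probability on the two residual branches during
#'   training (default 0; see vignette).
#' @param learning_rate,batch_size,max_epochs,patience,weight_decay AdamW /
#'   early-stopping protocol, as in [contrastive_config()].
#' @return a validated `decoder_config` list.
#' @export
decoder_config <- function(n_blocks = 8L, d_model = 256L, d_ff = 1024L,
                           attention_heads = 8L, max_len = 128L, dropout = 0,
                           learning_rate = 1e-3, batch_size = 16L,
                           max_epochs = 100L, patience = 10L,
                           weight_decay = 0.01) {
  cfg <- list(n_blocks = as.integer(n_blocks), d_model = as.integer(d_model),
              d_ff = as.integer(d_ff), attention_heads = as.integer(attention_heads),
              max_len = as.integer(max_len), dropout = dropout,
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              weight_decay = weight_decay)
  stopifnot(cfg$n_blocks >= 1, cfg$d_ff > cfg$d_model,
            cfg$d_model %% cfg$attention_heads == 0,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$patience <= cfg$max_epochs)
  class(cfg) <- c("decoder_config", "list")
  cfg
}

generator_init <- function(vocab_size, cfg) {
  params <- transformer_init(vocab_size, cfg$d_model, cfg$n_blocks, cfg$d_ff, cfg$max_len)
  params$out_W <- init_mat(cfg$d_model, vocab_size)
  params$out_b <- rep(0, vocab_size)
  params
}

core_params <- function(params) params[setdiff(names(params), c("out_W", "out_b"))]

#' Next-token logits of the decoder
#'
#' Causal: logits at position t depend only on positions <= t.
#'
#' @param ckpt a generator `model_checkpoint`.
#' @param ids list of 0-based token-id vectors (one per sequence).
#' @return array `[batch, positions, vocab_size]` of logits.
#' @export
decoder_logits <- function(ckpt, ids) {
  cfg <- ckpt$config
  batch <- pad_batch(ids)
  if (ncol(batch$ids) > cfg$max_len) stop("sequence exceeds max_len")
  fwd <- transformer_fwd(core_params(ckpt$params), batch$ids, batch$mask,
                         cfg$attention_heads, causal = TRUE, keep_cache = FALSE)
  logits <- add_bias(fwd$h %*% ckpt$params$out_W, ckpt$params$out_b)
  B <- nrow(batch$ids); L <- ncol(batch$ids)
  out <- array(0, c(B, L, ncol(logits)))
  for (b in seq_len(B)) out[b, , ] <- logits[((b - 1) * L + 1):(b * L), ]
  out
}

#' Transfer a pre-trained token embedding into a model
#'
#' Replaces the token-embedding table of `model` by the one extracted from a
#' contrastive checkpoint.  The two vocabularies must be identical.  With
#' `freeze = TRUE` the table is excluded from subsequent gradient updates
#' (bit-identical before/after training); positional embeddings are never
#' transferred.
#'
#' @param model a generator/CPI `model_checkpoint` or live model list with
#'   `params` and `vocab`.
#' @param ckpt the contrastive `model_checkpoint` donating its embedding.
#' @param freeze logical.
#' @return the modified model, with `frozen_embedding` recorded.
#' @export
load_pretrained_embedding <- function(model, ckpt, freeze = TRUE) {
  emb <- extract_embedding(ckpt)
  if (!identical(model$vocab$tokens, emb$vocab$tokens)) {
    stop("vocabulary mismatch: embedding cannot be transferred")
  }
  if (!identical(dim(model$params$tok_emb), dim(emb$embedding))) {
    stop("embedding dimension mismatch")
  }
  model$params$tok_emb <- emb$embedding
  model$frozen_embedding <- isTRUE(freeze)
  model
}

## ---- training ---------------------------------------------------------------

# mean next-token cross-entropy over a padded batch; pad targets excluded
lm_batch <- function(params, cfg, batch, want_grad = TRUE, n_heads = cfg$attention_heads) {
  fwd <- transformer_fwd(core_params(params), batch$ids, batch$mask, n_heads,
                         causal = TRUE, keep_cache = want_grad,
                         dropout = cfg$dropout, training = want_grad)
  logits <- add_bias(fwd$h %*% params$out_W, params$out_b)
  B <- nrow(batch$ids); L <- ncol(batch$ids)
  tgt <- cbind(batch$ids[, -1, drop = FALSE], 0L)      # next token
  wgt <- cbind(batch$mask[, -1, drop = FALSE], FALSE)  # predict only real ones
  targets <- as.vector(t(tgt))
  weights <- as.numeric(as.vector(t(wgt)))
  sx <- softmax_xent(logits, targets, weights)
  if (!want_grad) return(list(loss = sx$loss))
  dH <- sx$dlogits %*% t(params$out_W)
  grads <- transformer_bwd(core_params(params), fwd$cache, dH)
  grads$out_W <- crossprod(fwd$h, sx$dlogits)
  grads$out_b <- colSums(sx$dlogits)
  list(loss = sx$loss, grads = grads)
}

eval_lm_loss <- function(params, cfg, id_list) {
  n <- length(id_list)
  tot <- 0; cnt <- 0
  for (s in seq(1, n, cfg$batch_size)) {
    idx <- s:min(s + cfg$batch_size - 1L, n)
    batch <- pad_batch(id_list[idx])
    ntok <- sum(vapply(id_list[idx], length, integer(1)) - 1L)
    tot <- tot + lm_batch(params, cfg, batch, want_grad = FALSE)$loss * ntok
    cnt <- cnt + ntok
  }
  tot / cnt
}

#' Train the autoregressive SMILES generator
#'
#' Minimizes next-token cross-entropy over canonical SMILES with AdamW,
#' 19:1 train/validation split and early stopping on validation loss.
#' Optionally seeds the token embedding from a contrastive checkpoint.
#'
#' @param corpus character vector of valid SMILES or molecule records.
#' @param config a [decoder_config()].
#' @param embedding optional `list(ckpt = <contrastive checkpoint>,
#'   freeze = TRUE/FALSE)` for embedding transfer.
#' @param seed integer master seed.
#' @param log_file optional per-epoch log path.
#' @param verbose emit per-epoch log lines to stderr.
#' @return a generator `model_checkpoint`.
#' @export
train_generator <- function(corpus, config = decoder_config(), embedding = NULL,
                            seed = 0L, log_file = NULL, verbose = TRUE) {
  records <- as_molecule_records(corpus)
  if (!all(records$is_valid)) stop("corpus contains invalid SMILES")
  canon <- records$canonical

  frozen <- character(0)
  if (!is.null(embedding)) {
    stopifnot(is.list(embedding), inherits(embedding$ckpt, "model_checkpoint"))
    vocab <- embedding$ckpt$vocab
  } else {
    vocab <- build_vocab(canon)
  }
  ids_all <- safe_token_ids(canon, vocab, config$max_len)

  splits <- split_dataset(seq_along(canon), ratios = c(19, 1), seed = derive_seed(seed, 2L))
  train_ids <- ids_all[splits[[1]]]
  valid_ids <- ids_all[splits[[2]]]
  if (length(valid_ids) < 1L) stop("corpus too small for a 19:1 split")

  set.seed(derive_seed(seed, 101L))
  params <- generator_init(vocab$size, config)
  if (!is.null(embedding)) {
    model <- load_pretrained_embedding(list(params = params, vocab = vocab),
                                       embedding$ckpt, isTRUE(embedding$freeze))
    params <- model$params
    if (model$frozen_embedding) frozen <- "tok_emb"
  }
  opt <- adamw_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- list()

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(train_ids))
    losses <- c()
    for (s in seq(1, length(ord), config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      batch <- pad_batch(train_ids[idx])
      bl <- lm_batch(params, config, batch)
      if (!is.finite(bl$loss)) stop("non-finite training loss; aborting")
      st <- adamw_step(params, bl$grads, opt, config$learning_rate,
                       weight_decay = config$weight_decay, frozen = frozen)
      params <- st$params; opt <- st$opt
      losses <- c(losses, bl$loss)
    }
    vloss <- eval_lm_loss(params, config, valid_ids)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_loss = vloss, lr = config$learning_rate)
    line <- sprintf("epoch %3d  train %.5f  valid %.5f  lr %g",
                    epoch, mean(losses), vloss, config$learning_rate)
    if (verbose) message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
    if (vloss < best$loss) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  new_checkpoint(
    model_type = "generator",
    params = best$params,
    config = config,
    vocab = vocab,
    metadata = list(seed = seed, epochs_run = length(history),
                    best_epoch = best$epoch, best_val_loss = best$loss,
                    frozen_embedding = identical(frozen, "tok_emb"),
                    history = do.call(rbind, history))
  )
}

## ---- sampling ---------------------------------------------------------------

# single-step forward with per-layer key/value caches (inference only)
step_decoder <- function(params, cfg, caches, x, t) {
  nh <- cfg$attention_heads
  d <- cfg$d_model
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  for (li in seq_along(params$blocks)) {
    blk <- params$blocks[[li]]
    xn <- layernorm_fwd(x, blk$ln1_g, blk$ln1_b)$y
    q <- add_bias(xn %*% blk$Wq, blk$bq)
    caches[[li]]$K[, t, ] <- add_bias(xn %*% blk$Wk, blk$bk)
    caches[[li]]$V[, t, ] <- add_bias(xn %*% blk$Wv, blk$bv)
    out <- matrix(0, nrow(x), d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- q[, cols, drop = FALSE]
      sc <- vapply(seq_len(t), function(s) {
        Ks <- matrix(caches[[li]]$K[, s, cols], nrow = nrow(x))
        rowSums(Qh * Ks) * scale
      }, numeric(nrow(x)))
      if (!is.matrix(sc)) sc <- matrix(sc, nrow = nrow(x))
      A <- softmax_rows(sc)
      for (j in seq_along(cols)) {
        Vj <- matrix(caches[[li]]$V[, seq_len(t), cols[j]], nrow = nrow(x))
        out[, cols[j]] <- rowSums(A * Vj)
      }
    }
    x <- x + add_bias(out %*% blk$Wo, blk$bo)
    f <- layernorm_fwd(x, blk$ln2_g, blk$ln2_b)$y
    x <- x + add_bias(gelu(add_bias(f %*% blk$W1, blk$b1)) %*% blk$W2, blk$b2)
  }
  h_out <- layernorm_fwd(x, params$lnf_g, params$lnf_b)$y
  list(logits = add_bias(h_out %*% params$out_W, params$out_b), caches = caches)
}

sample_multinomial <- function(ckpt, n, temperature, seed, chunk = 128L) {
  cfg <- ckpt$config
  vocab <- ckpt$vocab
  set.seed(derive_seed(seed, 7L))
  out <- character(0)
  remaining <- n
  while (remaining > 0) {
    B <- min(chunk, remaining)
    ids <- matrix(vocab$bos, B, 1L)
    finished <- rep(FALSE, B)
    caches <- lapply(ckpt$params$blocks, function(b) {
      list(K = array(0, c(B, cfg$max_len, cfg$d_model)),
           V = array(0, c(B, cfg$max_len, cfg$d_model)))
    })
    last <- rep(vocab$bos, B)
    for (t in seq_len(cfg$max_len - 1L)) {
      x <- ckpt$params$tok_emb[last + 1L, , drop = FALSE] +
        matrix(ckpt$params$pos_emb[t, ], B, cfg$d_model, byrow = TRUE)
      st <- step_decoder(ckpt$params, cfg, caches, x, t)
      caches <- st$caches
      P <- softmax_rows(st$logits / temperature)
      nxt <- integer(B)
      for (b in seq_len(B)) {
        nxt[b] <- if (finished[b]) vocab$pad else
          sample.int(vocab$size, 1L, prob = P[b, ]) - 1L
      }
      finished <- finished | nxt == vocab$eos
      ids <- cbind(ids, nxt)
      last <- nxt
      if (all(finished)) break
    }
    out <- c(out, vapply(seq_len(B), function(b) {
      seq_ids <- ids[b, -1]
      detok_raw(seq_ids, vocab)
    }, character(1)))
    remaining <- remaining - B
  }
  out
}

# body up to first eos, specials dropped; tolerates missing eos
detok_raw <- function(ids, vocab) {
  eos_at <- which(ids == vocab$eos)
  if (length(eos_at)) ids <- ids[seq_len(eos_at[1] - 1L)]
  ids <- ids[!(ids %in% c(vocab$pad, vocab$bos, vocab$eos, vocab$unk))]
  paste(vocab$tokens[ids + 1L], collapse = "")
}

sample_beam <- function(ckpt, n, width) {
  cfg <- ckpt$config
  vocab <- ckpt$vocab
  width <- max(width, n)
  active <- list(list(ids = vocab$bos, logp = 0))
  done <- list()
  for (t in seq_len(cfg$max_len - 1L)) {
    if (!length(active)) break
    lg <- decoder_logits(ckpt, lapply(active, `[[`, "ids"))
    cand <- list()
    for (i in seq_along(active)) {
      pos <- length(active[[i]]$ids)
      lp <- lg[i, pos, ] - log(sum(exp(lg[i, pos, ] - max(lg[i, pos, ])))) - max(lg[i, pos, ])
      keep <- order(lp, decreasing = TRUE)[seq_len(min(width, length(lp)))]
      for (k in keep) {
        cand[[length(cand) + 1L]] <- list(
          ids = c(active[[i]]$ids, k - 1L),
          logp = active[[i]]$logp + lp[k]
        )
      }
    }
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "logp"), decreasing = TRUE)]
    active <- list()
    for (cd in cand) {
      if (utils::tail(cd$ids, 1) == vocab$eos) {
        done[[length(done) + 1L]] <- cd
      } else if (length(active) < width) {
        active[[length(active) + 1L]] <- cd
      }
      if (length(active) >= width && length(done) >= width) break
    }
    if (length(done) >= width) break
  }
  pool <- c(done, active)
  pool <- pool[order(vapply(pool, `[[`, numeric(1), "logp"), decreasing = TRUE)]
  pool <- pool[seq_len(min(n, length(pool)))]
  vapply(pool, function(b) detok_raw(b$ids[-1], vocab), character(1))
}

#' Sample molecules from a trained generator
#'
#' Each sample starts from bos and appends tokens until eos or `max_len`.
#' Multinomial sampling is seeded and reproducible; beam search is
#' deterministic and returns the top-`n` completed beams by total
#' log-probability (width 1 is greedy decoding).  Raw strings may be
#' invalid; validity is a metric, not a guarantee.
#'
#' @param ckpt a generator `model_checkpoint`.
#' @param n number of strings to return.
#' @param strategy `"multinomial"` or `"beam"`, or a list such as
#'   `list(type = "multinomial", temperature = 1)` /
#'   `list(type = "beam", width = 5)`.
#' @param seed integer seed (multinomial only).
#' @return a `generated_set`: list with `smiles`, `seed`, `strategy`.
#' @export
sample_molecules <- function(ckpt, n, strategy = "multinomial", seed = 0L) {
  stopifnot(n >= 1)
  if (is.character(strategy)) strategy <- list(type = strategy)
  if (!is.list(strategy) || !strategy$type %in% c("multinomial", "beam")) {
    stop("invalid sampling strategy; use 'multinomial' or 'beam'")
  }
  smiles <- if (strategy$type == "multinomial") {
    temp <- strategy$temperature %||% 1
    if (temp <= 0) stop("temperature must be positive")
    sample_multinomial(ckpt, n, temp, seed)
  } else {
    width <- strategy$width %||% n
    if (width < 1) stop("beam width must be >= 1")
    sample_beam(ckpt, n, width)
  }
  structure(list(smiles = smiles, seed = seed, strategy = strategy),
            class = "generated_set")
}
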