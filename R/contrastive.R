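# Contrastive pre-training over enumerated SMILES views.
#
# Two randomized writings of the same molecule form the positive pair; the
# other 2(N-1) writings in a batch of N molecules are the negatives.  The
# shared stack is token embedding -> transformer encoder f() -> mean pool ->
# projection head g(); the NT-Xent loss acts on the projected vectors.

#' Configuration for contrastive pre-training
#'
#' @param embed_dim token/word-vector dimension (default 256).
#' @param encoder_layers number of transformer encoder layers (default 4).
#' @param attention_heads attention heads; must divide `embed_dim`.
#' @param d_ff feed-forward hidden width (default `4 * embed_dim`).
#' @param proj_hidden_dim,proj_out_dim projection-head dimensions
#'   (defaults 256 / 128, the SimCLR convention).
#' @param temperature NT-Xent temperature tau (> 0, default 0.1).
#' @param batch_molecules molecules N per batch; the batch holds 2N views
#'   (default 16).
#' @param max_epochs epoch cap (default 100).
#' @param patience epochs without validation improvement before early stop
#'   (default 10).
#' @param learning_rate AdamW learning rate; a vector triggers a grid search
#'   selecting the rate with the best validation loss.  Default grid spans
#'   \[1e-4, 1e-2\].
#' @param max_len maximum token-sequence length incl. bos/eos.
#' @param weight_decay AdamW decoupled weight decay.
#' @return a validated `contrastive_config` list.
#' @export
contrastive_config <- function(embed_dim = 256L, encoder_layers = 4L,
                               attention_heads = 8L, d_ff = 4L * embed_dim,
                               proj_hidden_dim = 256L, proj_out_dim = 128L,
                               temperature = 0.1, batch_molecules = 16L,
                               max_epochs = 100L, patience = 10L,
                               learning_rate = c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2),
                               max_len = 128L, weight_decay = 0.01) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              encoder_layers = as.integer(encoder_layers),
              attention_heads = as.integer(attention_heads),
              d_ff = as.integer(d_ff),
              proj_hidden_dim = as.integer(proj_hidden_dim),
              proj_out_dim = as.integer(proj_out_dim),
              temperature = temperature,
              batch_molecules = as.integer(batch_molecules),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              learning_rate = learning_rate,
              max_len = as.integer(max_len),
              weight_decay = weight_decay)
  stopifnot(cfg$temperature > 0,
            cfg$embed_dim >= 1, cfg$encoder_layers >= 1,
            cfg$embed_dim %% cfg$attention_heads == 0,
            cfg$patience <= cfg$max_epochs,
            all(cfg$learning_rate > 0))
  class(cfg) <- c("contrastive_config", "list")
  cfg
}

#' Cosine similarity between two vectors
#' @param zi,zj numeric vectors of equal length, non-zero norm.
#' @return value in \[-1, 1\].
#' @export
cosine_similarity <- function(zi, zj) {
  ni <- sqrt(sum(zi^2)); nj <- sqrt(sum(zj^2))
  if (ni == 0 || nj == 0) stop("cosine similarity undefined for a zero vector")
  sum(zi * zj) / (ni * nj)
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' Rows of `Z` are projected views ordered so that rows (2k-1, 2k) are the
#' two views of molecule k.  For each anchor i with partner j the loss term
#' is `-log( exp(sim(zi,zj)/tau) / sum_{k != i} exp(sim(zi,zk)/tau) )`; the
#' returned value is the mean over all 2N anchors.  With N = 1 the
#' denominator holds only the positive, so the loss is exactly 0.
#'
#' @param Z numeric matrix, 2N x d.
#' @param tau temperature (> 0).
#' @return non-negative scalar.
#' @export
nt_xent_loss <- function(Z, tau = 0.1) {
  nt_xent_fwd_bwd(Z, tau, want_grad = FALSE)$loss
}

nt_xent_fwd_bwd <- function(Z, tau, want_grad = TRUE) {
  n2 <- nrow(Z)
  if (is.null(n2) || n2 < 2L || n2 %% 2L != 0L) stop("Z must have 2N rows, N >= 1")
  if (tau <= 0) stop("temperature must be positive")
  norms <- sqrt(rowSums(Z * Z))
  if (any(norms == 0)) stop("zero-norm projection vector")
  A <- Z / norms
  S <- tcrossprod(A) / tau
  diag(S) <- -Inf
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  M <- apply(S, 1, max)
  E <- exp(S - M)
  denom <- rowSums(E)
  logp <- (S - M) - log(denom)
  loss <- -mean(logp[cbind(seq_len(n2), partner)])
  if (!want_grad) return(list(loss = loss))
  P <- E / denom
  dS <- P / n2
  dS[cbind(seq_len(n2), partner)] <- dS[cbind(seq_len(n2), partner)] - 1 / n2
  diag(dS) <- 0
  dA <- ((dS + t(dS)) %*% A) / tau
  dZ <- (dA - A * rowSums(dA * A)) / norms
  list(loss = loss, dZ = dZ)
}

## ---- model pieces -----------------------------------------------------------

contrastive_init <- function(vocab_size, cfg) {
  params <- transformer_init(vocab_size, cfg$embed_dim, cfg$encoder_layers,
                             cfg$d_ff, cfg$max_len)
  params$proj <- list(
    W1 = init_mat(cfg$embed_dim, cfg$proj_hidden_dim),
    b1 = rep(0, cfg$proj_hidden_dim),
    W2 = init_mat(cfg$proj_hidden_dim, cfg$proj_out_dim),
    b2 = rep(0, cfg$proj_out_dim)
  )
  params
}

encoder_params <- function(params) params[setdiff(names(params), "proj")]

proj_fwd <- function(proj, R) {
  H <- add_bias(R %*% proj$W1, proj$b1)
  Hr <- pmax(H, 0)
  list(z = add_bias(Hr %*% proj$W2, proj$b2), H = H, Hr = Hr)
}

proj_bwd <- function(proj, cache, R, dZ) {
  dHr <- dZ %*% t(proj$W2)
  gW2 <- crossprod(cache$Hr, dZ); gb2 <- colSums(dZ)
  dH <- dHr * (cache$H > 0)
  gW1 <- crossprod(R, dH); gb1 <- colSums(dH)
  list(dR = dH %*% t(proj$W1),
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# tokenize, replacing writings that exceed max_len by their canonical form
# (randomized writings of a filtered molecule can be slightly longer)
safe_token_ids <- function(strings, vocab, max_len) {
  lapply(strings, function(s) {
    ids <- c(vocab$bos, vocab_id(vocab, tokenize_smiles_string(s)[[1]]), vocab$eos)
    if (length(ids) > max_len) ids <- ids[c(seq_len(max_len - 1L), length(ids))]
    as.integer(ids)
  })
}

#' Encode views with a contrastive model
#'
#' Runs the token embedding + transformer encoder and mean-pools over
#' non-pad positions: one fixed-length latent vector per input writing.
#' Padding does not influence the output.
#'
#' @param ckpt a contrastive `model_checkpoint` (or a live model list).
#' @param smiles character vector of SMILES writings.
#' @return numeric matrix, one row per input.
#' @export
encode_views <- function(ckpt, smiles) {
  cfg <- ckpt$config
  ids <- safe_token_ids(smiles, ckpt$vocab, cfg$max_len)
  batch <- pad_batch(ids)
  fwd <- transformer_fwd(encoder_params(ckpt$params), batch$ids, batch$mask,
                         cfg$attention_heads, causal = FALSE, keep_cache = FALSE)
  mean_pool(fwd$h, batch$mask)
}

#' Project latent representations into the contrastive space
#' @param ckpt a contrastive `model_checkpoint`.
#' @param R matrix of latent representations (rows).
#' @return matrix of projected vectors z.
#' @export
project <- function(ckpt, R) {
  if (is.null(ckpt$params$proj)) stop("checkpoint has no projection head")
  proj_fwd(ckpt$params$proj, R)$z
}

## ---- training ---------------------------------------------------------------

derive_seed <- function(seed, k) as.integer((as.double(seed) * 7919 + k) %% 2147483629)

contrastive_batch_loss <- function(params, cfg, id_list, want_grad = TRUE) {
  batch <- pad_batch(id_list)
  fwd <- transformer_fwd(encoder_params(params), batch$ids, batch$mask,
                         cfg$attention_heads, causal = FALSE, keep_cache = want_grad)
  R <- mean_pool(fwd$h, batch$mask)
  pf <- proj_fwd(params$proj, R)
  nt <- nt_xent_fwd_bwd(pf$z, cfg$temperature, want_grad = want_grad)
  if (!want_grad) return(list(loss = nt$loss))
  pb <- proj_bwd(params$proj, pf, R, nt$dZ)
  dH <- mean_pool_bwd(pb$dR, batch$mask)
  grads <- transformer_bwd(encoder_params(params), fwd$cache, dH)
  grads$proj <- pb$grads
  list(loss = nt$loss, grads = grads)
}

pairs_to_id_list <- function(x1, x2, vocab, max_len) {
  ids1 <- safe_token_ids(x1, vocab, max_len)
  ids2 <- safe_token_ids(x2, vocab, max_len)
  out <- vector("list", 2L * length(ids1))
  out[seq(1, length(out), 2)] <- ids1
  out[seq(2, length(out), 2)] <- ids2
  out
}

eval_pair_loss <- function(params, cfg, vocab, x1, x2) {
  n <- length(x1)
  N <- cfg$batch_molecules
  starts <- seq(1, n, N)
  losses <- numeric(0); sizes <- integer(0)
  for (s in starts) {
    idx <- s:min(s + N - 1L, n)
    if (length(idx) < 2L) next  # a single molecule contributes zero loss
    ids <- pairs_to_id_list(x1[idx], x2[idx], vocab, cfg$max_len)
    losses <- c(losses, contrastive_batch_loss(params, cfg, ids, want_grad = FALSE)$loss)
    sizes <- c(sizes, length(idx))
  }
  sum(losses * sizes) / sum(sizes)
}

#' Contrastive pre-training over enumerated SMILES views
#'
#' Splits the corpus 19:1 into train/validation, re-enumerates the training
#' view pairs every epoch, minimizes the NT-Xent loss with AdamW, and early
#' stops once the validation loss (on pairs fixed across epochs) has not
#' improved for `patience` epochs, keeping the best checkpoint.  When
#' `config$learning_rate` has several values, each is trained and the rate
#' with the best validation loss wins.
#'
#' @param corpus character vector of valid SMILES or a molecule-record
#'   data.frame from [molecule_records()].
#' @param config a [contrastive_config()].
#' @param seed integer master seed for enumeration, splitting, init and
#'   shuffling.
#' @param log_file optional path receiving the per-epoch training log.
#' @param verbose emit one log line per epoch to stderr.
#' @return a `model_checkpoint` carrying the transferable token embedding.
#' @export
pretrain_contrastive <- function(corpus, config = contrastive_config(),
                                 seed = 0L, log_file = NULL, verbose = TRUE) {
  records <- as_molecule_records(corpus)
  if (nrow(records) == 0) stop("empty corpus")
  if (!all(records$is_valid)) stop("corpus contains invalid SMILES")
  canon <- records$canonical

  # vocabulary must cover randomized writings, not just canonical forms
  vocab_views <- unlist(chem_enumerate(canon, 2L, derive_seed(seed, 1L)))
  vocab <- build_vocab(c(canon, vocab_views))

  splits <- split_dataset(canon, ratios = c(19, 1), seed = derive_seed(seed, 2L))
  train <- splits[[1]]; valid <- splits[[2]]
  if (length(valid) < 2L) stop("corpus too small for a 19:1 train/validation split")

  # validation pairs fixed across epochs for comparable losses
  vpairs <- chem_enumerate(valid, 2L, derive_seed(seed, 3L))
  vx1 <- vapply(vpairs, `[`, character(1), 1L)
  vx2 <- vapply(vpairs, `[`, character(1), 2L)

  run_one <- function(lr, run_id) {
    set.seed(derive_seed(seed, 100L + run_id))
    params <- contrastive_init(vocab$size, config)
    opt <- adamw_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- list()
    for (epoch in seq_len(config$max_epochs)) {
      tpairs <- chem_enumerate(train, 2L, derive_seed(seed, 1000L * run_id + epoch))
      tx1 <- vapply(tpairs, `[`, character(1), 1L)
      tx2 <- vapply(tpairs, `[`, character(1), 2L)
      ord <- sample(length(train))
      N <- config$batch_molecules
      losses <- c()
      for (s in seq(1, length(ord), N)) {
        idx <- ord[s:min(s + N - 1L, length(ord))]
        if (length(idx) < 2L) next
        ids <- pairs_to_id_list(tx1[idx], tx2[idx], vocab, config$max_len)
        bl <- contrastive_batch_loss(params, config, ids)
        if (!is.finite(bl$loss)) stop("non-finite contrastive loss; aborting")
        st <- adamw_step(params, bl$grads, opt, lr,
                         weight_decay = config$weight_decay)
        params <- st$params; opt <- st$opt
        losses <- c(losses, bl$loss)
      }
      vloss <- eval_pair_loss(params, config, vocab, vx1, vx2)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                     val_loss = vloss, lr = lr)
      line <- sprintf("epoch %3d  train %.5f  valid %.5f  lr %g",
                      epoch, mean(losses), vloss, lr)
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
    list(best = best, history = do.call(rbind, history), lr = lr)
  }

  runs <- lapply(seq_along(config$learning_rate), function(i) {
    run_one(config$learning_rate[i], i)
  })
  winner <- runs[[which.min(vapply(runs, function(r) r$best$loss, numeric(1)))]]

  new_checkpoint(
    model_type = "contrastive",
    params = winner$best$params,
    config = config,
    vocab = vocab,
    metadata = list(
      seed = seed,
      epochs_run = max(winner$history$epoch),
      best_epoch = winner$best$epoch,
      best_val_loss = winner$best$loss,
      learning_rate_selected = winner$lr,
      history = winner$history
    )
  )
}

#' Extract the transferable token-embedding table
#'
#' @param ckpt a contrastive `model_checkpoint`.
#' @return list with `embedding` (vocab_size x embed_dim matrix) and `vocab`.
#' @export
extract_embedding <- function(ckpt) {
  if (!inherits(ckpt, "model_checkpoint") || is.null(ckpt$params$tok_emb)) {
    stop("incompatible checkpoint: no token embedding found")
  }
  if (nrow(ckpt$params$tok_emb) != ckpt$vocab$size) {
    stop("incompatible checkpoint: embedding rows != vocabulary size")
  }
  list(embedding = ckpt$params$tok_emb, vocab = ckpt$vocab)
}

## ---- checkpoints ------------------------------------------------------------

new_checkpoint <- function(model_type, params, config, vocab, metadata,
                           extra = list()) {
  metadata$created <- format(Sys.time(), tz = "UTC")
  metadata$package_version <- as.character(utils::packageVersion("molcontrast"))
  structure(
    c(list(model_type = model_type, params = params, config = config,
           vocab = vocab, metadata = metadata), extra),
    class = "model_checkpoint"
  )
}

#' Save / load model checkpoints
#'
#' Single-file container with weights, config echo, vocabulary, seed and the
#' metric history.  A loaded checkpoint re-saves bit-identically.
#'
#' @param ckpt a `model_checkpoint`.
#' @param path destination file.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "model_checkpoint"))
  saveRDS(ckpt, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "model_checkpoint")) stop("not a model checkpoint: ", path)
  ckpt
}

#' @export
print.model_checkpoint <- function(x, ...) {
  cat("<model_checkpoint>", x$model_type, "\n")
  cat("  vocab size:", x$vocab$size, "\n")
  cat("  best val loss:", format(x$metadata$best_val_loss), "at epoch",
      x$metadata$best_epoch %||% NA, "\n")
  invisible(x)
}
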