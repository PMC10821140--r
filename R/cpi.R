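# Dual-encoder compound-protein interaction classifier: one transformer
# encoder over the molecule SMILES, one over the amino-acid sequence,
# mean-pooled outputs concatenated and mapped linearly to two logits.

#' Protein token vocabulary (one token per amino-acid letter)
#' @return a `token_vocabulary` over the 20-letter alphabet.
#' @export
protein_vocab <- function() {
  structure(
    list(tokens = c("<pad>", "<bos>", "<eos>", "<unk>", .aa_alphabet),
         pad = 0L, bos = 1L, eos = 2L, unk = 3L,
         size = 4L + length(.aa_alphabet)),
    class = "token_vocabulary"
  )
}

tokenize_protein_string <- function(seqs) strsplit(as.character(seqs), "")

protein_token_ids <- function(seqs, vocab, max_len) {
  lapply(tokenize_protein_string(seqs), function(tk) {
    ids <- c(vocab$bos, vocab_id(vocab, tk), vocab$eos)
    if (length(ids) > max_len) ids <- ids[c(seq_len(max_len - 1L), length(ids))]
    as.integer(ids)
  })
}

#' Configuration for the CPI classifier
#'
#' One shared hyperparameter block for both (independent) encoders.
#'
#' @param n_layers encoder layers per encoder.
#' @param d_model encoder width (default 256).
#' @param d_ff feed-forward width.
#' @param attention_heads heads; must divide `d_model`.
#' @param max_len maximum SMILES token length.
#' @param protein_max_len maximum protein token length; longer sequences are
#'   truncated (default 1000).
#' @param dropout residual-branch dropout during training.
#' @param learning_rate,batch_size,max_epochs,patience,weight_decay training
#'   protocol; batch size defaults to 128.
#' @export
cpi_config <- function(n_layers = 4L, d_model = 256L, d_ff = 4L * d_model,
                       attention_heads = 8L, max_len = 128L,
                       protein_max_len = 1000L, dropout = 0,
                       learning_rate = 1e-3, batch_size = 128L,
                       max_epochs = 100L, patience = 10L, weight_decay = 0.01) {
  cfg <- list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
              d_ff = as.integer(d_ff), attention_heads = as.integer(attention_heads),
              max_len = as.integer(max_len),
              protein_max_len = as.integer(protein_max_len), dropout = dropout,
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              weight_decay = weight_decay)
  stopifnot(cfg$d_model %% cfg$attention_heads == 0, cfg$n_layers >= 1,
            cfg$patience <= cfg$max_epochs, cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- c("cpi_config", "list")
  cfg
}

cpi_init <- function(mol_vocab_size, prot_vocab_size, cfg) {
  list(
    mol = transformer_init(mol_vocab_size, cfg$d_model, cfg$n_layers, cfg$d_ff, cfg$max_len),
    prot = transformer_init(prot_vocab_size, cfg$d_model, cfg$n_layers, cfg$d_ff,
                            cfg$protein_max_len),
    cls_W = init_mat(2L * cfg$d_model, 2L),
    cls_b = rep(0, 2L)
  )
}

cpi_encode_batch <- function(params, cfg, id_list, want_grad, dropout = 0) {
  batch <- pad_batch(id_list)
  fwd <- transformer_fwd(params, batch$ids, batch$mask, cfg$attention_heads,
                         causal = FALSE, keep_cache = want_grad,
                         dropout = dropout, training = want_grad)
  list(pooled = mean_pool(fwd$h, batch$mask), fwd = fwd, batch = batch)
}

cpi_batch <- function(params, cfg, mol_ids, prot_ids, labels, want_grad = TRUE) {
  em <- cpi_encode_batch(params$mol, cfg, mol_ids, want_grad, cfg$dropout)
  ep <- cpi_encode_batch(params$prot, cfg, prot_ids, want_grad, cfg$dropout)
  X <- cbind(em$pooled, ep$pooled)
  logits <- add_bias(X %*% params$cls_W, params$cls_b)
  if (is.null(labels)) return(list(logits = logits))
  sx <- softmax_xent(logits, as.integer(labels))
  if (!want_grad) return(list(loss = sx$loss, logits = logits))
  dX <- sx$dlogits %*% t(params$cls_W)
  d <- cfg$d_model
  dm <- mean_pool_bwd(dX[, seq_len(d), drop = FALSE], em$batch$mask)
  dp <- mean_pool_bwd(dX[, d + seq_len(d), drop = FALSE], ep$batch$mask)
  grads <- list(
    mol = transformer_bwd(params$mol, em$fwd$cache, dm),
    prot = transformer_bwd(params$prot, ep$fwd$cache, dp),
    cls_W = crossprod(X, sx$dlogits),
    cls_b = colSums(sx$dlogits)
  )
  list(loss = sx$loss, logits = logits, grads = grads)
}

#' Interaction logits for a batch of CPI records
#'
#' Both encoders pool over non-pad positions only, so padding never changes
#' the output; inference is deterministic.
#'
#' @param ckpt a CPI `model_checkpoint`.
#' @param dataset data.frame with `smiles` and `sequence` columns.
#' @return numeric matrix, one row of 2 logits per record.
#' @export
cpi_forward <- function(ckpt, dataset) {
  cfg <- ckpt$config
  out <- matrix(0, nrow(dataset), 2L)
  for (s in seq(1, nrow(dataset), cfg$batch_size)) {
    idx <- s:min(s + cfg$batch_size - 1L, nrow(dataset))
    mol_ids <- safe_token_ids(dataset$smiles[idx], ckpt$vocab, cfg$max_len)
    prot_ids <- protein_token_ids(dataset$sequence[idx], ckpt$protein_vocab,
                                  cfg$protein_max_len)
    out[idx, ] <- cpi_batch(ckpt$params, cfg, mol_ids, prot_ids, NULL,
                            want_grad = FALSE)$logits
  }
  out
}

#' Train the dual-encoder CPI classifier
#'
#' Splits the dataset 8:1:1 (train/validation/test), minimizes binary
#' cross-entropy with AdamW and early stopping on validation loss, and
#' caches test-set predictions in the returned checkpoint.  A contrastive
#' checkpoint can seed the molecule encoder's token embedding (frozen or
#' not); the protein encoder is never touched by the transfer.
#'
#' @param dataset data.frame with `smiles`, `sequence`, `label`.
#' @param config a [cpi_config()].
#' @param embedding optional `list(ckpt = <contrastive checkpoint>, freeze =
#'   TRUE/FALSE)`.
#' @param seed integer master seed.
#' @param log_file optional log path.
#' @param verbose emit per-epoch log lines.
#' @return a CPI `model_checkpoint`.
#' @export
train_cpi <- function(dataset, config = cpi_config(), embedding = NULL,
                      seed = 0L, log_file = NULL, verbose = TRUE) {
  stopifnot(all(c("smiles", "sequence", "label") %in% names(dataset)))
  if (!all(dataset$label %in% c(0L, 1L))) stop("labels must be 0/1")

  if (!is.null(embedding)) {
    stopifnot(inherits(embedding$ckpt, "model_checkpoint"))
    mol_vocab <- embedding$ckpt$vocab
  } else {
    mol_vocab <- build_vocab(dataset$smiles)
  }
  prot_vocab <- protein_vocab()

  splits <- split_dataset(dataset, ratios = c(8, 1, 1), seed = derive_seed(seed, 2L))
  dtrain <- splits[[1]]; dvalid <- splits[[2]]; dtest <- splits[[3]]
  if (nrow(dvalid) < 1L || nrow(dtest) < 1L) stop("dataset too small for an 8:1:1 split")

  set.seed(derive_seed(seed, 103L))
  params <- cpi_init(mol_vocab$size, prot_vocab$size, config)
  frozen_emb <- NULL
  if (!is.null(embedding)) {
    model <- load_pretrained_embedding(
      list(params = params$mol, vocab = mol_vocab), embedding$ckpt,
      isTRUE(embedding$freeze))
    params$mol <- model$params
    if (model$frozen_embedding) frozen_emb <- params$mol$tok_emb
  }
  opt <- adamw_init(params)

  tok_cache <- function(d) list(
    mol = safe_token_ids(d$smiles, mol_vocab, config$max_len),
    prot = protein_token_ids(d$sequence, prot_vocab, config$protein_max_len)
  )
  ttrain <- tok_cache(dtrain); tvalid <- tok_cache(dvalid)

  eval_split <- function(d, toks) {
    tot <- 0; n <- nrow(d)
    for (s in seq(1, n, config$batch_size)) {
      idx <- s:min(s + config$batch_size - 1L, n)
      bl <- cpi_batch(params, config, toks$mol[idx], toks$prot[idx],
                      d$label[idx], want_grad = FALSE)
      tot <- tot + bl$loss * length(idx)
    }
    tot / n
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(nrow(dtrain))
    losses <- c()
    for (s in seq(1, length(ord), config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      bl <- cpi_batch(params, config, ttrain$mol[idx], ttrain$prot[idx],
                      dtrain$label[idx])
      if (!is.finite(bl$loss)) stop("non-finite training loss; aborting")
      st <- adamw_step(params, bl$grads, opt, config$learning_rate,
                       weight_decay = config$weight_decay)
      params <- st$params; opt <- st$opt
      if (!is.null(frozen_emb)) params$mol$tok_emb <- frozen_emb
      losses <- c(losses, bl$loss)
    }
    vloss <- eval_split(dvalid, tvalid)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_loss = vloss, lr = config$learning_rate)
    line <- sprintf("epoch %3d  train %.5f  valid %.5f", epoch, mean(losses), vloss)
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

  ckpt <- new_checkpoint(
    model_type = "cpi",
    params = best$params,
    config = config,
    vocab = mol_vocab,
    metadata = list(seed = seed, epochs_run = length(history),
                    best_epoch = best$epoch, best_val_loss = best$loss,
                    frozen_embedding = !is.null(frozen_emb),
                    history = do.call(rbind, history)),
    extra = list(protein_vocab = prot_vocab)
  )
  preds <- max.col(cpi_forward(ckpt, dtest)) - 1L
  ckpt$metadata$test_predictions <- preds
  ckpt$metadata$test_labels <- dtest$label
  ckpt$metadata$test_metrics <- confusion_metrics(preds, dtest$label)
  ckpt
}

confusion_metrics <- function(pred, label) {
  classification_metrics(
    tp = sum(pred == 1 & label == 1),
    fp = sum(pred == 1 & label == 0),
    fn = sum(pred == 0 & label == 1),
    tn = sum(pred == 0 & label == 0)
  )
}

#' Evaluate a CPI classifier on a labeled dataset
#'
#' Argmax decision over the two logits, then precision/recall/F1 through
#' [classification_metrics()].
#'
#' @param ckpt a CPI `model_checkpoint`.
#' @param dataset labeled CPI data.frame.
#' @return a `classification_metrics` object.
#' @export
evaluate_cpi <- function(ckpt, dataset) {
  if (nrow(dataset) == 0) stop("empty dataset")
  preds <- max.col(cpi_forward(ckpt, dataset)) - 1L
  confusion_metrics(preds, dataset$label)
}
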