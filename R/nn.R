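# Native transformer stack with hand-derived backpropagation.
#
# There is no deep-learning runtime in the supported stack, so the encoder /
# decoder used by the contrastive, generation and CPI modules is implemented
# directly on matrices.  Activations for a batch of B sequences of padded
# length L live in a (B*L) x d matrix, batch-major (rows 1..L belong to
# sequence 1).  Token ids are 0-based everywhere (pad=0); +1 when indexing R
# matrices.  All gradients are checked against central finite differences in
# the test suite.

#' Gaussian error linear unit
#'
#' Exact form `x * pnorm(x)`: the input gated by the probability that a
#' standard normal variable is below it.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# gradient reusing Phi(x) already computed in the forward pass
gelu_grad_phi <- function(x, phi) phi + x * (0.3989422804014327 * exp(-0.5 * x * x))

add_bias <- function(M, b) M + rep(b, each = nrow(M))

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE), b),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * matrix(g, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

## ---- parameter initialisation ---------------------------------------------

init_mat <- function(nr, nc, scale = 0.02) matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)

transformer_block_init <- function(d_model, d_ff, scale = 0.02) {
  list(
    ln1_g = rep(1, d_model), ln1_b = rep(0, d_model),
    Wq = init_mat(d_model, d_model, scale), bq = rep(0, d_model),
    Wk = init_mat(d_model, d_model, scale), bk = rep(0, d_model),
    Wv = init_mat(d_model, d_model, scale), bv = rep(0, d_model),
    Wo = init_mat(d_model, d_model, scale), bo = rep(0, d_model),
    ln2_g = rep(1, d_model), ln2_b = rep(0, d_model),
    W1 = init_mat(d_model, d_ff, scale), b1 = rep(0, d_ff),
    W2 = init_mat(d_ff, d_model, scale), b2 = rep(0, d_model)
  )
}

transformer_init <- function(vocab_size, d_model, n_layers, d_ff, max_len, scale = 0.02) {
  list(
    tok_emb = init_mat(vocab_size, d_model, scale),
    pos_emb = init_mat(max_len, d_model, scale),
    blocks = lapply(seq_len(n_layers), function(i) transformer_block_init(d_model, d_ff, scale)),
    lnf_g = rep(1, d_model), lnf_b = rep(0, d_model)
  )
}

## ---- forward ----------------------------------------------------------------

# ids: B x L 0-based id matrix; mask: B x L logical (TRUE = real token)
transformer_fwd <- function(params, ids, mask, n_heads, causal,
                            keep_cache = TRUE, dropout = 0, training = FALSE) {
  use_drop <- training && dropout > 0
  B <- nrow(ids); L <- ncol(ids)
  d <- ncol(params$tok_emb)
  dh <- d %/% n_heads
  stopifnot(dh * n_heads == d, L <= nrow(params$pos_emb))

  flat_ids <- as.vector(t(ids)) + 1L                 # batch-major
  X <- params$tok_emb[flat_ids, , drop = FALSE] +
    params$pos_emb[rep(seq_len(L), B), , drop = FALSE]

  scale <- 1 / sqrt(dh)
  neg <- -1e30
  key_mask <- t(mask)                                # L x B, TRUE = usable key
  caches <- vector("list", length(params$blocks))

  for (li in seq_along(params$blocks)) {
    blk <- params$blocks[[li]]
    ln1 <- layernorm_fwd(X, blk$ln1_g, blk$ln1_b)
    Xn <- ln1$y
    Q <- add_bias(Xn %*% blk$Wq, blk$bq)
    K <- add_bias(Xn %*% blk$Wk, blk$bk)
    V <- add_bias(Xn %*% blk$Wv, blk$bv)
    O <- matrix(0, B * L, d)
    A_arr <- if (keep_cache) array(0, c(L, L, n_heads, B)) else NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      kmask <- key_mask[, b]
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scale
        S[, !kmask] <- neg
        if (causal) S[upper.tri(S)] <- neg
        A <- softmax_rows(S)
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        if (keep_cache) A_arr[, , h, b] <- A
      }
    }
    attn <- add_bias(O %*% blk$Wo, blk$bo)
    D1 <- if (use_drop) matrix(stats::rbinom(length(attn), 1, 1 - dropout) / (1 - dropout),
                               nrow(attn), ncol(attn)) else NULL
    if (use_drop) attn <- attn * D1
    X2 <- X + attn
    ln2 <- layernorm_fwd(X2, blk$ln2_g, blk$ln2_b)
    H1 <- add_bias(ln2$y %*% blk$W1, blk$b1)
    PH <- stats::pnorm(H1)
    G <- H1 * PH
    ffo <- add_bias(G %*% blk$W2, blk$b2)
    D2 <- if (use_drop) matrix(stats::rbinom(length(ffo), 1, 1 - dropout) / (1 - dropout),
                               nrow(ffo), ncol(ffo)) else NULL
    if (use_drop) ffo <- ffo * D2
    X3 <- X2 + ffo
    if (keep_cache) {
      caches[[li]] <- list(ln1 = ln1, Xn = Xn, Q = Q, K = K, V = V, A = A_arr,
                           O = O, ln2 = ln2, H1 = H1, PH = PH, G = G,
                           D1 = D1, D2 = D2)
    }
    X <- X3
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  list(h = lnf$y,
       cache = if (keep_cache) {
         list(blocks = caches, lnf = lnf, flat_ids = flat_ids,
              B = B, L = L, n_heads = n_heads, causal = causal, mask = mask)
       } else NULL)
}

## ---- backward ---------------------------------------------------------------

transformer_bwd <- function(params, cache, dh_out) {
  B <- cache$B; L <- cache$L
  n_heads <- cache$n_heads
  d <- ncol(params$tok_emb)
  dhh <- d %/% n_heads
  scale <- 1 / sqrt(dhh)

  grads <- list(blocks = vector("list", length(params$blocks)))
  lb <- layernorm_bwd(dh_out, cache$lnf, params$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dX <- lb$dx

  for (li in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[li]]
    cc <- cache$blocks[[li]]
    # feed-forward
    dFF <- dX                                        # grad at X3, residual
    if (!is.null(cc$D2)) dFF <- dFF * cc$D2
    dG <- dFF %*% t(blk$W2)
    gW2 <- crossprod(cc$G, dFF); gb2 <- colSums(dFF)
    dH1 <- dG * gelu_grad_phi(cc$H1, cc$PH)
    gW1 <- crossprod(cc$ln2$y, dH1); gb1 <- colSums(dH1)
    dXn2 <- dH1 %*% t(blk$W1)
    lb2 <- layernorm_bwd(dXn2, cc$ln2, blk$ln2_g)
    dX2 <- dX + lb2$dx
    # attention
    dAttn <- dX2
    if (!is.null(cc$D1)) dAttn <- dAttn * cc$D1
    dO <- dAttn %*% t(blk$Wo)
    gWo <- crossprod(cc$O, dAttn); gbo <- colSums(dAttn)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dhh + 1L):(h * dhh)
        A <- cc$A[, , h, b]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        dV[rows, cols] <- crossprod(A, dOh)
        dA <- tcrossprod(dOh, Vh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] * scale
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    Xn <- cc$Xn
    gWq <- crossprod(Xn, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(Xn, dK); gbk <- colSums(dK)
    gWv <- crossprod(Xn, dV); gbv <- colSums(dV)
    dXn <- dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
    lb1 <- layernorm_bwd(dXn, cc$ln1, blk$ln1_g)
    dX <- dX2 + lb1$dx
    grads$blocks[[li]] <- list(
      ln1_g = lb1$dg, ln1_b = lb1$db,
      Wq = gWq, bq = gbq, Wk = gWk, bk = gbk, Wv = gWv, bv = gbv,
      Wo = gWo, bo = gbo,
      ln2_g = lb2$dg, ln2_b = lb2$db,
      W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2
    )
  }
  # embeddings
  gtok <- matrix(0, nrow(params$tok_emb), d)
  sums <- rowsum(dX, group = cache$flat_ids)
  gtok[as.integer(rownames(sums)), ] <- sums
  gpos <- matrix(0, nrow(params$pos_emb), d)
  psum <- rowsum(dX, group = rep(seq_len(L), B))
  gpos[as.integer(rownames(psum)), ] <- psum
  grads$tok_emb <- gtok
  grads$pos_emb <- gpos
  grads
}

## ---- pooling / heads --------------------------------------------------------

# mean over non-pad positions -> B x d
mean_pool <- function(H, mask) {
  B <- nrow(mask); L <- ncol(mask)
  W <- as.vector(t(mask)) * 1
  counts <- rowSums(mask)
  pooled <- rowsum(H * W, group = rep(seq_len(B), each = L)) / counts
  dimnames(pooled) <- NULL
  pooled
}

mean_pool_bwd <- function(dpooled, mask) {
  B <- nrow(mask); L <- ncol(mask)
  counts <- rowSums(mask)
  dH <- dpooled[rep(seq_len(B), each = L), , drop = FALSE] / counts[rep(seq_len(B), each = L)]
  dH * as.vector(t(mask))
}

# combined softmax + cross-entropy; targets 0-based, weights >= 0
softmax_xent <- function(logits, targets, weights = NULL) {
  n <- nrow(logits)
  if (is.null(weights)) weights <- rep(1, n)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(n), targets + 1L)
  wsum <- sum(weights)
  loss <- sum(weights * -log(pmax(P[idx], 1e-30))) / wsum
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (weights / wsum)
  list(loss = loss, dlogits = dlogits, probs = P)
}

## ---- AdamW ------------------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

# recurse by name where both sides are named: gradient lists are not
# guaranteed to share the parameter list's element order
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    by_name <- !is.null(names(a)) && !is.null(names(b)) && all(nzchar(names(a)))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

adamw_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

# frozen: character vector of top-level parameter names excluded from updates
adamw_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01, frozen = character(0)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    opt$m[[nm]] <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                             opt$m[[nm]], grads[[nm]])
    opt$v[[nm]] <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                             opt$v[[nm]], grads[[nm]])
    step_fun <- function(p, mv) {
      m_hat <- mv$m / bc1
      v_hat <- mv$v / bc2
      # decoupled decay on weight matrices only (not biases/layer norms)
      wd <- if (is.matrix(p)) weight_decay else 0
      p - lr * (m_hat / (sqrt(v_hat) + eps) + wd * p)
    }
    params[[nm]] <- upd_rec(params[[nm]], opt$m[[nm]], opt$v[[nm]], step_fun)
  }
  list(params = params, opt = opt)
}

upd_rec <- function(p, m, v, step_fun) {
  if (is.list(p)) {
    for (i in seq_along(p)) p[[i]] <- upd_rec(p[[i]], m[[i]], v[[i]], step_fun)
    p
  } else {
    step_fun(p, list(m = m, v = v))
  }
}

## ---- batching helpers -------------------------------------------------------

# pad a list of 0-based id vectors to a B x L matrix + mask
pad_batch <- function(id_list, pad_id = 0L) {
  L <- max(vapply(id_list, length, integer(1)))
  B <- length(id_list)
  ids <- matrix(pad_id, B, L)
  mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    n <- length(id_list[[b]])
    ids[b, seq_len(n)] <- id_list[[b]]
    mask[b, seq_len(n)] <- TRUE
  }
  list(ids = ids, mask = mask)
}
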