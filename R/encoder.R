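## A small BERT-style masked-language-model encoder, written directly in R
## (token + position embeddings, multi-head self-attention, GELU FFN,
## post-layer-norm), with hand-derived backprop. Small enough to pretrain
## on a repertoire on one CPU; the contrastive projection fine-tunes it.

SPECIAL_TOKENS <- c("<pad>", "<mask>", "<cls>", "<sep>", "<unk>", "-")

build_vocab <- function(alphabet) {
  chars <- switch(alphabet,
                  amino_acid = AA_CHARS,
                  nucleotide = c(NT_CHARS, "N"),
                  stop("unknown alphabet: ", alphabet))
  setNames(seq_along(c(SPECIAL_TOKENS, chars)), c(SPECIAL_TOKENS, chars))
}

#' Configuration for the sequence encoder
#'
#' @param embed_dim model/embedding width (the pooled sequence embedding
#'   has this length; 256 for production maps, 32-64 is plenty for small
#'   repertoires and tests).
#' @param n_layers transformer blocks.
#' @param n_heads attention heads (`embed_dim` must be divisible).
#' @param hidden_dim FFN width.
#' @param mask_rate fraction of positions masked for the MLM objective.
#' @param max_len maximal tokenized sequence length.
#' @param alphabet `"amino_acid"` or `"nucleotide"`.
#' @param pooling `"mean"` over non-pad token states (default) or
#'   `"cls"`.
#' @param seed RNG seed for initialization/pretraining.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(embed_dim = 64L, n_layers = 2L, n_heads = 4L,
                           hidden_dim = 128L, mask_rate = 0.15,
                           max_len = 512L,
                           alphabet = c("amino_acid", "nucleotide"),
                           pooling = c("mean", "cls"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  pooling <- match.arg(pooling)
  stopifnot(embed_dim >= 2L, embed_dim %% n_heads == 0L,
            mask_rate > 0, mask_rate < 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 mask_rate = mask_rate, max_len = as.integer(max_len),
                 alphabet = alphabet, pooling = pooling,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

## ---- tokenizer ----------------------------------------------------------

tokenize_batch <- function(seqs, vocab, max_len, pooling = "mean",
                           strict = FALSE) {
  pieces <- strsplit(toupper(seqs), "")
  use_cls <- pooling == "cls"
  Lmax <- max(nchar(seqs)) + as.integer(use_cls)
  if (Lmax > max_len) {
    offenders <- which(nchar(seqs) + as.integer(use_cls) > max_len)
    stop("sequence(s) longer than max_len=", max_len, ": indices ",
         paste(head(offenders, 5L), collapse = ", "))
  }
  toks <- matrix(vocab[["<pad>"]], length(seqs), Lmax)
  unk_seen <- FALSE
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    p[p == "|"] <- "<sep>"
    ids <- vocab[p]
    if (anyNA(ids)) {
      if (strict) stop("out-of-vocabulary character(s) in sequence ", i)
      unk_seen <- TRUE
      ids[is.na(ids)] <- vocab[["<unk>"]]
    }
    if (use_cls) ids <- c(vocab[["<cls>"]], ids)
    if (length(ids)) toks[i, seq_along(ids)] <- ids
  }
  if (unk_seen) warning("out-of-vocabulary characters mapped to <unk>")
  toks
}

## ---- parameters ---------------------------------------------------------

init_encoder_params <- function(config, vocab) {
  set.seed(config$seed)
  d <- config$embed_dim
  h <- config$hidden_dim
  V <- length(vocab)
  rnd <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() list(
    Wq = rnd(d, d), bq = numeric(d), Wk = rnd(d, d), bk = numeric(d),
    Wv = rnd(d, d), bv = numeric(d), Wo = rnd(d, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = rnd(d, h), b1 = numeric(h), W2 = rnd(h, d), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d))
  list(tok = rnd(V, d), pos = rnd(config$max_len, d),
       layers = replicate(config$n_layers, layer(), simplify = FALSE),
       out_W = rnd(d, V), out_b = numeric(V))
}

## ---- layer norm ---------------------------------------------------------

ln_forward <- function(y, g, b, eps = 1e-5) {
  mu <- rowMeans(y)
  yc <- y - mu
  inv <- 1 / sqrt(rowMeans(yc * yc) + eps)
  xhat <- yc * inv
  out <- add_bias(xhat * rep(g, each = nrow(y)), b)
  list(out = out, xhat = xhat, inv = inv)
}

ln_backward <- function(dout, cache, g) {
  dxhat <- dout * rep(g, each = nrow(dout))
  dg <- colSums(dout * cache$xhat)
  db <- colSums(dout)
  dy <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dy = dy, dg = dg, db = db)
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

## X + row-vector bias without sweep()'s overhead
add_bias <- function(X, b) X + rep(b, each = nrow(X))

## ---- transformer forward / backward -------------------------------------

## tokens: B x L integer matrix. Returns final hidden states H (B*L x d,
## rows in sequence-major order) plus everything backprop needs.
enc_forward <- function(params, tokens, config, want_cache = FALSE) {
  B <- nrow(tokens)
  L <- ncol(tokens)
  d <- config$embed_dim
  H <- config$n_heads
  dh <- d %/% H
  tokvec <- as.vector(t(tokens))
  real <- tokvec != 1L  # <pad> is id 1
  X <- params$tok[tokvec, , drop = FALSE] +
    params$pos[rep.int(seq_len(L), B), , drop = FALSE]
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  realm <- matrix(real, B, L, byrow = TRUE)
  caches <- vector("list", length(params$layers))

  for (li in seq_along(params$layers)) {
    p <- params$layers[[li]]
    Q <- add_bias(X %*% p$Wq, p$bq)
    K <- add_bias(X %*% p$Wk, p$bk)
    Vv <- add_bias(X %*% p$Wv, p$bv)
    O <- matrix(0, nrow(X), d)
    A_list <- if (want_cache) vector("list", B * H) else NULL
    scale <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rws <- rows_of(b)
      rl <- realm[b, ]
      for (hh in seq_len(H)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        S <- (Q[rws, cols, drop = FALSE] %*%
                t(K[rws, cols, drop = FALSE])) * scale
        if (!all(rl)) S[, !rl] <- -Inf
        ## row-max stabilization (max.col is C-level, unlike apply)
        S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
        E <- exp(S)
        A <- E / rowSums(E)
        O[rws, cols] <- A %*% Vv[rws, cols, drop = FALSE]
        if (want_cache) A_list[[(b - 1L) * H + hh]] <- A
      }
    }
    attn <- add_bias(O %*% p$Wo, p$bo)
    ln1 <- ln_forward(X + attn, p$ln1_g, p$ln1_b)
    X1 <- ln1$out
    Hpre <- add_bias(X1 %*% p$W1, p$b1)
    Phi <- pnorm(Hpre)
    Hact <- Hpre * Phi
    FF <- add_bias(Hact %*% p$W2, p$b2)
    ln2 <- ln_forward(X1 + FF, p$ln2_g, p$ln2_b)
    if (want_cache) {
      caches[[li]] <- list(X = X, Q = Q, K = K, V = Vv, A = A_list, O = O,
                           ln1 = ln1, X1 = X1, Hpre = Hpre, Phi = Phi,
                           Hact = Hact, ln2 = ln2)
    }
    X <- ln2$out
  }
  list(H = X, caches = caches, tokens = tokens, tokvec = tokvec,
       real = real, realm = realm, B = B, L = L)
}

## dH: gradient on the final hidden states (B*L x d).
enc_backward <- function(params, fw, dH, config) {
  B <- fw$B
  L <- fw$L
  d <- config$embed_dim
  H <- config$n_heads
  dh <- d %/% H
  scale <- 1 / sqrt(dh)
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  gl <- vector("list", length(params$layers))
  dX <- dH

  for (li in rev(seq_along(params$layers))) {
    p <- params$layers[[li]]
    cc <- fw$caches[[li]]
    bk2 <- ln_backward(dX, cc$ln2, p$ln2_g)
    dZ <- bk2$dy                       # grad on X1 + FF
    dFF <- dZ
    dHact <- dFF %*% t(p$W2)
    dW2 <- t(cc$Hact) %*% dFF
    db2 <- colSums(dFF)
    dHpre <- dHact * (cc$Phi + cc$Hpre * dnorm(cc$Hpre))
    dW1 <- t(cc$X1) %*% dHpre
    db1 <- colSums(dHpre)
    dX1 <- dZ + dHpre %*% t(p$W1)
    bk1 <- ln_backward(dX1, cc$ln1, p$ln1_g)
    dY <- bk1$dy                       # grad on X + attn
    dAttnOut <- dY
    dO <- dAttnOut %*% t(p$Wo)
    dWo <- t(cc$O) %*% dAttnOut
    dbo <- colSums(dAttnOut)

    dQ <- matrix(0, nrow(dX), d)
    dK <- matrix(0, nrow(dX), d)
    dV <- matrix(0, nrow(dX), d)
    for (b in seq_len(B)) {
      rws <- rows_of(b)
      for (hh in seq_len(H)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        A <- cc$A[[(b - 1L) * H + hh]]
        dOb <- dO[rws, cols, drop = FALSE]
        Vb <- cc$V[rws, cols, drop = FALSE]
        dA <- dOb %*% t(Vb)
        dV[rws, cols] <- dV[rws, cols] + t(A) %*% dOb
        dS <- A * (dA - rowSums(dA * A))
        dQ[rws, cols] <- dQ[rws, cols] +
          (dS %*% cc$K[rws, cols, drop = FALSE]) * scale
        dK[rws, cols] <- dK[rws, cols] +
          (t(dS) %*% cc$Q[rws, cols, drop = FALSE]) * scale
      }
    }
    X <- cc$X
    gl[[li]] <- list(
      Wq = t(X) %*% dQ, bq = colSums(dQ),
      Wk = t(X) %*% dK, bk = colSums(dK),
      Wv = t(X) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln1_g = bk1$dg, ln1_b = bk1$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
      ln2_g = bk2$dg, ln2_b = bk2$db)
    dX <- dY + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }

  ## embeddings: scatter-add by token id / position
  dtok <- matrix(0, nrow(params$tok), d)
  agg <- rowsum(dX, group = fw$tokvec)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, nrow(params$pos), d)
  aggp <- rowsum(dX, group = rep.int(seq_len(L), B))
  dpos[as.integer(rownames(aggp)), ] <- aggp

  list(tok = dtok, pos = dpos, layers = gl,
       out_W = matrix(0, nrow(params$out_W), ncol(params$out_W)),
       out_b = numeric(length(params$out_b)))
}

## mean-pool (or CLS-pool) final states into one embedding per sequence
pool_forward <- function(fw, pooling = "mean") {
  if (pooling == "cls") {
    idx <- (seq_len(fw$B) - 1L) * fw$L + 1L
    return(fw$H[idx, , drop = FALSE])
  }
  w <- as.numeric(fw$real)
  sums <- rowsum(fw$H * w, group = rep(seq_len(fw$B), each = fw$L))
  sums / rowSums(fw$realm)
}

pool_backward <- function(fw, dE, pooling = "mean") {
  dH <- matrix(0, fw$B * fw$L, ncol(dE))
  if (pooling == "cls") {
    idx <- (seq_len(fw$B) - 1L) * fw$L + 1L
    dH[idx, ] <- dE
    return(dH)
  }
  nreal <- rowSums(fw$realm)
  per_row <- dE[rep(seq_len(fw$B), each = fw$L), , drop = FALSE] /
    nreal[rep(seq_len(fw$B), each = fw$L)]
  dH[fw$real, ] <- per_row[fw$real, , drop = FALSE]
  dH
}

## ---- MLM pretraining -----------------------------------------------------

apply_mlm_mask <- function(tokens, vocab, mask_rate) {
  B <- nrow(tokens)
  L <- ncol(tokens)
  real <- which(tokens != vocab[["<pad>"]] & tokens != vocab[["<cls>"]] &
                  tokens != vocab[["<sep>"]])
  n_mask <- max(1L, round(mask_rate * length(real)))
  sel <- resample(real, n_mask)
  targets <- tokens[sel]
  u <- runif(n_mask)
  masked <- tokens
  residue_ids <- setdiff(seq_along(vocab), seq_along(SPECIAL_TOKENS))
  masked[sel[u < 0.8]] <- vocab[["<mask>"]]
  rnd_sel <- sel[u >= 0.8 & u < 0.9]
  if (length(rnd_sel)) {
    masked[rnd_sel] <- resample(residue_ids, length(rnd_sel),
                                replace = TRUE)
  }
  list(tokens = masked, positions = sel, targets = targets)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## cross-entropy over masked positions; returns loss and dH contribution
mlm_loss <- function(params, fw, mask, config, with_grad = TRUE) {
  ## mask$positions index into the B x L token matrix (column-major);
  ## convert to rows of H (sequence-major)
  B <- fw$B
  L <- fw$L
  bidx <- ((mask$positions - 1L) %% B) + 1L
  lidx <- ((mask$positions - 1L) %/% B) + 1L
  rows <- (bidx - 1L) * L + lidx
  Hm <- fw$H[rows, , drop = FALSE]
  logits <- add_bias(Hm %*% params$out_W, params$out_b)
  P <- softmax_rows(logits)
  n <- length(rows)
  ll <- -mean(log(pmax(P[cbind(seq_len(n), mask$targets)], 1e-12)))
  if (!with_grad) return(list(loss = ll))
  dlogits <- P
  dlogits[cbind(seq_len(n), mask$targets)] <-
    dlogits[cbind(seq_len(n), mask$targets)] - 1
  dlogits <- dlogits / n
  dH <- matrix(0, B * L, config$embed_dim)
  dH[rows, ] <- dlogits %*% t(params$out_W)
  list(loss = ll, dH = dH,
       d_out_W = t(Hm) %*% dlogits, d_out_b = colSums(dlogits))
}

#' Pretrain the masked-language-model encoder on a repertoire
#'
#' Masks `mask_rate` of residue positions (80% to `<mask>`, 10% to a random
#' residue, 10% kept) and trains the transformer to reconstruct them with
#' Adam. A held-out split monitors the reconstruction loss, which must
#' decrease relative to initialization for training to be considered sane.
#'
#' @param table a [seq_table()] (all sequences; batches pad to equal
#'   length).
#' @param config an [encoder_config()].
#' @param epochs training epochs.
#' @param batch_size sequences per step.
#' @param lr Adam learning rate.
#' @param holdout_frac fraction of sequences held out for monitoring.
#' @param verbose log per-epoch losses.
#' @return A `seq_encoder`: list with `config`, `vocab`, `params`, and a
#'   `history` data.frame of held-out losses (row 0 = initialization).
#' @export
pretrain_mlm <- function(table, config = encoder_config(), epochs = 10L,
                         batch_size = 64L, lr = 1e-3, holdout_frac = 0.1,
                         verbose = FALSE) {
  stopifnot(inherits(table, "seq_table"), nrow(table) >= 1L)
  if (attr(table, "alphabet") != config$alphabet) {
    config$alphabet <- attr(table, "alphabet")
  }
  vocab <- build_vocab(config$alphabet)
  seqs <- full_sequences(table)
  set.seed(config$seed)
  params <- init_encoder_params(config, vocab)
  n <- length(seqs)
  n_hold <- max(1L, min(n - 1L, round(holdout_frac * n)))
  hold <- if (n > 1L) resample(seq_len(n), n_hold) else integer(0)
  train <- setdiff(seq_len(n), hold)
  if (!length(train)) train <- seq_len(n)
  if (!length(hold)) hold <- train

  heldout_loss <- function() {
    tot <- 0
    cnt <- 0
    for (batch in split(hold, ceiling(seq_along(hold) / batch_size))) {
      toks <- tokenize_batch(seqs[batch], vocab, config$max_len,
                             config$pooling)
      mk <- apply_mlm_mask(toks, vocab, config$mask_rate)
      fw <- enc_forward(params, mk$tokens, config, want_cache = FALSE)
      tot <- tot + mlm_loss(params, fw, mk, config,
                            with_grad = FALSE)$loss * length(batch)
      cnt <- cnt + length(batch)
    }
    tot / cnt
  }

  history <- data.frame(epoch = 0L, heldout_loss = heldout_loss())
  opt <- adam_init(params)
  for (ep in seq_len(epochs)) {
    idx <- resample(train, length(train))
    for (batch in split(idx, ceiling(seq_along(idx) / batch_size))) {
      toks <- tokenize_batch(seqs[batch], vocab, config$max_len,
                             config$pooling)
      mk <- apply_mlm_mask(toks, vocab, config$mask_rate)
      fw <- enc_forward(params, mk$tokens, config, want_cache = TRUE)
      ml <- mlm_loss(params, fw, mk, config)
      grads <- enc_backward(params, fw, ml$dH, config)
      grads$out_W <- ml$d_out_W
      grads$out_b <- ml$d_out_b
      step <- adam_step(params, grads, opt, lr = lr)
      params <- step$params
      opt <- step$state
      opt$t <- step$state$t
    }
    hl <- heldout_loss()
    history <- rbind(history, data.frame(epoch = ep, heldout_loss = hl))
    abmapr_msg(sprintf("MLM epoch %d/%d heldout loss %.4f", ep, epochs, hl),
               verbose = verbose)
  }
  structure(list(config = config, vocab = vocab, params = params,
                 history = history),
            class = "seq_encoder")
}

#' @export
print.seq_encoder <- function(x, ...) {
  cat(sprintf(paste0("seq_encoder: %s, embed_dim=%d, %d layer(s), ",
                     "%d head(s)\n"),
              x$config$alphabet, x$config$embed_dim, x$config$n_layers,
              x$config$n_heads))
  if (nrow(x$history) > 1L) {
    cat(sprintf("  heldout MLM loss: %.4f -> %.4f\n",
                x$history$heldout_loss[1L],
                x$history$heldout_loss[nrow(x$history)]))
  }
  invisible(x)
}

#' Build an encoder around an external embedding function
#'
#' Plug-in contract for pretrained models: any callable mapping a character
#' vector of sequences to an `N x d` numeric matrix can replace the
#' built-in masked-LM encoder (such an encoder cannot be fine-tuned by the
#' contrastive stages; they then train the linear transform and head only).
#'
#' @param fn function(character) -> numeric matrix.
#' @param embed_dim the embedding width `fn` produces.
#' @return A `seq_encoder` with `external = TRUE`.
#' @export
external_encoder <- function(fn, embed_dim) {
  stopifnot(is.function(fn), embed_dim >= 2L)
  structure(list(config = list(embed_dim = as.integer(embed_dim)),
                 fn = fn, external = TRUE),
            class = "seq_encoder")
}

#' Embed sequences with a trained encoder
#'
#' Deterministic in evaluation mode: identical sequences give identical
#' rows, repeat calls are bit-identical, and row order follows the table.
#'
#' @param encoder a `seq_encoder` from [pretrain_mlm()] or
#'   [external_encoder()].
#' @param table a [seq_table()] (or character vector of sequences).
#' @param batch_size sequences per forward pass.
#' @param strict error on out-of-vocabulary characters instead of mapping
#'   them to `<unk>` with a warning.
#' @return `N x embed_dim` numeric matrix.
#' @export
embed_sequences <- function(encoder, table, batch_size = 256L,
                            strict = FALSE) {
  stopifnot(inherits(encoder, "seq_encoder"))
  seqs <- if (inherits(table, "seq_table")) full_sequences(table)
          else as.character(table)
  if (!length(seqs)) {
    return(matrix(numeric(0), 0L, encoder$config$embed_dim))
  }
  if (isTRUE(encoder$external)) {
    E <- encoder$fn(seqs)
    stopifnot(nrow(E) == length(seqs))
    return(as.matrix(E))
  }
  out <- matrix(0, length(seqs), encoder$config$embed_dim)
  for (batch in split(seq_along(seqs),
                      ceiling(seq_along(seqs) / batch_size))) {
    toks <- tokenize_batch(seqs[batch], encoder$vocab,
                           encoder$config$max_len, encoder$config$pooling,
                           strict = strict)
    fw <- enc_forward(encoder$params, toks, encoder$config)
    out[batch, ] <- pool_forward(fw, encoder$config$pooling)
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint is a single RDS archive holding config, vocabulary and
#' parameters; the config is additionally written as `<path>.json`.
#'
#' @param encoder a `seq_encoder`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `seq_encoder` (load).
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "seq_encoder"))
  saveRDS(unclass(encoder), path)
  jsonlite::write_json(strip_classes(encoder$config),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- readRDS(path)
  class(obj) <- "seq_encoder"
  if (!is.null(obj$config) && !inherits(obj$config, "encoder_config")) {
    class(obj$config) <- "encoder_config"
  }
  obj
}
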