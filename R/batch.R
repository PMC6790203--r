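# Vectorised mini-batch forward/backward engine used for training and bulk
# prediction. Mirrors the per-message operations in model.R exactly (an
# equivalence test asserts agreement); gradients are hand-derived and
# verified against central finite differences.
#
# Conventions:
#   * word/char rows are 1-based into the parameter tables; row 1 is the
#     fixed zero padding row, row 2 the learned unknown row.
#   * sequences are right-padded to the batch maximum length with a 0/1
#     mask; masked positions carry the previous LSTM state through and are
#     excluded from attention, so padding cannot influence any output.
#   * the character convolution pools each word only over its own valid
#     window positions, so a word's character feature is independent of the
#     batch it appears in.

# ---- dataset encoding --------------------------------------------------

# Pre-encode a token corpus against a vocabulary: per-message word rows and
# indices into a dataset-wide unique-word table (for the char pathway).
encode_tokens <- function(tokens, vocab, config) {
  stopifnot(inherits(vocab, "hf_vocabulary"))
  toks <- lapply(tokens, function(t) {
    tt <- if (inherits(t, "hf_tokens")) t$tokens else as.character(t)
    if (length(tt) > config$max_seq_len) tt <- tt[seq_len(config$max_seq_len)]
    tt
  })
  if (any(lengths(toks) == 0L)) stop_validation("encode_tokens: empty message")
  uw <- unique(unlist(toks, use.names = FALSE))
  uw_chars <- lapply(uw, function(wrd) char_ids(wrd, vocab, config))
  wid <- lapply(toks, function(tt) {
    idx <- vocab$word_index[tt]
    idx[is.na(idx)] <- UNK_INDEX
    unname(idx) + 1L
  })
  uid <- lapply(toks, function(tt) match(tt, uw))
  list(wid = wid, uid = uid, uw = uw, uw_chars = uw_chars,
       labels = token_labels(tokens), n = length(toks))
}

# ---- character pathway -------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward convolution + max-pool for a set of unique words.
# chars: list of 1-based char-row vectors. Returns pooled (U x K) plus the
# cache needed for the backward pass. The im2col product is computed
# block-wise (one block per window offset) so the stacked input matrix is
# never materialized.
char_forward <- function(chars, params, config) {
  U <- length(chars)
  w <- config$kernel_width
  l <- config$char_dim
  K <- config$char_kernels
  lens <- lengths(chars)
  Lp <- max(max(lens), w)
  P <- Lp - w + 1L
  idmat <- matrix(1L, U, Lp)  # pad row
  for (u in seq_len(U)) idmat[u, seq_len(lens[u])] <- chars[[u]]
  vp <- pmax(lens, w) - w + 1L  # valid window positions per word
  # conv input rows ordered (u-1)*P + p
  imcols <- vector("list", w)
  Z <- matrix(rep(params$bc, each = U * P), U * P, K)
  for (j in seq_len(w)) {
    idx <- as.vector(t(idmat[, j:(j + P - 1L), drop = FALSE]))
    imcols[[j]] <- idx
    Z <- Z + params$C[idx, , drop = FALSE] %*%
      params$Wc[((j - 1L) * l + 1L):(j * l), , drop = FALSE]
  }
  A <- tanh(Z)
  pos <- rep(seq_len(P), times = U)
  invalid <- pos > vp[rep(seq_len(U), each = P)]
  if (any(invalid)) A[invalid, ] <- -Inf
  # max-pool over positions with argmax tracking
  rows1 <- seq(1L, U * P, by = P)
  pooled <- A[rows1, , drop = FALSE]
  argp <- matrix(1L, U, K)
  if (P > 1L) {
    for (p in 2L:P) {
      cand <- A[rows1 + (p - 1L), , drop = FALSE]
      upd <- cand > pooled
      pooled[upd] <- cand[upd]
      argp[upd] <- p
    }
  }
  list(pooled = pooled, argp = argp, imcols = imcols,
       A = A, U = U, P = P)
}

# Backward pass given d(pooled); accumulates into dWc, dbc, dC.
char_backward <- function(cache, dpooled, params, config) {
  U <- cache$U; P <- cache$P
  l <- config$char_dim
  w <- config$kernel_width
  K <- config$char_kernels
  dZ <- matrix(0, U * P, K)
  rows <- (rep(seq_len(U), times = K) - 1L) * P + as.vector(cache$argp)
  sel <- cbind(rows, rep(seq_len(K), each = U))
  a_at <- cache$A[sel]
  dZ[sel] <- as.vector(dpooled) * (1 - a_at^2)
  dbc <- colSums(dZ)
  dWc <- matrix(0, w * l, K)
  dC <- matrix(0, nrow(params$C), ncol(params$C))
  for (j in seq_len(w)) {
    jc <- ((j - 1L) * l + 1L):(j * l)
    idx <- cache$imcols[[j]]
    dWc[jc, ] <- crossprod(params$C[idx, , drop = FALSE], dZ)
    part <- rowsum(dZ %*% t(params$Wc[jc, , drop = FALSE]), idx)
    ids <- as.integer(rownames(part))
    dC[ids, ] <- dC[ids, , drop = FALSE] + part
  }
  dC[1L, ] <- 0  # padding row stays fixed
  list(dWc = dWc, dbc = dbc, dC = dC)
}

# ---- batched network forward ------------------------------------------

# sel: indices into the encoded dataset. Returns probabilities, loss pieces
# and (when keep_cache) everything the backward pass needs.
forward_batch <- function(enc, sel, model, keep_cache = FALSE) {
  params <- model$params
  config <- model$config
  B <- length(sel)
  lens <- lengths(enc$wid[sel])
  T <- max(lens)
  m <- config$lstm_units
  Wid <- matrix(1L, B, T)
  Uid <- matrix(0L, B, T)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    i <- sel[b]
    n <- lens[b]
    Wid[b, seq_len(n)] <- enc$wid[[i]]
    Uid[b, seq_len(n)] <- enc$uid[[i]]
    mask[b, seq_len(n)] <- 1
  }
  char_cache <- NULL
  CFaug <- NULL
  Lid <- NULL
  ub <- NULL
  if (config$use_char) {
    ub <- sort(unique(Uid[Uid > 0L]))
    Lid <- matrix(match(Uid, ub, nomatch = 0L), B, T)
    char_cache <- char_forward(enc$uw_chars[ub], params, config)
    CFaug <- rbind(rep(0, config$char_kernels), char_cache$pooled)
  }
  # stacked input matrix: row (t-1)*B + b is message b at position t,
  # matching as.vector() column-major order of the B x T index matrices
  XX <- params$E[as.vector(Wid), , drop = FALSE]
  if (config$use_char) {
    XX <- cbind(XX, CFaug[as.vector(Lid) + 1L, , drop = FALSE])
  }
  rows_t <- function(t) ((t - 1L) * B + 1L):(t * B)
  # input projections for both LSTM directions, all timesteps at once
  XPf <- XX %*% params$Wx_f
  XPf <- XPf + rep(params$b_f, each = B * T)
  XPb <- XX %*% params$Wx_b
  XPb <- XPb + rep(params$b_b, each = B * T)
  run_dir <- function(order, XP, Wh) {
    h <- matrix(0, B, m); c <- matrix(0, B, m)
    steps <- vector("list", T)
    H <- matrix(0, B * T, m)
    for (t in order) {
      G <- XP[rows_t(t), , drop = FALSE] + h %*% Wh
      i_g <- sigmoid(G[, 1:m, drop = FALSE])
      f_g <- sigmoid(G[, (m + 1L):(2L * m), drop = FALSE])
      g_c <- tanh(G[, (2L * m + 1L):(3L * m), drop = FALSE])
      o_g <- sigmoid(G[, (3L * m + 1L):(4L * m), drop = FALSE])
      c_new <- f_g * c + i_g * g_c
      tc <- tanh(c_new)
      h_new <- o_g * tc
      mt <- mask[, t]
      steps[[t]] <- list(i = i_g, f = f_g, g = g_c, o = o_g, tc = tc,
                         c_prev = c, h_prev = h)
      h <- h_new * mt + h * (1 - mt)
      c <- c_new * mt + c * (1 - mt)
      H[rows_t(t), ] <- h
    }
    list(H = H, steps = steps)
  }
  fwd <- run_dir(seq_len(T), XPf, params$Wh_f)
  bwd <- run_dir(rev(seq_len(T)), XPb, params$Wh_b)
  Hall <- cbind(fwd$H, bwd$H)  # (B*T) x 2m stacked annotations
  # attention over all positions at once
  Z <- tanh(Hall %*% params$Wa + rep(params$ba, each = B * T))
  umat <- matrix(drop(Z %*% params$hhat), B, T)
  umat[mask == 0] <- -Inf
  alpha <- softmax(umat)
  av <- as.vector(alpha)
  S <- rowsum(Hall * av, rep(seq_len(B), times = T))
  rownames(S) <- NULL
  logits <- S %*% params$Wo
  logits <- logits + rep(params$bo, each = B)
  P <- softmax(logits)
  out <- list(probabilities = P, alpha = alpha, S = S, mask = mask)
  if (keep_cache) {
    out$cache <- list(XX = XX, fwd = fwd, bwd = bwd, Hall = Hall, Z = Z,
                      Wid = Wid, Lid = Lid, ub = ub,
                      char_cache = char_cache, B = B, T = T)
  }
  out
}

# ---- batched backward --------------------------------------------------

# Returns gradients of the MEAN cross-entropy over the batch with respect
# to every parameter, as a named list matching model$params.
backward_batch <- function(fw, labels, model) {
  params <- model$params
  config <- model$config
  cache <- fw$cache
  B <- cache$B; T <- cache$T
  m <- config$lstm_units
  d <- config$word_dim
  P <- fw$probabilities
  Y <- matrix(0, B, config$n_classes)
  Y[cbind(seq_len(B), as.integer(labels))] <- 1
  dlogits <- (P - Y) / B
  grads <- list(
    Wo = crossprod(fw$S, dlogits),
    bo = colSums(dlogits)
  )
  dS <- dlogits %*% t(params$Wo)
  # attention backward, stacked over all (message, position) rows
  Hall <- cache$Hall; Z <- cache$Z
  alpha <- fw$alpha
  av <- as.vector(alpha)
  rows_t <- function(t) ((t - 1L) * B + 1L):(t * B)
  dSbig <- dS[rep(seq_len(B), times = T), , drop = FALSE]
  dalpha <- matrix(rowSums(Hall * dSbig), B, T)
  dHall <- av * dSbig
  du <- alpha * (dalpha - rowSums(alpha * dalpha))
  duv <- as.vector(du)
  dZ <- outer(duv, params$hhat)
  grads$hhat <- colSums(Z * duv)
  dA <- dZ * (1 - Z^2)
  grads$Wa <- crossprod(Hall, dA)
  grads$ba <- colSums(dA)
  dHall <- dHall + dA %*% t(params$Wa)
  # BPTT through each direction
  dX <- matrix(0, B * T, config$input_dim)
  mask <- fw$mask
  bptt_dir <- function(steps, order, Wx, Wh, half) {
    dh_next <- matrix(0, B, m)
    dc_next <- matrix(0, B, m)
    tWx <- t(Wx)
    tWh <- t(Wh)
    cols <- if (half == 1L) 1:m else (m + 1L):(2L * m)
    Gall <- matrix(0, B * T, 4L * m)
    Hprev <- matrix(0, B * T, m)
    for (t in rev(order)) {
      st <- steps[[t]]
      mt <- mask[, t]
      dh <- dHall[rows_t(t), cols, drop = FALSE] + dh_next
      dh_gate <- dh * mt
      dc_gate <- dc_next * mt
      do_ <- dh_gate * st$tc
      dc_new <- dc_gate + dh_gate * st$o * (1 - st$tc^2)
      di <- dc_new * st$g
      dg <- dc_new * st$i
      df <- dc_new * st$c_prev
      dc_prev <- dc_new * st$f
      G <- cbind(di * st$i * (1 - st$i),
                 df * st$f * (1 - st$f),
                 dg * (1 - st$g^2),
                 do_ * st$o * (1 - st$o))
      Gall[rows_t(t), ] <- G
      Hprev[rows_t(t), ] <- st$h_prev
      dh_next <- G %*% tWh + dh * (1 - mt)
      dc_next <- dc_prev + dc_next * (1 - mt)
    }
    dX <<- dX + Gall %*% tWx
    list(dWx = crossprod(cache$XX, Gall), dWh = crossprod(Hprev, Gall),
         db = colSums(Gall))
  }
  gf <- bptt_dir(cache$fwd$steps, seq_len(T), params$Wx_f, params$Wh_f, 1L)
  gb <- bptt_dir(cache$bwd$steps, rev(seq_len(T)), params$Wx_b, params$Wh_b, 2L)
  grads$Wx_f <- gf$dWx; grads$Wh_f <- gf$dWh; grads$b_f <- gf$db
  grads$Wx_b <- gb$dWx; grads$Wh_b <- gb$dWh; grads$b_b <- gb$db
  # word embedding gradient (masked positions have zero dX rows)
  ids <- as.vector(cache$Wid)
  part <- rowsum(dX[, 1:d, drop = FALSE], ids)
  dE <- matrix(0, nrow(params$E), d)
  dE[as.integer(rownames(part)), ] <- part
  dE[1L, ] <- 0  # padding row stays fixed
  grads$E <- dE
  # character pathway gradient
  if (config$use_char) {
    K <- config$char_kernels
    lids <- as.vector(cache$Lid) + 1L
    partc <- rowsum(dX[, (d + 1L):(d + K), drop = FALSE], lids)
    U <- length(cache$ub)
    dpooled <- matrix(0, U, K)
    idsc <- as.integer(rownames(partc))
    real <- idsc > 1L
    dpooled[idsc[real] - 1L, ] <- partc[real, , drop = FALSE]
    cg <- char_backward(cache$char_cache, dpooled, params, config)
    grads$Wc <- cg$dWc; grads$bc <- cg$dbc; grads$C <- cg$dC
  }
  grads
}

# ---- Adam optimizer ----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- bulk prediction ---------------------------------------------------

#' Predict classes for many messages
#'
#' Batched forward pass; identical results to calling [predict_tweet()] per
#' message, but substantially faster.
#'
#' @param tokens an `hf_token_corpus`.
#' @param model an [init_params()] (typically trained) object.
#' @param batch_size messages per forward batch.
#' @return list with `predicted` (integer classes) and `probabilities`
#'   (matrix, one row per message).
#' @export
predict_corpus <- function(tokens, model, batch_size = 256L) {
  enc <- encode_tokens(tokens, model$vocab, model$config)
  n <- enc$n
  pred <- integer(n)
  prob <- matrix(0, n, model$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    fw <- forward_batch(enc, sel, model)
    prob[sel, ] <- fw$probabilities
    pred[sel] <- max.col(fw$probabilities, ties.method = "first")
  }
  list(predicted = pred, probabilities = prob)
}
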