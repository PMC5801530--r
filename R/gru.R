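# Low-level GRU machinery: parameter initialisation, batched forward pass,
# backpropagation through time, Adam updates. Everything is plain R matrix
# algebra (BLAS-backed); gate order in the fused weight matrices is
# [update z | reset r | candidate c].
#
# Cell (for one layer, hidden state h, input x):
#   z = sigmoid(x W_z + h U_z + b_z)
#   r = sigmoid(x W_r + h U_r + b_r)
#   c = tanh(x W_c + (r * h) U_c + b_c)
#   h' = z * h + (1 - z) * c
# Output layer: logits = h_top W_y + b_y, softmax over the vocabulary.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

gru_init_params <- function(input_dim, hidden, layers, output_dim, seed = NULL) {
  with_seed(seed, {
    lay <- vector("list", layers)
    d_in <- input_dim
    for (l in seq_len(layers)) {
      lay[[l]] <- list(
        W = glorot(d_in, 3L * hidden),
        U = glorot(hidden, 3L * hidden),
        b = rep(0, 3L * hidden)
      )
      d_in <- hidden
    }
    list(layers = lay, Wy = glorot(hidden, output_dim), by = rep(0, output_dim),
         hidden = hidden, n_layers = layers,
         input_dim = input_dim, output_dim = output_dim)
  })
}

gru_zero_state <- function(params, n) {
  lapply(seq_len(params$n_layers),
         function(l) matrix(0, n, params$hidden))
}

# One step for a batch: X is n x input_dim, state a list of n x H matrices.
# Returns the new state plus softmax probabilities over the output symbols.
gru_step <- function(params, state, X) {
  H <- params$hidden
  zi <- seq_len(H); ri <- H + zi; ci <- 2L * H + zi
  inp <- X
  new_state <- state
  for (l in seq_len(params$n_layers)) {
    p <- params$layers[[l]]
    Hp <- state[[l]]
    A <- inp %*% p$W
    A <- sweep(A, 2L, p$b, "+")
    z <- sigmoid(A[, zi, drop = FALSE] + Hp %*% p$U[, zi, drop = FALSE])
    r <- sigmoid(A[, ri, drop = FALSE] + Hp %*% p$U[, ri, drop = FALSE])
    cc <- tanh(A[, ci, drop = FALSE] + (r * Hp) %*% p$U[, ci, drop = FALSE])
    Hn <- z * Hp + (1 - z) * cc
    new_state[[l]] <- Hn
    inp <- Hn
  }
  logits <- sweep(inp %*% params$Wy, 2L, params$by, "+")
  list(state = new_state, probs = softmax_rows(logits))
}

# Full forward pass over padded integer id matrices for training.
# in_ids, tgt_ids: n x T; id 0 means "start marker / padding" on the input
# side (encoded as the all-zero row) and "masked" on the target side.
# Returns mean masked cross-entropy and, if keep_cache, everything the
# backward pass needs.
gru_forward <- function(params, in_ids, tgt_ids, keep_cache = FALSE) {
  n <- nrow(in_ids); Tt <- ncol(in_ids)
  V <- params$input_dim; H <- params$hidden; L <- params$n_layers
  zi <- seq_len(H); ri <- H + zi; ci <- 2L * H + zi
  state <- gru_zero_state(params, n)
  cache <- if (keep_cache) vector("list", Tt)
  total_nll <- 0; n_pos <- 0L
  dP <- if (keep_cache) vector("list", Tt)
  for (t in seq_len(Tt)) {
    X <- matrix(0, n, V)
    nz <- which(in_ids[, t] > 0L)
    if (length(nz)) X[cbind(nz, in_ids[nz, t])] <- 1
    inp <- X
    step_cache <- if (keep_cache) vector("list", L)
    for (l in seq_len(L)) {
      p <- params$layers[[l]]
      Hp <- state[[l]]
      A <- sweep(inp %*% p$W, 2L, p$b, "+")
      z <- sigmoid(A[, zi, drop = FALSE] + Hp %*% p$U[, zi, drop = FALSE])
      r <- sigmoid(A[, ri, drop = FALSE] + Hp %*% p$U[, ri, drop = FALSE])
      cc <- tanh(A[, ci, drop = FALSE] + (r * Hp) %*% p$U[, ci, drop = FALSE])
      Hn <- z * Hp + (1 - z) * cc
      if (keep_cache) step_cache[[l]] <- list(inp = inp, Hp = Hp, z = z, r = r, cc = cc)
      state[[l]] <- Hn
      inp <- Hn
    }
    probs <- softmax_rows(sweep(inp %*% params$Wy, 2L, params$by, "+"))
    mask <- which(tgt_ids[, t] > 0L)
    if (length(mask)) {
      pt <- probs[cbind(mask, tgt_ids[mask, t])]
      total_nll <- total_nll - sum(log(pmax(pt, 1e-12)))
      n_pos <- n_pos + length(mask)
    }
    if (keep_cache) {
      # dLoss/dlogits for softmax CE (summed; divided by n_pos afterwards)
      d <- probs
      d[cbind(mask, tgt_ids[mask, t])] <-
        d[cbind(mask, tgt_ids[mask, t])] - 1
      keep <- logical(n); keep[mask] <- TRUE
      d[!keep, ] <- 0
      dP[[t]] <- d
      cache[[t]] <- list(layers = step_cache, X = X, Htop = inp)
    }
  }
  loss <- if (n_pos > 0L) total_nll / n_pos else 0
  list(loss = loss, n_pos = n_pos, cache = cache, dP = dP)
}

gru_zero_grads <- function(params) {
  list(layers = lapply(params$layers, function(p)
         list(W = p$W * 0, U = p$U * 0, b = p$b * 0)),
       Wy = params$Wy * 0, by = params$by * 0)
}

# Backpropagation through time given the forward cache; gradients are of the
# *mean* masked cross-entropy.
gru_backward <- function(params, fwd) {
  Tt <- length(fwd$cache)
  H <- params$hidden; L <- params$n_layers
  zi <- seq_len(H); ri <- H + zi; ci <- 2L * H + zi
  g <- gru_zero_grads(params)
  n <- if (Tt > 0L) nrow(fwd$cache[[1L]]$X) else 0L
  dH_next <- lapply(seq_len(L), function(l) matrix(0, n, H))
  scale <- if (fwd$n_pos > 0L) 1 / fwd$n_pos else 0
  for (t in rev(seq_len(Tt))) {
    ch <- fwd$cache[[t]]
    dlogits <- fwd$dP[[t]] * scale
    g$Wy <- g$Wy + crossprod(ch$Htop, dlogits)
    g$by <- g$by + colSums(dlogits)
    d_from_above <- dlogits %*% t(params$Wy)
    for (l in rev(seq_len(L))) {
      p <- params$layers[[l]]
      sc <- ch$layers[[l]]
      dH <- d_from_above + dH_next[[l]]
      dz <- dH * (sc$Hp - sc$cc)
      dcc <- dH * (1 - sc$z)
      dHp <- dH * sc$z
      dac <- dcc * (1 - sc$cc^2)
      drHp <- dac %*% t(p$U[, ci, drop = FALSE])
      dr <- drHp * sc$Hp
      dHp <- dHp + drHp * sc$r
      daz <- dz * sc$z * (1 - sc$z)
      dar <- dr * sc$r * (1 - sc$r)
      dHp <- dHp + daz %*% t(p$U[, zi, drop = FALSE]) +
        dar %*% t(p$U[, ri, drop = FALSE])
      gl <- g$layers[[l]]
      gl$U[, zi] <- gl$U[, zi] + crossprod(sc$Hp, daz)
      gl$U[, ri] <- gl$U[, ri] + crossprod(sc$Hp, dar)
      gl$U[, ci] <- gl$U[, ci] + crossprod(sc$r * sc$Hp, dac)
      gl$W[, zi] <- gl$W[, zi] + crossprod(sc$inp, daz)
      gl$W[, ri] <- gl$W[, ri] + crossprod(sc$inp, dar)
      gl$W[, ci] <- gl$W[, ci] + crossprod(sc$inp, dac)
      gl$b <- gl$b + c(colSums(daz), colSums(dar), colSums(dac))
      g$layers[[l]] <- gl
      d_from_above <- daz %*% t(p$W[, zi, drop = FALSE]) +
        dar %*% t(p$W[, ri, drop = FALSE]) +
        dac %*% t(p$W[, ci, drop = FALSE])
      dH_next[[l]] <- dHp
    }
  }
  g
}

# flatten/apply helpers used by the optimiser and the gradient-check tests
grad_leaves <- function(g) {
  out <- list()
  for (l in seq_along(g$layers)) {
    out[[paste0("W", l)]] <- g$layers[[l]]$W
    out[[paste0("U", l)]] <- g$layers[[l]]$U
    out[[paste0("b", l)]] <- g$layers[[l]]$b
  }
  out$Wy <- g$Wy
  out$by <- g$by
  out
}

map_leaves <- function(params, g, f) {
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$W <- f(params$layers[[l]]$W, g$layers[[l]]$W)
    params$layers[[l]]$U <- f(params$layers[[l]]$U, g$layers[[l]]$U)
    params$layers[[l]]$b <- f(params$layers[[l]]$b, g$layers[[l]]$b)
  }
  params$Wy <- f(params$Wy, g$Wy)
  params$by <- f(params$by, g$by)
  params
}

global_grad_norm <- function(g) {
  sqrt(sum(vapply(grad_leaves(g), function(x) sum(x^2), numeric(1))))
}

adam_init <- function(params) {
  zero <- gru_zero_grads(params)
  list(m = zero, v = zero, t = 0L)
}

adam_update <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, clip_norm = 5) {
  if (is.finite(clip_norm)) {
    gn <- global_grad_norm(grads)
    if (gn > clip_norm) {
      grads <- map_leaves(grads, grads, function(x, y) x * (clip_norm / gn))
    }
  }
  opt$t <- opt$t + 1L
  opt$m <- map_leaves(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- map_leaves(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step <- map_leaves(opt$m, opt$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map_leaves(params, step, function(p, s) p - s)
  list(params = params, opt = opt)
}
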