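# Internal engine for the 1D convolutional networks.
#
# Activations for a batch of b spectra at a layer with L positions and C
# channels are stored as a (b*L) x C matrix with row index r = b_idx +
# (pos-1)*b (sample index fastest). In this layout the rows a kernel offset
# j touches form the contiguous range (j-1)*b + 1:(b*L_out), so a valid
# convolution is one BLAS product A %*% [W_1 | ... | W_k] followed by k
# shifted contiguous block adds — no im2col patch matrix is materialised.

conv_out_len <- function(L, kernel) L - kernel + 1L

# layer sizes through the network; errors if the input is too short
cnn_layer_sizes <- function(arch, input_length) {
  L <- as.integer(input_length)
  sizes <- list()
  for (i in seq_along(arch$conv_blocks)) {
    blk <- arch$conv_blocks[[i]]
    Lc <- conv_out_len(L, blk$kernel)
    if (Lc < 1L)
      stop("cnn: input too short for conv block ", i)
    Lp <- Lc %/% blk$pool
    if (Lp < 1L)
      stop("cnn: input too short for pool in block ", i)
    sizes[[i]] <- list(L_in = L, L_conv = Lc, L_pool = Lp)
    L <- Lp
  }
  list(blocks = sizes,
       flat = L * arch$conv_blocks[[length(arch$conv_blocks)]]$filters,
       L_final = L)
}

# He-normal initialisation of all parameter matrices (uses current RNG).
# Conv weights are stored as (kernel*c_in) x c_out with offset-major rows:
# row (j-1)*c_in + ci maps kernel offset j, input channel ci.
cnn_init_params <- function(arch, input_length) {
  sizes <- cnn_layer_sizes(arch, input_length)
  params <- list(conv = list())
  c_in <- 1L
  for (i in seq_along(arch$conv_blocks)) {
    blk <- arch$conv_blocks[[i]]
    fan_in <- blk$kernel * c_in
    params$conv[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * blk$filters, 0, sqrt(2 / fan_in)),
                 fan_in, blk$filters),
      b = numeric(blk$filters))
    c_in <- blk$filters
  }
  params$dense <- list(
    W = matrix(stats::rnorm(sizes$flat * arch$dense_units, 0,
                            sqrt(2 / sizes$flat)),
               sizes$flat, arch$dense_units),
    b = numeric(arch$dense_units))
  out_dim <- if (arch$head == "classifier") 5L else 6L
  params$out <- list(
    W = matrix(stats::rnorm(arch$dense_units * out_dim, 0,
                            sqrt(1 / arch$dense_units)),
               arch$dense_units, out_dim),
    b = numeric(out_dim))
  params
}

sweep_add_rowvec <- function(M, v) M + rep(v, each = nrow(M))

# forward pass; returns output matrix (batch x out_dim) and, if cache=TRUE,
# everything the backward pass needs
cnn_forward <- function(params, arch, X, cache = FALSE,
                        dropout_active = FALSE) {
  batch <- nrow(X)
  A <- matrix(as.vector(X), batch * ncol(X), 1L)  # (b*L) x 1, sample-fastest
  caches <- if (cache) vector("list", length(arch$conv_blocks))
  for (i in seq_along(arch$conv_blocks)) {
    blk <- arch$conv_blocks[[i]]
    c_in <- ncol(A)
    L_in <- nrow(A) %/% batch
    L_out <- conv_out_len(L_in, blk$kernel)
    Z <- conv_fwd_cpp(A, params$conv[[i]]$W, batch, blk$kernel)
    Z <- sweep_add_rowvec(Z, params$conv[[i]]$b)
    relu_mask <- Z > 0
    H <- Z * relu_mask
    pf <- pool_fwd_cpp(H, batch, blk$pool)
    if (cache)
      caches[[i]] <- list(A = A, relu_mask = relu_mask, L_in = L_in,
                          L_out = L_out, L_pool = L_out %/% blk$pool,
                          c_in = c_in, argmax = pf$argmax)
    A <- pf$out
  }
  # flatten to batch x flat (sample-fastest layout makes this a dim change)
  flat <- length(A) %/% batch
  FL <- A
  dim(FL) <- c(batch, flat)
  D_in <- FL %*% params$dense$W
  D_in <- sweep_add_rowvec(D_in, params$dense$b)
  d_mask <- D_in > 0
  D <- D_in * d_mask
  drop_mask <- NULL
  if (dropout_active && arch$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(D)) >= arch$dropout,
                        nrow(D), ncol(D)) / (1 - arch$dropout)
    D <- D * drop_mask
  }
  O <- D %*% params$out$W
  O <- sweep_add_rowvec(O, params$out$b)
  if (!cache) return(O)
  list(out = O, conv = caches, FL = FL, d_mask = d_mask, D = D,
       drop_mask = drop_mask, batch = batch)
}

# backward pass from dO (batch x out_dim); returns gradients mirroring params
cnn_backward <- function(params, arch, fwd, dO) {
  batch <- fwd$batch
  grads <- list(conv = vector("list", length(arch$conv_blocks)))
  grads$out <- list(W = crossprod(fwd$D, dO), b = colSums(dO))
  dD <- tcrossprod(dO, params$out$W)
  if (!is.null(fwd$drop_mask)) dD <- dD * fwd$drop_mask
  dDin <- dD * fwd$d_mask
  grads$dense <- list(W = crossprod(fwd$FL, dDin), b = colSums(dDin))
  dFL <- tcrossprod(dDin, params$dense$W)
  nb <- length(arch$conv_blocks)
  dA <- dFL
  dim(dA) <- c(batch * fwd$conv[[nb]]$L_pool, arch$conv_blocks[[nb]]$filters)
  for (i in rev(seq_len(nb))) {
    ch <- fwd$conv[[i]]
    blk <- arch$conv_blocks[[i]]
    dH <- pool_bwd_cpp(dA, ch$argmax, batch, blk$pool, ch$L_out)
    dZ <- dH * ch$relu_mask
    cb <- conv_bwd_cpp(ch$A, params$conv[[i]]$W, dZ, batch, blk$kernel,
                       i > 1L)
    grads$conv[[i]] <- list(W = cb$dW, b = as.numeric(cb$db))
    if (i > 1L) dA <- cb$dA
  }
  grads
}

# --- Adam optimizer ----------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(m = rapply_params(params, zero_like),
       v = rapply_params(params, zero_like), t = 0L)
}

rapply_params <- function(params, f) {
  list(conv = lapply(params$conv, f), dense = f(params$dense),
       out = f(params$out))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m$W <- beta1 * m$W + (1 - beta1) * g$W
    m$b <- beta1 * m$b + (1 - beta1) * g$b
    v$W <- beta2 * v$W + (1 - beta2) * g$W^2
    v$b <- beta2 * v$b + (1 - beta2) * g$b^2
    p$W <- p$W - lr * (m$W / bc1) / (sqrt(v$W / bc2) + eps)
    p$b <- p$b - lr * (m$b / bc1) / (sqrt(v$b / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(params$conv)) {
    r <- upd(params$conv[[i]], grads$conv[[i]], state$m$conv[[i]],
             state$v$conv[[i]])
    params$conv[[i]] <- r$p; state$m$conv[[i]] <- r$m; state$v$conv[[i]] <- r$v
  }
  r <- upd(params$dense, grads$dense, state$m$dense, state$v$dense)
  params$dense <- r$p; state$m$dense <- r$m; state$v$dense <- r$v
  r <- upd(params$out, grads$out, state$m$out, state$v$out)
  params$out <- r$p; state$m$out <- r$m; state$v$out <- r$v
  list(params = params, state = state)
}

# --- losses ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# multilabel binary cross-entropy on logits; returns loss and dO
bce_loss <- function(O, Y) {
  P <- sigmoid(O)
  eps <- 1e-12
  loss <- -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  list(loss = loss, dO = (P - Y) / length(Y))
}

mse_loss <- function(O, Y) {
  E <- O - Y
  list(loss = mean(E^2), dO = 2 * E / length(Y))
}

# loss over a dataset, evaluated in chunks to bound memory
cnn_dataset_loss <- function(params, arch, X, Y, chunk = 512L) {
  n <- nrow(X)
  tot <- 0
  idx <- seq_len(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, n)]
    O <- cnn_forward(params, arch, X[sel, , drop = FALSE])
    l <- if (arch$head == "classifier") bce_loss(O, Y[sel, , drop = FALSE])
         else mse_loss(O, Y[sel, , drop = FALSE])
    tot <- tot + l$loss * length(sel)
  }
  tot / n
}
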