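# Minimal CNN engine: 3x3 same-padding convolutions, 2x2/stride-2 max
# pooling, a small dense head and softmax cross-entropy, trained by SGD
# with momentum.  Activations travel in channel-first (C, H, W, N) arrays;
# convolutions are lowered to GEMM through im2col with precomputed gather
# indices, which keeps everything inside BLAS.

# Gather indices turning a zero-padded (C, H+2, W+2) image into the
# im2col matrix of 3x3 patches: 9C rows, H*W columns (output positions in
# column-major order, matching array()).  Memoised per activation shape.
.idx_cache <- new.env(parent = emptyenv())

im2col_indices <- function(c_in, h, w) {
  key <- paste(c_in, h, w, sep = "x")
  cached <- .idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  hp <- h + 2L
  # element (c, i, j) of the padded array lives at c + (i-1)*C + (j-1)*C*Hp
  patch <- rep(seq_len(c_in), 9L) +
    c_in * rep(rep(0:2, each = c_in), 3L) +
    c_in * hp * rep(0:2, each = 3L * c_in)
  corner <- c_in * rep(0:(h - 1L), w) + c_in * hp * rep(0:(w - 1L), each = h)
  idx <- outer(patch, corner, "+")   # (9C) x (H*W)
  .idx_cache[[key]] <- idx
  idx
}

pad_batch <- function(x, c_in, h, w, n) {
  out <- array(0, c(c_in, h + 2L, w + 2L, n))
  out[, 2:(h + 1L), 2:(w + 1L), ] <- x
  out
}

# Forward 3x3 same convolution.  weights: F x 9C, bias: length F.
conv_forward <- function(x, weights, bias, c_in, h, w) {
  n <- dim(x)[4L]
  idx <- im2col_indices(c_in, h, w)
  padded <- pad_batch(x, c_in, h, w, n)
  per <- (c_in * (h + 2L) * (w + 2L))
  idx_all <- as.vector(outer(as.vector(idx), (seq_len(n) - 1L) * per, "+"))
  cols <- matrix(padded[idx_all], nrow = 9L * c_in)
  out <- weights %*% cols + bias
  list(out = array(out, c(nrow(weights), h, w, n)), cols = cols,
       idx_all = idx_all, pad_len = per * n)
}

# Backward pass of the same convolution.  d_out: (F, H, W, N).
conv_backward <- function(d_out, cache, weights, c_in, h, w, n) {
  f <- nrow(weights)
  d_mat <- matrix(d_out, nrow = f)
  d_w <- tcrossprod(d_mat, cache$cols)           # F x 9C
  d_b <- rowSums(d_mat)
  d_cols <- crossprod(weights, d_mat)            # 9C x (HWN)
  # scatter-add back into the padded gradient, then strip the padding
  sums <- rowsum(as.vector(d_cols), cache$idx_all)
  d_pad <- numeric(cache$pad_len)
  d_pad[as.integer(rownames(sums))] <- sums
  d_pad <- array(d_pad, c(c_in, h + 2L, w + 2L, n))
  list(d_x = d_pad[, 2:(h + 1L), 2:(w + 1L), , drop = FALSE],
       d_w = d_w, d_b = d_b)
}

# 2x2 stride-2 max pool on (C, H, W, N); odd trailing rows/cols dropped.
pool_forward <- function(x, h, w) {
  ho <- h %/% 2L; wo <- w %/% 2L
  i1 <- seq.int(1L, by = 2L, length.out = ho)
  j1 <- seq.int(1L, by = 2L, length.out = wo)
  cand <- list(x[, i1, j1, , drop = FALSE],
               x[, i1 + 1L, j1, , drop = FALSE],
               x[, i1, j1 + 1L, , drop = FALSE],
               x[, i1 + 1L, j1 + 1L, , drop = FALSE])
  out <- pmax(cand[[1L]], cand[[2L]], cand[[3L]], cand[[4L]])
  list(out = out, cand = cand, i1 = i1, j1 = j1, ho = ho, wo = wo)
}

pool_backward <- function(d_out, cache, x_dim) {
  d_x <- array(0, x_dim)
  taken <- array(FALSE, dim(d_out))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  out <- pmax(cache$cand[[1L]], cache$cand[[2L]], cache$cand[[3L]],
              cache$cand[[4L]])
  for (k in 1:4) {
    sel <- (cache$cand[[k]] == out) & !taken    # ties -> first candidate
    taken <- taken | sel
    di <- offs[[k]][1L]; dj <- offs[[k]][2L]
    block <- d_x[, cache$i1 + di, cache$j1 + dj, , drop = FALSE]
    block[sel] <- d_out[sel]
    d_x[, cache$i1 + di, cache$j1 + dj, ] <- block
  }
  d_x
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

init_params <- function(arch) {
  params <- list()
  c_in <- arch$input[3L]
  for (b in seq_len(arch$n_blocks)) {
    f <- arch$filters[b]
    params[[paste0("conv", b, "_w")]] <- he_init(f, 9L * c_in, 9L * c_in)
    params[[paste0("conv", b, "_b")]] <- numeric(f)
    c_in <- f
  }
  flat <- arch$flat_dim
  params$fc1_w <- he_init(arch$dense_width, flat, flat)
  params$fc1_b <- numeric(arch$dense_width)
  params$fc2_w <- he_init(2L, arch$dense_width, arch$dense_width)
  params$fc2_b <- numeric(2L)
  params
}

# Forward through the whole network.  Returns class probabilities
# (2 x N) and, when `keep` is TRUE, the caches backprop needs.
net_forward <- function(x, arch, params, keep = FALSE) {
  n <- dim(x)[4L]
  caches <- if (keep) vector("list", arch$n_blocks)
  h <- arch$input[1L]; w <- arch$input[2L]; c_in <- arch$input[3L]
  act <- x
  for (b in seq_len(arch$n_blocks)) {
    cv <- conv_forward(act, params[[paste0("conv", b, "_w")]],
                       params[[paste0("conv", b, "_b")]],
                       c_in, h, w)
    pre <- cv$out
    post <- relu(pre)
    pl <- pool_forward(post, h, w)
    if (keep) caches[[b]] <- list(conv = cv, pre = pre, post_dim = dim(post),
                                  pool = pl, in_dim = c(c_in, h, w, n),
                                  x_in = act)
    act <- pl$out
    c_in <- arch$filters[b]; h <- pl$ho; w <- pl$wo
  }
  flat <- matrix(act, nrow = arch$flat_dim)
  z1 <- params$fc1_w %*% flat + params$fc1_b
  a1 <- relu(z1)
  z2 <- params$fc2_w %*% a1 + params$fc2_b
  probs <- softmax_cols(z2)
  res <- list(probs = probs)
  if (keep) {
    res$caches <- caches; res$flat <- flat; res$z1 <- z1; res$a1 <- a1
    res$last <- list(c = c_in, h = h, w = w, n = n)
  }
  res
}

# Gradients of mean cross-entropy w.r.t. every parameter.
net_backward <- function(fw, y01, arch, params) {
  n <- length(y01)
  d_z2 <- fw$probs
  d_z2[cbind(y01 + 1L, seq_len(n))] <-
    d_z2[cbind(y01 + 1L, seq_len(n))] - 1
  d_z2 <- d_z2 / n
  grads <- list(
    fc2_w = tcrossprod(d_z2, fw$a1),
    fc2_b = rowSums(d_z2))
  d_a1 <- crossprod(params$fc2_w, d_z2)
  d_z1 <- d_a1 * (fw$z1 > 0)
  grads$fc1_w <- tcrossprod(d_z1, fw$flat)
  grads$fc1_b <- rowSums(d_z1)
  d_flat <- crossprod(params$fc1_w, d_z1)
  d_act <- array(d_flat, c(fw$last$c, fw$last$h, fw$last$w, fw$last$n))
  for (b in rev(seq_len(arch$n_blocks))) {
    cache <- fw$caches[[b]]
    d_post <- pool_backward(d_act, cache$pool, cache$post_dim)
    d_pre <- d_post * (cache$pre > 0)
    dims <- cache$in_dim
    bk <- conv_backward(d_pre, cache$conv,
                        params[[paste0("conv", b, "_w")]],
                        dims[1L], dims[2L], dims[3L], dims[4L])
    grads[[paste0("conv", b, "_w")]] <- bk$d_w
    grads[[paste0("conv", b, "_b")]] <- bk$d_b
    d_act <- bk$d_x
  }
  grads
}

cross_entropy <- function(probs, y01) {
  p <- pmax(probs[cbind(y01 + 1L, seq_along(y01))], 1e-12)
  -mean(log(p))
}

# Evaluate probabilities in manageable chunks to bound memory.
net_predict_probs <- function(x, arch, params, chunk = 64L) {
  n <- dim(x)[4L]
  probs <- matrix(0, 2L, n)
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    probs[, idx] <- net_forward(x[, , , idx, drop = FALSE], arch,
                                params)$probs
  }
  probs
}
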