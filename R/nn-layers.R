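# Differentiable layer primitives for the 3D segmentation network.
#
# Feature maps are stored channels-first as a (C x N) matrix where N is the
# number of voxels of the current grid, with the grid dimensions carried
# separately. Convolutions are evaluated as 27 shifted matrix products
# (one per kernel tap), which routes all heavy arithmetic through BLAS; the
# backward passes are written by hand and verified against finite
# differences in the test suite.

conv3_init <- function(c_in, c_out) {
  sd <- sqrt(2 / (c_in * 27))
  list(W = array(stats::rnorm(c_out * c_in * 27, 0, sd), c(c_out, c_in, 27)),
       b = numeric(c_out))
}

conv3_forward <- function(x, p, dims, stride = 1L, keep_col = TRUE) {
  cin <- dim(p$W)[2]; cout <- dim(p$W)[1]
  w2d <- matrix(p$W, cout, cin * 27L)
  r <- conv3_fwd_cpp(x, w2d, p$b, as.integer(dims), as.integer(stride),
                     keep_col)
  list(out = r$out, cache = list(col = r$col, dims = as.integer(dims),
                                 stride = as.integer(stride)))
}

conv3_backward <- function(dout, p, cache) {
  cin <- dim(p$W)[2]; cout <- dim(p$W)[1]
  w2d <- matrix(p$W, cout, cin * 27L)
  r <- conv3_bwd_cpp(cache$col, w2d, dout, cache$dims, cache$stride)
  dW <- r$dW
  dim(dW) <- dim(p$W)
  list(dx = r$dx, grads = list(W = dW, b = as.numeric(r$db)))
}

conv1_init <- function(c_in, c_out) {
  list(W = matrix(stats::rnorm(c_out * c_in, 0, sqrt(2 / c_in)), c_out, c_in),
       b = numeric(c_out))
}

conv1_forward <- function(x, p) {
  list(out = p$W %*% x + p$b, cache = x)
}

conv1_backward <- function(dout, p, cache) {
  list(dx = crossprod(p$W, dout),
       grads = list(W = dout %*% t(cache), b = rowSums(dout)))
}

instnorm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

instnorm_forward <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_std
  list(out = xhat * p$gamma + p$beta,
       cache = list(xhat = xhat, inv_std = inv_std))
}

instnorm_backward <- function(dout, p, cache) {
  xhat <- cache$xhat
  dxhat <- dout * p$gamma
  dx <- cache$inv_std *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(gamma = rowSums(dout * xhat), beta = rowSums(dout)))
}

lrelu_forward <- function(x, alpha = 0.01) {
  slope <- (x > 0) * (1 - alpha) + alpha
  list(out = x * slope, cache = list(slope = slope))
}

lrelu_backward <- function(dout, cache) {
  dout * cache$slope
}

# Nearest-neighbour 2x upsampling; backward sums gradients over each
# 2x2x2 block of children.
upsample2_forward <- function(x, dims) {
  cin <- nrow(x)
  xa <- array(x, c(cin, dims))
  out <- xa[, rep(seq_len(dims[1]), each = 2), rep(seq_len(dims[2]), each = 2),
            rep(seq_len(dims[3]), each = 2), drop = FALSE]
  dim(out) <- c(cin, 8L * prod(dims))
  list(out = out, dims_out = 2L * dims)
}

upsample2_backward <- function(dout, dims_in) {
  cin <- nrow(dout)
  v <- array(dout, c(cin, 2L, dims_in[1], 2L, dims_in[2], 2L, dims_in[3]))
  dx <- array(0, c(cin, dims_in))
  for (e1 in 1:2) for (e2 in 1:2) for (e3 in 1:2) {
    g <- v[, e1, , e2, , e3, , drop = FALSE]
    dim(g) <- c(cin, dims_in)
    dx <- dx + g
  }
  dim(dx) <- c(cin, prod(dims_in))
  dx
}

layernorm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# Normalization over channels, per token (column).
layernorm_forward <- function(x, p, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  inv_std <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, inv_std, `*`)
  list(out = xhat * p$gamma + p$beta,
       cache = list(xhat = xhat, inv_std = inv_std))
}

layernorm_backward <- function(dout, p, cache) {
  xhat <- cache$xhat
  dxhat <- dout * p$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat - outer(rep(1, nrow(xhat)), m1) - sweep(xhat, 2, m2, `*`),
              2, cache$inv_std, `*`)
  list(dx = dx,
       grads = list(gamma = rowSums(dout * xhat), beta = rowSums(dout)))
}

mhsa_init <- function(c, n_tokens, heads) {
  if (c %% heads != 0) stop("bottleneck channels must be divisible by heads")
  sd <- sqrt(1 / c)
  list(ln = layernorm_init(c),
       Wq = matrix(stats::rnorm(c * c, 0, sd), c, c),
       Wk = matrix(stats::rnorm(c * c, 0, sd), c, c),
       Wv = matrix(stats::rnorm(c * c, 0, sd), c, c),
       Wo = matrix(stats::rnorm(c * c, 0, sd), c, c),
       bo = numeric(c),
       pos = matrix(stats::rnorm(c * n_tokens, 0, 0.02), c, n_tokens))
}

# Pre-norm multi-head self-attention over the flattened bottleneck voxels,
# with a learned positional embedding and a residual connection:
#   stream = x + pos;  out = stream + Wo . MHSA(LN(stream)) + bo
mhsa_forward <- function(x, p, heads) {
  stream <- x + p$pos
  ln <- layernorm_forward(stream, p$ln)
  q <- p$Wq %*% ln$out
  k <- p$Wk %*% ln$out
  v <- p$Wv %*% ln$out
  c_tot <- nrow(x)
  hd <- c_tot %/% heads
  o <- matrix(0, c_tot, ncol(x))
  att <- vector("list", heads)
  for (h in seq_len(heads)) {
    rows <- (h - 1L) * hd + seq_len(hd)
    s <- crossprod(q[rows, , drop = FALSE], k[rows, , drop = FALSE]) / sqrt(hd)
    a <- exp(s - max(s))                # global shift: softmax is invariant
    a <- a / rowSums(a)
    o[rows, ] <- tcrossprod(v[rows, , drop = FALSE], a)
    att[[h]] <- a
  }
  proj <- p$Wo %*% o + p$bo
  list(out = stream + proj,
       cache = list(ln = ln, q = q, k = k, v = v, o = o, att = att, hd = hd))
}

mhsa_backward <- function(dout, p, heads, cache) {
  hd <- cache$hd
  dproj <- dout                       # residual: dstream gets dout directly too
  dWo <- dproj %*% t(cache$o)
  dbo <- rowSums(dproj)
  do_ <- crossprod(p$Wo, dproj)
  dq <- matrix(0, nrow(cache$q), ncol(cache$q))
  dk <- dq; dv <- dq
  for (h in seq_len(heads)) {
    rows <- (h - 1L) * hd + seq_len(hd)
    a <- cache$att[[h]]
    doh <- do_[rows, , drop = FALSE]
    vh <- cache$v[rows, , drop = FALSE]
    dv[rows, ] <- doh %*% a
    da <- crossprod(doh, vh)          # t(doh) %*% vh : T x T
    ds <- a * (da - rowSums(da * a))
    dq[rows, ] <- cache$k[rows, , drop = FALSE] %*% t(ds) / sqrt(hd)
    dk[rows, ] <- cache$q[rows, , drop = FALSE] %*% ds / sqrt(hd)
  }
  lnout <- cache$ln$out
  dWq <- dq %*% t(lnout); dWk <- dk %*% t(lnout); dWv <- dv %*% t(lnout)
  dln <- crossprod(p$Wq, dq) + crossprod(p$Wk, dk) + crossprod(p$Wv, dv)
  lb <- layernorm_backward(dln, p$ln, cache$ln$cache)
  dstream <- dout + lb$dx
  list(dx = dstream,
       grads = list(ln = lb$grads, Wq = dWq, Wk = dWk, Wv = dWv,
                    Wo = dWo, bo = dbo, pos = dstream))
}

resblock_init <- function(c_in, c_out) {
  p <- list(conv1 = conv3_init(c_in, c_out), in1 = instnorm_init(c_out),
            conv2 = conv3_init(c_out, c_out), in2 = instnorm_init(c_out))
  if (c_in != c_out) p$short <- conv1_init(c_in, c_out)
  p
}

# conv -> IN -> LReLU -> conv -> IN, plus (projected) identity, then LReLU.
resblock_forward <- function(x, p, dims, keep_col = TRUE) {
  c1 <- conv3_forward(x, p$conv1, dims, keep_col = keep_col)
  n1 <- instnorm_forward(c1$out, p$in1)
  a1 <- lrelu_forward(n1$out)
  c2 <- conv3_forward(a1$out, p$conv2, dims, keep_col = keep_col)
  n2 <- instnorm_forward(c2$out, p$in2)
  if (!is.null(p$short)) {
    sc <- conv1_forward(x, p$short)
    shortcut <- sc$out
  } else {
    sc <- NULL
    shortcut <- x
  }
  a2 <- lrelu_forward(n2$out + shortcut)
  list(out = a2$out,
       cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache,
                    c2 = c2$cache, n2 = n2$cache, sc = sc, a2 = a2$cache))
}

resblock_backward <- function(dout, p, cache) {
  d <- lrelu_backward(dout, cache$a2)
  n2 <- instnorm_backward(d, p$in2, cache$n2)
  c2 <- conv3_backward(n2$dx, p$conv2, cache$c2)
  d1 <- lrelu_backward(c2$dx, cache$a1)
  n1 <- instnorm_backward(d1, p$in1, cache$n1)
  c1 <- conv3_backward(n1$dx, p$conv1, cache$c1)
  grads <- list(conv1 = c1$grads, in1 = n1$grads, conv2 = c2$grads,
                in2 = n2$grads)
  if (!is.null(p$short)) {
    sb <- conv1_backward(d, p$short, cache$sc$cache)
    grads$short <- sb$grads
    dx <- c1$dx + sb$dx
  } else {
    dx <- c1$dx + d
  }
  list(dx = dx, grads = grads)
}
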