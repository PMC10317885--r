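#' Network configuration
#'
#' Describes the residual 3D U-Net with a multi-head self-attention (MHSA)
#' bottleneck. The encoder halves the grid per level with strided
#' convolutions while doubling the channel width (`base_channels * 2^(l-1)`
#' at level `l`); the bottleneck grid is `patch_shape / 2^(levels-1)` and its
#' flattened voxels are the attention tokens.
#'
#' @param levels number of resolution levels, >= 2 (default 4).
#' @param base_channels channel width of the first level (default 16; a tiny
#'   model with `base_channels = 4` trains on a desktop CPU).
#' @param attention_heads number of self-attention heads (default 8); must
#'   divide the bottleneck channel count.
#' @param attention_dim per-head dimensionality; `NULL` (default) derives it
#'   as bottleneck channels / heads.
#' @param num_classes number of output classes (3: background, primary
#'   tumor, LN metastasis).
#' @param patch_shape input patch dimensions; each in-plane/axial extent must
#'   be divisible by `2^(levels-1)`.
#' @param seed integer seed for deterministic weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 4L, base_channels = 16L,
                           attention_heads = 8L, attention_dim = NULL,
                           num_classes = 3L, patch_shape = c(128L, 128L, 32L),
                           seed = 1L) {
  levels <- as.integer(levels)
  patch_shape <- as.integer(patch_shape)
  if (levels < 2L) stop("levels must be >= 2")
  fac <- 2L^(levels - 1L)
  if (any(patch_shape %% fac != 0L)) {
    stop("patch_shape must be divisible by 2^(levels-1) = ", fac)
  }
  c_bott <- as.integer(base_channels) * 2L^(levels - 1L)
  if (c_bott %% as.integer(attention_heads) != 0L) {
    stop("bottleneck channels (", c_bott, ") must be divisible by attention_heads")
  }
  if (is.null(attention_dim)) attention_dim <- c_bott %/% as.integer(attention_heads)
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 attention_heads = as.integer(attention_heads),
                 attention_dim = as.integer(attention_dim),
                 num_classes = as.integer(num_classes),
                 patch_shape = patch_shape, seed = as.integer(seed)),
            class = "network_config")
}

level_channels <- function(cfg) {
  as.integer(cfg$base_channels * 2^(seq_len(cfg$levels) - 1))
}

bottleneck_shape <- function(cfg) {
  as.integer(cfg$patch_shape %/% 2^(cfg$levels - 1))
}

#' Build the residual 3D U-Net with self-attention bottleneck
#'
#' Encoder: a residual block per level (two 3x3x3 convolutions with instance
#' normalization, leaky-ReLU, and an identity shortcut), with strided-
#' convolution downsampling between levels. At the bottom, one pre-norm
#' multi-head self-attention block over the flattened bottleneck voxels with
#' a learned positional embedding and residual connection. Decoder: nearest-
#' neighbour upsampling, concatenation with the skip connection, and a
#' residual block per level. A final 1x1x1 convolution and voxel-wise softmax
#' produce the 3-class probability map. Weights are initialized
#' deterministically from `cfg$seed`.
#'
#' @param cfg a [network_config()].
#' @return An object of class `mtv_model` holding `config` and `params`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- level_channels(cfg)
  L <- cfg$levels
  n_tokens <- prod(bottleneck_shape(cfg))
  params <- withr::with_seed(cfg$seed, {
    p <- list(enc = vector("list", L), down = vector("list", L),
              dec = vector("list", L))
    p$enc[[1]] <- resblock_init(2L, ch[1])
    for (l in 2:L) {
      p$down[[l]] <- conv3_init(ch[l - 1], ch[l])
      p$enc[[l]] <- resblock_init(ch[l], ch[l])
    }
    p$mhsa <- mhsa_init(ch[L], n_tokens, cfg$attention_heads)
    for (l in seq_len(L - 1)) {
      p$dec[[l]] <- resblock_init(ch[l + 1] + ch[l], ch[l])
    }
    p$head <- conv1_init(ch[1], cfg$num_classes)
    p
  })
  structure(list(config = cfg, params = params), class = "mtv_model")
}

col_softmax <- function(logits) {
  mx <- Reduce(pmax, asplit(logits, 1))
  e <- exp(logits - rep(mx, each = nrow(logits)))
  e / rep(colSums(e), each = nrow(logits))
}

# Forward pass on a single patch. x is a (2 x N) matrix (PET row, CT row).
net_forward <- function(params, cfg, x, dims, keep_cache = FALSE) {
  L <- cfg$levels
  caches <- list(enc = vector("list", L), down = vector("list", L),
                 dec = vector("list", L))
  skips <- vector("list", L)
  dlist <- vector("list", L)
  cur <- x; curdims <- as.integer(dims)
  for (l in seq_len(L)) {
    if (l > 1L) {
      dn <- conv3_forward(cur, params$down[[l]], curdims, stride = 2L,
                          keep_col = keep_cache)
      caches$down[[l]] <- dn$cache
      cur <- dn$out; curdims <- curdims %/% 2L
    }
    rb <- resblock_forward(cur, params$enc[[l]], curdims, keep_cache)
    caches$enc[[l]] <- rb$cache
    cur <- rb$out
    skips[[l]] <- cur; dlist[[l]] <- curdims
  }
  at <- mhsa_forward(cur, params$mhsa, cfg$attention_heads)
  caches$mhsa <- at$cache
  cur <- at$out
  for (l in rev(seq_len(L - 1))) {
    up <- upsample2_forward(cur, dlist[[l + 1]])
    cur <- rbind(up$out, skips[[l]])
    rb <- resblock_forward(cur, params$dec[[l]], dlist[[l]], keep_cache)
    caches$dec[[l]] <- rb$cache
    cur <- rb$out
  }
  hd <- conv1_forward(cur, params$head)
  caches$head <- hd$cache
  probs <- col_softmax(hd$out)
  if (!keep_cache) return(list(probs = probs))
  caches$dlist <- dlist
  list(probs = probs, caches = caches)
}

net_backward <- function(params, cfg, dlogits, caches) {
  L <- cfg$levels
  ch <- level_channels(cfg)
  dlist <- caches$dlist
  # same element order as the params tree built in build_model, so the two
  # flatten to aligned vectors
  grads <- list(enc = vector("list", L), down = vector("list", L),
                dec = vector("list", L), mhsa = NULL, head = NULL)
  hb <- conv1_backward(dlogits, params$head, caches$head)
  grads$head <- hb$grads
  dcur <- hb$dx
  dskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    rb <- resblock_backward(dcur, params$dec[[l]], caches$dec[[l]])
    grads$dec[[l]] <- rb$grads
    c_up <- ch[l + 1]
    dskip[[l]] <- rb$dx[c_up + seq_len(ch[l]), , drop = FALSE]
    dcur <- upsample2_backward(rb$dx[seq_len(c_up), , drop = FALSE],
                               dlist[[l + 1]])
  }
  ab <- mhsa_backward(dcur, params$mhsa, cfg$attention_heads, caches$mhsa)
  grads$mhsa <- ab$grads
  dskip[[L]] <- ab$dx
  for (l in rev(seq_len(L))) {
    rb <- resblock_backward(dskip[[l]], params$enc[[l]], caches$enc[[l]])
    grads$enc[[l]] <- rb$grads
    if (l > 1L) {
      cb <- conv3_backward(rb$dx, params$down[[l]], caches$down[[l]])
      grads$down[[l]] <- cb$grads
      dskip[[l - 1]] <- dskip[[l - 1]] + cb$dx
    }
  }
  grads
}

#' Predict class probabilities for one preprocessed patch
#'
#' @param model an [build_model()] result.
#' @param pet,ct 3D arrays with values in \[0, 1\], shaped like
#'   `model$config$patch_shape`.
#' @return 4D probability array `(x, y, z, class)`; a simplex at every voxel.
#' @export
predict_patch <- function(model, pet, ct) {
  cfg <- model$config
  stopifnot(identical(as.integer(dim(pet)), cfg$patch_shape),
            identical(dim(pet), dim(ct)))
  x <- rbind(as.numeric(pet), as.numeric(ct))
  probs <- net_forward(model$params, cfg, x, cfg$patch_shape)$probs
  out <- array(t(probs), dim = c(cfg$patch_shape, cfg$num_classes))
  out
}

# Coerce probability/one-hot input to a (C x N) matrix. Accepts a 4D
# channel-last array or a matrix that is already channels-first.
as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L) {
    m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
    return(t(m))
  }
  stop("expected a (C x N) matrix or a 4D channel-last array")
}

dice_ce_item <- function(p, t, eps = 1) {
  if (!identical(dim(p), dim(t))) stop("prediction/target shape mismatch")
  n <- ncol(p)
  ce <- -sum(t * log(pmax(p, 1e-12))) / n
  fg <- 2:nrow(p)
  d <- vapply(fg, function(cc) {
    (2 * sum(p[cc, ] * t[cc, ]) + eps) /
      (sum(p[cc, ]) + sum(t[cc, ]) + eps)
  }, numeric(1))
  list(ce = ce, dice = mean(d), loss = ce + 1 - mean(d))
}

#' Dice + cross-entropy segmentation loss
#'
#' Sum of the mean voxel-wise negative log-likelihood and a soft-Dice term
#' `1 - mean over foreground classes of (2 sum(p t) + eps) / (sum(p) + sum(t)
#' + eps)`. The background class is excluded from the Dice term (standard for
#' sparse lesions) and the smoothing `eps = 1` keeps lesion-free patches
#' finite and well-behaved. For a list (batch), the mean item loss is
#' returned, so the loss is invariant under batch duplication and item
#' permutation.
#'
#' @param pred probability map(s): 4D channel-last array, (C x N) matrix, or
#'   list of these.
#' @param target one-hot target(s) of matching shape.
#' @param eps Dice smoothing constant.
#' @return Scalar loss (non-negative up to the Dice eps-residual).
#' @export
dice_ce_loss <- function(pred, target, eps = 1) {
  if (is.list(pred)) {
    stopifnot(is.list(target), length(pred) == length(target))
    return(mean(mapply(function(p, t) dice_ce_loss(p, t, eps), pred, target)))
  }
  dice_ce_item(as_class_matrix(pred), as_class_matrix(target), eps)$loss
}

# Loss and its gradient with respect to the pre-softmax logits.
dice_ce_grad <- function(probs, target, eps = 1) {
  n <- ncol(probs)
  nc <- nrow(probs)
  fg <- 2:nc
  parts <- dice_ce_item(probs, target, eps)
  # CE through softmax: (P - T)/n
  dlogits <- (probs - target) / n
  # Dice part: dL/dP, then chain through the softmax Jacobian
  g <- matrix(0, nc, n)
  for (cc in fg) {
    num <- 2 * sum(probs[cc, ] * target[cc, ]) + eps
    den <- sum(probs[cc, ]) + sum(target[cc, ]) + eps
    g[cc, ] <- -(2 * target[cc, ] * den - num) / (den^2 * length(fg))
  }
  gp <- colSums(g * probs)
  dlogits <- dlogits + probs * (g - rep(gp, each = nc))
  list(loss = parts$loss, ce = parts$ce, dice = parts$dice, dlogits = dlogits)
}

#' Soft Dice similarity coefficient
#'
#' Mean over foreground classes of `2 sum(p t) / (sum(p) + sum(t) + eps)`
#' computed on continuous probabilities; equals the hard DSC up to the
#' `eps` regularization when `pred` is binary, and scores 0 for a foreground
#' class that is absent from both maps. Used to monitor validation
#' performance during training. Batches (lists) are averaged item-wise.
#'
#' @inheritParams dice_ce_loss
#' @return Scalar in \[0, 1\].
#' @export
soft_dsc <- function(pred, target, eps = 1) {
  if (is.list(pred)) {
    return(mean(mapply(function(p, t) soft_dsc(p, t, eps), pred, target)))
  }
  p <- as_class_matrix(pred); t <- as_class_matrix(target)
  if (!identical(dim(p), dim(t))) stop("prediction/target shape mismatch")
  fg <- 2:nrow(p)
  mean(vapply(fg, function(cc) {
    2 * sum(p[cc, ] * t[cc, ]) / (sum(p[cc, ]) + sum(t[cc, ]) + eps)
  }, numeric(1)))
}

#' @export
print.mtv_model <- function(x, ...) {
  cfg <- x$config
  ch <- level_channels(cfg)
  bs <- bottleneck_shape(cfg)
  cat("Residual 3D U-Net with MHSA bottleneck\n")
  cat(sprintf("  patch %s, %d levels, channels %s\n",
              paste(cfg$patch_shape, collapse = "x"), cfg$levels,
              paste(ch, collapse = "/")))
  cat(sprintf("  bottleneck %s = %d tokens, %d heads x %d dims\n",
              paste(bs, collapse = "x"), prod(bs), cfg$attention_heads,
              cfg$attention_dim))
  cat(sprintf("  parameters: %d\n", length(flatten_tree(x$params))))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration, the weights, and optionally
#' the training log, so a saved model is self-describing.
#'
#' @param model an `mtv_model`.
#' @param path file path (.rds).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "mtv_model")) stop("not a model checkpoint: ", path)
  m
}

# ---- parameter-tree utilities ----

flatten_tree <- function(x) {
  if (is.list(x)) {
    return(unlist(lapply(x, flatten_tree), use.names = FALSE))
  }
  as.numeric(x)
}

unflatten_into <- function(vec, skel, pos = 1L) {
  if (is.list(skel)) {
    out <- skel
    for (i in seq_along(skel)) {
      r <- unflatten_into(vec, skel[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    return(list(value = out, pos = pos))
  }
  n <- length(skel)
  if (n == 0L) return(list(value = skel, pos = pos))
  v <- vec[pos:(pos + n - 1L)]
  attributes(v) <- attributes(skel)
  if (!is.null(dim(skel))) dim(v) <- dim(skel)
  list(value = v, pos = pos + n)
}

unflatten_tree <- function(vec, skel) unflatten_into(vec, skel)$value

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}
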