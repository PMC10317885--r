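# Shared fixtures, all built in code.

geom25 <- function(shape = c(16L, 16L, 16L)) {
  grid_geometry(shape, c(2.5, 2.5, 2.5))
}

# Label map from an integer array at 2.5 mm spacing.
lmap <- function(arr) {
  label_map(arr, geom25(dim(arr)))
}

# A random 3-class label map with a few blob-like components.
random_label_map <- function(shape = c(16L, 16L, 16L), n_blobs = 3,
                             p_class2 = 0.5) {
  arr <- array(0L, shape)
  for (b in seq_len(n_blobs)) {
    cls <- if (stats::runif(1) < p_class2) 2L else 1L
    c0 <- sapply(shape, function(n) sample.int(n, 1))
    r <- sample(1:3, 1)
    for (ax in 1:3) c0[ax] <- min(max(c0[ax], 1), shape[ax])
    xs <- pmax(1, c0[1] - r):pmin(shape[1], c0[1] + r)
    ys <- pmax(1, c0[2] - r):pmin(shape[2], c0[2] + r)
    zs <- pmax(1, c0[3] - r):pmin(shape[3], c0[3] + r)
    arr[xs, ys, zs] <- cls
  }
  arr
}

# Brute-force connected-component labelling via repeated neighbour sweeps
# (union-find over explicit voxel pairs); independent of the package's
# frontier-expansion implementation.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- arrayInd(idx, d)
  key <- function(x, y, z) (z - 1) * d[1] * d[2] + (y - 1) * d[1] + x
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (i in seq_along(idx)) {
    for (o in seq_len(nrow(offs))) {
      nx <- pos[i, 1] + offs[o, 1]; ny <- pos[i, 2] + offs[o, 2]
      nz <- pos[i, 3] + offs[o, 3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      j <- mget(as.character(key(nx, ny, nz)), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  out <- array(0L, d)
  out[idx] <- as.integer(factor(roots))
  out
}

# Tiny training samples: a bright box on dark background, patch-shaped.
toy_samples <- function(n, patch_shape, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    lab <- array(0L, patch_shape)
    c0 <- sapply(patch_shape, function(d) sample(2:(d - 1), 1))
    r <- 1L
    xs <- (c0[1] - r):(c0[1] + r); ys <- (c0[2] - r):(c0[2] + r)
    zs <- pmax(1, c0[3] - 1):pmin(patch_shape[3], c0[3] + 1)
    lab[xs, ys, zs] <- 1L
    pet <- array(stats::runif(prod(patch_shape), 0, 0.08), patch_shape)
    pet[lab == 1L] <- stats::runif(sum(lab == 1L), 0.7, 1)
    ct <- array(stats::runif(prod(patch_shape), 0.4, 0.6), patch_shape)
    list(pet = pet, ct = ct, target = one_hot_encode(lab))
  }))
}
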