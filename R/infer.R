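#' Gaussian fusion weights for a patch
#'
#' Separable 3D Gaussian centred on the patch with per-axis full-width at
#' half-maximum equal to the patch side length, i.e.
#' `sigma_d = L_d / (2 sqrt(2 ln 2))`: along each axis the weight falls to
#' half the central value at a distance of half the patch side. The grid is
#' scaled so its maximum is 1; predictions near the patch centre, where the
#' network is most reliable, therefore dominate in overlap regions.
#'
#' @param patch_shape integer length-3 patch dimensions.
#' @return 3D weight array with peak value 1.
#' @export
gaussian_patch_weights <- function(patch_shape) {
  patch_shape <- as.integer(patch_shape)
  if (any(patch_shape < 1L)) stop("patch shape must be positive")
  ax <- lapply(patch_shape, function(L) {
    d <- seq_len(L) - (L + 1) / 2
    exp(-4 * log(2) * d^2 / L^2)
  })
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  w / max(w)
}

#' Fuse overlapping patch probability maps into one volume
#'
#' Every voxel's fused probability is the Gaussian-weighted average of all
#' patch predictions covering it: `sum_i w_i(v) p_i(v) / sum_i w_i(v)`. The
#' quotient form makes per-patch weight normalization irrelevant, preserves
#' the probability simplex, and reduces to the input probabilities wherever a
#' single patch contributes.
#'
#' @param patch_probs list of patch predictions, each a list with `probs`
#'   (4D array `(x, y, z, class)`) and 0-based voxel `offset` locating the
#'   patch in the output volume.
#' @param out_shape integer length-3 shape of the fused volume.
#' @return 4D fused probability array `(out_shape, class)`.
#' @export
fuse_patches <- function(patch_probs, out_shape) {
  out_shape <- as.integer(out_shape)
  if (length(patch_probs) == 0) stop("no patches supplied")
  nc <- dim(patch_probs[[1]]$probs)[4]
  if (length(patch_probs) == 1 &&
      identical(as.integer(dim(patch_probs[[1]]$probs)[1:3]), out_shape) &&
      all(patch_probs[[1]]$offset == 0)) {
    return(patch_probs[[1]]$probs)  # weights cancel exactly
  }
  num <- array(0, dim = c(out_shape, nc))
  den <- array(0, dim = out_shape)
  w_cache <- list()
  for (pp in patch_probs) {
    pd <- dim(pp$probs)[1:3]
    key <- paste(pd, collapse = "x")
    if (is.null(w_cache[[key]])) w_cache[[key]] <- gaussian_patch_weights(pd)
    w <- w_cache[[key]]
    off <- as.integer(pp$offset)
    ix <- off[1] + seq_len(pd[1])
    iy <- off[2] + seq_len(pd[2])
    iz <- off[3] + seq_len(pd[3])
    if (min(ix, iy, iz) < 1L || ix[pd[1]] > out_shape[1] ||
        iy[pd[2]] > out_shape[2] || iz[pd[3]] > out_shape[3]) {
      stop("patch at offset (", paste(off, collapse = ","),
           ") exceeds the output volume")
    }
    den[ix, iy, iz] <- den[ix, iy, iz] + w
    for (cc in seq_len(nc)) {
      num[ix, iy, iz, cc] <- num[ix, iy, iz, cc] + w * pp$probs[, , , cc]
    }
  }
  if (any(den == 0)) stop("patches do not cover every voxel of the volume")
  for (cc in seq_len(nc)) num[, , , cc] <- num[, , , cc] / den
  num
}

#' Average probability maps from an ensemble of models
#'
#' Unweighted voxel-wise mean of the per-model fused probability maps, as
#' used when pooling the cross-validation models on external data. The mean
#' of simplex-valued maps is simplex-valued.
#'
#' @param model_probs non-empty list of equally shaped probability arrays.
#' @return Probability array of the same shape.
#' @export
ensemble_average <- function(model_probs) {
  if (length(model_probs) == 0) stop("empty model list")
  d <- dim(model_probs[[1]])
  for (m in model_probs) {
    if (!identical(dim(m), d)) stop("probability maps differ in shape")
  }
  Reduce(`+`, model_probs) / length(model_probs)
}

#' Assign each voxel to its most probable class
#'
#' Voxel label is the argmax over class probabilities (0 background,
#' 1 primary tumor, 2 LN metastasis). Exact ties are broken toward the lower
#' class index, i.e. toward background — the conservative choice for a
#' diagnostic tool.
#'
#' @param prob 4D probability array `(x, y, z, class)`.
#' @param geometry optional [grid_geometry()]; when supplied a [label_map()]
#'   is returned, otherwise a plain integer array.
#' @return [label_map()] or integer array of class indices starting at 0.
#' @export
assign_classes <- function(prob, geometry = NULL) {
  d <- dim(prob)
  m <- matrix(prob, nrow = prod(d[1:3]), ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  arr <- array(as.integer(lab), dim = d[1:3])
  if (is.null(geometry)) return(arr)
  label_map(arr, geometry)
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  g
}

#' Label connected components of a 3D mask
#'
#' Frontier-expansion labelling under 26- (default) or 6-connectivity.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return Integer array of component labels; background is 0.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  fg <- array(as.logical(mask), dim = d)
  lab <- array(0L, dim = d)
  offs <- neighbor_offsets(connectivity)
  remaining <- which(fg)
  comp <- 0L
  nxy <- d[1] * d[2]
  for (seed in remaining) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    lab[seed] <- comp
    frontier <- seed
    while (length(frontier) > 0) {
      i0 <- frontier - 1L
      x <- i0 %% d[1] + 1L
      y <- (i0 %/% d[1]) %% d[2] + 1L
      z <- i0 %/% nxy + 1L
      nx <- rep(x, each = nrow(offs)) + offs[, 1]
      ny <- rep(y, each = nrow(offs)) + offs[, 2]
      nz <- rep(z, each = nrow(offs)) + offs[, 3]
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
        nz >= 1L & nz <= d[3]
      lin <- unique((nz[ok] - 1L) * nxy + (ny[ok] - 1L) * d[1] + nx[ok])
      lin <- lin[fg[lin] & lab[lin] == 0L]
      lab[lin] <- comp
      frontier <- lin
    }
  }
  lab
}

#' Remove regions smaller than a volume threshold
#'
#' Computes connected components per class and relabels components whose
#' volume is strictly below `min_ml` (default 0.1 ml) to background, matching
#' the analysis rule that regions under 0.1 ml — manual or automatic — are
#' excluded. At 2.5 mm isotropic spacing this removes components of 6 voxels
#' (0.09375 ml) and keeps 7-voxel ones (0.109 ml).
#'
#' @param labels a [label_map()].
#' @param min_ml volume threshold in ml.
#' @param connectivity component connectivity, 26 (default) or 6.
#' @return Filtered [label_map()].
#' @export
filter_small_rois <- function(labels, min_ml = 0.1, connectivity = 26L) {
  stopifnot(inherits(labels, "label_map"))
  arr <- labels$labels
  vox_ml <- prod(labels$geometry$spacing) / 1000
  for (cls in sort(unique(arr[arr > 0L]))) {
    cc <- connected_components(arr == cls, connectivity)
    if (max(cc) == 0L) next
    sizes <- tabulate(cc[cc > 0L])
    drop <- which(sizes * vox_ml < min_ml)
    if (length(drop)) arr[cc %in% drop] <- 0L
  }
  label_map(arr, labels$geometry)
}

#' Predict a full label map from preprocessed PET/CT
#'
#' Runs the complete inference chain on one preprocessed (common-grid,
#' cropped, normalized) volume pair: axial patch extraction, per-patch
#' forward passes for every model, Gaussian-weighted fusion per model,
#' ensemble averaging across models, argmax class assignment, and small-ROI
#' exclusion.
#'
#' @param models a single `mtv_model` or a list of them (an ensemble).
#' @param pet01,ct01 normalized [scalar_volume()]s in \[0, 1\] whose in-plane
#'   shape equals the models' patch in-plane shape.
#' @param axial_overlap minimum fractional axial patch overlap.
#' @param min_ml small-ROI exclusion threshold in ml.
#' @param connectivity component connectivity for the exclusion step.
#' @return list with `labels` (filtered [label_map()]) and `probs` (4D fused
#'   probability array).
#' @export
predict_volume <- function(models, pet01, ct01, axial_overlap = 0.75,
                           min_ml = 0.1, connectivity = 26L) {
  if (inherits(models, "mtv_model")) models <- list(models)
  cfg <- models[[1]]$config
  stack <- list(pet = pet01$values, ct = ct01$values)
  patches <- extract_patches(stack, patch_shape = cfg$patch_shape,
                             axial_overlap = axial_overlap)
  depth <- attr(patches, "source_depth")
  fused_shape <- c(cfg$patch_shape[1:2], max(depth, cfg$patch_shape[3]))
  per_model <- lapply(models, function(m) {
    pp <- lapply(patches, function(s) {
      list(probs = predict_patch(m, s$pet, s$ct), offset = s$offset)
    })
    fuse_patches(pp, fused_shape)
  })
  probs <- ensemble_average(per_model)
  probs <- probs[, , seq_len(depth), , drop = FALSE]  # undo axial padding
  labels <- assign_classes(probs, pet01$geometry)
  list(labels = filter_small_rois(labels, min_ml, connectivity), probs = probs)
}
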