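#' Resample a volume or label map to a common grid
#'
#' Resamples onto an axis-aligned grid with the requested voxel spacing
#' (default 2.5 mm isotropic, the common analysis grid). Scalar volumes are
#' interpolated trilinearly; label maps with nearest-neighbour so labels stay
#' integral. The output shape is chosen so the world-space extent is preserved
#' to within one voxel, and the origin is kept.
#'
#' @param x a [scalar_volume()] or [label_map()].
#' @param target_spacing numeric length-3 spacing in mm, all > 0.
#' @return Object of the same class as `x` on the new grid.
#' @export
resample_to_common_grid <- function(x, target_spacing = c(2.5, 2.5, 2.5)) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    stop("target spacing must be positive")
  }
  geom <- x$geometry
  if (all(abs(geom$spacing - target_spacing) < 1e-9)) return(x)

  out_shape <- pmax(1L, as.integer(round(geom$shape * geom$spacing / target_spacing)))
  out_geom <- grid_geometry(out_shape, target_spacing, geom$origin)
  # Continuous input index (1-based) of each output voxel centre, per axis.
  idx <- lapply(1:3, function(ax) {
    world <- (seq_len(out_shape[ax]) - 1) * target_spacing[ax]
    pmin(pmax(world / geom$spacing[ax] + 1, 1), geom$shape[ax])
  })

  if (inherits(x, "label_map")) {
    gather <- lapply(idx, function(v) as.integer(round(v)))
    out <- x$labels[gather[[1]], gather[[2]], gather[[3]], drop = FALSE]
    dim(out) <- out_shape
    return(label_map(out, out_geom))
  }

  lo <- lapply(1:3, function(ax) pmin(as.integer(floor(idx[[ax]])), geom$shape[ax] - 1L))
  lo <- lapply(1:3, function(ax) pmax(lo[[ax]], 1L))
  fr <- lapply(1:3, function(ax) idx[[ax]] - lo[[ax]])
  vol <- x$values
  out <- array(0, dim = out_shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wx, wy), wz)
    g <- vol[pmin(lo[[1]] + dx, geom$shape[1]),
             pmin(lo[[2]] + dy, geom$shape[2]),
             pmin(lo[[3]] + dz, geom$shape[3]), drop = FALSE]
    dim(g) <- out_shape
    out <- out + w * g
  }
  res <- scalar_volume(out, out_geom, x$modality)
  res
}

# Offsets are 0-based voxel triples locating output voxel (1,1,1) inside the
# volume the operation was applied to; negative entries indicate padding.
get_offset <- function(x) {
  off <- attr(x, "source_offset")
  if (is.null(off)) c(0L, 0L, 0L) else off
}

set_offset <- function(x, off) {
  attr(x, "source_offset") <- as.integer(off)
  x
}

crop_pad_axis <- function(arr, ax, size, fill) {
  n <- dim(arr)[ax]
  if (size == n) return(list(arr = arr, offset = 0L))
  if (size < n) {
    start <- (n - size) %/% 2L
    idx <- seq_len(size) + start
    arr <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    return(list(arr = arr, offset = start))
  }
  pad <- size - n
  left <- pad %/% 2L
  d <- dim(arr); d[ax] <- size
  out <- array(fill, dim = d)
  idx <- seq_len(n) + left
  if (ax == 1) out[idx, , ] <- arr else if (ax == 2) out[, idx, ] <- arr
  else out[, , idx] <- arr
  list(arr = out, offset = -left)
}

rebuild_like <- function(x, arr, offset_delta) {
  geom <- x$geometry
  new_geom <- grid_geometry(dim(arr), geom$spacing,
                           geom$origin + offset_delta * geom$spacing)
  out <- if (inherits(x, "label_map")) label_map(arr, new_geom)
         else scalar_volume(arr, new_geom, x$modality)
  set_offset(out, get_offset(x) + offset_delta)
}

#' Central crop (or pad) in the transaxial plane
#'
#' Crops the volume symmetrically in x and y to `size_xy` voxels per side
#' (default 128, i.e. 32 x 32 cm coverage at 2.5 mm spacing). Inputs smaller
#' than the target are padded symmetrically instead — with zeros for scalar
#' volumes and background for label maps. The voxel offset into the source
#' grid is recorded on the result (attribute `source_offset`) so patch
#' coordinates remain invertible back to the original grid.
#'
#' @param x a [scalar_volume()] or [label_map()].
#' @param size_xy target in-plane matrix size.
#' @return Cropped/padded object of the same class.
#' @export
central_crop_transaxial <- function(x, size_xy = 128L) {
  arr <- if (inherits(x, "label_map")) x$labels else x$values
  fill <- if (inherits(x, "label_map")) 0L else 0
  cx <- crop_pad_axis(arr, 1L, as.integer(size_xy), fill)
  cy <- crop_pad_axis(cx$arr, 2L, as.integer(size_xy), fill)
  rebuild_like(x, cy$arr, c(cx$offset, cy$offset, 0L))
}

#' Axial crop to a slice range
#'
#' Retains axial slices in the half-open 0-based interval
#' `[z_range[1], z_range[2])`. The study applied a variable axial crop
#' preserving the head-and-neck region; the rule deciding that region is not
#' part of this package, so the range is an explicit parameter (phantoms
#' default to the full extent).
#'
#' @param x a [scalar_volume()] or [label_map()].
#' @param z_range integer length-2, `0 <= z_range[1] < z_range[2] <= shape_z`.
#' @return Cropped object of the same class.
#' @export
axial_crop <- function(x, z_range) {
  nz <- x$geometry$shape[3]
  z0 <- as.integer(z_range[1]); z1 <- as.integer(z_range[2])
  if (z0 < 0 || z1 > nz || z0 >= z1) stop("invalid axial range")
  arr <- if (inherits(x, "label_map")) x$labels else x$values
  arr <- arr[, , (z0 + 1L):z1, drop = FALSE]
  rebuild_like(x, arr, c(0L, 0L, z0))
}

minmax01 <- function(v) {
  rng <- range(v)
  if (!all(is.finite(rng))) stop("non-finite input values")
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' CT windowing and per-volume intensity normalization
#'
#' Clips CT values to the soft-tissue window (default \[-150, 150\] HU), then
#' min-max scales both CT and PET individually to \[0, 1\]. Per-volume
#' scaling makes network inputs contrast-relative: the model sees relative
#' uptake, not absolute SUV. Constant volumes map to all-zeros.
#'
#' @param pet PET [scalar_volume()].
#' @param ct CT [scalar_volume()] on the same grid.
#' @param hu_window length-2 clipping window in HU.
#' @return list with `pet` and `ct` [scalar_volume()]s holding values in \[0, 1\].
#' @export
window_and_normalize <- function(pet, ct, hu_window = c(-150, 150)) {
  stopifnot(identical(pet$geometry$shape, ct$geometry$shape))
  ctv <- pmin(pmax(ct$values, hu_window[1]), hu_window[2])
  pet01 <- set_offset(scalar_volume(minmax01(pet$values), pet$geometry, "PET_SUV"),
                      get_offset(pet))
  ct01 <- set_offset(scalar_volume(minmax01(ctv), ct$geometry, "CT_HU"),
                     get_offset(ct))
  list(pet = pet01, ct = ct01)
}

#' One-hot encode a label map
#'
#' @param labels a [label_map()] or integer array with values in \{0, 1, 2\}.
#' @param num_classes number of classes.
#' @return 4D array `(x, y, z, class)` of 0/1 with channels summing to 1.
#' @export
one_hot_encode <- function(labels, num_classes = 3L) {
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  if (any(arr < 0 | arr >= num_classes)) stop("label out of range")
  out <- array(0, dim = c(dim(arr), num_classes))
  n <- length(arr)
  out[seq_len(n) + n * as.numeric(arr)] <- 1
  out
}

#' Extract overlapping axial patches
#'
#' Slides a `patch_shape` window along the axial (z) axis with stride
#' `floor(patch_depth * (1 - axial_overlap))` — depth 32 with 75% overlap
#' gives stride 8. The final patch is aligned flush with the last slice so
#' every slice is covered; in-plane dimensions must already match the patch
#' (use [central_crop_transaxial()]), and volumes shallower than one patch
#' are zero-padded at the end.
#'
#' @param stack list with 3D arrays `pet` and `ct` (values in \[0, 1\]) and
#'   optionally `target` (4D one-hot array), all on the same grid.
#' @param patch_shape integer length-3 patch dimensions.
#' @param axial_overlap minimum fractional overlap between consecutive
#'   patches, in `[0, 1)`; default 0.75.
#' @return list of patch samples; each has `pet`, `ct`, optional `target`,
#'   and a 0-based `offset` voxel triple locating the patch in the input
#'   volume. The original (pre-padding) depth is kept in attribute
#'   `source_depth`.
#' @export
extract_patches <- function(stack, patch_shape = c(128L, 128L, 32L),
                            axial_overlap = 0.75) {
  patch_shape <- as.integer(patch_shape)
  d <- dim(stack$pet)
  if (!identical(as.integer(d[1:2]), patch_shape[1:2])) {
    stop("in-plane shape must equal the patch in-plane shape; crop first")
  }
  stride <- as.integer(floor(patch_shape[3] * (1 - axial_overlap)))
  if (stride < 1L) stop("axial overlap too large: stride would be zero")
  depth <- d[3]
  if (depth < patch_shape[3]) {
    pad <- patch_shape[3] - depth
    padz <- function(a) {
      dd <- dim(a); dd[3] <- patch_shape[3]
      out <- array(0, dim = dd)
      if (length(dd) == 3L) out[, , seq_len(depth)] <- a
      else out[, , seq_len(depth), ] <- a
      out
    }
    stack$pet <- padz(stack$pet)
    stack$ct <- padz(stack$ct)
    if (!is.null(stack$target)) {
      stack$target <- padz(stack$target)
      # padded voxels are background
      stack$target[, , depth + seq_len(pad), 1] <- 1
    }
    depth_eff <- patch_shape[3]
  } else depth_eff <- depth

  offsets <- seq(0L, depth_eff - patch_shape[3], by = stride)
  if (offsets[length(offsets)] != depth_eff - patch_shape[3]) {
    offsets <- c(offsets, depth_eff - patch_shape[3])
  }
  patches <- lapply(offsets, function(z0) {
    zi <- z0 + seq_len(patch_shape[3])
    s <- list(pet = stack$pet[, , zi, drop = FALSE],
              ct = stack$ct[, , zi, drop = FALSE],
              offset = c(0L, 0L, as.integer(z0)))
    if (!is.null(stack$target)) s$target <- stack$target[, , zi, , drop = FALSE]
    s
  })
  attr(patches, "source_depth") <- depth
  patches
}
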