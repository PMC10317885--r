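#' Grid geometry of a 3D image volume
#'
#' Describes the voxel lattice a volume lives on: its shape in voxels, the
#' voxel spacing in millimetres, and the world-space position of the first
#' voxel. The package's internal axis convention is (x, y, z) with z the
#' cranio-caudal (axial) axis; transaxial crops act on x/y and axial crops
#' on z.
#'
#' @param shape integer vector of length 3, voxels along (x, y, z); all >= 1.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm; all > 0.
#' @param origin numeric vector of length 3, world coordinates (mm) of the
#'   centre of voxel (1,1,1).
#' @return An object of class `grid_geometry`.
#' @examples
#' geom <- grid_geometry(c(128, 128, 32), c(2.5, 2.5, 2.5))
#' voxels_to_ml(64, geom)
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all spacings must be positive and finite")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Scalar image volume (PET or CT)
#'
#' A 3D scalar grid plus its geometry and modality tag. PET volumes are
#' SUV-scaled and must be non-negative; CT volumes are in Hounsfield units.
#'
#' @param values 3D numeric array matching `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @param modality `"PET_SUV"` or `"CT_HU"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, geometry, modality = c("PET_SUV", "CT_HU")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!identical(as.integer(dim(values)), geometry$shape)) {
    stop("value array shape must equal geometry$shape")
  }
  if (any(!is.finite(values))) stop("non-finite voxel values")
  if (modality == "PET_SUV" && any(values < 0)) {
    stop("PET_SUV values must be >= 0")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, geometry = geometry, modality = modality),
            class = "scalar_volume")
}

#' Integer class label map
#'
#' Voxel-wise class assignment on a grid: 0 background, 1 primary tumor,
#' 2 lymph-node metastasis.
#'
#' @param labels 3D array of integers in \{0, 1, 2\}.
#' @param geometry a [grid_geometry()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, geometry) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (!identical(as.integer(dim(labels)), geometry$shape)) {
    stop("label array shape must equal geometry$shape")
  }
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(!(labels %in% 0:2))) {
    stop("labels must all lie in {0, 1, 2}")
  }
  structure(list(labels = labels, geometry = geometry), class = "label_map")
}

#' Convert a voxel count to millilitres
#'
#' One voxel occupies `prod(spacing)` cubic millimetres; 1 ml = 1000 mm^3.
#' At the 2.5 mm isotropic analysis grid, 64 voxels are exactly 1 ml, and the
#' 0.1 ml exclusion threshold for small regions corresponds to 6.4 voxels.
#'
#' @param count non-negative voxel count (vectorised).
#' @param geometry a [grid_geometry()].
#' @return Volume in ml.
#' @export
voxels_to_ml <- function(count, geometry) {
  count * prod(geometry$spacing) / 1000
}

nifti_geometry <- function(img) {
  dm <- dim(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  grid_geometry(dm, abs(pd[seq_len(3)]))
}

#' Read a 3D volume from NIfTI
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz) into a [scalar_volume()]. The voxel
#' spacing is taken from the header; axes whose header affine points in the
#' negative world direction are flipped on read so internal arrays follow one
#' right-handed (x, y, z) convention.
#'
#' @param path file path to a 3D NIfTI image.
#' @param modality `"PET_SUV"` or `"CT_HU"`.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, modality = c("PET_SUV", "CT_HU")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D image, got ", length(dim(img)), "D")
  arr <- normalize_axes(img)
  if (any(!is.finite(arr))) stop("non-finite voxel values in ", path)
  scalar_volume(arr, nifti_geometry(img), modality)
}

#' Read a label map from NIfTI
#'
#' @param path file path to a 3D NIfTI image holding integer labels 0/1/2.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D image, got ", length(dim(img)), "D")
  arr <- round(normalize_axes(img))
  label_map(arr, nifti_geometry(img))
}

# Flip axes whose direction cosines are negative so that data follow a
# right-handed convention regardless of how the file was stored.
normalize_axes <- function(img) {
  arr <- as.array(img)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (!is.null(xf) && all(dim(xf) >= c(3L, 3L))) {
    for (ax in 1:3) {
      if (xf[ax, ax] < 0) {
        idx <- rev(seq_len(dim(arr)[ax]))
        arr <- switch(ax, arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
      }
    }
  }
  attributes(arr) <- list(dim = dim(arr))  # drop NIfTI header attributes
  arr
}

#' Write a volume or label map to NIfTI
#'
#' @param x a [scalar_volume()] or [label_map()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "label_map")) x$labels else x$values
  geom <- x$geometry
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
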