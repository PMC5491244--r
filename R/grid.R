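#' Voxel grid geometry
#'
#' Light container for the geometry shared by all volumes in a phantom:
#' array dimensions, isotropic-or-not voxel spacing and the physical
#' coordinate of the first voxel centre.  Axes follow the LPS convention
#' (x = patient left, y = posterior, z = superior); the axial plane is the
#' x-y plane, so coplanar beam angles are unambiguous.  All lengths are in
#' centimetres.
#'
#' @param dim integer(3), voxels per axis.
#' @param spacing numeric(3) or scalar, voxel size in cm (default 0.2 cm).
#' @param origin numeric(3), physical coordinate (cm) of voxel (1,1,1).
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, spacing = 0.2, origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim > 0))
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (is.null(origin)) origin <- -(dim - 1) * spacing / 2  # centre the grid
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_geometry")
}

#' Voxel volume of a grid in cubic centimetres
#' @param geom a [grid_geometry()].
#' @return scalar, cm^3 per voxel.
#' @export
voxel_volume_cm3 <- function(geom) prod(geom$spacing)

#' Physical coordinates of voxel centres along one axis
#' @param geom a [grid_geometry()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of length `geom$dim[axis]`, in cm.
#' @export
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$dim[axis]) - 1) * geom$spacing[axis]
}

#' Volume of a binary mask
#' @param mask logical array on the grid.
#' @param geom a [grid_geometry()].
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask, geom) sum(mask) * voxel_volume_cm3(geom)

# physical coordinates (n x 3 matrix, cm) of voxels selected by a mask
mask_coords <- function(mask, geom) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(geom$origin[1] + (idx[, 1] - 1) * geom$spacing[1],
        geom$origin[2] + (idx[, 2] - 1) * geom$spacing[2],
        geom$origin[3] + (idx[, 3] - 1) * geom$spacing[3])
}

#' Write a volume to a NIfTI file
#'
#' Volumes (HU grids, label maps, masks, dose maps) are exchanged as NIfTI,
#' a standard medical-image format; voxel spacing is recorded in mm.
#'
#' @param vol 3D array.
#' @param geom a [grid_geometry()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, geom, path) {
  if (is.logical(vol)) vol <- array(as.integer(vol), dim(vol))  # masks
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- geom$spacing * 10  # cm -> mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path NIfTI file path.
#' @return list with `vol` (3D array) and `geom` (a [grid_geometry()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3] / 10  # mm -> cm
  vol <- array(as.numeric(img), dim = dim(img))
  list(vol = vol, geom = grid_geometry(dim(img), spacing))
}
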