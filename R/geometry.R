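#' Grid geometry of a volume
#'
#' Bundles the voxel grid dimensions with the 4x4 voxel-to-world affine
#' (NIfTI convention: 0-based voxel indices map to mm coordinates in the
#' template space, typically MNI).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric voxel-to-world transform. Must be invertible.
#' @return An object of class \code{grid_geometry} with fields \code{shape},
#'   \code{affine} and \code{voxel_size} (mm, derived from the affine).
#' @export
grid_geometry <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  affine <- as.matrix(affine)
  storage.mode(affine) <- "double"
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps^0.5)
    stop("'affine' is singular: not a valid voxel-to-world transform")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(shape = shape, affine = affine, voxel_size = voxel_size),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("<grid_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Test whether two grid geometries coincide
#'
#' @param a,b \code{grid_geometry} objects.
#' @param tol numeric tolerance on affine entries.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

# 0-based voxel index matrix (n x 3) -> world coordinates (n x 3)
voxel_to_world <- function(geometry, ijk) {
  ijk <- cbind(ijk, 1)
  t(geometry$affine %*% t(ijk))[, 1:3, drop = FALSE]
}

# world (n x 3) -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(geometry, xyz) {
  inv <- solve(geometry$affine)
  xyz <- cbind(xyz, 1)
  t(inv %*% t(xyz))[, 1:3, drop = FALSE]
}

# geometry extracted from an RNifti image
geometry_from_nifti <- function(img) {
  d <- dim(img)
  grid_geometry(d[1:3], structure(RNifti::xform(img), imagedim = NULL,
                                  code = NULL))
}

stop_geometry <- function(what) {
  stop(sprintf("geometry mismatch: %s", what), call. = FALSE)
}
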