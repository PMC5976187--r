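#' 3D scalar volume on an anisotropic axis-aligned grid
#'
#' A `vol3d` is the carrier for images, cost maps and action maps: a 3D
#' array of finite reals together with voxel spacing (mm) and the world
#' coordinate (mm) of voxel index (0,0,0). Only axis-aligned grids are
#' supported; the world coordinate of voxel index `(i,j,k)` (0-based) is
#' `origin + (i*h_x, j*h_y, k*h_z)`.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#'   The third axis is the axial (slice) direction.
#' @param origin numeric length-3, world mm of voxel (0,0,0).
#' @param check if `TRUE`, validate finiteness of `data` (O(n); skip for
#'   internally constructed volumes known to be finite).
#' @return An object of class `vol3d`.
#' @examples
#' v <- vol3d(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.9))
#' voxel_to_world(v, c(1, 1, 1))
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                  check = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values")
  if (check && !all(is.finite(data)))
    stop("'data' must be finite everywhere")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel indices are 0-based and continuous; rounding a result of
#' `world_to_voxel()` to the nearest integer gives the containing voxel.
#' The two functions are exact inverses. Points may be given as a length-3
#' vector or an n x 3 matrix. Out-of-bounds coordinates are returned
#' unclamped; callers are expected to check bounds where it matters.
#'
#' @param v a [vol3d] volume.
#' @param point world-mm coordinates (length-3 vector or n x 3 matrix).
#' @param index continuous 0-based voxel coordinates (same shapes).
#' @return Coordinates in the other frame, same shape as the input.
#' @export
world_to_voxel <- function(v, point) {
  stopifnot(inherits(v, "vol3d"))
  if (is.matrix(point))
    sweep(sweep(point, 2, v$origin), 2, v$spacing, "/")
  else (as.numeric(point) - v$origin) / v$spacing
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(v, index) {
  stopifnot(inherits(v, "vol3d"))
  if (is.matrix(index))
    sweep(sweep(index, 2, v$spacing, "*"), 2, v$origin, "+")
  else as.numeric(index) * v$spacing + v$origin
}

# TRUE if the (0-based, continuous) voxel coordinate lies inside the grid.
in_bounds <- function(v, index, margin = 0) {
  d <- dim(v$data)
  all(index >= -0.5 + margin) && all(index <= d - 0.5 - margin)
}

#' Read and write volumes as NIfTI-1
#'
#' Spacing and origin are taken from (written to) the NIfTI sform. Only
#' axis-aligned affines with positive scales are supported: a rotated or
#' flipped orientation raises an error rather than silently reinterpreting
#' the grid.
#'
#' @param path file path, `.nii` or `.nii.gz`.
#' @param v a [vol3d] to write.
#' @return `read_volume()` returns a [vol3d]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume: ", path)
  aff <- unclass(RNifti::xform(img))
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 * max(abs(rot)) ||
      any(diag(rot) <= 0))
    stop("unsupported orientation: affine is not axis-aligned with ",
         "positive scales")
  vol3d(array(as.numeric(img), dim = dim(img)),
        spacing = diag(rot), origin = aff[1:3, 4])
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vol3d"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
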