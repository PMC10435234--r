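#' Label volume objects
#'
#' A `label_volume` is a 3-D grid of non-negative integer region labels
#' (0 = background) together with the voxel size in micrometres and the
#' assignment of the dorsoventral anatomical axis to a grid axis. It is the
#' unit of volumetric measurement throughout the package: region volumes are
#' voxel counts of each label, expressed as fractions of the total brain
#' (all nonzero voxels).
#'
#' The anatomical axis assignment is taken from the `dv_axis` argument, not
#' from the NIfTI header affine: atlases in this field are typically stored
#' in a scanner-agnostic grid and the dorsoventral direction is a property
#' of the acquisition convention. By default the third grid axis is
#' dorsoventral with increasing index running dorsal to ventral.
#'
#' @param grid 3-D array of non-negative integers (label IDs; 0 = background).
#' @param voxel_size numeric length-3, voxel edge lengths in micrometres.
#' @param dv_axis integer in 1:3, the grid axis that is dorsoventral.
#' @param dv_increasing_ventral logical; if `TRUE` (default) increasing index
#'   along `dv_axis` runs towards ventral.
#' @return An object of class `label_volume`.
#' @examples
#' g <- array(0L, c(4, 4, 4)); g[1:2, , ] <- 1L; g[3:4, , ] <- 2L
#' vol <- label_volume(g, voxel_size = c(2, 2, 2))
#' region_voxel_counts(vol)
#' @export
label_volume <- function(grid, voxel_size = c(1, 1, 1), dv_axis = 3L,
                         dv_increasing_ventral = TRUE) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array")
  if (any(dim(grid) < 1L)) stop("grid dimensions must all be >= 1")
  if (anyNA(grid)) stop("grid contains missing values")
  if (any(grid < 0)) stop("negative labels are not allowed")
  if (any(grid != round(grid))) stop("labels must be integer-valued")
  grid <- array(as.integer(grid), dim(grid))   # drop foreign classes/attrs
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers (micrometres)")
  dv_axis <- as.integer(dv_axis)
  if (!dv_axis %in% 1:3) stop("`dv_axis` must be 1, 2 or 3")
  structure(
    list(grid = grid, voxel_size = voxel_size, dv_axis = dv_axis,
         dv_increasing_ventral = isTRUE(dv_increasing_ventral)),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$grid)))
  labs <- labs[labs != 0L]
  cat(sprintf(
    "label_volume: %s grid, voxel %s um, %d region(s), %d brain voxel(s)\n",
    paste(dim(x$grid), collapse = "x"),
    paste(format(x$voxel_size, trim = TRUE), collapse = "x"),
    length(labs), sum(x$grid != 0L)))
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' Reads a `.nii`/`.nii.gz` file and validates that it holds non-negative
#' integer labels. Voxel size is taken from the header `pixdim` (assumed
#' micrometres); the dorsoventral axis assignment is supplied by the caller.
#'
#' @param path path to a NIfTI-1 file.
#' @inheritParams label_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, dv_axis = 3L, dv_increasing_ventral = TRUE) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) > 3L) {
    extra <- dim(dat)[-(1:3)]
    if (any(extra != 1L)) stop("label volume must be 3-D: ", path)
    dim(dat) <- dim(dat)[1:3]
  }
  if (any(!is.finite(dat)) || any(dat != round(dat)))
    stop("non-integer voxel data in ", path, ": not a label volume")
  if (any(dat < 0)) stop("negative labels in ", path)
  vs <- RNifti::pixdim(img)[1:3]
  label_volume(dat, voxel_size = vs, dv_axis = dv_axis,
               dv_increasing_ventral = dv_increasing_ventral)
}

#' Write a label volume as NIfTI
#'
#' Labels are written with the smallest integer datatype that holds the
#' maximum label; the round trip `read_label_volume(write_label_volume(x))`
#' preserves labels exactly and voxel size to within 1e-6.
#'
#' @param vol a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  maxlab <- max(vol$grid)
  dtype <- if (maxlab <= 255L) "uint8" else if (maxlab <= 32767L) "int16"
           else "int32"
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Write a real-valued voxel map as NIfTI
#'
#' Used for population difference maps and cluster maps, which are real- or
#' id-valued companions of a label volume and share its grid geometry.
#'
#' @param values 3-D numeric array.
#' @param template a [label_volume()] supplying voxel size.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(values, template, path) {
  stopifnot(inherits(template, "label_volume"))
  if (!identical(dim(values), dim(template$grid)))
    stop("map grid does not match template grid")
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- template$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
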