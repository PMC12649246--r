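#' 3-D scalar image volume
#'
#' Container for a 3-D scalar grid in Hounsfield units on an axis-aligned,
#' possibly anisotropic voxel lattice. The voxel-to-physical mapping is
#' `x_mm = origin + (index - 1) * spacing` per axis (1-based indices), so the
#' mapping is affine and invertible for positive spacing.
#'
#' @param data numeric 3-D array (HU).
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(0.17, 0.17, 0.2),
                         origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("grid dimensions must be >= 1 per axis", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_volume> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  cat("  HU range: [", signif(min(x$data), 6), ", ", signif(max(x$data), 6),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Binary label mask on an image grid
#'
#' A logical grid congruent with an [image_volume()]: same dimensions,
#' spacing and origin.
#'
#' @param data logical 3-D array.
#' @param spacing,origin grid geometry, as for [image_volume()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("mask data must be a logical 3-D array", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$data)

#' Level-set image
#'
#' Scalar grid whose zero level approximates an object boundary; negative
#' inside, positive outside.
#'
#' @param data numeric 3-D array.
#' @param spacing,origin grid geometry, as for [image_volume()].
#' @return An object of class `level_set_image`.
#' @export
level_set_image <- function(data, spacing, origin = c(0, 0, 0)) {
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "level_set_image")
}

#' @export
print.level_set_image <- function(x, ...) {
  cat("<level_set_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, value range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.level_set_image <- function(x) dim(x$data)

#' Convert between voxel indices and physical coordinates
#'
#' @param vol an `image_volume`, `label_mask` or `level_set_image`.
#' @param index numeric matrix (n x 3) of 1-based voxel indices.
#' @param points numeric matrix (n x 3) of physical mm coordinates.
#' @return A numeric n x 3 matrix in the other frame.
#' @export
index_to_physical <- function(vol, index) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname index_to_physical
#' @export
physical_to_index <- function(vol, points) {
  points <- rbind(points)
  sweep(sweep(points, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

grid_congruent <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
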