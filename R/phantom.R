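#' Specification of a synthetic carpal-bone CT phantom
#'
#' Describes a scaphoid-like object for CT-style simulation: a dense thin
#' cortical shell around a lower-intensity trabecular interior, embedded in
#' soft-tissue background, with optional additive Gaussian acquisition noise
#' and an optional adjacent "capitate-like" second body at a controlled gap
#' (for joint-space tests). Shapes are `"ellipsoid"` or `"two_lobe"` (a
#' smooth-max blend of two overlapping ellipsoids, emulating the scaphoid's
#' waisted outline).
#'
#' The cortical shell occupies the band between the outer surface and an
#' inner surface whose semi-axes are reduced by `shell_mm`; strictly inside
#' the inner surface the phantom is trabecular.
#'
#' @param shape `"ellipsoid"` or `"two_lobe"`.
#' @param semi_axes numeric length-3 outer semi-axes in mm.
#' @param shell_mm cortical shell thickness in mm; must be positive and
#'   smaller than the smallest semi-axis.
#' @param hu_cortical,hu_trabecular,hu_background intensity levels (HU);
#'   must be strictly decreasing in that order. The cortical default of
#'   2106 HU is the nominal cortical-layer intensity used throughout the
#'   package (it is also the refill value of the smooth workflow).
#' @param noise_sd standard deviation of additive zero-mean Gaussian noise
#'   (HU); 0 disables noise.
#' @param spacing voxel spacing mm (default 0.17 x 0.17 x 0.2, a
#'   high-resolution wrist protocol).
#' @param rotation Euler angles (degrees, applied z-y-x) rotating the shape
#'   within the grid.
#' @param translation shape centre offset (mm) from the grid centre.
#' @param margin_voxels margin (voxels) kept between the shape and every
#'   grid face; the grid extent is derived from shape + margin unless
#'   `extent` is given.
#' @param extent optional explicit grid dimensions (voxels); an error is
#'   raised if the shape plus margin does not fit.
#' @param lobe_offset,lobe_scale,blend two-lobe geometry: second lobe centre
#'   offset along local x (mm; default 0.3 times the first semi-axis), its
#'   relative size, and the smooth-max blend sharpness.
#' @param second_axes optional semi-axes (mm) of a second ellipsoidal body.
#' @param gap_mm surface-to-surface gap (mm) between main shape and second
#'   body along +x (required with `second_axes`).
#' @param seed integer random seed for the noise draw.
#' @param truth_oversample per-axis oversampling factor of the quadrature
#'   grid used when no closed-form volume exists (two-lobe shapes).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_condition_pair()]
#' @export
phantom_spec <- function(shape = c("ellipsoid", "two_lobe"),
                         semi_axes = c(12, 5, 5),
                         shell_mm = 0.75,
                         hu_cortical = 2106,
                         hu_trabecular = 300,
                         hu_background = 40,
                         noise_sd = 20,
                         spacing = c(0.17, 0.17, 0.2),
                         rotation = c(0, 0, 0),
                         translation = c(0, 0, 0),
                         margin_voxels = 5,
                         extent = NULL,
                         lobe_offset = NULL,
                         lobe_scale = 0.85,
                         blend = 8,
                         second_axes = NULL,
                         gap_mm = NULL,
                         seed = 1L,
                         truth_oversample = 10L) {
  shape <- match.arg(shape)
  spec <- structure(list(
    shape = shape, semi_axes = as.numeric(semi_axes),
    shell_mm = as.numeric(shell_mm),
    hu_cortical = hu_cortical, hu_trabecular = hu_trabecular,
    hu_background = hu_background, noise_sd = noise_sd,
    spacing = as.numeric(spacing), rotation = as.numeric(rotation),
    translation = as.numeric(translation),
    margin_voxels = as.integer(margin_voxels), extent = extent,
    lobe_offset = if (is.null(lobe_offset)) 0.3 * semi_axes[1] else lobe_offset,
    lobe_scale = lobe_scale, blend = blend,
    second_axes = if (is.null(second_axes)) NULL else as.numeric(second_axes),
    gap_mm = gap_mm, seed = as.integer(seed),
    truth_oversample = as.integer(truth_oversample)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$semi_axes) != 3L || any(spec$semi_axes <= 0))
    stop("semi_axes must be three positive values (mm)", call. = FALSE)
  if (spec$shell_mm <= 0 || spec$shell_mm >= min(spec$semi_axes))
    stop("cortical shell thickness must be > 0 and < the smallest semi-axis",
         call. = FALSE)
  if (!(spec$hu_cortical > spec$hu_trabecular &&
        spec$hu_trabecular > spec$hu_background))
    stop("HU levels must satisfy cortical > trabecular > background",
         call. = FALSE)
  if (any(spec$spacing <= 0))
    stop("spacing components must be positive", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(spec$second_axes)) {
    if (is.null(spec$gap_mm) || spec$gap_mm <= 0)
      stop("a second body requires a positive gap_mm", call. = FALSE)
    if (length(spec$second_axes) != 3L || any(spec$second_axes <= 0))
      stop("second_axes must be three positive values (mm)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$shape, ", semi-axes ",
      paste(signif(x$semi_axes, 4), collapse = "/"), " mm, shell ",
      x$shell_mm, " mm, noise SD ", x$noise_sd, " HU\n", sep = "")
  invisible(x)
}

euler_rotation <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# signed implicit value of the outer (or inner, shrink > 0) surface at local
# coordinates q (n x 3): negative inside. For the two-lobe blend the smooth
# minimum of the two normalized ellipsoid fields is used.
phantom_implicit <- function(spec, q, shrink = 0) {
  ax <- pmax(spec$semi_axes - shrink, 1e-6)
  f1 <- sqrt((q[, 1] / ax[1])^2 + (q[, 2] / ax[2])^2 + (q[, 3] / ax[3])^2) - 1
  if (spec$shape == "ellipsoid") return(f1)
  ax2 <- pmax(spec$lobe_scale * spec$semi_axes - shrink, 1e-6)
  qx <- q[, 1] - spec$lobe_offset
  f2 <- sqrt((qx / ax2[1])^2 + (q[, 2] / ax2[2])^2 + (q[, 3] / ax2[3])^2) - 1
  k <- spec$blend
  m <- pmin(f1, f2)
  # smooth minimum, evaluated stably around the running minimum
  m - log(exp(-k * (f1 - m)) + exp(-k * (f2 - m))) / k
}

# physical half-extent (mm per axis) of the outer shape, conservative
phantom_halfwidth <- function(spec) {
  hw <- spec$semi_axes
  if (spec$shape == "two_lobe")
    hw[1] <- max(hw[1], abs(spec$lobe_offset) + spec$lobe_scale * spec$semi_axes[1])
  # rotation can mix axes; bound by the rotated box of the axis-aligned bound
  R <- euler_rotation(spec$rotation)
  hw_rot <- abs(R) %*% hw
  as.numeric(hw_rot)
}

# classify physical points: 0 background, 1 cortical, 2 trabecular, for the
# main shape centred at `centre`; second body handled by the caller.
phantom_classify <- function(spec, pts, centre) {
  R <- euler_rotation(spec$rotation)
  q <- sweep(pts, 2, centre, "-") %*% R  # R^T applied as right-multiplication
  f_out <- phantom_implicit(spec, q, shrink = 0)
  f_in <- phantom_implicit(spec, q, shrink = spec$shell_mm)
  cls <- integer(nrow(pts))
  cls[f_out <= 0] <- 1L
  cls[f_in < 0] <- 2L
  cls
}

# analytic (or quadrature) volume of the outer and inner surfaces
phantom_truth_volumes <- function(spec) {
  if (spec$shape == "ellipsoid") {
    a <- spec$semi_axes
    ai <- a - spec$shell_mm
    return(list(outer = 4 / 3 * pi * prod(a), inner = 4 / 3 * pi * prod(ai),
                method = "closed_form"))
  }
  # fine-grid quadrature at `truth_oversample` x the voxel resolution,
  # restricted to the (unrotated) bounding box of the blend
  os <- max(1L, spec$truth_oversample)
  h <- spec$spacing / os
  hw <- spec$semi_axes
  hw[1] <- max(hw[1], abs(spec$lobe_offset) + spec$lobe_scale * spec$semi_axes[1])
  hw <- hw + 2 * max(h)
  xs <- seq(-hw[1], hw[1], by = h[1])
  ys <- seq(-hw[2], hw[2], by = h[2])
  zs <- seq(-hw[3], hw[3], by = h[3])
  nxy <- length(xs) * length(ys)
  xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  n_out <- 0; n_in <- 0
  spec0 <- spec
  spec0$rotation <- c(0, 0, 0) # volume is rotation-invariant
  for (z in zs) {
    q <- cbind(xy, z)
    n_out <- n_out + sum(phantom_implicit(spec0, q, 0) <= 0)
    n_in <- n_in + sum(phantom_implicit(spec0, q, spec$shell_mm) < 0)
  }
  vsub <- prod(h)
  list(outer = n_out * vsub, inner = n_in * vsub, method = "quadrature")
}

#' Generate a synthetic CT phantom with analytic ground truth
#'
#' Renders the [phantom_spec()] onto a voxel grid: voxels strictly inside the
#' inner surface receive the trabecular level, voxels between the inner and
#' outer surfaces the cortical level, all others the background level; then
#' adds zero-mean Gaussian noise of the requested SD. The same spec and seed
#' always produce a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `volume` (an
#'   [image_volume()]) and `truth` (class `phantom_truth`: analytic outer and
#'   inner volumes in mm^3, the computation method, the shape centre, the
#'   second-body centre and true surface gap when present, and the seed voxel
#'   index of a cortical voxel usable to start region growing).
#' @examples
#' ph <- generate_phantom(phantom_spec(semi_axes = c(6, 6, 6),
#'                                     spacing = c(0.4, 0.4, 0.4),
#'                                     noise_sd = 0))
#' ph$truth$outer_volume  # 4/3 * pi * 216
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  hw <- phantom_halfwidth(spec)
  need_mm <- hw + abs(spec$translation)
  second_extra <- 0
  if (!is.null(spec$second_axes))
    second_extra <- spec$gap_mm + 2 * spec$second_axes[1]
  need_half_vox <- ceiling((need_mm + c(second_extra, 0, 0)) / spec$spacing) +
    spec$margin_voxels
  dims <- 2L * as.integer(need_half_vox) + 1L
  if (!is.null(spec$extent)) {
    ext <- as.integer(spec$extent)
    short <- which(ext < dims)
    if (length(short))
      stop(sprintf(
        "shape plus %d-voxel margin exits the grid on axis %s (needs %d voxels, extent %d)",
        spec$margin_voxels, paste(short, collapse = ","),
        dims[short[1]], ext[short[1]]), call. = FALSE)
    dims <- ext
  }
  centre_idx <- (dims + 1) / 2
  origin <- c(0, 0, 0)
  centre <- origin + (centre_idx - 1) * spec$spacing + spec$translation
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spec$spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spec$spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spec$spacing[3]
  vals <- array(spec$hu_background, dim = dims)
  xy <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  second_centre <- NULL
  if (!is.null(spec$second_axes)) {
    # surface gap along +x: main outer extent + gap + second semi-axis
    second_centre <- centre + c(phantom_halfwidth(spec)[1] + spec$gap_mm +
                                  spec$second_axes[1], 0, 0)
  }
  for (k in seq_len(dims[3])) {
    pts <- cbind(xy, zs[k])
    cls <- phantom_classify(spec, pts, centre)
    slab <- vals[, , k]
    slab[cls == 1L] <- spec$hu_cortical
    slab[cls == 2L] <- spec$hu_trabecular
    if (!is.null(second_centre)) {
      spec2 <- spec
      spec2$shape <- "ellipsoid"
      spec2$semi_axes <- spec$second_axes
      spec2$rotation <- c(0, 0, 0)
      cls2 <- phantom_classify(spec2, pts, second_centre)
      slab[cls2 == 1L] <- spec$hu_cortical
      slab[cls2 == 2L] <- spec$hu_trabecular
    }
    vals[, , k] <- slab
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(rnorm(prod(dims), 0, spec$noise_sd), dim = dims)
  }
  tv <- phantom_truth_volumes(spec)
  # a guaranteed-cortical seed voxel: walk from the centre along +x in index
  # space until the classification leaves the trabecular region
  seed_idx <- cortical_seed(spec, dims, origin, centre)
  truth <- structure(list(
    outer_volume = tv$outer, inner_volume = tv$inner,
    truth_method = tv$method, centre = centre,
    second_centre = second_centre,
    gap_mm = spec$gap_mm, seed_voxel = seed_idx), class = "phantom_truth")
  list(volume = image_volume(vals, spec$spacing, origin), truth = truth)
}

cortical_seed <- function(spec, dims, origin, centre) {
  ci <- round((centre - origin) / spec$spacing) + 1
  for (ix in seq.int(ci[1], dims[1])) {
    p <- origin + (c(ix, ci[2], ci[3]) - 1) * spec$spacing
    cls <- phantom_classify(spec, rbind(p), centre)
    if (cls == 1L) return(as.integer(c(ix, ci[2], ci[3])))
  }
  stop("no cortical voxel found along the +x axis", call. = FALSE)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> outer volume ", signif(x$outer_volume, 7),
      " mm^3 (", x$truth_method, "), inner ", signif(x$inner_volume, 7),
      " mm^3\n", sep = "")
  invisible(x)
}

#' Generate replicate phantom pairs for a two-condition experiment
#'
#' Emulates repeated scanning of one specimen in two conditions (e.g. frozen
#' and thawed): condition A renders `spec` as is; condition B scales the
#' outer geometry isotropically so that its true volume is
#' `(1 + volume_perturbation)` times condition A's. Replicate pairs differ
#' only by fresh noise draws (seeds derived deterministically from `seed`).
#'
#' @param spec a [phantom_spec()].
#' @param volume_perturbation fractional volume change of condition B;
#'   `abs(volume_perturbation) < 0.1`.
#' @param n_replicates number of replicate pairs (>= 1).
#' @param seed integer seed for the replicate noise streams.
#' @return A list of class `condition_pair_set`: `pairs` (list of
#'   `list(a, b)` image volumes), `truth_a`, `truth_b`.
#' @export
generate_condition_pair <- function(spec, volume_perturbation = 0,
                                    n_replicates = 1, seed = 1L) {
  if (abs(volume_perturbation) >= 0.1)
    stop("abs(volume_perturbation) must be < 0.1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  s <- (1 + volume_perturbation)^(1 / 3)
  spec_b <- spec
  spec_b$semi_axes <- spec$semi_axes * s
  spec_b$shell_mm <- spec$shell_mm * s
  spec_b$lobe_offset <- spec$lobe_offset * s
  pairs <- vector("list", n_replicates)
  truth_a <- NULL; truth_b <- NULL
  for (i in seq_len(n_replicates)) {
    sa <- spec;   sa$seed <- as.integer(seed + 2L * i - 1L)
    sb <- spec_b; sb$seed <- as.integer(seed + 2L * i)
    pa <- generate_phantom(sa)
    pb <- generate_phantom(sb)
    if (is.null(truth_a)) { truth_a <- pa$truth; truth_b <- pb$truth }
    pairs[[i]] <- list(a = pa$volume, b = pb$volume)
  }
  structure(list(pairs = pairs, truth_a = truth_a, truth_b = truth_b,
                 volume_perturbation = volume_perturbation),
            class = "condition_pair_set")
}
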