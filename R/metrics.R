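#' Rigid transform
#'
#' A proper rigid-body transform `x -> R x + t` with orthonormal rotation
#' (det = +1) and translation in mm.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric length-3 (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0)
    stop("rotation must be a proper orthonormal 3 x 3 matrix", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation angle ", signif(rotation_angle(x), 6),
      " deg, translation ", signif(sqrt(sum(x$translation^2)), 6), " mm\n",
      sep = "")
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first,
#' then `a`.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

#' Rotation angle of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The rotation angle in degrees.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param degrees rotation angle.
#' @param translation optional translation (mm).
#' @return A [rigid_transform()].
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), degrees,
                          translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  r <- degrees * pi / 180
  cs <- cos(r); sn <- sin(r)
  R <- switch(axis,
    z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3),
    x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3),
    y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3))
  rigid_transform(R, translation)
}

# Kabsch: best rigid transform mapping points p onto q (both n x 3)
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, as.numeric(cq - R %*% cp))
}

#' Rigid registration by trimmed iterative closest point
#'
#' Aligns `moving` to `fixed` by iterating: (1) nearest point on the fixed
#' surface for every moving vertex (point-to-surface correspondence via a
#' bounding-volume hierarchy); (2) trimming of correspondences beyond the
#' `trim` quantile of distances, to resist outliers; (3) the optimal rigid
#' transform of the trimmed pairs (Kabsch/SVD). Iteration stops when the RMS
#' correspondence distance improves by less than `tolerance`, or at
#' `max_iterations`. The transform with the smallest observed RMS is
#' returned, so the reported final RMS never exceeds the initial RMS.
#'
#' @param moving,fixed [triangle_mesh()] objects.
#' @param max_iterations iteration cap.
#' @param tolerance RMS improvement (mm) below which iteration stops.
#' @param trim quantile of correspondences kept per iteration (1 = all).
#' @return A [rigid_transform()] with metadata fields `converged`,
#'   `iterations`, `rms` (final trimmed RMS, mm) and `rms_history`.
#' @export
register_meshes <- function(moving, fixed, max_iterations = 100,
                            tolerance = 1e-8, trim = 0.95) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0)
    stop("both meshes must be nonempty", call. = FALSE)
  pts0 <- moving$vertices
  cur <- rigid_transform()
  rms_of <- function(d) sqrt(mean(d^2))
  pts <- pts0
  cp <- cpp_closest_on_mesh(pts, fixed$vertices, fixed$faces)
  best_rms <- rms_of(trimmed(cp$distance, trim))
  best <- cur
  history <- best_rms
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    keep <- cp$distance <= stats::quantile(cp$distance, trim, names = FALSE)
    step <- kabsch(pts[keep, , drop = FALSE], cp$closest[keep, , drop = FALSE])
    cur <- compose_transforms(step, cur)
    pts <- apply_transform(pts0, cur)
    cp <- cpp_closest_on_mesh(pts, fixed$vertices, fixed$faces)
    r <- rms_of(trimmed(cp$distance, trim))
    history <- c(history, r)
    if (r < best_rms) { best <- cur; improved <- best_rms - r; best_rms <- r }
    else improved <- 0
    if (improved < tolerance && it > 1) { converged <- TRUE; break }
  }
  out <- best
  out$converged <- converged
  out$iterations <- length(history) - 1L
  out$rms <- best_rms
  out$rms_history <- history
  out
}

trimmed <- function(d, trim) {
  if (trim >= 1) return(d)
  d[d <= stats::quantile(d, trim, names = FALSE)]
}

#' Signed surface-distance map between two registered meshes
#'
#' For every vertex of `reference`, the unsigned distance is the nearest
#' point-to-triangle distance over all triangles of `other`; the sign is
#' positive where the reference vertex lies outside `other` (the reference
#' object is locally larger) and negative inside, determined by the
#' angle-weighted pseudonormal of the closest feature. `other` must be
#' closed, otherwise inside/outside is undefined. Registration is the
#' caller's responsibility.
#'
#' @param reference,other [triangle_mesh()] objects.
#' @return An object of class `distance_map`: `points` (the reference
#'   vertices), `signed` (mm per point), and `summary` with min, max, mean,
#'   SD (sample convention, n-1) and included count for the signed and
#'   absolute variants.
#' @export
signed_distance_map <- function(reference, other) {
  stopifnot(inherits(reference, "triangle_mesh"),
            inherits(other, "triangle_mesh"))
  be <- boundary_edge_count(other)
  if (be > 0)
    stop(sprintf("other mesh is not closed (%d boundary edges): sign undefined",
                 be), call. = FALSE)
  res <- cpp_signed_distance_mesh(reference$vertices, other$vertices,
                                  other$faces)
  new_distance_map(reference$vertices, res$signed)
}

new_distance_map <- function(points, signed) {
  summarise <- function(x) list(
    min = min(x), max = max(x), mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else 0,
    n = length(x))
  structure(list(points = points, signed = signed,
                 summary = list(signed = summarise(signed),
                                absolute = summarise(abs(signed)))),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  s <- x$summary
  cat("<distance_map> ", s$signed$n, " sample points\n", sep = "")
  cat(sprintf("  signed  : min %.3f  max %.3f  mean %.3f  sd %.3f mm\n",
              s$signed$min, s$signed$max, s$signed$mean, s$signed$sd))
  cat(sprintf("  absolute: min %.3f  max %.3f  mean %.3f  sd %.3f mm\n",
              s$absolute$min, s$absolute$max, s$absolute$mean, s$absolute$sd))
  invisible(x)
}

#' Distance-statistics report
#'
#' Tabulates a [signed_distance_map()] as a two-column report (absolute and
#' signed variants; rows minimum, maximum, mean, standard deviation, included
#' count), the layout used for surface-deviation heat-map statistics, and
#' carries the per-point scalars for rendering.
#'
#' @param map a `distance_map`.
#' @return An object of class `distance_report`: `table` (data.frame) and
#'   `per_point` (numeric vector of signed distances).
#' @export
distance_report <- function(map) {
  stopifnot(inherits(map, "distance_map"))
  if (map$summary$signed$n == 0) stop("empty distance map", call. = FALSE)
  s <- map$summary
  tab <- data.frame(
    statistic = c("minimum_mm", "maximum_mm", "mean_mm", "sd_mm",
                  "included_n"),
    absolute = c(s$absolute$min, s$absolute$max, s$absolute$mean,
                 s$absolute$sd, s$absolute$n),
    signed = c(s$signed$min, s$signed$max, s$signed$mean, s$signed$sd,
               s$signed$n))
  structure(list(table = tab, per_point = map$signed),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat("<distance_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Joint-space thickness between two articulating bones
#'
#' The articular region of `bone_a` consists of its vertices whose nearest
#' point on `bone_b` lies within `distance_cap` mm and whose outward normal
#' points toward that nearest point within `facing_angle_limit` degrees. The
#' joint-space thickness (JST) is the unsigned nearest distance over that
#' region; its minimum is the narrowest cartilage space. Meshes must be
#' disjoint (no interpenetration).
#'
#' @param bone_a,bone_b closed [triangle_mesh()] objects.
#' @param distance_cap articular-region distance cap (mm).
#' @param facing_angle_limit maximum angle (degrees) between the outward
#'   vertex normal and the direction to the nearest point on `bone_b`.
#' @return An object of class `jst_map`: `vertex` (indices of articular
#'   vertices of `bone_a`), `thickness` (mm per articular vertex), `minimum`
#'   (mm), and `n_articular`. If no vertex faces `bone_b` the result has
#'   `n_articular = 0` and `minimum = NA` (an explicit "no facing surface"
#'   outcome).
#' @export
joint_space_thickness <- function(bone_a, bone_b, distance_cap = 5,
                                  facing_angle_limit = 60) {
  stopifnot(inherits(bone_a, "triangle_mesh"), inherits(bone_b, "triangle_mesh"))
  if (boundary_edge_count(bone_b) > 0)
    stop("bone_b must be closed", call. = FALSE)
  sd_ab <- cpp_signed_distance_mesh(bone_a$vertices, bone_b$vertices,
                                    bone_b$faces)
  if (any(sd_ab$signed <= 0))
    stop(sprintf("meshes interpenetrate: %d vertices of bone_a inside bone_b",
                 sum(sd_ab$signed <= 0)), call. = FALSE)
  cp <- cpp_closest_on_mesh(bone_a$vertices, bone_b$vertices, bone_b$faces)
  nrm <- cpp_vertex_normals(bone_a$vertices, bone_a$faces)
  dirv <- cp$closest - bone_a$vertices
  len <- sqrt(rowSums(dirv^2))
  cosang <- rowSums(dirv * nrm) / pmax(len, 1e-12)
  facing <- cp$distance <= distance_cap &
    cosang >= cos(facing_angle_limit * pi / 180)
  idx <- which(facing)
  structure(list(vertex = idx, thickness = cp$distance[idx],
                 minimum = if (length(idx)) min(cp$distance[idx]) else NA_real_,
                 n_articular = length(idx),
                 distance_cap = distance_cap,
                 facing_angle_limit = facing_angle_limit),
            class = "jst_map")
}

#' @export
print.jst_map <- function(x, ...) {
  if (x$n_articular == 0) {
    cat("<jst_map> no facing surface within ", x$distance_cap, " mm\n", sep = "")
  } else {
    cat("<jst_map> ", x$n_articular, " articular vertices, minimum JST ",
        signif(x$minimum, 4), " mm\n", sep = "")
  }
  invisible(x)
}
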