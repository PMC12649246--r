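#' Triangle mesh
#'
#' A triangle surface in physical mm coordinates. Meshes produced by
#' [extract_mesh()] are closed, consistently outward-oriented 2-manifolds.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles\n", sep = "")
  if (nrow(x$faces) > 0) {
    be <- boundary_edge_count(x)
    v <- tryCatch(mesh_volume(x), error = function(e) NA_real_)
    cat("  ", if (be == 0) "closed" else paste0("open (", be, " boundary edges)"),
        if (!is.na(v)) paste0(", enclosed volume ", signif(v, 7), " mm^3"),
        "\n", sep = "")
  }
  invisible(x)
}

# number of edges not shared by exactly two triangles
boundary_edge_count <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  r <- rle(sort(key))
  sum(r$lengths != 2L)
}

#' Is a mesh closed (watertight)?
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` if every edge is shared by exactly two triangles.
#' @export
is_closed_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  boundary_edge_count(mesh) == 0L
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes
#' `det(v0, v1, v2) / 6` over all triangles, which is translation-invariant
#' for a closed surface and positive for outward orientation.
#'
#' @param mesh a closed, oriented [triangle_mesh()].
#' @return Signed enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  be <- boundary_edge_count(mesh)
  if (be > 0)
    stop(sprintf("mesh is not closed: %d boundary edge(s) found", be),
         call. = FALSE)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Apply a rigid transform to a mesh or point matrix
#'
#' @param x a [triangle_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return The transformed mesh or point matrix.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  pts <- rbind(x)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Flip the orientation of every triangle
#'
#' @param mesh a [triangle_mesh()].
#' @return The mesh with reversed winding (and negated enclosed volume).
#' @export
flip_orientation <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

# average edge length (mm), used as a sampling-scale reference
mean_edge_length <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  d <- v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# analytic meshes for tests and examples ------------------------------------

#' Analytic meshes: icosphere and box
#'
#' `icosphere_mesh` subdivides an icosahedron and projects onto the sphere;
#' `box_mesh` triangulates an axis-aligned box. Both are closed and
#' outward-oriented.
#'
#' @param radius sphere radius (mm).
#' @param centre sphere/box centre (mm).
#' @param subdivisions icosahedron subdivision level (0 = 20 triangles).
#' @param lengths box edge lengths (mm).
#' @return A [triangle_mesh()].
#' @export
icosphere_mesh <- function(radius = 1, centre = c(0, 0, 0), subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, nrow(f) * 4, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      nv <<- nv + 1L
      mid_cache[[key]] <- nv
      nv
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(c_, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, centre, "+")
  triangle_mesh(v, f)
}

#' @rdname icosphere_mesh
#' @export
box_mesh <- function(lengths = c(1, 1, 1), centre = c(0, 0, 0)) {
  h <- lengths / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, centre, "+")
  # corners: 1:(-,-,-) 2:(+,-,-) 3:(-,+,-) 4:(+,+,-) 5:(-,-,+) 6:(+,-,+)
  #          7:(-,+,+) 8:(+,+,+); outward-oriented quads split on a diagonal
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z-
    c(5, 6, 8), c(5, 8, 7),   # z+
    c(1, 2, 6), c(1, 6, 5),   # y-
    c(3, 7, 8), c(3, 8, 4),   # y+
    c(1, 5, 7), c(1, 7, 3),   # x-
    c(2, 4, 8), c(2, 8, 6))   # x+
  triangle_mesh(v, f)
}
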