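# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive (queue-based flood fills, exhaustive triangle
# searches, direct solid-angle sums) and share no code with the package
# internals they check.

# coarse, fast phantom used by most unit tests (0.4 mm isotropic voxels)
coarse_sphere_spec <- function(r = 5, shell = 0.8, noise_sd = 0, seed = 1,
                               ...) {
  phantom_spec(semi_axes = c(r, r, r), shell_mm = shell, noise_sd = noise_sd,
               spacing = c(0.4, 0.4, 0.4), seed = seed, ...)
}

# breadth-first flood fill over a logical "allowed" array from a seed,
# returning the visited logical array
oracle_flood_fill <- function(allowed, seed, connectivity = 6) {
  d <- dim(allowed)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, , drop = FALSE]
  }
  visited <- array(FALSE, d)
  if (!allowed[seed[1], seed[2], seed[3]]) return(visited)
  queue <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      nb <- cur + offs[k, ]
      if (any(nb < 1) || any(nb > d)) next
      if (visited[nb[1], nb[2], nb[3]] || !allowed[nb[1], nb[2], nb[3]]) next
      visited[nb[1], nb[2], nb[3]] <- TRUE
      queue <- rbind(queue, nb)
    }
  }
  visited
}

# background voxels unreachable from the grid border (the cavity set)
oracle_cavities <- function(mask, bg_connectivity = 26) {
  d <- dim(mask)
  border <- which(array(
    slice.index(mask, 1) %in% c(1, d[1]) |
      slice.index(mask, 2) %in% c(1, d[2]) |
      slice.index(mask, 3) %in% c(1, d[3]), d) & !mask, arr.ind = TRUE)
  visited <- array(FALSE, d)
  for (i in seq_len(nrow(border))) {
    s <- border[i, ]
    if (!visited[s[1], s[2], s[3]])
      visited <- visited | oracle_flood_fill(!mask & !visited, s,
                                             bg_connectivity)
  }
  !mask & !visited
}

# exact closest distance from point p to triangle (a, b, c), by direct
# projection onto the plane and clamping to edges/vertices
oracle_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

# exhaustive nearest distance from each query point to every mesh triangle
oracle_mesh_distance <- function(queries, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(queries, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(t) {
      oracle_point_triangle(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
    }, numeric(1)))
  })
}

# generalized winding number of query points wrt a closed oriented mesh
# (van Oosterom & Strackee solid-angle sum); ~1 inside, ~0 outside
oracle_winding_number <- function(queries, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(queries, 1, function(p) {
    a <- sweep(v[f[, 1], , drop = FALSE], 2, p)
    b <- sweep(v[f[, 2], , drop = FALSE], 2, p)
    cc <- sweep(v[f[, 3], , drop = FALSE], 2, p)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cc^2))
    num <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * cc) * lb +
      rowSums(b * cc) * la
    sum(2 * atan2(num, den)) / (4 * pi)
  })
}

# icosphere with radial jitter: an irregular closed test mesh
jittered_sphere <- function(radius = 5, subdivisions = 2, jitter = 0.15,
                            seed = 1) {
  m <- icosphere_mesh(radius, subdivisions = subdivisions)
  set.seed(seed)
  r <- radius * (1 + stats::runif(nrow(m$vertices), -jitter, jitter))
  len <- sqrt(rowSums(m$vertices^2))
  m$vertices <- m$vertices * (r / len)
  m
}
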