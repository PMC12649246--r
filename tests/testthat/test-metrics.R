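scalene_mesh <- function() {
  m <- icosphere_mesh(5, subdivisions = 3)
  m$vertices <- sweep(m$vertices, 2, c(1.6, 1.0, 0.7), "*")
  m
}

test_that("registering a mesh to itself yields the identity", {
  m <- scalene_mesh()
  tf <- register_meshes(m, m, max_iterations = 10)
  expect_lt(rotation_angle(tf), 1e-6)
  expect_lt(sqrt(sum(tf$translation^2)), 1e-6)
  expect_equal(tf$rms, 0, tolerance = 1e-9)
})

test_that("ICP recovers a known 10 degree / 2 mm rigid transform", {
  m <- scalene_mesh()
  tf_true <- axis_rotation("z", 10, translation = c(2, 0, 0))
  moved <- apply_transform(m, tf_true)
  tf <- register_meshes(moved, m)
  resid <- compose_transforms(tf, tf_true) # should be the identity
  expect_lt(rotation_angle(resid), 0.1)
  expect_lt(sqrt(sum(apply_transform(c(0, 0, 0), resid)^2)), 0.01)
  expect_lte(tf$rms, tf$rms_history[1]) # descent contract
})

test_that("final registration RMS never exceeds the initial RMS", {
  a <- jittered_sphere(5, 2, jitter = 0.1, seed = 11)
  b <- jittered_sphere(5, 2, jitter = 0.1, seed = 12)
  tf <- register_meshes(a, b, max_iterations = 25)
  expect_lte(tf$rms, tf$rms_history[1] + 1e-12)
})

test_that("registration plus distance map closes the loop on a moved copy", {
  m <- scalene_mesh()
  tf_true <- axis_rotation("y", 8, translation = c(1.5, -1, 0.5))
  moved <- apply_transform(m, tf_true)
  tf <- register_meshes(moved, m)
  dm <- signed_distance_map(m, apply_transform(moved, tf))
  expect_lt(dm$summary$absolute$max, 0.02)
})

test_that("distance map of a mesh against itself is identically zero", {
  m <- jittered_sphere(4, 2, seed = 3)
  dm <- signed_distance_map(m, m)
  expect_equal(dm$summary$absolute$max, 0, tolerance = 1e-12)
  expect_equal(dm$summary$signed$sd, 0, tolerance = 1e-12)
  expect_identical(dm$summary$signed$n, nrow(m$vertices))
})

test_that("concentric spheres give a constant positive offset with the documented sign", {
  outer_m <- icosphere_mesh(6, subdivisions = 3)
  inner_m <- icosphere_mesh(5.5, subdivisions = 3)
  dm <- signed_distance_map(outer_m, inner_m)
  # reference larger than other -> positive
  expect_gt(dm$summary$signed$min, 0.5 - 0.01)
  expect_lt(dm$summary$signed$max, 0.5 + 0.01)
  dm2 <- signed_distance_map(inner_m, outer_m)
  expect_lt(dm2$summary$signed$max, -0.5 + 0.01)
})

test_that("per-vertex distances equal the exhaustive brute-force minimum", {
  a <- jittered_sphere(5, 2, jitter = 0.2, seed = 21)   # 162 vertices
  b <- jittered_sphere(5, 2, jitter = 0.2, seed = 22)
  dm <- signed_distance_map(a, b)
  oracle <- oracle_mesh_distance(a$vertices, b)
  expect_equal(abs(dm$signed), oracle, tolerance = 1e-9)
})

test_that("inside/outside signs agree with the generalized winding number", {
  b <- jittered_sphere(5, 2, jitter = 0.2, seed = 31)
  set.seed(32)
  q <- matrix(runif(300, -7, 7), ncol = 3)
  res <- carposeg:::cpp_signed_distance_mesh(q, b$vertices, b$faces)
  w <- oracle_winding_number(q, b)
  keep <- abs(res$signed) > 1e-6 # exclude points on the surface
  expect_identical(res$signed[keep] < 0, w[keep] > 0.5)
})

test_that("absolute summary is consistent with the signed summary", {
  a <- jittered_sphere(4, 2, jitter = 0.15, seed = 41)
  b <- jittered_sphere(4, 2, jitter = 0.15, seed = 42)
  dm <- signed_distance_map(a, b)
  expect_equal(dm$summary$absolute$max,
               max(abs(dm$summary$signed$min), abs(dm$summary$signed$max)),
               tolerance = 1e-12)
  expect_equal(abs(dm$signed), vapply(dm$signed, abs, numeric(1)),
               tolerance = 0)
  expect_gte(dm$summary$absolute$min, 0)
  expect_lte(dm$summary$signed$min, dm$summary$signed$mean)
  expect_lte(dm$summary$signed$mean, dm$summary$signed$max)
})

test_that("open meshes are rejected where the sign would be undefined", {
  a <- icosphere_mesh(3, subdivisions = 1)
  open_b <- a
  open_b$faces <- open_b$faces[-1, , drop = FALSE]
  expect_error(signed_distance_map(a, open_b), "not closed")
  expect_error(joint_space_thickness(a, open_b), "closed")
})

test_that("distance report reproduces summary statistics exactly", {
  m <- icosphere_mesh(1, subdivisions = 1)
  const_map <- carposeg:::new_distance_map(m$vertices,
                                           rep(0.2, nrow(m$vertices)))
  rep1 <- distance_report(const_map)
  tab <- rep1$table
  expect_identical(tab$statistic,
                   c("minimum_mm", "maximum_mm", "mean_mm", "sd_mm",
                     "included_n"))
  expect_equal(tab$absolute[3], 0.2)
  expect_equal(tab$signed[3], 0.2)
  expect_equal(tab$absolute[4], 0)
  sym_map <- carposeg:::new_distance_map(m$vertices[1:2, ], c(-0.3, 0.3))
  rep2 <- distance_report(sym_map)$table
  expect_equal(rep2$signed[3], 0)
  expect_equal(rep2$absolute[3], 0.3)
  # 1000 seeded draws against an independent single-pass reference
  set.seed(99)
  x <- rnorm(1000, 0.05, 0.2)
  pts <- matrix(0, 1000, 3)
  rep3 <- distance_report(carposeg:::new_distance_map(pts, x))$table
  n <- length(x)
  mu <- sum(x) / n
  ssd <- sqrt(sum((x - mu)^2) / (n - 1))
  expect_equal(rep3$signed[3], mu, tolerance = 1e-12)
  expect_equal(rep3$signed[4], ssd, tolerance = 1e-12)
  expect_equal(rep3$absolute[1], min(abs(x)), tolerance = 1e-12)
  expect_equal(rep3$signed[5], 1000)
})

test_that("joint-space thickness of parallel plates equals the gap", {
  a <- box_mesh(c(10, 10, 2), centre = c(0, 0, -1 - 0))
  b <- box_mesh(c(10, 10, 2), centre = c(0, 0, 2)) # gap 1 mm: z in [0,1]
  j <- joint_space_thickness(a, b)
  expect_equal(j$minimum, 1.0, tolerance = 1e-9)
  expect_true(all(abs(j$thickness - 1) < 1e-9))
})

test_that("joint-space thickness of offset spheres matches the closed form", {
  a <- icosphere_mesh(5, c(0, 0, 0), subdivisions = 4)
  b <- icosphere_mesh(5, c(11.3, 0, 0), subdivisions = 4)
  j <- joint_space_thickness(a, b)
  edge <- carposeg:::mean_edge_length(a)
  expect_equal(j$minimum, 1.3, tolerance = edge)
  # symmetry up to sampling
  j2 <- joint_space_thickness(b, a)
  expect_lt(abs(j$minimum - j2$minimum), edge)
})

test_that("interpenetrating or absent facing surfaces are flagged", {
  a <- icosphere_mesh(5, c(0, 0, 0), subdivisions = 2)
  b <- icosphere_mesh(5, c(8, 0, 0), subdivisions = 2)
  expect_error(joint_space_thickness(a, b), "interpenetrate")
  far <- icosphere_mesh(5, c(30, 0, 0), subdivisions = 2)
  j <- joint_space_thickness(a, far)
  expect_identical(j$n_articular, 0L)
  expect_true(is.na(j$minimum))
})

test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(1:9, 3)), "orthonormal")
  tf <- axis_rotation("x", 25, translation = c(1, 2, 3))
  id <- compose_transforms(invert_transform(tf), tf)
  expect_lt(rotation_angle(id), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
})
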