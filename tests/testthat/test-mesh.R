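test_that("divergence-theorem volume matches closed forms", {
  expect_equal(mesh_volume(box_mesh(c(2, 3, 4))), 24, tolerance = 1e-12)
  # the icosphere is inscribed, so its volume approaches the ball from below
  v5 <- mesh_volume(icosphere_mesh(5, subdivisions = 5))
  expect_lt(v5, 4 / 3 * pi * 125)
  expect_equal(v5, 4 / 3 * pi * 125, tolerance = 0.001)
  expect_equal(mesh_volume(icosphere_mesh(5, subdivisions = 4)),
               4 / 3 * pi * 125, tolerance = 0.003)
})

test_that("volume is invariant under translation and rigid motion", {
  m <- jittered_sphere(4, 2, seed = 2)
  v0 <- mesh_volume(m)
  shifted <- m
  shifted$vertices <- sweep(m$vertices, 2, c(100, -50, 7), "+")
  expect_equal(mesh_volume(shifted), v0, tolerance = 1e-9)
  tf <- axis_rotation("y", 33, translation = c(-4, 12, 3))
  expect_equal(mesh_volume(apply_transform(m, tf)), v0, tolerance = 1e-9)
})

test_that("open meshes are rejected with the boundary edge count", {
  m <- box_mesh()
  m$faces <- m$faces[-1, , drop = FALSE]
  expect_false(is_closed_mesh(m))
  expect_error(mesh_volume(m), "3 boundary edge")
})

test_that("flipping orientation negates the enclosed volume", {
  m <- icosphere_mesh(3, subdivisions = 2)
  expect_equal(mesh_volume(flip_orientation(m)), -mesh_volume(m),
               tolerance = 1e-12)
})

test_that("volume round trips through MetaImage and NIfTI preserve the grid", {
  ph <- generate_phantom(coarse_sphere_spec(r = 3, shell = 0.7,
                                            noise_sd = 12, seed = 9))
  vol <- ph$volume
  vol$origin <- c(1.5, -2.25, 10)
  for (ext in c("mha", "nii.gz")) {
    f <- file.path(tempdir(), paste0("vol.", ext))
    write_volume(vol, f)
    back <- read_volume(f)
    expect_equal(as.numeric(back$data), as.numeric(vol$data), tolerance = 1e-12)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  }
  expect_error(read_volume("x.foo"), "unknown volume format")
  bad <- file.path(tempdir(), "bad.mha")
  writeLines("not a header", bad)
  expect_error(read_volume(bad), "corrupt")
})

test_that("mesh round trips preserve triangles and volume", {
  m <- jittered_sphere(4, 2, seed = 5)
  v0 <- mesh_volume(m)
  fb <- file.path(tempdir(), "m.stl")
  write_mesh(m, fb)
  back <- read_mesh(fb)
  expect_identical(nrow(back$faces), nrow(m$faces))
  expect_equal(mesh_volume(back), v0, tolerance = 1e-6)
  fa <- file.path(tempdir(), "ma.stl")
  write_mesh(m, fa, ascii = TRUE)
  back2 <- read_mesh(fa)
  expect_identical(nrow(back2$faces), nrow(m$faces))
  expect_true(is_closed_mesh(back2))
  expect_error(read_mesh("m.xyz"), "unknown mesh format")
})

test_that("PLY per-vertex scalars survive a round trip", {
  m <- icosphere_mesh(2, subdivisions = 1)
  sc <- seq_len(nrow(m$vertices)) * 0.25
  f <- file.path(tempdir(), "m.ply")
  write_mesh(m, f, scalar = sc)
  back <- read_mesh(f)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(back$faces, m$faces)
  expect_equal(attr(back, "scalar"), sc, tolerance = 1e-12)
})
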