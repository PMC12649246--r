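test_that("analytic truth volume matches the closed form for ellipsoids", {
  ph <- generate_phantom(coarse_sphere_spec(r = 6, shell = 0.75))
  expect_equal(ph$truth$outer_volume, 4 / 3 * pi * 216, tolerance = 1e-12)
  expect_equal(ph$truth$inner_volume, 4 / 3 * pi * (6 - 0.75)^3,
               tolerance = 1e-12)
  expect_identical(ph$truth$truth_method, "closed_form")
})

test_that("phantom generation is deterministic for a fixed seed", {
  s <- coarse_sphere_spec(noise_sd = 25, seed = 42)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  s2 <- coarse_sphere_spec(noise_sd = 25, seed = 43)
  expect_false(identical(generate_phantom(s2)$volume$data, a$volume$data))
})

test_that("cortical voxels are exactly those between the analytic surfaces", {
  # independent per-voxel membership test against ellipsoid inequalities
  spec <- phantom_spec(semi_axes = c(7, 5, 4), shell_mm = 0.75, noise_sd = 0,
                       spacing = c(0.17, 0.17, 0.2))
  ph <- generate_phantom(spec)
  vol <- ph$volume
  d <- dim(vol$data)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1] - ph$truth$centre[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2] - ph$truth$centre[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3] - ph$truth$centre[3]
  gx <- array(xs, d)
  gy <- array(rep(ys, each = d[1]), d)
  gz <- array(rep(zs, each = d[1] * d[2]), d)
  in_outer <- (gx / 7)^2 + (gy / 5)^2 + (gz / 4)^2 <= 1
  in_inner <- (gx / 6.25)^2 + (gy / 4.25)^2 + (gz / 3.25)^2 < 1
  expect_identical(sum(vol$data >= spec$hu_cortical - 1),
                   sum(in_outer & !in_inner))
  expect_identical(sum(vol$data == spec$hu_trabecular), sum(in_inner))
})

test_that("voxelized volume approximates the analytic volume at wrist-protocol spacing", {
  spec <- phantom_spec(semi_axes = c(6, 6, 6), shell_mm = 0.75, noise_sd = 0,
                       spacing = c(0.17, 0.17, 0.2))
  ph <- generate_phantom(spec)
  # any threshold separating object levels from background selects the
  # voxelized object; midway between trabecular and background is safe
  mid <- (spec$hu_trabecular + spec$hu_background) / 2
  vox <- sum(ph$volume$data > mid) * prod(spec$spacing)
  expect_lt(abs(vox - ph$truth$outer_volume) / ph$truth$outer_volume, 0.01)
})

test_that("added noise layer is zero-mean within 3 SD / sqrt(N)", {
  s0 <- coarse_sphere_spec(noise_sd = 0)
  s1 <- coarse_sphere_spec(noise_sd = 30, seed = 7)
  clean <- generate_phantom(s0)$volume$data
  noisy <- generate_phantom(s1)$volume$data
  resid <- noisy - clean
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 30 / sqrt(n))
  expect_equal(sd(resid), 30, tolerance = 0.02)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(shell_mm = 0), "shell thickness")
  expect_error(phantom_spec(semi_axes = c(12, 5, 5), shell_mm = 6),
               "shell thickness")
  expect_error(phantom_spec(hu_trabecular = 2200), "cortical > trabecular")
  expect_error(phantom_spec(spacing = c(0.17, -0.17, 0.2)), "spacing")
  expect_error(phantom_spec(second_axes = c(3, 3, 3)), "gap_mm")
})

test_that("a shape that exits an explicit grid raises an error naming the margin", {
  spec <- coarse_sphere_spec(r = 5)
  spec$extent <- c(20L, 60L, 60L)
  expect_error(generate_phantom(spec), "margin exits the grid on axis 1")
})

test_that("two-lobe truth quadrature agrees with the closed form when the blend degenerates", {
  # second lobe entirely inside the first: the blend is a slightly inflated
  # ellipsoid, so quadrature must land near the single-ellipsoid volume
  spec <- phantom_spec("two_lobe", semi_axes = c(6, 5, 4), shell_mm = 0.7,
                       noise_sd = 0, spacing = c(0.4, 0.4, 0.4),
                       lobe_offset = 0, lobe_scale = 0.5,
                       truth_oversample = 4)
  ph <- generate_phantom(spec)
  expect_identical(ph$truth$truth_method, "quadrature")
  expect_equal(ph$truth$outer_volume, 4 / 3 * pi * 6 * 5 * 4,
               tolerance = 0.01)
})

test_that("condition pairs share truth at zero perturbation and scale exactly otherwise", {
  spec <- coarse_sphere_spec(noise_sd = 10)
  set0 <- generate_condition_pair(spec, 0, n_replicates = 2, seed = 5)
  expect_identical(set0$truth_a$outer_volume, set0$truth_b$outer_volume)
  expect_length(set0$pairs, 2L)
  # replicates differ only by the noise draw
  expect_false(identical(set0$pairs[[1]]$a$data, set0$pairs[[2]]$a$data))
  set1 <- generate_condition_pair(spec, 0.01, n_replicates = 1, seed = 5)
  expect_equal(set1$truth_b$outer_volume / set1$truth_a$outer_volume, 1.01,
               tolerance = 1e-12)
  expect_error(generate_condition_pair(spec, 0.2), "0.1")
})
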