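test_that("a straight bundle yields one x-aligned fixel per traversed voxel", {
  scene <- phantom_scene(
    shape = c(12, 5, 5), voxel_size = c(1, 1, 1), seed = 4,
    bundles = list(bundle_spec(rbind(c(1, 2.5, 2.5), c(11, 2.5, 2.5)),
                               radius = 1, n_streamlines = 120,
                               dispersion_sd = 0.4, label = "straight"))
  )
  ph <- generate_phantom(scene)
  per_voxel <- table(ph$grid$fixels$voxel)
  expect_true(all(per_voxel == 1))
  ang <- axial_angle_deg(fixel_directions(ph$grid), c(1, 0, 0))
  expect_true(all(ang < 5))
  expect_true(all(ph$truth))
})

test_that("orthogonally crossing bundles produce two fixels about 90 degrees apart", {
  scene <- phantom_scene(
    shape = c(11, 11, 5), voxel_size = c(1, 1, 1), seed = 6,
    bundles = list(
      bundle_spec(rbind(c(1, 5.5, 2.5), c(10, 5.5, 2.5)), radius = 1,
                  n_streamlines = 100, dispersion_sd = 0.4, label = "bx"),
      bundle_spec(rbind(c(5.5, 1, 2.5), c(5.5, 10, 2.5)), radius = 1,
                  n_streamlines = 100, dispersion_sd = 0.4, label = "by")
    )
  )
  ph <- generate_phantom(scene)
  vx <- unique(ph$grid$fixels$voxel[ph$bundle_masks$bx])
  vy <- unique(ph$grid$fixels$voxel[ph$bundle_masks$by])
  crossing <- intersect(vx, vy)
  expect_gt(length(crossing), 0)
  for (vox in crossing) {
    ids <- which(ph$grid$fixels$voxel == vox)
    expect_equal(length(ids), 2)
    d <- fixel_directions(ph$grid, ids)
    expect_gt(axial_angle_deg(d[1, , drop = FALSE], d[2, ]), 60)
  }
})

test_that("central-voxel streamline counts match a direct recount", {
  scene <- phantom_scene(
    shape = c(9, 5, 5), voxel_size = c(1, 1, 1), seed = 12,
    bundles = list(bundle_spec(rbind(c(1, 2.5, 2.5), c(8, 2.5, 2.5)),
                               radius = 1.5, n_streamlines = 200,
                               dispersion_sd = 0.8, label = "b"))
  )
  ph <- generate_phantom(scene)
  central <- voxel_linear(ph$grid, matrix(c(5, 3, 3), 1))
  # recount from the generated tractogram itself
  oracle <- sum(vapply(ph$tract, function(s) {
    any(traverse_voxels(s, ph$grid)$voxel == central)
  }, logical(1)))
  ids <- which(ph$grid$fixels$voxel == central)
  got <- max(ph$conn$n_streamlines_per_fixel[ids])
  # assignment can only lose visits through the angular cutoff
  expect_lte(got, oracle)
  expect_gt(got, 0.8 * oracle)
})

test_that("phantom generation is deterministic given the seed", {
  sc <- builtin_scenes("arc", seed = 77, n_streamlines = 40)
  a <- generate_phantom(sc)
  b <- generate_phantom(sc)
  expect_identical(lapply(a$tract, identity), lapply(b$tract, identity))
  expect_identical(a$grid$fixels, b$grid$fixels)
  expect_identical(as.matrix(a$conn$matrix), as.matrix(b$conn$matrix))
  c2 <- generate_phantom(builtin_scenes("arc", seed = 78, n_streamlines = 40))
  expect_false(identical(a$tract[[1]], c2$tract[[1]]))
})

test_that("builtin scenes generate valid phantoms with contained truth", {
  for (nm in c("arc", "fanning", "thin", "focal", "multi")) {
    ph <- generate_phantom(builtin_scenes(nm, n_streamlines = 60))
    expect_gt(sum(ph$truth), 0)
    expect_true(all(ph$grid$shape <= 32))
    expect_true(all(abs(sqrt(rowSums(fixel_directions(ph$grid)^2)) - 1) < 1e-6))
  }
  # focal truth is a strict subset of the thin bundle's full fixel set
  thin <- generate_phantom(builtin_scenes("thin", n_streamlines = 60))
  focal <- generate_phantom(builtin_scenes("focal", n_streamlines = 60))
  expect_lt(sum(focal$truth), sum(thin$truth))
  expect_true(all(which(focal$truth) %in% which(focal$bundle_masks$thin)))
})

test_that("fixels of one straight bundle are fully mutually connected", {
  scene <- phantom_scene(
    shape = c(8, 3, 3), voxel_size = c(1, 1, 1), seed = 3,
    bundles = list(bundle_spec(rbind(c(1, 1.5, 1.5), c(7, 1.5, 1.5)),
                               radius = 0.4, n_streamlines = 50,
                               dispersion_sd = 0.1, label = "b"))
  )
  ph <- generate_phantom(scene)
  # narrow dispersion: every streamline traverses every bundle voxel
  core <- which(ph$conn$n_streamlines_per_fixel == 50)
  expect_gt(length(core), 3)
  expect_equal(as.matrix(ph$conn$matrix)[core, core],
               matrix(1, length(core), length(core)))
})

test_that("statistic images have the designed moments and pairing", {
  mask <- rep(TRUE, 500)
  truth <- c(rep(TRUE, 100), rep(FALSE, 400))
  maps <- generate_statistic_images(mask, truth, snr = 2,
                                    n_realisations = 250, seed = 31)
  noise_all <- unlist(maps$noise)
  sig_truth <- unlist(lapply(maps$signal, function(m) m[truth]))
  expect_equal(mean(noise_all), 0, tolerance = 0.02)
  expect_equal(sd(noise_all), 1, tolerance = 0.02)
  expect_equal(mean(sig_truth), 2, tolerance = 0.02)
  # paired: signal = noise + snr * truth, identical noise draw
  expect_equal(maps$signal[[7]] - maps$noise[[7]], 2 * as.numeric(truth))
  # snr 0: identical maps
  maps0 <- generate_statistic_images(mask, truth, snr = 0,
                                     n_realisations = 3, seed = 1)
  expect_identical(maps0$noise, maps0$signal)
  # realisation substreams: a subset regenerates identically
  maps_sub <- generate_statistic_images(mask, truth, snr = 2,
                                        n_realisations = 10, seed = 31)
  expect_identical(maps$noise[1:10], maps_sub$noise)
  expect_error(generate_statistic_images(mask, !mask & truth | truth, snr = -1,
                                         n_realisations = 1), ">= 0")
  expect_error(generate_statistic_images(!truth, truth, 1, 1), "inside")
})

test_that("the illustrative SNR construction reports signal-to-noise 2", {
  # unit binary signal plus Gaussian noise of sd 0.5: SNR = 1 / 0.5 = 2
  set.seed(55)
  truth <- c(rep(TRUE, 2000), rep(FALSE, 10000))
  map <- as.numeric(truth) + rnorm(length(truth), sd = 0.5)
  expect_equal(estimate_snr(map, truth), 2, tolerance = 0.05)
})
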