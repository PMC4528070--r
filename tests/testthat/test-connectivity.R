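test_that("axis-aligned traversal visits voxels in path order", {
  g <- line_grid(3)
  tv <- traverse_voxels(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)), g)
  expect_equal(tv$i, 1:3)
  expect_equal(tv$j, rep(1L, 3))
  # entry/exit of the middle voxel are its faces
  expect_equal(tv$entry_x[2], 1)
  expect_equal(tv$exit_x[2], 2)
})

test_that("streamlines outside the grid yield an empty traversal", {
  g <- line_grid(3)
  tv <- traverse_voxels(rbind(c(0.5, 5, 0.5), c(2.5, 5, 0.5)), g)
  expect_equal(nrow(tv), 0)
})

test_that("diagonal corner-crossing traversal matches a supersampling oracle", {
  g <- fixel_grid(c(6, 6, 6), c(1, 1, 1),
                  data.frame(i = 1, j = 1, k = 1, x = 1, y = 0, z = 0))
  polys <- list(
    rbind(c(0.2, 0.2, 0.2), c(5.8, 5.8, 5.8)),          # body diagonal
    rbind(c(0.1, 0.5, 0.5), c(3.02, 2.97, 0.5), c(5.9, 0.3, 4.8)),
    rbind(c(-1, -1, -1), c(2.5, 3.5, 1.5), c(8, 2, 2))  # enters and exits
  )
  for (s in polys) {
    tv <- traverse_voxels(s, g)
    got <- unique(cbind(tv$i, tv$j, tv$k))
    want <- supersample_voxels(s, g)
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(want, 1, paste, collapse = ","))
  }
})

test_that("revisited voxels produce one record per contiguous visit", {
  g <- line_grid(3)
  s <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5), c(1.5, 0.5, 0.5))
  tv <- traverse_voxels(s, g)
  expect_equal(tv$i, c(1L, 2L, 3L, 2L))
})

test_that("tangent-based assignment picks the aligned fixel", {
  g <- fixel_grid(c(1, 1, 1), c(1, 1, 1),
                  data.frame(i = 1, j = 1, k = 1, x = c(1, 0), y = c(0, 1), z = 0))
  # x-axis streamline: x fixel (id 1), not the y fixel
  expect_equal(assign_streamline_to_fixels(rbind(c(-0.5, 0.5, 0.5), c(1.5, 0.5, 0.5)), g),
               1L)
  # exact 45-degree tangent between two orthogonal fixels: lowest id wins
  s45 <- rbind(c(0.5, 0.5, 0.5) - 0.3 * c(sqrt(0.5), sqrt(0.5), 0),
               c(0.5, 0.5, 0.5) + 0.3 * c(sqrt(0.5), sqrt(0.5), 0))
  expect_equal(assign_streamline_to_fixels(s45, g), 1L)
  # no fixel within the angular cutoff: nothing assigned
  gz <- fixel_grid(c(1, 1, 1), c(1, 1, 1),
                   data.frame(i = 1, j = 1, k = 1, x = 0, y = 0, z = 1))
  expect_equal(assign_streamline_to_fixels(rbind(c(-0.5, 0.5, 0.5), c(1.5, 0.5, 0.5)), gz),
               integer(0))
})

test_that("connectivity ratios follow the streamline-count definition", {
  g <- line_grid(4)
  # one streamline through fixels 1..3: all pairwise c = 1 among them
  co1 <- build_connectivity(tractogram(list(line_streamline(1, 3))), g)
  m <- as.matrix(co1$matrix)
  expect_equal(m[1:3, 1:3], matrix(1, 3, 3))
  expect_equal(co1$unvisited, 4L)
  expect_equal(m[4, 4], 1)  # implicit self-connection survives

  # 10 streamlines through f = 1, 4 of which continue to i = 3 -> c_13 = 0.4
  sl <- c(replicate(6, line_streamline(1, 2), simplify = FALSE),
          replicate(4, line_streamline(1, 3), simplify = FALSE))
  co2 <- build_connectivity(tractogram(sl), g)
  expect_equal(as.matrix(co2$matrix)[1, 3], 0.4)
  expect_equal(as.matrix(co2$matrix)[3, 1], 1)  # all of fixel 3's streamlines pass 1
})

test_that("sub-prune connectivity values are removed without renormalisation", {
  g <- line_grid(3)
  sl <- c(replicate(995, line_streamline(1, 2), simplify = FALSE),
          replicate(5, line_streamline(1, 3), simplify = FALSE))
  co <- build_connectivity(tractogram(sl), g, prune = 0.01)
  m <- as.matrix(co$matrix)
  expect_equal(m[1, 3], 0)          # 5/1000 = 0.005 < 0.01: deleted
  expect_equal(m[1, 2], 1)          # untouched, no renormalisation
  expect_equal(m[3, 1], 1)          # reverse direction kept (asymmetric prune)
})

test_that("doubling the tractogram leaves connectivity unchanged", {
  g <- line_grid(5)
  set.seed(21)
  sl <- replicate(30, {
    ab <- sort(sample(5, 2))
    line_streamline(ab[1], ab[2])
  }, simplify = FALSE)
  co1 <- build_connectivity(tractogram(sl), g)
  co2 <- build_connectivity(tractogram(c(sl, sl)), g)
  expect_equal(as.matrix(co1$matrix), as.matrix(co2$matrix))
})

test_that("sparse construction equals a dense interval-arithmetic oracle", {
  n_fix <- 20
  g <- line_grid(n_fix)
  set.seed(5)
  ranges <- t(replicate(60, sort(sample(n_fix, 2))))
  sl <- lapply(seq_len(nrow(ranges)), function(r) {
    line_streamline(ranges[r, 1], ranges[r, 2])
  })
  co <- build_connectivity(tractogram(sl), g, prune = 0.01)
  # oracle: fixel f is traversed iff f lies in the streamline's voxel range
  sets <- lapply(seq_len(nrow(ranges)), function(r) ranges[r, 1]:ranges[r, 2])
  dense <- matrix(0, n_fix, n_fix)
  counts <- tabulate(unlist(sets), n_fix)
  for (s in sets) dense[s, s] <- dense[s, s] + 1
  dense <- dense / counts
  dense[dense < 0.01 & row(dense) != col(dense)] <- 0
  diag(dense)[counts == 0] <- 1
  expect_equal(as.matrix(co$matrix), dense)
})

test_that("trunk-and-branch geometry witnesses the asymmetry of c_fi", {
  g <- line_grid(4)
  sl <- c(replicate(10, line_streamline(1, 2), simplify = FALSE),
          replicate(10, line_streamline(1, 4), simplify = FALSE))
  co <- build_connectivity(tractogram(sl), g)
  m <- as.matrix(co$matrix)
  expect_equal(m[1, 4], 0.5)  # half of trunk streamlines reach the branch
  expect_equal(m[4, 1], 1)    # every branch streamline passes the trunk
})

test_that("connectivity matrices round-trip through the triplet container", {
  co <- cached_arc_phantom()$conn
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_connectivity(co, path)
  back <- read_connectivity(path)
  expect_equal(as.matrix(back$matrix), as.matrix(co$matrix), tolerance = 1e-12)
  expect_equal(back$prune, co$prune)
  expect_equal(back$n_streamlines, co$n_streamlines)
})

test_that("empty tractograms and unmappable streamlines are errors", {
  g <- line_grid(2)
  expect_error(build_connectivity(structure(list(), class = "tractogram"), g),
               "empty")
  far <- tractogram(list(rbind(c(0, 50, 50), c(1, 50, 50))))
  expect_error(build_connectivity(far, g), "no streamline")
})
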