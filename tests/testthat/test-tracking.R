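test_that("seed generation is uniform within the mask and reproducible", {
  mask <- array(FALSE, c(6, 6, 6))
  mask[2:4, 2:4, 2:4] <- TRUE
  aff <- diag(c(2, 2, 2, 1))
  expect_equal(nrow(generate_seeds(mask, 0, 1, aff)), 0)
  s <- generate_seeds(mask, 500, rng_seed = 8, affine = aff)
  vox <- round(odfmatch:::world_to_vox(s, aff))
  lin <- 1 + vox[, 1] + 6 * (vox[, 2] + 6 * vox[, 3])
  expect_true(all(mask[lin]))
  expect_identical(s, generate_seeds(mask, 500, rng_seed = 8, affine = aff))
  expect_error(generate_seeds(array(FALSE, c(3, 3, 3)), 10), "empty")
})

test_that("direction interpolation respects alignment and antipodal symmetry", {
  pf <- uniform_peak_field(c(8, 8, 8), c(1, 0, 0))
  pt <- matrix(c(7.3, 7.3, 7.3), 1, 3)
  fwd <- interpolate_direction(pf, pt, matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.numeric(fwd$direction), c(1, 0, 0))
  expect_equal(fwd$nqa, 1)
  bwd <- interpolate_direction(pf, pt, matrix(c(-1, 0, 0), 1, 3))
  expect_equal(as.numeric(bwd$direction), c(-1, 0, 0))  # sign follows travel
  out <- interpolate_direction(pf, matrix(c(100, 0, 0), 1, 3),
                               matrix(c(1, 0, 0), 1, 3))
  expect_false(out$ok)
})

test_that("interpolation follows the population aligned with travel in a crossing", {
  # two interleaved peak populations: +x as peak 1, +y as peak 2 everywhere
  pf <- uniform_peak_field(c(8, 8, 8), c(1, 0, 0))
  nvox <- prod(pf$dim)
  pf$dirs[, 2, ] <- matrix(c(0, 1, 0), nvox, 3, byrow = TRUE)
  pf$qa[, 2] <- 1
  pf$n_fibers[] <- 2L
  pf$nqa <- pf$qa
  res_x <- interpolate_direction(pf, matrix(c(7, 7, 7), 1, 3),
                                 matrix(c(0.9, 0.1, 0) / sqrt(0.82), 1, 3))
  expect_lt(axial_angle(as.numeric(res_x$direction), c(1, 0, 0)), 5)
  res_y <- interpolate_direction(pf, matrix(c(7, 7, 7), 1, 3),
                                 matrix(c(0.1, 0.9, 0) / sqrt(0.82), 1, 3))
  expect_lt(axial_angle(as.numeric(res_y$direction), c(0, 1, 0)), 5)
})

test_that("a uniform field yields straight equally spaced streamlines", {
  pf <- uniform_peak_field(c(21, 5, 5), c(1, 0, 0))  # 40 mm extent in x
  params <- tracking_params(step_size = 1, min_length = 10, max_length = 200,
                            n_seeds = 1)
  sl <- track_streamline(pf, c(20, 4, 4), params)
  expect_gt(nrow(sl), 30)
  steps <- sqrt(rowSums(diff(sl)^2))
  expect_lt(max(abs(steps - 1)), 1e-6)            # step-length conservation
  expect_lt(max(abs(sl[, 2] - 4)), 1e-9)          # straight in y
  expect_lt(max(abs(sl[, 3] - 4)), 1e-9)          # straight in z
  expect_gt(diff(range(sl[, 1])), 35)             # spans the mask
})

test_that("tracking terminates below the NQA threshold", {
  pf <- uniform_peak_field(c(21, 5, 5), c(1, 0, 0), nqa = 0.05)
  params <- tracking_params(nqa_threshold = 0.10, step_size = 1,
                            min_length = 1, max_length = 200, n_seeds = 50,
                            rng_seed = 2)
  tg <- run_tractography(pf, params)
  expect_equal(length(tg$streamlines), 0)
})

test_that("a sharp corner beyond the turning limit stops the track", {
  # +x peaks for x < 10, +y peaks beyond: a 90-degree corner
  pf <- uniform_peak_field(c(21, 21, 3), c(1, 0, 0))
  nvox <- prod(pf$dim)
  ijk <- expand.grid(i = 0:20, j = 0:20, k = 0:2)
  right <- which(ijk$i >= 10)
  pf$dirs[right, 1, ] <- matrix(c(0, 1, 0), length(right), 3, byrow = TRUE)
  params <- tracking_params(max_turning_angle = 60, step_size = 1,
                            min_length = 1, max_length = 200, n_seeds = 1)
  sl <- track_streamline(pf, c(4, 20, 2), params)
  # the forward half must stop near the corner instead of turning 90 degrees
  expect_lt(max(sl[, 1]), 22)
  segs <- diff(sl)
  ang <- acos(pmin(rowSums(segs[-1, , drop = FALSE] * segs[-nrow(segs), , drop = FALSE]) /
                     (sqrt(rowSums(segs[-1, , drop = FALSE]^2)) *
                        sqrt(rowSums(segs[-nrow(segs), , drop = FALSE]^2))), 1)) * 180 / pi
  expect_true(all(ang <= 60 + 1e-6))              # angle bound holds exactly
})

test_that("length filtering retains only plausible bundle lengths", {
  pf <- uniform_peak_field(c(31, 5, 5), c(1, 0, 0))  # 60 mm bundle
  params <- tracking_params(step_size = 1, min_length = 30, max_length = 200,
                            n_seeds = 100, rng_seed = 4)
  tg <- run_tractography(pf, params)
  expect_gt(length(tg$streamlines), 0)
  lens <- streamline_lengths(tg)
  expect_true(all(lens >= 30 & lens <= 200))
  # about the bundle length: 60 mm between outer voxel centers plus the
  # sub-voxel margin where interpolated NQA still clears the threshold
  expect_true(all(lens >= 58 & lens <= 67))

  short <- uniform_peak_field(c(11, 5, 5), c(1, 0, 0))  # 20 mm < min_length
  tg2 <- run_tractography(short, params)
  expect_equal(length(tg2$streamlines), 0)
})

test_that("tractography is reproducible from its seed", {
  pf <- uniform_peak_field(c(31, 5, 5), c(1, 0, 0))
  params <- tracking_params(step_size = 1, n_seeds = 60, rng_seed = 11)
  a <- run_tractography(pf, params)
  b <- run_tractography(pf, params)
  expect_identical(a$streamlines, b$streamlines)
})

test_that("tracking parameter validation enforces its invariants", {
  expect_error(tracking_params(nqa_threshold = 1.5), "nqa_threshold")
  expect_error(tracking_params(min_length = 200, max_length = 100), "min_length")
  pf <- uniform_peak_field(c(5, 5, 5), c(1, 0, 0), voxel_size = 2)
  expect_error(run_tractography(pf, tracking_params(step_size = 5, n_seeds = 1)),
               "step_size")
})
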