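test_that("GQI transform is exactly constant when all weighting vanishes", {
  sph <- fix_sphere()
  gt0 <- gradient_table(rep(0, 8), matrix(0, 8, 3))
  k <- gqi_kernel(gt0, sph)
  expect_equal(as.numeric(k), rep(1, length(k)))  # sinc(0) = 1 everywhere
  a <- odfmatch:::gqi_transform_signals(rbind(rep(1, 8)), k)
  expect_equal(as.numeric(a), rep(8, nrow(sph$vertices)))
})

test_that("isotropic signal gives a near-flat ODF; single fiber peaks on axis", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  odf_iso <- voxel_odf(microstructure_params(0, free_water_fraction = 1))
  spread <- (max(odf_iso) - min(odf_iso)) / mean(odf_iso)
  expect_lt(spread, 0.01)  # finite direction-set ripple only
  expect_true(all(odf_iso >= 0))

  ax <- c(0.6, 0.0, 0.8)
  p <- microstructure_params(1, fiber_dirs = ax, fiber_fractions = 0.9,
                             free_water_fraction = 0.1)
  sig <- simulate_voxel_signal(p, gtab)
  odf <- voxel_odf(p)
  grid_argmax <- sph$vertices[which.max(odf), ]
  dense_argmax <- dense_odf_argmax(sig, gtab)
  expect_lt(axial_angle(grid_argmax, dense_argmax), vertex_spacing_deg())
})

test_that("ODFs are invariant to global signal scaling through b0 normalization", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  p <- microstructure_params(1, fiber_dirs = c(0, 0, 1), fiber_fractions = 0.8,
                             free_water_fraction = 0.2)
  s <- simulate_voxel_signal(p, gtab)
  dwi1 <- array(s, c(1, 1, 1, length(s)))
  dwi2 <- dwi1 * 2
  f1 <- gqi_odf_transform(dwi1, gtab, sph)
  f2 <- gqi_odf_transform(dwi2, gtab, sph)
  expect_equal(normalize_odf(f1$amplitudes[1, ]), normalize_odf(f2$amplitudes[1, ]),
               tolerance = 1e-12)
})

test_that("GQI transform is linear in the signal", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  k <- fix_kernel()
  set.seed(5)
  s1 <- runif(length(gtab$bvals)); s2 <- runif(length(gtab$bvals))
  mix <- 0.3 * s1 + 0.7 * s2
  a_mix <- as.numeric(rbind(mix) %*% t(k))
  a_sep <- 0.3 * as.numeric(rbind(s1) %*% t(k)) + 0.7 * as.numeric(rbind(s2) %*% t(k))
  expect_equal(a_mix, a_sep, tolerance = 1e-10)
})

test_that("normalize_odf has the documented closed forms and properties", {
  nv <- nrow(fix_sphere()$vertices)
  expect_equal(normalize_odf(rep(0.5, nv)), rep(1 / sqrt(nv), nv))
  u <- normalize_odf(runif(nv) + 0.1)
  expect_equal(normalize_odf(u), u)  # idempotent
  set.seed(2)
  v <- runif(nv) + 1e-3
  w <- normalize_odf(v)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-9)
  expect_equal(sum(w * v) / sqrt(sum(v^2)), 1, tolerance = 1e-12)  # direction kept
  expect_error(normalize_odf(rep(0, nv)), "unmatchable")
})

test_that("peak finding matches brute-force local-maximum enumeration", {
  sph <- fix_sphere()
  expect_equal(nrow(find_odf_peaks(rep(1, 321), sph)$directions), 0)  # flat: none
  set.seed(9)
  cases <- list(
    voxel_odf(microstructure_params(1, fiber_dirs = c(0, 0, 1),
                                    fiber_fractions = 0.9, free_water_fraction = 0.1)),
    voxel_odf(microstructure_params(2, fiber_dirs = rbind(c(1, 0, 0), c(0, 1, 0)),
                                    fiber_fractions = c(0.5, 0.5))),
    voxel_odf(microstructure_params(2, fiber_dirs = rbind(c(1, 0, 0), c(0, 1, 0)),
                                    fiber_fractions = c(0.15, 0.15),
                                    free_water_fraction = 0.7),
              snr = 20, noise_seed = 1),
    voxel_odf(microstructure_params(3,
                                    fiber_dirs = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                                    fiber_fractions = rep(1 / 3, 3)))
  )
  for (odf in cases) {
    pk <- find_odf_peaks(odf, sph)
    bf <- bf_find_peaks(odf, sph)
    expect_equal(nrow(pk$directions), length(bf))
    if (length(bf) > 0)
      expect_equal(pk$directions, sph$vertices[bf, , drop = FALSE])
    expect_true(all(diff(pk$qa) <= 0))  # sorted by amplitude
    expect_true(all(pk$qa >= 0))
  }
})

test_that("a 90-degree crossing yields two peaks near the true axes", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  p <- microstructure_params(2, fiber_dirs = rbind(c(1, 0, 0), c(0, 1, 0)),
                             fiber_fractions = c(0.5, 0.5))
  odf <- voxel_odf(p)
  pk <- find_odf_peaks(odf, sph)
  expect_equal(nrow(pk$directions), 2)
  errs <- c(min(axial_angle(pk$directions, matrix(c(1, 0, 0), 2, 3, byrow = TRUE))),
            min(axial_angle(pk$directions, matrix(c(0, 1, 0), 2, 3, byrow = TRUE))))
  expect_lt(max(errs), vertex_spacing_deg())
})

test_that("single-fiber argmax is rotation-equivariant at grid resolution", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  set.seed(31)
  base_ax <- c(0, 0, 1)
  for (i in 1:5) {
    rot <- odfmatch:::rotation_between(c(0, 0, 1), normalize_odf(abs(rnorm(3)) + 0.1))
    ax <- as.numeric(rot %*% base_ax)
    p <- microstructure_params(1, fiber_dirs = ax, fiber_fractions = 0.85,
                               free_water_fraction = 0.15)
    odf <- voxel_odf(p)
    got <- sph$vertices[which.max(odf), ]
    expect_lt(axial_angle(got, dense_odf_argmax(simulate_voxel_signal(p, gtab), gtab)),
              vertex_spacing_deg())
  }
})

test_that("NQA normalization is a scale-invariant max rescaling", {
  pf <- uniform_peak_field(c(3, 3, 3), c(1, 0, 0), nqa = 1)
  pf$qa[, 1] <- seq_len(27) / 10
  pf$qa[1, 1] <- 0
  out <- compute_nqa_field(pf)
  expect_equal(max(out$nqa), 1)
  expect_equal(out$nqa[1, 1], 0)
  pf2 <- pf; pf2$qa <- pf$qa * 7
  expect_equal(compute_nqa_field(pf2)$nqa, out$nqa, tolerance = 1e-12)
  pf3 <- pf; pf3$qa[] <- 0
  expect_error(compute_nqa_field(pf3), "all-zero")
})
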