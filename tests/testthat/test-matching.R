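# Helper: hand-built two-element dictionary with prescribed score fields.
toy_dict <- function(odfs, n_fibers, min_amplitude, sphere = fix_sphere()) {
  n <- nrow(odfs)
  fd <- array(0, c(n, 3, 3))
  for (i in seq_len(n)) if (n_fibers[i] > 0) fd[i, 1, ] <- c(0, 0, 1)
  d <- structure(list(
    odfs = odfs, n_fibers = as.integer(n_fibers),
    min_amplitude = min_amplitude, fiber_dirs = fd,
    free_water_fraction = rep(0.1, n),
    meta = list(format_version = 1L, size = n, seed = 0L,
                sphere_checksum = sphere$checksum, n_vertices = ncol(odfs),
                bvals = NULL, odf_checksum = 0)), class = "odf_dictionary")
  attach_sphere(d, sphere)
}

test_that("cosine similarity has the documented closed forms", {
  nv <- 321
  x <- rep(0, nv); x[1] <- 0.6; x[2] <- 0.8
  d <- rep(0, nv); d[1] <- 0.8; d[2] <- 0.6
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(x, d), 0.96)
  e <- rep(0, nv); e[3] <- 1
  expect_equal(cosine_similarity(x, e), 0)  # disjoint supports
  expect_error(cosine_similarity(x * 2, d), "unit")
})

test_that("penalized score is the exact three-term expression", {
  nv <- 321
  x <- rep(0, nv); x[1] <- 0.95; x[2] <- sqrt(1 - 0.95^2)
  el <- list(odf = c(1, rep(0, nv - 1)), n_fibers = 2L, min_amplitude = 0.1)
  reg <- reg_params(lambda = 2e-5, mu = 0.1)
  expect_equal(penalized_score(x, el, reg), 0.95 - 4e-5 - 0.01, tolerance = 1e-12)
  reg0 <- reg_params(lambda = 0, mu = 0)
  expect_equal(penalized_score(x, el, reg0, mu_here = 0),
               cosine_similarity(x, el$odf))
  expect_error(reg_params(lambda = -1), ">= 0")
})

test_that("at mu > 0 an isotropic element loses to a sharp one at equal cosine", {
  gtab <- fix_gtab(); sph <- fix_sphere(); k <- fix_kernel()
  sharp <- element_odf(microstructure_params(1, fiber_dirs = c(0, 0, 1),
                                             fiber_fractions = 1,
                                             free_water_fraction = 0), gtab, sph, k)
  iso <- element_odf(microstructure_params(0, free_water_fraction = 1), gtab, sph, k)
  x <- normalize_odf(0.5 * sharp$odf + 0.5 * iso$odf)
  reg <- reg_params(lambda = 0, mu = 0.3)
  cos_gap <- cosine_similarity(x, sharp$odf) - cosine_similarity(x, iso$odf)
  score_gap <- penalized_score(x, sharp, reg, 0.3) -
    penalized_score(x, iso, reg, 0.3)
  expect_gt(score_gap, cos_gap)  # the mu term moves the balance toward sharp
})

test_that("canonical alignment round-trips rotations at grid resolution", {
  sph <- fix_sphere()
  p <- microstructure_params(2, fiber_dirs = rbind(c(0, 0, 1), c(1, 0, 0)),
                             fiber_fractions = c(0.5, 0.4),
                             free_water_fraction = 0.1)
  odf_z <- voxel_odf(p)
  al <- canonical_align(odf_z, sph)
  expect_false(al$isotropic)
  # largest peak already on +z: rotation close to identity on z
  expect_lt(axial_angle(as.numeric(al$rotation %*% c(0, 0, 1)), c(0, 0, 1)), 3)

  # rotate the voxel, re-align, and check the primary direction is recovered
  rot0 <- odfmatch:::rotation_between(c(0, 0, 1), c(0.6, -0.64, 0.48))
  p_rot <- microstructure_params(2, fiber_dirs = t(rot0 %*% t(p$fiber_dirs)),
                                 fiber_fractions = c(0.5, 0.4),
                                 free_water_fraction = 0.1)
  al_rot <- canonical_align(voxel_odf(p_rot), sph)
  recovered_primary <- as.numeric(t(al_rot$rotation) %*% c(0, 0, 1))
  expect_lt(axial_angle(recovered_primary, p_rot$fiber_dirs[1, ]),
            vertex_spacing_deg())
  # aligned amplitude patterns of both voxels agree closely
  a1 <- normalize_odf(al$amplitudes); a2 <- normalize_odf(al_rot$amplitudes)
  expect_gt(sum(a1 * a2), 0.99)

  flat <- canonical_align(rep(1, nrow(sph$vertices)), sph)
  expect_true(flat$isotropic)
  expect_equal(flat$rotation, diag(3))
})

test_that("match_one equals the self-match and the brute-force scan", {
  dict <- fix_dict_small()
  reg0 <- reg_params(lambda = 0, mu = 0)
  x <- dict$odfs[17, ]
  res <- match_one(x, dict, reg0, mu_here = 0)
  expect_equal(res$index, 17)
  expect_equal(res$score, 1, tolerance = 1e-9)

  set.seed(4)
  xs <- random_unit_odfs(20)
  reg <- reg_params()
  for (i in seq_len(nrow(xs))) {
    got <- match_one(xs[i, ], dict, reg, mu_here = 0.2)$index
    expect_identical(got, bf_match_index(xs[i, ], dict, reg$lambda, 0.2))
  }
  empty <- toy_dict(matrix(numeric(0), 0, 321), integer(0), numeric(0))
  expect_error(match_one(xs[1, ], empty, reg), "empty")
})

test_that("mu switches the winner from blunt to sharp as documented", {
  nv <- 321
  x <- rep(0, nv); x[1] <- 1
  # prescribed cosines via first coordinate; cached minima as stated
  sharp <- rep(0, nv); sharp[1] <- 0.90; sharp[2] <- sqrt(1 - 0.81)
  blunt <- rep(0, nv); blunt[1] <- 0.905; blunt[2] <- sqrt(1 - 0.905^2)
  dict <- toy_dict(rbind(sharp, blunt), n_fibers = c(2L, 1L),
                   min_amplitude = c(0.01, 0.06))
  reg <- reg_params(lambda = 0)
  expect_equal(match_one(x, dict, reg, mu_here = 0)$index, 2)    # blunt wins on cosine
  expect_equal(match_one(x, dict, reg, mu_here = 0.5)$index, 1)  # boosting flips it
})

test_that("ties break toward fewer fibers, then lower index", {
  nv <- 321
  d <- rep(0, nv); d[1] <- 1
  dict <- toy_dict(rbind(d, d, d), n_fibers = c(2L, 1L, 1L),
                   min_amplitude = rep(0.02, 3))
  reg0 <- reg_params(lambda = 0, mu = 0)
  expect_equal(match_one(d, dict, reg0, mu_here = 0)$index, 2)
})

test_that("selected fiber count and ODF minimum respond monotonically to penalties", {
  dict <- fix_dict_small()
  set.seed(12)
  xs <- random_unit_odfs(40)
  lam_grid <- c(0, 1e-5, 2e-5, 1e-4)
  mu_grid <- seq(0, 0.5, by = 0.1)
  for (i in seq_len(nrow(xs))) {
    nj <- sapply(lam_grid, function(l)
      match_one(xs[i, ], dict, reg_params(lambda = l, mu = 0.1), mu_here = 0.1)$n_fibers)
    expect_true(all(diff(nj) <= 0))
    mins <- sapply(mu_grid, function(m)
      dict$min_amplitude[match_one(xs[i, ], dict, reg_params(), mu_here = m)$index])
    expect_true(all(diff(mins) <= 1e-15))
  }
})

test_that("field matching honors the edema mask and equals voxel-wise matching", {
  sph <- fix_sphere(); gtab <- fix_gtab()
  dict <- fix_dict_small()
  spec <- phantom_spec(dim = c(9, 9, 5), voxel_size = 2, edema_radius = 4,
                       bundles = list(list(start = c(0, 8, 4), end = c(16, 8, 4),
                                           radius = 3)),
                       snr = 25, seed = 2)
  ph <- make_edema_phantom(spec, gtab)
  odfs <- gqi_odf_transform(ph$dwi, gtab, sph, mask = ph$wm_mask,
                            affine = ph$affine)
  reg <- reg_params(mu = 0.1, mu_edema = 0.4)

  pf_none <- match_field(odfs, dict, reg, edema_mask = NULL)
  pf_empty <- match_field(odfs, dict, reg,
                          edema_mask = array(FALSE, dim(ph$wm_mask)))
  expect_identical(pf_none$matched_index, pf_empty$matched_index)

  reg_same <- reg_params(mu = 0.1, mu_edema = 0.1)
  pf_all <- match_field(odfs, dict, reg_same,
                        edema_mask = array(TRUE, dim(ph$wm_mask)))
  expect_identical(pf_all$matched_index, pf_none$matched_index)

  # batch result equals voxel-wise match_one on aligned inputs
  al <- align_field(odfs)
  pf <- match_field(odfs, dict, reg, edema_mask = ph$edema_mask)
  for (r in seq(1, length(al$voxel_index), by = 7)) {
    if (al$isotropic[r]) next
    v <- al$voxel_index[r]
    mu_here <- if (ph$edema_mask[v]) reg$mu_edema else reg$mu
    solo <- match_one(al$x[r, ], dict, reg, mu_here = mu_here,
                      rotation = al$rotations[r, , ], raw_norm = al$raw_norm[r])
    expect_identical(pf$matched_index[v], solo$index)
    if (solo$n_fibers > 0)
      expect_equal(pf$qa[v, seq_len(solo$n_fibers)], solo$qa)
  }
  expect_error(match_field(odfs, dict, reg, edema_mask = array(TRUE, c(2, 2, 2))),
               "grids")
})
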