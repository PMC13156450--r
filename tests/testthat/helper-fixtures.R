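# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fix_sphere <- function() cached("sphere321", function() build_sphere_grid(321))

fix_gtab <- function() cached("gtab", default_gradient_scheme)

fix_kernel <- function() cached("kernel", function() gqi_kernel(fix_gtab(), fix_sphere()))

# Small dictionary for unit tests.
fix_dict_small <- function() cached("dict_small", function() {
  attach_sphere(build_dictionary(800, fix_gtab(), fix_sphere(), seed = 11),
                fix_sphere())
})

# Full-size desk-scale dictionary shared by the acceptance tests.
fix_dict_big <- function() cached("dict_big", function() {
  attach_sphere(build_dictionary(10000, fix_gtab(), fix_sphere(), seed = 101),
                fix_sphere())
})

# Noiseless GQI ODF (raw amplitudes) of one synthetic voxel.
voxel_odf <- function(params, gtab = fix_gtab(), kernel = fix_kernel(),
                      snr = Inf, noise_seed = NULL) {
  s <- simulate_voxel_signal(params, gtab)
  if (is.finite(snr)) s <- add_rician_noise(s, snr, rng_seed = noise_seed)
  a <- as.numeric(s %*% t(kernel))
  a[a < 0] <- 0
  a
}

# Random strictly positive unit-norm "ODF" vectors for matcher oracles.
random_unit_odfs <- function(n, nv = nrow(fix_sphere()$vertices)) {
  m <- matrix(abs(stats::rnorm(n * nv)) + 0.05, n, nv)
  m / sqrt(rowSums(m^2))
}

# Largest neighbor angle on the grid = "one sphere-vertex spacing".
vertex_spacing_deg <- function(sphere = fix_sphere()) {
  cached("vertex_spacing", function() {
    mx <- 0
    for (i in seq_len(nrow(sphere$vertices))) {
      for (j in sphere$neighbors[i, ]) {
        if (j != i)
          mx <- max(mx, axial_angle(sphere$vertices[i, ], sphere$vertices[j, ]))
      }
    }
    mx
  })
}

# Uniform synthetic peak field: every voxel has one peak along `dir`.
uniform_peak_field <- function(dim, dir, nqa = 1, voxel_size = 2) {
  pf <- odfmatch:::empty_peak_field(dim, diag(c(rep(voxel_size, 3), 1)))
  nvox <- prod(dim)
  pf$dirs[, 1, ] <- matrix(dir, nvox, 3, byrow = TRUE)
  pf$qa[, 1] <- nqa
  pf$n_fibers[] <- 1L
  pf$nqa <- pf$qa
  pf
}

angular_error_to_truth <- function(result, true_dirs) {
  if (result$n_fibers == 0) return(90)
  mean(apply(true_dirs, 1, function(tv) {
    min(axial_angle(result$directions, matrix(tv, result$n_fibers, 3, byrow = TRUE)))
  }))
}
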