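# Multi-compartment diffusion signal synthesis.
#
# Each voxel is a mixture of up to three axially symmetric tensor ("zeppelin")
# fiber compartments plus one isotropic free-water compartment, with no
# exchange. For a gradient g at b-value b the normalized signal is
#
#   S(b, g)/S0 = f_fw * exp(-b * D_fw)
#              + sum_k f_k * exp(-b * (RD_k + (AD_k - RD_k) * (g . u_k)^2))
#
# where u_k is the k-th fiber direction and AD/RD its axial/radial
# diffusivity. The quadratic form follows from D_k = RD*I + (AD-RD)*u u^T.

#' Microstructure parameters of one voxel
#'
#' @param n_fibers Integer 0..3.
#' @param fiber_dirs Matrix (`n_fibers` x 3) of unit fiber directions
#'   (NULL when `n_fibers == 0`).
#' @param fiber_fractions Nonnegative volume fractions, one per fiber.
#' @param free_water_fraction Fraction in `[0, 1]`; fractions must total 1.
#' @param axial_diffusivity,radial_diffusivity Per-fiber diffusivities
#'   (mm^2/s), recycled to `n_fibers`.
#' @param free_water_diffusivity Isotropic diffusivity (mm^2/s).
#' @param min_separation_deg Minimum pairwise fiber angle enforced (degrees).
#' @return Object of class `microstructure_params`.
#' @export
microstructure_params <- function(n_fibers,
                                  fiber_dirs = NULL,
                                  fiber_fractions = NULL,
                                  free_water_fraction = 0,
                                  axial_diffusivity = 1.7e-3,
                                  radial_diffusivity = 0.3e-3,
                                  free_water_diffusivity = 3.0e-3,
                                  min_separation_deg = 30) {
  n_fibers <- as.integer(n_fibers)
  if (n_fibers < 0L || n_fibers > 3L) stop("n_fibers must be in 0..3")
  if (n_fibers == 0L) {
    if (abs(free_water_fraction - 1) > 1e-9)
      stop("n_fibers == 0 requires free_water_fraction == 1")
    fiber_dirs <- matrix(numeric(0), 0, 3)
    fiber_fractions <- numeric(0)
  } else {
    fiber_dirs <- matrix(as.numeric(fiber_dirs), ncol = 3)
    if (nrow(fiber_dirs) != n_fibers) stop("need one direction per fiber")
    nrm <- sqrt(rowSums(fiber_dirs^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("fiber directions must be unit vectors")
    if (is.null(fiber_fractions))
      fiber_fractions <- rep((1 - free_water_fraction) / n_fibers, n_fibers)
    if (length(fiber_fractions) != n_fibers) stop("need one fraction per fiber")
    if (any(fiber_fractions < 0)) stop("fiber fractions must be >= 0")
    if (n_fibers >= 2) {
      for (a in 1:(n_fibers - 1)) for (b in (a + 1):n_fibers) {
        if (axial_angle(fiber_dirs[a, ], fiber_dirs[b, ]) < min_separation_deg - 1e-6)
          stop(sprintf("fibers %d and %d are separated by less than %g degrees",
                       a, b, min_separation_deg))
      }
    }
  }
  if (free_water_fraction < 0 || free_water_fraction > 1)
    stop("free_water_fraction must be in [0, 1]")
  if (abs(sum(fiber_fractions) + free_water_fraction - 1) > 1e-9)
    stop("fiber fractions plus free-water fraction must sum to 1")
  structure(list(
    n_fibers = n_fibers,
    fiber_dirs = fiber_dirs,
    fiber_fractions = as.numeric(fiber_fractions),
    free_water_fraction = free_water_fraction,
    axial_diffusivity = rep_len(axial_diffusivity, max(n_fibers, 1L))[seq_len(n_fibers)],
    radial_diffusivity = rep_len(radial_diffusivity, max(n_fibers, 1L))[seq_len(n_fibers)],
    free_water_diffusivity = free_water_diffusivity
  ), class = "microstructure_params")
}

#' Simulate the normalized DWI signal of one voxel
#'
#' @param params A [microstructure_params()] object.
#' @param gtab A [gradient_table()].
#' @return Numeric vector of S/S0 values, one per gradient table entry,
#'   each in (0, 1]; exactly 1 at b = 0.
#' @examples
#' gtab <- default_gradient_scheme()
#' p <- microstructure_params(1, fiber_dirs = c(0, 0, 1),
#'                            fiber_fractions = 0.8,
#'                            free_water_fraction = 0.2)
#' s <- simulate_voxel_signal(p, gtab)
#' @export
simulate_voxel_signal <- function(params, gtab) {
  if (!inherits(params, "microstructure_params"))
    stop("params must be a microstructure_params object")
  b <- gtab$bvals
  g <- gtab$bvecs
  s <- params$free_water_fraction * exp(-b * params$free_water_diffusivity)
  if (params$n_fibers > 0) {
    for (k in seq_len(params$n_fibers)) {
      ad <- params$axial_diffusivity[k]
      rd <- params$radial_diffusivity[k]
      proj2 <- (g %*% params$fiber_dirs[k, ])^2
      s <- s + params$fiber_fractions[k] * exp(-b * (rd + (ad - rd) * proj2))
    }
  }
  as.numeric(s)
}

#' Add Rician noise to a magnitude signal
#'
#' Models magnitude MRI noise: each sample becomes
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, 1/snr)`. SNR is
#' defined relative to the b = 0 signal, which is 1 for normalized signals.
#'
#' @param signal Numeric vector (or matrix, noised elementwise).
#' @param snr Signal-to-noise ratio (> 0).
#' @param rng_seed Optional integer; when given, the result is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Noisy signal of the same shape.
#' @export
add_rician_noise <- function(signal, snr, rng_seed = NULL) {
  if (snr <= 0) stop("snr must be > 0")
  sigma <- 1 / snr
  with_seed(rng_seed, {
    n1 <- stats::rnorm(length(signal), 0, sigma)
    n2 <- stats::rnorm(length(signal), 0, sigma)
    out <- sqrt((signal + n1)^2 + n2^2)
    if (is.matrix(signal)) dim(out) <- dim(signal)
    out
  })
}
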