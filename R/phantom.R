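# Crossing-fiber phantoms with an embedded free-water "edema" region.
#
# The phantom emulates the scenario the matcher is built for: white-matter
# bundles crossing inside a region of vasogenic edema, modeled as a sharply
# raised free-water fraction with the fiber compartments retained. It is the
# package's stand-in for clinical data, which is not publicly deposited.

#' Specification of a synthetic edema phantom
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: two orthogonal straight bundles crossing at the grid center
#' inside a spherical edema region with free-water fraction 0.7, imaged at
#' 2 mm isotropic resolution with Rician noise at SNR 20 on the b0 signal.
#'
#' @param dim Grid size in voxels.
#' @param voxel_size Isotropic voxel edge (mm).
#' @param bundles List of bundles, each `list(start, end, radius)` in mm
#'   (world frame, voxel-center 0-based convention).
#' @param edema_center,edema_radius Sphere defining the edema region (mm);
#'   `NULL` center disables edema.
#' @param edema_fw Free-water fraction inside edema.
#' @param wm_fw Free-water fraction of normal white matter.
#' @param axial_diffusivity,radial_diffusivity Fiber diffusivities (mm^2/s).
#' @param snr Rician SNR on b0 (`Inf` for noiseless).
#' @param seed RNG seed for the noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(31, 31, 13), voxel_size = 2,
                         bundles = NULL,
                         edema_center = NULL, edema_radius = 10,
                         edema_fw = 0.7, wm_fw = 0.05,
                         axial_diffusivity = 1.7e-3,
                         radial_diffusivity = 0.3e-3,
                         snr = 20, seed = 1L) {
  dim <- as.integer(dim)
  ext <- (dim - 1) * voxel_size
  ctr <- ext / 2
  if (is.null(bundles)) {
    bundles <- list(
      list(start = c(0, ctr[2], ctr[3]), end = c(ext[1], ctr[2], ctr[3]), radius = 4),
      list(start = c(ctr[1], 0, ctr[3]), end = c(ctr[1], ext[2], ctr[3]), radius = 4))
  }
  if (is.null(edema_center) && edema_radius > 0) edema_center <- ctr
  if (!is.null(edema_center)) {
    lo <- edema_center - edema_radius; hi <- edema_center + edema_radius
    if (any(lo < -voxel_size / 2) || any(hi > ext + voxel_size / 2))
      stop("edema region extends outside the grid")
  }
  if (snr <= 0) stop("snr must be > 0")
  structure(list(dim = dim, voxel_size = voxel_size, bundles = bundles,
                 edema_center = edema_center, edema_radius = edema_radius,
                 edema_fw = edema_fw, wm_fw = wm_fw,
                 axial_diffusivity = axial_diffusivity,
                 radial_diffusivity = radial_diffusivity,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 < 1e-12) 0 else pmin(1, pmax(0, ((p - a) %*% ab) / len2))
  sqrt(sum((a + as.numeric(tt) * ab - p)^2))
}

#' Generate a DWI phantom with ground-truth fiber directions
#'
#' Voxels inside a bundle carry the bundle tangent as ground truth; voxels
#' inside the edema sphere keep their fiber compartments but have the
#' free-water fraction raised to `spec$edema_fw`; voxels outside any bundle
#' are pure free water. Voxels covered by several bundles become crossings
#' with equal fiber fractions (more than 3 overlapping bundles is an error).
#'
#' @param spec A [phantom_spec()].
#' @param gtab Gradient table to simulate.
#' @return List: `dwi` (4-D array), `gt_dirs` (x,y,z,9; up to three xyz
#'   triplets, zero-padded), `edema_mask`, `wm_mask` (3-D logical),
#'   `affine` (voxel-to-world, mm), `gtab`, `spec`.
#' @export
make_edema_phantom <- function(spec, gtab) {
  d <- spec$dim
  nvox <- prod(d)
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  tangents <- lapply(spec$bundles, function(b) unit(b$end - b$start))
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  pts <- ijk * spec$voxel_size
  in_bundle <- sapply(seq_along(spec$bundles), function(bi) {
    b <- spec$bundles[[bi]]
    apply(pts, 1, function(p) point_segment_distance(p, b$start, b$end)) <= b$radius
  })
  in_bundle <- matrix(in_bundle, nvox)
  nb <- rowSums(in_bundle)
  if (any(nb > 3)) stop("more than 3 bundles overlap in at least one voxel")
  edema <- if (is.null(spec$edema_center)) rep(FALSE, nvox) else
    sqrt(colSums((t(pts) - spec$edema_center)^2)) <= spec$edema_radius
  signals <- matrix(0, nvox, length(gtab$bvals))
  gt <- matrix(0, nvox, 9)
  for (v in seq_len(nvox)) {
    k <- nb[v]
    if (k == 0) {
      p <- microstructure_params(0, free_water_fraction = 1)
    } else {
      dirs <- do.call(rbind, tangents[which(in_bundle[v, ])])
      fw <- if (edema[v]) spec$edema_fw else spec$wm_fw
      p <- microstructure_params(
        k, fiber_dirs = dirs,
        fiber_fractions = rep((1 - fw) / k, k),
        free_water_fraction = fw,
        axial_diffusivity = spec$axial_diffusivity,
        radial_diffusivity = spec$radial_diffusivity)
      gt[v, seq_len(3 * k)] <- as.numeric(t(dirs))
    }
    signals[v, ] <- simulate_voxel_signal(p, gtab)
  }
  if (is.finite(spec$snr))
    signals <- add_rician_noise(signals, spec$snr, rng_seed = spec$seed)
  list(
    dwi = array(signals, c(d, length(gtab$bvals))),
    gt_dirs = array(gt, c(d, 9)),
    edema_mask = array(edema, d),
    wm_mask = array(nb > 0, d),
    affine = affine,
    gtab = gtab,
    spec = spec
  )
}

#' Write a phantom to disk in standard formats
#'
#' DWI as 4-D NIfTI with FSL-dialect .bval/.bvec, masks as uint8 NIfTI,
#' ground-truth directions as a 4-D NIfTI whose last axis holds up to three
#' xyz triplets (zero-padded).
#'
#' @param phantom Result of [make_edema_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dwi = file.path(dir, "dwi.nii.gz"),
    bval = file.path(dir, "dwi.bval"),
    bvec = file.path(dir, "dwi.bvec"),
    gt = file.path(dir, "gt_dirs.nii.gz"),
    edema = file.path(dir, "edema_mask.nii.gz"),
    wm = file.path(dir, "wm_mask.nii.gz"))
  write_dwi(phantom$dwi, phantom$gtab, paths["dwi"], paths["bval"], paths["bvec"],
            affine = phantom$affine)
  write_nifti_volume(phantom$gt_dirs, paths["gt"], phantom$affine)
  write_mask(phantom$edema_mask, paths["edema"], phantom$affine)
  write_mask(phantom$wm_mask, paths["wm"], phantom$affine)
  invisible(paths)
}
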