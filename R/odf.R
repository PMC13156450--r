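# GQI-style ODF reconstruction, peak finding, and QA/NQA.

#' GQI reconstruction kernel
#'
#' Linear operator mapping b0-normalized signals to ODF amplitudes on a
#' sphere grid: `K[v, i] = sinc(L * sqrt(6 * D * b_i) * <g_i, u_v>)` with
#' `sinc(x) = sin(x)/x`. `L` is the diffusion sampling length ratio and `D`
#' the free-water diffusivity used by the kernel.
#'
#' @param gtab A [gradient_table()].
#' @param sphere A [build_sphere_grid()] object.
#' @param sampling_length Sampling length ratio (default 1.25).
#' @param water_diffusivity Kernel diffusivity in mm^2/s (default 3.0e-3).
#' @return Matrix (vertices x volumes).
#' @export
gqi_kernel <- function(gtab, sphere, sampling_length = 1.25,
                       water_diffusivity = 3.0e-3) {
  if (sampling_length <= 0) stop("sampling_length must be > 0")
  l <- sampling_length * sqrt(6 * water_diffusivity * gtab$bvals)
  arg <- sphere$vertices %*% t(gtab$bvecs * l)  # V x n
  out <- ifelse(abs(arg) < 1e-12, 1, sin(arg) / ifelse(arg == 0, 1, arg))
  dim(out) <- c(nrow(sphere$vertices), length(gtab$bvals))
  out
}

# Signals (rows) -> raw ODF amplitudes (rows), floor-clipped at 0.
gqi_transform_signals <- function(signals, kernel) {
  a <- signals %*% t(kernel)
  a[a < 0] <- 0
  a
}

#' Reconstruct an ODF field from a DWI volume
#'
#' Normalizes each voxel by its mean b = 0 signal and applies the GQI kernel.
#' Voxels whose b0 signal is not strictly positive are removed from the mask.
#'
#' @param dwi 4-D array (x, y, z, volumes).
#' @param gtab Matching [gradient_table()].
#' @param sphere Sphere grid for the amplitudes.
#' @param sampling_length,water_diffusivity Passed to [gqi_kernel()].
#' @param mask Optional 3-D logical array restricting reconstruction.
#' @param affine 4x4 voxel-to-world matrix (mm); defaults to identity spacing.
#' @return Object of class `odf_field`: `amplitudes` (masked voxels x
#'   vertices, raw unnormalized GQI amplitudes), `voxel_index` (linear grid
#'   indices of the rows), `dim`, `affine`, `mask`, `sphere`.
#' @export
gqi_odf_transform <- function(dwi, gtab, sphere, sampling_length = 1.25,
                              water_diffusivity = 3.0e-3, mask = NULL,
                              affine = NULL) {
  d <- dim(dwi)
  if (length(d) != 4) stop("dwi must be a 4-D array")
  if (d[4] != length(gtab$bvals))
    stop(sprintf("dwi has %d volumes but the gradient table has %d entries",
                 d[4], length(gtab$bvals)))
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot_same_grid(dim(mask), d[1:3], "mask and dwi")
  if (is.null(affine)) affine <- diag(4)
  nvox <- prod(d[1:3])
  dim(dwi) <- c(nvox, d[4])
  idx <- which(as.logical(mask))
  b0 <- rowMeans(dwi[idx, gtab$b0_mask, drop = FALSE])
  ok <- b0 > 0
  if (!all(ok)) {
    mask[idx[!ok]] <- FALSE
    idx <- idx[ok]
    b0 <- b0[ok]
  }
  if (length(idx) == 0) stop("no voxels with positive b0 signal in mask")
  signals <- dwi[idx, , drop = FALSE] / b0
  kernel <- gqi_kernel(gtab, sphere, sampling_length, water_diffusivity)
  amps <- gqi_transform_signals(signals, kernel)
  structure(list(
    amplitudes = amps,
    voxel_index = idx,
    dim = d[1:3],
    affine = affine,
    mask = array(as.logical(mask), d[1:3]),
    sphere = sphere
  ), class = "odf_field")
}

#' Normalize an ODF amplitude vector to unit Euclidean norm
#'
#' @param amplitudes Nonnegative numeric vector (or matrix of row vectors)
#'   with at least one strictly positive entry per vector.
#' @return Amplitudes scaled to unit norm; direction preserved.
#' @export
normalize_odf <- function(amplitudes) {
  if (is.matrix(amplitudes)) {
    n <- sqrt(rowSums(amplitudes^2))
    if (any(n < 1e-300)) stop("all-zero ODF cannot be normalized (unmatchable voxel)")
    return(amplitudes / n)
  }
  n <- vnorm(amplitudes)
  if (n < 1e-300) stop("all-zero ODF cannot be normalized (unmatchable voxel)")
  amplitudes / n
}

#' Find ODF peaks (local maxima on the sphere grid)
#'
#' A vertex is a peak when its amplitude strictly exceeds all grid
#' neighbors and exceeds `relative_threshold * (max - min) + min`. Peaks
#' closer than `min_separation_angle` to a stronger peak are suppressed,
#' and at most 3 peaks are kept, sorted by amplitude.
#'
#' @param odf Amplitude vector on `sphere` (raw or normalized).
#' @param sphere Sphere grid the ODF lives on.
#' @param min_separation_angle Degrees (default 25).
#' @param relative_threshold In `[0, 1]` (default 0.1).
#' @return Object of class `peak_set`: `directions` (k x 3), `qa`
#'   (amplitude minus the ODF global minimum, per peak), `amplitudes`.
#'   `k` may be 0.
#' @export
find_odf_peaks <- function(odf, sphere, min_separation_angle = 25,
                           relative_threshold = 0.1) {
  nb <- sphere$neighbors
  self <- seq_along(odf)
  nbr_max <- do.call(pmax, lapply(seq_len(ncol(nb)), function(j) {
    v <- odf[nb[, j]]
    v[nb[, j] == self] <- -Inf  # rows with < k neighbors are padded with self
    v
  }))
  mn <- min(odf); mx <- max(odf)
  thr <- mn + relative_threshold * (mx - mn)
  cand <- which(odf > nbr_max & odf >= thr)
  empty <- function() structure(list(
    directions = matrix(numeric(0), 0, 3), qa = numeric(0),
    amplitudes = numeric(0)), class = "peak_set")
  if (length(cand) == 0) return(empty())
  cand <- cand[order(odf[cand], decreasing = TRUE)]
  kept <- integer(0)
  cos_sep <- cos(deg2rad(min_separation_angle))
  for (c_ in cand) {
    if (length(kept) == 3) break
    if (length(kept) > 0) {
      d <- abs(sphere$vertices[kept, , drop = FALSE] %*% sphere$vertices[c_, ])
      if (any(d > cos_sep)) next
    }
    kept <- c(kept, c_)
  }
  structure(list(
    directions = sphere$vertices[kept, , drop = FALSE],
    qa = odf[kept] - mn,
    amplitudes = odf[kept]
  ), class = "peak_set")
}

#' Per-voxel fiber directions from ODF local maxima (GQI baseline)
#'
#' The classical peak-finding reconstruction used as a comparator for
#' fingerprint matching: each voxel's fibers are the local maxima of its
#' (unnormalized) GQI ODF.
#'
#' @param odf_field An `odf_field`.
#' @param min_separation_angle,relative_threshold See [find_odf_peaks()].
#' @return A `peak_field` (see [match_field()] for the layout).
#' @export
gqi_peak_field <- function(odf_field, min_separation_angle = 25,
                           relative_threshold = 0.1) {
  pf <- empty_peak_field(odf_field$dim, odf_field$affine)
  for (r in seq_along(odf_field$voxel_index)) {
    pk <- find_odf_peaks(odf_field$amplitudes[r, ], odf_field$sphere,
                         min_separation_angle, relative_threshold)
    k <- nrow(pk$directions)
    v <- odf_field$voxel_index[r]
    pf$n_fibers[v] <- k
    if (k > 0) {
      pf$dirs[v, seq_len(k), ] <- pk$directions
      pf$qa[v, seq_len(k)] <- pk$qa
    }
  }
  pf
}

empty_peak_field <- function(dim, affine) {
  nvox <- prod(dim)
  structure(list(
    dirs = array(0, c(nvox, 3, 3)),
    qa = matrix(0, nvox, 3),
    nqa = NULL,
    n_fibers = integer(nvox),
    dim = dim,
    affine = affine
  ), class = "peak_field")
}

#' Save / load an ODF field
#'
#' Serialized container (version-tagged) holding the amplitude matrix with
#' the sphere vertices and the affine alongside, so a reloaded field can
#' never be silently interpreted on the wrong grid.
#'
#' @param odf_field An `odf_field`.
#' @param path File path.
#' @export
save_odf_field <- function(odf_field, path) {
  if (!inherits(odf_field, "odf_field")) stop("not an odf_field")
  saveRDS(list(format_version = 1L, field = odf_field,
               checksum = array_checksum(odf_field$amplitudes)),
          path, version = 3)
  invisible(path)
}

#' @rdname save_odf_field
#' @export
load_odf_field <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or truncated ODF field file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$field, "odf_field"))
    stop("file is not an odfmatch ODF field")
  if (obj$format_version != 1L)
    stop("unsupported ODF field format version ", obj$format_version)
  if (abs(array_checksum(obj$field$amplitudes) - obj$checksum) > 1e-6)
    stop("ODF field integrity check failed")
  obj$field
}

#' Normalize a QA field to NQA
#'
#' NQA rescales Quantitative Anisotropy to `[0, 1]` by the maximum QA over
#' the brain, making the tracking stop threshold comparable across data sets.
#'
#' @param peak_field A `peak_field` with per-fiber `qa`.
#' @return The field with an `nqa` matrix added (`qa / max(qa)`).
#' @export
compute_nqa_field <- function(peak_field) {
  if (any(peak_field$qa < 0)) stop("QA must be >= 0")
  mx <- max(peak_field$qa)
  if (mx <= 0) stop("all-zero QA field: nothing to normalize")
  peak_field$nqa <- peak_field$qa / mx
  peak_field
}
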