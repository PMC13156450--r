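# Deterministic Euler streamline tractography over a peak field.
#
# Streamlines grow bidirectionally from random seeds in fixed steps along
# the trilinearly interpolated fiber direction best aligned with the
# incoming direction, and stop when the interpolated NQA falls below the
# threshold, the per-step turning angle exceeds the limit, or the front
# leaves the grid. Surviving lines are filtered by length.

#' Tractography parameters
#'
#' Defaults follow a standard deterministic protocol: NQA stop threshold
#' 0.10, maximum turning angle 60 degrees, streamline lengths restricted to
#' 30-200 mm, and 1e6 random seeds at research scale (pass smaller values
#' for desk-scale work).
#'
#' @param nqa_threshold Stop when interpolated NQA drops below this.
#' @param max_turning_angle Degrees per step.
#' @param step_size Step in mm; `NULL` means half the smallest voxel edge.
#' @param min_length,max_length Retained streamline lengths (mm).
#' @param n_seeds Number of random seeds.
#' @param rng_seed Seed RNG.
#' @return Object of class `tracking_params`.
#' @export
tracking_params <- function(nqa_threshold = 0.10, max_turning_angle = 60,
                            step_size = NULL, min_length = 30,
                            max_length = 200, n_seeds = 1e6,
                            rng_seed = 1L) {
  if (nqa_threshold < 0 || nqa_threshold > 1) stop("nqa_threshold must be in [0, 1]")
  if (min_length >= max_length) stop("min_length must be < max_length")
  if (!is.null(step_size) && step_size <= 0) stop("step_size must be > 0")
  structure(list(nqa_threshold = nqa_threshold,
                 max_turning_angle = max_turning_angle,
                 step_size = step_size, min_length = min_length,
                 max_length = max_length, n_seeds = n_seeds,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Draw random seed points inside a mask
#'
#' Seeds are uniform within the volume of the masked voxels: a voxel is
#' drawn uniformly (with replacement), then a uniform offset within it.
#'
#' @param mask 3-D logical array.
#' @param n Number of seeds.
#' @param rng_seed Integer seed.
#' @param affine Voxel-to-world matrix (mm).
#' @return n x 3 matrix of world coordinates (mm).
#' @export
generate_seeds <- function(mask, n, rng_seed = 1L, affine = diag(4)) {
  idx <- which(as.logical(mask))
  if (length(idx) == 0) stop("empty seed mask")
  if (n == 0) return(matrix(numeric(0), 0, 3))
  d <- dim(mask)
  with_seed(rng_seed, {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    ijk <- cbind((pick - 1) %% d[1],
                 ((pick - 1) %/% d[1]) %% d[2],
                 (pick - 1) %/% (d[1] * d[2]))
    off <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
    vox_to_world(ijk + off, affine)
  })
}

vox_to_world <- function(ijk, affine) {
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

world_to_vox <- function(pts, affine) {
  out <- cbind(pts, 1) %*% t(solve(affine))
  out[, 1:3, drop = FALSE]
}

#' Interpolate the tracking direction and NQA at arbitrary points
#'
#' Trilinear interpolation over the 8 surrounding voxels; each voxel
#' contributes its peak best aligned (by absolute dot product) with the
#' incoming direction, sign-flipped to propagate forward. Voxels without
#' peaks, and corners outside the grid, contribute zero direction and zero
#' NQA, so both decay naturally toward field boundaries.
#'
#' @param peak_field A `peak_field` with `nqa` (see [compute_nqa_field()]).
#' @param points n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @param previous_direction n x 3 matrix (or vector) of unit directions.
#' @return List of `direction` (n x 3, unit rows or NA when terminated),
#'   `nqa` (n), `ok` (n logical; FALSE means terminate).
#' @export
interpolate_direction <- function(peak_field, points, previous_direction) {
  if (is.null(peak_field$nqa))
    stop("peak field has no NQA; run compute_nqa_field() first")
  pts <- if (is.matrix(points)) points else matrix(points, 1, 3)
  prev <- if (is.matrix(previous_direction)) previous_direction else
    matrix(previous_direction, 1, 3)
  n <- nrow(pts)
  d <- peak_field$dim
  vox <- world_to_vox(pts, peak_field$affine)
  i0 <- floor(vox)
  fr <- vox - i0
  dir_acc <- matrix(0, n, 3)
  nqa_acc <- numeric(n)
  w_acc <- numeric(n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
    w <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (cz == 1) fr[, 3] else 1 - fr[, 3])
    valid <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & w > 0
    if (!any(valid)) next
    lin <- 1 + ii[valid] + d[1] * (jj[valid] + d[2] * kk[valid])
    m <- sum(valid)
    best_dot <- numeric(m); best_dir <- matrix(0, m, 3); best_nqa <- numeric(m)
    for (k in 1:3) {
      dk <- peak_field$dirs[lin, k, , drop = FALSE]
      dim(dk) <- c(m, 3)
      dot_k <- rowSums(dk * prev[valid, , drop = FALSE])
      better <- abs(dot_k) > abs(best_dot)
      if (any(better)) {
        best_dot[better] <- dot_k[better]
        best_dir[better, ] <- dk[better, , drop = FALSE]
        best_nqa[better] <- peak_field$nqa[lin[better], k]
      }
    }
    sgn <- ifelse(best_dot < 0, -1, 1)
    has_peak <- abs(best_dot) > 0
    contrib <- w[valid] * has_peak
    dir_acc[valid, ] <- dir_acc[valid, , drop = FALSE] + contrib * sgn * best_dir
    nqa_acc[valid] <- nqa_acc[valid] + w[valid] * best_nqa * has_peak
    w_acc[valid] <- w_acc[valid] + w[valid]
  }
  nrm <- sqrt(rowSums(dir_acc^2))
  ok <- w_acc > 1e-9 & nrm > 1e-9
  dir_out <- dir_acc / ifelse(nrm > 0, nrm, 1)
  dir_out[!ok, ] <- NA_real_
  list(direction = dir_out, nqa = nqa_acc, ok = ok)
}

# Grow all streamlines one direction in lockstep. Returns an array
# (max_steps x n x 3) of visited points (NA past termination) and the step
# count per line.
propagate_all <- function(peak_field, starts, dirs, params, step, max_steps) {
  n <- nrow(starts)
  traj <- array(NA_real_, c(max_steps, n, 3))
  pos <- starts
  prev <- dirs
  active <- rep(TRUE, n)
  steps <- integer(n)
  cos_limit <- cos(deg2rad(params$max_turning_angle))
  for (s in seq_len(max_steps)) {
    if (!any(active)) break
    res <- interpolate_direction(peak_field,
                                 pos[active, , drop = FALSE],
                                 prev[active, , drop = FALSE])
    cosang <- rowSums(res$direction * prev[active, , drop = FALSE])
    go <- res$ok & res$nqa >= params$nqa_threshold & !is.na(cosang) &
      cosang >= cos_limit
    idx <- which(active)
    stopped <- idx[!go]
    active[stopped] <- FALSE
    moving <- idx[go]
    if (length(moving) > 0) {
      newd <- res$direction[go, , drop = FALSE]
      pos[moving, ] <- pos[moving, , drop = FALSE] + step * newd
      prev[moving, ] <- newd
      traj[s, moving, ] <- pos[moving, , drop = FALSE]
      steps[moving] <- s
    }
  }
  list(traj = traj, steps = steps)
}

#' Track a single streamline from one seed
#'
#' Bidirectional Euler growth; both half-tracks share the seed point. No
#' length filtering is applied (see [run_tractography()]).
#'
#' @param peak_field A `peak_field` with NQA.
#' @param seed Length-3 world coordinate (mm).
#' @param params A [tracking_params()].
#' @return Matrix of points (possibly a single row when tracking stops
#'   immediately).
#' @export
track_streamline <- function(peak_field, seed, params = tracking_params()) {
  tg <- run_tractography_core(peak_field, matrix(seed, 1, 3), params)
  tg[[1]]
}

run_tractography_core <- function(peak_field, seeds, params) {
  d <- peak_field$dim
  voxel_edges <- sqrt(colSums(peak_field$affine[1:3, 1:3]^2))
  step <- params$step_size %||% (min(voxel_edges) / 2)
  if (step > min(voxel_edges) + 1e-9)
    stop("step_size must not exceed the voxel size")
  n <- nrow(seeds)
  if (n == 0) return(list())
  # initial direction: strongest peak of the nearest voxel
  vox <- round(world_to_vox(seeds, peak_field$affine))
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 & vox[, 2] < d[2] &
    vox[, 3] >= 0 & vox[, 3] < d[3]
  lin <- ifelse(inside, 1 + vox[, 1] + d[1] * (vox[, 2] + d[2] * vox[, 3]), 1L)
  init <- peak_field$dirs[lin, 1, , drop = FALSE]
  dim(init) <- c(n, 3)
  has_dir <- inside & sqrt(rowSums(init^2)) > 1e-9 &
    peak_field$nqa[lin, 1] >= params$nqa_threshold
  max_steps <- floor(params$max_length / step) + 1L
  fwd <- propagate_all(peak_field, seeds[has_dir, , drop = FALSE],
                       init[has_dir, , drop = FALSE], params, step, max_steps)
  bwd <- propagate_all(peak_field, seeds[has_dir, , drop = FALSE],
                       -init[has_dir, , drop = FALSE], params, step, max_steps)
  out <- vector("list", n)
  live <- which(has_dir)
  for (q in seq_along(live)) {
    i <- live[q]
    nf <- fwd$steps[q]; nb <- bwd$steps[q]
    fpts <- if (nf > 0) matrix(fwd$traj[seq_len(nf), q, ], nf, 3) else NULL
    bpts <- if (nb > 0) matrix(bwd$traj[seq_len(nb), q, ], nb, 3) else NULL
    pts <- rbind(if (!is.null(bpts)) bpts[rev(seq_len(nb)), , drop = FALSE],
                 seeds[i, , drop = FALSE], fpts)
    out[[i]] <- pts
  }
  dead <- which(!has_dir)
  for (i in dead) out[[i]] <- seeds[i, , drop = FALSE]
  attr(out, "step_size") <- step
  out
}

#' Whole-field deterministic tractography
#'
#' Seeds `params$n_seeds` random points in `seed_mask`, grows each
#' bidirectionally, and keeps streamlines whose length lies within
#' `[min_length, max_length]`. Fully reproducible from `params$rng_seed`.
#'
#' @param peak_field A `peak_field` with NQA (see [compute_nqa_field()]).
#' @param params A [tracking_params()].
#' @param seed_mask 3-D logical array of allowed seed voxels.
#' @return Object of class `tractogram`: `streamlines` (list of n x 3
#'   world-mm matrices), `affine`, `step_size`, `params`.
#' @export
run_tractography <- function(peak_field, params = tracking_params(),
                             seed_mask = NULL) {
  if (is.null(seed_mask)) seed_mask <- array(TRUE, peak_field$dim)
  stopifnot_same_grid(dim(seed_mask), peak_field$dim, "seed mask and peaks")
  seeds <- generate_seeds(seed_mask, params$n_seeds, params$rng_seed,
                          peak_field$affine)
  lines <- run_tractography_core(peak_field, seeds, params)
  step <- attr(lines, "step_size")
  lens <- vapply(lines, function(p) (nrow(p) - 1) * step, numeric(1))
  keep <- lens >= params$min_length & lens <= params$max_length
  structure(list(streamlines = lines[keep], affine = peak_field$affine,
                 step_size = step, params = params),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  lens <- streamline_lengths(x)
  cat(sprintf("tractogram: %d streamlines, lengths %.1f-%.1f mm (step %.2f mm)\n",
              length(x$streamlines),
              if (length(lens)) min(lens) else NA, if (length(lens)) max(lens) else NA,
              x$step_size))
  invisible(x)
}

#' Streamline lengths in mm
#' @param tractogram A `tractogram`.
#' @return Numeric vector of polyline lengths.
#' @export
streamline_lengths <- function(tractogram) {
  vapply(tractogram$streamlines, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
}
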