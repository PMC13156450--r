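# Regularized ODF-fingerprint matching.
#
# A measured, normalized ODF x is matched against dictionary elements d_j by
# maximizing
#
#   x' d_j  -  N_j * lambda  -  min(d_j) * mu
#
# The first term is plain cosine similarity (both vectors unit norm). The
# lambda term penalizes elements with more fibers, suppressing spurious
# crossings fitted to noise. The mu term penalizes elements with a high ODF
# global minimum: free-water contamination (vasogenic edema) inflates the
# isotropic floor of measured ODFs, and boosting mu steers the match toward
# sharper, more anisotropic fingerprints whose fiber directions survive the
# partial-volume dilution. mu may differ inside an edema mask (mu_edema).

#' Regularization parameters for fingerprint matching
#'
#' @param lambda Spurious-fiber penalty factor (>= 0, default 2e-5).
#' @param mu Anisotropy boosting factor outside edema (>= 0, default 0.1).
#' @param mu_edema Boosting factor inside the edema mask (default 0.3).
#' @return Object of class `reg_params`.
#' @export
reg_params <- function(lambda = 2e-5, mu = 0.1, mu_edema = 0.3) {
  if (lambda < 0 || mu < 0 || mu_edema < 0)
    stop("lambda, mu and mu_edema must all be >= 0")
  structure(list(lambda = lambda, mu = mu, mu_edema = mu_edema),
            class = "reg_params")
}

#' Cosine similarity of two unit-norm ODFs
#'
#' @param x,d Unit-norm amplitude vectors.
#' @return `x . d`, in `[0, 1]` for nonnegative ODFs.
#' @export
cosine_similarity <- function(x, d) {
  if (!is_unit(x) || !is_unit(d))
    stop("cosine_similarity requires unit-norm inputs")
  sum(x * d)
}

#' Regularized matching score of one dictionary element
#'
#' @param x Unit-norm measured ODF (already in the dictionary frame).
#' @param element A dictionary element (or [element_odf()] result) with
#'   `odf`, `n_fibers`, `min_amplitude`.
#' @param reg A [reg_params()] object.
#' @param mu_here The boosting factor in force at this voxel
#'   (`reg$mu` or `reg$mu_edema`).
#' @return The scalar penalized score.
#' @export
penalized_score <- function(x, element, reg, mu_here = reg$mu) {
  if (mu_here < 0) stop("mu must be >= 0")
  cosine_similarity(x, element$odf) -
    element$n_fibers * reg$lambda -
    element$min_amplitude * mu_here
}

#' Rotate a measured ODF into the dictionary's canonical frame
#'
#' The strongest ODF peak is mapped to +z; when a second peak exists, an
#' extra rotation about z places it in the x-z half-plane, matching the
#' frame the dictionary elements are generated in. The rotated ODF is
#' resampled on the same grid by nearest-dominant-weight spherical
#' interpolation: for each target vertex, the dominant (closest) source
#' vertex and its grid neighbors are combined with inverse-angle weights.
#' Peakless (flat) ODFs are flagged isotropic and left unrotated.
#'
#' @param x Amplitude vector on `sphere` (any positive scale).
#' @param sphere Sphere grid.
#' @param peaks Optional precomputed [find_odf_peaks()] result for `x`.
#' @return List with `amplitudes` (resampled, same scale), `rotation` (the
#'   3x3 matrix mapping measured directions into the canonical frame; its
#'   transpose de-rotates dictionary directions back), `isotropic`, `peaks`.
#' @export
canonical_align <- function(x, sphere, peaks = NULL) {
  if (is.null(peaks)) peaks <- find_odf_peaks(x, sphere)
  if (nrow(peaks$directions) == 0)
    return(list(amplitudes = x, rotation = diag(3), isotropic = TRUE,
                peaks = peaks))
  p1 <- refine_peak_direction(x, sphere, peaks$directions[1, ])
  r1 <- rotation_between(p1, c(0, 0, 1))
  rot <- r1
  if (nrow(peaks$directions) >= 2) {
    p2 <- refine_peak_direction(x, sphere, peaks$directions[2, ])
    p2 <- as.numeric(r1 %*% p2)
    if (p2[3] < 0) p2 <- -p2
    if (sqrt(p2[1]^2 + p2[2]^2) > 1e-9)
      rot <- rotation_about_z(-atan2(p2[2], p2[1])) %*% r1
  }
  list(amplitudes = resample_rotated(x, sphere, rot), rotation = rot,
       isotropic = FALSE, peaks = peaks)
}

# Sub-vertex refinement of a peak direction: amplitude-above-floor weighted
# mean of the peak vertex and its grid neighbors (sign-aligned for antipodal
# symmetry). Reduces grid quantization of the alignment rotation.
refine_peak_direction <- function(x, sphere, peak_dir) {
  i <- which.max(abs(sphere$vertices %*% peak_dir))
  nb <- unique(c(i, sphere$neighbors[i, ]))
  vv <- sphere$vertices[nb, , drop = FALSE]
  sgn <- sign(vv %*% sphere$vertices[i, ])
  w <- pmax(0, x[nb] - min(x))
  m <- colSums(as.numeric(w * sgn) * vv)
  if (vnorm(m) < 1e-12) return(sphere$vertices[i, ])
  unit(m)
}

# Evaluate x(R^T v) for every grid vertex v: dominant source vertex plus its
# neighbors, inverse-angle weighted (antipodal symmetry via |dot|).
resample_rotated <- function(x, sphere, rot) {
  v <- sphere$vertices
  w <- v %*% rot                      # row i = t(rot) %*% v_i
  dots <- abs(w %*% t(v))
  best <- max.col(dots, ties.method = "first")
  cand <- cbind(best, sphere$neighbors[best, , drop = FALSE])
  n <- nrow(v)
  dv <- matrix(dots[cbind(rep(seq_len(n), ncol(cand)), as.integer(cand))],
               n, ncol(cand))
  ang <- acos(pmin(dv, 1))
  wt <- 1 / (ang + 1e-4)
  # padded neighbor slots can repeat the dominant vertex; zero their weight
  dup <- cand == best & col(cand) > 1
  wt[dup] <- 0
  xs <- matrix(x[as.integer(cand)], n, ncol(cand))
  rowSums(wt * xs) / rowSums(wt)
}

#' Match one aligned ODF against the dictionary
#'
#' Returns the element maximizing the regularized score. Ties are broken by
#' the lowest fiber count, then the lowest element index.
#'
#' @param x Unit-norm ODF, already rotated into the dictionary frame
#'   (see [canonical_align()]).
#' @param dict An `odf_dictionary`.
#' @param reg A [reg_params()] object.
#' @param mu_here Boosting factor in force at this voxel.
#' @param rotation The alignment rotation from [canonical_align()]; used to
#'   de-rotate the matched fiber directions into the measured frame.
#' @param raw_norm Euclidean norm of the unnormalized measured ODF; scales
#'   the per-fiber QA values.
#' @return Object of class `match_result`: `index`, `score`, `n_fibers`,
#'   `directions` (world frame, k x 3), `qa`, `free_water_fraction`,
#'   `isotropic`.
#' @export
match_one <- function(x, dict, reg, mu_here = reg$mu,
                      rotation = diag(3), raw_norm = 1) {
  if (dict$meta$size < 1) stop("empty dictionary")
  if (!is_unit(x)) stop("x must be unit norm (normalize after alignment)")
  if (mu_here < 0) stop("mu must be >= 0")
  scores <- as.numeric(dict$odfs %*% x) -
    dict$n_fibers * reg$lambda - dict$min_amplitude * mu_here
  j <- argmax_tiebreak(scores, dict$n_fibers)
  build_match_result(j, scores[j], dict, rotation, raw_norm)
}

argmax_tiebreak <- function(scores, n_fibers) {
  m <- max(scores)
  cand <- which(scores == m)
  if (length(cand) > 1) cand <- cand[order(n_fibers[cand], cand)]
  cand[1]
}

build_match_result <- function(j, score, dict, rotation, raw_norm) {
  k <- dict$n_fibers[j]
  dirs_canon <- dict$fiber_dirs[j, seq_len(k), , drop = FALSE]
  dim(dirs_canon) <- c(k, 3)
  dirs_world <- dirs_canon %*% rotation  # rows = t(rotation) %*% d
  qa <- numeric(k)
  if (k > 0) {
    # element sharpness at each fiber, scaled by the measured ODF magnitude
    nv <- length(dict$odfs[j, ])
    for (f in seq_len(k)) {
      amp <- dict$odfs[j, which.max(abs(dict_vertex_cache(dict) %*% dirs_canon[f, ]))]
      qa[f] <- raw_norm * (amp - dict$min_amplitude[j])
    }
  }
  structure(list(index = j, score = score, n_fibers = k,
                 directions = dirs_world, qa = qa,
                 free_water_fraction = dict$free_water_fraction[j],
                 isotropic = k == 0L),
            class = "match_result")
}

# Dictionaries do not store the sphere; cache vertices alongside for QA
# lookups (set by match_field / tests via attribute).
dict_vertex_cache <- function(dict) {
  v <- attr(dict, "sphere_vertices")
  if (is.null(v)) stop("dictionary has no sphere vertices attached; ",
                       "use match_field() or attach_sphere()")
  v
}

#' Attach a sphere grid to a dictionary for direction-amplitude lookups
#' @param dict An `odf_dictionary`.
#' @param sphere The sphere grid it was built on.
#' @export
attach_sphere <- function(dict, sphere) {
  if (abs(sphere$checksum - dict$meta$sphere_checksum) > 1e-6)
    stop("sphere grid does not match the dictionary")
  attr(dict, "sphere_vertices") <- sphere$vertices
  dict
}

#' Align every masked voxel of an ODF field to the dictionary frame
#'
#' Splitting alignment from scoring lets several regularization settings be
#' evaluated against the same aligned field without recomputing rotations.
#'
#' @param odf_field An `odf_field`.
#' @return List with `x` (masked voxels x vertices, unit rows; isotropic
#'   voxels hold their normalized flat ODF), `rotations` (n x 3 x 3),
#'   `raw_norm`, `isotropic`, `voxel_index`, `dim`, `affine`, `sphere`.
#' @export
align_field <- function(odf_field) {
  n <- length(odf_field$voxel_index)
  nv <- nrow(odf_field$sphere$vertices)
  x <- matrix(0, n, nv)
  rotations <- array(0, c(n, 3, 3))
  raw_norm <- numeric(n)
  isotropic <- logical(n)
  for (r in seq_len(n)) {
    amp <- odf_field$amplitudes[r, ]
    raw_norm[r] <- vnorm(amp)
    if (raw_norm[r] < 1e-300) { isotropic[r] <- TRUE; rotations[r, , ] <- diag(3); next }
    al <- canonical_align(amp, odf_field$sphere)
    rotations[r, , ] <- al$rotation
    isotropic[r] <- al$isotropic
    x[r, ] <- normalize_odf(al$amplitudes)
  }
  list(x = x, rotations = rotations, raw_norm = raw_norm,
       isotropic = isotropic, voxel_index = odf_field$voxel_index,
       dim = odf_field$dim, affine = odf_field$affine,
       sphere = odf_field$sphere)
}

#' Match every voxel of an ODF field against the dictionary
#'
#' Voxels inside `edema_mask` are scored with `reg$mu_edema`, all others
#' with `reg$mu`. Isotropic-flagged voxels get 0 fibers and QA 0, so
#' tracking stops there.
#'
#' @param odf_field An `odf_field` (or the result of [align_field()]).
#' @param dict An `odf_dictionary` built on the same sphere grid.
#' @param reg A [reg_params()] object.
#' @param edema_mask Optional 3-D logical array on the same grid.
#' @return Object of class `peak_field`: flat-grid arrays `dirs`
#'   (voxels x 3 x 3), `qa` (voxels x 3), `n_fibers`, `matched_index`,
#'   `free_water`, plus `dim` and `affine`. Run [compute_nqa_field()] before
#'   tracking.
#' @export
match_field <- function(odf_field, dict, reg, edema_mask = NULL) {
  aligned <- if (inherits(odf_field, "odf_field")) {
    if (abs(odf_field$sphere$checksum - dict$meta$sphere_checksum) > 1e-6)
      stop("dictionary and ODF field use different sphere grids")
    align_field(odf_field)
  } else odf_field
  mu_vox <- rep(reg$mu, length(aligned$voxel_index))
  if (!is.null(edema_mask)) {
    stopifnot_same_grid(dim(edema_mask), aligned$dim, "edema mask and data")
    mu_vox[as.logical(edema_mask)[aligned$voxel_index]] <- reg$mu_edema
  }
  match_aligned(aligned, dict, reg, mu_vox)
}

#' Score an aligned field under given per-voxel boosting factors
#'
#' Lower-level entry used by [match_field()] and by parameter sweeps over
#' mu_edema; the cosine term is one matrix product over all voxels.
#'
#' @param aligned Result of [align_field()].
#' @param dict Dictionary.
#' @param reg A [reg_params()].
#' @param mu_vox Numeric vector, one boosting factor per masked voxel.
#' @return A `peak_field` (see [match_field()]).
#' @export
match_aligned <- function(aligned, dict, reg, mu_vox) {
  n <- nrow(aligned$x)
  if (length(mu_vox) != n) stop("mu_vox must have one entry per masked voxel")
  dict <- attach_sphere(dict, aligned$sphere)
  cos_mat <- dict$odfs %*% t(aligned$x)   # size x n
  pen_l <- dict$n_fibers * reg$lambda
  pf <- empty_peak_field(aligned$dim, aligned$affine)
  pf$matched_index <- integer(prod(aligned$dim))
  pf$free_water <- rep(NA_real_, prod(aligned$dim))
  for (r in seq_len(n)) {
    v <- aligned$voxel_index[r]
    if (aligned$isotropic[r]) next
    s <- cos_mat[, r] - pen_l - dict$min_amplitude * mu_vox[r]
    j <- argmax_tiebreak(s, dict$n_fibers)
    res <- build_match_result(j, s[j], dict, aligned$rotations[r, , ],
                              aligned$raw_norm[r])
    pf$matched_index[v] <- j
    pf$free_water[v] <- res$free_water_fraction
    k <- res$n_fibers
    pf$n_fibers[v] <- k
    if (k > 0) {
      pf$dirs[v, seq_len(k), ] <- res$directions
      pf$qa[v, seq_len(k)] <- res$qa
    }
  }
  pf
}
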