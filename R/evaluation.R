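# Tract-evaluation statistics: edema overlap enhancement, TPR, Dice, HD95,
# and per-subject min-max normalization across methods.

#' Voxelize a tractogram onto a reference grid
#'
#' Marks every voxel visited by any streamline point (each point mapped to
#' its containing voxel under the voxel-center convention).
#'
#' @param tractogram A `tractogram` (world-mm streamlines).
#' @param dim Reference grid size (voxels).
#' @param affine Voxel-to-world matrix of the reference grid.
#' @return 3-D logical array.
#' @export
tract_to_mask <- function(tractogram, dim, affine = tractogram$affine) {
  mask <- array(FALSE, dim)
  pts <- do.call(rbind, tractogram$streamlines)
  if (is.null(pts) || nrow(pts) == 0) return(mask)
  vox <- round(world_to_vox(pts, affine))
  ok <- vox[, 1] >= 0 & vox[, 1] < dim[1] & vox[, 2] >= 0 & vox[, 2] < dim[2] &
    vox[, 3] >= 0 & vox[, 3] < dim[3]
  lin <- 1 + vox[ok, 1] + dim[1] * (vox[ok, 2] + dim[2] * vox[ok, 3])
  mask[unique(lin)] <- TRUE
  mask
}

check_binary <- function(m, name) {
  v <- as.numeric(m)
  if (!all(v %in% c(0, 1))) stop(name, " must be binary")
  invisible(TRUE)
}

#' Overlap volume of two masks
#'
#' @param tract_mask,roi_mask 3-D binary arrays on the same grid.
#' @param voxel_volume Voxel volume in mm^3 (default 1).
#' @return List with `voxels` (count) and `mm3`.
#' @export
overlap_volume <- function(tract_mask, roi_mask, voxel_volume = 1) {
  stopifnot_same_grid(dim(tract_mask), dim(roi_mask), "masks")
  check_binary(tract_mask, "tract_mask"); check_binary(roi_mask, "roi_mask")
  n <- sum(as.logical(tract_mask) & as.logical(roi_mask))
  list(voxels = n, mm3 = n * voxel_volume)
}

#' Normalized edema overlap enhancement across methods
#'
#' Min-max normalizes per-method tract-edema overlap volumes to percent:
#' the worst method maps to 0%, the best to 100%.
#'
#' @param volumes Named numeric vector of overlap volumes, one per method.
#' @return Named vector of percentages; all-`NaN` with a warning when all
#'   volumes are equal (the enhancement is then undefined).
#' @export
edema_overlap_enhancement <- function(volumes) {
  normalize_metric(volumes)
}

#' Per-subject min-max normalization of a metric across methods
#'
#' @param scores Named numeric vector (>= 2 methods).
#' @return Named vector mapping the minimum to 0% and the maximum to 100%.
#' @export
normalize_metric <- function(scores) {
  if (length(scores) < 2) stop("normalization needs at least 2 methods")
  rng <- range(scores)
  if (diff(rng) == 0) {
    warning("all methods scored equally; normalized metric is undefined")
    out <- rep(NaN, length(scores))
    names(out) <- names(scores)
    return(out)
  }
  (scores - rng[1]) / diff(rng) * 100
}

#' True positive ratio of a tract against a reference mask
#'
#' `|tract & ref| / |ref|`.
#'
#' @param tract_mask,ref_mask Binary arrays on the same grid.
#' @return Ratio in `[0, 1]`.
#' @export
tpr <- function(tract_mask, ref_mask) {
  stopifnot_same_grid(dim(tract_mask), dim(ref_mask), "masks")
  nb <- sum(as.logical(ref_mask))
  if (nb == 0) stop("reference mask is empty")
  sum(as.logical(tract_mask) & as.logical(ref_mask)) / nb
}

#' Dice coefficient of two masks
#'
#' `2 |A & B| / (|A| + |B|)`; symmetric, in `[0, 1]`.
#'
#' @param mask_a,mask_b Binary arrays on the same grid.
#' @return Dice coefficient.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot_same_grid(dim(mask_a), dim(mask_b), "masks")
  na <- sum(as.logical(mask_a)); nb <- sum(as.logical(mask_b))
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(as.logical(mask_a) & as.logical(mask_b)) / (na + nb)
}

# Min distance from each row of A to the rows of B (mm), chunked.
nearest_distances <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  b2 <- rowSums(b^2)
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    m <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(m^2), b2, "+") - 2 * m %*% t(b)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

mask_coords_mm <- function(mask, affine) {
  idx <- which(as.logical(mask))
  d <- dim(mask)
  ijk <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  vox_to_world(ijk, affine)
}

#' 95% Hausdorff distance between two voxel masks
#'
#' The maximum over both directions of the 95th percentile of
#' nearest-neighbor Euclidean distances between voxel centers (mm).
#' Percentiles use linear interpolation between order statistics.
#'
#' @param mask_a,mask_b Nonempty binary arrays on the same grid.
#' @param affine Voxel-to-world matrix (mm).
#' @return HD95 in mm.
#' @export
hd95 <- function(mask_a, mask_b, affine = diag(4)) {
  stopifnot_same_grid(dim(mask_a), dim(mask_b), "masks")
  if (sum(as.logical(mask_a)) == 0 || sum(as.logical(mask_b)) == 0)
    stop("hd95 requires two nonempty masks")
  pa <- mask_coords_mm(mask_a, affine)
  pb <- mask_coords_mm(mask_b, affine)
  d_ab <- stats::quantile(nearest_distances(pa, pb), 0.95, type = 7, names = FALSE)
  d_ba <- stats::quantile(nearest_distances(pb, pa), 0.95, type = 7, names = FALSE)
  max(d_ab, d_ba)
}
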