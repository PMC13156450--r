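# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

is_unit <- function(v, tol = 1e-6) abs(vnorm(v) - 1) <= tol

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two directions under antipodal symmetry
#'
#' Fiber orientations are axial quantities: `u` and `-u` denote the same
#' fiber. The angle reported is therefore in `[0, 90]` degrees.
#'
#' @param u,v Unit 3-vectors (rows of a matrix are also accepted, pairwise).
#' @return Angle(s) in degrees.
#' @export
axial_angle <- function(u, v) {
  if (is.matrix(u) || is.matrix(v)) {
    u <- if (is.matrix(u)) u else matrix(u, nrow(v), 3, byrow = TRUE)
    v <- if (is.matrix(v)) v else matrix(v, nrow(u), 3, byrow = TRUE)
    d <- abs(rowSums(u * v))
  } else {
    d <- abs(sum(u * v))
  }
  rad2deg(acos(pmin(1, d)))
}

# Rotation matrix mapping unit vector `v` onto `target` (both unit norm),
# via Rodrigues' formula around axis v x target.
rotation_between <- function(v, target = c(0, 0, 1)) {
  v <- unit(v); target <- unit(target)
  c_ <- sum(v * target)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate around any axis orthogonal to v
    axis <- if (abs(v[1]) < 0.9) unit(pracma_cross(v, c(1, 0, 0))) else unit(pracma_cross(v, c(0, 1, 0)))
    K <- skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- unit(pracma_cross(v, target))
  s_ <- sqrt(max(0, 1 - c_^2))
  K <- skew(axis)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

# Rotation about +z by `phi` radians (right-handed).
rotation_about_z <- function(phi) {
  cp <- cos(phi); sp <- sin(phi)
  matrix(c(cp, sp, 0, -sp, cp, 0, 0, 0, 1), 3, 3)
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable numeric checksum of an array: order-sensitive weighted sum of
# values rounded to 8 decimals. Used to tie dictionaries to sphere grids
# and to assert byte-level reproducibility in a portable way.
array_checksum <- function(x) {
  v <- round(as.numeric(x), 8)
  w <- seq_along(v) %% 97 + 1
  sum(v * w) + length(v) * 1e-3
}

stopifnot_same_grid <- function(dim_a, dim_b, what = "inputs") {
  if (!identical(as.integer(dim_a), as.integer(dim_b)))
    stop(sprintf("%s are defined on different grids (%s vs %s)",
                 what, paste(dim_a, collapse = "x"), paste(dim_b, collapse = "x")))
  invisible(TRUE)
}
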