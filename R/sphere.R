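# Hemisphere sampling grids for ODFs.
#
# Diffusion ODFs are antipodally symmetric, so amplitudes are stored on one
# hemisphere only. Grids come from repeated 4-fold subdivision of a regular
# icosahedron projected back to the unit sphere; the icosahedron is
# antipodally symmetric and subdivision preserves that symmetry, so every
# vertex has its antipode in the tessellation and exactly half the vertices
# represent the full sphere. A subdivision level s yields 10*4^s + 2 full
# vertices, i.e. 5*4^s + 1 hemisphere vertices (s = 3 gives the default 321).

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_icosphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midpoint_cache <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- midpoint_cache[[key]]
    if (!is.null(hit)) return(hit)
    m <- unit(verts[[i]] + verts[[j]])
    verts[[length(verts) + 1]] <<- m
    idx <- length(verts)
    midpoint_cache[[key]] <- idx
    idx
  }
  new_faces <- matrix(0L, nrow(f) * 4L, 3L)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
    new_faces[(k - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = new_faces)
}

# Pick one representative per antipodal pair: upper hemisphere by z, ties
# broken by y then x, so the choice is deterministic.
hemisphere_select <- function(v, tol = 1e-9) {
  keep <- v[, 3] > tol |
    (abs(v[, 3]) <= tol & v[, 2] > tol) |
    (abs(v[, 3]) <= tol & abs(v[, 2]) <= tol & v[, 1] > tol)
  keep
}

#' Build a quasi-uniform hemisphere grid for ODF sampling
#'
#' Constructs the hemisphere half of a subdivided icosahedron, together with
#' the neighbor structure needed for local-maximum (peak) detection. The
#' subdivision level is chosen so the hemisphere vertex count is as close as
#' possible to `n_vertices`; achievable counts are `5 * 4^s + 1`
#' (21, 81, 321, 1281, ...). A warning is emitted when the request is rounded.
#'
#' @param n_vertices Requested number of hemisphere vertices (>= 60).
#' @return An object of class `sphere_grid` with elements
#'   `vertices` (n x 3 unit rows), `neighbors` (n x k index matrix, rows
#'   padded with the vertex's own index), `subdivision`, and `checksum`
#'   (a numeric fingerprint used to tie dictionaries to grids).
#' @examples
#' sph <- build_sphere_grid(321)
#' nrow(sph$vertices)
#' @export
build_sphere_grid <- function(n_vertices = 321) {
  if (n_vertices < 60) stop("n_vertices must be >= 60")
  levels <- 2:6
  counts <- 5 * 4^levels + 1
  s <- levels[which.min(abs(counts - n_vertices))]
  if (counts[match(s, levels)] != n_vertices)
    warning(sprintf("no icosphere subdivision has %d hemisphere vertices; using %d",
                    n_vertices, counts[match(s, levels)]))
  mesh <- icosahedron()
  for (i in seq_len(s)) mesh <- subdivide_icosphere(mesh)
  v <- mesh$vertices
  keep <- hemisphere_select(v)
  hemi_idx <- which(keep)
  # map every full-sphere vertex to its hemisphere representative
  rep_of <- integer(nrow(v))
  rep_of[hemi_idx] <- seq_along(hemi_idx)
  anti <- -v
  for (i in which(!keep)) {
    d <- colSums((t(v[hemi_idx, , drop = FALSE]) - anti[i, ])^2)
    rep_of[i] <- which.min(d)
  }
  # adjacency between hemisphere representatives, from triangulation edges
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e1 <- rep_of[edges[, 1]]; e2 <- rep_of[edges[, 2]]
  ok <- e1 != e2
  nb <- split(c(e2[ok], e1[ok]), c(e1[ok], e2[ok]))
  nb <- lapply(nb, function(x) sort(unique(x)))
  k <- max(lengths(nb))
  neighbors <- matrix(0L, length(hemi_idx), k)
  for (i in seq_along(hemi_idx)) {
    ni <- nb[[as.character(i)]]
    neighbors[i, ] <- c(ni, rep(i, k - length(ni)))
  }
  vertices <- v[hemi_idx, , drop = FALSE]
  structure(list(
    vertices = vertices,
    neighbors = neighbors,
    subdivision = s,
    checksum = array_checksum(vertices)
  ), class = "sphere_grid")
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("sphere_grid: %d hemisphere vertices (subdivision %d)\n",
              nrow(x$vertices), x$subdivision))
  invisible(x)
}
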