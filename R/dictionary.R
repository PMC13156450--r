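# Random ODF-fingerprint dictionaries.
#
# Each element is the normalized GQI ODF of a synthetic voxel with a known
# number of fibers (0..3), known canonical fiber directions, and known
# microstructure. By default the dictionary is built in a canonical frame:
# the first fiber lies on +z and the second in the x-z half-plane, so the
# dictionary spends its elements on relative fiber geometry; measured ODFs
# are rotated into this frame before matching (see canonical_align()).

#' Default microstructure sampling ranges for dictionary generation
#'
#' Biologically standard ranges for healthy-to-edematous white matter:
#' axial diffusivity U(1.0, 2.0)e-3 mm^2/s, radial U(0.1, 0.7)e-3 mm^2/s,
#' free water fixed at 3.0e-3 mm^2/s, per-fiber volume fractions >= 0.05,
#' minimum inter-fiber angle 30 degrees, fiber counts uniform on {0,1,2,3}.
#' Every entry can be overridden to substitute other parameter tables.
#'
#' @return Named list of ranges understood by [sample_element_params()].
#' @export
default_param_ranges <- function() {
  list(
    axial_diffusivity = c(1.0e-3, 2.0e-3),
    radial_diffusivity = c(0.1e-3, 0.7e-3),
    free_water_diffusivity = 3.0e-3,
    min_fraction = 0.05,
    min_separation_deg = 30,
    n_fiber_weights = rep(0.25, 4),
    randomize_orientation = FALSE
  )
}

check_ranges <- function(r) {
  for (f in c("axial_diffusivity", "radial_diffusivity")) {
    if (r[[f]][1] > r[[f]][2])
      stop(sprintf("degenerate range for %s: min > max", f))
  }
  if (length(r$n_fiber_weights) != 4 || any(r$n_fiber_weights < 0) ||
      sum(r$n_fiber_weights) <= 0)
    stop("n_fiber_weights must be 4 nonnegative weights for counts 0..3")
  invisible(r)
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])

# Uniform direction on the upper hemisphere.
random_hemi_dir <- function() {
  z <- stats::runif(1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

#' Draw one random microstructure configuration
#'
#' Fiber count follows `ranges$n_fiber_weights`. In the canonical frame the
#' first fiber lies on +z, the second in the x-z half-plane at a polar angle
#' at least `min_separation_deg`, and the third anywhere at least that far
#' from both. The free-water fraction is uniform on what the per-fiber
#' minimum fractions leave available; fiber fractions share the remainder.
#'
#' @param ranges See [default_param_ranges()].
#' @return A [microstructure_params()] object.
#' @export
sample_element_params <- function(ranges = default_param_ranges()) {
  check_ranges(ranges)
  n <- sample.int(4, 1, prob = ranges$n_fiber_weights) - 1L
  if (n == 0L)
    return(microstructure_params(0, free_water_fraction = 1,
                                 free_water_diffusivity = ranges$free_water_diffusivity))
  fw <- stats::runif(1, 0, 1 - n * ranges$min_fraction)
  repeat {
    w <- stats::runif(n)
    fr <- (1 - fw) * w / sum(w)
    if (all(fr >= ranges$min_fraction - 1e-12)) break
  }
  min_sep <- ranges$min_separation_deg
  dirs <- matrix(c(0, 0, 1), 1, 3)
  if (n >= 2L) {
    th <- deg2rad(stats::runif(1, min_sep, 90))
    dirs <- rbind(dirs, c(sin(th), 0, cos(th)))
  }
  if (n >= 3L) {
    repeat {
      d3 <- random_hemi_dir()
      if (all(axial_angle(dirs, matrix(d3, nrow(dirs), 3, byrow = TRUE)) >= min_sep))
        break
    }
    dirs <- rbind(dirs, d3)
  }
  if (isTRUE(ranges$randomize_orientation)) {
    rot <- rotation_between(c(0, 0, 1), random_hemi_dir()) %*%
      rotation_about_z(stats::runif(1, 0, 2 * pi))
    dirs <- dirs %*% t(rot)
  }
  microstructure_params(
    n, fiber_dirs = dirs, fiber_fractions = fr, free_water_fraction = fw,
    axial_diffusivity = stats::runif(n, ranges$axial_diffusivity[1], ranges$axial_diffusivity[2]),
    radial_diffusivity = stats::runif(n, ranges$radial_diffusivity[1], ranges$radial_diffusivity[2]),
    free_water_diffusivity = ranges$free_water_diffusivity,
    min_separation_deg = min_sep)
}

#' Build one dictionary element from microstructure parameters
#'
#' Pipeline: simulate the noiseless voxel signal, apply the GQI transform,
#' and normalize to unit Euclidean norm. The ODF global minimum is cached
#' because the anisotropy-boosting penalty uses it for every match.
#'
#' @param params A [microstructure_params()] object.
#' @param gtab Gradient table.
#' @param sphere Sphere grid.
#' @param kernel Optional precomputed [gqi_kernel()].
#' @return List with `odf` (unit norm), `n_fibers`, `fiber_dirs`,
#'   `min_amplitude`, `free_water_fraction`, `params`.
#' @export
element_odf <- function(params, gtab, sphere, kernel = NULL) {
  if (is.null(kernel)) kernel <- gqi_kernel(gtab, sphere)
  s <- simulate_voxel_signal(params, gtab)
  odf <- normalize_odf(as.numeric(gqi_transform_signals(rbind(s), kernel)))
  list(odf = odf,
       n_fibers = params$n_fibers,
       fiber_dirs = params$fiber_dirs,
       min_amplitude = min(odf),
       free_water_fraction = params$free_water_fraction,
       params = params)
}

#' Build a random ODF-fingerprint dictionary
#'
#' @param size Number of elements (>= 1). The research-scale default
#'   configuration is 1e6 elements; desk-scale work uses 1e4.
#' @param gtab Gradient table the dictionary is generated for.
#' @param sphere Sphere grid.
#' @param ranges Microstructure sampling ranges ([default_param_ranges()]).
#' @param seed Integer RNG seed; together with `ranges` it fully determines
#'   the dictionary.
#' @param max_bytes Refuse to allocate an element matrix larger than this
#'   (default 4 GiB).
#' @return Object of class `odf_dictionary`: `odfs` (size x vertices, unit
#'   rows), `n_fibers`, `min_amplitude`, `fiber_dirs` (size x 3 x 3,
#'   zero-padded), `free_water_fraction`, and `meta`.
#' @export
build_dictionary <- function(size, gtab, sphere,
                             ranges = default_param_ranges(),
                             seed = 1L, max_bytes = 4e9) {
  if (size < 1) stop("size must be >= 1")
  check_ranges(ranges)
  nv <- nrow(sphere$vertices)
  need <- size * nv * 8
  if (need > max_bytes)
    stop(sprintf(paste0("a %d x %d dictionary needs %.1f GiB > budget %.1f GiB; ",
                        "reduce size or raise max_bytes"),
                 size, nv, need / 2^30, max_bytes / 2^30))
  ng <- length(gtab$bvals)
  signals <- matrix(0, size, ng)
  n_fibers <- integer(size)
  fiber_dirs <- array(0, c(size, 3, 3))
  fw <- numeric(size)
  with_seed(seed, {
    for (i in seq_len(size)) {
      p <- sample_element_params(ranges)
      signals[i, ] <- simulate_voxel_signal(p, gtab)
      n_fibers[i] <- p$n_fibers
      if (p$n_fibers > 0) fiber_dirs[i, seq_len(p$n_fibers), ] <- p$fiber_dirs
      fw[i] <- p$free_water_fraction
    }
  })
  kernel <- gqi_kernel(gtab, sphere)
  odfs <- normalize_odf(gqi_transform_signals(signals, kernel))
  structure(list(
    odfs = odfs,
    n_fibers = n_fibers,
    min_amplitude = apply(odfs, 1, min),
    fiber_dirs = fiber_dirs,
    free_water_fraction = fw,
    meta = list(
      format_version = 1L,
      size = as.integer(size),
      seed = as.integer(seed),
      ranges = ranges,
      sphere_checksum = sphere$checksum,
      n_vertices = nv,
      bvals = gtab$bvals,
      odf_checksum = array_checksum(odfs)
    )
  ), class = "odf_dictionary")
}

#' @export
print.odf_dictionary <- function(x, ...) {
  cat(sprintf("odf_dictionary: %d elements x %d vertices (seed %d)\n",
              x$meta$size, x$meta$n_vertices, x$meta$seed))
  cat(sprintf("  fiber counts: %s\n",
              paste(sprintf("%d-fiber %d", 0:3, tabulate(x$n_fibers + 1L, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Save / load a dictionary
#'
#' Dictionaries are stored as a single serialized container with an embedded
#' format version and a checksum of the element matrix; the checksum and the
#' sphere fingerprint are verified on load so that a dictionary can never be
#' silently matched against data on an incompatible grid.
#'
#' @param dict An `odf_dictionary`.
#' @param path File path.
#' @export
save_dictionary <- function(dict, path) {
  if (!inherits(dict, "odf_dictionary")) stop("not an odf_dictionary")
  saveRDS(dict, path, version = 3)
  invisible(path)
}

#' @rdname save_dictionary
#' @param sphere Optional sphere grid the dictionary will be used with;
#'   loading fails if its fingerprint differs from the one stored.
#' @param gtab Optional gradient table to validate against stored b-values.
#' @export
load_dictionary <- function(path, sphere = NULL, gtab = NULL) {
  dict <- tryCatch(readRDS(path),
                   error = function(e) stop("corrupt or truncated dictionary file: ",
                                            conditionMessage(e)))
  if (!inherits(dict, "odf_dictionary") || is.null(dict$meta$format_version))
    stop("file is not an odfmatch dictionary")
  if (dict$meta$format_version != 1L)
    stop(sprintf("unsupported dictionary format version %s", dict$meta$format_version))
  if (abs(array_checksum(dict$odfs) - dict$meta$odf_checksum) > 1e-6)
    stop("dictionary integrity check failed: element matrix does not match its checksum")
  if (!is.null(sphere) && abs(sphere$checksum - dict$meta$sphere_checksum) > 1e-6)
    stop("dictionary was built on a different sphere grid than the target data")
  if (!is.null(gtab) && !isTRUE(all.equal(gtab$bvals, dict$meta$bvals)))
    stop("dictionary was built for a different gradient scheme")
  dict
}
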