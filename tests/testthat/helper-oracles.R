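# Independent oracles, kept deliberately naive and separate from package code.

# Exhaustive regularized-match scan with explicit per-element arithmetic.
bf_match_index <- function(x, dict, lambda, mu) {
  n <- dict$meta$size
  scores <- numeric(n)
  for (j in seq_len(n)) {
    scores[j] <- sum(x * dict$odfs[j, ]) -
      dict$n_fibers[j] * lambda - dict$min_amplitude[j] * mu
  }
  m <- max(scores)
  cand <- which(scores == m)
  if (length(cand) > 1) cand <- cand[order(dict$n_fibers[cand], cand)]
  cand[1]
}

# Brute-force local-maximum enumeration mirroring the documented peak rules.
bf_find_peaks <- function(odf, sphere, min_sep = 25, rel_thr = 0.1) {
  n <- length(odf)
  mn <- min(odf); mx <- max(odf)
  thr <- mn + rel_thr * (mx - mn)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    nb <- setdiff(unique(sphere$neighbors[i, ]), i)
    is_max[i] <- all(odf[i] > odf[nb]) && odf[i] >= thr
  }
  cand <- which(is_max)
  cand <- cand[order(odf[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (c_ in cand) {
    if (length(kept) == 3) break
    ok <- TRUE
    for (k in kept) {
      a <- acos(min(1, abs(sum(sphere$vertices[c_, ] * sphere$vertices[k, ])))) * 180 / pi
      if (a < min_sep) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, c_)
  }
  kept
}

# Dense exhaustive ODF argmax on an independent 3210-direction point set.
dense_odf_argmax <- function(signal, gtab, sampling_length = 1.25,
                             water_diffusivity = 3.0e-3) {
  dirs <- odfmatch:::fibonacci_directions(3210)
  l <- sampling_length * sqrt(6 * water_diffusivity * gtab$bvals)
  best_val <- -Inf; best_dir <- NULL
  for (chunk in split(seq_len(nrow(dirs)), ceiling(seq_len(nrow(dirs)) / 500))) {
    arg <- dirs[chunk, , drop = FALSE] %*% t(gtab$bvecs * l)
    k <- ifelse(abs(arg) < 1e-12, 1, sin(arg) / ifelse(arg == 0, 1, arg))
    vals <- as.numeric(k %*% signal)
    i <- which.max(vals)
    if (vals[i] > best_val) { best_val <- vals[i]; best_dir <- dirs[chunk[i], ] }
  }
  best_dir
}

# All-pairs directed 95th-percentile distance with a hand-rolled
# linear-interpolation percentile (same order-statistic rule the package
# documents, implemented independently).
bf_hd95 <- function(mask_a, mask_b, voxel_size = 1) {
  coords <- function(m) {
    idx <- which(array(as.logical(m), dim(m)), arr.ind = TRUE) - 1
    idx * voxel_size
  }
  pa <- coords(mask_a); pb <- coords(mask_b)
  directed <- function(a, b) {
    d <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b))) {
        dist <- sqrt(sum((a[i, ] - b[j, ])^2))
        if (dist < best) best <- dist
      }
      d[i] <- best
    }
    d <- sort(d)
    n <- length(d)
    h <- (n - 1) * 0.95 + 1
    lo <- floor(h); hi <- ceiling(h)
    d[lo] + (h - lo) * (d[hi] - d[lo])
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Explicit 3x3 tensor quadratic-form signal for one zeppelin compartment.
bf_tensor_signal <- function(bval, gvec, fiber_dir, ad, rd) {
  D <- rd * diag(3) + (ad - rd) * (fiber_dir %o% fiber_dir)
  exp(-bval * as.numeric(t(gvec) %*% D %*% gvec))
}
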