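# odfmatch

Fiber-direction reconstruction for diffusion MRI by **ODF-fingerprint
matching**, built to keep deterministic tractography alive inside
peritumoral **vasogenic edema**.

## The problem and the method

Edema floods white matter with isotropic free water. Diffusion ODFs in the
affected voxels flatten, anisotropy collapses below tracking thresholds,
and streamlines stop at the edema boundary even though the axons are still
there — precisely where presurgical tractography matters most.

Instead of finding ODF local maxima, `odfmatch` matches each measured,
unit-normalized ODF `x` against a large dictionary `D = {d_j : ||d_j|| = 1}`
of synthetic ODF fingerprints with known microstructure (`N_j ∈ {0,1,2,3}`
fibers, known directions and compartment fractions) and reads the fiber
configuration off the best-scoring element under the regularized score

```
x~ = argmax_{d_j in D}   xᵀ d_j  −  N_j λ  −  min(d_j) μ
```

* `xᵀ d_j` — data consistency (cosine similarity),
* `N_j λ` — spurious-fiber penalty (suppresses false crossings),
* `min(d_j) μ` — **anisotropy boosting**: penalizes elements with a high ODF
  global minimum, steering matches toward sharp, anisotropic fingerprints.
  Raising `μ` only inside an edema mask (`μ_edema`, default 0.3; brain-wide
  `μ = 0.1`, `λ = 2·10⁻⁵`) recovers fiber directions in free-water-diluted
  voxels and lets the tracker cross the edematous segment.

The package provides the full desk-scale pipeline: multi-compartment signal
simulation and crossing-fiber edema phantoms, GQI ODF reconstruction on a
321-vertex hemisphere, dictionary generation/persistence, regularized
matching with a spatially varying `μ`, a deterministic Euler tracker
(NQA ≥ 0.10, ≤ 60° turns, 30–200 mm lengths), tract metrics (edema overlap
enhancement, TPR, Dice, HD95), and NIfTI/bval/bvec/TCK I/O.

## Worked example

Two orthogonal bundles crossing inside an edema sphere (free-water fraction
0.7, Rician SNR 20); the same data matched with `μ_edema = 0` and `0.4`:

```r
library(odfmatch)

gtab   <- default_gradient_scheme()                 # 6 b0 + 20/60/60 dirs
sphere <- build_sphere_grid(321)
dict   <- build_dictionary(10000, gtab, sphere, seed = 101)

ph   <- make_edema_phantom(phantom_spec(seed = 1), gtab)
odfs <- gqi_odf_transform(ph$dwi, gtab, sphere, mask = ph$wm_mask,
                          affine = ph$affine)

for (mu_edema in c(0, 0.4)) {
  reg <- reg_params(mu = 0.1, mu_edema = mu_edema)
  pf  <- compute_nqa_field(match_field(odfs, dict, reg, ph$edema_mask))
  tg  <- run_tractography(pf, tracking_params(n_seeds = 300, rng_seed = 7),
                          seed_mask = ph$wm_mask)
  ov  <- overlap_volume(tract_to_mask(tg, dim(ph$wm_mask), ph$affine),
                        ph$edema_mask, voxel_volume = 8)
  cat(sprintf("mu_edema = %.1f: %3d streamlines, edema overlap %3d voxels (%d mm^3)\n",
              mu_edema, length(tg$streamlines), ov$voxels, ov$mm3))
}
```

```
mu_edema = 0.0: 197 streamlines, edema overlap 205 voxels (1640 mm^3)
mu_edema = 0.4: 288 streamlines, edema overlap 259 voxels (2072 mm^3)
```

Without boosting, many matches inside the edema sphere collapse onto blunt
high-free-water fingerprints whose anisotropy falls below the NQA stopping
threshold: streamlines die at the edema boundary and then fail the 30 mm
length filter. With `μ_edema = 0.4` the same voxels match sharp crossing
fingerprints and the bundles are tracked through the edema — 46% more
surviving streamlines and a 26% larger tract–edema overlap volume.

A command-line front end wrapping the same functions is installed at
`inst/cli/odfmatch.R` (`phantom`, `build-dict`, `fit`, `track`, `evaluate`
subcommands).

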