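Package: odfmatch
Title: ODF-Fingerprint Matching for Fiber Tracking Through Vasogenic Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs white-matter fiber directions from diffusion MRI by
    matching measured orientation distribution functions (ODFs) against a
    dictionary of synthetic ODF fingerprints with known microstructure.
    A regularized matching score penalizes spurious fibers and boosts
    diffusion anisotropy, so that fiber orientations can be recovered in
    voxels heavily contaminated by isotropic free water, such as peritumoral
    vasogenic edema. Includes generalized q-sampling (GQI) ODF
    reconstruction, a deterministic Euler streamline tracker with NQA-based
    stopping, crossing-fiber phantom simulation with Rician noise, and
    tract-evaluation statistics (edema overlap enhancement, TPR, Dice, 95%
    Hausdorff distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
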