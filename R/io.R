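# Readers/writers: NIfTI volumes, FSL bval/bvec, TCK tractograms.
#
# Conventions: 0-based voxel indices, voxel-center convention, RAS world
# frame in mm. bvec files use the FSL dialect (3 whitespace-separated rows
# of x, y, z components) interpreted in the image frame.

affine_header <- function(affine) {
  RNifti::niftiHeader(list(sform_code = 2L, qform_code = 0L,
                           srow_x = affine[1, ], srow_y = affine[2, ],
                           srow_z = affine[3, ]))
}

#' Write a numeric volume as NIfTI
#' @param data 3-D or 4-D array.
#' @param path Output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @export
write_nifti_volume <- function(data, path, affine = diag(4)) {
  img <- RNifti::asNifti(data, reference = affine_header(affine))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume with its affine
#' @param path NIfTI file.
#' @return List with `data` (array), `affine` (4x4).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  if (abs(det(aff)) < 1e-12) stop("non-invertible affine in ", path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (!(length(dim(data)) %in% c(3, 4)))
    stop("expected a 3-D or 4-D volume in ", path)
  if (anyNA(data)) stop("volume contains NaN values: ", path)
  list(data = data, affine = aff)
}

#' Write / read a binary mask as uint8 NIfTI
#' @param mask 3-D logical (or 0/1) array.
#' @param path File path.
#' @param affine Voxel-to-world matrix.
#' @export
write_mask <- function(mask, path, affine = diag(4)) {
  img <- RNifti::asNifti(array(as.integer(as.logical(mask)), dim(mask)),
                         reference = affine_header(affine))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_nifti_volume(path)
  if (!all(as.numeric(v$data) %in% c(0, 1))) stop("mask is not binary: ", path)
  list(data = array(v$data > 0, dim(v$data)), affine = v$affine)
}

#' Write a DWI series with FSL-dialect gradient files
#' @param dwi 4-D array.
#' @param gtab Gradient table.
#' @param nifti_path,bval_path,bvec_path Output paths; bval/bvec default to
#'   the NIfTI path with extensions swapped.
#' @param affine Voxel-to-world matrix.
#' @export
write_dwi <- function(dwi, gtab, nifti_path,
                      bval_path = sub("\\.nii(\\.gz)?$", ".bval", nifti_path),
                      bvec_path = sub("\\.nii(\\.gz)?$", ".bvec", nifti_path),
                      affine = diag(4)) {
  if (dim(dwi)[4] != length(gtab$bvals))
    stop("dwi volume count does not match the gradient table")
  write_nifti_volume(dwi, nifti_path, affine)
  writeLines(paste(format(gtab$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  bv <- t(gtab$bvecs)
  writeLines(apply(bv, 1, function(r) paste(format(r, digits = 10), collapse = " ")),
             bvec_path)
  invisible(nifti_path)
}

#' Read a DWI series with FSL-dialect gradient files
#'
#' @param nifti_path 4-D NIfTI file.
#' @param bval_path,bvec_path Gradient files (bvec: 3 rows of x/y/z).
#' @return List with `dwi` (4-D array), `affine`, `gtab`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  vol <- read_nifti_volume(nifti_path)
  if (length(dim(vol$data)) != 4) stop("DWI must be 4-D: ", nifti_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  bvec_rows <- bvec_rows[lengths(bvec_rows) > 0]
  if (length(bvec_rows) != 3) stop("bvec file must have 3 rows (x, y, z): ", bvec_path)
  bvecs <- t(do.call(rbind, bvec_rows))
  if (length(bvals) != dim(vol$data)[4])
    stop(sprintf("bval file has %d entries but the DWI has %d volumes",
                 length(bvals), dim(vol$data)[4]))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("bvec file has %d directions but the bval file has %d entries",
                 nrow(bvecs), length(bvals)))
  list(dwi = vol$data, affine = vol$affine, gtab = gradient_table(bvals, bvecs))
}

#' Extract a subset of b-shells from a DWI series
#'
#' b0 volumes are always retained; acquisition order is preserved.
#'
#' @param dwi 4-D array.
#' @param gtab Matching gradient table.
#' @param keep_bvals Shell b-values to keep (matched within `tol` s/mm^2).
#' @param tol Shell matching tolerance (default 50 s/mm^2).
#' @return List with subsetted `dwi` and `gtab`.
#' @export
subsample_shell <- function(dwi, gtab, keep_bvals, tol = 50) {
  if (length(keep_bvals) == 0) stop("keep_bvals must not be empty")
  shells <- unique(round(gtab$bvals[!gtab$b0_mask]))
  for (b in keep_bvals) {
    if (!any(abs(shells - b) <= tol))
      stop(sprintf("no acquired shell within %g s/mm^2 of b=%g", tol, b))
  }
  keep <- gtab$b0_mask
  for (b in keep_bvals) keep <- keep | abs(gtab$bvals - b) <= tol
  list(dwi = dwi[, , , keep, drop = FALSE],
       gtab = gradient_table(gtab$bvals[keep], gtab$bvecs[keep, , drop = FALSE]))
}

# ---- TCK (MRtrix tracks) ----------------------------------------------------

#' Write a tractogram in TCK format
#'
#' Header fields: `datatype: Float32LE`, `count`, and `file` offset;
#' coordinates are world mm (single precision). Streamlines are separated
#' by NaN triplets and the stream ends with an Inf triplet.
#'
#' @param tractogram A `tractogram` (or list of n x 3 matrices).
#' @param path Output path.
#' @export
write_tck <- function(tractogram, path) {
  lines <- if (inherits(tractogram, "tractogram")) tractogram$streamlines else tractogram
  header_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", length(lines)),
           "odfmatch: world-mm coordinates\n",
           sprintf("file: . %d\n", offset),
           "END\n")
  }
  offset <- nchar(header_for(0), type = "bytes")
  # offset digits can change the header length; iterate to a fixed point
  repeat {
    new_offset <- nchar(header_for(offset), type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(offset), con, eos = NULL)
  for (sl in lines) {
    writeBin(as.numeric(t(sl)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#' @param path TCK file.
#' @return A `tractogram` (identity affine; TCK stores world coordinates).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(first, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NULL
  datatype <- NULL
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0) stop("malformed TCK header (no END): ", path)
    if (l == "END") break
    kv <- strsplit(l, ": ", fixed = TRUE)[[1]]
    if (kv[1] == "file") offset <- as.integer(strsplit(kv[2], " ")[[1]][2])
    if (kv[1] == "datatype") datatype <- kv[2]
  }
  if (is.null(offset)) stop("TCK header missing file offset: ", path)
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype: ", datatype %||% "missing")
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4, endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- NULL
  for (i in seq_len(nrow(m))) {
    p <- m[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      streamlines[[length(streamlines) + 1]] <- cur %||% matrix(numeric(0), 0, 3)
      cur <- NULL
    } else cur <- rbind(cur, p)
  }
  streamlines <- lapply(streamlines, function(x) { dimnames(x) <- NULL; x })
  structure(list(streamlines = streamlines, affine = diag(4),
                 step_size = NA_real_, params = NULL),
            class = "tractogram")
}
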