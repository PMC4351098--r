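#' Write and read DWI data as NIfTI-1 with FSL-dialect gradient tables
#'
#' `write_dwi_nifti` writes the 4-D data to `<prefix>.nii.gz` plus
#' `<prefix>.bvec` / `<prefix>.bval`; `read_dwi_nifti` reads them back into
#' a `dwi_volume`.
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix.
#' @return the written file paths (invisibly) / a `dwi_volume`.
#' @export
write_dwi_nifti <- function(dwi, prefix) {
  nii <- RNifti::asNifti(dwi$data)
  nii <- RNifti::`sform<-`(nii, structure(dwi$affine, code = 2L))
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, path)
  write_fsl_gradients(dwi$scheme, paste0(prefix, ".bvec"),
                      paste0(prefix, ".bval"))
  invisible(c(nifti = path, bvec = paste0(prefix, ".bvec"),
              bval = paste0(prefix, ".bval")))
}

#' @rdname write_dwi_nifti
#' @export
read_dwi_nifti <- function(prefix) {
  nii <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  scheme <- read_fsl_gradients(paste0(prefix, ".bvec"), paste0(prefix, ".bval"))
  structure(list(data = array(as.numeric(nii), dim(nii)),
                 affine = unclass(RNifti::xform(nii)),
                 scheme = scheme),
            class = "dwi_volume")
}

#' Write a scalar or coefficient map as NIfTI-1
#'
#' @param arr 3-D or 4-D numeric (or logical) array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output `.nii.gz` path.
#' @export
write_map_nifti <- function(arr, affine, path) {
  nii <- RNifti::asNifti(arr * 1)
  nii <- RNifti::`sform<-`(nii, structure(affine, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write streamlines in the MRtrix TCK track-file format
#'
#' Binary Float32LE triplets, streamlines separated by NaN triplets and the
#' file ended by an Inf triplet, after a plain-text header.
#'
#' @param streamlines a `streamline_set` or list of n x 3 world-mm matrices.
#' @param path output `.tck` path.
#' @export
write_tck <- function(streamlines, path) {
  pts <- if (inherits(streamlines, "streamline_set")) streamlines$points
         else streamlines
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(pts)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_txt <- paste0(paste(hdr, collapse = "\n"), "\nfile: . ")
  # offset field: header length once the offset digits themselves are fixed
  base <- nchar(hdr_txt, type = "bytes") + nchar("\nEND\n")
  off <- base + 4
  while (nchar(as.character(off)) + base != off)
    off <- base + nchar(as.character(off))
  writeChar(paste0(hdr_txt, off, "\nEND\n"), con, eos = NULL)
  for (m in pts) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK track file
#'
#' @param path `.tck` file path.
#' @return list of n x 3 matrices (world mm).
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  hdr_end <- grepRaw("\nEND\n", raw, fixed = TRUE)
  if (!length(hdr_end)) stop("not a TCK file")
  txt <- rawToChar(raw[seq_len(hdr_end[1] + 4)])
  if (!startsWith(txt, "mrtrix tracks")) stop("not a TCK file")
  m <- regmatches(txt, regexpr("file: \\. [0-9]+", txt))
  off <- as.integer(sub("file: \\. ", "", m))
  vals <- readBin(raw[(off + 1):length(raw)], "numeric", size = 4,
                  n = (length(raw) - off) / 4, endian = "little")
  tri <- matrix(vals, ncol = 3, byrow = TRUE)
  out <- list(); cur <- NULL
  for (i in seq_len(nrow(tri))) {
    if (all(is.infinite(tri[i, ]))) break
    if (all(is.nan(tri[i, ]))) {
      if (!is.null(cur)) out[[length(out) + 1]] <- do.call(rbind, cur)
      cur <- NULL
    } else cur <- c(cur, list(tri[i, ]))
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- do.call(rbind, cur)
  out
}
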