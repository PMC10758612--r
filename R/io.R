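# NIfTI I/O, thin wrappers over RNifti.

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return Numeric 3D array with the source image attached as attribute
#'   `"template"` for header-preserving writes.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "template") <- img
  arr
}

#' Write a 3D volume to NIfTI
#'
#' @param arr Numeric or integer 3D array.
#' @param path Output path.
#' @param template Optional source image (or array carrying a
#'   `"template"` attribute) whose header/affine is reused; otherwise an
#'   isotropic 1 mm header is written.
#' @export
write_volume <- function(arr, path, template = NULL) {
  if (is.null(template)) template <- attr(arr, "template")
  a <- array(as.numeric(arr), dim(arr))
  img <- if (!is.null(template)) {
    RNifti::asNifti(a, reference = template)
  } else {
    out <- RNifti::asNifti(a)
    RNifti::pixdim(out) <- c(1, 1, 1)
    out
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
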