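#' Read a volumetric image from a NIfTI file
#'
#' Volumes are represented throughout the package as plain 3D numeric arrays
#' indexed `[x, y, z]`, optionally carrying a `spacing` attribute with the
#' per-axis physical voxel size in millimetres. Voxel and slice indices in all
#' user-facing coordinates (rectangles, slice indices, crop boxes) are 0-based,
#' matching the annotation file convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a 3D numeric array with a `spacing` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  attr(v, "spacing") <- RNifti::pixdim(img)
  validate_volume(v)
  v
}

#' Write a volume (or an upsampled saliency volume) to NIfTI
#'
#' @param volume 3D numeric array, optionally with a `spacing` attribute.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  validate_volume(volume)
  img <- RNifti::asNifti(volume)
  sp <- attr(volume, "spacing")
  if (!is.null(sp)) RNifti::pixdim(img) <- sp[seq_len(3)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

validate_volume <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("a volume must be a 3D array", call. = FALSE)
  if (any(dim(volume) < 1L))
    stop("all three volume dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(volume)))
    stop("volume intensities must be finite", call. = FALSE)
  invisible(volume)
}
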