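#' NIfTI storage of orientation fields and label atlases
#'
#' An [orientation_field()] is stored as two NIfTI volumes: `*_peaks.nii.gz`
#' with the last dimension holding the `3*K` peak components (peak-major:
#' columns 1..3 are peak 1, and so on, zero-padded for absent peaks) and
#' `*_qa.nii.gz` with the last dimension holding the `K` QA values. A
#' [region_atlas()] is an integer 3-D NIfTI plus a two-column CSV of label
#' names. Voxel dimensions travel in the NIfTI `pixdim`.
#'
#' @param field an [orientation_field()].
#' @param atlas a [region_atlas()].
#' @param prefix output path prefix (files get `_peaks.nii.gz`,
#'   `_qa.nii.gz` / `_labels.nii.gz`, `_labels.csv` suffixes).
#' @return Writers return the file paths invisibly; readers return the
#'   reconstructed object.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_field_nifti <- function(field, prefix) {
  gs <- field$grid_shape; K <- field$K
  pk <- field$peaks
  # [X,Y,Z,K,3] -> [X,Y,Z,3K] peak-major (components of peak k adjacent)
  pk <- aperm(pk, c(1L, 2L, 3L, 5L, 4L))
  dim(pk) <- c(gs, 3L * K)
  ppath <- paste0(prefix, "_peaks.nii.gz")
  qpath <- paste0(prefix, "_qa.nii.gz")
  attr(pk, "pixdim") <- c(field$voxel_size, 1)
  RNifti::writeNifti(RNifti::asNifti(pk), ppath)
  qa <- field$qa
  attr(qa, "pixdim") <- c(field$voxel_size, 1)
  RNifti::writeNifti(RNifti::asNifti(qa), qpath)
  invisible(c(peaks = ppath, qa = qpath))
}

#' @rdname nifti_io
#' @export
read_field_nifti <- function(prefix) {
  pk <- RNifti::readNifti(paste0(prefix, "_peaks.nii.gz"))
  qa <- RNifti::readNifti(paste0(prefix, "_qa.nii.gz"))
  vs <- RNifti::pixdim(pk)[1:3]
  gs <- dim(pk)[1:3]
  K <- dim(qa)[4L]
  pk <- array(as.numeric(pk), dim = c(gs, 3L, K))
  pk <- aperm(pk, c(1L, 2L, 3L, 5L, 4L))
  orientation_field(pk, array(as.numeric(qa), dim = c(gs, K)), vs)
}

#' @rdname nifti_io
#' @export
write_atlas_nifti <- function(atlas, prefix) {
  lpath <- paste0(prefix, "_labels.nii.gz")
  npath <- paste0(prefix, "_labels.csv")
  vol <- atlas$volume
  attr(vol, "pixdim") <- atlas$voxel_size
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "int16"), lpath)
  utils::write.csv(
    data.frame(label = seq_along(atlas$names), name = atlas$names),
    npath, row.names = FALSE)
  invisible(c(labels = lpath, names = npath))
}

#' @rdname nifti_io
#' @export
read_atlas_nifti <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  nm <- utils::read.csv(paste0(prefix, "_labels.csv"))
  vol <- array(as.integer(img), dim = dim(img))
  region_atlas(vol, nm$name[order(nm$label)], RNifti::pixdim(img)[1:3])
}
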