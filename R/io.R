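#' Write a 3D/4D array as NIfTI-1
#'
#' Builds the affine from the voxel size (identity rotation) and writes via
#' RNifti.
#'
#' @param x an \code{epi_volume4d}, \code{epi_phantom} labels, 3D or 4D
#'   array.
#' @param path output file (.nii or .nii.gz).
#' @param voxel_size mm per axis (taken from the object when available).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size = NULL) {
  if (inherits(x, "epi_volume4d")) {
    arr <- x$data
    voxel_size <- x$voxel_size
  } else if (inherits(x, "epi_phantom")) {
    arr <- x$labels
    voxel_size <- x$voxel_size
  } else if (inherits(x, "epi_fieldmap")) {
    arr <- x$delta_f
    voxel_size <- x$voxel_size
  } else arr <- x
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  img <- RNifti::asNifti(arr)
  pd <- voxel_size
  if (length(dim(arr)) == 4)   # 4D images carry the volume TR in pixdim[4]
    pd <- c(voxel_size, if (inherits(x, "epi_volume4d")) x$tr_vol_s else 1)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a 4D series object
#'
#' @param path NIfTI file.
#' @param tr_vol_s volume repetition time; taken from the header pixdim
#'   when not supplied.
#' @return an \code{epi_volume4d} (3D images get a singleton time axis).
#' @export
read_nifti_volume <- function(path, tr_vol_s = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_vol_s)) tr_vol_s <- if (length(pd) >= 4) pd[4] else 1
  if (!is.finite(tr_vol_s) || tr_vol_s <= 0) tr_vol_s <- 1
  as_volume4d(arr, voxel_size = pd[1:3], tr_vol_s = tr_vol_s,
              meta = list(source = path))
}

#' Write the phantom parcel table as TSV
#'
#' @param phantom an \code{epi_phantom}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_parcel_table <- function(phantom, path) {
  stopifnot(inherits(phantom, "epi_phantom"))
  utils::write.table(phantom$parcels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a confound matrix as TSV
#' @param confounds numeric matrix with named columns.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_confound_table <- function(confounds, path) {
  utils::write.table(as.data.frame(confounds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an adjacency (or any ROI x ROI) matrix as TSV with ROI headers
#' @param mat square matrix with ROI names on both axes.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_roi_matrix <- function(mat, path) {
  df <- as.data.frame(mat)
  utils::write.table(cbind(roi = rownames(mat) %||% seq_len(nrow(mat)), df),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
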