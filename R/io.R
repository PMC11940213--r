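#' Write a multi-echo volume as NIfTI with an echo-time sidecar
#'
#' @param volume 4D array (x, y, z, echo).
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}; the
#'   sidecar JSON is written next to it with extension \code{.json}.
#' @param echo_times_ms Echo times (ms), one per 4th-dim index.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @return Invisibly, the two paths written.
#' @export
write_multiecho_nifti <- function(volume, path, echo_times_ms,
                                  voxel_dims_mm = c(1.5, 1.5, 1.8)) {
  if (length(dim(volume)) != 4L) stop("volume must be 4D")
  if (dim(volume)[4] != length(echo_times_ms))
    stop("echo_times_ms must match the 4th dimension")
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(voxel_dims_mm, 1)
  RNifti::writeNifti(img, path)
  sidecar <- sidecar_path(path)
  jsonlite::write_json(list(echo_times_ms = echo_times_ms,
                            voxel_dims_mm = voxel_dims_mm),
                       sidecar, digits = NA)
  invisible(c(path, sidecar))
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a multi-echo volume and its echo-time sidecar
#'
#' @param path NIfTI path written by \code{\link{write_multiecho_nifti}}.
#' @return List: \code{volume} (4D array), \code{echo_times_ms},
#'   \code{voxel_dims_mm}.
#' @export
read_multiecho_nifti <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing echo-time sidecar: ", sidecar)
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vol <- array(as.numeric(img), dim = dim(img))
  if (dim(vol)[4] != length(meta$echo_times_ms))
    stop("echo count in ", path, " does not match its sidecar")
  list(volume = vol, echo_times_ms = meta$echo_times_ms,
       voxel_dims_mm = meta$voxel_dims_mm)
}

#' Write / read an integer label mask as NIfTI
#'
#' @param mask 3D integer array.
#' @param path NIfTI path.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @return \code{write_mask_nifti}: the path, invisibly.
#' @export
write_mask_nifti <- function(mask, path, voxel_dims_mm = c(1.5, 1.5, 1.8)) {
  storage.mode(mask) <- "integer"
  img <- RNifti::asNifti(mask)
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @return \code{read_mask_nifti}: a 3D integer array with a
#'   \code{voxel_dims_mm} attribute.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.integer(img), dim = dim(img))
  attr(m, "voxel_dims_mm") <- RNifti::pixdim(img)[1:3]
  m
}

#' Write a 3D float map (e.g. a T2 map) as NIfTI
#'
#' @param map 3D numeric array.
#' @inheritParams write_mask_nifti
#' @export
write_map_nifti <- function(map, path, voxel_dims_mm = c(1.5, 1.5, 1.8)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img), dim = dim(img))
  attr(m, "voxel_dims_mm") <- RNifti::pixdim(img)[1:3]
  m
}
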