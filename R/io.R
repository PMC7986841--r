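#' Write a tissue model as NIfTI volumes with a JSON sidecar
#'
#' Writes the label grid and the implant mask as separate NIfTI volumes
#' (voxel dimensions carry the spacing in mm) and a JSON sidecar with the
#' property table, spacing, origin and metadata.
#'
#' @param model a \code{TissueModel}.
#' @param prefix output path prefix; creates prefix_labels.nii.gz,
#'   prefix_implant.nii.gz, prefix.json.
#' @return the sidecar path, invisibly.
#' @export
writeTissueModel <- function(model, prefix) {
  pix <- model@spacing * 1e3
  lab <- RNifti::asNifti(array(as.integer(model@labels), dim(model@labels)),
                         pixdim = rep(pix, 3))
  RNifti::writeNifti(lab, paste0(prefix, "_labels.nii.gz"))
  imp <- RNifti::asNifti(array(as.integer(model@implantMask),
                               dim(model@labels)), pixdim = rep(pix, 3))
  RNifti::writeNifti(imp, paste0(prefix, "_implant.nii.gz"))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(spacing = model@spacing, origin = model@origin,
         properties = model@properties, meta = model@meta),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a tissue model written by \code{\link{writeTissueModel}}
#'
#' @param prefix the path prefix used at write time.
#' @return a \code{TissueModel}.
#' @export
readTissueModel <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lab <- as.array(RNifti::readNifti(paste0(prefix, "_labels.nii.gz")))
  imp <- as.array(RNifti::readNifti(paste0(prefix, "_implant.nii.gz")))
  props <- as.data.frame(side$properties)
  meta <- as.list(side$meta)
  if (!is.null(meta$headCenterZLocal))
    meta$headCenterZLocal <- as.numeric(meta$headCenterZLocal)
  methods::new("TissueModel", spacing = as.numeric(side$spacing),
               labels = array(as.integer(lab), dim(lab)),
               implantMask = array(imp != 0, dim(imp)),
               properties = props, origin = as.numeric(side$origin),
               meta = meta)
}

#' Write a 3D field as NIfTI on the model grid
#'
#' @param field 3D numeric array (e.g. a temperature-increase snapshot or
#'   a power-density map).
#' @param model the \code{TissueModel} providing the grid geometry.
#' @param path output NIfTI path.
#' @export
writeFieldNifti <- function(field, model, path) {
  stopifnot(identical(dim(field), dim(model@labels)))
  vol <- RNifti::asNifti(field, pixdim = rep(model@spacing * 1e3, 3))
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' Write a safety report as JSON
#'
#' @param report a list from \code{\link{safetyReport}}.
#' @param path output path.
#' @export
writeSafetyReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
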