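#' Implant and tissue material properties
#'
#' Packaged property table used to build phantoms. The implant materials
#' (CoCrMo alloy, polyethylene) carry their standard handbook values. The
#' soft-tissue entries (muscle, fat, subcutaneous adipose tissue, skin,
#' cortical bone) are literature-typical values of the kind tabulated in
#' tissue-property databases; they are configuration, not constants, and can
#' be overridden by supplying a modified table to \code{\link{makePhantom}}.
#'
#' Columns: \code{label} integer id; \code{name}; \code{sigma} electric
#' conductivity (S/m); \code{epsR} relative permittivity; \code{muR}
#' relative permeability; \code{lambdaTh} thermal conductivity (W/m/K);
#' \code{cP} specific heat capacity (J/kg/K); \code{rho} mass density
#' (kg/m^3); \code{hB0} perfusion coefficient at rest (W/m^3/K);
#' \code{pMet0} metabolic power density at rest (W/m^3); \code{isSkin}
#' flag selecting the skin thermoregulation cap; \code{isImplant} flag
#' (implant materials have zero perfusion and metabolism).
#'
#' @return data.frame with one row per material.
#' @export
#' @examples
#' tissueTable()
tissueTable <- function() {
  data.frame(
    label = 1:7,
    name = c("muscle", "fat", "sat", "skin", "bone", "cocrmo", "pe"),
    sigma = c(0.72, 0.068, 0.068, 0.44, 0.02, 1.16e6, 0),
    epsR = c(60, 12, 12, 50, 15, 1, 2.25),
    muR = rep(1, 7),
    lambdaTh = c(0.49, 0.21, 0.21, 0.37, 0.32, 14, 0.47),
    cP = c(3421, 2348, 2348, 3391, 1313, 450, 1900),
    rho = c(1090, 911, 911, 1109, 1908, 8445, 940),
    hB0 = c(2700, 500, 600, 6000, 340, 0, 0),
    pMet0 = c(690, 300, 300, 1620, 290, 0, 0),
    isSkin = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    isImplant = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

labelOf <- function(table, nm) {
  i <- match(nm, table$name)
  if (any(is.na(i))) stop("unknown tissue name: ", paste(nm[is.na(i)],
                                                         collapse = ", "))
  table$label[i]
}

#' Grid dimensions of a tissue model
#' @param model a \code{TissueModel}.
#' @return integer length-3.
#' @export
gridDim <- function(model) dim(model@labels)

#' Voxel spacing (m)
#' @param model a \code{TissueModel}.
#' @export
voxelSpacing <- function(model) model@spacing

#' Voxel volume (m^3)
#' @param model a \code{TissueModel}.
#' @export
voxelVolume <- function(model) model@spacing^3

#' Tissue label array
#' @param model a \code{TissueModel}.
#' @export
tissueLabels <- function(model) model@labels

#' Implant voxel mask
#' @param model a \code{TissueModel}.
#' @export
implantMask <- function(model) model@implantMask

#' Property table of a model
#' @param model a \code{TissueModel}.
#' @export
tissueProps <- function(model) model@properties

#' Linear indices of implant metal voxels
#' @param model a \code{TissueModel}.
#' @export
metalIndices <- function(model) {
  metalLabels <- model@properties$label[model@properties$isImplant &
                                        model@properties$sigma > 0]
  which(array(model@labels %in% metalLabels, dim(model@labels)))
}

# Per-voxel lookup of one property column, 0 for air.
propArray <- function(model, column) {
  lut <- numeric(max(model@properties$label) + 1L)
  lut[model@properties$label + 1L] <- model@properties[[column]]
  array(lut[as.integer(model@labels) + 1L], dim(model@labels))
}

#' Voxel-center coordinates in scanner space
#'
#' @param model a \code{TissueModel}.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return numeric vector of center coordinates (m) along that axis.
#' @export
voxelCenters <- function(model, axis) {
  n <- dim(model@labels)[axis]
  model@origin[axis] + (seq_len(n) - 0.5) * model@spacing
}

#' Total model mass (kg)
#' @param model a \code{TissueModel}.
#' @export
modelMass <- function(model) sum(propArray(model, "rho")) * voxelVolume(model)
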