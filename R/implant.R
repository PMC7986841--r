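#' Simplified unilateral hip implant geometry
#'
#' Parameters of the canonical hip-implant stand-in: a stem cylinder, a neck
#' cylinder connecting the stem to the femoral head, a hemispherical head,
#' a hemispherical acetabular shell with a polyethylene liner filling the
#' gap between head and shell, and a fixation screw on top of the shell.
#' Default dimensions give a 142 mm stem, 30 mm head, 66 mm / 8 mm shell,
#' 34 mm screw, 10 mm liner and a 230 mm height from stem tip to head top.
#'
#' The pose is a documented canonical one: the implant axis is vertical
#' (along z), the stem occupies local z in [0, stemLength], the head is the
#' upper half-ball of radius headDiameter/2 centred at
#' z = totalHeight - headDiameter/2, the shell/liner are concentric upper
#' hemispherical shells, and the screw extends axially from the shell apex.
#'
#' @param stemLength,headDiameter,shellOuterDiameter,shellThickness,
#'   screwLength,linerThickness,totalHeight geometry (m).
#' @param stemRadius,screwRadius radii (m) of stem/neck and screw cylinders
#'   (not constrained further by the printed geometry; canonical values).
#' @return list of class "ImplantSpec".
#' @export
implantSpec <- function(stemLength = 0.142, headDiameter = 0.030,
                        shellOuterDiameter = 0.066, shellThickness = 0.008,
                        screwLength = 0.034, linerThickness = 0.010,
                        totalHeight = 0.230, stemRadius = 0.007,
                        screwRadius = 0.00325) {
  spec <- list(stemLength = stemLength, headDiameter = headDiameter,
               shellOuterDiameter = shellOuterDiameter,
               shellThickness = shellThickness, screwLength = screwLength,
               linerThickness = linerThickness, totalHeight = totalHeight,
               stemRadius = stemRadius, screwRadius = screwRadius)
  lens <- unlist(spec)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all implant dimensions must be positive")
  if (shellThickness >= shellOuterDiameter / 2)
    stop("shellThickness must be smaller than shellOuterDiameter/2")
  if (totalHeight <= stemLength + headDiameter / 2)
    stop("totalHeight too small to fit stem, neck and head")
  class(spec) <- "ImplantSpec"
  spec
}

#' Analytic solid volume of the implant primitives
#'
#' Hand-computable union volume of the disjoint primitives (stem + neck
#' cylinders, head half-ball, hemispherical shell, screw cylinder); used as
#' the voxelization oracle. Returns metal and liner volumes in m^3.
#'
#' @param spec an \code{\link{implantSpec}}.
#' @export
implantAnalyticVolume <- function(spec) {
  rHead <- spec$headDiameter / 2
  rOut <- spec$shellOuterDiameter / 2
  rIn <- rOut - spec$shellThickness
  neckLength <- spec$totalHeight - rHead - spec$stemLength
  metal <- pi * spec$stemRadius^2 * (spec$stemLength + neckLength) +
    (2 / 3) * pi * rHead^3 +
    (2 / 3) * pi * (rOut^3 - rIn^3) +
    pi * spec$screwRadius^2 * spec$screwLength
  liner <- (2 / 3) * pi * (rIn^3 - (rIn - spec$linerThickness)^3)
  list(metal = metal, liner = liner)
}

#' Voxelize the implant
#'
#' Rasterises the implant primitives onto an isotropic grid using the
#' voxel-center membership rule (a voxel belongs to a primitive iff its
#' center lies inside). Coordinates are local: x = y = 0 on the implant
#' axis, z = 0 at the stem tip.
#'
#' @param spec an \code{\link{implantSpec}}.
#' @param spacing voxel edge (m); must be at most headDiameter/4 so the
#'   head is resolvable.
#' @param dim optional grid dimensions; by default a minimal bounding grid.
#' @param center optional local coordinates (m) of the implant axis/stem tip
#'   inside the grid; defaults to the grid center in x/y and a one-voxel
#'   margin in z.
#' @return list with logical 3D arrays \code{metal} and \code{liner}
#'   (disjoint), the grid \code{spacing}, and \code{headCenterZ}, the local
#'   z-index-space coordinate (m, relative to the grid corner) of the
#'   femoral head centre.
#' @export
makeImplant <- function(spec, spacing, dim = NULL, center = NULL) {
  if (spacing > spec$headDiameter / 4)
    stop("resolution error: spacing must be <= headDiameter/4 = ",
         spec$headDiameter / 4, " m")
  rHead <- spec$headDiameter / 2
  rOut <- spec$shellOuterDiameter / 2
  rIn <- rOut - spec$shellThickness
  rLiner <- rIn - spec$linerThickness
  zHead <- spec$totalHeight - rHead       # head centre height above stem tip
  zTop <- zHead + rOut + spec$screwLength # screw tip

  if (is.null(dim)) {
    lateral <- 2 * ceiling(rOut / spacing) + 4L
    dim <- c(lateral, lateral, ceiling(zTop / spacing) + 4L)
  }
  if (is.null(center))
    center <- c(dim[1] / 2 * spacing, dim[2] / 2 * spacing, 2 * spacing)

  cx <- (seq_len(dim[1]) - 0.5) * spacing - center[1]
  cy <- (seq_len(dim[2]) - 0.5) * spacing - center[2]
  cz <- (seq_len(dim[3]) - 0.5) * spacing - center[3]
  X <- array(cx, dim)
  Y <- array(rep(cy, each = dim[1]), dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  R2 <- X^2 + Y^2                       # squared distance from implant axis
  S2 <- R2 + (Z - zHead)^2              # squared distance from head centre
  up <- Z >= zHead

  stem <- R2 <= spec$stemRadius^2 & Z >= 0 & Z <= zHead  # stem + neck
  head <- S2 <= rHead^2 & up
  shell <- S2 <= rOut^2 & S2 >= rIn^2 & up
  screw <- R2 <= spec$screwRadius^2 & Z >= zHead + rOut &
    Z <= zHead + rOut + spec$screwLength
  metal <- stem | head | shell | screw
  liner <- S2 < rIn^2 & S2 >= rLiner^2 & up & !metal

  list(metal = metal, liner = liner, spacing = spacing,
       headCenterZ = zHead + center[3])
}

#' Build a layered phantom with an embedded hip implant
#'
#' Constructs a layered cylindrical soft-tissue phantom (skin, subcutaneous
#' adipose tissue, fat, muscle, from the surface inwards, with a cortical
#' bone core) on a cuboid grid, and embeds the voxelized implant with its
#' axis on the phantom axis, vertically centred. The outermost tissue voxels
#' (those with an air neighbour) form the Robin boundary of the thermal
#' solve.
#'
#' @param shape integer length-3: voxel counts (default c(100, 100, 250)).
#' @param spacing isotropic voxel edge (m), default 0.002.
#' @param spec implant geometry, or NULL for no implant.
#' @param layers named numeric vector of radial layer thicknesses (m) from
#'   the surface inward; names must exist in the property table.
#' @param boneRadius radius (m) of the bone core.
#' @param radius outer phantom radius (m); default fills the cross-section
#'   minus one voxel margin.
#' @param properties property table (see \code{\link{tissueTable}}).
#' @return a \code{\link{TissueModel}} centred on the isocenter.
#' @export
makePhantom <- function(shape = c(100L, 100L, 250L), spacing = 0.002,
                        spec = implantSpec(),
                        layers = c(skin = 0.002, sat = 0.006, fat = 0.012),
                        boneRadius = 0.020, radius = NULL,
                        properties = tissueTable()) {
  shape <- as.integer(shape)
  if (is.null(radius))
    radius <- (min(shape[1:2]) / 2 - 1) * spacing
  if (sum(layers) + boneRadius >= radius)
    stop("layers do not fit inside the phantom radius")

  cx <- (seq_len(shape[1]) - 0.5) * spacing - shape[1] * spacing / 2
  cy <- (seq_len(shape[2]) - 0.5) * spacing - shape[2] * spacing / 2
  R <- sqrt(outer(cx^2, cy^2, "+"))
  plane <- array(0L, shape[1:2])
  bounds <- radius - c(0, cumsum(layers))  # outer edge of each layer
  for (i in seq_along(layers))
    plane[R <= bounds[i] & R > bounds[i + 1]] <-
      labelOf(properties, names(layers)[i])
  plane[R <= bounds[length(bounds)] & R > boneRadius] <-
    labelOf(properties, "muscle")
  plane[R <= boneRadius] <- labelOf(properties, "bone")
  labels <- array(rep(plane, shape[3]), shape)

  implant <- array(FALSE, shape)
  headZ <- NA_real_
  if (!is.null(spec)) {
    rOut <- spec$shellOuterDiameter / 2
    zTop <- spec$totalHeight - spec$headDiameter / 2 + rOut + spec$screwLength
    if (zTop >= (shape[3] - 4) * spacing || 2 * rOut >= 2 * radius)
      stop("geometry error: implant exceeds phantom bounds")
    z0 <- (shape[3] * spacing - zTop) / 2  # vertically centred
    vox <- makeImplant(spec, spacing, dim = shape,
                       center = c(shape[1] / 2 * spacing,
                                  shape[2] / 2 * spacing, z0))
    if (any((vox$metal | vox$liner) & labels == 0L))
      stop("geometry error: implant extends into air")
    labels[vox$metal] <- labelOf(properties, "cocrmo")
    labels[vox$liner] <- labelOf(properties, "pe")
    implant <- vox$metal | vox$liner
    headZ <- vox$headCenterZ
  }

  origin <- -shape * spacing / 2
  methods::new("TissueModel", spacing = spacing, labels = labels,
               implantMask = implant, properties = properties,
               origin = origin,
               meta = list(headCenterZLocal = headZ))
}

#' Conducting-disk validation model
#'
#' A thin conducting disk (axis along z, centred at the isocenter) in air,
#' used to validate the quasi-static eddy solver against the closed-form
#' resistive-limit power of a disk in a uniform axial field,
#' P = sigma omega^2 B^2 pi t a^4 / 16.
#'
#' @param radius disk radius a (m).
#' @param thickness disk thickness t (m).
#' @param spacing voxel edge (m).
#' @param material property-table name of the disk material.
#' @param properties property table.
#' @return a \code{TissueModel} containing only the disk.
#' @export
makeDiskModel <- function(radius = 0.020, thickness = 0.004,
                          spacing = 0.001, material = "cocrmo",
                          properties = tissueTable()) {
  nxy <- 2L * ceiling(radius / spacing) + 4L
  nz <- ceiling(thickness / spacing) + 4L
  shape <- c(nxy, nxy, nz)
  cx <- (seq_len(nxy) - 0.5) * spacing - nxy * spacing / 2
  cz <- (seq_len(nz) - 0.5) * spacing - nz * spacing / 2
  R <- sqrt(outer(cx^2, cx^2, "+"))
  inPlane <- R <= radius
  inZ <- abs(cz) <= thickness / 2
  labels <- array(0L, shape)
  lab <- labelOf(properties, material)
  for (k in which(inZ)) labels[, , k][inPlane] <- lab
  mask <- labels == lab
  methods::new("TissueModel", spacing = spacing, labels = labels,
               implantMask = mask, properties = properties,
               origin = -shape * spacing / 2, meta = list())
}

#' Figure-of-merit axial offsets for the 12 imaging positions
#'
#' Implant-head z offsets (m) relative to isocenter for position indices
#' 1..12 (thorax imaging through femur/knee imaging), spaced by 64 mm.
#' @export
positionOffsets <- function() seq(0.288, by = -0.064, length.out = 12L)

#' Place the body at one of the 12 imaging positions
#'
#' Shifts the model origin along the bore axis so that the implant head
#' centre sits at the axial offset of the requested position index
#' (+288 mm for index 1 down to -416 mm for index 12, in 64 mm steps).
#'
#' @param model a \code{TissueModel} built with an implant.
#' @param positionIndex integer in 1..12.
#' @return the repositioned \code{TissueModel}.
#' @export
placeBody <- function(model, positionIndex) {
  if (!(positionIndex %in% 1:12)) stop("positionIndex must be in 1..12")
  zLocal <- model@meta$headCenterZLocal
  if (is.null(zLocal) || is.na(zLocal))
    stop("model carries no implant head position")
  model@origin[3] <- positionOffsets()[positionIndex] - zLocal
  model
}

#' Implant head z position (m) in scanner coordinates
#' @param model a \code{TissueModel}.
#' @export
implantHeadZ <- function(model) model@origin[3] + model@meta$headCenterZLocal

#' Body-surface voxel mask
#'
#' Tissue voxels with at least one air (label 0) face neighbour; these are
#' the voxels carrying the Robin (convective) boundary condition.
#' @param model a \code{TissueModel}.
#' @return logical 3D array.
#' @export
surfaceMask <- function(model) {
  lab <- model@labels != 0L
  d <- dim(lab)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  nAir <- array(FALSE, d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (2:(d[3] + 1)) + s[3], drop = FALSE]
    nAir <- nAir | !nb
  }
  nAir & lab
}
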