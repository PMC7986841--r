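# Shared fixtures, built in code at test time.

# Homogeneous block of one tissue (label 1 = muscle by default), optionally
# with modified properties; air-free unless padAir.
uniformModel <- function(shape, spacing = 0.002, tissue = "muscle",
                         props = tissueTable(), padAir = FALSE) {
  lab <- array(labelOf_(props, tissue), shape)
  if (padAir) {
    lab[c(1, shape[1]), , ] <- 0L
    lab[, c(1, shape[2]), ] <- 0L
    lab[, , c(1, shape[3])] <- 0L
  }
  methods::new("TissueModel", spacing = spacing, labels = lab,
               implantMask = array(FALSE, shape), properties = props,
               origin = -shape * spacing / 2, meta = list())
}

labelOf_ <- function(props, nm) props$label[match(nm, props$name)]

# Property table with perfusion/metabolism switched off (linear conduction).
linearProps <- function() {
  p <- tissueTable()
  p$hB0[] <- 0
  p$pMet0[] <- 0
  p
}

# Small phantom with implant used by several suites (cached).
.fixtures <- new.env(parent = emptyenv())
smallPhantom <- function() {
  if (is.null(.fixtures$smallPhantom))
    .fixtures$smallPhantom <- makePhantom(shape = c(60L, 60L, 160L))
  .fixtures$smallPhantom
}

smallDisk <- function() {
  if (is.null(.fixtures$smallDisk))
    .fixtures$smallDisk <- makeDiskModel(radius = 0.012, thickness = 0.004,
                                         spacing = 0.002)
  .fixtures$smallDisk
}

# Uniform-axial-field vector potential (symmetric gauge), B in tesla.
uniformAxialA <- function(B) function(p) cbind(-p[, 2], p[, 1], 0) * B / 2
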