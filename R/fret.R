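#' Dye-to-dye distance for a binding configuration
#'
#' The DNA is a planar polyline of base-pair steps of length `risePerBp`.
#' Every bound protein whose footprint centre lies strictly between the two
#' dye anchors inserts a coplanar, same-sense kink of that register's bend
#' angle; kinks outside the dye span leave the inter-dye distance unchanged.
#' An optional dye-linker offset is added in quadrature.
#'
#' @param lattice a [LatticeSpec-class] with both dyes defined.
#' @param config sorted integer vector of 0-based bound registers (may be
#'   empty).
#' @param bend a [BendModel-class].
#' @return Distance in Angstrom between the dye anchor points.
#' @examples
#' lat <- latticeSpec(19, specificRegister = 9, dyeDonor = dyeSite(0),
#'                    dyeAcceptor = dyeSite(18))
#' dyeDistance(lat, integer(0), bendModel())   # 18 * 3.4 = 61.2
#' dyeDistance(lat, 9L, bendModel())           # ~37.3 (105 deg kink)
#' @export
dyeDistance <- function(lattice, config, bend) {
  d1 <- min(lattice@dyeDonor@bpIndex, lattice@dyeAcceptor@bpIndex)
  d2 <- max(lattice@dyeDonor@bpIndex, lattice@dyeAcceptor@bpIndex)
  if (d1 == d2) return(bend@dyeLinkerOffset)
  config <- as.integer(config)
  kinks <- config[config > d1 & config < d2]
  angleOf <- function(r)
    if (!is.na(lattice@specificRegister) && r == lattice@specificRegister)
      bend@bendAngleSpecific else bend@bendAngleNonspecific
  pos <- c(0, 0)
  theta <- 0
  for (v in seq.int(d1, d2 - 1L)) {
    # turn at vertex v (strictly between the dyes) before stepping onward
    if (v %in% kinks && v > d1)
      theta <- theta + angleOf(v) * pi / 180
    pos <- pos + bend@risePerBp * c(cos(theta), sin(theta))
  }
  sqrt(sum(pos^2) + bend@dyeLinkerOffset^2)
}

#' FRET efficiency from the Foerster law
#'
#' `E = 1 / (1 + (r / R0)^6)`.
#'
#' @param r dye separation in Angstrom (> 0); vectorised.
#' @param params a [FretParameters-class] supplying the Foerster radius.
#' @return Efficiency in (0, 1].
#' @examples
#' fretEfficiency(51, fretParameters())    # 0.5 at r = R0
#' fretEfficiency(61.2, fretParameters())  # ~0.251
#' @export
fretEfficiency <- function(r, params = fretParameters()) {
  if (any(r <= 0)) stop("dye separation r must be > 0")
  1 / (1 + (r / params@r0)^6)
}

# Forward signal model shared by proximityRatio and the burst simulator.
# Returns the expected donor / acceptor channel signals (unit total emission
# scale) for a molecule with FRET efficiency e, before background.
channelSignals <- function(e, params) {
  fD <- (1 - e)
  fA <- params@gamma * e + params@donorCrosstalkFraction * (1 - e) +
    params@directExcitationFraction
  list(donor = fD, acceptor = fA)
}

#' Proximity ratio from FRET efficiency
#'
#' Synthesises apparent channel signals `F_D = (1 - E)` and
#' `F_A = gamma * E + crosstalk * (1 - E) + directExcitation`, adds the
#' configured backgrounds, and forms the proximity ratio. With
#' `corrected = TRUE` the background, crosstalk and direct-excitation terms
#' are removed before forming the ratio, so that with `gamma = 1` and zero
#' artifacts `P = E` exactly; with `corrected = FALSE` the raw ratio of the
#' apparent signals is returned.
#'
#' @param e FRET efficiency in \[0, 1\]; vectorised.
#' @param params a [FretParameters-class].
#' @param corrected logical, apply background/crosstalk/direct-excitation
#'   corrections (default `TRUE`).
#' @return Proximity ratio.
#' @examples
#' proximityRatio(0.5, fretParameters())   # 0.5
#' proximityRatio(0, fretParameters(donorCrosstalkFraction = 0.1))  # 0
#' @export
proximityRatio <- function(e, params = fretParameters(), corrected = TRUE) {
  if (any(e < 0 | e > 1)) stop("efficiency must be in [0, 1]")
  sig <- channelSignals(e, params)
  fD <- sig$donor + params@backgroundDonor
  fA <- sig$acceptor + params@backgroundAcceptor
  if (!corrected) return(fA / (fA + fD))
  aCorr <- fA - params@backgroundAcceptor -
    params@donorCrosstalkFraction * (fD - params@backgroundDonor) -
    params@directExcitationFraction
  dCorr <- fD - params@backgroundDonor
  aCorr / (aCorr + dCorr)
}

#' Proximity ratio of one binding configuration
#'
#' Convenience chain [dyeDistance()] -> [fretEfficiency()] ->
#' [proximityRatio()].
#'
#' @inheritParams dyeDistance
#' @param fret a [FretParameters-class].
#' @param corrected logical, passed to [proximityRatio()].
#' @return Proximity ratio of the configuration's dye geometry.
#' @export
configProximityRatio <- function(lattice, config, bend = bendModel(),
                                 fret = fretParameters(), corrected = TRUE) {
  r <- dyeDistance(lattice, config, bend)
  proximityRatio(fretEfficiency(r, fret), fret, corrected = corrected)
}
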