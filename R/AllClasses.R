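#' @import methods
NULL

#' Dye attachment site on a DNA construct
#'
#' Position of a donor or acceptor fluorophore on the lattice, given as a
#' 0-based base-pair index together with the chemistry of attachment
#' (5' terminal C6 linker or internal amino-dT).
#'
#' @slot bpIndex integer, 0-based base-pair index of the dye anchor.
#' @slot attachment character, `"five_prime_end"` or `"internal_dT"`.
#' @exportClass DyeSite
setClass("DyeSite",
  representation(bpIndex = "integer", attachment = "character"),
  prototype(bpIndex = 0L, attachment = "five_prime_end"))

setValidity("DyeSite", function(object) {
  if (length(object@bpIndex) != 1L || is.na(object@bpIndex) || object@bpIndex < 0L)
    return("bpIndex must be a single non-negative integer")
  if (!object@attachment %in% c("five_prime_end", "internal_dT"))
    return("attachment must be 'five_prime_end' or 'internal_dT'")
  TRUE
})

#' Construct a DyeSite
#'
#' @param bpIndex 0-based base-pair index of the dye anchor point.
#' @param attachment attachment chemistry, `"five_prime_end"` (default) or
#'   `"internal_dT"`.
#' @return A [DyeSite-class] object.
#' @examples
#' dyeSite(0)
#' dyeSite(13, "internal_dT")
#' @export
dyeSite <- function(bpIndex, attachment = "five_prime_end") {
  new("DyeSite", bpIndex = as.integer(bpIndex), attachment = attachment)
}

#' DNA construct as a one-dimensional binding lattice
#'
#' A labelled DNA fragment represented as a lattice of candidate TBP binding
#' registers, one register per base pair (the footprint centre may overhang
#' the lattice ends). One register may be designated specific (the TATA box);
#' all others are non-specific. Registers can be marked inactive, e.g. to
#' represent a single-stranded extension that does not support binding.
#'
#' @slot name character construct name.
#' @slot lengthBp integer lattice length in base pairs.
#' @slot sequence character IUPAC DNA sequence or `NA`.
#' @slot specificRegister integer 0-based footprint-centre index of the
#'   specific site, or `NA` if the construct has none.
#' @slot footprintBp integer occluded length n (bp): two bound proteins must
#'   have centre separation >= n.
#' @slot contactSpanBp integer furthest span m (bp) between protein-DNA
#'   contacts; stored for reporting, not used in the statistical weights.
#' @slot inactiveRegisters integer vector of 0-based indices excluded from
#'   binding.
#' @slot dyeDonor,dyeAcceptor [DyeSite-class] dye positions.
#' @seealso [latticeSpec()], [countBindingRegisters()],
#'   [equilibriumOccupancy()]
#' @exportClass LatticeSpec
setClass("LatticeSpec",
  representation(
    name = "character",
    lengthBp = "integer",
    sequence = "character",
    specificRegister = "integer",
    footprintBp = "integer",
    contactSpanBp = "integer",
    inactiveRegisters = "integer",
    dyeDonor = "DyeSite",
    dyeAcceptor = "DyeSite"))

setValidity("LatticeSpec", function(object) {
  l <- object@lengthBp
  if (length(l) != 1L || is.na(l) || l < 1L || l > 200L)
    return("lengthBp must be in [1, 200]")
  n <- object@footprintBp; m <- object@contactSpanBp
  if (is.na(n) || n < 1L || n > l)
    return("footprintBp must satisfy 1 <= n <= lengthBp")
  if (is.na(m) || m < 1L || m > n)
    return("contactSpanBp must satisfy 1 <= m <= footprintBp")
  if (!is.na(object@specificRegister) &&
      (object@specificRegister < 0L || object@specificRegister >= l))
    return("specificRegister must lie in [0, lengthBp)")
  if (!is.na(object@sequence) && nchar(object@sequence) != l)
    return("sequence length must equal lengthBp")
  if (any(object@inactiveRegisters < 0L | object@inactiveRegisters >= l))
    return("inactiveRegisters must lie in [0, lengthBp)")
  for (s in c("dyeDonor", "dyeAcceptor")) {
    d <- slot(object, s)
    if (d@bpIndex >= l) return(sprintf("%s position outside the lattice", s))
  }
  TRUE
})

#' Construct a LatticeSpec
#'
#' @param lengthBp lattice length in bp (1-200).
#' @param sequence optional IUPAC DNA string of length `lengthBp`.
#' @param specificRegister 0-based centre index of the specific (TATA)
#'   register; `NA` for none; `"auto"` to locate the first TATAWAWR match in
#'   `sequence` via [locateSpecificSite()].
#' @param footprintBp occluded footprint n in bp (default 8, the TATAWAWR
#'   length).
#' @param contactSpanBp contact span m in bp (default `footprintBp`).
#' @param inactiveRegisters 0-based indices of registers that cannot bind.
#' @param dyeDonor,dyeAcceptor [DyeSite-class] objects (defaults: donor at
#'   index 0, acceptor at the last base).
#' @param name construct name.
#' @return A validated [LatticeSpec-class].
#' @examples
#' latticeSpec(14, name = "TATA-14E")
#' latticeSpec(25, sequence = paste(rep("A", 25), collapse = ""),
#'             specificRegister = 5)
#' @export
latticeSpec <- function(lengthBp, sequence = NA_character_,
                        specificRegister = NA, footprintBp = 8L,
                        contactSpanBp = footprintBp,
                        inactiveRegisters = integer(0),
                        dyeDonor = dyeSite(0L),
                        dyeAcceptor = dyeSite(lengthBp - 1L),
                        name = "construct") {
  if (identical(specificRegister, "auto")) {
    if (is.na(sequence))
      stop("specificRegister = 'auto' requires a sequence")
    specificRegister <- locateSpecificSite(sequence)
    if (is.na(specificRegister))
      warning("no TATAWAWR match in sequence; construct has no specific site")
  }
  new("LatticeSpec",
      name = name,
      lengthBp = as.integer(lengthBp),
      sequence = as.character(sequence),
      specificRegister = as.integer(specificRegister),
      footprintBp = as.integer(footprintBp),
      contactSpanBp = as.integer(contactSpanBp),
      inactiveRegisters = as.integer(sort(unique(inactiveRegisters))),
      dyeDonor = dyeDonor, dyeAcceptor = dyeAcceptor)
}

#' Binding energetics of TBP on the lattice
#'
#' Dissociation constants for the specific and non-specific registers at a
#' reference monovalent salt concentration, nearest-neighbour cooperativity,
#' a log-log salt scaling law with separate exponents for the two register
#' classes, and an optional TFIIA mode that boosts specificity while
#' suppressing non-specific affinity.
#'
#' Salt scaling follows `log Kd = log Kd_ref + z * log(salt / saltRef)`, a
#' Record-style linear law in log-log coordinates. With
#' `saltExpNonspecific > saltExpSpecific`, non-specific binding is
#' preferentially lost at elevated salt, reproducing the suppression of
#' cooperative off-TATA binding at 150 mM KCl.
#'
#' @slot kdSpecific nM, Kd of the TATA register at `saltRefMM`.
#' @slot kdNonspecific nM, Kd of every other register at `saltRefMM`.
#' @slot cooperativityOmega dimensionless weight applied per pair of proteins
#'   bound at centre separation exactly equal to the footprint.
#' @slot saltMM monovalent salt (mM) of the modelled condition.
#' @slot saltRefMM reference salt (mM) at which the Kd values are quoted.
#' @slot saltExpSpecific,saltExpNonspecific log-log salt slopes.
#' @slot tfiiaMode logical, TFIIA co-titrated.
#' @slot tfiiaSpecificityBoost factor (>= 1) dividing the specific Kd in
#'   TFIIA mode.
#' @slot tfiiaNsSuppression factor (>= 1) multiplying the non-specific Kd in
#'   TFIIA mode.
#' @exportClass BindingEnergetics
setClass("BindingEnergetics",
  representation(
    kdSpecific = "numeric", kdNonspecific = "numeric",
    cooperativityOmega = "numeric",
    saltMM = "numeric", saltRefMM = "numeric",
    saltExpSpecific = "numeric", saltExpNonspecific = "numeric",
    tfiiaMode = "logical",
    tfiiaSpecificityBoost = "numeric", tfiiaNsSuppression = "numeric"))

setValidity("BindingEnergetics", function(object) {
  if (object@kdSpecific <= 0 || object@kdNonspecific <= 0)
    return("all Kd must be > 0")
  if (object@cooperativityOmega < 0) return("cooperativityOmega must be >= 0")
  if (object@saltMM <= 0 || object@saltRefMM <= 0)
    return("salt concentrations must be > 0")
  if (object@tfiiaSpecificityBoost < 1 || object@tfiiaNsSuppression < 1)
    return("TFIIA boost/suppression factors must be >= 1")
  TRUE
})

#' Construct BindingEnergetics
#'
#' Defaults describe the low-salt reference condition: tight TATA binding
#' (Kd 5 nM at 50 mM KCl), weaker but cooperative non-specific binding.
#'
#' @param kdSpecific,kdNonspecific Kd (nM) at the reference salt.
#' @param cooperativityOmega nearest-neighbour cooperativity (1 = none).
#' @param saltMM modelled KCl (mM).
#' @param saltRefMM reference KCl (mM) for the quoted Kd values.
#' @param saltExpSpecific,saltExpNonspecific log-log salt exponents.
#' @param tfiiaMode logical, model TFIIA co-titration.
#' @param tfiiaSpecificityBoost,tfiiaNsSuppression TFIIA multipliers (>= 1).
#' @return A [BindingEnergetics-class].
#' @examples
#' bindingEnergetics()                      # 50 mM KCl reference
#' bindingEnergetics(saltMM = 150)          # physiological salt
#' @export
bindingEnergetics <- function(kdSpecific = 5, kdNonspecific = 40,
                              cooperativityOmega = 5,
                              saltMM = 50, saltRefMM = 50,
                              saltExpSpecific = 0.4,
                              saltExpNonspecific = 4,
                              tfiiaMode = FALSE,
                              tfiiaSpecificityBoost = 4,
                              tfiiaNsSuppression = 25) {
  new("BindingEnergetics",
      kdSpecific = kdSpecific, kdNonspecific = kdNonspecific,
      cooperativityOmega = cooperativityOmega,
      saltMM = saltMM, saltRefMM = saltRefMM,
      saltExpSpecific = saltExpSpecific,
      saltExpNonspecific = saltExpNonspecific,
      tfiiaMode = tfiiaMode,
      tfiiaSpecificityBoost = tfiiaSpecificityBoost,
      tfiiaNsSuppression = tfiiaNsSuppression)
}

#' FRET detection and correction parameters
#'
#' @slot r0 Foerster radius (Angstrom); 51 A for the Atto-488/Atto-633(647N)
#'   pairs used with these constructs.
#' @slot gamma detection-efficiency/quantum-yield normalisation; 1 means the
#'   corrected proximity ratio equals the FRET efficiency.
#' @slot donorCrosstalkFraction fraction of donor signal leaking into the
#'   acceptor channel.
#' @slot directExcitationFraction acceptor signal from direct excitation,
#'   as a fraction of the total emission scale.
#' @slot backgroundDonor,backgroundAcceptor additive backgrounds (counts per
#'   burst or per well, on the same scale as the signals).
#' @exportClass FretParameters
setClass("FretParameters",
  representation(r0 = "numeric", gamma = "numeric",
                 donorCrosstalkFraction = "numeric",
                 directExcitationFraction = "numeric",
                 backgroundDonor = "numeric",
                 backgroundAcceptor = "numeric"))

setValidity("FretParameters", function(object) {
  if (object@r0 <= 0) return("r0 must be > 0")
  if (object@gamma <= 0) return("gamma must be > 0")
  for (s in c("donorCrosstalkFraction", "directExcitationFraction")) {
    v <- slot(object, s)
    if (v < 0 || v >= 1) return(sprintf("%s must be in [0, 1)", s))
  }
  TRUE
})

#' Construct FretParameters
#'
#' @param r0 Foerster radius in Angstrom (default 51).
#' @param gamma gamma normalisation factor (default 1, i.e. "uncorrected").
#' @param donorCrosstalkFraction donor-to-acceptor channel crosstalk.
#' @param directExcitationFraction direct acceptor excitation fraction.
#' @param backgroundDonor,backgroundAcceptor additive channel backgrounds.
#' @return A [FretParameters-class].
#' @examples
#' fretParameters()
#' fretParameters(gamma = 0.8, donorCrosstalkFraction = 0.1)
#' @export
fretParameters <- function(r0 = 51, gamma = 1,
                           donorCrosstalkFraction = 0,
                           directExcitationFraction = 0,
                           backgroundDonor = 0, backgroundAcceptor = 0) {
  new("FretParameters", r0 = r0, gamma = gamma,
      donorCrosstalkFraction = donorCrosstalkFraction,
      directExcitationFraction = directExcitationFraction,
      backgroundDonor = backgroundDonor,
      backgroundAcceptor = backgroundAcceptor)
}

#' DNA bending geometry for bound TBP
#'
#' The DNA is modelled as a planar polyline of base-pair steps; each bound
#' protein whose footprint centre lies strictly between the two dyes inserts
#' a coplanar, same-sense kink of the register's bend angle.
#'
#' @slot bendAngleSpecific,bendAngleNonspecific kink angles in degrees
#'   (default 105, human TBP).
#' @slot risePerBp helical rise per base pair in Angstrom (default 3.4).
#' @slot dyeLinkerOffset scalar dye-linker offset in Angstrom added in
#'   quadrature to the axis-anchor distance (default 0).
#' @exportClass BendModel
setClass("BendModel",
  representation(bendAngleSpecific = "numeric",
                 bendAngleNonspecific = "numeric",
                 risePerBp = "numeric",
                 dyeLinkerOffset = "numeric"))

setValidity("BendModel", function(object) {
  for (s in c("bendAngleSpecific", "bendAngleNonspecific")) {
    a <- slot(object, s)
    if (a < 0 || a >= 180) return(sprintf("%s must be in [0, 180)", s))
  }
  if (object@risePerBp <= 0) return("risePerBp must be > 0")
  if (object@dyeLinkerOffset < 0) return("dyeLinkerOffset must be >= 0")
  TRUE
})

#' Construct a BendModel
#'
#' @param bendAngleSpecific,bendAngleNonspecific kink angle (degrees)
#'   inserted by TBP bound at the specific / a non-specific register.
#' @param risePerBp rise per base pair (Angstrom).
#' @param dyeLinkerOffset dye linker offset (Angstrom), added in quadrature.
#' @return A [BendModel-class].
#' @examples
#' bendModel()
#' @export
bendModel <- function(bendAngleSpecific = 105, bendAngleNonspecific = 105,
                      risePerBp = 3.4, dyeLinkerOffset = 0) {
  new("BendModel", bendAngleSpecific = bendAngleSpecific,
      bendAngleNonspecific = bendAngleNonspecific,
      risePerBp = risePerBp, dyeLinkerOffset = dyeLinkerOffset)
}

#' Kinetic scheme for the branched association/dissociation pathway
#'
#' Single-occupancy continuous-time Markov model on a [LatticeSpec-class]:
#' one unbound state plus one state per active register. Association to every
#' register proceeds with a uniform pseudo-first-order rate `kOn * [TBP]`;
#' dissociation is register-class specific; adjacent registers exchange by
#' sliding at rate `kSlide` (Metropolis-balanced so that equilibrium
#' occupancies are unchanged by sliding).
#'
#' @slot lattice [LatticeSpec-class].
#' @slot kOnPerRegister association rate constant, M^-1 s^-1.
#' @slot kOffSpecific,kOffNonspecific dissociation rates, s^-1.
#' @slot kSlide base hop rate to an adjacent register, s^-1.
#' @slot tbpNM TBP concentration during incubation (nM).
#' @slot competitorNM unlabelled competitor added at the chase (nM).
#' @slot incubationS,observationS incubation and post-chase observation
#'   windows (s).
#' @exportClass KineticScheme
setClass("KineticScheme",
  representation(lattice = "LatticeSpec",
                 kOnPerRegister = "numeric",
                 kOffSpecific = "numeric", kOffNonspecific = "numeric",
                 kSlide = "numeric",
                 tbpNM = "numeric", competitorNM = "numeric",
                 incubationS = "numeric", observationS = "numeric"))

setValidity("KineticScheme", function(object) {
  rates <- c(object@kOnPerRegister, object@kOffSpecific,
             object@kOffNonspecific, object@kSlide)
  if (any(rates < 0)) return("all rates must be >= 0")
  if (object@tbpNM < 0 || object@competitorNM < 0)
    return("concentrations must be >= 0")
  if (object@incubationS < 0 || object@observationS <= 0)
    return("incubationS >= 0 and observationS > 0 required")
  TRUE
})

#' Construct a KineticScheme
#'
#' Defaults mirror the chase protocol on the minimal TATA construct: 1 nM
#' labelled DNA pre-incubated with 30 nM TBP at 50 mM KCl, then chased with
#' 2 uM unlabelled competitor. The association rate constant defaults to
#' 2e6 M^-1 s^-1 (consensus-site bending association) applied uniformly to
#' all registers; dissociation defaults are the fast (non-specific,
#' 0.02 s^-1) and slow (TATA, 0.0014 s^-1) rates.
#'
#' @param lattice a [LatticeSpec-class]; default the 14-bp TATA construct
#'   with the specific register at its centre.
#' @param kOnPerRegister M^-1 s^-1.
#' @param kOffSpecific,kOffNonspecific s^-1.
#' @param kSlide s^-1 hop rate (default 0).
#' @param tbpNM,competitorNM nM.
#' @param incubationS,observationS seconds.
#' @return A [KineticScheme-class].
#' @examples
#' kineticScheme(incubationS = 60)
#' @export
kineticScheme <- function(lattice = latticeSpec(14, specificRegister = 6,
                                                name = "TATA-14E"),
                          kOnPerRegister = 2e6,
                          kOffSpecific = 0.0014, kOffNonspecific = 0.02,
                          kSlide = 0, tbpNM = 30, competitorNM = 2000,
                          incubationS = 60, observationS = 1800) {
  new("KineticScheme", lattice = lattice, kOnPerRegister = kOnPerRegister,
      kOffSpecific = kOffSpecific, kOffNonspecific = kOffNonspecific,
      kSlide = kSlide, tbpNM = tbpNM, competitorNM = competitorNM,
      incubationS = incubationS, observationS = observationS)
}

#' Species mixture for single-pair FRET burst simulation
#'
#' @slot p true proximity ratios of the donor-acceptor species.
#' @slot weight species weights; together with `donorOnlyFraction` they sum
#'   to 1.
#' @slot donorOnlyFraction fraction of molecules with a missing or inactive
#'   acceptor.
#' @exportClass SpeciesMixture
setClass("SpeciesMixture",
  representation(p = "numeric", weight = "numeric",
                 donorOnlyFraction = "numeric"))

setValidity("SpeciesMixture", function(object) {
  if (length(object@p) != length(object@weight))
    return("p and weight must have equal length")
  if (any(object@p < 0 | object@p > 1)) return("p values must be in [0, 1]")
  if (any(object@weight < 0) || object@donorOnlyFraction < 0)
    return("weights must be >= 0")
  tot <- sum(object@weight) + object@donorOnlyFraction
  if (abs(tot - 1) > 1e-8)
    return("weights plus donorOnlyFraction must sum to 1")
  TRUE
})

#' Construct a SpeciesMixture
#'
#' @param p numeric vector of true proximity ratios.
#' @param weight species weights (normalised together with
#'   `donorOnlyFraction` if they do not already sum to 1 with it).
#' @param donorOnlyFraction donor-only subpopulation fraction.
#' @return A [SpeciesMixture-class].
#' @examples
#' speciesMixture(p = c(0.15, 0.5), weight = c(0.4, 0.4),
#'                donorOnlyFraction = 0.2)
#' @export
speciesMixture <- function(p, weight, donorOnlyFraction = 0) {
  tot <- sum(weight) + donorOnlyFraction
  new("SpeciesMixture", p = p, weight = weight / tot,
      donorOnlyFraction = donorOnlyFraction / tot)
}

#' Nucleosome competition scenario
#'
#' A TATA box placed a few base pairs inside the last histone-DNA contacts
#' of a positioned nucleosome (entry-exit site), competing with TBP binding.
#'
#' @slot constructLengthBp total DNA length (159 bp for the TATA-601
#'   construct).
#' @slot wrappedBp nucleosome-wrapped length (147 bp).
#' @slot tataDepthBp depth of the TATA register inside the last histone
#'   contact (bp, default 5).
#' @slot histoneState one of `"recombinant"`, `"ac_all"`, `"ac_H3"`,
#'   `"ac_H4"`, `"hela"`, `"hela_hyperac"`.
#' @slot saltMM monovalent salt (mM).
#' @slot tfiia logical; TFIIA present (fast-exchange competition).
#' @exportClass NucleosomeScenario
setClass("NucleosomeScenario",
  representation(constructLengthBp = "integer", wrappedBp = "integer",
                 tataDepthBp = "integer", histoneState = "character",
                 saltMM = "numeric", tfiia = "logical"))

setValidity("NucleosomeScenario", function(object) {
  if (object@constructLengthBp < object@wrappedBp)
    return("constructLengthBp must be >= wrappedBp")
  if (object@tataDepthBp < 0L || object@tataDepthBp > object@wrappedBp %/% 2L)
    return("tataDepthBp must be in [0, wrappedBp/2]")
  states <- c("recombinant", "ac_all", "ac_H3", "ac_H4", "hela",
              "hela_hyperac")
  if (!object@histoneState %in% states)
    return(paste("histoneState must be one of:", paste(states, collapse = ", ")))
  if (object@saltMM <= 0) return("saltMM must be > 0")
  TRUE
})

#' Construct a NucleosomeScenario
#'
#' @param constructLengthBp DNA length in bp (default 159, TATA-601).
#' @param wrappedBp wrapped length (default 147).
#' @param tataDepthBp TATA depth inside the last histone contact (default 5).
#' @param histoneState histone composition/modification state.
#' @param saltMM KCl in mM.
#' @param tfiia logical, TFIIA present.
#' @return A [NucleosomeScenario-class].
#' @examples
#' nucleosomeScenario(histoneState = "ac_H3", saltMM = 150)
#' @export
nucleosomeScenario <- function(constructLengthBp = 159, wrappedBp = 147,
                               tataDepthBp = 5,
                               histoneState = "recombinant",
                               saltMM = 150, tfiia = FALSE) {
  new("NucleosomeScenario",
      constructLengthBp = as.integer(constructLengthBp),
      wrappedBp = as.integer(wrappedBp),
      tataDepthBp = as.integer(tataDepthBp),
      histoneState = histoneState, saltMM = saltMM, tfiia = tfiia)
}
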