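#' Predicted bulk titration isotherm
#'
#' Ensemble mean proximity ratio as a function of TBP concentration: at each
#' concentration the configuration distribution from
#' [equilibriumOccupancy()] (enumeration path) is combined with the
#' proximity ratio of each configuration's dye geometry.
#'
#' By default concentrations are interpreted as free TBP (valid when the
#' labelled DNA is at trace concentration, well below Kd). With `dnaNM > 0`
#' and/or a competitor block, the free concentration at each titration point
#' is obtained from mass balance
#' `total = free + dnaNM * <n bound | labelled> + compNM * <n bound | competitor>`
#' by damped fixed-point iteration (tolerance 1e-9 nM, at most 1e4
#' iterations).
#'
#' @param lattice a [LatticeSpec-class] (at most 30 active registers; the
#'   configuration average requires the enumeration path).
#' @param energetics a [BindingEnergetics-class].
#' @param concGrid ascending, non-negative total TBP concentrations (nM).
#' @param fret a [FretParameters-class].
#' @param bend a [BendModel-class].
#' @param dnaNM labelled DNA concentration for depletion correction
#'   (default 0 = free equals total).
#' @param competitor optional list with elements `lattice`
#'   ([LatticeSpec-class]), optional `energetics` (defaults to `energetics`)
#'   and `concNM`, either a numeric scalar/vector (nM) or `"equimolar"` to
#'   co-titrate the competitor 1:1 with TBP.
#' @param corrected logical, corrected proximity ratios (default `TRUE`).
#' @return `data.frame` with columns `conc_nM`, `proximity_ratio`, and
#'   `free_nM` (solved free TBP).
#' @examples
#' lat <- latticeSpec(14, specificRegister = 6, inactiveRegisters = 0:5,
#'                    dyeDonor = dyeSite(0), dyeAcceptor = dyeSite(13))
#' iso <- predictedIsotherm(lat, bindingEnergetics(cooperativityOmega = 1),
#'                          concGrid = c(0, 1, 5, 25, 100))
#' @export
predictedIsotherm <- function(lattice, energetics, concGrid,
                              fret = fretParameters(), bend = bendModel(),
                              dnaNM = 0, competitor = NULL,
                              corrected = TRUE) {
  if (any(concGrid < 0)) stop("concGrid must be non-negative")
  if (is.unsorted(concGrid)) stop("concGrid must be ascending")
  configs <- enumerateConfigurations(lattice)
  pConfig <- vapply(configs, function(cf)
    configProximityRatio(lattice, cf, bend, fret, corrected), numeric(1))

  compConc <- NULL
  if (!is.null(competitor)) {
    if (is.null(competitor$energetics)) competitor$energetics <- energetics
    compConc <- if (identical(competitor$concNM, "equimolar")) concGrid
      else rep_len(competitor$concNM, length(concGrid))
  }

  meanBound <- function(lat, en, free)
    expectedBound(equilibriumOccupancy(lat, en, free, method = "transfer"))

  out <- data.frame(conc_nM = concGrid, proximity_ratio = NA_real_,
                    free_nM = NA_real_)
  for (i in seq_along(concGrid)) {
    total <- concGrid[i]
    free <- total
    if ((dnaNM > 0 || !is.null(competitor)) && total > 0) {
      cN <- if (is.null(compConc)) 0 else compConc[i]
      excess <- function(fr) {
        bound <- dnaNM * meanBound(lattice, energetics, fr)
        if (cN > 0)
          bound <- bound + cN * meanBound(competitor$lattice,
                                          competitor$energetics, fr)
        fr + bound - total
      }
      # excess() is strictly increasing in fr with excess(0) <= 0, so the
      # mass balance has a unique bracketed root; iterate to 1e-9 nM
      sol <- tryCatch(stats::uniroot(excess, c(0, total), tol = 1e-9,
                                     maxiter = 1e4),
                      error = function(e)
                        stop("mass balance failed to converge at ",
                             total, " nM: ", conditionMessage(e)))
      free <- sol$root
    }
    w <- vapply(configs, configurationWeight, numeric(1), lattice = lattice,
                energetics = energetics, freeTbp = free)
    out$proximity_ratio[i] <- sum(w * pConfig) / sum(w)
    out$free_nM[i] <- free
  }
  out
}
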