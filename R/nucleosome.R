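#' Default nucleosome unwrapping-constant table
#'
#' Equilibrium constants for transient exposure of the TATA register at the
#' entry-exit site, indexed by monovalent salt and histone state. All values
#' are package calibration choices (no unwrapping constants are available
#' for these constructs): they are set so that every state is near-fully
#' exposed at 5-50 mM KCl, while at physiological salt exposure collapses
#' for recombinant octamers and is partially restored by acetylation, more
#' so by endogenous (HeLa) histones and their hyperacetylated form.
#'
#' @return `data.frame` with columns `salt_mM`, `state`, `k_unwrap`.
#' @export
defaultUnwrapTable <- function() {
  states <- c(recombinant = NA, ac_all = NA, ac_H3 = NA, ac_H4 = NA,
              hela = NA, hela_hyperac = NA)
  k <- rbind(
    recombinant  = c(30, 12, 0.80, 0.18),
    ac_all       = c(30, 12, 1.50, 0.60),
    ac_H3        = c(30, 12, 1.50, 0.60),
    ac_H4        = c(30, 12, 1.45, 0.58),
    hela         = c(30, 12, 2.50, 1.20),
    hela_hyperac = c(30, 12, 2.80, 1.35))
  salts <- c(5, 50, 100, 150)
  data.frame(salt_mM = rep(salts, times = nrow(k)),
             state = rep(rownames(k), each = length(salts)),
             k_unwrap = as.numeric(t(k)))
}

#' Site-exposure accessibility model
#'
#' @param kUnwrapTable lookup table as from [defaultUnwrapTable()].
#' @param exchangeMode `"auto"` (slow for TBP alone, fast with TFIIA),
#'   `"slow"` or `"fast"`.
#' @return List of class `"AccessibilityModel"`.
#' @examples
#' accessibilityModel()
#' @export
accessibilityModel <- function(kUnwrapTable = defaultUnwrapTable(),
                               exchangeMode = c("auto", "slow", "fast")) {
  exchangeMode <- match.arg(exchangeMode)
  stopifnot(all(c("salt_mM", "state", "k_unwrap") %in% names(kUnwrapTable)),
            all(kUnwrapTable$k_unwrap > 0))
  out <- list(kUnwrapTable = kUnwrapTable, exchangeMode = exchangeMode)
  class(out) <- "AccessibilityModel"
  out
}

#' Probability that the TATA register is transiently exposed
#'
#' `p_exp = K_unwrap / (1 + K_unwrap)`, with `K_unwrap` interpolated
#' log-linearly in salt from the model's lookup table for the scenario's
#' histone state (constant extrapolation outside the tabulated range).
#'
#' @param model an `"AccessibilityModel"`.
#' @param scenario a [NucleosomeScenario-class].
#' @return Exposure probability in (0, 1).
#' @examples
#' siteExposureProbability(accessibilityModel(),
#'                         nucleosomeScenario(saltMM = 50))
#' @export
siteExposureProbability <- function(model, scenario) {
  tab <- model$kUnwrapTable[model$kUnwrapTable$state ==
                              scenario@histoneState, ]
  if (nrow(tab) == 0L)
    stop("no unwrapping constants for histone state '",
         scenario@histoneState, "'")
  tab <- tab[order(tab$salt_mM), ]
  k <- if (nrow(tab) == 1L) tab$k_unwrap else
    exp(stats::approx(log(tab$salt_mM), log(tab$k_unwrap),
                      xout = log(scenario@saltMM), rule = 2)$y)
  k / (1 + k)
}

#' Nucleosome competition isotherm
#'
#' Site-exposure competition between TBP and the nucleosome in two regimes.
#' In slow exchange (TBP alone) a fraction `p_exp` of nucleosomes titrates
#' with the naked-DNA Kd at full amplitude while the blocked remainder
#' contributes only the residual off-consensus signal of the free linker
#' DNA, so the apparent Kd stays near the naked value and the saturation
#' amplitude is suppressed to about `p_exp`. In fast exchange (TFIIA) the
#' whole population titrates with `Kd_app = Kd_naked / p_exp` at full
#' amplitude: a competitive affinity shift without amplitude loss.
#'
#' @param scenario a [NucleosomeScenario-class].
#' @param model an `"AccessibilityModel"`; its `exchangeMode = "auto"`
#'   resolves to fast when `scenario@tfiia` is `TRUE`, slow otherwise.
#' @param energetics a [BindingEnergetics-class]; its specific Kd at the
#'   scenario's salt (and TFIIA mode) defines the naked-DNA affinity.
#' @param concGrid ascending TBP concentrations (nM).
#' @param pMin,amplitude unbound proximity ratio and naked-DNA saturation
#'   amplitude of the titration observable.
#' @param residualAmplitude saturation amplitude of the off-consensus
#'   linker signal on blocked nucleosomes, as a fraction of `amplitude`
#'   (default 0: the residual 150 mM signal is left unattributed; set > 0
#'   to represent off-consensus linker binding explicitly).
#' @return Object of class `"CompetitionResult"`: list with
#'   `exposureProbability`, `apparentKd` (nM, from refitting the predicted
#'   curve with [fitSingleSite()]), `maxAmplitudeFraction`, `mode`,
#'   `nakedKd`, and the `isotherm` `data.frame` (`conc_nM`,
#'   `proximity_ratio`).
#' @examples
#' res <- nucleosomeIsotherm(nucleosomeScenario(saltMM = 150),
#'                           concGrid = 10^seq(-1, 2.5, length.out = 12))
#' res$maxAmplitudeFraction
#' @export
nucleosomeIsotherm <- function(scenario, model = accessibilityModel(),
                               energetics = bindingEnergetics(
                                 saltMM = scenario@saltMM,
                                 tfiiaMode = scenario@tfiia),
                               concGrid = 10^seq(-1, 2.5, length.out = 12),
                               pMin = 0.3, amplitude = 0.3,
                               residualAmplitude = 0) {
  if (is.unsorted(concGrid)) stop("concGrid must be ascending")
  pExp <- siteExposureProbability(model, scenario)
  mode <- model$exchangeMode
  if (mode == "auto") mode <- if (scenario@tfiia) "fast" else "slow"
  saltFac <- energetics@saltMM / energetics@saltRefMM
  kdNaked <- energetics@kdSpecific * saltFac^energetics@saltExpSpecific
  if (energetics@tfiiaMode) kdNaked <- kdNaked / energetics@tfiiaSpecificityBoost

  if (mode == "slow") {
    # residual off-consensus signal: occupancy of the free linker treated
    # as a short non-specific-only lattice
    linkerBp <- max(scenario@constructLengthBp - scenario@wrappedBp, 1L)
    linker <- latticeSpec(linkerBp, name = "linker")
    occ <- vapply(concGrid, function(cc) {
      o <- equilibriumOccupancy(linker, energetics, cc, method = "transfer")
      1 - o@multiOccupancyFractions[["0"]]
    }, numeric(1))
    p <- pMin + pExp * amplitude * concGrid / (concGrid + kdNaked) +
      (1 - pExp) * residualAmplitude * amplitude * occ
  } else {
    kdApp <- kdNaked / pExp
    p <- pMin + amplitude * concGrid / (concGrid + kdApp)
  }
  iso <- data.frame(conc_nM = concGrid, proximity_ratio = p)
  if (diff(range(p)) < 1e-8) {   # fully blocked: nothing titrates
    fit <- list(pMin = p[1L], pMax = p[1L], kd = NA_real_)
  } else {
    fit <- fitSingleSite(iso)
  }
  out <- list(exposureProbability = pExp,
              apparentKd = fit$kd,
              maxAmplitudeFraction = min(max((fit$pMax - fit$pMin) /
                                               amplitude, 0), 1),
              mode = mode, nakedKd = kdNaked, isotherm = iso, fit = fit)
  class(out) <- "CompetitionResult"
  out
}

#' @export
print.CompetitionResult <- function(x, ...) {
  cat(sprintf("Nucleosome competition (%s exchange)\n", x$mode))
  cat(sprintf("  exposure p = %.3g | apparent Kd = %.4g nM (naked %.4g)\n",
              x$exposureProbability, x$apparentKd, x$nakedKd))
  cat(sprintf("  amplitude fraction vs naked = %.3g\n",
              x$maxAmplitudeFraction))
  invisible(x)
}

#' Relative saturation amplitude vs a reference isotherm
#'
#' Ratio of fitted `Pmax - Pmin` between a competition result and a
#' reference result (conventionally naked DNA at 150 mM KCl).
#'
#' @param result,reference `"CompetitionResult"` objects (or any list
#'   carrying a `fit` element from [fitSingleSite()]).
#' @return Dimensionless amplitude ratio.
#' @export
relativeAmplitude <- function(result, reference) {
  ampR <- reference$fit$pMax - reference$fit$pMin
  if (abs(ampR) < 1e-12) stop("reference amplitude is zero")
  (result$fit$pMax - result$fit$pMin) / ampR
}
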