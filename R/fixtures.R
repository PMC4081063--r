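# Synthetic-data fixtures: every input the analysis pipeline consumes can be
# regenerated bit-exactly from (fixture name, seed). The parameter catalog
# lives in inst/extdata/fixture_catalog.yaml with per-value provenance notes.

#' Load the fixture catalog
#'
#' @return Named list of fixture definitions (parsed from the package's
#'   versioned YAML catalog).
#' @examples
#' names(fixtureCatalog())
#' @export
fixtureCatalog <- function() {
  path <- system.file("extdata", "fixture_catalog.yaml", package = "TBPbind",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' List available fixtures
#'
#' @return `data.frame` with columns `name` and `kind`.
#' @export
listFixtures <- function() {
  cat <- fixtureCatalog()
  data.frame(name = names(cat$fixtures),
             kind = vapply(cat$fixtures, `[[`, character(1), "kind"))
}

getFixture <- function(name, kind = NULL) {
  cat <- fixtureCatalog()
  fx <- cat$fixtures[[name]]
  if (is.null(fx))
    stop("unknown fixture '", name, "'; see listFixtures()")
  if (!is.null(kind) && fx$kind != kind)
    stop("fixture '", name, "' has kind '", fx$kind, "', not '", kind, "'")
  fx
}

defaultTitrationGrid <- function() {
  cat <- fixtureCatalog()$titration_grid
  10^seq(log10(cat$min_nM), log10(cat$max_nM), length.out = cat$points)
}

fixtureLattice <- function(fx) {
  latticeSpec(fx$lattice$length_bp,
              specificRegister = fx$lattice$specific_register,
              footprintBp = fx$lattice$footprint_bp,
              dyeDonor = dyeSite(fx$lattice$donor_bp),
              dyeAcceptor = dyeSite(fx$lattice$acceptor_bp))
}

fixtureEnergetics <- function(fx) {
  bindingEnergetics(kdSpecific = fx$energetics$kd_specific_nM,
                    kdNonspecific = fx$energetics$kd_nonspecific_nM,
                    cooperativityOmega = fx$energetics$omega,
                    saltMM = fx$energetics$salt_mM)
}

fixtureBend <- function(fx) {
  bendModel(bendAngleSpecific = fx$bend$angle_specific_deg,
            bendAngleNonspecific = fx$bend$angle_nonspecific_deg)
}

#' Generate a synthetic titration series
#'
#' Evaluates the fixture's binding model (hyperbolic single-site curve or
#' the full lattice model) on the default log-spaced concentration grid and
#' adds i.i.d. Gaussian noise of the fixture's `sigma_p`.
#'
#' @param fixtureName fixture of kind `"titration"` (see [listFixtures()]).
#' @param seed integer seed (default: the fixture's default seed).
#' @param sigmaP noise level override (`NULL` = fixture value; 0 gives the
#'   exact model curve).
#' @return `data.frame` with columns `conc_nM`, `proximity_ratio`, `sigma`.
#' @examples
#' head(generateTitration("fig1_tata14E_50mM", seed = 1))
#' @export
generateTitration <- function(fixtureName, seed = NULL, sigmaP = NULL) {
  fx <- getFixture(fixtureName, "titration")
  seed <- as.integer(seed %||% fx$default_seed)
  sigmaP <- sigmaP %||% fx$sigma_p
  conc <- defaultTitrationGrid()
  if (fx$model == "eq1") {
    mu <- fx$p_min + (fx$p_max - fx$p_min) * conc / (conc + fx$kd_nM)
  } else {
    iso <- predictedIsotherm(fixtureLattice(fx), fixtureEnergetics(fx),
                             concGrid = conc, bend = fixtureBend(fx))
    mu <- iso$proximity_ratio
  }
  set.seed(seed)
  data.frame(conc_nM = conc,
             proximity_ratio = mu + stats::rnorm(length(mu), 0, sigmaP),
             sigma = rep(max(sigmaP, 1e-6), length(mu)))
}

#' Generate a synthetic competitor-chase trace
#'
#' Biexponential decay
#' `P(t) = offset + amplitude * (f exp(-k_fast t) + (1 - f) exp(-k_slow t))`
#' from the fixture's rates and fast fraction, sampled at the fixture rate
#' with additive Gaussian noise.
#'
#' @param fixtureName fixture of kind `"chase"` (e.g. `"fig4_1min"`,
#'   `"fig4_20min"`).
#' @param seed integer seed (default: fixture default).
#' @param sigmaP noise override (`NULL` = fixture value).
#' @return `data.frame` with columns `time_s`, `proximity_ratio`.
#' @examples
#' head(generateChase("fig4_1min", seed = 1))
#' @export
generateChase <- function(fixtureName, seed = NULL, sigmaP = NULL) {
  fx <- getFixture(fixtureName, "chase")
  seed <- as.integer(seed %||% fx$default_seed)
  sigmaP <- sigmaP %||% fx$sigma_p
  t <- seq(0, fx$duration_s, by = 1 / fx$rate_hz)
  f <- fx$fast_fraction
  mu <- fx$offset + fx$amplitude *
    (f * exp(-fx$k_fast_per_s * t) + (1 - f) * exp(-fx$k_slow_per_s * t))
  set.seed(seed)
  data.frame(time_s = t,
             proximity_ratio = mu + stats::rnorm(length(t), 0, sigmaP))
}

#' Generate a synthetic photon-burst stream
#'
#' Builds the species mixture implied by the fixture's lattice model at the
#' fixture concentration ([latticeMixture()]) and delegates to
#' [simulateBursts()].
#'
#' @param fixtureName fixture of kind `"bursts"`.
#' @param seed integer seed (default: fixture default).
#' @return A `"BurstSet"` (see [simulateBursts()]).
#' @examples
#' b <- generateBurstStream("fig2_tata14E_0nM", seed = 1)
#' nrow(b)
#' @export
generateBurstStream <- function(fixtureName, seed = NULL) {
  fx <- getFixture(fixtureName, "bursts")
  seed <- as.integer(seed %||% fx$default_seed)
  mix <- latticeMixture(fixtureLattice(fx), fixtureEnergetics(fx),
                        freeTbp = fx$conc_nM, bend = fixtureBend(fx),
                        donorOnlyFraction = fx$donor_only_fraction)
  simulateBursts(mix, nBursts = fx$n_bursts,
                 photonModel = list(meanSize = fx$mean_burst_size,
                                    sdLog = 0.5),
                 seed = seed)
}
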