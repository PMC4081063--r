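#' Simulate diffusing-molecule photon bursts
#'
#' For each burst a species is drawn from the mixture (including the
#' donor-only subpopulation), a total detected photon count is drawn from a
#' lognormal burst-size distribution, and acceptor counts are binomial with
#' the apparent acceptor probability implied by the forward signal model
#' (gamma, crosstalk, direct excitation); Poisson backgrounds are added to
#' both channels. Bit-reproducible for a given seed.
#'
#' @param mixture a [SpeciesMixture-class].
#' @param nBursts number of bursts (>= 1).
#' @param photonModel list with `meanSize` (mean total photons per burst,
#'   default 60) and `sdLog` (lognormal log-sd, default 0.5).
#' @param fret a [FretParameters-class].
#' @param seed integer RNG seed.
#' @return `data.frame` of class `"BurstSet"` with columns `burst_id`,
#'   `donor_counts`, `acceptor_counts`; the seed is kept in
#'   `attr(, "seed")`.
#' @examples
#' b <- simulateBursts(speciesMixture(0.5, 1), nBursts = 100, seed = 1)
#' head(b)
#' @export
simulateBursts <- function(mixture, nBursts,
                           photonModel = list(meanSize = 60, sdLog = 0.5),
                           fret = fretParameters(), seed = 1L) {
  stopifnot(nBursts >= 1)
  meanSize <- photonModel$meanSize %||% 60
  sdLog <- photonModel$sdLog %||% 0.5
  set.seed(as.integer(seed))
  specP <- c(mixture@p, 0)                       # last slot: donor-only, E = 0
  specW <- c(mixture@weight, mixture@donorOnlyFraction)
  idx <- sample.int(length(specP), nBursts, replace = TRUE, prob = specW)
  n <- pmax(1L, as.integer(round(stats::rlnorm(
    nBursts, meanlog = log(meanSize) - sdLog^2 / 2, sdlog = sdLog))))
  # apparent acceptor probability: species' underlying efficiency pushed
  # through the uncorrected forward signal model
  sig <- channelSignals(specP[idx], fret)
  q <- sig$acceptor / (sig$acceptor + sig$donor)
  acc <- stats::rbinom(nBursts, n, q)
  don <- n - acc
  if (fret@backgroundDonor > 0)
    don <- don + stats::rpois(nBursts, fret@backgroundDonor)
  if (fret@backgroundAcceptor > 0)
    acc <- acc + stats::rpois(nBursts, fret@backgroundAcceptor)
  out <- data.frame(burst_id = seq_len(nBursts), donor_counts = don,
                    acceptor_counts = acc)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("BurstSet", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select bursts above a total-photon threshold
#'
#' @param bursts a `"BurstSet"`.
#' @param threshold minimum donor + acceptor counts (>= 0).
#' @return The retained subset, same class and attributes.
#' @examples
#' b <- simulateBursts(speciesMixture(0.5, 1), 100, seed = 1)
#' nrow(selectBursts(b, 30))
#' @export
selectBursts <- function(bursts, threshold) {
  stopifnot(threshold >= 0)
  keep <- bursts$donor_counts + bursts$acceptor_counts >= threshold
  out <- bursts[keep, , drop = FALSE]
  attr(out, "seed") <- attr(bursts, "seed")
  class(out) <- c("BurstSet", "data.frame")
  out
}

#' Per-burst proximity ratios
#'
#' Gamma-uncorrected per-burst ratio `acceptor / (donor + acceptor)`.
#'
#' @param bursts a `"BurstSet"`.
#' @return Numeric vector.
#' @export
burstProximityRatios <- function(bursts) {
  tot <- bursts$donor_counts + bursts$acceptor_counts
  bursts$acceptor_counts / tot
}

#' Proximity-ratio histogram of a burst set
#'
#' @param bursts a non-empty `"BurstSet"`.
#' @param bins number of bins (default 40).
#' @param range histogram range (default `c(-0.1, 1.1)`).
#' @return `data.frame` of class `"ProximityHistogram"` with columns
#'   `bin_left`, `bin_right`, `rel_freq` (summing to 1).
#' @examples
#' b <- simulateBursts(speciesMixture(0.5, 1), 500, seed = 1)
#' h <- proximityHistogram(b)
#' sum(h$rel_freq)
#' @export
proximityHistogram <- function(bursts, bins = 40L, range = c(-0.1, 1.1)) {
  if (nrow(bursts) == 0L) stop("burst set is empty")
  p <- burstProximityRatios(bursts)
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  counts <- graphics::hist(p, breaks = breaks, plot = FALSE)$counts
  out <- data.frame(bin_left = breaks[-length(breaks)],
                    bin_right = breaks[-1L],
                    rel_freq = counts / sum(counts))
  class(out) <- c("ProximityHistogram", "data.frame")
  out
}

#' Single-Gaussian width fit of a proximity-ratio histogram
#'
#' Least-squares fit of a single Gaussian to the histogram, restricted to
#' bins whose centre lies above the donor-only exclusion bound (default
#' 0.05, just above the donor-only peak near 0).
#'
#' @param hist a `"ProximityHistogram"`.
#' @param excludeBelow donor-only exclusion bound on the proximity ratio.
#' @return Object of class `"GaussianFit"`: list with `mean`, `sigma`,
#'   `amplitude`, `exclusionBound`.
#' @examples
#' b <- simulateBursts(speciesMixture(0.5, 1), 2000, seed = 1)
#' fitWidth(proximityHistogram(b))$sigma
#' @export
fitWidth <- function(hist, excludeBelow = 0.05) {
  centre <- (hist$bin_left + hist$bin_right) / 2
  keep <- centre > excludeBelow
  x <- centre[keep]; y <- hist$rel_freq[keep]
  if (sum(y > 0) < 5L)
    stop("fewer than 5 occupied bins above the exclusion bound")
  mu0 <- sum(x * y) / sum(y)
  sd0 <- sqrt(max(sum(y * (x - mu0)^2) / sum(y), 1e-6))
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ amp * exp(-(x - mu)^2 / (2 * sigma^2)),
    start = list(amp = max(y), mu = mu0, sigma = sd0),
    lower = c(1e-12, -0.1, 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Gaussian width fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  out <- list(mean = unname(cf["mu"]), sigma = unname(cf["sigma"]),
              amplitude = unname(cf["amp"]), exclusionBound = excludeBelow)
  class(out) <- "GaussianFit"
  out
}

#' @export
print.GaussianFit <- function(x, ...) {
  cat(sprintf("Gaussian fit: mean = %.4g, sigma = %.4g (excluding P < %g)\n",
              x$mean, x$sigma, x$exclusionBound))
  invisible(x)
}

#' Summarise a burst-set titration series
#'
#' One row per concentration: the average proximity ratio over all selected
#' bursts (whole population, donor-only included) and the Gaussian
#' distribution width excluding the donor-only peak.
#'
#' @param burstSets list of `"BurstSet"` objects.
#' @param concentrations numeric labels (nM), same length (>= 2).
#' @param threshold burst-selection total-photon threshold (default 30).
#' @param bins histogram bins (default 40).
#' @param excludeBelow donor-only exclusion bound for the width fit.
#' @return `data.frame` with columns `conc_nM`, `mean_p`, `sigma`.
#' @examples
#' sets <- lapply(c(1, 2), function(s)
#'   simulateBursts(speciesMixture(0.5, 1), 1000, seed = s))
#' titrationSummary(sets, c(0, 10))
#' @export
titrationSummary <- function(burstSets, concentrations, threshold = 30,
                             bins = 40L, excludeBelow = 0.05) {
  stopifnot(length(burstSets) == length(concentrations),
            length(burstSets) >= 2L)
  rows <- lapply(seq_along(burstSets), function(i) {
    sel <- selectBursts(burstSets[[i]], threshold)
    h <- proximityHistogram(sel, bins = bins)
    data.frame(conc_nM = concentrations[i],
               mean_p = mean(burstProximityRatios(sel)),
               sigma = fitWidth(h, excludeBelow)$sigma)
  })
  do.call(rbind, rows)
}

#' Species mixture implied by the equilibrium lattice model
#'
#' Collapses the configuration distribution of [equilibriumOccupancy()]
#' (enumeration path) at one concentration into a [SpeciesMixture-class]:
#' one species per distinct configuration proximity ratio, plus an optional
#' donor-only subpopulation.
#'
#' @param lattice a [LatticeSpec-class].
#' @param energetics a [BindingEnergetics-class].
#' @param freeTbp free TBP (nM).
#' @param bend a [BendModel-class].
#' @param fret a [FretParameters-class].
#' @param donorOnlyFraction donor-only fraction of all molecules.
#' @return A [SpeciesMixture-class].
#' @examples
#' lat <- latticeSpec(14, specificRegister = 6)
#' latticeMixture(lat, bindingEnergetics(), freeTbp = 10)
#' @export
latticeMixture <- function(lattice, energetics, freeTbp,
                           bend = bendModel(), fret = fretParameters(),
                           donorOnlyFraction = 0.2) {
  configs <- enumerateConfigurations(lattice)
  w <- vapply(configs, configurationWeight, numeric(1), lattice = lattice,
              energetics = energetics, freeTbp = freeTbp)
  pv <- vapply(configs, function(cf)
    configProximityRatio(lattice, cf, bend, fret, corrected = FALSE),
    numeric(1))
  prob <- w / sum(w)
  key <- round(pv, 6)
  agg <- tapply(prob, key, sum)
  speciesMixture(p = as.numeric(names(agg)), weight = as.numeric(agg) *
                   (1 - donorOnlyFraction),
                 donorOnlyFraction = donorOnlyFraction)
}
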