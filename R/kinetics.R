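#' Generator matrix of the branched kinetic scheme
#'
#' States are `{unbound}` followed by one state per active register (in
#' ascending register order). Off-diagonal entries hold transition rates:
#' unbound -> register i at `kOn * [TBP]` (pseudo-first order, identical for
#' every register), register -> unbound at the register-class dissociation
#' rate, and adjacent-register sliding at `kSlide`, Metropolis-balanced
#' (`k(i -> j) = kSlide * min(1, kOff_i / kOff_j)`) so that sliding leaves
#' the equilibrium occupancies unchanged. Columns sum to zero; the
#' probability vector evolves as `dp/dt = Q p`.
#'
#' @param scheme a [KineticScheme-class].
#' @param association logical; `FALSE` zeroes the association rates
#'   (post-chase regime, rebinding removed by the competitor sink).
#' @return Square numeric matrix with dimnames `"unbound"`, `"r<index>"`.
#' @examples
#' q <- buildRateMatrix(kineticScheme())
#' colSums(q)   # all ~0
#' @export
buildRateMatrix <- function(scheme, association = TRUE) {
  regs <- activeRegisters(scheme@lattice)
  R <- length(regs)
  kOff <- rep(scheme@kOffNonspecific, R)
  if (!is.na(scheme@lattice@specificRegister)) {
    isSpec <- regs == scheme@lattice@specificRegister
    kOff[isSpec] <- scheme@kOffSpecific
  }
  kOnEff <- if (association) scheme@kOnPerRegister * scheme@tbpNM * 1e-9
    else 0
  Q <- matrix(0, R + 1L, R + 1L,
              dimnames = rep(list(c("unbound", paste0("r", regs))), 2L))
  for (i in seq_len(R)) {
    Q[i + 1L, 1L] <- kOnEff           # unbound -> register i
    Q[1L, i + 1L] <- kOff[i]          # register i -> unbound
  }
  if (scheme@kSlide > 0 && R > 1L) for (i in seq_len(R - 1L)) {
    if (regs[i + 1L] - regs[i] != 1L) next   # only adjacent registers hop
    Q[i + 2L, i + 1L] <- Q[i + 2L, i + 1L] +
      scheme@kSlide * min(1, kOff[i] / kOff[i + 1L])
    Q[i + 1L, i + 2L] <- Q[i + 1L, i + 2L] +
      scheme@kSlide * min(1, kOff[i + 1L] / kOff[i])
  }
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  Q
}

# Propagate p0 under generator Q to the (sorted, uniform or arbitrary)
# times; returns a matrix with one column per time point.
propagateMasterEquation <- function(Q, p0, times) {
  out <- matrix(NA_real_, length(p0), length(times))
  prev <- 0
  p <- p0
  cache <- list()
  for (j in seq_along(times)) {
    dt <- times[j] - prev
    if (dt > 0) {
      key <- format(dt, digits = 15)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.matrix(Matrix::expm(Q * dt))
      p <- as.numeric(cache[[key]] %*% p)
    }
    out[, j] <- p
    prev <- times[j]
  }
  out
}

#' Simulate a competitor-chase dissociation experiment
#'
#' The system starts all-unbound and is propagated with association active
#' for the incubation period; at the chase, association to the labelled DNA
#' is set to zero (the unlabelled competitor acts as an irreversible sink
#' for free TBP) and the mean proximity ratio is recorded over the
#' observation window in equal time bins.
#'
#' @param scheme a [KineticScheme-class].
#' @param fret a [FretParameters-class].
#' @param bend a [BendModel-class].
#' @param binS time bin width in seconds (default 1).
#' @param corrected logical, corrected proximity ratios.
#' @return `data.frame` with columns `time_s` (time since the chase) and
#'   `proximity_ratio`.
#' @examples
#' tr <- simulateChase(kineticScheme(incubationS = 60, observationS = 300))
#' head(tr)
#' @export
simulateChase <- function(scheme, fret = fretParameters(),
                          bend = bendModel(), binS = 1, corrected = TRUE) {
  regs <- activeRegisters(scheme@lattice)
  pState <- c(configProximityRatio(scheme@lattice, integer(0), bend, fret,
                                   corrected),
              vapply(regs, function(r)
                configProximityRatio(scheme@lattice, r, bend, fret,
                                     corrected), numeric(1)))
  p0 <- c(1, numeric(length(regs)))
  if (scheme@incubationS > 0) {
    Qon <- buildRateMatrix(scheme, association = TRUE)
    p0 <- propagateMasterEquation(Qon, p0, scheme@incubationS)[, 1L]
  }
  Qoff <- buildRateMatrix(scheme, association = FALSE)
  times <- seq(0, scheme@observationS, by = binS)
  traj <- propagateMasterEquation(Qoff, p0, times)
  data.frame(time_s = times,
             proximity_ratio = as.numeric(crossprod(traj, pState)))
}

#' Fit one- or two-phase exponential decay to a chase trace
#'
#' Nonlinear least squares of `P(t) = offset + sum_k a_k exp(-k_k t)` using
#' a deterministic initialisation: the offset guess is the final observed
#' value, the total amplitude guess the first-minus-last difference split
#' evenly between phases, and the rate guesses are log-spaced across the
#' observation window (`10^seq(log10(1/T), log10(50/T))`).
#'
#' @param trace `data.frame` with columns `time_s` and `proximity_ratio`
#'   (at least 8 points).
#' @param phases 1 or 2.
#' @return Object of class `"DecayFit"`: a list with `kFast`, `kSlow`,
#'   `aFast`, `aSlow` (for `phases = 1` the slow phase is zero), `offset`,
#'   `se` (named standard errors), `rss`, `aic`, `nPhases`, `fitted`,
#'   `residuals`.
#' @examples
#' tr <- simulateChase(kineticScheme(incubationS = 60, observationS = 600))
#' fit <- fitExponential(tr, phases = 2)
#' fit$kFast
#' @export
fitExponential <- function(trace, phases = 2) {
  stopifnot(all(c("time_s", "proximity_ratio") %in% names(trace)))
  if (nrow(trace) < 8L) stop("at least 8 time points are required")
  phases <- as.integer(phases)
  stopifnot(phases %in% c(1L, 2L))
  t <- trace$time_s
  y <- trace$proximity_ratio
  Tspan <- max(t) - min(t)
  offset0 <- y[length(y)]
  amp0 <- max(y[1L] - offset0, 1e-3)
  kGrid <- 10^seq(log10(1 / Tspan), log10(50 / Tspan), length.out = phases)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  if (phases == 1L) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ offset + a1 * exp(-k1 * t),
      start = list(offset = offset0, a1 = amp0, k1 = kGrid[1L]),
      lower = c(-Inf, 0, 0), control = ctl),
      error = function(e) stop("single-exponential fit failed: ",
                               conditionMessage(e)))
    cf <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    res <- list(kFast = unname(cf["k1"]), kSlow = 0,
                aFast = unname(cf["a1"]), aSlow = 0,
                offset = unname(cf["offset"]),
                se = c(kFast = unname(se["k1"]), aFast = unname(se["a1"]),
                       offset = unname(se["offset"])))
  } else {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ offset + a1 * exp(-k1 * t) + a2 * exp(-k2 * t),
      start = list(offset = offset0, a1 = amp0 / 2, k1 = kGrid[2L],
                   a2 = amp0 / 2, k2 = kGrid[1L]),
      lower = c(-Inf, 0, 0, 0, 0), control = ctl),
      error = function(e) stop("two-phase exponential fit failed: ",
                               conditionMessage(e)))
    cf <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    fastIsOne <- cf["k1"] >= cf["k2"]
    pick <- function(nm1, nm2) if (fastIsOne) c(nm1, nm2) else c(nm2, nm1)
    kn <- pick("k1", "k2"); an <- pick("a1", "a2")
    res <- list(kFast = unname(cf[kn[1L]]), kSlow = unname(cf[kn[2L]]),
                aFast = unname(cf[an[1L]]), aSlow = unname(cf[an[2L]]),
                offset = unname(cf["offset"]),
                se = c(kFast = unname(se[kn[1L]]), kSlow = unname(se[kn[2L]]),
                       aFast = unname(se[an[1L]]), aSlow = unname(se[an[2L]]),
                       offset = unname(se["offset"])))
  }
  res$nPhases <- phases
  res$fitted <- stats::fitted(fit)
  res$residuals <- stats::residuals(fit)
  res$rss <- sum(res$residuals^2)
  res$aic <- stats::AIC(fit)
  class(res) <- "DecayFit"
  res
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf("DecayFit (%d phase%s)\n", x$nPhases,
              if (x$nPhases > 1) "s" else ""))
  cat(sprintf("  k_fast = %.4g /s  k_slow = %.4g /s\n", x$kFast, x$kSlow))
  cat(sprintf("  a_fast = %.4g  a_slow = %.4g  offset = %.4g\n",
              x$aFast, x$aSlow, x$offset))
  cat(sprintf("  RSS = %.4g  AIC = %.4g\n", x$rss, x$aic))
  invisible(x)
}

#' Fast-phase mole fraction of a two-phase fit
#'
#' @param fit a `"DecayFit"` from [fitExponential()] with `phases = 2`.
#' @return `aFast / (aFast + aSlow)` in \[0, 1\].
#' @examples
#' \dontrun{fastFraction(fitExponential(trace, phases = 2))}
#' @export
fastFraction <- function(fit) {
  stopifnot(inherits(fit, "DecayFit"))
  if (fit$nPhases < 2L) stop("fast fraction requires a two-phase fit")
  tot <- fit$aFast + fit$aSlow
  if (tot <= 0) stop("total amplitude is zero; fast fraction undefined")
  fit$aFast / tot
}
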