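#' Fit a single-site binding isotherm
#'
#' Weighted nonlinear least squares of the hyperbolic single-site model
#' `P = Pmin + (Pmax - Pmin) * [T] / ([T] + Kd)`, where `[T]` is the total
#' TBP concentration. Initialisation is deterministic: `Pmin` from the first
#' point, `Pmax` from the last, and `Kd` from the concentration nearest the
#' half-amplitude response.
#'
#' @param series `data.frame` with columns `conc_nM`, `proximity_ratio` and
#'   optionally `sigma` (per-point standard deviation used as weights);
#'   at least 6 rows.
#' @return Object of class `"IsothermFit"`: list with `pMin`, `pMax`,
#'   `kd` (nM), `se` (named standard errors), `rss`, `aic`, `fitted`,
#'   `residuals`, `data`.
#' @examples
#' conc <- 10^seq(-1, 2.5, length.out = 12)
#' p <- 0.3 + 0.3 * conc / (conc + 5)
#' fitSingleSite(data.frame(conc_nM = conc, proximity_ratio = p))$kd
#' @export
fitSingleSite <- function(series) {
  stopifnot(all(c("conc_nM", "proximity_ratio") %in% names(series)))
  if (nrow(series) < 6L) stop("at least 6 titration points are required")
  if (any(series$conc_nM < 0)) stop("concentrations must be >= 0")
  conc <- series$conc_nM
  p <- series$proximity_ratio
  w <- if ("sigma" %in% names(series)) 1 / series$sigma^2 else
    rep(1, length(p))
  p0 <- p[1L]; p1 <- p[length(p)]
  half <- p0 + 0.5 * (p1 - p0)
  kd0 <- max(conc[which.min(abs(p - half))], min(conc[conc > 0]))
  doFit <- function(start) minpack.lm::nlsLM(
    p ~ pMin + (pMax - pMin) * conc / (conc + kd),
    start = start, lower = c(-Inf, -Inf, 1e-9), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  fit <- tryCatch(doFit(list(pMin = p0, pMax = p1, kd = kd0)),
                  error = function(e) e)
  if (inherits(fit, "error"))   # degenerate start (e.g. flat endpoints):
    fit <- tryCatch(doFit(list(pMin = min(p), pMax = max(p),
                               kd = stats::median(pos <- conc[conc > 0]))),
                    error = function(e) stop("single-site fit failed: ",
                                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  out <- list(pMin = unname(cf["pMin"]), pMax = unname(cf["pMax"]),
              kd = unname(cf["kd"]),
              se = c(pMin = unname(se["pMin"]), pMax = unname(se["pMax"]),
                     kd = unname(se["kd"])),
              fitted = stats::fitted(fit),
              residuals = stats::residuals(fit),
              rss = sum(stats::residuals(fit)^2),
              aic = stats::AIC(fit), data = series)
  class(out) <- "IsothermFit"
  out
}

#' @export
print.IsothermFit <- function(x, ...) {
  cat("Single-site isotherm fit\n")
  cat(sprintf("  Kd = %.4g nM (SE %.3g)\n", x$kd, x$se["kd"]))
  cat(sprintf("  Pmin = %.4g  Pmax = %.4g  RSS = %.4g\n",
              x$pMin, x$pMax, x$rss))
  invisible(x)
}

#' Detect biphasic (rise-then-decline) titration behaviour
#'
#' Fits both the single-site model and a composite rise-plus-decline model
#' `P = Pmin + A * c/(c + Kd1) - D * c^h / (c^h + M^h)` and declares the
#' series biphasic when the composite is decisively better (delta AIC > 10)
#' and the fitted decline amplitude exceeds three times the residual noise
#' of the composite fit. The decline amplitude is bounded by the observed
#' data range. This classifier describes the deviation from single-site
#' behaviour seen with cooperative non-specific binding at low salt.
#'
#' @param series `data.frame` as for [fitSingleSite()], at least 8 rows
#'   spanning at least two decades of positive concentration.
#' @return Object of class `"BiphasicAssessment"`: list with `isBiphasic`,
#'   `riseFit` (`kd1`, `amplitude`), `decline` (`midpoint_nM`, `amplitude`,
#'   `steepness`), `deltaAIC`, `singleSite` (the [fitSingleSite()] result).
#' @examples
#' conc <- 10^seq(-1, 2.5, length.out = 12)
#' p <- 0.3 + 0.3 * conc / (conc + 5)
#' detectBiphasic(data.frame(conc_nM = conc, proximity_ratio = p))$isBiphasic
#' @export
detectBiphasic <- function(series) {
  stopifnot(all(c("conc_nM", "proximity_ratio") %in% names(series)))
  if (nrow(series) < 8L) stop("at least 8 titration points are required")
  pos <- series$conc_nM[series$conc_nM > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 100)
    stop("titration must span at least two decades of concentration")
  single <- fitSingleSite(series)
  conc <- series$conc_nM
  p <- series$proximity_ratio
  rng <- diff(range(p))
  amp0 <- max(single$pMax - single$pMin, 1e-3)
  fit2 <- tryCatch(minpack.lm::nlsLM(
    p ~ pMin + A * conc / (conc + kd1) - D * conc^h / (conc^h + M^h),
    start = list(pMin = p[1L], A = amp0, kd1 = max(single$kd, 1e-3),
                 D = rng / 4, M = stats::median(pos), h = 2),
    lower = c(-Inf, 0, 1e-9, 0, 1e-9, 1),
    upper = c(Inf, Inf, Inf, rng, Inf, 8),
    control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit2)) {
    out <- list(isBiphasic = FALSE, riseFit = list(kd1 = single$kd,
                amplitude = single$pMax - single$pMin),
                decline = list(midpoint_nM = NA_real_, amplitude = 0,
                               steepness = NA_real_),
                deltaAIC = -Inf, singleSite = single)
    class(out) <- "BiphasicAssessment"
    return(out)
  }
  cf <- stats::coef(fit2)
  resid2 <- stats::residuals(fit2)
  noise <- stats::sd(resid2)
  dAIC <- single$aic - stats::AIC(fit2)
  out <- list(
    isBiphasic = isTRUE(dAIC > 10 && cf["D"] > 3 * noise),
    riseFit = list(kd1 = unname(cf["kd1"]), amplitude = unname(cf["A"])),
    decline = list(midpoint_nM = unname(cf["M"]),
                   amplitude = unname(cf["D"]),
                   steepness = unname(cf["h"])),
    deltaAIC = dAIC, singleSite = single)
  class(out) <- "BiphasicAssessment"
  out
}

#' @export
print.BiphasicAssessment <- function(x, ...) {
  cat("Biphasic assessment:",
      if (x$isBiphasic) "BIPHASIC" else "single-phase", "\n")
  cat(sprintf("  delta AIC (composite vs single-site) = %.3g\n", x$deltaAIC))
  cat(sprintf("  rise: Kd1 = %.4g nM, amplitude = %.4g\n",
              x$riseFit$kd1, x$riseFit$amplitude))
  cat(sprintf("  decline: midpoint = %.4g nM, amplitude = %.4g\n",
              x$decline$midpoint_nM, x$decline$amplitude))
  invisible(x)
}
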