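oneRegisterScheme <- function(...) {
  lat <- latticeSpec(14, specificRegister = 6,
                     inactiveRegisters = setdiff(0:13, 6))
  kineticScheme(lattice = lat, ...)
}

test_that("the generator conserves probability and has the two-state relaxation rate", {
  sc <- oneRegisterScheme(tbpNM = 30)
  q <- buildRateMatrix(sc)
  expect_equal(dim(q), c(2L, 2L))
  expect_equal(colSums(q), c(unbound = 0, r6 = 0), tolerance = 1e-15)
  # relaxation rate of the 2x2 generator is kon*c + koff
  konC <- 2e6 * 30e-9
  expect_equal(sort(eigen(q)$values), sort(c(0, -(konC + sc@kOffSpecific))),
               tolerance = 1e-12)
  # full scheme, with sliding
  sc14 <- kineticScheme(kSlide = 0.05)
  q14 <- buildRateMatrix(sc14)
  expect_equal(max(abs(colSums(q14))), 0, tolerance = 1e-12)
})

test_that("master-equation propagation matches a Gillespie simulation", {
  lat3 <- latticeSpec(3, specificRegister = 1, footprintBp = 1,
                      contactSpanBp = 1)
  sc <- kineticScheme(lattice = lat3, tbpNM = 30, kSlide = 0.02,
                      incubationS = 40, observationS = 100)
  q <- buildRateMatrix(sc)
  p0 <- c(1, 0, 0, 0)
  pT <- as.numeric(as.matrix(Matrix::expm(q * 40)) %*% p0)
  nTraj <- 4000
  counts <- gillespieCounts(q, start = 1L, tEnd = 40, nTraj = nTraj,
                            seed = 99)
  for (s in 1:4) {
    se <- sqrt(pT[s] * (1 - pT[s]) / nTraj)
    expect_lt(abs(counts[s] / nTraj - pT[s]), 3 * se + 1e-9)
  }
  # probability conserved along the trace
  tr <- simulateChase(sc)
  expect_true(all(is.finite(tr$proximity_ratio)))
})

test_that("a long-incubation chase decays with the pure dissociation eigenrates", {
  sc <- kineticScheme(incubationS = 36000, observationS = 1500)
  tr <- simulateChase(sc)
  fit <- fitExponential(tr, phases = 2)
  # with kSlide = 0 the post-chase eigenvalues are exactly the two koff
  expect_equal(fit$kFast, sc@kOffNonspecific, tolerance = 1e-4)
  expect_equal(fit$kSlow, sc@kOffSpecific, tolerance = 1e-4)
  # amplitude oracle: with k_slide = 0 each register decays independently,
  # so P(t) - P0 = sum_i p_i(eq) (P_i - P0) exp(-koff_i t); the fast/slow
  # amplitudes weight the equilibrium populations by each state's
  # proximity-ratio contrast
  kd_s <- sc@kOffSpecific / (sc@kOnPerRegister * 1e-9)   # nM
  kd_n <- sc@kOffNonspecific / (sc@kOnPerRegister * 1e-9)
  regs <- activeRegisters(sc@lattice)
  w <- ifelse(regs == sc@lattice@specificRegister,
              sc@tbpNM / kd_s, sc@tbpNM / kd_n)
  pEq <- w / (1 + sum(w))
  p0 <- configProximityRatio(sc@lattice, integer(0))
  dP <- vapply(regs, function(r)
    configProximityRatio(sc@lattice, r) - p0, numeric(1))
  isSpec <- regs == sc@lattice@specificRegister
  aFastExp <- sum((pEq * dP)[!isSpec])
  aSlowExp <- sum((pEq * dP)[isSpec])
  expect_equal(fastFraction(fit), aFastExp / (aFastExp + aSlowExp),
               tolerance = 0.01)
})

test_that("equal dissociation rates give a monoexponential chase", {
  sc <- kineticScheme(kOffSpecific = 0.01, kOffNonspecific = 0.01,
                      incubationS = 120, observationS = 600)
  tr <- simulateChase(sc)
  fit1 <- fitExponential(tr, phases = 1)
  expect_equal(fit1$kFast, 0.01, tolerance = 1e-5)
  fit2 <- fitExponential(tr, phases = 2)
  expect_equal(fit2$kFast, fit2$kSlow, tolerance = 0.05)
})

test_that("noiseless exponential fits recover parameters and flag lack of fit", {
  t <- seq(0, 1800, by = 1)
  y1 <- 0.3 + 0.25 * exp(-0.01 * t)
  f1 <- fitExponential(data.frame(time_s = t, proximity_ratio = y1), 1)
  expect_lt(abs(f1$kFast - 0.01) / 0.01, 1e-6)
  y2 <- 0.3 + 0.25 * (0.38 * exp(-0.02 * t) + 0.62 * exp(-0.0014 * t))
  f2 <- fitExponential(data.frame(time_s = t, proximity_ratio = y2), 2)
  expect_lt(abs(f2$kFast - 0.02) / 0.02, 1e-4)
  expect_lt(abs(f2$kSlow - 0.0014) / 0.0014, 1e-4)
  expect_equal(fastFraction(f2), 0.38, tolerance = 1e-4)
  # one-phase fit of biexponential data leaves structured residuals
  f1on2 <- fitExponential(data.frame(time_s = t, proximity_ratio = y2), 1)
  expect_gt(f1on2$rss, 5 * f2$rss)
  expect_error(fitExponential(data.frame(time_s = 0:5,
                                         proximity_ratio = rep(1, 6)), 2),
               "8 time points")
})

test_that("fast fraction handles the degenerate amplitude cases", {
  mk <- function(aF, aS) structure(list(kFast = 0.02, kSlow = 0.001,
                                        aFast = aF, aSlow = aS,
                                        nPhases = 2L), class = "DecayFit")
  expect_equal(fastFraction(mk(0.5, 0.5)), 0.5)
  expect_equal(fastFraction(mk(0.38, 0.62)), 0.38)
  expect_equal(fastFraction(mk(0, 1)), 0)
  expect_error(fastFraction(mk(0, 0)), "undefined")
})

test_that("fast fraction falls with incubation time while rates stay put", {
  fits <- lapply(c(60, 1200), function(inc)
    fitExponential(simulateChase(kineticScheme(incubationS = inc)),
                   phases = 2))
  expect_gt(fastFraction(fits[[1]]), fastFraction(fits[[2]]))
  expect_lt(abs(fits[[1]]$kFast - fits[[2]]$kFast) / fits[[2]]$kFast, 0.05)
  expect_lt(abs(fits[[1]]$kSlow - fits[[2]]$kSlow) / fits[[2]]$kSlow, 0.05)
})

test_that("sliding preserves equilibrium but accelerates specific-site relaxation", {
  schemes <- lapply(c(0, 0.05), function(ks)
    kineticScheme(kSlide = ks, incubationS = 0, observationS = 100))
  eq <- lapply(schemes, function(sc) {
    q <- buildRateMatrix(sc, association = TRUE)
    v <- eigen(q)$vectors[, which.min(abs(eigen(q)$values))]
    Re(v) / sum(Re(v))
  })
  expect_equal(eq[[1]], eq[[2]], tolerance = 1e-8)
  # time to reach half the equilibrium specific occupancy shrinks with k_slide
  halfTime <- function(sc) {
    q <- buildRateMatrix(sc, association = TRUE)
    regs <- activeRegisters(sc@lattice)
    iSpec <- which(regs == sc@lattice@specificRegister) + 1L
    target <- eq[[1]][iSpec] / 2
    ts <- seq(5, 4000, by = 5)
    p <- c(1, numeric(length(regs)))
    eA <- as.matrix(Matrix::expm(q * 5))
    for (t in ts) {
      p <- as.numeric(eA %*% p)
      if (p[iSpec] >= target) return(t)
    }
    Inf
  }
  expect_lt(halfTime(schemes[[2]]), halfTime(schemes[[1]]))
})
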