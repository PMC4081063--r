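test_that("burst simulation is seed-reproducible and concentrates at large N", {
  mix <- speciesMixture(0.5, 1)
  b1 <- simulateBursts(mix, 500, seed = 3)
  b2 <- simulateBursts(mix, 500, seed = 3)
  expect_identical(b1, b2)
  expect_false(identical(b1, simulateBursts(mix, 500, seed = 4)))
  # law of large numbers: huge bursts pin the per-burst ratio at P
  big <- simulateBursts(mix, 300,
                        photonModel = list(meanSize = 5e4, sdLog = 0.1),
                        seed = 5)
  expect_lt(stats::sd(burstProximityRatios(big)), 0.005)
  expect_equal(mean(burstProximityRatios(big)), 0.5, tolerance = 0.005)
})

test_that("single-species histogram width matches the binomial shot-noise oracle", {
  mix <- speciesMixture(0.5, 1)
  b <- simulateBursts(mix, 1e4, seed = 7)
  f <- fitWidth(proximityHistogram(b))
  nBar <- mean(b$donor_counts + b$acceptor_counts)
  expect_equal(f$sigma, sqrt(0.5 * 0.5 / nBar), tolerance = 0.1)
  expect_equal(f$mean, 0.5, tolerance = 0.01)
})

test_that("the donor-only subpopulation lands below the exclusion bound", {
  b <- simulateBursts(speciesMixture(0.5, 0.7, donorOnlyFraction = 0.3),
                      1e4, seed = 8)
  expect_equal(mean(burstProximityRatios(b) < 0.05), 0.3, tolerance = 0.03)
})

test_that("burst selection thresholds behave like a brute-force filter", {
  b <- simulateBursts(speciesMixture(0.5, 1), 2000, seed = 9)
  expect_identical(nrow(selectBursts(b, 0)), nrow(b))
  expect_identical(nrow(selectBursts(b, 1e6)), 0L)
  kept <- selectBursts(b, 30)
  expect_identical(nrow(kept),
                   sum(b$donor_counts + b$acceptor_counts >= 30))
  expect_true(all(kept$donor_counts + kept$acceptor_counts >= 30))
})

test_that("histograms are normalised and resolve mixture modes", {
  one <- simulateBursts(speciesMixture(0.5, 1), 1, seed = 2)
  h1 <- proximityHistogram(one)
  expect_equal(sum(h1$rel_freq), 1)
  expect_identical(sum(h1$rel_freq > 0), 1L)
  b <- simulateBursts(speciesMixture(c(0.15, 0.5), c(0.5, 0.5)), 8000,
                      photonModel = list(meanSize = 120, sdLog = 0.3),
                      seed = 10)
  h <- proximityHistogram(b)
  expect_equal(sum(h$rel_freq), 1)
  centre <- (h$bin_left + h$bin_right) / 2
  # local maxima in the bins containing the two species
  near <- function(p) which.min(abs(centre - p))
  ord <- order(h$rel_freq, decreasing = TRUE)
  top <- centre[ord[1:6]]
  expect_true(any(abs(top - 0.15) < 0.05))
  expect_true(any(abs(top - 0.5) < 0.05))
  expect_error(proximityHistogram(selectBursts(b, 1e6)), "empty")
})

test_that("Gaussian width fitting recovers parameters and ignores the donor-only peak", {
  centre <- seq(-0.0875, 1.0875, length.out = 40)
  width <- diff(centre[1:2])
  gauss <- exp(-(centre - 0.45)^2 / (2 * 0.07^2))
  h <- data.frame(bin_left = centre - width / 2,
                  bin_right = centre + width / 2,
                  rel_freq = gauss / sum(gauss))
  f <- fitWidth(h)
  expect_equal(f$mean, 0.45, tolerance = 1e-3)
  expect_equal(f$sigma, 0.07, tolerance = 1e-3)
  # adding a donor-only spike below the bound leaves the fit unchanged
  h2 <- h
  donorBin <- which.min(abs(centre - 0))
  h2$rel_freq[donorBin] <- h2$rel_freq[donorBin] + 0.5
  h2$rel_freq <- h2$rel_freq / sum(h2$rel_freq)
  f2 <- fitWidth(h2)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)
  expect_equal(f2$mean, f$mean, tolerance = 1e-6)
  # broadened two-species histogram is wider than either single species
  bNarrow <- simulateBursts(speciesMixture(0.45, 1), 6000, seed = 11)
  bBroad <- simulateBursts(speciesMixture(c(0.3, 0.6), c(0.5, 0.5)), 6000,
                           seed = 11)
  expect_gt(fitWidth(proximityHistogram(bBroad))$sigma,
            fitWidth(proximityHistogram(bNarrow))$sigma)
})

test_that("two-state titrations show the rise-then-fall width signature", {
  kd <- 5
  concs <- c(0, 1, 2.5, 5, 10, 30, 200)
  sets <- lapply(seq_along(concs), function(i) {
    f <- langmuir(concs[i], kd)
    simulateBursts(speciesMixture(c(0.3, 0.6), c(1 - f, f) * 0.8,
                                  donorOnlyFraction = 0.2),
                   4000, seed = 100 + i)
  })
  s <- titrationSummary(sets, concs)
  expect_true(all(diff(s$mean_p) > 0))        # binding isotherm in mean P
  iPeak <- which.max(s$sigma)
  expect_gt(iPeak, 1)
  expect_lt(iPeak, length(concs))
  expect_gt(max(s$sigma), 2 * s$sigma[1])
  # final width returns to within 20% of the unbound width
  expect_lt(abs(s$sigma[length(concs)] - s$sigma[1]) / s$sigma[1], 0.2)
  # determinism: duplicated concentration with the same seed gives the
  # same row
  dup <- titrationSummary(list(sets[[3]], sets[[3]]), c(2.5, 2.5))
  expect_identical(dup$mean_p[1], dup$mean_p[2])
  expect_identical(dup$sigma[1], dup$sigma[2])
})

test_that("increasingly heterogeneous mixtures broaden monotonically", {
  concs <- c(0.5, 2.5, 10, 30, 200)
  sets <- lapply(seq_along(concs), function(i) {
    f <- langmuir(concs[i], 5)
    spread <- 0.05 + 0.4 * langmuir(concs[i], 20)
    pv <- seq(0.45 - spread / 2, 0.45 + spread / 2, length.out = 7)
    wv <- rep(f / 7, 7)
    simulateBursts(speciesMixture(c(0.3, pv), c(1 - f, wv) * 0.8,
                                  donorOnlyFraction = 0.2),
                   4000, seed = 500 + i)
  })
  s <- titrationSummary(sets, concs)
  expect_true(all(diff(s$sigma) > 0))
})

test_that("the cooperative lattice mixture fails to coalesce at saturation", {
  lat <- tata18I()
  en <- bindingEnergetics(saltMM = 50)
  bendC <- bendModel(bendAngleNonspecific = 70)
  concs <- c(0, 2.5, 10, 200)
  sets <- lapply(seq_along(concs), function(i)
    simulateBursts(latticeMixture(lat, en, concs[i], bend = bendC,
                                  donorOnlyFraction = 0.2),
                   4000, seed = 200 + i))
  s <- titrationSummary(sets, concs)
  # width at saturation stays far above the unbound width, unlike the
  # two-state case
  expect_gt(s$sigma[4], 2 * s$sigma[1])
})
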