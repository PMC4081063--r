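test_that("register counting follows the one-register-per-bp convention", {
  expect_identical(countBindingRegisters(tata14E()), 14L)
  expect_identical(countBindingRegisters(latticeSpec(1, footprintBp = 1)), 1L)
  expect_identical(
    countBindingRegisters(latticeSpec(25, inactiveRegisters = 14:24)), 14L)
})

test_that("TATAWAWR motif location matches an exhaustive scan", {
  expect_identical(locateSpecificSite("GGTATAAAAGGG"), 5L)
  expect_true(is.na(locateSpecificSite("GGGGGGGG")))
  expect_identical(locateSpecificSite("TATATATA"), 3L)
  # exhaustive-scan oracle on random sequences
  iupacMatch <- function(s) {
    ok <- function(ch, cls) switch(cls, N = TRUE,
                                   W = ch %in% c("A", "T"),
                                   R = ch %in% c("A", "G"),
                                   ch == cls)
    pat <- c("T", "A", "T", "A", "W", "A", "W", "R")
    chars <- strsplit(s, "")[[1]]
    for (i in seq_len(nchar(s) - 7L)) {
      if (all(mapply(ok, chars[i:(i + 7L)], pat))) return(i + 2L)  # centre
    }
    NA_integer_
  }
  set.seed(11)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    expect_identical(locateSpecificSite(s), iupacMatch(s), info = s)
  }
  expect_error(locateSpecificSite("TAXA"), "invalid")
})

test_that("configuration enumeration matches the DP count and excludes overlap", {
  cfg <- enumerateConfigurations(latticeSpec(2, footprintBp = 2,
                                             contactSpanBp = 2))
  expect_length(cfg, 3L)
  expect_length(enumerateConfigurations(latticeSpec(14, footprintBp = 14)),
                15L)
  for (L in c(10, 17, 25)) for (n in c(3, 8)) {
    cfgs <- enumerateConfigurations(latticeSpec(L, footprintBp = n,
                                                contactSpanBp = n))
    expect_length(cfgs, dpConfigCount(L, n))
    seps <- unlist(lapply(cfgs, function(x) diff(sort(x))))
    if (length(seps)) expect_true(all(seps >= n))
    expect_identical(anyDuplicated(vapply(cfgs, paste, "", collapse = ",")),
                     0L)
  }
  expect_error(enumerateConfigurations(latticeSpec(40, footprintBp = 1,
                                                   contactSpanBp = 1)),
               "transfer-matrix")
})

test_that("configuration weights multiply statistical factors and cooperativity", {
  lat <- tata14I()
  en <- bindingEnergetics(kdSpecific = 5, kdNonspecific = 10,
                          cooperativityOmega = 3)
  expect_identical(configurationWeight(integer(0), lat, en, 100), 1)
  expect_equal(configurationWeight(6L, lat, en, 5), 1)
  # two non-specific proteins in contact: (c/Kd)^2 * omega = 2*2*3
  expect_equal(configurationWeight(c(14L, 22L), lat, en, 20), 12)
  expect_error(configurationWeight(c(6L, 8L), lat, en, 5), "separation")
  expect_error(configurationWeight(6L, lat, en, -1), ">= 0")
})

test_that("single active register reduces to the Langmuir isotherm", {
  lat <- latticeSpec(14, specificRegister = 6,
                     inactiveRegisters = setdiff(0:13, 6))
  en <- bindingEnergetics(kdSpecific = 5, cooperativityOmega = 1)
  for (conc in c(0, 1, 5, 50)) {
    occ <- equilibriumOccupancy(lat, en, conc)
    expect_equal(pSpecificBound(occ), langmuir(conc, 5), tolerance = 1e-12)
  }
})

test_that("transfer matrix and enumeration agree for all small lattices", {
  set.seed(42)
  for (rep in 1:12) {
    L <- sample(5:25, 1)
    n <- sample(2:min(8, L), 1)
    spec <- sample(0:(L - 1), 1)
    en <- bindingEnergetics(kdSpecific = runif(1, 1, 10),
                            kdNonspecific = runif(1, 10, 100),
                            cooperativityOmega = runif(1, 0, 6))
    lat <- latticeSpec(L, specificRegister = spec, footprintBp = n,
                       contactSpanBp = n)
    conc <- runif(1, 0, 200)
    oe <- equilibriumOccupancy(lat, en, conc, method = "enumeration")
    ot <- equilibriumOccupancy(lat, en, conc, method = "transfer")
    expect_equal(ot@partitionFunction, oe@partitionFunction,
                 tolerance = 1e-9)
    expect_equal(ot@registerOccupancy, oe@registerOccupancy,
                 tolerance = 1e-9)
    kmin <- min(length(ot@multiOccupancyFractions),
                length(oe@multiOccupancyFractions))
    expect_equal(ot@multiOccupancyFractions[seq_len(kmin)],
                 oe@multiOccupancyFractions[seq_len(kmin)],
                 tolerance = 1e-9)
  }
})

test_that("homogeneous lattice density matches the McGhee-von Hippel closed form", {
  lat <- latticeSpec(200)
  en <- bindingEnergetics(kdNonspecific = 10, cooperativityOmega = 1)
  for (x in c(0.1, 1, 10)) {
    occ <- equilibriumOccupancy(lat, en, 10 * x, method = "transfer")
    interior <- mean(occ@registerOccupancy[60:140])
    expect_equal(interior, mvhDensity(x, 8), tolerance = 0.01)
  }
})

test_that("partition function grows with concentration and occupancy vanishes at zero", {
  lat <- tata14I()
  en <- bindingEnergetics()
  zs <- vapply(c(0, 0.5, 2, 10, 50), function(cc)
    equilibriumOccupancy(lat, en, cc)@partitionFunction, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_equal(equilibriumOccupancy(lat, en, 0)@partitionFunction, 1)
  expect_equal(pSpecificBound(equilibriumOccupancy(lat, en, 1e-9)), 0,
               tolerance = 1e-8)
  fr <- equilibriumOccupancy(lat, en, 30)@multiOccupancyFractions
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("competing registers can only suppress occupancy when omega <= 1", {
  lat <- tata14I()
  en <- bindingEnergetics(cooperativityOmega = 0.7)
  occFull <- equilibriumOccupancy(lat, en, 30)@registerOccupancy
  for (r in c(0L, 6L, 14L, 24L)) {
    alone <- latticeSpec(25, specificRegister = lat@specificRegister,
                         inactiveRegisters = setdiff(0:24, r))
    occAlone <- equilibriumOccupancy(alone, en, 30)@registerOccupancy
    expect_lte(occFull[r + 1L], occAlone[r + 1L] + 1e-12)
  }
})

test_that("equimolar competitor lowers free TBP and binding", {
  lat <- tata14I()
  en <- bindingEnergetics(cooperativityOmega = 1)
  grid <- c(1, 10, 100)
  noComp <- predictedIsotherm(lat, en, grid, dnaNM = 1)
  withComp <- predictedIsotherm(lat, en, grid, dnaNM = 1,
                                competitor = list(lattice = latticeSpec(25),
                                                  concNM = "equimolar"))
  expect_true(all(withComp$free_nM < noComp$free_nM))
  # total binding on the labelled lattice drops at every titration point
  for (i in seq_along(grid)) {
    nN <- expectedBound(equilibriumOccupancy(lat, en, noComp$free_nM[i]))
    nC <- expectedBound(equilibriumOccupancy(lat, en, withComp$free_nM[i]))
    expect_lt(nC, nN)
  }
  # on a homogeneous lattice at moderate coverage every register occupancy
  # drops with the competitor (near close-packing, commensurability
  # oscillations make individual registers non-monotone in activity, so the
  # per-register claim is checked below saturation only)
  hom <- latticeSpec(25)
  for (i in 1:2) {
    oN <- equilibriumOccupancy(hom, en, noComp$free_nM[i])@registerOccupancy
    oC <- equilibriumOccupancy(hom, en,
                               withComp$free_nM[i])@registerOccupancy
    expect_true(all(oC < oN))
  }
})

test_that("predicted isotherms reproduce flat, Langmuir and biphasic regimes", {
  # zero concentration everywhere -> flat at the unbound proximity ratio
  lat <- tata14E()
  flat <- predictedIsotherm(lat, bindingEnergetics(), c(0, 0, 0))
  p0 <- configProximityRatio(lat, integer(0))
  expect_equal(flat$proximity_ratio, rep(p0, 3))
  # specific-only lattice follows Eq. 1 with Kd = kdSpecific
  only <- latticeSpec(14, specificRegister = 6,
                      inactiveRegisters = setdiff(0:13, 6),
                      dyeDonor = dyeSite(0), dyeAcceptor = dyeSite(13))
  grid <- c(0, 1, 2, 5, 10, 50, 200)
  iso <- predictedIsotherm(only, bindingEnergetics(cooperativityOmega = 1),
                           grid)
  pb <- configProximityRatio(only, 6L)
  expect_equal(iso$proximity_ratio,
               p0 + (pb - p0) * langmuir(grid, 5), tolerance = 1e-9)
  # cooperative low-salt flanked construct: rise then fall >= 10% below peak
  bendI <- bendModel(bendAngleNonspecific = 0)
  grid2 <- 10^seq(-1, 3, length.out = 16)
  lowSalt <- predictedIsotherm(tata14I(), bindingEnergetics(saltMM = 50),
                               grid2, bend = bendI)$proximity_ratio
  peak <- max(lowSalt)
  expect_gt(which.max(lowSalt), 3)           # rises first
  expect_lt(lowSalt[16], peak - 0.1 * (peak - lowSalt[1]))
  highSalt <- predictedIsotherm(tata14I(), bindingEnergetics(saltMM = 150),
                                grid2, bend = bendI)$proximity_ratio
  expect_true(all(diff(highSalt) > -1e-9))    # monotonic at 150 mM
})
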