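#' Equilibrium occupancy result for a lattice
#'
#' Partition function and occupancy probabilities of a
#' [LatticeSpec-class]/[BindingEnergetics-class] pair at one free TBP
#' concentration.
#'
#' @slot partitionFunction dimensionless partition function Z (>= 1; the
#'   empty lattice carries weight 1).
#' @slot registerOccupancy numeric vector, probability that each register
#'   (0-based position `i-1` at element `i`) is occupied.
#' @slot pSpecificBound probability that the specific register is occupied
#'   (`NA` if the lattice has no specific site).
#' @slot multiOccupancyFractions probability of 0, 1, 2, ... bound proteins
#'   (named "0", "1", ...; sums to 1).
#' @slot freeTbpNM the free TBP concentration used (nM).
#' @exportClass OccupancyResult
setClass("OccupancyResult",
  representation(partitionFunction = "numeric",
                 registerOccupancy = "numeric",
                 pSpecificBound = "numeric",
                 multiOccupancyFractions = "numeric",
                 freeTbpNM = "numeric"))

setValidity("OccupancyResult", function(object) {
  if (object@partitionFunction < 1) return("partition function must be >= 1")
  p <- c(object@registerOccupancy, object@multiOccupancyFractions)
  if (any(p < -1e-12 | p > 1 + 1e-12))
    return("all probabilities must lie in [0, 1]")
  if (abs(sum(object@multiOccupancyFractions) - 1) > 1e-9)
    return("multiOccupancyFractions must sum to 1")
  TRUE
})

#' Active binding registers of a lattice
#'
#' @param lattice a [LatticeSpec-class].
#' @return Sorted integer vector of 0-based active register indices.
#' @export
activeRegisters <- function(lattice) {
  setdiff(seq_len(lattice@lengthBp) - 1L, lattice@inactiveRegisters)
}

#' Count candidate binding registers
#'
#' Under the default convention there is one binding register per base pair
#' (the protein footprint centre may overhang the lattice ends), so a 14-bp
#' construct presents 14 candidate sites; inactive registers (e.g. a
#' single-stranded extension) are excluded.
#'
#' @param lattice a [LatticeSpec-class].
#' @return Integer number of active registers.
#' @examples
#' countBindingRegisters(latticeSpec(14))   # 14
#' @export
countBindingRegisters <- function(lattice) {
  stopifnot(is(lattice, "LatticeSpec"))
  length(activeRegisters(lattice))
}

#' Locate the TATA box in a DNA sequence
#'
#' Scans the forward strand for the first match to the TATAWAWR consensus
#' (W = A/T, R = A/G) and returns the 0-based centre index of the match
#' (offset + 3 for the 8-bp motif).
#'
#' @param sequence IUPAC DNA string.
#' @return 0-based centre index of the first match, or `NA` if none.
#' @examples
#' locateSpecificSite("GGTATAAAAGGG")  # 5
#' locateSpecificSite("GGGGGGGG")      # NA
#' @export
locateSpecificSite <- function(sequence) {
  subject <- tryCatch(Biostrings::DNAString(sequence),
                      error = function(e) stop("invalid IUPAC DNA sequence: ",
                                               conditionMessage(e)))
  hits <- Biostrings::matchPattern("TATAWAWR", subject, fixed = FALSE)
  if (length(hits) == 0L) return(NA_integer_)
  offset0 <- BiocGenerics::start(hits)[1L] - 1L
  offset0 + 3L
}

# Per-register effective Kd (nM), applying salt scaling and TFIIA mode.
# Returns a numeric vector of length lengthBp; inactive registers get Inf.
effectiveKd <- function(lattice, energetics) {
  saltFac <- energetics@saltMM / energetics@saltRefMM
  kdS <- energetics@kdSpecific * saltFac^energetics@saltExpSpecific
  kdN <- energetics@kdNonspecific * saltFac^energetics@saltExpNonspecific
  if (energetics@tfiiaMode) {
    kdS <- kdS / energetics@tfiiaSpecificityBoost
    kdN <- kdN * energetics@tfiiaNsSuppression
  }
  kd <- rep(kdN, lattice@lengthBp)
  if (!is.na(lattice@specificRegister))
    kd[lattice@specificRegister + 1L] <- kdS
  kd[lattice@inactiveRegisters + 1L] <- Inf
  kd
}

#' Enumerate all allowed binding configurations
#'
#' Brute-force enumeration of every subset of active registers in which all
#' pairwise centre separations are at least the footprint `n`, including the
#' empty configuration. Intended as the exact reference for small lattices;
#' larger lattices must use the transfer-matrix path of
#' [equilibriumOccupancy()].
#'
#' @param lattice a [LatticeSpec-class] with at most 30 active registers.
#' @return List of sorted integer vectors of 0-based bound registers; the
#'   first element is the empty configuration `integer(0)`.
#' @examples
#' length(enumerateConfigurations(latticeSpec(14, footprintBp = 14)))  # 15
#' @export
enumerateConfigurations <- function(lattice) {
  regs <- activeRegisters(lattice)
  if (length(regs) > 30L)
    stop("lattice has ", length(regs), " active registers (> 30); ",
         "use the transfer-matrix path of equilibriumOccupancy()")
  n <- lattice@footprintBp
  out <- vector("list", 0L)
  recurse <- function(prefix, remaining) {
    out[[length(out) + 1L]] <<- prefix
    for (k in seq_along(remaining)) {
      r <- remaining[k]
      recurse(c(prefix, r), remaining[remaining >= r + n])
    }
  }
  recurse(integer(0), regs)
  out
}

#' Statistical weight of a binding configuration
#'
#' The weight of a configuration is the product over bound registers of
#' `freeTbp / Kd(register)` times `omega` per pair of proteins at centre
#' separation exactly equal to the footprint; the empty configuration has
#' weight 1 (the reference state).
#'
#' @param config sorted integer vector of 0-based bound registers.
#' @param lattice a [LatticeSpec-class].
#' @param energetics a [BindingEnergetics-class].
#' @param freeTbp free TBP concentration (nM, >= 0).
#' @return Dimensionless statistical weight.
#' @examples
#' lat <- latticeSpec(14, specificRegister = 6)
#' en <- bindingEnergetics(kdSpecific = 5)
#' configurationWeight(6L, lat, en, freeTbp = 5)  # 1 at c = Kd
#' @export
configurationWeight <- function(config, lattice, energetics, freeTbp) {
  if (freeTbp < 0) stop("freeTbp must be >= 0")
  if (length(config) == 0L) return(1)
  config <- sort(as.integer(config))
  n <- lattice@footprintBp
  if (any(diff(config) < n))
    stop("invalid configuration: centre separation below the footprint")
  if (any(config %in% lattice@inactiveRegisters))
    stop("invalid configuration: bound at an inactive register")
  kd <- effectiveKd(lattice, energetics)
  w <- prod(freeTbp / kd[config + 1L])
  nContacts <- sum(diff(config) == n)
  w * energetics@cooperativityOmega^nContacts
}

# Transfer-matrix (sequential DP) pass over registers 1..L with per-register
# statistical weights x and contact cooperativity omega at separation exactly
# n. Returns forward weights B[i] (sum over configurations of registers 1..i
# in which i is bound), backward weights F[i], Z, and the per-count totals
# N[k] (sum of weights of configurations with exactly k proteins).
latticeDP <- function(x, n, omega) {
  L <- length(x)
  kmax <- max(1L, (L - 1L) %/% n + 1L)
  B <- numeric(L); cumB <- numeric(L)
  Bk <- matrix(0, L, kmax); cumBk <- matrix(0, L, kmax)
  for (i in seq_len(L)) {
    j <- i - n
    prev <- if (j >= 1L) cumB[j] else 0
    coopTerm <- if (j >= 1L) (omega - 1) * B[j] else 0
    B[i] <- x[i] * (1 + prev + coopTerm)
    cumB[i] <- (if (i > 1L) cumB[i - 1L] else 0) + B[i]
    Bk[i, 1L] <- x[i]
    if (kmax > 1L) for (k in 2:kmax) {
      prevK <- if (j >= 1L) cumBk[j, k - 1L] else 0
      coopK <- if (j >= 1L) (omega - 1) * Bk[j, k - 1L] else 0
      Bk[i, k] <- x[i] * (prevK + coopK)
    }
    cumBk[i, ] <- (if (i > 1L) cumBk[i - 1L, ] else 0) + Bk[i, ]
  }
  Fw <- numeric(L); cumF <- numeric(L)  # cumF[i] = sum_{j >= i} Fw[j]
  for (i in rev(seq_len(L))) {
    j <- i + n
    nxt <- if (j <= L) cumF[j] else 0
    coopTerm <- if (j <= L) (omega - 1) * Fw[j] else 0
    Fw[i] <- x[i] * (1 + nxt + coopTerm)
    cumF[i] <- (if (i < L) cumF[i + 1L] else 0) + Fw[i]
  }
  Z <- 1 + cumB[L]
  list(B = B, Fw = Fw, Z = Z, Nk = cumBk[L, ])
}

#' Equilibrium occupancy of the lattice
#'
#' Computes the partition function and occupancy probabilities of the
#' branched cooperative lattice model: every active register carries
#' statistical weight `freeTbp / Kd(register)`, configurations exclude
#' overlapping footprints, and each pair of proteins in contact (centre
#' separation exactly the footprint) is weighted by `omega`.
#'
#' Two computational paths are available and agree to within 1e-9: explicit
#' enumeration of configurations (`method = "enumeration"`, up to 30 active
#' registers) and a linear-time transfer-matrix recursion with a
#' forward-backward pass for per-register occupancies (`method =
#' "transfer"`, any size). The default picks enumeration only when asked.
#'
#' @param lattice a [LatticeSpec-class].
#' @param energetics a [BindingEnergetics-class].
#' @param freeTbp free TBP concentration (nM, >= 0).
#' @param method `"transfer"` (default), `"enumeration"`, or `"auto"`.
#' @return An [OccupancyResult-class].
#' @examples
#' lat <- latticeSpec(14, specificRegister = 6)
#' occ <- equilibriumOccupancy(lat, bindingEnergetics(), freeTbp = 5)
#' pSpecificBound(occ)
#' @export
equilibriumOccupancy <- function(lattice, energetics, freeTbp,
                                 method = c("transfer", "enumeration",
                                            "auto")) {
  method <- match.arg(method)
  if (freeTbp < 0) stop("freeTbp must be >= 0")
  if (method == "auto")
    method <- if (countBindingRegisters(lattice) <= 20L) "enumeration" else
      "transfer"
  L <- lattice@lengthBp
  n <- lattice@footprintBp
  omega <- energetics@cooperativityOmega
  x <- freeTbp / effectiveKd(lattice, energetics)
  if (method == "enumeration") {
    configs <- enumerateConfigurations(lattice)
    w <- vapply(configs, configurationWeight, numeric(1),
                lattice = lattice, energetics = energetics,
                freeTbp = freeTbp)
    Z <- sum(w)
    sizes <- lengths(configs)
    kmax <- max(sizes)
    occ <- numeric(L)
    for (i in seq_along(configs))
      occ[configs[[i]] + 1L] <- occ[configs[[i]] + 1L] + w[i]
    occ <- occ / Z
    fractions <- vapply(0:kmax, function(k) sum(w[sizes == k]) / Z,
                        numeric(1))
  } else {
    dp <- latticeDP(x, n, omega)
    Z <- dp$Z
    occ <- ifelse(x > 0, dp$B * dp$Fw / (x * Z), 0)
    fractions <- c(1, dp$Nk) / Z
  }
  names(fractions) <- as.character(seq_along(fractions) - 1L)
  pSpec <- if (is.na(lattice@specificRegister)) NA_real_ else
    occ[lattice@specificRegister + 1L]
  new("OccupancyResult", partitionFunction = Z,
      registerOccupancy = pmin(pmax(occ, 0), 1),
      pSpecificBound = pSpec,
      multiOccupancyFractions = fractions / sum(fractions),
      freeTbpNM = freeTbp)
}

#' @describeIn equilibriumOccupancy Probability that the specific (TATA)
#'   register is occupied.
#' @param object an [OccupancyResult-class].
#' @export
pSpecificBound <- function(object) object@pSpecificBound

#' @describeIn equilibriumOccupancy Expected number of bound proteins per
#'   lattice.
#' @export
expectedBound <- function(object) {
  k <- seq_along(object@multiOccupancyFractions) - 1L
  sum(k * object@multiOccupancyFractions)
}

setMethod("show", "OccupancyResult", function(object) {
  cat("OccupancyResult @", object@freeTbpNM, "nM free TBP\n")
  cat("  Z =", format(object@partitionFunction, digits = 6),
      "| P(specific bound) =",
      format(object@pSpecificBound, digits = 4),
      "| <n bound> =", format(expectedBound(object), digits = 4), "\n")
})

setMethod("show", "LatticeSpec", function(object) {
  cat("LatticeSpec '", object@name, "': ", object@lengthBp, " bp, footprint ",
      object@footprintBp, " bp, contact span ", object@contactSpanBp,
      " bp\n", sep = "")
  cat("  specific register:",
      if (is.na(object@specificRegister)) "none" else object@specificRegister,
      "| active registers:", countBindingRegisters(object), "\n")
  cat("  dyes: donor @", object@dyeDonor@bpIndex, "/ acceptor @",
      object@dyeAcceptor@bpIndex, "\n")
})

setMethod("show", "BindingEnergetics", function(object) {
  cat("BindingEnergetics:", object@saltMM, "mM KCl",
      if (object@tfiiaMode) "(+TFIIA)" else "", "\n")
  cat("  Kd(specific) =", format(object@kdSpecific, digits = 4),
      "nM | Kd(non-specific) =", format(object@kdNonspecific, digits = 4),
      "nM (at", object@saltRefMM, "mM) | omega =",
      object@cooperativityOmega, "\n")
})
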