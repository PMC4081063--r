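# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Langmuir / single-site isotherm
langmuir <- function(conc, kd, pmin = 0, pmax = 1)
  pmin + (pmax - pmin) * conc / (conc + kd)

# McGhee-von Hippel non-cooperative lattice isotherm: bound-protein density
# per lattice residue nu solves x (1 - n nu) ((1 - n nu)/(1 - (n-1) nu))^(n-1)
# = nu, with x = c / Kd per residue.
mvhDensity <- function(x, n) {
  stats::uniroot(function(v)
    x * (1 - n * v) * ((1 - n * v) / (1 - (n - 1) * v))^(n - 1) - v,
    c(0, 1 / n - 1e-12), tol = 1e-12)$root
}

# Count of hard-rod configurations (centre separation >= n) on registers
# 0..(L-1) by dynamic programming over the rightmost placed register.
dpConfigCount <- function(L, n) {
  b <- numeric(L)   # b[i]: configurations whose last bound register is i-1
  for (i in seq_len(L)) {
    j <- i - n
    b[i] <- 1 + if (j >= 1) sum(b[seq_len(j)]) else 0
  }
  1 + sum(b)
}

# Plain Gillespie simulation of a continuous-time Markov chain with
# generator Q (dp/dt = Q p). Returns state counts at time tEnd over nTraj
# trajectories starting from state `start`.
gillespieCounts <- function(Q, start, tEnd, nTraj, seed) {
  set.seed(seed)
  nState <- nrow(Q)
  rates <- Q
  diag(rates) <- 0
  counts <- integer(nState)
  for (tr in seq_len(nTraj)) {
    s <- start
    t <- 0
    repeat {
      out <- rates[, s]
      tot <- sum(out)
      if (tot <= 0) break
      t <- t + stats::rexp(1, tot)
      if (t > tEnd) break
      s <- sample.int(nState, 1, prob = out)
    }
    counts[s] <- counts[s] + 1L
  }
  counts
}

# Isoceles-triangle chord for a single kink of `angleDeg` placed between two
# arms of lengths a and b (straight-line polyline geometry).
kinkChord <- function(a, b, angleDeg) {
  th <- angleDeg * pi / 180
  sqrt((a + b * cos(th))^2 + (b * sin(th))^2)
}

# Standard lattice used widely in tests: minimal 14-bp TATA construct with
# end-labelled dyes and the specific register at the motif centre.
tata14E <- function() latticeSpec(14, specificRegister = 6,
                                  dyeDonor = dyeSite(0),
                                  dyeAcceptor = dyeSite(13),
                                  name = "TATA-14E")

# 25-bp construct with 11 bp of flanking DNA and an internal acceptor.
tata14I <- function() latticeSpec(25, specificRegister = 6,
                                  dyeDonor = dyeSite(0),
                                  dyeAcceptor = dyeSite(14),
                                  name = "TATA-14I")

tata18I <- function() latticeSpec(25, specificRegister = 6,
                                  dyeDonor = dyeSite(0),
                                  dyeAcceptor = dyeSite(18),
                                  name = "TATA-18I")
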