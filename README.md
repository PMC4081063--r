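# TBPbind

Equilibrium, kinetic and single-molecule FRET modelling of TATA-binding
protein (TBP) association with promoter DNA, for biophysicists studying how
sequence-specific transcription-factor binding emerges from — and competes
with — non-specific DNA binding and nucleosome occupancy.

TBP binds the TATA box tightly and bends the DNA by ~105°, which makes
FRET-labelled DNA fragments a direct binding reporter. But TBP also lands on
essentially any register of a DNA duplex, and on fragments with flanking
sequence multiple TBP molecules bind cooperatively, out-competing the TATA
box at elevated concentration. TBPbind implements this picture as one tested
model family:

* **Cooperative lattice equilibrium** — a DNA fragment of ℓ bp is a lattice
  with one binding register per base pair (a 14-bp construct presents 14
  candidate sites), one specific (TATA) register with dissociation constant
  K_s, non-specific registers with K_ns, footprint exclusion (centre
  separation ≥ n, default 8 bp) and nearest-neighbour cooperativity ω.
  A configuration's weight is `prod(c / K_i) * omega^(#contacts)`; partition
  function and occupancies come from exact enumeration or an equivalent
  transfer-matrix recursion, reducing to the McGhee–von Hippel isotherm in
  the homogeneous non-cooperative limit.
* **FRET observables** — configurations map to dye distances via a kinked
  polyline (3.4 Å/bp, one coplanar kink per bound protein between the dyes),
  the Förster law `E = 1/(1 + (r/R0)^6)` with R0 = 51 Å, and a
  background/crosstalk/direct-excitation/γ signal model for corrected and
  uncorrected proximity ratios.
* **Branched kinetics and competitor chases** — a master-equation model with
  uniform association to all registers, class-specific dissociation
  (0.02 s⁻¹ non-specific vs 0.0014 s⁻¹ TATA) and optional detailed-balanced
  sliding; chase traces are fit with one- or two-phase exponentials. The
  fast-phase fraction falls with incubation time while the rates stay put.
* **Single-pair FRET bursts** — lognormal burst sizes, binomial photon
  partition with shot-noise-limited histogram widths, donor-only
  subpopulation, Gaussian width fits excluding the donor-only peak, and
  titration width-series diagnostics (two-state rise-and-fall vs
  cooperative monotone broadening).
* **Nucleosome site-exposure competition** — a TATA box ~5 bp inside the
  entry–exit site is exposed with probability K_unwrap/(1+K_unwrap) (salt-
  and histone-state-dependent); TBP alone sees a slow-exchange partition
  (amplitude suppressed, Kd unshifted) while TBP·TFIIA competes fast
  (Kd shifted by 1/p_exp at full amplitude).
* **Fitting and synthetic data** — single-site isotherm fits
  (`P = Pmin + (Pmax−Pmin)·[T]/([T]+K_D)`), a biphasic-deviation classifier,
  and a seeded fixture catalog regenerating every input type
  (titrations, chase traces, burst streams) bit-exactly.

## Worked example

```r
library(TBPbind)

lat <- latticeSpec(14, specificRegister = 6, name = "TATA-14E")
lat
#> LatticeSpec 'TATA-14E': 14 bp, footprint 8 bp, contact span 8 bp
#>   specific register: 6 | active registers: 14
#>   dyes: donor @ 0 / acceptor @ 13

equilibriumOccupancy(lat, bindingEnergetics(saltMM = 50), freeTbp = 10)
#> OccupancyResult @ 10 nM free TBP
#>   Z = 9.0625 | P(specific bound) = 0.2207 | <n bound> = 1.2

fit <- fitExponential(simulateChase(kineticScheme(incubationS = 60)),
                      phases = 2)
fit
#> DecayFit (2 phases)
#>   k_fast = 0.02 /s  k_slow = 0.0014 /s
#>   a_fast = 0.1542  a_slow = 0.03742  offset = 0.7024
#>   RSS = 6.004e-27  AIC = -1.171e+05
fastFraction(fit)
#> [1] 0.805
```

The chase fit recovers the two dissociation rate constants of the branched
scheme exactly (the trace is noiseless), and after only 60 s of incubation
80% of the decay amplitude is in the fast (non-specific) phase — the
population has not yet re-equilibrated onto the TATA box.

```r
fitSingleSite(generateTitration("fig1_tata14E_50mM", seed = 11))
#> Single-site isotherm fit
#>   Kd = 4.223 nM (SE 0.448)
#>   Pmin = 0.2893  Pmax = 0.5934  RSS = 0.0007376

nucleosomeIsotherm(nucleosomeScenario(histoneState = "hela", saltMM = 150))
#> Nucleosome competition (slow exchange)
#>   exposure p = 0.545 | apparent Kd = 7.759 nM (naked 7.759)
#>   amplitude fraction vs naked = 0.545
```

A single noisy synthetic titration recovers the generating Kd (5 nM) within
two standard errors; the nucleosome prediction shows the slow-exchange
signature — saturation amplitude cut to the site-exposure probability with
the apparent affinity unchanged.

A thin command-line wrapper over the same functions lives at
`inst/scripts/tbpbind.R` (subcommands `simulate-isotherm`, `simulate-chase`,
`simulate-bursts`, `fit-isotherm`, `fit-chase`, `analyze-bursts`,
`nucleosome-predict`, `fixtures`; every run writes its artifacts plus a
manifest with the resolved configuration and seed).

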