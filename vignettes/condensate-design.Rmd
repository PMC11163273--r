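---
title: "Modelling and evolving multiphasic protein-RNA condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and evolving multiphasic protein-RNA condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condevol)
```

# The scientific problem

Mixtures of positively charged disordered proteins (poly-arginine R50,
poly-lysine K50, and their mixed-composition relatives RmK(50-m)) and short
poly-uracil RNA phase-separate by complex coacervation. Depending on the
balance of interactions, the condensed phase can itself split into layered
sub-phases of distinct composition — a *multiphasic* condensate with an
inner core and an outer shell. `condevol` provides the complete desk-scale
computational workflow for studying this behavior:

1. a residue/nucleotide-resolution coarse-grained interaction model,
2. direct-coexistence Langevin dynamics in slab geometry,
3. axial density-profile analysis with quantitative multiphasicity
   fitness functions, and
4. a genetic algorithm (GA) that evolves the two protein sequences toward
   more or less multiphasic condensates.

# The interaction model

Every amino-acid residue and RNA nucleotide is one bead. Three energy terms
act between beads (internal units: nm, ps, kJ/mol, g/mol, elementary
charge):

**Harmonic bonds** between consecutive beads of a chain,
$E = \tfrac12 k (r - r_{\mathrm{ref}})^2$, with
$k = 8030\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$ (the conventional
$8.03\ \mathrm{J\,mol^{-1}\,pm^{-2}}$ converted to package units) and
reference lengths $r_{\mathrm{ref}} = 0.381$ nm for protein and $0.500$ nm
for RNA beads.

**Wang-Frenkel short-range pairs** for all non-bonded pairs,
$$\phi(r) = \varepsilon\,\alpha
  \left[\left(\tfrac{\sigma}{r}\right)^{2\mu} - 1\right]
  \left[\left(\tfrac{R}{r}\right)^{2\mu} - 1\right]^{2\nu},$$
with the normalizing prefactor $\alpha(\sigma,\mu,\nu,R)$ chosen so the
well depth is exactly $-\varepsilon$ (`wf_alpha()`). The potential and its
derivative vanish identically at the cutoff $R$, so there is no truncation
artifact in this term. Defaults: $\nu = 1$ and $R = 3\sigma$.

**Debye-Hückel electrostatics**,
$E(r) = \frac{q_i q_j}{4\pi\varepsilon_r\varepsilon_0 r} e^{-\kappa r}$,
with relative dielectric $\varepsilon_r = 80$, screening length
$\kappa^{-1} = 0.795$ nm, and a plain 3.5 nm cutoff. Directly bonded pairs
interact only through the bond term (the 1–2 exclusion rule); no further
exclusions are applied.

## The bundled toy parameter set

The quantitative pair-parameter table of the published Mpipi-class model is
not redistributed here; `load_forcefield()` reads any table in the
documented tab-separated dialect, so the real parameters are a drop-in
file. For a self-contained artifact, `toy_forcefield()` supplies a default
set built from per-bead "stickiness" values $\lambda_i$ by geometric-mean
combination, $\varepsilon_{ij} = \sqrt{\lambda_i\lambda_j}$, with explicit
overrides that enforce the interaction orderings that drive the phenomena
of interest:

* arginine–uracil more attractive than lysine–uracil
  ($\varepsilon_{RU} = 1.10$ vs $\varepsilon_{KU} = 0.55$ kJ/mol), the
  origin of the R-rich core in R/K/RNA multiphasic condensates;
* for each aromatic residue A in {Y, F, W}:
  $\varepsilon_{AA} > \varepsilon_{AU} > \varepsilon_{RU}$, so aromatic-rich
  sequences can condense on their own and exclude RNA.

All toy pairs use $\mu = 2$, $\nu = 1$, $R = 3\sigma$, with
$\sigma \in [0.45, 0.65]$ nm assigned by residue-size class. Charges are
R, K = +1; D, E = −1; H = +0.5 (configurable); U = −1. Masses are average
residue/nucleotide masses. The overall $\lambda$ scale was calibrated once
so that the desk-scale R50/K50/U10 reference mixture is comfortably inside
the two-phase region at 250 K with a condensed-phase protein density near
2.5 beads nm$^{-3}$, comparable to residue-level coarse-grained condensate
densities. Histidine's +0.5 charge follows the model family's convention;
it is a parameter, not a fitted value.

# Direct-coexistence dynamics

Phase behavior is probed with the direct-coexistence method: dense and
dilute phases share one elongated periodic box with explicit planar
interfaces perpendicular to the long (z) axis. The equations of motion are
integrated with velocity Verlet at a 10 fs time step; temperature is fixed
at 250 K by a Langevin thermostat with a 10 ps relaxation time.

Numerical choices worth knowing:

* **Thermostat discretization.** The package uses the BAOAB splitting with
  friction $\gamma = 1/\tau$ ($\tau$ = `friction_time`). BAOAB gives
  accurate configurational sampling at large time steps; with $\gamma = 0$
  the scheme reduces exactly to velocity Verlet, which is how the NVE mode
  is implemented. The thermostat's noise stream is an internal
  counter-free generator seeded from `settings$seed`, so trajectories are
  bitwise reproducible.
* **Neighbor lists.** A Verlet list with 0.3 nm skin over a cell grid
  (all-pairs fallback when the box is under three cells wide) with the
  standard half-skin displacement rebuild trigger. The validated contract
  is exact equality (to 1e-9 relative) with an all-pairs reference
  implementation written independently in R.
* **Electrostatic truncation.** The Debye-Hückel term is truncated,
  unshifted, at 3.5 nm, where the screening factor is
  $e^{-4.4} \approx 0.012$. The small discontinuity is invisible to NVT
  sampling but shows up as slow energy drift if strongly charged systems
  are run NVE; the NVE conservation tests therefore use neutral chains.
* **Initial conditions.** The builder grows chains as self-avoiding random
  walks confined to the middle third of the long axis, so the dense slab
  exists from step one and direct coexistence equilibrates quickly; a
  short capped steepest-descent relaxation removes growth artifacts, and
  velocities are Maxwell-Boltzmann at the target temperature with zero
  net momentum. The condensate is tracked at analysis time by recentring
  each frame on the periodic circular mean of the protein bead positions
  (RNA excluded to avoid vapor bias) rather than by restraining it during
  dynamics.

The standard protocol (`coexistence_protocol()`) equilibrates for 40 ns
and accumulates production frames for 20 ns. These defaults reproduce the
reference setup; the bundled `desk` (16+16 chains, 7 × 7 × 35 nm, 2+1 ns)
and `micro` (6+6 chains, 7 × 7 × 25 nm, 0.2+0.15 ns) presets exercise the
same code paths at workstation scale.

# Density profiles, regions and multiphasicity

Production frames are binned into 150 bins along z (`compute_profile()`),
giving per-species number densities (nm$^{-3}$). Two regions are defined
from the two protein profiles (`find_regions()`):

* **center** — the bins between the two sign changes of the smoothed
  difference $\rho_A - \rho_B$ nearest the condensate midpoint,
  implemented as the contiguous constant-sign run containing the
  density-weighted circular mean of the total protein profile. Profiles
  are smoothed with a 5-bin circular moving average first; raw binned
  profiles are noisy and the crossing rule is otherwise ill-conditioned.
* **vapor** — exactly 50 bins placed diametrically opposite the
  center-region midpoint on the periodic axis, so the first and last
  vapor bins are equidistant from the middle of the center region.

If the difference profile never changes sign (monophasic or degenerate
systems) the detector falls back to the bins holding at least half the
maximum total protein density and flags the result. For GA runs the
region specification of the initial reference system is computed once,
frozen, and reused for every fitness evaluation.

Two fitness functions quantify the architecture (`phase_metrics()`), with
densities in nm$^{-3}$ and the vapor penalty weight $s = 5$ nm$^3$ by
default:

* `fitness_demix()`:
  $f = |\rho_{A,c} - \rho_{B,c}|^{-1}
  - s(\rho_{A,v} + \rho_{B,v} + \rho_{RNA,v})$ — large when the two
  proteins share the condensate evenly; the penalty discourages
  dissolving the condensate altogether. The reciprocal diverges when the
  densities coincide, so the difference is floored at one bead per bin
  slab volume (configurable), capping the fitness.
* `fitness_multiphase()`:
  $f = |\rho_{A,c} - \rho_{B,c}| + \rho_{RNA,c}
  - s(\rho_{A,v} + \rho_{B,v} + \rho_{RNA,v})$ — large for layered
  condensates with RNA-rich cores.

# The genetic algorithm

An individual is the combined sequence of the two proteins; the RNA is
never evolved. The defaults follow the standard procedure: a population
of 20 is created by mutating the base sequences site-wise with
probability 0.05; each round selects 8 parents by size-5 tournaments,
pairs them randomly into 4 pairs, applies single-point crossover in the
evolvable region, mutates the children (again 0.05/site), evaluates them,
and inserts each child by weak replacement — a child enters only by
replacing the current weakest member, and only if strictly fitter.
A fitness cache guarantees no combined sequence is ever simulated twice
in a run.

Documented conventions where the procedure is underdetermined:

* Mutation draws uniformly from the allowed alphabet *including* the
  incumbent residue (effective change rate $0.05 \times 19/20$);
  `allow_self = FALSE` switches to forced-change draws. Constrained runs
  exclude forbidden target residues (e.g. no mutations to arginine, or
  none to Y/F/W) from the draw.
* Tournament ties go to the lowest population index; replacement requires
  strict improvement. Both choices make runs reproducible.
* The crossover cut is uniform on positions 0..L−1 of the evolvable
  region (0-based), exchanging suffixes; a cut at 0 swaps the parents.
* Children enter the population incrementally within a round, so a strong
  child can be displaced by a stronger sibling in the same round.
* Duplicates of existing members may enter; no uniqueness constraint is
  imposed.
* One master seed drives everything; per-round RNG streams are derived
  from it by counter, and the simulation evaluator uses a fixed seed per
  run so that fitness is a pure function of the sequence.

`cmd_evolve()` wires this to the simulation stack: the reference system is
simulated first, its regions frozen, and each evaluation rebuilds the
mixture with the individual's sequences — holding the RNA amount at the
reference value even when mutations break charge neutrality — runs the
coexistence protocol, and scores the frozen-region densities.

# What the synthetic generator does and does not emulate

The generator reproduces every input family of the study design:
homopolymers (R50, K50, Un), the RmK(50-m)/R(50-m)Km split-composition
families in block, random and alternating patternings, repeat proteins
((NNNGG)10, (FFFGG)10), charge-matched mixtures, charge-zeroing variants,
and slab initial conditions. It does **not** emulate RNA base pairing or
secondary structure (excluded by design), solvent or ions beyond the
implicit screened dielectric, or sequence-specific backbone geometry.
Desk-scale tests therefore demonstrate that the *mechanisms* — R-over-K
selectivity for RNA, composition-dependent layering, GA improvement of
the fitness — operate in the implemented model; quantitative condensate
properties at the reference scale additionally require the published
pair-parameter table and cluster-scale sampling.

# Problem sizes used by the test suite

The validation suite runs every physics check at sizes chosen for a
single workstation CPU: oracle comparisons on ~100–200-bead random
systems; NVE conservation on neutral 3-chain systems at 1 fs;
thermostat calibration on a 250-bead gas over 1 ns; and phase-behavior
checks on 4+4-chain RmK(50-m) mixtures with charge-matched U10
(7 × 7 × 20 nm box) with a 0.1 ns equilibration and 0.15 ns production
window, repeated over three seeds, scoring all systems against a common
frozen region set from the R50/K50/U10 reference so that Eq.-style
fitness values are commensurable across systems. These are deliberate
scale choices: the segregation of the two protein species and the
arginine–uracil selectivity are sign-resolvable there, while absolute
densities, fitness values and the fine composition dependence of the
multiphasicity remain strongly size- and time-affected (at four chains
per species, single-chain density fluctuations are comparable to the
composition-driven signal) and are not compared against reference-scale
numbers.

# Known limitations

* The toy parameter set is ordinal, not quantitative: it preserves the
  stated interaction orderings but not published well depths, so absolute
  energies, densities and transition RNA lengths differ from the
  reference model.
* Electrostatic truncation without shift makes strict NVE conservation
  inapplicable to charged systems (NVT sampling is unaffected).
* Desk-scale slabs are thin (a few nm); interfacial regions overlap the
  layers, which compresses fitness differences relative to the reference
  geometry.
* The GA evaluator is serial; a scan or evolution run is embarrassingly
  parallel across evaluations but no scheduler integration is provided.
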