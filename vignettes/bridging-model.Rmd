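---
title: "The bridging-induced attraction model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bridging-induced attraction model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bridgesim)
```

# The model

`bridgesim` simulates a coarse-grained chromatin fiber as a bead-spring
polymer and transcription factors as diffusing spheres that bind
reversibly to cognate ("same-color") beads.  The only specified
interactions are excluded volume, chain connectivity and a short-range
factor–bead attraction; yet bound factors cluster spontaneously.  The
mechanism is a positive feedback: once a factor bridges two beads, the
local concentration of binding sites rises, which recruits further
factors, which raises it further, until entropic crowding of the
accumulated loops halts growth.  Because red and green binding sites
occupy different places in the one-dimensional sequence, red and green
clusters end up in different places in three-dimensional space:
clusters of different types demix without any cross-repulsion.  Loops
around clusters express themselves in contact maps as TAD-like blocks
on the diagonal and compartment-like long-range enrichment between
same-color regions.

The transcription readout is geometric: a bead counts as transcribed in
a frame when its centre lies within 54 nm of a binding-competent factor
of a matching color.  Because transcription in this model is proximity
to a factor-rich cluster, perturbing one binding site (an "eQTL": a
bead losing its color) perturbs the cluster network and hence, weakly
but measurably, the transcription probabilities of many other beads —
the package's differential pipeline quantifies exactly this.

## Units and physical mapping

| quantity | unit | mapping |
|---|---|---|
| length | bead diameter σ = 30 nm | 1 bead = 3 kb |
| energy | kT | — |
| time | Brownian time τ~B~ | τ~B~ ≈ 0.01 s |

τ~B~ is the time for a 30-nm bead to diffuse its own diameter
(`MSD(τ~B~) = 6 D τ~B~ = σ²`), so `D = σ²/6` per τ~B~; smaller/larger
particles scale as `D ∝ 1/diameter`.  The mapping τ~B~ = 0.01 s makes
the default competence-switching rate of 10⁻⁵ τ~B~⁻¹ equal to
10⁻³ s⁻¹.

## Force laws and numerical choices

* **Bonds**: harmonic, `k = 100 kT/σ²`, rest length σ.  Bonded pairs
  are excluded from non-bonded interactions, so two bonded beads at
  rest length feel exactly zero force.
* **Excluded volume**: WCA (purely repulsive Lennard-Jones truncated at
  2^{1/6} × contact) of strength 1 kT between all non-bonded pairs.
  Below 0.95 × contact the repulsive force is capped at its value there
  and the potential continues linearly: the residual barrier to deep
  overlap still exceeds 100 kT, so the fiber remains effectively
  self-avoiding, while single-step forces stay bounded.
* **Specific binding**: a smooth half-cosine well between a competent
  factor and a cognate bead — `U = −ε` at contact, rising to zero at
  1.8 × contact (54 nm for 30-nm spheres, deliberately the same scale
  as the transcription criterion).  Default depth ε = 7 kT gives
  residence times long enough for clusters to assemble while thermal
  unbinding remains observable: a lone factor at a lone cognate bead
  exchanges dozens of times over 2 × 10⁴ τ~B~ (tested).  Inside a
  cluster the bridging feedback stretches escape times by orders of
  magnitude — there, factor exchange at desk scale is verified one kT
  lower, at the differential experiment's 6 kT operating point.  The
  bounded maximal force `ε π / (2 × 0.8 × contact)` is what keeps the
  overdamped update stable at the default timestep; a deep *Lennard-
  Jones* well of the same depth would demand a ~5× smaller timestep
  for no change in the stationary (Boltzmann) statistics, which the
  test suite verifies directly against a Monte-Carlo oracle.
* **Binding is implicit**: "bound" is a geometric statement (centre
  distance below the 54-nm well cutoff), not a discrete bond list, so
  valency emerges from sphere surface area rather than being imposed.
* **Bending**: optional Kratky–Porod term, default 0 (flexible fiber).
* **Confinement**: optional harmonic spherical wall (1 kT/nm²).
* **Integration**: Euler–Maruyama with Δt = 0.01 τ~B~.  Rare force
  pile-ups (many overlapping neighbours inside a dense cluster) have
  their deterministic displacement capped at σ/4 so that no particle
  ever moves more than σ/2 in a step; the capping rate is logged, and a
  run that caps more than 0.1% of updates warns.  A raw deterministic
  displacement of 2σ — the signature of a timestep that cannot resolve
  the stiffest force, since a diverging integration grows without
  bound — aborts the run naming the step and particle.
* **Neighbour search**: Verlet pair list with a 1σ skin over a linked
  cell grid, rebuilt when accumulated displacements could let a pair
  cross the skin.
* **Reproducibility**: every stochastic routine draws from R's RNG;
  `sim_config(seed =)` fixes a run bit-for-bit, ensembles derive
  per-run seeds as `master_seed + run index`, and the CLI writes
  manifests with seeds and file digests.

## The synthetic-genome generator

`generate_random_string()` scatters cognate beads of each color
independently along the fiber (at most one color per random bead;
multi-colored beads arise only from annotation binning, where a 50/50
window split yields a doubly-colored bead at the default 50% occupancy
threshold).  Per-color counts are Binomial(n, density); the default
density of 0.04 per color reproduces the ~200 cognate beads per color
per 5000 beads of the headline wild-type string.  The generator *does
not* emulate sequence correlations of real annotations (clustered
peaks, domain-scale runs); for those, bin a real BED track with
`beads_from_track()`.  Consequently, passing tests on random strings
demonstrates the physics of bridging, not agreement with any
particular genome.

## The eQTL experiment

`run_ensemble()` runs matched independent simulations and reduces each
to per-bead *run-level* transcription means — SEs are taken across
runs, never across frames, because frames within a run are strongly
autocorrelated.  `compare_ensembles()` applies a per-bead two-sample
Gaussian z-test.  Two open choices were resolved as follows:

* **No multiple-testing correction.**  The comparison reports the
  expected-by-chance count α × n_binding alongside the significant set
  (with α = 0.009, the headline configuration expects < 2 chance
  calls), which is the transparent convention for this experiment; a
  null calibration on wild-type splits verifies the type-I error level
  empirically.
* **Zero-variance beads** (probability identically 0 or 1 in both
  arms) get p = 1 and a `degenerate` flag — no evidence of change is
  representable that way.  The mutated bead itself, non-binding in the
  mutant arm, has mutant probability identically 0; it is reported but
  excluded from distal-change counts, since the scientific question is
  the effect on *other* genes.

## Analytics

* **Dimerization** solves 2M ⇌ D exactly; "fraction dimerized"
  defaults to molecules-in-dimers (2[D]/total) with the
  complexes convention selectable, because the two straddle the ~1%
  reference point at 1 nM and K~d~ = 10⁻⁷ M.
* **Local concentration** places one molecule in a sphere whose radius
  is the RMS end-to-end distance of the tether as an ideal chain
  (rod-limit fallback below one Kuhn segment).  For a 10-kb tether
  with the default geometry this gives ≈ 1.6 µM; the ~67% tethered
  occupancy quoted for such loops corresponds to an effective local
  concentration of 2 × 10⁻⁷ M = 2 K~d~ in the two-state formula, and
  the package exposes both numbers rather than forcing them to agree —
  the sphere model is one reasonable reading, not a fit.
* **Melt contact probability** treats the fiber as a phantom (ideal)
  chain — the melt-screened limit — with Kuhn length defaulting to the
  fiber diameter (20 nm ⇒ 1 kb per segment).  The closure probability
  is the exact spherical integral `P(χ²₃ < r_c²/(N b²/3))`, which
  reproduces the three printed reference values (~1.5 × 10⁻²,
  ~5 × 10⁻⁴, ~2 × 10⁻⁵ at 0.1/1/10 Mb) within a factor of 1.4 and
  decays as s^(−3/2).  The Kuhn choice is exposed; no printed value
  pins it down exactly.

## The tethered-loop calculation

`tether_visit_profile()` asks how often each monomer of a 77-kb loop
anchored to a 75-nm "factory" sphere visits a 30-nm shell around the
sphere.  The loop is discretized at 3 kb per 30-nm segment (~26
segments) and sampled as a closed *Gaussian* ring bridge with both
ends at one surface anchor, rejecting conformations that penetrate the
sphere.  Gaussian segments were chosen over a fixed-length
freely-jointed ring because the bridge can be sampled exactly and
independently (no Markov chain, no autocorrelation); since segment
lengths then fluctuate, only ordering and symmetry properties are
asserted — anchor-adjacent monomers visit almost always, the quarter
point less, the midpoint least, mirror-symmetrically — never absolute
visit frequencies.

## Problem sizes used by the test suite

The package's own checks run at desk scale, chosen once and frozen:

* clustering vs zero-affinity control: 300-bead string, 20% cognate
  beads, 30 factors, 2 × 10⁵ steps;
* two-color demixing: 400 beads, 5% cognate density per color, 2 × 10
  factors, ten seeds;
* TAD/compartment emergence: six alternating 50-bead blocks,
  3 × 10⁵ steps;
* eQTL experiment: 400-bead five-color string (≈ 90 binding beads), 4
  factors per color with default switching at 6 kT affinity, 40 runs
  per arm of 2.5 × 10⁵ steps.  Two condition choices matter for the
  omnigenic readout.  The affinity sits one kT below the engine
  default so that factors exchange fast enough for each run to average
  several cluster configurations — at 7 kT, cluster turnover is slower
  than a desk-scale run and per-bead run means degenerate towards
  Bernoulli outcomes, drowning distal effects in run-to-run variance
  (the robustness check still verifies the mutated-bead call at 7 kT).
  And factors are scarce relative to their cognate beads (4 factors
  per ~16 sites), so abolishing one strong site frees factor capacity
  that redistributes to clusters elsewhere on the string: distal
  beads, typically of *other* colors, measurably gain transcription
  while the mutated bead's same-color neighbours lose it.  The mutated
  bead is the most-transcribed mid-string bead of the wild type — a
  cluster hub, matching the experimental design in which the
  wild-type bead is typically found in a cluster and the mutant
  rarely is.

Simulation-backed experiments use a confinement sphere at 2% particle
volume fraction — the dilute-chromatin regime of coarse-grained
nuclear models, in which unbound factors remain available for exchange
while chance colocalization stays rare.  (At nuclear-like 10% packing
everything is within two diameters of something, and *any* cluster
statistic saturates; that regime is available through
`confinement_for_fraction(..., volume_fraction = 0.1)`.)

## Known limitations

* No loop extrusion, CTCF orientation logic, or hydrodynamic
  interactions; no depletion-attraction force term (its qualitative
  effect — clustering of bound complexes — is already produced by
  bridging).
* The soft repulsive core permits rare strand crossings over >10 kT
  barriers; topological observables (catenation, knotting) are
  therefore outside the model's remit.
* Transcription is a static geometric criterion; there is no polymerase
  kinetics, initiation/termination cycle, or mRNA accounting.
* Random strings have no sequence correlation structure; real
  annotation tracks should be binned with `beads_from_track()`.
* Effect sizes in the differential experiment depend on factor counts,
  affinity and run length; the pipeline reproduces the experiment's
  design and statistical behaviour, not any particular published
  effect-size table.
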