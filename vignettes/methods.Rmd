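---
title: "Methods: models, parameters and design choices in titrascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in titrascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrascape)
```

`titrascape` is a desk-scale pipeline for studying pH-driven
conformational change in K2P-type potassium channels: self-consistent
protonation assignment, per-frame trajectory geometry, 2D
distance-occurrence landscapes and replicate statistics, backed by a
synthetic trajectory generator. This vignette records the models, the
parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the package's tests
do not themselves compute.

## 1. The titration model

### Sites, charges, couplings

A titratable site is an acid (Asp, Glu, Tyr) or a base (His, Lys, Arg).
With protonation indicator $x_i \in \{0,1\}$, charges are $q_i = x_i-1$
(acid) and $q_i = x_i$ (base): binding a proton always adds one positive
charge. Pairwise couplings $w_{ij} \ge 0$ are in pK units per
unit-charge product — the sign of an interaction enters only through
$q_i q_j$. The default coupling backend is a screened Coulomb law,

$$ w(r) = \frac{e^2/(4\pi\varepsilon_0)}{\varepsilon\, r\, k_B T \ln 10}
   = \frac{332.064\ \mathrm{kcal\,\mathring{A}/mol}}
          {\varepsilon\, r \cdot k_B T \ln 10}, $$

with temperature 310 K (matching a physiological thermostat; it enters
only through $k_B T \ln 10 = 1.418$ kcal/mol) and dielectric
$\varepsilon = 80$ (solvent-like screening), both configurable. At
$\varepsilon = 80$ this gives $w \approx 0.98$ pK at 3 Å contact and
0.03 pK at 100 Å. This backend is deliberately simple: it is a
*pluggable stand-in* for a Poisson–Boltzmann engine, whose grid and
dielectric parameters a production study would have to choose. The
package makes no claim to reproduce any published per-residue pKa set;
what it validates is the *protocol* around the backend.

### Intrinsic pKas

Model-compound values, overridable per site: Asp 4.0, Glu 4.25, His 6.5,
Lys 10.4, Arg 12.0, Tyr 9.6. These are the standard textbook null values;
conformation-dependent intrinsic pKas are out of scope.

### The self-consistent protocol

One round is: **relax** (any callable mapping a system and protonation
vector to an ensemble of frames; the default is the identity ensemble,
and `jitter_relaxer()` emulates the convention of a short relaxation
sampled as 6 frames at 2 ns spacing from a 10 ns window) → **estimate**
per-frame per-site pKas with the backend, using the mean-field formula
$\mathrm{p}K_{a,i} = \mathrm{p}K_{a,i}^{int} - \sum_{j\ne i} w_{ij} q_j$
→ **average** into a report (mean, sd, and $n$ = identical residues per
assembly × frames, so a symmetric dimer relaxed into 6 frames reports
$n = 12$) → **assign** $x_i = 1$ iff $\mathrm{p}K_{a,i} > \mathrm{pH}$.
Rounds repeat until the assignment is unchanged or `max_rounds` is hit.

*Tie rule*: a site with pKa exactly equal to the pH is left
deprotonated. The underlying convention ("update as a function of the
desired pH") does not fix the boundary; strict inequality makes the
assignment deterministic.

*Cycle handling*: threshold dynamics on frustrated systems can enter a
period-2 oscillation (e.g. two nearby acids whose double deprotonation
is penalized more than either pKa–pH gap). The protocol detects an
assignment equal to the one two updates earlier, freezes the cycling
sites at the exact oracle's per-site majority, and lets the remaining
sites re-converge. This makes the protocol total without changing its
behaviour on convergent systems.

*Non-convergence* after `max_rounds` without a detected cycle is a
flagged result (`converged = FALSE`), not an exception.

### The exact oracle

For $N \le 20$ sites, all $2^N$ microstates are enumerated with energy
(pK units)

$$ G(x) = \sum_i x_i(\mathrm{pH} - \mathrm{p}K_{a,i}^{int})
        + \sum_{i<j} w_{ij}\, q_i(x_i)\, q_j(x_j), \qquad
   P(x) \propto 10^{-G(x)}, $$

giving $\theta_i = \sum_x x_i P(x)$ and effective
$\mathrm{p}K_{a,i} = \mathrm{pH} + \log_{10}(\theta_i/(1-\theta_i))$.
With $w \equiv 0$ this is Henderson–Hasselbalch per site. Numerically,
$1-\theta_i$ is computed as its own microstate sum rather than by
subtraction, so effective pKas keep full precision even when
$\theta \to 1$ (needed for the $10^{-10}$ zero-coupling agreement the
tests assert).

**A limit of intuition worth recording**: per-site titration curves
$\theta_i(\mathrm{pH})$ are *not* monotone in general. At the screened
couplings this package defaults to they are (the test suite checks this
on random systems), but strongly coupled mixed acid/base clusters
genuinely violate it — deprotonating a base removes the positive charge
that stabilized a neighbouring acid's deprotonated form, transiently
re-protonating that acid as pH *rises*. The suite pins a frozen 3-site
counterexample (couplings up to 6.6 pK) where $\theta$ increases by
0.14 over a pH step.

### The reference protonation pattern

`protonation_preset()` returns the converged pattern for the titratable
residues within 12 Å of the residue-122 Cα: His122, Glu45, Glu49 and
Asp230 protonated at low pH only; Glu235 always deprotonated (charged);
Lys246 and Lys131 always deprotonated (neutral); site 122 absent for the
H122N variant. This is data, not computation — it documents the
published convention the generator presets emulate.

## 2. Geometry metrics

- **Principal axis**: leading eigenvector of the *Cα-only* covariance
  (the atom selection is not dictated by the underlying convention; Cα
  is robust to side-chain motion), anchored at the selection centroid,
  sign fixed so the reference residue (His67, the extracellular CAP
  apex) projects positively. Decreasing residue-122 angle therefore
  means "pointing toward the CAP". Near-equal leading eigenvalues
  (relative gap below $10^{-6}$) are an ambiguity error, not a silent
  choice.
- **Orientation angle**: angle between the oriented axis and the vector
  from the residue's Cα to the *unweighted midpoint* of its two
  side-chain reference atoms (His ND1/NE2, Asn OD1/ND2; the map is
  extensible). Midpoint vs mass-weighting is immaterial for N/N pairs
  and differs negligibly for O/N; midpoint was chosen and documented.
- **Side-chain COM distance**: mass-weighted centre of side-chain heavy
  atoms (heavy = by element, excluding backbone N/CA/C/O), per the
  "centres-of-mass of side chain heavy atoms" convention; glycine is an
  error.
- **Length proxy**: His67–Arg171 Cα–Cα distance. Which chain anchors the
  whole-channel metric is unstated in the underlying convention; chain A
  is used and documented.
- **Equilibration**: frames before 50 ns (default, overridable) are
  excluded from every average. Pooling: subunits are independent
  replicates for angle/distance metrics; the whole channel is the
  replicate for the length metric.

## 3. Landscapes

Matched distance pairs (same trajectory, same timestamps and subunit
labels — misalignment is an error) are binned on a uniform grid,
default **60×60 over 2–14 Å** (0.2 Å bins). That range covers salt
bridges (~4 Å), stacking (~6 Å) and dissociated pairs (~10–11 Å); the
underlying convention does not state a binning, so this default is the
package's own. Out-of-range pairs are counted and reported, never
silently dropped. Frequencies are normalized to total mass 1 per panel.

**Smoothing** is tensor-product natural cubic spline interpolation onto
a refined grid (default 4×), with negative artifacts clipped to zero.
Smoothing is for reporting and display; **region statistics are computed
on the raw grid** so they are estimator-independent. The suite asserts
that smoothing relocates a unimodal peak by at most one original bin
width.

**Regions**: bins are ranked by frequency and the smallest set reaching
80% cumulative mass is labelled into 4-connected components, each
reported with mass and frequency-weighted centroid, sorted by mass.
Finite sampling produces dust: isolated selected bins holding a few
frames. Components below **1% mass** are reported but flagged `minor`;
`n_major` counts the rest. The 1% floor was fixed a priori as the noise
scale of a few-hundred-frame histogram and is not tuned against test
outcomes.

**Angle densities** use a Gaussian KDE with boundary reflection at 0°
and 180° (no probability mass may leak outside the angular support) and
Scott's rule bandwidth $\hat\sigma n^{-1/5}$ by default. Mode detection
keeps local maxima with topographic prominence at least 5% of the global
maximum; a curve is unimodal iff exactly one such mode survives; an
exactly flat density reports its global maximum as one mode (documented
degenerate-input convention).

## 4. Statistics

Welch's unequal-variance t-test (two-sided; zero variance in both groups
with equal means is defined as $t=0, p=1$) and two-way ANOVA with
**Type II** sums of squares (each main effect adjusted for the other,
interaction against the full model; the choice is unstated in the
underlying convention and Type II is the standard default for unbalanced
factorial data). All-equal responses return $F=0, p=1$ rather than the
0/0 the formulas produce. Significance stars follow the usual
publication convention (*, **, *** at 0.05, 0.01, 0.001). No
multiple-testing correction is applied, matching per-panel reporting.

## 5. The synthetic generator: what it emulates, what it does not

The generator exists so that every downstream stage is testable without
molecular dynamics. It emulates, per condition, exactly the statistical
structure the analyses consume:

- a two-subunit scaffold whose long axis is z (chain B is the C2
  rotation of chain A, making the Cα covariance diagonal by
  construction), carrying the tracked residues with their real atom
  names;
- a hidden-Markov state sequence per subunit: with probability 0.02 per
  frame (default) the state is *redrawn from the occupancy
  distribution* — the redraw may land on the same state, so the
  stationary distribution equals the configured occupancies exactly,
  while dwell times (~50 frames) exercise the time-series and
  equilibration logic that i.i.d. draws would not;
- per-frame placement of the Glu235/Lys246 side-chain COMs and the
  residue-122 side chain so that the tracked pair distances and the
  orientation angle are *exactly* Gaussian around the active state's
  targets (the placement solves the pair geometry in a plane, with the
  triangle inequality checked at configuration time when all three
  distances are specified);
- isotropic Gaussian jitter (default 0.05 Å) on scaffold atoms only,
  so the principal axis is exercised without biasing the placed
  metrics.

Presets encode the four studied conditions with approximate published
distance/angle scales, *documented as presets, not ground truth*:
high-pH wild type is a three-state mixture — a (E235–K246 ≈ 4 Å,
122–E235 ≈ 8 Å, occupancy 0.40), b (8 Å, 5 Å, 0.35), c (10 Å, 10 Å,
0.25) — with angle ~80°; low-pH wild type collapses to the single
salt-bridge state (8 Å, 4 Å) with angle ~50°; the H122N variant keeps
the three-state pattern at both pH values with angle ~90°. Where the
underlying description gives only ranges ("~4 Å", "6.5–10 Å"), single
representative values were fixed once: state c's (10, 10) Å represents
"interacts with neither" at a separation clearly outside salt-bridge and
stacking range, occupancies were chosen once as a plausible mixture
(none are published), and distance sd 0.25 Å / angle sd 8° give
fluctuation scales typical of a stable side-chain contact in equilibrium
MD.

What the generator does **not** emulate: force fields, solvent,
membranes, realistic rotamers, inter-metric correlations beyond the
shared hidden state, or the slow drift of real trajectories. A green
recovery test therefore establishes that the *analysis stack* measures
what it claims with correct statistics — not that any MD observation is
reproduced. The published headline numbers (angle decrease ~80°→~50°,
2–3 Å elongation, per-residue pKa rankings) derive from ~12 μs of
all-atom MD and an unstated Poisson–Boltzmann configuration, and are
explicitly not desk-reproducible; acceptance is property-based for that
reason.

## 6. Numerical and format conventions

- Coordinates in Å, residue numbering 1-based, no re-indexing;
  hydrogens kept on read, excluded from heavy-atom selections by
  element.
- Multi-model PDB is the portable trajectory format; coordinates
  round-trip to the format's 10^-3 Å precision. Alternate locations
  keep the highest-occupancy conformer (ties toward altloc A);
  insertion codes are rejected; only the first model is read by
  `read_structure()`.
- Input trajectories are assumed whole-molecule (no periodic imaging);
  frame times must increase strictly — violating input is rejected,
  never reordered.
- Tables serialize numerics at 6 significant digits with headers;
  re-reading reproduces values within that precision.
- Every random stage takes a mandatory seed and uses a private RNG
  stream that never touches the caller's `.Random.seed`; pipeline stage
  seeds are derived deterministically from the master seed, and a rerun
  of the same config is checksum-identical.

## 7. Known limitations

- The screened-Coulomb backend ignores desolvation, burial and
  conformational reorganization; computed pKas validate the protocol,
  not any specific protein.
- The mean-field + threshold update can disagree with the exact
  majority when some $\theta_i$ is near 0.5 (near-degenerate sites);
  the acceptance suite bounds this at ≤ 5% of random 8-site systems and
  checks that disagreements are confined to the near-degenerate band.
- Region segmentation is resolution-dependent (4-connectivity on 0.2 Å
  bins); very sparse histograms fragment, which the minor-region floor
  mitigates but does not eliminate.
- The CLI is a thin wrapper for interactive use; programmatic users
  should call the exported functions.
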