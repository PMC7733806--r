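---
title: "Methods: quantifying conformational states of a Ca2+ pump"
author: "pumpgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying conformational states of a Ca2+ pump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpgeom)
```

## The scientific problem

SERCA, the sarco(endo)plasmic reticulum Ca2+-ATPase, pumps two Ca2+
ions per hydrolysed ATP across the SR/ER membrane by cycling through E1
and E2 conformations. Its cytosolic headpiece (actuator A,
nucleotide-binding N and phosphorylation P domains) and its ten
transmembrane helices (M1-M10) communicate through a small set of
structural elements: the P1 helix (Pro337-Cys344) at the membrane face
of the P domain, the N-terminal tip of M3, and the L6-7 loop
(Phe809-Ser830). A glutamate in the middle of P1 (residue 340) is
nearly invariant across P-type ATPases; substituting it by alanine
slows Ca2+ binding roughly threefold and reduces turnover to about a
quarter, and a crystal structure of the mutant shows a globally shifted
headpiece over an almost unchanged transmembrane core.

`pumpgeom` implements the complete quantitative battery needed to
characterize such a mutant against the wild type: segment-decomposed
rigid-body superposition, the named geometric observables, polar-contact
and hydrogen-bond accounting, trajectory observable analysis
(distributions, modes, one-way switches, correlations), catalytic
in-line geometry, and the functional-assay computations (two-phase
binding kinetics, coupled-assay activity, Ca/EGTA speciation). A
synthetic-data module generates every fixture class with exact ground
truth, so the entire pipeline is testable without third-party data.

## Segment registry

All analyses resolve structural elements through one registry
(`segment_registry()`), in rabbit SERCA1a author numbering with
inclusive ranges. Three entries are fixed by the structural definitions
of this pump and cannot be overridden: M5-M10 = 750-994, P1 = 337-344,
L6-7 = 809-830. Domain and helix boundaries that the comparative
analyses need but that are not similarly fixed carry explicit,
overridable defaults:

```{r}
segment_registry()
```

Two default choices deserve a note. First, M3 is defined as 247-273 so
that the landmark residues of the P1-to-M3 contact network (Thr247,
Pro248, Leu249 at the helix tip) fall inside M3; the membrane-embedded
part of the helix begins a few residues later, and users who prefer a
stricter definition can override it. Second, residue 124 is shared
between M2 and the A domain, reflecting the continuous transition from
helix to domain at that boundary. Because per-domain RMSD values
reported for this system were published without the exact boundaries
used, the body RMSDs computed here are validation guides rather than
strict targets; the three RMSDs that have unambiguous definitions
(M5-M10 fit, M1-M4 in that frame, global main chain) are treated as
exact.

## Superposition and RMSD decomposition

`kabsch_superpose()` solves the closed-form least-squares rigid-body
problem via SVD of the covariance of the centered point sets, with the
determinant correction that guarantees a proper rotation. Collinear
point sets (second singular value below 1e-10 of the first) are
rejected because the rotation about the line is undefined.

`compare_structures()` pairs atoms across the two structures by the key
(chain, residue number, insertion code, atom name) — never by sequence
alignment — computes **one** fit on the fit segment, and evaluates every
report segment's RMSD in that fitted frame without refitting. This is
the operation behind the canonical comparison: fit on the C-terminal
transmembrane bundle M5-M10, then read off how much the rest moved.
"Main chain" means N, CA, C, O including the carbonyl oxygen; `atom_set
= "CA"` and `"all"` are available because published main-chain RMSDs do
not always state whether O was included. The global comparison
(`fit_segment = "ALL"`) fits on all paired main-chain atoms, the
natural reading of a superposition with no stated fit set. Waters and
heteroatoms never enter RMSD fits.

## Geometric observables

Angles between three residues (`residue_triplet_angle()`) use one named
atom per residue (CA unless stated otherwise) with the **middle residue
as vertex**. This is the only reading under which a kink angle
decreases as a helix kinks more sharply, which is how the M1 metric
(Trp50-Arg63-Val74) behaves: ~109 deg in the wild type versus ~105 deg
in the mutant crystal form. The headpiece tilt uses Leu13 (A domain),
Thr86 (vertex) and Leu98 (both M2). Landmark distances
(`residue_pair_distance()`) are CA-CA unless another atom is named;
the arginine-swing observable offers both the Cβ convention of the
descriptive text and a Cα option.

`catalytic_geometry()` measures phosphoryl-transfer readiness at the
catalytic aspartate (Asp351): it locates the γ-phosphate analog centre
(Pγ of ATP/AMPPCP, or the Al atom of an aluminium fluoride
transition-state mimic), picks the nearer carboxyl oxygen (OD1/OD2),
and returns their distance together with the angle at the centre
between that oxygen and the bridging atom of the terminal
phosphoanhydride bond — O3B, or the methylene carbon C3B in AMPPCP,
which substitutes for the bridging oxygen both chemically and in this
metric. An in-line associative geometry approaches 180 deg at ~2 Å, the
configuration trapped by ADP·AlF4 transition-state complexes
(2.1 Å, 159 deg).

## Contacts and hydrogen bonds

Crystal structures at ~3 Å resolution carry no hydrogens, so the
default polar-contact criterion is a heavy-atom donor/acceptor distance
cutoff of 3.5 Å over N and O (S accepted as acceptor), with no angle
term; this reproduces conventional "polar contacts" renderings.
Backbone N and O participate — the Glu340 carboxylate to Leu249
backbone-amide link requires it. When hydrogens are present (simulation
frames) `count_hbonds()` switches to the hydrogen-aware criterion
H···A ≤ 2.5 Å and D-H···A ≥ 120 deg, with donors required to carry a
covalent hydrogen (≤ 1.25 Å). Water-mediated contacts are searched
through single water bridges only (both legs within the cutoff), which
is the topology of the one water-mediated link this analysis cares
about (residue 340 to Arg822). Because the exact criterion behind
published contact counts is rarely stated, counts are compared as
presence/absence of named pairs and as distributions, not as exact
integers against external sources; against the package's own
generators they are exact.

## Trajectory analysis

`evaluate_observable()` maps any of the four observable kinds
(distance, triplet angle, hydrogen-bond count, catalytic geometry) over
the frames of a multi-model PDB trajectory, reusing the static
operations so a one-frame trajectory reproduces the crystal-structure
value by construction. Distributions use a Gaussian KDE with
Silverman's rule (or fixed bins), normalized to unit area; modes are
local maxima above a height threshold (default 5% of the maximum),
which is invariant under rescaling of the density axis — full
topographic prominence is deliberately not computed.

Two-state classification (`classify_two_state()`) is hysteretic: a
frame is "low" at or below the lower threshold, "high" at or above the
upper one, and inherits the previous state inside the band, so noise
never flickers states. The defaults (10 and 12 Å) bracket the observed
levels of the arginine-swing analysis: "in" at ~7-10 Å, "out" at
~13 Å. `is_irreversible()` formalizes the one-way character of that
switch: true when no high-to-low transition follows the first
low-to-high one. Correlated motions (the M3 tip closing on L6-7 as the
arginine leaves) are quantified as plain Pearson correlation between
the two distance series. Equilibration discard and frame stride are
left to the caller (defaults: none, 1).

## Functional assays

**Two-phase association.** Fluorescence transients are fitted on the
first 60 s with F(t) = F0 + A1(1−e^(−k1 t)) + A2(1−e^(−k2 t)) by
Levenberg-Marquardt least squares from eight deterministic starts
spanning rates 0.01-10 s⁻¹ (two-exponential fits are
initialization-sensitive; the best residual sum wins). The half-time is
deliberately parameter-free: the time at which the fitted curve covers
half of its total amplitude A1+A2, solved numerically by bisection.
For a single phase this reduces to ln(2)/k, and for any monotone
two-phase rise it is bracketed by the two phase half-lives. Rates
within 5% of each other are reported with a single-phase warning.

**Specific activity.** The enzyme-coupled assay regenerates each
hydrolysed ATP at the cost of one NADH, so activity =
|dA340/dt| / (ε·l) / [protein], with the standard ε(NADH, 340 nm) =
6.22 mM⁻¹cm⁻¹ and a 1 cm path as defaults.

**Ca/EGTA speciation.** Free Ca2+ follows from the positive root of
the 1:1 binding quadratic free² + (Kd + EGTA_tot − Ca_tot)·free −
Kd·Ca_tot = 0 with an *apparent*, pH-dependent Kd supplied by the
caller; no multi-proton speciation machinery is attempted, because the
quantities of interest here do not need it. The protocol's final state
— ~12.6 mM total Ca against 5 mM EGTA — is in the excess-calcium
regime where the answer (~7.6 mM free) is insensitive to Kd over
orders of magnitude. The intermediate EGTA-clamped state is
Kd-sensitive; the analysis driver uses Kd_app = 4 µM for pH 6.5
(EGTA's affinity for Ca2+ weakens steeply below neutral pH), chosen
once as a representative apparent constant, and the resulting ~90 nM
clamp should be read as order-of-magnitude only.

## The synthetic-data module

Every generator emits a machine-readable ground-truth record consumed
directly by the tests; no expected value is hand-copied. Identical
seeds reproduce artifacts bit-exactly. Synthetic structures are
idealized poly-alanine-style chains: only the atoms a tested observable
needs are guaranteed chemically meaningful.

The study conditions the generators emulate are fixed as follows:
switch traces use in/out levels 7 and 13 Å with 0.3 Å Gaussian noise;
bimodal distance traces use the observed mode positions (7.5/8.8 Å
wild type, 6.9 Å mutant) with 0.3-0.35 Å component widths;
fluorescence transients sample every 2 s (the instrument integration
time) with Gaussian noise at 2% of total amplitude, and ensembles of
50 traces represent the per-experiment half-time analysis with true
half-times of 1.6 s (fast, wild-type-like) and 4.5 s (slow,
mutant-like). The rigid-pair generator records the analytic expected
post-fit RMSD noise_sd·sqrt(3 − 6/n), the 6 degrees of freedom being
those the rigid fit absorbs.

**The synthetic stand-in pair.** `synthetic_pump_pair()` builds a
full-length (residues 1-994) wild-type/mutant pair whose comparison
observables equal the published values of the real structure pair *by
construction*: the deposited entries cannot be redistributed with the
package, so the stand-ins carry the target quantities as generator
ground truth and the pipeline must recover them from raw coordinates.
Angle and distance landmarks are placed exactly (cone/line projections
that preserve arm lengths). RMSD targets are realized by per-segment
Gaussian displacement fields with the rigid component projected out
(so each group's own fit stays at identity to first order) plus rigid
domain rotations — the N domain relative to P, the A domain relative
to both, and the whole headpiece about a pivot at residue 340, the
axis oriented so the tilt closes the headpiece hinge angle, mirroring
the conformational change being emulated. Field amplitudes and
rotation angles are calibrated numerically (fixed-point refinement and
1-D root finding against the package's own superposition) to ~0.01 Å.
Because the calibration uses the same Kabsch solver it later
validates, that solver is independently verified elsewhere in the
suite against a 10,000-sample random-rotation optimality oracle, a
closed-form rigid-motion oracle and a second implementation (bio3d).
Interdomain contacts are planted as explicit side-chain/water atoms
with deterministic kept/lost status (eight A-to-N pairs in the wild
type, two surviving in the mutant; a water bridge from Glu340 to
Arg822 in the wild type only), and each structure carries a minimal
nucleotide site with prescribed in-line geometry.

What passing on these stand-ins does and does not show: it shows the
measurement pipeline — pairing, single-fit decomposition, angles,
distances, contact detection, catalytic geometry, reporting — recovers
known ground truth from raw coordinates under realistic magnitudes; it
does not re-derive the published numbers from the deposited
experimental structures, which requires fetching those entries and
running the identical `run_compare_report()` call on them.

## Numerical choices and degenerate inputs

- Altloc policy: keep the highest-occupancy conformer; ties go to
  altloc "A". Deterministic and standard.
- Kabsch degeneracy: collinear sets rejected at a relative singular
  value threshold of 1e-10; fewer than 3 points rejected.
- Angle degeneracy: zero-length arms (< 1e-9 Å) are errors; cosines are
  clamped to [-1, 1] before acos.
- Empty selections resolve to zero atoms without error; empty report
  segments yield per-segment error entries, not a global failure.
- Two-phase fits refuse fewer than 8 points in the window and
  non-increasing time axes; non-convergence from all starts raises an
  error carrying the collected optimizer diagnostics.
- The speciation quadratic is evaluated in the numerically safe root
  form and clamped to [0, Ca_tot]; conservation holds to 1e-12
  relative.
- Problem sizes in tests and drivers (50-trace ensembles, 2x10^4-10^5
  sample densities, 100-seed property sweeps, ~4,000-atom stand-in
  structures) were chosen to make every statistical tolerance
  comfortable at interactive run times.

## Known limitations

- No sequence-alignment-based residue matching: structures must share
  author numbering (true for the crystal forms of one protein, not for
  homologs).
- No periodic-boundary handling in trajectory observables; molecules
  are assumed whole.
- Mode finding uses height-threshold prominence, which can merge a
  shoulder into a neighbouring peak that full prominence would
  separate.
- The hydrogen-aware bond criterion requires explicit hydrogens; no
  hydrogen placement is attempted.
- The speciation model is a single apparent-Kd 1:1 equilibrium; ionic
  strength, Mg2+ competition and proton release are folded into the
  caller-supplied constant.
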