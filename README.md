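# pumpgeom

Quantitative structural and kinetic analysis of conformational states
of the sarco(endo)plasmic reticulum Ca2+-ATPase (SERCA) and related
P-type ion pumps.

## The problem

SERCA couples ATP hydrolysis to Ca2+ transport by cycling between E1
and E2 conformations. The communication between its cytosolic headpiece
(A, N, P domains) and the transmembrane Ca2+ sites runs through a small
hub — the P1 helix (Pro337-Cys344), the tip of M3, and the L6-7 loop —
centred on a nearly invariant glutamate (residue 340). Characterizing a
mutation in this hub requires a battery of quantitative comparisons
between structures, trajectories and functional assays. `pumpgeom`
implements that battery as reusable, tested operations:

- **Segment-decomposed superposition.** Closed-form Kabsch fit
  (`kabsch_superpose`), with `compare_structures()` computing one fit on
  a named segment (e.g. the M5-M10 bundle, residues 750-994) and
  evaluating every other segment's RMSD in that fitted frame. For
  paired coordinates x_i, y_i it minimizes
  `sqrt(mean ||R x_i + t - y_i||^2)` over proper rotations R.
- **Named observables.** Triplet angles with middle-residue vertex
  (headpiece tilt Leu13-Thr86-Leu98; M1 kink Trp50-Arg63-Val74),
  landmark CA-CA distances (Pro337-Pro312, residue340-Leu249), and the
  catalytic in-line geometry at Asp351: the distance from the nearer
  carboxyl oxygen to the γ-phosphate analog centre and the attack angle
  through the bridging phosphoanhydride atom.
- **Polar contacts / hydrogen bonds.** Heavy-atom criterion (3.5 Å) for
  crystal structures, hydrogen-aware criterion (H···A ≤ 2.5 Å, angle ≥
  120°) for simulation frames, single-water bridges for water-mediated
  links.
- **Trajectory observables.** Per-frame evaluation over multi-model PDB
  trajectories, KDE/histogram densities with mode finding, hysteretic
  two-state classification with an irreversibility test (one-way
  switches), Pearson correlation between traces.
- **Functional assays.** Two-phase association fits
  `F(t) = F0 + A1(1-e^(-k1 t)) + A2(1-e^(-k2 t))` with a parameter-free
  half-time (time to half of A1+A2, solved by bisection); coupled-assay
  ATPase specific activity from NADH absorbance slopes; free Ca2+ in
  Ca/EGTA buffers from the 1:1 binding quadratic.
- **Synthetic data.** Generators for every fixture class with exact
  ground truth, including a full synthetic stand-in structure pair
  (`synthetic_pump_pair`) whose comparison observables carry the
  published wild-type/E340A values by construction.

## Worked example

The analysis drivers under `analysis/` run the complete workflow
(`01_structure_comparison.R`, `02_md_observables.R`,
`03_functional_assays.R`) and write their tables under `results/`. The
core comparison in a few lines:

```r
library(pumpgeom)

pair <- synthetic_pump_pair(seed = 1)   # or two read_structure() calls
rep  <- run_compare_report(pair$wt, pair$mut)
report_table(rep)
```

```
                quantity         ref mobile
1   rmsd_M5M10_fit_frame   0.4900000     NA
2    rmsd_M1M4_fit_frame   0.5600000     NA
3  rmsd_global_mainchain   2.3000000     NA
...
10       angle_headpiece 152.0000000  147.0
11         angle_m1_kink 109.0000000  105.0
12        dist_p337_p312  15.6000000   12.3
13      dist_res340_l249   8.0000000    6.9
14     n_contacts_a_to_n   8.0000000    2.0
```

Reading: the transmembrane core is nearly identical (fit on M5-M10,
rmsd 0.49 Å; M1-M4 in that frame 0.56 Å) while the global main-chain
rmsd of 2.3 Å shows the whole headpiece has moved; the headpiece tilts
5° further down (152° → 147°), M1 kinks slightly more (109° → 105°),
the P1 helix approaches M4 (15.6 → 12.3 Å), and six of eight A-to-N
interdomain contacts are lost. The functional side:

```r
r <- free_calcium(ca_total = 105e-6 + 4e-6 + 12.5e-3,
                  egta_total = 5e-3, Kd_app = 1e-7)
r$free_ca * 1000
#> [1] 7.609066      # mM free Ca2+ after the final CaCl2 addition

ks <- rates_for_half_time(4.5)          # two-phase law with t1/2 = 4.5 s
tr <- make_fluorescence_trace(F0 = 1, A1 = .5, k1 = ks$k1,
                              A2 = .5, k2 = ks$k2,
                              noise_sd = .02, dt = 2, seed = 1)
fit_two_phase_association(tr$data$time_s, tr$data$intensity)$t_half
#> [1] 4.303411      # s, recovered from one noisy 60 s window
#> (median over the 50-trace ensemble: 4.47 s against a true 4.5 s)
```

Because the deposited crystal structures cannot be redistributed here,
the drivers and tests exercise the crystal-structure comparisons on the
synthetic stand-in pair, which is constructed to carry the published
comparison values as ground truth; applying the same
`run_compare_report()` to downloaded PDB entries is a two-line change.

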