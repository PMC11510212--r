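---
title: "Methods: GPCR activation-dynamics analysis with gactdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPCR activation-dynamics analysis with gactdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gactdyn)
```

## Scope and scientific background

Class A G-protein-coupled receptors switch between inactive and active
conformations through a small set of well-characterised microswitches: the
ionic lock between R3.50 (DRY motif, intracellular end of TM3) and E6.30
(TM6), the W6.48 toggle switch in the CWxP motif, and proline-induced kinks
in TM5/TM6/TM7.  Agonist binding at the extracellular face propagates
through backbone and side-chain torsion changes to an outward swing of the
intracellular end of TM6, breaking the ionic lock and opening the G-protein
coupling interface.

`gactdyn` implements the trajectory-analysis layer of that picture for
molecular-dynamics coordinate ensembles: ionic-lock distance monitoring,
RMSD/RMSF, proline-kink geometry (bend, wobble and face-shift angles),
backbone/side-chain dihedral statistics with circular averaging and
half-trajectory transition detection, differential salt-bridge,
hydrogen-bond and hydrophobic occupancy networks between a test and a
reference ensemble, combined PCA of concatenated trajectories, dynamic
cross-correlation matrices (DCCM), windowed correlation fractions, and
helix-end projections on the membrane plane.  It does not build, dock or
run simulations; its inputs are coordinate ensembles plus a segment table.

## Data model and conventions

* Coordinates are in Angstrom, times in ns, the membrane normal is `+z`
  (intracellular side at negative z).  All internal atom and residue
  indices are 1-based, the natural convention in R; user-facing tables
  carry author residue numbers and Ballesteros-Weinstein (BW) generic
  numbers.
* The canonical ensemble format is multi-model PDB, read and written by the
  package itself so that fixtures remain plain text; binary trajectory
  readers can feed coordinate matrices in through `as_frame_series()`.
  Waters and ions (`HOH, WAT, TIP3, NA, CL, K`) are excluded at load time;
  other HETATM residues become `LIGAND` segments.
* BW numbering is anchored: a segment table row such as `TM3: 155-180,
  anchor 3.50@173` numbers every residue in the range by its offset from
  the anchor.  Loop residues are numbered only when the table anchors them
  explicitly (e.g. a GPCRdb-style `45.52`), because author and generic
  numbering mix freely in loops.

## Ionic-lock metric

The lock distance is the distance between charge centers: the mean of the
Arg guanidinium atoms (CZ, NH1, NH2; NZ for Lys) and the mean of the Glu
carboxylate atoms (CD, OE1, OE2; CG, OD1, OD2 for Asp).  A formed lock
sits near 4.5 A; a broken one ranges up to ~12.5 A.  The broken fraction
counts frames above a configurable `formed_threshold` (default 5.0 A;
charge-center metrics have no universally printed cutoff, so the value is a
parameter and is echoed in provenance).  With the default threshold a
formed state at 4.5 A with 0.3 A Gaussian jitter is misclassified in about
4.8% of frames; analyses that need an unbiased two-state estimate should
either lower the noise, raise the threshold toward the state midpoint, or
average replicas.

## Helix-axis fit and kink angles

Kink geometry needs per-segment helix axes.  A raw principal direction of
the C-alpha cloud is biased by several degrees on segments shorter than
about four turns, because partial turns leave the in-plane coordinates
unbalanced; we measured 6-9 degrees of tilt for 8-11 residue ideal
helices, which would swamp a 1-degree kink-recovery requirement.
`fit_helix_axis()` therefore uses the second-difference construction:
for an ideal helix the second differences of consecutive C-alpha positions
are exactly radial, so cross products of successive second differences lie
exactly along the axis.  The direction is refined by an algebraic (Kasa)
circle fit in the axis-normal plane, subtracting the fitted radial
component and re-fitting the principal direction of the residual on-axis
points (three iterations; exact on ideal helices, stable under 0.3 A
noise for TM-length segments).  The fit also returns radius, per-residue
phase, signed twist and rise.

`prokink_angles()` computes, per frame, with independent pre- and
post-kink axis fits:

* **bend** — the angle between the two axis directions;
* **wobble** — the signed angle (right-handed about the pre-axis, in its
  normal plane) from the kink-residue C-alpha radial direction to the
  projection of the post-axis: the direction in which the helix bends;
* **face shift** — the circular mean over post residues of the observed
  helical phase about the post axis (measured in the pre-axis frame
  transported by the minimal rotation carrying the pre-axis onto the
  post-axis) minus the phase predicted by extrapolating the pre-segment
  twist: the rotation of the helix face across the kink.

Wobble is flagged unreliable when the bend is below `bend_floor` (default
5 degrees): the bending direction of a nearly straight helix is
meaningless.  These conventions are internally consistent and validated by
the generator round trip (construction parameters recovered to well below
a degree); other kink-analysis programs may differ by a fixed sign or
offset in wobble/face-shift, so cross-program comparisons should compare
*differences* between ensembles rather than absolute values.

## Dihedral statistics

phi/psi use the standard atom quadruples `(C(i-1), N, CA, C)` and
`(N, CA, C, N(i+1))`; chi1/chi2 use the standard per-residue gamma/delta
atom tables.  All angles are wrapped to `(-180, 180]` with the IUPAC sign
convention (cis = 0, trans = 180).  Averages and spreads are circular
(`atan2` of mean sine and cosine; Mardia circular SD) — arithmetic means
are wrong near the wrap, e.g. for backbone phi values around -157 degrees.
The half-split summary compares circular means of the first and second
trajectory halves and flags a transition when they differ by more than
`transition_threshold` (default 30 degrees; reported "substantial"
half-trajectory changes are of this scale and the threshold is
configurable).

## Interaction detectors

All detectors aggregate at residue level — a pair is in contact in a frame
if ANY qualifying atom pair is — and report the occupancy fraction over the
analysis window.

* **Salt bridges**: basic side-chain N (Arg NE/NH1/NH2, Lys NZ) to acidic
  side-chain O (Asp OD1/OD2, Glu OE1/OE2) within 4.0 A.  His counts as
  basic only when requested, since protonation is usually unknown.
* **Hydrogen bonds**: donor-acceptor heavy distance <= 3.5 A AND D-H...A
  angle >= 120 degrees.  H attachment is inferred from first-frame
  geometry (H within 1.25 A of N/O in the same residue).  Heavy-atom-only
  topologies fall back to the distance criterion alone, flagged in
  `settings$hydrogens_used`.
* **Hydrophobic contacts**: any side-chain heavy-atom pair with at least
  one carbon within 4.5 A, where at least one partner is apolar (Ala, Val,
  Leu, Ile, Pro, Phe, Met, Trp, Cys).  Mixed pairs such as Ser-Ile count:
  the criterion is carbon-mediated proximity, not mutual apolarity.
  Sequence neighbours (separation < 3 within one segment) are excluded.
* **Ligand contacts**: any residue heavy atom within 4.0 A of any ligand
  heavy atom, reported as a percentage of frames.

Differential networks (`delta_fractions`) compare a test with a reference
ensemble pair-by-pair, `delta = f_test - f_ref` with missing pairs counted
as zero occupancy; positive deltas are interactions formed in the test
ensemble, negative ones broken.  Antisymmetry is exact by construction.
`top_differential_pairs` ranks by `|delta|` above a report threshold
(default 0.2) with a deterministic author-number tie-break.

## Combined PCA, DCCM and windowed correlation fractions

Combined PCA concatenates the frames of all ensembles, superposes them on
the concatenated mean (mean and fit iterated twice, so neither ensemble's
own mean biases the difference mode), and eigendecomposes the 3N x 3N
coordinate covariance.  Contributions are eigenvalue shares of the total
variance; per-frame projections keep their ensemble tag.  Mode traces
(`ev_trace_frames`) display a component as the mean structure displaced at
six evenly spaced amplitudes spanning +/-2 standard deviations of the mode.

DCCM entries are `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` for
one atom per residue after superposition.  Zero-variance atoms (relative
variance below 1e-12 of the selection maximum) give NA entries — an
undefined correlation is reported missing, never coerced to 0.  With fewer
than three fit atoms a least-squares fit is underdetermined and frames are
used as-is; displacement statistics are invariant under rigid motions of
the whole trajectory either way.

"Correlation fraction" statistics cut the trajectory into
**non-overlapping** windows (default 100 frames = 10 ns at the 0.1 ns
stride), compute a DCCM per window, and report per pair the fraction of
windows with `C > +t` and with `C < -t` (default `t = 0.5`).
Non-overlapping windows keep the window count independent for the fraction
statistic.  Both the raw DCCM difference and the windowed-fraction
difference are exported, since either convention is defensible for a
correlation-difference map; the choice is a documented flag of the
analysis, not hidden in the output.

## Synthetic generators: what they emulate and what they do not

Every analysis stage is validated against generators whose ground truth is
known and exported (`ground_truth` on the returned ensemble):

* `make_ideal_helix` / `make_kinked_helix` — ideal alpha-helix geometry
  (rise 1.5 A, twist 100 degrees, radius 2.3 A) and a kink constructed by
  rotating the ideal continuation by (bend, wobble, face shift) about the
  kink residue.  The construction and the measurement are mutually
  consistent by design, which makes recovery a genuine round-trip oracle.
* `make_two_state_lock_trajectory` — a hidden two-state Markov chain with
  stationary open probability `p_open`, state dwells `2 dwell p_open` and
  `2 dwell (1-p_open)` (so the average state dwell is `dwell`, default 50
  frames), formed/broken distances 4.5/12.5 A and Gaussian distance noise
  (default 0.3 A).  The Markov structure gives occupancy estimators the
  dwell autocorrelation seen in real lock traces, rather than i.i.d.
  frames.
* `make_occupancy_trajectory` — per-frame Bernoulli contact placement at
  designed fractions for salt-bridge, hydrophobic or hydrogen-bond
  templates, with the draw matrix retained.
* `make_correlated_trajectory` — per-axis bivariate-normal displacements
  at designed Pearson correlations (exact at +/-1).
* `make_pseudo_receptor` — seven 31-residue C-alpha helices on a 12 A
  circle with real-receptor up/down topology, BW generics x.30..x.60
  anchored at x.50 mid-membrane, an R3.50-E6.30 charge-group lock at
  4.5 A, and (when active) a progressive outward swing of the TM6
  intracellular third over the second half of the frames that carries the
  lock to 12.5 A, plus a pseudo-ligand against the extracellular ends of
  TM5/TM6.  Helices are 31 residues rather than a shorter bundle so that
  6.30 exists and sits at the intracellular end while 6.48 stays near the
  membrane middle.

These fixtures emulate the *measured signatures* of activation, not its
physics: there are no force fields, no solvent, no side-chain rotamers
beyond the atoms the detectors read, and contact events are independent
Bernoulli draws rather than cooperative transitions.  Passing tests
therefore demonstrate that the estimators recover known truth at realistic
noise and autocorrelation scales — not that any particular real receptor
behaves this way.

## Numerical choices and degenerate inputs

* Superposition uses the SVD (Kabsch) solution with the determinant
  correction; fewer than 3 atoms or collinear selections raise degenerate-
  fit errors.
* RMSF superposes to the mean structure with two mean-refit passes.  The
  least-squares fit absorbs 6 rigid degrees of freedom of 3N, which
  slightly deflates fluctuations on small systems (factor
  `sqrt(1 - 6/(3N))` under isotropic noise); tests account for it.
* Circular means with resultant length below 1e-12 are undefined and raise
  an error rather than returning an arbitrary angle.
* Generators are pure functions of spec + seed: they snapshot and restore
  the caller's RNG state, so the same seed is bit-reproducible regardless
  of the surrounding session.
* All randomized tests and the acceptance script use fixed or derived
  seeds below 2^31.

Problem sizes used throughout the test-suite and the acceptance script —
8000-frame lock chains, 5000-frame occupancy runs, 10000-frame correlation
runs, 200-frame pseudo-receptor ensembles — were chosen so that sampling
error is comfortably below each tolerance under the standard-error
calculations given in the tests.

## Command-line interface

The package's interface is its exported functions plus `run_pipeline()`,
which executes the whole two-ensemble comparison from a YAML or list
configuration, writes TSV/CSV tables, a JSON summary and a provenance
record (package version, config hash, per-stage parameter echo), and is
deterministic given config + inputs + seed.  `validate_config()` reports
every configuration violation at once.  A separate shell binary would add
nothing over `Rscript -e 'gactdyn::run_pipeline("config.yaml")'`, so none
is shipped.

## Known limitations

* Wobble/face-shift sign conventions are self-consistent but may differ
  from other kink-analysis software by fixed offsets; compare differences,
  not absolutes.
* The hydrogen-bond donor inference requires hydrogens within 1.25 A in
  frame 1; topologies with unusual protonation need explicit curation.
* No pi-stacking, cation-pi or water-mediated bridge detection.
* The PDB reader handles coordinate records and MODEL blocks only; it is
  not a general PDB validator.
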