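# gactdyn

Trajectory analysis of class A GPCR activation dynamics from molecular
dynamics coordinate ensembles, for structural bioinformaticians comparing a
ligand-bound (test) ensemble against a reference (e.g. apo) ensemble.

Class A receptors activate through a conserved mechanical relay: agonist
contacts at the extracellular face perturb backbone torsions, the TM6
proline kink and the W6.48 toggle switch, and the intracellular end of TM6
swings outward, breaking the R3.50–E6.30 "ionic lock".  `gactdyn` measures
each link of that relay from coordinate frames:

* **Ionic lock** — per-frame distance between charge centers,
  d(t) = |mean(CZ, NH1, NH2) − mean(CD, OE1, OE2)|, with the broken
  fraction P(d > θ) over the analysis window (θ = 5.0 Å by default).
* **Kink geometry** — per-frame helix-axis fits give the **bend**
  arccos(û_pre · û_post), the **wobble** (signed bend direction about the
  pre-axis, measured from the kink-residue Cα radial vector) and the
  **face shift** (circular-mean phase offset of the post-helix relative to
  the extrapolated pre-helix twist).
* **Dihedral statistics** — φ/ψ/χ1/χ2 series with circular means/SDs and a
  first-half vs second-half transition flag.
* **Differential contact networks** — salt-bridge, hydrogen-bond and
  hydrophobic occupancies per residue pair; Δf = f_test − f_ref, negative
  when an interaction breaks in the test ensemble.
* **Collective motion** — combined PCA of concatenated ensembles
  (contribution_k = λ_k / Σλ · 100%), DCCM
  C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩), windowed correlation
  fractions, RMSD/RMSF and helix-end projections on the membrane plane.

A synthetic-trajectory module generates ensembles with known ground truth
(kink angles, lock-open fraction under a dwell-autocorrelated Markov chain,
designed contact occupancies and motion correlations, and a seven-helix
pseudo-receptor with an activation-like TM6 swing), so every estimator is
validated by round-trip recovery rather than by eye.

## Worked example

```r
library(gactdyn)

active   <- make_pseudo_receptor(n_frames = 200, activation = TRUE,  seed = 7)
inactive <- make_pseudo_receptor(n_frames = 200, activation = FALSE, seed = 8)

ionic_lock_series(active$frames,   active$map)
ionic_lock_series(inactive$frames, inactive$map)

ca  <- select_atoms(active$frames$topology, "name CA and protein")
combined_pca(list(active$frames, inactive$frames), ca)

kh <- make_kinked_helix(helix_spec(11), helix_spec(11),
                        kink_spec(34.5, -63.1, 89.3, 11))
prokink_angles(kh, 11, 1:11, 12:22)
```

prints

```
<gact_lock_series> R321(3.50)-E601(6.30) [ACTIVE]: mean 6.52 A, broken 47.5% (> 5.0 A)
<gact_lock_series> R321(3.50)-E601(6.30) [INACTIVE]: mean 4.51 A, broken 0.0% (> 5.0 A)
<gact_pca> 651 modes; EV1 51.78%, EV2 0.38% of total variance
<gact_kink_series> 1 frames: bend 34.50, wobble -63.10, face shift 89.30
```

The active ensemble's lock is broken in 47.5% of frames while the inactive
lock never opens; the leading combined-PCA mode (≈52% of the pooled
variance) is the designed TM6 intracellular swing separating the two
ensembles; and the kink analysis recovers the construction angles of a
synthetic kinked helix exactly.  `run_pipeline()` executes the same
comparison end-to-end from a YAML config (ensemble PDBs + segment table)
and writes TSV/CSV tables, a JSON summary and a provenance record.

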