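# hairpinfel

Conformational-ensemble analysis of beta-hairpin peptides in R.

## The problem

Two homologous 19-residue peptides from the loop region of laminin LG4
modules behave very differently: EF1 (`DYATLQLQEGRLHFMFDLG`) folds into a
stable antiparallel beta-hairpin and promotes cell attachment, while EF2
(`DFATVQLRNGFPYFSYDLG`) frays and does not. The difference tracks the
*census* of non-covalent interactions the sequence can form across the
hairpin register: EF1 supports 8 stabilizing pairs (4 hydrogen-bonded
register pairs, 3 facing hydrophobic pairs, 1 central ionic pair), EF2
only 6 — and EF2 is missing exactly the outermost hydrophobic pair that
pins the termini.

`hairpinfel` is for structural bioinformaticians and molecular modellers
who want to run this style of analysis on hairpin ensembles — their own
multi-model PDB ensembles or the package's built-in coarse-grained
sampler — without an all-atom MD stack.

## What it computes

* **Sequence census** — four-group polarity classification; positional
  facing pairs (i, L−i); the eight register hydrogen bonds HB1–HB8;
  hydrophobic and ionic pair counts and totals.
* **Descriptors** — Kabsch-superposition RMSD series, radius of gyration
  (mass-weighted), per-atom RMSF about the iterated mean structure with
  strand-split fitting, Shrake–Rupley SASA on a deterministic Fibonacci
  lattice.
* **Secondary structure** — Kabsch–Sander H-bond energies
  (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond below
  −0.5), DSSP-style codes E/B/H/G/T/C, per-frame beta-sheet rate.
* **Register H-bond tracking** — per-frame H⋯O lengths and formed counts
  under a geometric criterion (N⋯O ≤ 0.35 nm, angle ≤ 30°).
* **Time series & landscapes** — raw and normalized autocorrelation
  C(t) = (1/(N−j)) Σ f(iΔt) f((i+j)Δt); free-energy maps over (RMSD, Rg)
  by Boltzmann inversion ΔG = −k_B T ln(P/P_max) with k_B = 0.0083145
  kJ/mol/K; basin extraction at ΔG thresholds (1.5 / 2.5 kJ/mol);
  trajectory overlay and basin occupancy.
* **Synthetic ensembles** — a Gō-type torsion-space model whose wells are
  generated from the sequence census, sampled by replica-exchange
  Metropolis Monte Carlo over a temperature ladder (packaged 48-replica
  300–450.5 K protocol, or geometric ladders), fully seed-deterministic.

## Worked example

```r
library(hairpinfel)

noncovalent_census(hairpin_peptide("EF1"))
#> <noncovalent_census> EF1: 4 H-bond register + 3 hydrophobic + 1 ionic = 8 pairs
noncovalent_census(hairpin_peptide("EF2"))
#> <noncovalent_census> EF2: 4 H-bond register + 2 hydrophobic + 0 ionic = 6 pairs

run  <- generate_ensembles("EF1", seed = 1)   # REMD, 8 replicas, ~5 s
traj <- run$trajectories[[1]]                 # demultiplexed 300 K analog
ref  <- build_hairpin(hairpin_peptide("EF1"))

rmsd_series(traj, ref)
#> <descriptor_series> RMSD: 1080 frames, mean 0.3697 (sd 0.1111) nm
rg <- rg_series(traj)
#> <descriptor_series> Rg: 1080 frames, mean 0.8581 (sd 0.0468) nm

fel <- free_energy_map(rmsd_series(traj, ref)$values, rg$values,
                       temperature = 300)
basin_extract(fel, threshold = 2.5)
#> <fel_basin> dG <= 2.50 kJ/mol: 26 bins, RMSD 0.220-0.440 nm,
#>             Rg 0.800-0.920 nm (occupancy 0.49)

hbond_trace(traj, hbond_register(hairpin_peptide("EF1")))
#> <hbond_traces> 8 bonds, 1080 frames; count 2.10 (1.18)
#>  bond     length_nm
#>   HB1 0.721 (0.360)
#>   HB2 0.484 (0.264)
#>   ...
#>   HB8 0.199 (0.029)
```

Read the trace: the basin around the global minimum spans RMSD
0.22–0.44 nm — the folded hairpin with partially frayed termini. The
per-bond length gradient (HB1 at the termini broken near 0.72 nm, HB8 at
the turn held at 0.199 nm) is the turn-outward fraying signature; the
EF2 profile loses more of the ladder, holds fewer bonds on average, and
its basin is wider. `run_pipeline(pipeline_config(...))` runs every stage
and writes CSV/JSON artifacts with a summary report.

Ensembles can also come from disk: `read_pdb_models()` ingests
multi-model PDB files (coordinates converted to nm), and
`write_pdb_models()` writes them back.

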