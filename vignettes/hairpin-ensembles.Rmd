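---
title: "Analyzing beta-hairpin conformational ensembles with hairpinfel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing beta-hairpin conformational ensembles with hairpinfel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinfel)
```

## The scientific problem

Two 19-residue peptides from the loop region of laminin LG4 modules ask a
sharp structural question. EF1 (`DYATLQLQEGRLHFMFDLG`, alpha1 chain)
promotes cell attachment and folds into a stable two-strand antiparallel
beta-hairpin; its close homolog EF2 (`DFATVQLRNGFPYFSYDLG`, alpha2 chain)
does not promote attachment, and its hairpin frays. The working hypothesis
this package operationalizes is combinatorial: fold stability is set by the
*census* of non-covalent interactions the sequence can form across the
hairpin — the inter-strand backbone hydrogen bonds of the register, the
facing hydrophobic pairs that alternate with them, and any salt bridge near
the turn. EF1 supports 8 such pairs, EF2 only 6, and EF2 is missing
precisely the outermost hydrophobic pair that pins the termini.

`hairpinfel` implements the full analysis chain used to interrogate this
picture — interaction census, structural descriptors, secondary structure,
per-bond hydrogen-bond tracking, autocorrelation, and free-energy
landscapes with basin extraction — together with a coarse-grained sampler
that generates hairpin ensembles with exactly the census-controlled
stability contrast, so every stage can be exercised end to end without
all-atom molecular dynamics.

## The positional register and the census

For a hairpin of length $L$ with a two-residue turn, residue $i$ on the
N-strand faces residue $L-i$ on the C-strand. Even-index facing pairs
carry two backbone hydrogen bonds each (amide of $i$ to carbonyl of
$L-i$ and vice versa); for $L=19$ these are the pairs
$(2,17), (4,15), (6,13), (8,11)$, giving the eight bonds labelled
HB1–HB8, ordered from the termini toward the turn. Odd-index pairs where
both residues are non-polar are counted as hydrophobic contacts. Possible
ionic pairs are detected by a deterministic heuristic: oppositely charged
residues within sequence separation 2, both inside the central five
positions around the turn. The heuristic is intentionally positional (not
structure-derived): the census is a property of the sequence.

Residues are classified into four groups — positively charged polar
(R, K, H), negatively charged polar (D, E), uncharged polar
(S, T, N, Q, Y, C, W) and non-polar (A, V, L, I, M, F, P, G). Two
assignments deserve comment: histidine is counted as positively charged
(it sits at a register position unused by either census, so the choice is
count-neutral here), and tyrosine is uncharged polar, which is what makes
EF2's (3,16) pair (Ala–Tyr) a non-contact while EF1's (Ala–Phe) counts.

```{r census}
noncovalent_census(hairpin_peptide("EF1"))
noncovalent_census(hairpin_peptide("EF2"))
```

## Structural descriptors

**RMSD.** Frames are superposed on a reference by the Kabsch algorithm
(SVD of the weighted covariance, reflection branch corrected), then the
root-mean-square deviation is evaluated on a chosen atom selection. The
default "main-chain" selection is {N, CA, O}; the carbonyl carbon can be
added with `include_c = TRUE`. The three-atom default follows the
convention of reporting amide nitrogen, chiral carbon and oxygen; since
selections are explicit arguments, either convention is one flag away.

**Radius of gyration.** Mass-weighted by default
($R_g = \sqrt{\sum_i w_i \lVert r_i - r_\mathrm{com}\rVert^2 / \sum_i w_i}$),
with an unweighted switch. The CB pseudo-atom counts as carbon.

**RMSF.** Per-atom fluctuation about the time-average structure. The
reference is built by an iterated fit: superpose all frames on the mean of
the raw frames, re-average, re-fit (two rounds), a standard convention for
making the mean structure self-consistent. Fitting can be restricted to a
residue range; fitting only the N-side strand (residues 1–10) and reading
CA fluctuations strand by strand exposes which half of the hairpin frays.
Whether the C-strand panel of such an analysis should re-fit on residues
11–19 or reuse the N-strand fit is genuinely ambiguous; both modes are
available through `fit_residue_range`.

**SASA.** Shrake–Rupley with a deterministic Fibonacci sphere lattice
(no RNG, so results are bit-stable), probe radius 0.14 nm, default 960
points for single frames. Radii are Bondi-type for backbone N, C, O; the
CB pseudo-atom carries one of three side-chain size classes (0.20 /
0.25 / 0.30 nm for small / medium / large side chains). Because a
coarse-grained surface model's absolute areas depend strongly on this
radius set, absolute SASA values are not comparison targets; differences
and time-variation within one model are.

## Secondary structure and the beta-sheet rate

Backbone hydrogen bonds use the Kabsch–Sander electrostatic criterion,
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol (distances in Angstrom), with a bond declared below
$-0.5$ kcal/mol. Amide hydrogens are taken from the frame when present
and otherwise reconstructed 1.01 Angstrom from N along the direction
opposing the bisector of N→CA and N→C(prev); proline has no donor.
Assignment follows the DSSP bridge and turn rules: antiparallel or
parallel bridges give B, runs of two or more bridged residues give E,
double $i \to i+4$ turns give H, $i \to i+3$ give G, isolated turns T,
else C, with priority H > E > B > G > T > C. The per-frame beta-sheet
rate is the fraction of residues coded E; whether isolated bridges (B)
should count is not a settled convention, so `count_b` exposes both.

## Register hydrogen-bond tracking

For each HB1–HB8 the package records the H⋯O distance per frame and a
formed/broken flag. "Length" is the hydrogen–acceptor distance: formed
bonds then average near 0.20 nm, the scale a donor–acceptor (N⋯O)
distance cannot reach (~0.29 nm), which is how the convention was fixed.
The formation criterion is geometric — N⋯O ≤ 0.35 nm and H–N–O angle
≤ 30° — the common MD-analysis default, and configurable, since no
universal criterion exists. On ideal geometry every geometrically formed
register bond also passes the Kabsch–Sander energy test, which the test
suite asserts as a cross-module consistency property.

## Autocorrelation

Two estimators are provided. The raw product estimator
$C(j\Delta t) = \frac{1}{N-j}\sum_{i=0}^{N-1-j} f(i\Delta t) f((i+j)\Delta t)$
and the mean-subtracted, lag-0-normalized variant that decays from 1
toward 0 for a mixing process. The raw form is the literal definition;
it neither subtracts the mean nor normalizes, so for a quantity with a
non-zero mean it plateaus at the squared mean rather than decaying to
zero. Because published figures are usually of the normalized kind, both
are exposed and the variant is always recorded in the result.

## Free-energy landscapes

Given reaction-coordinate samples (RMSD, $R_g$), the landscape is the
Boltzmann inversion of the 2D histogram:
$\Delta G = -k_B T \ln\left( P(x,y) / P_{max} \right)$, with
$k_B = 0.0083145$ kJ/mol/K so maps carry kJ/mol. The sign is chosen so
that $\Delta G \ge 0$ with 0 at the most-populated bin — the convention
required for thresholds like "the region where $\Delta G$ is at most
1.5 kJ/mol around the global minimum" to make sense. Numerical choices:

* bin width 0.02 nm on both axes by default, data range padded by one
  bin; a `bins` argument overrides;
* empty bins are undefined (NA), never capped — a capped value would
  silently enter basin connectivity;
* the basin around the global minimum is the 8-connected component of
  sub-threshold bins containing the $\Delta G = 0$ bin; 8-connectivity is
  deliberately tolerant of sparse desk-scale sampling;
* basin RMSD/$R_g$ ranges are reported as the outer edges of member bins.

`basin_extract` reports the global-minimum basin at a threshold
(conventionally 1.5 kJ/mol for the vicinity of the minimum, 2.5 kJ/mol
for the region around its bottom), `local_minima` enumerates all
sub-threshold components, and `overlay_trajectory` maps an independent
trajectory onto a landscape to measure basin occupancy.

The core correctness oracle for this module is Boltzmann recovery:
Metropolis samples of a known 2D double-well potential, fed through
`free_energy_map`, must reproduce the quadrature-computed inter-well
free-energy difference within stochastic tolerance. This is asserted in
the test suite over ten seeded repeats.

## The synthetic-data model

The sampler is a Gō-type coarse-grained model in torsion space:

* **Geometry.** Each residue contributes backbone N, H, CA, C, O and a
  CB pseudo-atom (no CB for glycine, no amide H for proline or the
  first residue). Atoms are placed by sequential internal-coordinate
  construction (NeRF) with standard bond lengths and angles (N–CA
  1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, omega fixed at 180°); only phi/psi
  are degrees of freedom.
* **Ideal hairpin.** Packaged torsion constants close the 19-mer into an
  antiparallel hairpin with all eight register H⋯O distances at 0.20 nm:
  beta-strand angles near (−139°, 135°) and a type-II'-like turn at
  positions 9–10. They were obtained once by minimizing the built chain's
  register distances with a clash penalty, and are frozen — the tuning is
  not re-run at build time.
* **Energy.** Census-derived attraction wells — one bounded Gaussian
  $-w\,e^{-((d-r_0)/\sigma)^2}$ per register H-bond (on H⋯O, $r_0$ =
  0.20 nm) and per hydrophobic/ionic pair (on CB⋯CB, $r_0$ from the
  ideal structure: 0.465 / 0.54 nm) — plus soft-sphere repulsion between
  CA/CB atoms more than two residues apart and a weak cosine bias of each
  torsion toward its ideal-hairpin value (the Gō-type stand-in for local
  backbone propensity). Reduced units with $k_B = 1$.
* **Sampling.** Metropolis sweeps of single-torsion and crankshaft moves
  with full-chain rebuild per proposal, and a replica-exchange driver:
  replicas at a temperature ladder propagate independently between
  exchange attempts; attempts alternate even/odd neighbor pairings and
  accept with $\min(1, e^{(\beta_i-\beta_j)(E_i-E_j)})$. Ladder
  temperatures in kelvin map to reduced temperature as $T/300$, so the
  300 K analog is reduced temperature 1. Frames are demultiplexed by
  temperature, and the first 10% of sweeps are discarded as burn-in.

**Calibration.** The energy scale was set once to the physical regime the
model must emulate: a marginally stable hairpin whose folding midpoint
lies inside the 300–450.5 K analog ladder, with *gradual terminal
fraying* rather than two-state unfolding. Hydrogen-bond wells are
deliberately weaker than contact wells ($w_{hb} = 3$, $w_{phob} =
w_{ionic} = 6$): individually weak, solvent-exposed outer backbone bonds
with collectively decisive side-chain contacts is the regime in which the
outermost contact pair controls how deep terminal fraying proceeds — the
mechanism the EF1/EF2 contrast probes. With these defaults the EF1-like
profile holds more register bonds, shows a narrower $\Delta G \le 2.5$
kJ/mol basin along RMSD, and fluctuates less over residues 4–14 than the
EF2-like profile, across seeds.

**What the generator does and does not emulate.** It reproduces the
statistical structure the analysis assumes: register-dependent bond and
contact stabilities, temperature-dependent fraying, and the
census-controlled EF1 > EF2 stability ordering. It has no explicit
solvent, no force-field realism, no side chains beyond CB, and makes no
attempt to reproduce absolute trajectory-derived values (bond counts,
SASA, basin boundaries) of any all-atom study; passing tests demonstrate
that the *analysis chain* is correct and directionally faithful, not that
the toy model is quantitatively predictive of real peptides.

## Study conditions and problem sizes

The packaged desk-scale conditions are: 8 replicas in geometric
progression over 300–450.5 K (the packaged 48-replica ladder is
available via `remd_ladder(mode = "table2")` for protocol work), 6000
sweeps per replica, exchange attempts every 10 sweeps, one frame saved
per 4 sweeps, 10% burn-in — about 1100 frames per temperature. One such
run takes a few seconds on one core. The test suite uses shorter runs
for unit properties and the full conditions for the contrast experiment.

## Worked example

```{r example, eval = FALSE}
run <- generate_ensembles("EF1", seed = 1)
traj <- run$trajectories[[1]]        # 300 K analog, demultiplexed
ref  <- build_hairpin(hairpin_peptide("EF1"))

rms <- rmsd_series(traj, ref)
rg  <- rg_series(traj)
fel <- free_energy_map(rms$values, rg$values, temperature = 300)
basin_extract(fel, threshold = 2.5)

hbond_trace(traj, hbond_register(hairpin_peptide("EF1")))
sheet_rate_series(traj, stride = 5)
```

## Known limitations

* The ionic-pair rule is a sequence heuristic, not a structural salt
  bridge detector; it exists to make the census well-defined.
* The coarse-grained SASA radius classes make absolute areas
  model-specific.
* `local_minima` separates basins by histogram connectivity only; two
  wells joined by a sampled saddle below the threshold merge.
* The sampler's crankshaft move is a torsion-space approximation (phi/psi
  counter-rotation), not a Cartesian local move; acceptance rates, not
  kinetics, are meaningful.
* Packaged ideal torsions exist for the 19-residue geometry; other
  lengths require supplying a `torsion_state`.
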