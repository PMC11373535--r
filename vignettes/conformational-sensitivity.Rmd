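---
title: "Conformational sensitivity of predicted chemical shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational sensitivity of predicted chemical shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csens)
```

## The question and the statistic

Intrinsically disordered proteins are described by conformational ensembles,
and a common way to refine such ensembles is to reweight them against
experimental NMR chemical shifts.  Reweighting only works if the observable
actually separates conformations: a shift that looks the same for a compact
and an extended state carries no conformational information.  `csens`
quantifies that separation for *predicted* shifts.

The experimental design it supports is two groups of $n$ (typically five)
near-identical configurations, one group per macroscopic conformation
(here labelled *stretched* and *globular*).  For each atom this yields two
samples of predicted shifts, treated as $n$ independent measurements of each
conformation.  Assuming the two distributions are Gaussian with a common
spread, the pooled standard deviation

$$ s_p = \sqrt{\frac{(n_s-1)s_s^2 + (n_g-1)s_g^2}{n_s+n_g-2}} $$

defines the natural unit, and the **conformational sensitivity** of the
atom's shift is

$$ \varsigma = \frac{|\bar\delta_s - \bar\delta_g|}{s_p}. $$

A shift is called *conformationally sensitive* when the overlap of the two
equal-spread Gaussians is below 10%.  The overlap of two unit-variance
normals separated by $d$ is $2\Phi(-d/2)$ (each tail beyond the midpoint
crossing contributes $\Phi(-d/2)$), and inverting it at 10% gives
$d = 3.29$:

```{r}
overlap_threshold_separation(0.10)
```

The comparison is strict ($\varsigma > 3.29$): "overlap below 10%" excludes
the boundary, and the worked 3.0-sigma example is classified not sensitive
either way.

Key properties of the statistic, all asserted in the test suite: it is
invariant under a common affine rescaling of all shifts (so referencing
conventions cannot change it), the estimator at $n = 5 + 5$ has the
noncentral-$t$ sampling distribution (its aggregate bias factor
$\sqrt{df/2}\,\Gamma((df-1)/2)/\Gamma(df/2)$ at $df = 8$ is about 1.11), and
with a true separation of 0 the false-positive rate of the 3.29 rule is
$2\,P(t_8 < -3.29\sqrt{5/2}) \approx 4\cdot10^{-4}$.

## Pipeline stages

**Structure input and frame selection.**  Multi-model PDB files are read one
conformer per MODEL; waters (HOH/WAT/SOL) and ACE/NME cap groups are
flagged.  Frames are selected by the backbone radius of gyration (most
stretched = maximum, most globular = minimum) and each group is completed
with the $k = 4$ most similar frames.  "Similar" is backbone heavy-atom RMSD
after Kabsch superposition -- the metric is a package decision, since group
RMSD values are conventionally reported without naming the superposition
selection.  Ties in all argmin/argmax selections break to the lowest frame
index for determinism.

**Fragmentation.**  Quantum shielding calculations cannot treat a solvated
peptide whole, so one fragment is built per central unit, where central
units are all amino acids *plus* the two terminal cap groups (a 31-residue
capped peptide yields 33 fragments).  A fragment contains every residue or
end group with at least one atom (hydrogens included) within 4.0 Å of the
central unit; the boundary is inclusive.  Chain breaks are capped with ACE
(built from the excluded N-side neighbour's C, O, C$\alpha$, the C$\alpha$
becoming the acetyl methyl carbon) or NME (from the excluded C-side
neighbour's N, H, C$\alpha$); cap methyl hydrogens are placed with ideal
tetrahedral geometry and no optimisation.  A proline neighbour has no amide
H; rather than failing, the NME H is built in-plane at 1.01 Å.  Original
termini are never re-capped.  Micro-solvation keeps whole waters with any
atom within the cutoff of the central unit, geometry untouched.

**Referencing.**  DFT methods produce isotropic shieldings $\sigma$, not
shifts.  ¹H and ¹³C are referenced against calculated TMS,
$\delta_X = \sigma^{calc}_{TMS} - \sigma^{calc}_X$; ¹⁵N uses methylamine as
a calculated secondary standard placed on the ammonia scale with the two
literature absolute shieldings (NH₃ 244.6 ppm, CH₃NH₂ 249.5 ppm):
$\delta_X = \sigma^{calc}_{CH_3NH_2} - \sigma^{calc}_X + (244.6 - 249.5)$.
The fixed offset, $-4.9$ ppm, is determined solely by the two constants;
both referencing branches are affine with slope $-1$ in $\sigma_X$.  After
referencing, each fragment contributes only its central residue's shifts to
the peptide table, and every residue must be central exactly once.

**Exclusions and categories.**  Cap-group and oxygen shifts are excluded
before analysis (rarely measured, hence useless for reweighting).  Remaining
atoms are categorised as C$\alpha$, C$_{carbonyl}$, H$_{amide}$,
N$_{amide}$, C$\beta$, C$_{other}$, H$_{other}$, N$_{other}$.  The source
material counts "seven groups" but lists these eight labels; all eight are
implemented and empty categories simply do not appear in reports.

**Aggregation.**  Per-residue sensitivity is the mean over backbone atoms
plus C$\beta$, or a named single atom.  Across prediction methods, the
agreement matrix counts per-atom sensitive votes, with a not-computed entry
counting as no vote; the conventional flagging threshold is at least 4
agreeing methods.

**Validation.**  Agreement with experiment is the mean relative error
$\mathrm{MRE} = \langle |\delta^{sim}_{mean} - \delta^{exp}| / |\delta^{exp}|
\rangle$ over joined atoms; atoms with $\delta^{exp} = 0$ are excluded with
a warning, and because ¹H shifts near 0 ppm inflate relative errors a
per-element breakdown is reported alongside the pooled number.  Secondary
shifts use the modern sign convention $\Delta\delta = \delta_{obs} -
\delta_{rc}$ against a user-supplied random-coil table, and
$\Delta\Delta\delta_{\alpha\beta} = \Delta\delta_{C\alpha} -
\Delta\delta_{C\beta}$ calls alpha above $+1.0$ ppm, beta below $-1.0$ ppm,
random coil otherwise -- the 1 ppm threshold is deliberately coarse and
conventional.

**Feature importance.**  To ask *which* atom properties predict
sensitivity, a per-atom feature table is built: atom category/name/element,
residue name/number, signed changes (stretched minus globular, matching the
"switching from globular to stretched" direction used throughout) in
distance to the nearest oxygen / nitrogen / residue centre of geometry at
sequence separation of at least three residues, backbone $\Delta\phi$ and
$\Delta\psi$, per-atom $\Delta$SASA (Shrake–Rupley, probe 1.4 Å), a
side-chain flag, per-atom alignability (mean self-distance over member pairs
after superposition onto the group's central member, averaged over the two
groups), and two negative controls (uniform real on [0, 20]; uniform
integer on {0, ..., 6}, inclusive bounds).  A random-forest regressor (100
trees, squared-error splits, 80/20 split, `min_samples_leaf` 10,
`min_samples_split` 15, `max_depth` 10) is trained 50 times under different
seeds; repeats with negative test $R^2$ are dropped, and permutation
importance is the mean test-$R^2$ drop over 10 joint shuffles of each
feature's encoded columns.  One-hot blocks are shuffled jointly so both
encodings yield feature-level importances; ordinal encoding remains
available for whole-feature questions.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| environment cutoff | 4.0 | Å | first-shell interaction distance; all-atom, inclusive |
| sensitivity threshold | 3.29 | pooled σ | 10% Gaussian overlap; strict inequality |
| agreement vote threshold | 4 | methods | "at least four of nine" convention |
| SASA probe / points | 1.4 / 240 | Å / – | water probe; total converges < 1% on doubling |
| ΔΔδ call threshold | 1.0 | ppm | conventional coarse cut |
| forest | 100 trees, depth 10, leaf 10, split 15 | – | stated protocol |
| repeats / shuffles | 50 / 10 | – | repeats stated; shuffles a package choice |
| min sequence separation (Δ-distance) | 3 | residues | "at least three amino acids away" |

## The synthetic world

`synthetic_spec()` states the world the generator emulates: a 31-residue
ACE/NME-capped peptide, one extended backbone ($\phi, \psi$ = −135°, 135°)
and one compact one (−75°, −30°), five configurations per group, and
per-method shift tables in which each atom's two groups are Gaussian with a
planted mean separation in units of the within-group standard deviation
(default 0.1 ppm, nine pseudo-methods to exercise the agreement matrix at
the study's method count).  Chains are built with ideal bond geometry
(N–C$\alpha$ 1.458 Å, C$\alpha$–C 1.525 Å, C–N 1.329 Å, trans ω), and the
built chain's dihedrals recover the targets to numerical precision -- that
recovery is itself a test.  Replicas beyond the central member get iid
Gaussian coordinate jitter (default sd 0.5 Å, giving within-group backbone
RMSDs of the order reported for the study's two groups).  Everything is
deterministic under the spec seed, with documented sub-seeds for geometry
(seed) and shifts (seed + 10⁶).

The experimental table is constructed as the per-atom ensemble mean divided
by $1 + f$, so the ensemble mean has a mean relative error of *exactly* $f$
against it (the exactness is what makes the round-trip testable); the
random-coil table is the experimental table minus planted offsets, making
chosen $\Delta\Delta\delta_{\alpha\beta}$ values exact by construction.

What the generator does **not** emulate: replica variation as collective
backbone motion (the jitter is iid Cartesian noise, so alignability is
spatially unstructured), any physical relation between structure and shift
(planted separations are assigned, not computed from geometry), solvation
thermodynamics, side chains beyond C$\beta$, and predictor-specific error
structure.  A green recovery test therefore establishes that the
*estimator and classification machinery* recover planted truth at the
stated sample sizes -- not that any real predictor is conformationally
sensitive.

## Numerical choices and degenerate inputs

- Angles live in (−180°, 180°]; dihedral differences are wrapped to the
  same interval, so $\Delta$(170°, −170°) = 20°.  Group-mean dihedrals are
  circular means.
- Terminal residues without a peptide neighbour get `NA` angles, never 0.
- `pooled_sd = 0`: sensitivity is 0 when the means agree and `Inf`
  otherwise (`Inf` classifies as sensitive).  The generator keeps a nonzero
  planted separation (1 ppm per σ unit) when the within-group sd is zero,
  so the divergent case is exercisable.
- Atoms are matched across conformers and methods by
  (`residue_number`, `atom_name`); PDB serial numbers are never trusted.
- The negative controls are *re-drawn under each repeat's seed* inside
  `fit_importance()` (the stated protocol re-seeds the whole procedure per
  repeat).  With a single fixed draw, a control's chance correlation with
  the label is a dataset-level constant: it does not average out over
  repeats, while the standard error of the mean shrinks, so the
  "indistinguishable from zero" check would fail for almost any dataset.
  Redrawing makes the check coherent; `redraw_controls = FALSE` restores
  fixed columns.
- Hydrogens get a 1.10 Å radius in the SASA so that every atom, including
  H$_{amide}$, has a defined $\Delta$SASA feature.
- SASA quadrature uses a deterministic golden-spiral grid; per-atom areas
  of nearly buried atoms carry large relative quadrature noise at any
  sensible point count, so convergence is judged on totals.

## Limitations

- The PDB reader handles the common fixed-width ATOM/HETATM + MODEL dialect
  only (no insertion codes, altloc handling, or mmCIF).
- No slope/intercept regression re-referencing of shieldings; a single
  reference point per element is used by design.
- The random-forest implementation is a compact CART forest sufficient for
  the stated protocol; it does not expose OOB estimates or parallelism.
- Plotting parity with the study's figures is out of scope; all results are
  tables.
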