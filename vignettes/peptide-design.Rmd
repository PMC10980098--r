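---
title: "Structure-guided multi-objective peptide design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided multi-objective peptide design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepforge)
```

## The problem

Peptide binders are short amino-acid chains (typically under 20 residues)
designed to attach to a protein target. Sequence-only generative approaches
ignore the one thing that determines binding: the three-dimensional complex
the peptide forms with its target. pepforge implements the
structure-in-the-loop alternative: candidate peptide sequences are turned
into protein-peptide complex structures by a pluggable *structure provider*,
scored with objective functions computed directly on those structures, and
optimized with a multi-objective Bayesian-optimization (BO) loop that
balances exploration of sequence space against exploitation of what the
surrogate model has already learned.

The package separates three concerns:

1. **Structural objectives** — interface buried surface area, residue
   contact ("binding site") ratios, and a stability energy.
2. **The optimizer** — a Gaussian-process surrogate over a deterministic
   sequence embedding, driving a noisy-expected-hypervolume-improvement
   acquisition over batches of mutant sequences.
3. **Evaluation** — native-recovery metrics (Kabsch superposition, TM-score,
   binding-site-count match rates) for benchmarking against a known native
   complex.

Everything runs at desk scale on synthetic fixtures; the interfaces where a
GPU structure predictor or an empirical force field would plug in are
explicit adapter contracts (`external_provider()`, `external_energy()`).

## Structural objective functions

### Interface buried surface area

Solvent-accessible surface area (SASA) is computed with the Shrake–Rupley
method: each atom's van der Waals sphere is expanded by a probe radius of
1.4 Å (an idealized water molecule) and sampled with a deterministic
golden-spiral lattice; a sample point is exposed when it lies inside no
other expanded sphere. Per-atom area is the exposed fraction of
$4\pi (r_i + p)^2$.

The *interface* (buried) area of a complex is

$$\mathrm{SASA}_{\text{protein}} + \mathrm{SASA}_{\text{peptide}} -
  \mathrm{SASA}_{\text{complex}},$$

with each term computed on the rigid split — the partner's atoms are
deleted, nothing is re-relaxed — so the subtraction isolates exactly the
surface hidden by binding.

Numerical choices:

* **Lattice size** defaults to 960 points per atom, the classic choice for
  this algorithm; at 960 points, rigid-body motion of the whole complex
  changes totals by well under 0.5 % (the lattice has a fixed orientation),
  and two-sphere test systems agree with the closed-form spherical-cap area
  within 2 %. The count is a config field.
* **Clamping.** For well-separated chains the subtraction is analytically
  zero but can come out a few hundredths negative from discretisation; the
  value is clamped at zero and the raw difference kept in the `"raw"`
  attribute.
* **Radii.** A Bondi-style element table (C 1.70, N 1.55, O 1.52, S 1.80 Å,
  carbon-like default), override-able via `radii_table()`. Hydrogens are
  dropped at parse time: crystallographic structures rarely resolve them and
  heavy-atom radii sets account for them implicitly.
* **Direction.** In the optimizer the buried area is *maximized* by default
  (more buried interface = tighter packing), but the direction is a config
  field. This is deliberate: published optimization traces of this family of
  workflows show interface-SASA *declining* over rounds, which is consistent
  with minimizing a differently-signed convention, and the convention is not
  fully standardized; rather than guess, the package makes the direction
  explicit per objective.

### Binding sites and binding ratios

Two residues are in contact when the minimum distance over their heavy-atom
pairs is **strictly** below 5 Å — the standard residue-contact criterion for
protein–peptide interfaces; the strictness at the boundary is tested even
though exact ties are measure-zero. A chain's *binding ratio* is the number
of its residues in contact with the partner chain divided by its residue
count. Which side (protein, peptide, or their mean) enters the optimizer as
a scalar objective is a config choice (`binding_side`, default protein):
both are standard summaries and neither is canonical, so the package
computes both and lets the run choose. A Cα-only distance mode exists for
coarse structures.

### Stability energy

The package's self-contained stability objective is an inter-chain
square-well contact potential: −1 per heavy-atom pair in the 2.5–5 Å well,
+10 per pair closer than 2.5 Å (a steric clash), zero beyond. Units are
arbitrary by design — objectives are standardised inside the surrogate, so
only the ordering of candidates matters. Intra-chain strain is deliberately
not scored: the objective tracks interaction stability. A real free-energy
calculator is wired in through `external_energy()`, a subprocess contract
(PDB path in, last stdout token out) whose every failure mode raises a
structured error rather than a silent default; which stability estimate the
external program reports is the user's choice.

## The optimizer

### Sequence embedding

BO needs a continuous representation of a discrete sequence. Learned
autoencoder embeddings require trained weights; pepforge instead uses a
deterministic physicochemical embedding: per residue, four z-scored
descriptors (Kyte–Doolittle hydropathy, net charge at pH 7, Zamyatnin
residue volume, a polarity flag) plus a 20-way one-hot identity, zero-padded
to `max_len` residues, with a normalised length feature appended. The map is
local (a substitution changes only its own 24-component block), which keeps
the GP's view of sequence space smooth under single mutations. The trade-off
is explicit: this embedding encodes chemistry, not learned context, and is
one of the two principal simplifications of the package (the other is the
template-threading provider below).

### Gaussian-process surrogate

One exact GP per objective (no inter-objective covariance — the multi-output
structure is not identifiable from the small per-round datasets this loop
produces), squared-exponential kernel, objectives standardised internally.
Hyperparameters (length-scale, signal variance, noise variance) maximise the
log marginal likelihood by L-BFGS from a fixed three-point start grid, so
fits are deterministic without a seed. One numerical subtlety: at very small
length-scales the likelihood surface has a ridge along which the
signal/noise split is unidentifiable; near-ties are broken toward the
lower-noise solution, which preserves the noiseless-interpolation property
(posterior mean through the data) that the rest of the machinery assumes.
Degenerate all-identical inputs get jitter and a warning.

### Acquisition: noisy expected hypervolume improvement

With two objectives the quality of an archive is its *hypervolume* — the
area of objective space dominated by the Pareto front relative to a
reference point. The acquisition for a candidate $x$ is

$$\alpha(x) = \mathbb{E}\big[\,\mathrm{HV}(F \cup \{f(x)\}) -
  \mathrm{HV}(F)\,\big],$$

where the expectation runs over the *joint* GP posterior of the latent
objective values at all observed points (forming the sampled noise-free
front $F$) and at the candidate. This joint-sampling construction is the
defining form of the noisy variant: the front itself is uncertain, so it is
integrated over rather than fixed at the observed means. The estimator is
Monte-Carlo (default 128 draws, seeded, base samples shared across
candidates); per draw, candidate contributions are computed against the
sampled front's staircase in a single vectorised sweep. Values are
non-negative by construction, and a candidate duplicating an observed front
point scores zero in the noiseless limit (up to a ~1e-5 sampling-jitter
floor). 2-D hypervolume itself is computed exactly by sort-and-sweep.

The reference point is recomputed each round as the componentwise minimum of
observed canonical objectives minus 10 % of the observed range — a standard
adaptive rule; archive-summary hypervolumes instead use the reference point
fixed after seed scoring, so the logged trace is guaranteed non-decreasing
as the pool grows.

### Candidate generation and the round loop

The loop defaults to 64 rounds with a batch of 16 — the budget used by the
benchmark workflow this package operationalises — with seeds drawn as random
mutants of the native peptide (default 16 at Hamming distance 2). Candidate
generation is *discrete*: each round proposes up to `n_candidates` (256)
unique single-point mutants of the current Pareto-archive parents, scores
them with the acquisition, and takes the top `batch_size`, ties broken
toward the lexicographically smaller sequence for determinism. This replaces
latent-space decoding (which needs a trained decoder) with local search
around the front — the package's principal deviation from
latent-space-native BO, chosen so the whole loop is self-contained and
reproducible. Natural-variant seed pools (e.g. homolog harvesting) can be
reproduced externally and supplied via the `seed_fasta` config key.

Other loop rules: the GP is refit from scratch each round (no warm start —
determinism beats the negligible saving at these data sizes); provider
failures mark the candidate `failed`, exclude it from the surrogate, and the
run continues, keeping evaluation budgets exact; the pool is unique by
sequence and grows monotonically; all randomness derives from the single
config seed, so identical configs give byte-identical archives on disk.

## Structure providers

`thread_template()` is the desk-scale provider: candidate sequences are
threaded onto the native complex by keeping all coordinates rigid and, at
each mutated position, replacing the side chain with a single pseudo-atom
along the template's Cα→Cβ direction. Both the pseudo-atom's radius and its
offset from Cα scale with the cube root of the residue volume (alanine lands
at the canonical ~1.5 Å Cα–Cβ length; real side-chain centroids do sit
farther out for bulkier residues). The offset scaling matters: the contact
energy and the binding-site criterion are functions of atom *positions*, so
a fixed-position pseudo-atom would leave them blind to sequence and the
optimizer would have nothing to learn from two of its three objectives.
Threading the native sequence returns the template bit-for-bit.

This provider is a geometric surrogate, not a structure prediction: no
repacking, no backbone relaxation, no rotamers. A real predictor is attached
via `external_provider()` (FASTA in, PDB path out), which is the documented
route to production use and is never required by the test suite.

## Synthetic fixtures and what they do (not) show

`make_toy_complex()` builds an extended protein chain (Cα spacing 3.8 Å, one
volume-scaled pseudo side-chain atom per residue) with a parallel peptide
whose side chains face it, in three modes: docked (contacts at the 5 Å
cutoff), separated (100 Å apart — every interface objective must be exactly
zero), and clashing (steric overlap — the clash penalty must dominate).

`make_recovery_landscape()` builds the fixture for end-to-end validation: a
docked complex plus threading provider in which the native sequence is the
*verified global optimum* of both default objectives. Each protein pocket
atom is placed so the native side chain sits just inside the contact well
(4.93 Å, against the 5 Å cutoff); any substitution shrinks that position's
side chain, which simultaneously reduces its buried area and pushes it out
of the contact well. Because buried area grows monotonically with side-chain
volume, a construction of this shape can only make a volume-maximal native
optimal — hence the all-tryptophan default native, and a warning for any
other. Optimality is verified by exhaustive enumeration of all 19·L single
mutants plus the per-position revert property on sampled 2- and 3-mutants
(full enumeration of all ≤3-mutants — 137,000 structures for a 6-mer — buys
no additional coverage given the per-position construction).

Passing on these fixtures demonstrates that the algorithms are correct and
that the loop can exploit a learnable structure–sequence coupling; it says
nothing about predictive validity on real complexes, which depends entirely
on the structure provider and energy model plugged in.

## Native-recovery evaluation

`kabsch()` computes the closed-form least-squares rigid superposition
(SVD of the cross-covariance, reflection corrected to a proper rotation;
collinear point sets are rejected because their rotation is not unique).
`tm_score()` superposes Cα traces and computes
$\frac{1}{L}\sum_i 1/(1 + (d_i/d_0)^2)$ with
$d_0 = 1.24\,(L-15)^{1/3} - 1.8$, floored at 0.5 Å for selections of 21
residues or fewer where the formula goes non-positive — the convention of
reference implementations for short chains. No alignment search is
performed: by construction the loop's candidates share the native peptide
length, so residue correspondence is positional; this is a documented
limitation, not an approximation of a full structural aligner.

`recovery_report()` summarises an archive against the native: the percentage
of candidates whose *peptide-side* binding-site count exactly matches the
native's, the best TM-score, the best candidate per objective, and the
per-round min/mean/max traces.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` exercise the full loop at sizes
chosen to make every property checkable by an independent oracle: toy
complexes of 3–14 protein and 3–6 peptide residues; a 6-mer recovery
landscape; guided-vs-random comparisons over 10 independent seeds at 10
rounds × batch 4 from 6 seeds (46 structure evaluations per arm); acquisition
estimates cross-checked against a 10^5-draw independent estimator; exact
hypervolumes against 10^6-point Monte-Carlo areas; and surface areas against
closed-form sphere/cap values and an independent reference implementation.
The defaults (64 × 16, 960 lattice points) remain the package's production
settings.

## Known limitations

* The physicochemical embedding carries no evolutionary or structural
  context; a learned embedding is strictly more expressive when trained
  weights are acceptable.
* Template threading cannot move the backbone, so candidates never change
  the binding mode; all structural variation is side-chain-scale.
* The contact potential has no electrostatics, solvation or intra-chain
  terms; its role is ordering candidates, not estimating physical energies.
* Exactly two objectives are supported; the exact sweep hypervolume and the
  staircase contribution computation are 2-D constructions.
* PDB input only (first MODEL, ATOM records, two chains); no mmCIF,
  cofactors or multi-chain assemblies.
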