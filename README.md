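# pepforge

Structure-guided multi-objective Bayesian optimization of peptide binders.

## What it is for

Designing a peptide that binds a protein target means searching an enormous
discrete sequence space where each evaluation — predicting and scoring the
protein–peptide complex — is expensive. pepforge implements the
structure-in-the-loop design workflow for computational structural
biologists: candidate peptide sequences are turned into complex structures
by a pluggable provider, scored with objective functions computed directly
on the 3-D structure, and optimized by multi-objective Bayesian optimization
(BO), with native-recovery metrics for benchmarking against a known
complex. Everything is deterministic, runs at desk scale on built-in
synthetic fixtures, and exposes adapter contracts where a GPU structure
predictor or an empirical force-field program would plug in.

## The method in brief

**Objectives** (any two drive a run, each with an explicit optimization
direction):

* *Interface buried SASA* — Shrake–Rupley solvent-accessible surface area
  (probe 1.4 Å, deterministic 960-point golden-spiral lattice per atom),
  combined as `SASA(protein) + SASA(peptide) − SASA(complex)`: the surface
  hidden by binding.
* *Binding ratio* — residues of one chain whose minimum heavy-atom distance
  to the partner is strictly below 5 Å, divided by chain length.
* *Stability energy* — an inter-chain square-well contact potential
  (−1 per contact pair in 2.5–5 Å, +10 per clash pair below 2.5 Å), or any
  external calculator via a subprocess adapter.

**Optimizer** — sequences are embedded by a deterministic physicochemical
map (hydropathy, charge, volume, polarity + one-hot per residue); one exact
Gaussian process per objective (squared-exponential kernel, marginal
likelihood hyperparameters) is fit to all scored candidates; each round
proposes mutants of the Pareto-archive parents and selects a batch by the
Monte-Carlo *noisy expected hypervolume improvement*

&nbsp;&nbsp;&nbsp;&nbsp;α(x) = E[ HV(F ∪ {f(x)}) − HV(F) ],

where the expectation is over the joint GP posterior at all observed points
(the sampled noise-free front F) and the candidate, and HV is the exact 2-D
hypervolume against an adaptive reference point.

**Evaluation** — Kabsch superposition, TM-score
(`mean(1/(1+(d_i/d0)^2))`, d0 floored at 0.5 Å for short chains), and the
percentage of archive candidates whose peptide-side binding-site count
matches the native's.

## Worked example

Build the native-recovery fixture — a docked complex whose native peptide
(`WWWWWW`) is, by construction, the global optimum of both default
objectives — then run ten rounds of guided optimization:

```r
library(pepforge)

landscape <- make_recovery_landscape()
native    <- attr(landscape, "native_complex")

interface_buried_sasa(native)
#> [1] 132.7493
contact_energy(native)
#> [1] -6
binding_pairs(native)
#> <binding_pairs> 6 contacts at cutoff 5.00 A
#>   protein_resno peptide_resno distance
#> 1             1             1     4.93
#> ...

cfg <- bo_config(n_rounds = 10, batch_size = 4, n_seeds = 6, seed = 2)
arc <- run_optimization(native, cfg, provider = landscape)
arc
#> <pep_archive> 46 candidates (46 scored) over 10 rounds
#>   objectives: interface_sasa (maximize), energy (minimize)
#>   final archive hypervolume: 95.28

recovery_report(arc, native)
#> <recovery_report>
#>   native peptide binding sites: 6 (cutoff 5.0 A)
#>   binding-site-count match rate: 2.17% of 46 candidates
#>   best TM-score vs native: 1.000
#>   native sequence recovered: TRUE
```

Reading the output: the six seed mutants start two substitutions from the
native (mean buried area 106.6 Å², mean energy −4); over ten rounds the
acquisition steers proposals back toward bulkier, better-packed side chains
until the native sequence itself is proposed and scored (energy −6, all six
contacts restored), and the archive hypervolume rises from 2.9 to 95.3.
`summary(arc)` prints the full per-round min/mean/max trace and the Pareto
archive; `plot(arc)` draws them. `write_archive(arc, dir)` writes
deterministic TSV/FASTA outputs.

A thin command-line wrapper over the same functions is installed at
`inst/cli/pepforge.R` (`score`, `optimize`, `evaluate`, `make-toy`
subcommands).

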