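---
title: "Evolution-informed protein design with Potts models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-informed protein design with Potts models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evhdesign)
```

## The model

A protein family's multiple sequence alignment records which residues, and
which residue combinations, evolution tolerates. `evhdesign` summarizes that
record with a Potts model: over the `L` focus columns of the alignment and a
`q`-state alphabet (20 amino acids plus gap by default), a sequence
$\sigma$ receives the statistical energy

$$\mathrm{EVH}(\sigma) \;=\; \sum_i h_i(\sigma_i) \;+\; \sum_{i<j}
J_{ij}(\sigma_i, \sigma_j),$$

where the site terms $h_i$ capture positional preferences and the coupling
terms $J_{ij}$ capture pairwise epistasis. Higher EVH means a sequence looks
more like a fit member of the family. Substitution effects
($\Delta\mathrm{EVH}$), double-mutant epistasis, and coupling-based contact
predictions all derive from the same parameters.

### Alignment preparation

Inputs pass through the standard preparation pipeline before fitting:

* **Fragment filter.** Records whose non-gap overlap with the target's
  non-gap columns is below 50% of the target's non-gap length are dropped.
* **Column filter.** Columns with more than 30% gaps (over the remaining
  records) are dropped; the survivors are the focus columns.
  Fragments are removed before columns, the usual convention in
  evolutionary-couplings pipelines, and the order matters, so it is fixed
  and documented here.
* **Redundancy reweighting.** Each record is weighted by the reciprocal of
  the number of records within normalized Hamming distance $\theta = 0.2$
  of it; $N_\mathrm{eff} = \sum_s w_s$.

The normalized Hamming distance treats gap-versus-residue as a mismatch and
gap-versus-gap as a match. This makes the distance a metric over aligned
rows and makes $1 - D$ coincide with the intuitive percent identity; it is a
documented convention, as redundancy-weighting thresholds are not usually
stated to that level of detail. Ambiguous residues (X, B, Z, U, O) are
mapped to the gap state so `q` stays fixed.

### Pseudolikelihood inference

`fit_plm()` maximizes the weighted sum of per-site conditional
log-likelihoods minus L2 penalties $\lambda_h \|h\|^2 + \lambda_J \|J\|^2$.
The per-site problems decouple, so each site is an independent multinomial
logistic regression solved by L-BFGS-B with an analytic gradient (compiled);
couplings are then symmetrized as the average of the two one-sided
estimates, which makes $J_{ij}(a,b) = J_{ji}(b,a)$ exact. Defaults are
$\lambda_h = 0.01$ and $\lambda_J = 0.01\,(L-1)(q-1)$, the conventional
size-scaled shrinkage for pseudolikelihood direct coupling analysis; both
are recorded in the model metadata, and a fit that hits the iteration cap
warns and sets `metadata$converged = FALSE` rather than failing silently.
No gauge is fixed beyond the L2 shrinkage: every downstream quantity the
package reports (EVH differences, coupling norms) is robust to the
residual gauge freedom.

## The design sampler

`design_batch()` draws a batch of `M` sequences from the penalized energy

$$U(\sigma_a) = -\mathrm{EVH}(\sigma_a)
 + \lambda_\mathrm{T}\,\mathbb{1}\!\left[D(\sigma_a,\sigma_\mathrm{target})
   \notin [d_\min, d_\max]\right]\,\bigl|D(\sigma_a,\sigma_\mathrm{target}) - d_\min\bigr|
 + \lambda_\mathrm{D} \sum_{b \neq a}
   \mathbb{1}\!\left[D(\sigma_a,\sigma_b) < d_\mathrm{Div}\right]
 + \lambda_\mathrm{A} \sum_{s \in \mathrm{MSA}}
   \mathbb{1}\!\left[D(\sigma_a, s) < d_\mathrm{Aln}\right],$$

with total batch energy $U = \sum_a U(\sigma_a)$. The three penalties keep a
design (i) inside a band of distances from the target, (ii) diverse within
its batch, and (iii) distinct from every known homolog. Defaults are
$\lambda_\mathrm{T} = 1000$, $\lambda_\mathrm{D} = \lambda_\mathrm{A} = 10$,
$d_\mathrm{Div} = d_\mathrm{Aln} = d_\min$ and $d_\max = d_\min + 0.05$ — a
small margin of tolerated target distances rather than a knife-edge
constraint. A target identity of 70% maps to $d_\min = 0.30$ over focus
columns.

Sampling details, each a point where a convention had to be fixed:

* **Sweep.** One batch sweep is $M \cdot L$ single-site updates at uniformly
  random (member, position) pairs. The inverse temperature ramps linearly
  from 0.5 to 10 over 1000 sweeps by default.
* **Conditional.** A site is resampled from
  $p(x) \propto \exp(-\beta\, U_\mathrm{total})$ over the 20 amino acids
  (gaps are never proposed: designs are full-length proteins). Because the
  diversity term of an unordered pair appears in both members' $U(\sigma_a)$,
  its delta enters the conditional twice; `batch_energy()` reproduces the
  same double count, and a test verifies the sampler against the exact
  enumerated equilibrium of that joint energy.
* **Exact incremental bookkeeping.** The alignment penalty is recomputed per
  candidate symbol from cached per-pair mismatch counts — exact and O(N)
  per update, not an approximation. Incremental energies agree with
  recomputation from scratch to 1e-9, enforced by tests.
* **Band tolerance.** Distances are multiples of $1/L$; band membership is
  checked with a 1e-9 tolerance so exact boundary distances (e.g.
  $12/40 = 0.30$) compare reliably.
* **Initialization and RNG.** Each member starts from an independent
  uniformly random amino-acid sequence. A single seeded generator drives
  member, position and symbol draws in documented order, so a (seed,
  config) pair reproduces a run exactly.

### Greedy and tempering optimizers

`greedy_design()` repeatedly applies the single most favorable point
mutation among all $L \times 19$ substitutions until none is strictly
positive; ties break by position, then alphabet order. It is verified
against an exhaustive hill-climb oracle with the same tie rule.

`tempering_design()` targets the global EVH optimum: 19 replicas by
default, inverse temperatures initialized with linear spacing on
$[0.1, 1.0]$ and multiplied by $1.002$ each sweep, with adjacent-replica
Metropolis swaps (acceptance
$\min\{1, \exp[(\beta_r - \beta_{r+1})(U_r - U_{r+1})]\}$, $U = -\mathrm{EVH}$)
every sweep. Two conventions were genuinely open and are fixed as package
choices: the returned sequence is the best-EVH state ever visited (more
robust than the final cold-replica state, and never worse), and the
tempering chains are unconstrained — the penalty terms belong to the batch
designer, while tempering serves the unconstrained-optimum use case.

## Evaluation analyses

* `coupling_scores()` ranks position pairs by the Frobenius norm of
  $J_{ij}$ over the amino-acid states, with the average-product correction
  by default. The ranking statistic is a parameter choice (the norm-plus-APC
  convention of contact prediction); both corrected and raw scores are
  available. `contact_precision()` compares the top pairs at a minimum
  primary-sequence separation (default 5) against a user-supplied contact
  list; how that list was derived from a structure is the user's choice.
* `dms_compare()` reports Spearman correlations (average ranks for ties)
  per replicate over the matched (position, mutant) keys;
  `fitness_defect_flags()` marks mutations scoring strictly below -1 in
  any replicate.
* `quadrant_analysis()` scores each design mutation — the identical
  wild-type-to-design substitution — in both the wild-type and the design
  background and classifies the sign pair; "positive" means strictly
  greater than zero, so an exactly-zero effect lands on the negative side
  (zero effects do not occur with continuous parameters).
  `reversion_scan()` is its complement: the cost of undoing each design
  mutation in the design background.
* `reverse_translate()` keeps wild-type codons at unchanged residues and,
  at changed residues, picks the synonymous codon with usage frequency
  closest to the wild-type codon's, breaking ties alphabetically.

## The synthetic-data module

All tests run on data the package generates itself: `planted_model()` draws
fields and edge-supported couplings from seeded Gaussians (random-graph
edges keep at least 5 positions of sequence separation so contact-ranking
tests exercise the separation filter); `enumerate_boltzmann()` is the exact
oracle for everything sampler-shaped (guarded to $q^L \le 10^6$);
`sample_msa()` draws i.i.d. sequences exactly or via a Gibbs chain;
`synthetic_dms()` adds Gaussian replicate noise to the model's own
substitution effects.

What passing these tests shows — and does not. The suite demonstrates that
the samplers target exactly the distributions they claim, that inference
recovers planted interactions from i.i.d. equilibrium samples, and that
every score is internally exact. Real alignments violate the i.i.d.
assumption (phylogeny correlates sequences; the reweighting step mitigates
but does not remove this), real mutational scans carry structured rather
than Gaussian noise, and a planted Gaussian landscape is smoother than a
real family's. Performance on synthetic data is therefore a correctness
statement about the algorithms, not a guarantee about any particular
protein family.

## Problem sizes

The verification suite uses sizes chosen so exact enumeration and
brute-force oracles stay available: sampler exactness on $L=6, q=3$ (729
states, $10^5$ sweeps, total-variation distance ~0.02); constraint
satisfaction on an $L=40$, $q=21$ model with a 50-record sampled alignment
over 20 seeded runs; greedy-versus-oracle on 100 random $L=5, q=3$ models;
tempering on an enumerable two-basin Ising-like landscape ($L=8, q=2$);
and pseudolikelihood recovery of 30 planted edges ($L=30, q=8$) from 2000
sampled sequences, where top-30 APC precision is 1.0. The same quantities
are recomputed end to end by `scripts/acceptance.R`.

## Known limitations

* Pseudolikelihood inference is dense in $L$ and $q$: memory is
  $O(L^2 q^2)$ and a fit at full protein scale ($L \approx 250$, $q = 21$)
  is minutes-to-hours on one core, as expected for this model class.
* The i.i.d. sampling assumption above; no phylogenetic simulation is
  provided.
* The tempering optimizer does not support the distance penalties; use the
  batch sampler for constrained design.
* Model files store raw float64 arrays; they are portable across platforms
  (little-endian, versioned header) but not compressed.
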