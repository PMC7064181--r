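---
title: "Hypermutator population dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypermutator population dynamics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermutr)
```

`hypermutr` studies a question from bacterial experimental evolution: how can
a lineage whose genomic mutation rate `U` is 100- to 1,000-fold elevated (a
*hypermutator*) persist in a gut-commensal population for a thousand
generations without being destroyed by its own deleterious mutation load —
and how do we recognise, in sequenced clones, the adaptive mutations that
such lineages accumulate? The package provides the four computational
pillars of that analysis: forward Wright–Fisher simulation under explicit
distributions of fitness effects (DFEs), Luria–Delbrück fluctuation-assay
estimation of mutation rates, a spectrum-preserving randomisation test for
parallel mutational targets, and spectrum-corrected dN/dS. Everything runs
on synthetic data with known ground truth.

## The Wright–Fisher engine

A haploid clonal population of constant size `N` evolves in discrete
generations. Each generation consists of

1. **selection/reproduction**: `N` offspring are drawn multinomially with
   weights proportional to parental absolute fitness, then
2. **mutation**: each offspring acquires `Poisson(U)` new mutations with
   effects drawn from the DFE.

Fitness is multiplicative: an individual carrying deleterious effects
`s_1..s_k` and beneficial effects `b_1..b_m` has fitness
`prod(1 - s_i) * prod(1 + b_j)`. For the fixed-effect model this collapses
to `w_i = (1 - s_d)^i` for an individual with `i` deleterious mutations.
The order (selection first, mutation second) means a generation-`t`
summary includes `U*t` expected mutation draws; the model specifies both
steps but not their order, and this choice makes the bookkeeping exact.

Two interchangeable representations back the engine:

* **classes** — individuals binned by (deleterious count, neutral count).
  Exact and fast for fixed-effect DFEs even at `N = 1e6`, because fitness
  depends only on the deleterious count. Used for the mutation-load grids
  and the NFDS competitions.
* **individuals** — per-individual accumulated log fitness and mutation
  counts, required for continuous (exponential) DFEs. Recommended at
  `N = 1e5`, where a 1,000-generation two-clone run takes seconds to
  minutes.

The two engines agree in distribution for fixed-effect DFEs (tested by
comparing replicate means). Fitness is accumulated as a log sum in the
individuals engine; a deleterious magnitude ≥ 1 maps to `-Inf` log fitness,
i.e. a lethal genotype.

### DFE kinds and their parameters

| kind | parameters | meaning |
|---|---|---|
| `fixed` | `s_d` | every mutation deleterious, effect `s_d` per generation |
| `fixed_with_neutral` | `s_d`, `f_neut` | a fraction `f_neut` neutral, rest fixed `s_d` |
| `exponential_deleterious` | `s_d` | effects exponential with mean `s_d` |
| `exponential_mixture` | `s_d`, `f_ben`, `s_b` (+ optional `f_neut`) | beneficial fraction `f_ben`, exponential effects with means `s_d`/`s_b` |

All effects are per-generation selection coefficients, dimensionless.
Exponential draws are unbounded, so a deleterious magnitude above 1 is
possible; fitness is clamped at 0 (lethal) rather than allowed to go
negative, because fitness is a sampling weight. We chose the clamp over
truncating draws at 1: truncation would distort the stated exponential
mean, while the clamp only affects the (vanishingly rare at the default
`s_d` values) draws beyond 1. Effects are independent across mutations —
no epistasis, matching the multiplicative model.

### The deterministic oracle, and where it must fail

`poisson_recursion_oracle()` iterates the infinite-population recursion
`lambda[t+1] = lambda[t](1 - s_d) + U` with mean fitness
`exp(-s_d * lambda[t])`. It is exact when the mutation-count distribution
stays Poisson — that is, in the absence of drift. The stochastic engine
matches it closely whenever the least-loaded class is well populated
(`N * exp(-U/s_d)` large). In the strong-ratchet regime — e.g. `U = 1`,
`s_d = 1e-3`, where the equilibrium least-loaded-class frequency would be
`e^-1000` — Muller's ratchet clicks continuously, the travelling wave of
load is much narrower than Poisson, and the finite-`N` mean load runs
systematically **ahead** of the recursion. This is not an engine defect
but the central biology: deterministic mutation-selection balance is
unreachable, fitness declines open-endedly, and that is exactly why a
strong hypermutator with `s_d ~ 1e-3` cannot persist. The oracle-agreement
test in the acceptance suite documents this divergence quantitatively;
the weak-selection cells (`s_d = 1e-5`) match the oracle within
Monte-Carlo error.

### Two-clone competitions and negative frequency-dependent selection

`simulate_competition()` carries a marker locus determining the mutation
rate (`U1` vs `U2`). Each generation the next-generation size of
subpopulation 1 is drawn `Binomial(N, p)` with
`p = m1*W1 / (m1*W1 + m2*W2)`, where `W_k` is the **total** fitness
(sum of individual fitness weights) of subpopulation `k` and
`(m1, m2) = (1 + s_freq*(1 - p1), 1 + s_freq*p1)` are the NFDS
multipliers (`s_freq = 0` disables them; the study's value is 0.1). The
multipliers act on subpopulation totals, exactly as the sampling formula
is written, not on individuals. Within each subpopulation, offspring are
drawn multinomially conditional on the drawn size — the standard
conditional decomposition of full multinomial Wright–Fisher sampling,
which the between-subpopulation binomial step leaves unspecified. A
subpopulation hitting size 0 is absorbed; the marker never mutates, so
mutation-rate variants arise only by configuration.

"Loss of coexistence" needs an explicit cutoff to be testable: we declare
it when the minority clone drops below 1% frequency (absorption counts),
the smallest frequency visible on trajectory plots. Likewise the "largest
mutation-count class" of a subpopulation is reported at a 1%
within-subpopulation frequency cutoff, mirroring what Muller-plot shading
can resolve. This cutoff matters near class boundaries: a subpopulation
whose load is approximately Poisson with mean ~1 has its 4-mutation class
at ~1.4% frequency, so a 1% cutoff reports class 4 where a 2% cutoff
would report class 3; `top_class_at_freq()` exposes the cutoff.

## Fluctuation assays: the MSS estimator

`ld_pmf()` implements the standard mutant-count recursion
(`p_0 = exp(-m)`; `p_r = (m/r) * sum_{i<r} p_i/(r-i+1)`), `estimate_m_mss()`
maximises the resulting log-likelihood over the expected number of
mutational events `m` per culture (bounded golden-section search, ties
toward smaller `m`, validated against an exhaustive likelihood grid), and
the mutation rate is `m_hat / mean(Nt)` per cell per generation. The 95%
CI uses the Stewart log-normal approximation adopted by FALCOR:
`sigma_ln(m) = 1.225 * m^-0.315 / sqrt(C)` for `C` cultures, with
`rate * exp(±1.96 sigma)` as the interval; two rates are called different
when their intervals do not overlap. Cultures from repeated experimental
blocks are pooled **before** the MLE (the alternative — averaging
per-block estimates — discards the likelihood's weighting of culture
counts). The plating fraction is fixed at 1; phenotypic lag, differential
mutant fitness and partial plating corrections are out of scope. The
recursion underflows for `m > ~500`, so the generator and estimator
refuse that regime; a strong mutator is assayed at a smaller effective
`Nt`, which is precisely what plating a dilution does at the bench.

## Mutation-selection balance and fitness-decline slopes

At mutation-selection balance the frequency of resistance mutants is
proportional to the mutation rate, so the ratio of mean resistant
frequency (test clone over ancestor) estimates the rate fold change with
nothing but plate counts. The default is the ratio of arithmetic means
over all replicates and time points; a log-scale variant (back-transformed
mean of log frequencies) is provided because frequency data are commonly
log10-transformed for inference. All supplied time points enter the mean;
a window option belongs to the caller, since equilibration time is a
property of the experiment, not the estimator.

Competitive fitness declines are the OLS slope of `ln(A/B)` colony-count
ratios against elapsed generations. Conversions are fixed conventions:
19 generations/day in the mouse gut, 10/day for 1,000-fold serial
dilution in vitro (`log2(1000) ≈ 10`), ~25 per single-colony plate
passage. When clone A falls below detection, the count is floored at 1
and the slope flagged as a *minimum* selection coefficient, not an
estimate. Per-replicate slopes plus plain summaries replace the original
mixed-effects fits; the random-effect machinery adds nothing at the
package's scale and would drag in animal-level structure the synthetic
data does not model.

## Parallel mutational targets: the G-score randomisation test

For mutator-grade clones, a gene can collect several hits by chance alone,
so candidate adaptive targets must beat a null that preserves both gene
length and the mutational spectrum. The test:

1. tabulate the observed substitution spectrum over the 12 reference-strand
   types (`A>C` … `T>G`) from **all** SNPs — synonymous, nonsynonymous and
   intergenic. We keep 12 types rather than collapsing strands because the
   placement null conditions on the reference base; a 6-type tally is
   available for reporting.
2. generate `n_sims` (default 100) randomised datasets: each SNP type is
   re-placed uniformly among genome positions carrying its reference base,
   coding or not — intergenic placements are allowed and simply drop out
   when only nonsynonymous SNPs are kept, mirroring how the spectrum was
   tabulated.
3. score each gene with `G_i = 2 N_i ln(N_i / E_i)`, `E_i = N_tot L_i/L_tot`
   (`G_i = 0` when `N_i = 0`), in the observed data and in each
   randomisation. Observed `N_i` and `N_tot` are halved (without rounding;
   `G` is well defined for non-integer counts) as a conservative guard
   against 2-fold regional mutation-rate variation.
4. `Z_i = (G_obs - mean(G_sim)) / sd(G_sim)`, one-sided upper-tail normal
   p (the test asks for an *excess* of hits), Benjamini–Hochberg across
   all genes with at least one observed nonsynonymous SNP.
5. candidates: genes hit in ≥ 3 distinct clones with `q < 0.05`. The
   3-clone filter makes a parallel hit as improbable under neutrality for
   mutators as a 2-clone hit is for nonmutators.

`permutation_p()` gives empirical upper-tail p-values from the stored
simulated G matrix as an independent check on the normal-tail
approximation. Genes whose simulated G distribution is degenerate
(sd = 0, possible at very low SNP density) are excluded with a warning.
A SNP inside two overlapping genes counts for both genes, while `L_tot`
counts overlapping bases once; synthetic genomes contain no overlaps, so
this convention only matters for user-supplied annotation. Indels, IS
insertions and structural variants are outside the randomisation — the
test is SNP-only.

For nonmutator-grade clones (a handful of mutations each), parallelism
needs no statistics: `cross_host_parallel_targets()` lists any target
mutated in more than one clone, annotated with the number of hosts.

## Spectrum-corrected dN/dS

The probability that a random SNP is nonsynonymous differs by substitution
type, so raw N/S is normalised by its expectation under the clone's own
spectrum. `expected_ns_ratio()` enumerates **all** coding (site, alt)
opportunities in the genome — each coding site once per alternative
allele, stop-gaining changes counted as nonsynonymous (the simplest
defensible convention) — and weights the per-type nonsynonymous fractions
by the clone's spectrum. `normalized_dnds()` reports `(N/S)` divided by
that expectation and a two-sided binomial test of `N` among `N + S` with
success probability `ratio/(1 + ratio)`: deviation is interesting in
either direction (purifying < 1, adaptive > 1). On spectrum-randomised
tables the normalised value is unbiased around 1 and the test rejects at
no more than the nominal rate. Mutations must already be partitioned to
terminal branches by the caller; tree construction is out of scope, and
the synthetic generator emits terminal-branch-like tables by construction.

## Synthetic data: what it emulates, and what it does not

`make_genome()` builds random coding genes (start codon, sense codons,
stop) on alternating strands with controllable GC content — random
sequence, deliberately not derived from any organism, so the repository
needs no downloads; `read_genome()` accepts a user FASTA for realism.
`make_snp_table()` places per-clone background SNPs by the same
spectrum-preserving null the test uses and then plants extra
nonsynonymous hits in chosen genes across chosen numbers of clones.
`make_fluctuation_data()` and `make_competition_counts()` generate
culture counts and CFU ratio series with planted rates and selection
coefficients. Every generator is a pure function of its parameters and
seed, and every emitted file ships with a JSON ground-truth sidecar;
recovery tests read truth only from the sidecar.

Scale choices: synthetic genomes default to 100 genes of 300 bp — about
40-fold smaller than a real enterobacterial genome — so background SNP
counts in tests are scaled to preserve the **per-gene** expected hit
density of the study regime (~0.5 nonsynonymous hits per gene across a
cohort), about 4–8 background SNPs per clone. Per-clone dN/dS, by
contrast, needs per-clone loads in the mutator regime (hundreds of SNPs),
which a 100-gene genome can host but at higher per-gene density; the two
regimes cannot be emulated by one desk-scale table, so the analysis
scripts use separate cohorts. The default background spectrum is
transition-biased (4:1), the broad shape of proofreading-deficient
enterobacteria.

What the generators do **not** model: codon usage, indels and IS
elements, linkage between SNPs within a clone beyond shared genome,
read-level noise (no FASTQ), phenotypic lag in fluctuation assays, and
host-to-host migration. Passing recovery tests therefore demonstrate
estimator correctness under the stated models, not robustness to these
real-data complications.

## Numerical choices

* Per-offspring mutation kicks truncate the Poisson at upper tail mass
  1e-12; class keys pack (deleterious, neutral) counts as
  `i * 2^20 + j`, safe under `2^53`.
* Class fitness uses `exp(i * log1p(-s_d))` to avoid `(1-s)^i` underflow
  inaccuracy at large `i`.
* Offspring sampling uses `rmultinom` over parents (O(parents)) rather
  than weighted `sample()` (O(parents × N)).
* The MSS likelihood truncates the count distribution at
  `max(100, 2*max(r)+10, 50*m)` and floors probabilities at 1e-300 before
  logging; the optimizer brackets `m` in `(1e-8, max(2, 4*mean(r), max(r)))`.
* `fits_observed_range()` is inclusive at both ends ("contained within
  the range").
* Extinction (total fitness weight 0) halts a run with a flagged summary
  rather than silently continuing.
* Problem sizes in the shipped tests and acceptance script: `N = 1e6`
  class-based and `N = 1e5` individual-based populations over 1,000
  generations, 3 replicate seeds per stochastic quantity, 50–200
  randomisations per parallelism run, 10–20 generator seeds per
  calibration loop — sizes chosen so the full suite exercises the study's
  own regimes in minutes on one core.

## Known limitations

* The deterministic oracle is an infinite-population object; in
  strong-ratchet regimes the simulated mean load exceeds it by
  construction (see above), so oracle agreement is a weak-selection
  check only.
* The Stewart CI is an approximation calibrated for moderate `m` and
  culture counts; at `m` below ~0.3 the MSS likelihood is flat and the
  CI optimistic.
* The normal-tail p of the parallelism Z score is asymptotic in the
  number of randomisations; with 100 simulations the smallest honest
  empirical p is ~0.01, which is why both readings are reported.
* Coordinates are 0-based half-open internally and 1-based in all files;
  mixing the two is the classic failure mode when importing external SNP
  tables, so `read_snp_tsv()`/`write_snp_tsv()` do the conversion and
  `annotate_snps()` cross-checks the ref allele against the genome.
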