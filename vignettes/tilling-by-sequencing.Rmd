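---
title: "Mutation discovery in tridimensionally pooled TILLING screens"
author: "tillcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation discovery in tridimensionally pooled TILLING screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillcall)
```

## The screening problem

A TILLING (Targeting Induced Local Lesions IN Genomes) screen starts from a
chemically mutagenized population — here an EMS-mutagenized sunflower M2
population — and asks, for a set of target genes, which individuals carry
induced point mutations. Sequencing every individual separately is wasteful
when the per-individual mutation rate over a few tens of kilobases is far
below one; instead, target amplicons are PCR-amplified from *pooled* DNA
and the pools are sequenced deeply.

`tillcall` implements the analysis for *tridimensional* pooling: `s^3`
individuals (a *set*) are arranged in an `s x s x s` cube and each of the
`3s` axis slices (8 row, 8 column and 8 dimension pools for `s = 8`)
becomes one pool of `s^2` individuals. Every individual then sits in
exactly three pools, and a mutation present in exactly one individual
appears in exactly one row, one column and one dimension pool — the triple
identifies the carrier. A 2048-plant screen is four such sets: 96 pools of
64 plants.

```{r}
scheme <- build_scheme(2048, 64)
scheme
pools_of(scheme, 1337)
```

The pipeline stages, also exposed as subcommands of the bundled
`inst/scripts/tillcall` script, are: pool design (`design-pools`),
synthetic data generation (`simulate`), Bayesian calling (`call`), effect
and severity annotation (`classify`) and population-level QC (`diagnose`).
The pipeline boundary is the *parsed pileup* — a per-pool, per-position
table of A/C/G/T counts. Demultiplexing, trimming and alignment are
upstream of the package; a reader for single-sample `samtools mpileup`
text is provided for convenience.

## The calling model

At 64-plex pooling a heterozygous mutation contributes an expected allele
fraction of only `1/128 ~ 0.78%` to each of its three pools — close to the
error rate of short-read sequencing (at least 0.1% per base). Calling is
therefore a model comparison exercise, not a thresholding one.

At each amplicon position, for each alternate base, and independently per
set, the package enumerates *configurations*: the null configuration (no
mutation) and one configuration per (individual, zygosity) pair, under the
assumption of at most one mutant individual per position within a set
(two individuals hitting the same base of the same amplicon is vanishingly
rare at realistic mutation loads, and such positions are treated as
unscorable noise rather than decoded). Under configuration `c`, the
alternate-base count `m_j` of pool `j` with depth `d_j` is binomial:

    m_j ~ Binomial(d_j, p_j),
    p_j = e + f (1 - e)   if pool j carries the mutant individual,
    p_j = e               otherwise,

where `e` is the position- and change-specific error rate and `f` is the
carrier allele fraction — `1/(2 * pool_size)` for a heterozygote,
`1/pool_size` for a homozygote. Writing the success probability as
`e + f(1-e)` rather than `e + f` keeps it a probability for any `e` and
reflects that error reads and true mutant reads both produce the alternate
base.

Priors encode the biology of EMS: a per-base per-individual mutation
probability `mu` (default `1e-5`), of which 90% (`canonical_weight`) is
assigned to the canonical G:C>A:T change at G/C sites, with the remainder
split evenly over the other changes (and split evenly three ways at A/T
sites); a mutant individual is homozygous with prior 1/3, the M2
segregation expectation for a mutation induced in the M1. The posterior
follows from Bayes' theorem, and the confidence score of a candidate is

    F = log10 [ posterior(best non-null configuration) / posterior(null) ].

Because this is a posterior *odds*, the normalising constant cancels and
the score can be computed without summing over all configurations; the
full normalised posterior is still available from
`score_position(..., return_posterior = TRUE)` and is verified in the test
suite against a brute-force enumeration oracle on small 2-cube schemes to
`1e-9`.

Candidates are reported with confidence classes split at `F = 2` (below:
likely noise, not reported by default) and `F = 7.69` (above: high
confidence); `19.1` is carried alongside as the empirically validated
bound — in the screen this package models, no Sanger false positive was
ever observed above it, while only 10 of 31 predictions between 7.7 and 19
validated. These bounds are configurable (`caller_config()`), and
`validation_curve()` reproduces the corresponding true/false tallies from
any labelled candidate set.

### Noise estimation

Deep pooled amplicon data shows sequence variation at essentially every
position, mostly sequencing error with strong positional structure. The
error rate for each (position, alternate base) is estimated from the data
itself: the mean alternate-allele frequency across pools after discarding,
in every set, the three highest-frequency pools. A genuine single-carrier
mutation occupies exactly three pools of one set, so the trimming removes
its signal from its own noise estimate while leaving 21 of 24 pools to
average over. Estimates are floored at `error_floor` (default 0.001).
Pools below `min_depth` (default 100x) are excluded, and positions with
fewer than six usable pools are left unscored; a candidate whose carrier
triple includes a pool below `min_depth` is kept but flagged
(`low_depth`), since low-coverage bases dominate the noise and deserve
scrutiny rather than silent deletion.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mutation_prior` | `1e-5` /base/individual | prior induced-mutation rate |
| `canonical_weight` | 0.9 | prior mass on G:C>A:T at G/C sites |
| `error_floor` | 0.001 | minimum per-change error rate |
| `zygosity_prior_hom` | 1/3 | M2 homozygote fraction among mutants |
| `confidence_bounds` | 2, 7.69 | low/medium/high class splits (F) |
| `validated_bound` | 19.1 | no-false-positive bound (F) |
| `min_depth` | 100x | usable-pool depth cutoff |

Ties between configurations (identical posterior) break to the lower
individual id, heterozygous before homozygous, so output is deterministic;
candidate tables are sorted by decreasing `F`.

## Effect prediction and severity

Effect prediction needs the exact gene model: each amplicon carries exon
intervals, the strand of the gene relative to the amplicon, and the CDS
bounds in transcript coordinates (`target_reference()`, read from a GFF3
subset). A substitution is classified `utr`, `splice` (intronic within
2 nt of an exon boundary — the canonical GT/AG dinucleotides; the
original screen tallies a Splice category without defining the window, so
the 2-nt canonical window is this package's choice), `intron`, or — inside
the CDS — `silent`, `missense` or `truncation` after rebuilding the
affected codon in transcript orientation (reverse-complemented for `-`
strand genes; pileup coordinates always stay amplicon-forward, so
in-paper-style positions like `C3741T` address the data verbatim).
Stop-loss changes fall outside the screen's reporting categories and are
reported as missense with a warning.

Missense severity follows BLOSUM62 (from Biostrings): score `>= 0` is a
conservative replacement, *not severe* (`NSM`); `< 0` is a *possible
severe mutation* (`PSM`); truncations and splice changes are always PSM.
The zero cutoff is the unique integer threshold consistent with every row
of the screen's Sanger-validated table (13 PSM, 2 NSM over the 15 missense
changes — `A173T` at score 0 pins the boundary from above, `D122N` at +1
from below, and the PSM rows at -1 pin it from below); the test suite
verifies this reproduction.

```{r}
vm <- validated_mutations()
table(severity(vm[vm$category == "missense", ]))
spectrum_summary(vm)
```

## Population diagnostics

Induced mutations hit individuals independently, so per-individual
mutation counts should be Poisson with `lambda = M/N` estimated from the
calls themselves (a mutagenesis dose model would add assumptions the data
can check for free). Deviations are informative: noise spreads across
individuals, while *genetic contamination* — outcrossing or seed-stock
heterogeneity, a real concern in an allogamous species like sunflower —
concentrates excess variants in few individuals.

```{r}
round(poisson_expected(2048, 1123), 1)
```

`mutation_load_test()` compares the observed histogram against this
expectation with a chi-square goodness-of-fit test (tail bins pooled from
the right until every expected cell is at least 5, one degree of freedom
charged for estimating `lambda`) and flags individuals with load above 3
— at `lambda ~ 0.55` the Poisson probability of more than three hits is
about `2e-3`, so a 2048-plant population should contain a handful at most.
The singleton deficit (expected minus observed one-mutation individuals)
is reported alongside, being the other fingerprint of contamination.
`length_correlation()` checks that per-fragment counts track tilled
length (Pearson `r`), and `spectrum_summary()` reports the canonical
G:C>A:T fraction, which for clean EMS material should exceed 90%.

## The synthetic screen

No raw sequencing data accompanies the screen this package models, so the
generator in `simulate_screen()` is a first-class part of the package: it
defines the study conditions under which every stage is tested.

* **References** — random amplicons with valid gene models (ATG, sense
  codons, in-frame stop, GT/AG introns, UTRs, primer flanks; ~30% of genes
  on the reverse strand to exercise strand handling).
* **Population** — per-individual counts `Poisson(lambda = 0.548)`
  (1123 mutations / 2048 individuals); a mutation is canonical with
  probability 0.9 (uniform over G/C sites) and otherwise a uniform
  non-canonical change at a uniform site, so the *marginal* canonical
  fraction equals the configured bias; homozygous with probability 1/3.
  Positions are drawn without replacement across the population by
  default: the real screen spreads its mutations over ~58 kb where
  same-position collisions are negligible, while desk-scale references
  would otherwise manufacture collisions that the one-carrier
  configuration space is explicitly not meant to decode.
* **Contaminants** — optionally, individuals that receive 5–10 extra
  heterozygous variants ignoring the canonical bias, emulating natural
  polymorphisms from outcrossing.
* **Pileups** — per pool and position, depth is negative binomial (mean
  12,000x, dispersion 5, spanning the huge pool-to-pool variation of real
  amplicon sequencing, optionally with low-coverage "primer shadow"
  dropout cells); the variant base draws `Binomial(d, e + f(1-e))` with
  `f` summed over the pool's carriers, other alternates draw error at
  `e/3` each, and the reference base takes the remainder, so the depth
  identity holds exactly. The generator works at the count level — no
  reads, no aligner — because alignment is outside the package boundary.

What the simulator does *not* emulate — misalignment between paralogs,
index hopping, PCR chimeras, indels, base-quality structure — is exactly
the failure mode the real screen's low validation rate was attributed to.
Passing the closed-loop tests therefore demonstrates that the *model and
its implementation* are correct and well calibrated, not that real
sunflower data would validate at the same rate.

```{r, eval = FALSE}
cfg <- simulation_config(seed = 2024, n_individuals = 512, pool_size = 64,
                         lambda = 200 / 512, depth_mean = 12000,
                         base_error = 0.001, n_targets = 6)
sim <- simulate_screen(cfg)
calls <- call_mutations(sim$pileup, sim$scheme, sim$references)
```

At these settings (one 512-plant set, ~3.2 kb of amplicon space, ~200
planted variants) the test suite requires site recall of at least 0.9 at
`F >= 2` with at least 95% carrier-decoding and zygosity accuracy; the
run completes in a few seconds.

## Numerical and design notes

* Likelihoods are computed in log space; per-configuration scores reuse
  the null log-likelihood and update only the three carrier pools, which
  makes whole-amplicon scoring a handful of matrix operations per
  alternate base.
* Zero-depth pools contribute nothing (binomial pmf at `n = 0`), so
  partially covered positions degrade gracefully.
* The test problem sizes (2-cube schemes for the enumeration oracle, one
  512-plant set for the closed loop, 100 seeds for the clean-population
  calibration) were chosen as the smallest sizes at which the respective
  properties are meaningful.
* Configuration files for the command-line runner are YAML mirroring
  `caller_config()` / `simulation_config()`; every run writes a JSON
  manifest (arguments, input checksums, seed, version) so deterministic
  commands are reproducible bit for bit.
* The cube filling order is fixed (row-major) so that generated schemes
  are reproducible; any other bijection can be supplied via the scheme
  file, and all scoring is invariant to pool relabeling.

## Known limitations

Substitutions only — the screen reports no indels, and the binomial count
model has no notion of them. Base qualities are not used; the empirical
per-position noise model stands in for them. The error rate is estimated
per position but not re-estimated jointly with the calls (no EM). Multiple
mutant individuals at one position within a set are not decoded. Severity
is sequence-intrinsic (BLOSUM62); conserved-domain context, which the
original screen annotated from an external database, is out of scope.
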