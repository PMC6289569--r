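---
title: "Modelling spontaneous ligation and recombination in random oligonucleotide pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spontaneous ligation and recombination in random oligonucleotide pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolforge)
```

## The system being modelled

Random-sequence RNA oligomer pools — for example a pool of ~10^15 random
eicosamers (N20, 20-nt oligomers) — can undergo spontaneous, non-enzymatic
intermolecular ligation and recombination. Strand scission via internal
transesterification leaves a 2',3'-cyclic phosphate (>p) and a free 5'-OH,
the very termini competent for re-ligation, so a hydrolysis-prone pool is
also a recombination-prone pool. Two questions drive the package:

1. **Population level**: what does one round of hydrolysis-plus-ligation do
   to the informational content of a redundant pool, measured as the
   Shannon diversity index over unique sequences?
2. **Sequence level**: what do deep-sequenced ligation/recombination
   products look like — product size ladders, positional nucleotide
   signatures, junction dinucleotide fingerprints, secondary-structure
   biases near the junction — and how do we detect those features reliably?

Because experiments of this kind leave no public raw reads, the package
pairs every analysis stage with a synthetic-data generator that produces
reads with known truth labels, so each estimator can be validated by
parameter recovery.

## The recombination simulator

A pool is a multiset of sequences. One simulated round has two steps.

**Hydrolysis.** Each molecule of length $L \ge 2$ is cleaved independently
with probability `hydrolysis_rate`. The breakpoint is a bond index drawn
from $\mathrm{Normal}(L/2, \sigma)$, rounded to an integer and clipped to
$[1, L-1]$. Both fragments are kept: nucleotide mass is conserved exactly,
and the suite asserts this invariant across random parameter draws.

**Ligation.** Fragments of length $\ge 3$ (`min_ligatable_length`; shorter
fragments are chemically uninteresting end products) are visited in random
order; each initiates a ligation with probability `ligation_rate`. The
partner is drawn from the union of the remaining eligible fragments and
the intact survivors — which weights the choice of partner class by each
population's current size — and uniformly within the class. Partners are
consumed without replacement, the partner is joined 3' of the initiator,
and products do not react again within the round (single-pass ligation).

Diversity is the Shannon index over unique sequences,
$D = -\sum_i n_i \log_2 n_i$ with $n_i$ the proportion of molecules with
the $i$-th unique sequence: 0 bits for a monomorphic pool, $\log_2 N$ bits
for a uniform pool of $N$ unique sequences. `simulate_recombination()`
reports $D$ before and after the round and their difference $\Delta D$;
`delta_D_grid()` averages $\Delta D$ over replicate fresh pools for every
cell of a hydrolysis-rate x ligation-rate grid.

For the reference condition — N20, 4-letter code, 1000 unique sequences at
100 copies each — mean $\Delta D$ is positive over the entire 5x5 grid of
rates spanning (0, 1], and grows with pool redundancy and code complexity.
Intuition: cleavage of a redundant pool creates new (shorter) unique
species without destroying the originals' identity entirely, and random
re-joining samples a combinatorially vast product space, so both steps
push a redundant pool's composition towards more unique species at more
even proportions. Only a nearly pure-degradation regime on a non-redundant
pool can lower $D$.

### Choices the description leaves open

* **Breakpoint spread.** The breakpoint law is "normal around the
  midpoint" with unstated variance; the default is $\sigma = L/6$ (about
  95% of draws fall inside the strand before clipping), exposed as a
  parameter. Out-of-range draws are clipped, not resampled — at
  $\sigma \le L/4$ the distortion is negligible.
* **One cleavage per molecule per round**, and single-pass ligation with
  partners consumed without replacement; iterating rounds is an explicit
  loop (`rounds` argument), default 1, since diversity is accounted
  "before" and "after" one recombination event.
* **Partner weighting** reads "weighted by the size of each population" as:
  choose the partner class (hydrolysed vs unhydrolysed) with probability
  proportional to current class sizes, then uniformly within the class.
  This is implemented as a single uniform draw over the union, which is
  exactly that two-stage law.
* **Orientation**: the partner is concatenated 3' of the initiating
  fragment; no reverse orientation is modelled.
* **Seeding**: every stochastic stage takes an explicit seed; grids derive
  per-cell, per-replicate seeds from one master seed with a fixed hash, so
  landscapes are bit-for-bit reproducible.

## The synthetic read generator

`make_pool()` draws `n_unique` distinct random cores (default eicosamers
over ACGU) without replacement and replicates each `redundancy` times;
constant flanks (primer binding sites such as C1/C2), homopolymer tails
(A10) and a 5'-blocked flag (modelling a 5'-FAM label, which cannot act as
the downstream ligation partner) mirror the experimental pool designs.
Simulating all 4^20 sequences is impossible, so "a pool of 100-fold
redundancy" is represented by `n_unique` sampled cores (default 1000) at
100 copies each.

`make_products()` forms bait-prey concatenations: a possibly 3'-truncated
bait prefix joined to a full-length prey — prey length is always preserved,
reproducing the truncation-ladder asymmetry of recombination products. The
truncation prior is geometric from the bait 3' end (progressive truncation)
or fixed. A junction dinucleotide bias (e.g. `c(CN = 8)` for an 8-fold CpN
preference) reweights the candidate (molecule, truncation) pairs jointly,
so the realized junction dinucleotide frequencies converge to the bias
weights as the pool grows; every product carries its true junction bond,
class (B-P / P-P / B-B) and truncation for test bookkeeping.
`attach_quality()` adds uniform substitution errors (no indels) and
Phred+33 qualities, optionally injecting low-quality 3' tails to exercise
the quality filter; truth columns are retained.

What the generator deliberately does *not* emulate: hybridization-driven
proximity (products are formed by sampling, not by duplex modelling),
amplification and sequencing biases beyond uniform substitutions,
indels, and chemistry-level kinetics. Passing tests therefore demonstrate
that the estimators recover known parameters from data with the right
first-order statistical structure — not that real libraries are free of
the biases the generator omits.

## The analysis stack

* **Preprocessing** mirrors the standard read pipeline: Phred+33 FASTQ
  (other encodings rejected), quality filter keeping reads with at least
  90% of bases at Q >= 20 (a `>=` comparison at the boundary, so 9/10
  passes), exact-duplicate collapsing ordered by descending count then
  lexicographically, terminus-anchored adapter trimming with Hamming
  mismatches only (constant regions are fixed length, so no indel
  alignment is needed), and length splitting, which doubles as the
  product-size histogram.
* **Nucleotide signatures**: per-position base frequencies (optionally
  count-weighted), converted to RGB via
  $R = 255(1 - f_C - f_A)$, $G = 255(1 - f_C - f_U)$,
  $B = 255(1 - f_A - f_G - f_U)$, so pure C/U/A/G map to
  blue/red/green/yellow. Channels are kept as reals (a uniform position is
  (127.5, 127.5, 63.75)) and rounded half-up only for display/export.
* **Junction fingerprints**: the dinucleotide (N-1, N+1) table at the
  junction bond, compared against the unligated input-pool profile under
  independence; both the log2 ratio and the raw difference are reported
  (the display convention for enrichment panels is not fixed, so both are
  emitted). A zero-background cell observed with nonzero frequency is
  flagged as +Inf rather than silently dropped. Bias-fold estimation uses
  the odds ratio of observed to expected, which cancels the pool's
  residual base composition.
* **Matched pools**: `generate_matched_pool()` samples each position
  independently from a frequency profile — the null model sharing the
  experimental composition but no ligation-specific structure; the
  reference comparison uses 3 replicates of 300,000 sequences.
* **Folding**: `nussinov_fold()` is an exact base-pair-maximization DP
  (min hairpin loop 3, Watson-Crick plus GU wobble, deterministic
  traceback pairing each position with its smallest admissible partner,
  pairing preferred over leaving a tied position unpaired). It is the
  package's deterministic, dependency-free oracle and pair-count proxy —
  it is *not* a thermodynamic model. Minimum-free-energy structures come
  from a pluggable external backend (`external_fold()`, e.g. RNAfold)
  or precomputed dot-bracket files (`read_dotbracket()`); external
  energies are treated as inputs, never as values to reproduce.
  `structure_profile()` tabulates opening-pair/closing-pair/unpaired
  frequencies per position; `compare_structure_profiles()` reports the
  experimental-minus-synthetic difference with across-replicate standard
  deviations.
* **Motifs**: the reference submotif catalogue is not published, so
  `submotif_catalogue()` generates a parametric family over internal-loop
  strands (unpaired runs 0-6 flanked by 1-4 nt helical runs, both
  orientations) and hairpins, with the J and H patterns (4-nt loop flanked
  by 3-nt helices) predefined; a submotif such as J4 is the J pattern with
  the junction on its 4th internal bond. Consensus extraction replaces an
  external motif-discovery tool with a pseudocounted PWM plus per-column
  information content $IC = \log_2|A| - H$ — deterministic and adequate
  for anchored windows. Ligation-site frequencies are normalized within
  each motif; cross-motif abundance is reported separately rather than
  folded into the normalization.
* **Combinatorics**: sequence-space sizes (4^20 ~ 1.1 x 10^12; binary
  interaction space its square, > 10^24) overflow 53-bit doubles well
  before length 60, so `pool_combinatorics()` uses an exact base-10^4
  big-integer representation internally and reports both exact digit
  strings and doubles. A 10^15-molecule eicosamer pool works out to 909
  copies per sequence and 1.66 nmol (Avogadro fixed at 6.02214076e23).
* **Kinetics**: ligation yield curves are fit to a single-exponential
  approach to plateau, $y(t) = \mathrm{plateau}(1 - e^{-k_{obs}t})$, by
  bounded Levenberg-Marquardt least squares with a multi-start over rate
  scales (the SSE surface has a shallow local optimum at plateau -> 1 with
  small $k$). All-zero yields return plateau 0 with $k_{obs}$ flagged
  indeterminate; estimates at a bound are flagged with a warning.

## Problem sizes and runtime

The test and acceptance runs use the reference conditions directly: the
$\Delta D$ landscape at 5x5 rate cells x 10 replicate pools of 100,000
molecules (about a minute), parameter recovery at 10,000 products, matched
pools at 10^5 sequences, folding-oracle equivalence on 200 random 6-12-mers
against exhaustive enumeration, and mass-conservation over 100 random
parameter draws on 10^4-molecule pools. Nussinov folding is cubic in
length, so structure-profile stages subsample folded sequences
(`fold$max_seqs` in the pipeline configuration) rather than folding
300,000-sequence pools.

## Known limitations

* The simulator is sequence-agnostic: the CpN preference is an
  analysis-side observable, not a simulator rule, and no
  hybridization/thermodynamics enters product formation.
* The pair-count folder ignores stacking energies; conclusions about MFE
  distributions require an external folder.
* Circular, lariat and branched products are not modelled (the assays the
  analyses mirror do not detect them).
* The kinetics module fixes the single-exponential form; biphasic
  reactions would need a different model.

## A minimal session

```{r example, eval = FALSE}
pool <- make_pool(pool_spec(length = 20, n_unique = 1000, redundancy = 100),
                  seed = 42)
out <- simulate_recombination(pool, sim_params(0.5, 0.5), seed = 42)
glance(out)

grid <- delta_D_grid(pool_spec(n_unique = 1000, redundancy = 100),
                     hydrolysis_rates = seq(0.2, 1, 0.2),
                     ligation_rates = seq(0.2, 1, 0.2),
                     replicates = 10, seed = 1)
autoplot(grid)

pool_combinatorics(1e15, 20, 4)
```
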