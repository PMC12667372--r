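---
title: "Data-oblivious reference-based phasing: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-oblivious reference-based phasing: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obliphase)
```

# The problem

Reference-based phasing reconstructs the two parental haplotypes of a diploid
sample from its unphased genotypes, using a panel of known haplotypes.  When
the computation runs on infrastructure the user does not control — the
motivating deployment is a trusted execution environment, where the host can
observe memory access patterns and timing — a faithful phasing algorithm must
also be *data-oblivious*: the sequence of memory accesses and the control flow
may depend only on public shape parameters (panel dimensions, window layout),
never on the genotypes being phased.  `obliphase` implements the full
algorithmic stack for this setting: an M3VCF-style block-compressed panel,
per-block PBWT prefix trees with oblivious target insertion, conditioned-panel
selection by longest-suffix matching, and a diploid Li–Stephens HMM evaluated
entirely in dynamically scaled fixed-point integer arithmetic.

The obliviousness contract here is *algorithmic*, at the level of the logical
access trace: a high-level language cannot control microarchitectural
behaviour, so what the package reproduces and tests is the input-independence
of the access sequence, via the `trace_capture()` harness.  Hardware
constant-time guarantees, enclave deployment and attestation are out of scope.

# The phasing model

## Genotype graph

Heterozygous sites carry all the phase information.  They are partitioned in
order into segments of at most `H_seg` (default 3) sites; a segment with $h$
hets enumerates all $2^h$ assignments of its het alleles to haplotype A
(haplotype B is the complement; homozygous sites are forced).  Any consistent
haplotype pair is a path through the per-segment options.

## Diploid Li–Stephens HMM

Given a conditioned panel of $K$ haplotypes, the hidden state at site $i$ is
$(k_1, k_2, o)$: the two copy sources and the phase option of the covering
segment.  Each copy process independently switches source with probability
$\rho_i = 1 - \exp(-0.04\,N_e\,d_i/K)$ per interval ($d_i$ the genetic
distance in cM, constant 0.01 cM without a map; $N_e = 15{,}000$), jumping
uniformly over the valid panel rows.  Emission is $1-\varepsilon$ on allele
match and $\varepsilon$ (default $10^{-4}$) on mismatch, for each haplotype
against its source.  At segment boundaries the option transitions under a
uniform prior; within a segment it persists.  The transition operator
$A = (1-\rho) I + \rho\, w \mathbf{1}^\top$ is rank-one structured, so the
forward and backward updates cost $O(K^2)$ per option per site.

`forward_backward()` returns, per adjacent segment pair, the joint posterior
over option transitions, and per segment the option marginal.  Because
relabelling the haplotypes (A↔B) maps every option to its complement with
identical probability, these posteriors are exactly swap-symmetric; all
downstream consumers work with relative phase.  In particular `prune()` folds
each boundary posterior over the joint complement before thresholding
(default 0.999) — without folding, no boundary could ever exceed 0.5 — and a
merged segment keeps exactly the confident transition and its complement,
collapsing its option space to 2.  Merges are never undone.

## MCMC schedule

`mcmc_run()` follows a SHAPEIT4-style schedule (default `5×burn-in, prune,
burn-in, prune, burn-in, prune, 5×main`).  Every iteration rebuilds the
conditioned panel from the *current* phase estimate via the compressed PBWT,
then: burn-in iterations sample a new estimate from the boundary posteriors
(backward sampling over the chain, inverse-CDF on fixed-point cumulative
sums); prune iterations merge confident boundaries; main iterations run
Viterbi (max-product, deterministic lowest-index tie-breaks) and the decode
with the best accumulated log-likelihood across main iterations is returned.
Windows sized so that `H_seg × window_min_segments` het sites are expected at
the minimum heterozygosity rate (defaults 3 × 20 at 10%, i.e. 600 sites) are
phased independently and stitched over a configurable overlap (default 60
sites), flipping a window's haplotype labels when that increases het-phase
agreement in the overlap.

# Compressed panel and PBWT selection

The panel is tiled greedily into blocks, closing a block when the next site
would exceed `max_width` (32) sites or `max_uniques` (256) distinct
haplotype prefixes; blocks store only unique rows plus an index map.  Blocks
do not overlap; continuity across blocks is handled explicitly by the
global-LCS carryover below.

Each block's unique rows get a positional prefix order and divergence values
(a PBWT), organised as a prefix tree whose nodes group identical prefixes.
This structure is built once from public panel data and reused across
iterations and samples.  The secret phase estimate is inserted obliviously:
per column, its rank in the prefix order is maintained through allele-count
scans over the full column, and its divergences to the neighbours above and
below are selected by linear scans — every loop runs over the full public
shape.

At each search position (one uniformly chosen het site in each of at most
`max_positions` segments per haplotype), candidates are gathered by walking
prefix-tree nodes outward from the insertion rank, computing block-level LCS
on the fly from the divergences via running maxima, until at least `S`
original haplotypes are covered; the walk extends through ties at the
smallest included LCS, which guarantees the candidate set contains the true
top-`S`.  Candidates are ranked by total match length — the block-level LCS,
extended by the global carryover when the entire block prefix matches.  The
global LCS per haplotype is updated only at block starts by the recursion
“carry forward on a full-block match, restart otherwise”.  Ties rank the
smaller haplotype id first, and the ranking runs through the bitonic sorting
network.  The union of all neighbour sets becomes the conditioned panel: a
membership bitmap set by linear-scan oblivious writes, filtered to the fixed
public capacity `K_cap = 2 × max_positions × S` (default 64) with the
oblivious filter; shortfall slots hold sentinel copies of the first selected
row, flagged so the HMM assigns them zero weight.  The public panel size
therefore never reveals the union cardinality.

The spec-level idea of one search position per segment is kept, but the
number of positions per iteration is capped (default 8 per haplotype):
uncapped, a desk-scale window with ~50 segments would condition on the whole
panel and the $O(K^2)$ diploid state space would defeat the purpose of
conditioning.  The capped positions are resampled every iteration, so across
the schedule the search still covers the window.

# Dynamic fixed point

All HMM arithmetic uses integer mantissas with a shared power-of-two exponent
per row (or per site-distribution): value $= m \cdot 2^{e-F}$.  After every
operation the scaling factor is recomputed as the power of two that puts the
largest scaled magnitude of the row in $[0.5, 1)$, applied by bit shifts.
Choices worth recording:

* **Mantissa width.** Mantissas are bounded by $2^{53}$ with $F = 50$
  fractional bits, so they cross the R/C++ boundary as IEEE doubles exactly;
  arithmetic runs on `int64` with 128-bit intermediate products.  (The
  64-bit/52-fractional-bit configuration appears only as the *static*
  baseline the dynamic scheme is compared against.)
* **Rounding** is truncation toward zero on right shifts — branch-free, and
  the per-op error is absorbed by the stated tolerances.
* **Addition** aligns both operands to the larger row exponent plus one
  headroom bit (overflow-safe without a loss-minimising search).
* **Column sums** shift all rows to the highest row scale only; the 64-bit
  accumulator already has 13 bits of headroom above the mantissas, and
  adding a pre-shift would cost exactly the precision the per-op tolerance
  budget needs.
* **Distribution renormalisation** computes one constant-time reciprocal of
  the sum (restoring long division with a fixed iteration schedule, six
  guard bits) and multiplies through — one division per distribution rather
  than one per entry, with the same constant control flow and the same
  $n \cdot 2^{-F}$ bound on the deviation of the sum from 1.  The all-zero
  vector maps to the uniform distribution, which keeps sampling total and is
  precisely the failure mode the static baseline exhibits.
* **All-zero rows** carry a reserved minimum exponent.

`dfp_chain_demo()` reproduces the mechanism that motivates the scheme: 200
repeated multiplications by $\approx 2^{-10}$ leave the dynamic
representation with its row ordering intact (exponents absorb the shrinkage)
while a static 52-fractional-bit fixed point truncates to exact zero within
ten steps — the state a phasing run then renormalises into a uniform
distribution, destroying the posterior.

# Oblivious primitives

Linear-scan ORAM reads/writes touch every slot in fixed order; out-of-range
reads return an `NA` sentinel rather than raising (a data-dependent exception
is itself a side channel).  Sorting is a bitonic network padded to the next
power of two with maximal-key sentinels (finite keys are checked at ingest);
stability comes from composite `(key, index)` comparisons, which
`oblivious_filter` relies on to preserve relative order while routing
selected elements to a fixed public length.  `ct_divide` is restoring long
division with exactly `width` iterations; division by zero yields the
all-ones sentinel.  `cond_select` materialises both operands.  Secret values
(`secret()`) propagate through arithmetic and cannot subscript arrays or
coerce to plain numerics; exposure requires an explicit `declassify()`.

The trace harness records (op, label, index) events from the instrumented
kernels; tests assert byte-identical event streams across resampled secret
inputs for every primitive and for the full insert → search → rank → union
pipeline.  The HMM kernel contributes no events: its loop structure is fixed
by public shapes by construction, and its secret-dependent values flow
through arithmetic only.

# Synthetic data and what passing tests show

`simulate_panel()` draws founder haplotypes site-wise from uniform
minor-allele frequencies in `[0.05, 0.5]` and fills the panel with founder
mosaics (switch probability 0.01 per interval, allele flips at 0.001),
emulating the haplotype-sharing structure that both the compression and the
Li–Stephens model exploit.  Targets are panel mosaics with exactly 3
uniformly placed recombinations per haplotype and dosage-resampling genotype
errors at 0.2%; at an error site the truth pair is adjusted (a resulting het
split at random) so the dosage identity holds and error-created hets are
scored like any other.  The reference benchmark uses a 200-haplotype ×
500-site panel over 20 seeds — sizes chosen as desk-scale stand-ins with the
same qualitative structure as biobank panels, not to reproduce their
compression ratios or error rates.  Accordingly, passing tests demonstrate
correctness of the algorithmic core and its numerics; they do not certify
accuracy on real cohort data, where allele-frequency spectra, LD decay,
genotyping-array error structure and rare variants differ substantially.

Evaluation is the switch error rate: the fraction of consecutive
heterozygous site pairs whose relative phase disagrees with the truth,
invariant to the global haplotype swap; with simulated truth there are no
phase-ambiguous trio sites to exclude.  Under the reference conditions the
suite requires mean SER ≤ 2% (observed ≈ 0.4%), and SER = 0 in at least
19/20 seeds when targets are exact panel rows.

# Numerical and degenerate-input conventions

Zero het sites yield a trivial single-segment graph and the forced phase.
Fewer than two het sites make SER undefined; it returns 0 with an
`undefined` attribute.  Fixed-point comparisons in Viterbi break ties toward
the lower index; sampling uses R's RNG exclusively, so a fixed seed gives
byte-identical phased VCF output.  Windows, schedules, S, `max_positions`,
thresholds and fractional bits are all exposed in `phase_config()`; the
iteration counts and pruning threshold are conventional SHAPEIT4-class
defaults rather than tuned values.

# Known limitations

* Multiallelic sites and missing genotypes are rejected at ingest (the
  latter belong to an imputation tool, not the phasing core).
* The diploid state space is evaluated directly at $O(K^2)$; the further
  factorisations used by SHAPEIT4 for very large conditioned panels are out
  of scope, which is why `K_cap` is deliberately small.
* Log-space fixed point is intentionally absent (its runtime cost is the
  reason the dynamic scaling scheme exists).
* Obliviousness is demonstrated at the logical access-trace level, not at
  the level of cache lines or speculative execution.
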