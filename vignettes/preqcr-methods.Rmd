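---
title: "Reference-free read QC and genome characterization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free read QC and genome characterization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`preqcr` estimates genome characteristics (size, heterozygosity, repeat
content) and data-quality metrics (per-base error rates, fragment sizes,
coverage uniformity) from raw shotgun reads alone. This vignette explains
the statistical models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
more than one reasonable construction exists.

## The counting substrate

Every metric reduces to exact substring counting over the read
collection. The index stores, for each pre-declared k, strand-aware
occurrence counts of every A/C/G/T k-mer keyed by its canonical form (the
lexicographic minimum of the k-mer and its reverse complement), plus the
reads themselves for random extraction and, optionally, per-read seed
positions for overlap lookup. K-mers containing `N` are skipped; reads
containing `N` stay in the set. Compressed full-text indexes can answer
the same queries in less memory; at the scales this package addresses, an
exact hash table has identical semantics, and the query contract — not
the data structure — is what the methods rely on. Internally k-mers are
packed two bits per base into fixed-width 192-bit codes updated by
rolling shifts, so one code path serves every k up to 96 and counting
does per-position hashing rather than string allocation.

Two conventions matter downstream:

* **Both-strand edge validation.** A de Bruijn neighbor counts as a
  valid edge only if it was seen at least once on each sequencing strand
  separately. Strand-specific systematic errors then cannot create
  branches, at the cost of requiring modest coverage on both strands.
* **Fixed neighbor order.** Neighbor enumeration and greedy tie-breaks
  use base order A < C < G < T, making every traversal deterministic
  given the index and the sampled starts.

## The count-spectrum mixture

Sampled k-mer counts are modeled as a ten-component mixture of
zero-truncated Poisson distributions: an error component with free rate
`lambda_e`, a heterozygous component at `lambda / 2`, a homozygous
component at `lambda`, and seven repeat components pinned to
`2 * lambda, ..., 8 * lambda` (each representing an integral number of
extra genomic copies). Zero truncation reflects that an unobserved k-mer
has count zero by construction. EM updates the weights and `lambda_e`
only; the genomic rates stay tied to `lambda` because copy-number states
are determined by overall coverage, not fitted freely. A negative
binomial mixture would absorb overdispersion, but the Poisson form is
sufficient for the decisions these metrics inform and keeps every
posterior a closed-form ratio.

`lambda` itself is initialized from the histogram: the first local
minimum of the spectrum marks the trough between the error peak and the
genomic peak, and the modal count above that trough is taken as the
homozygous mean. On error-dominated, monotone-decreasing spectra there is
no trough; the weighted mean count is used instead and a warning is
emitted, since any estimate from such data is unreliable. Initial weights
are 0.3 (error), 0.1 (het), 0.5 (hom) and 0.1 spread over the repeat
states, with `lambda_e` starting at 1.0; these are documented defaults,
and the EM is insensitive to them on any spectrum with a visible genomic
peak. Iteration stops at 30 rounds or a relative log-likelihood change
below 1e-6. Histogram counts are capped at 1000 (mass above the cap is
binned at the cap): the far tail is repeat mass whose exact placement
does not affect the fitted weights at any realistic coverage.

Genome size follows from the coverage identity
`lambda = n (l - k + 1) / G` evaluated at k = 31, corrected by the
fitted error-k-mer fraction `w0`:
`G = (1 - w0) * n (l - k + 1) / lambda`. Read sets with heterogeneous
lengths use the modal read length for `l`.

## Branch classification

A homozygous k-mer (posterior of the `lambda` component at least 0.90)
with two or more strand-validated suffix neighbors is a branch, and the
classifier assigns it posterior probabilities of being caused by a
sequencing error, an allelic variant, or a repeat. Two independent
observations enter:

* **Excess reads `d`.** With `c_ia` and `c_ib` the counts of the
  (k+1)-mers joining the vertex to its two top neighbors,
  `d = max(0, (c_a - c_ia) + (c_b - c_ib))` counts reads containing a
  neighbor but not the vertex. Under the error and variant models this
  requires the neighbor to be a read's first k-mer (or a first-base
  error), so `d ~ Poisson(rho + 0.05)` where
  `rho = lambda / (l - k + 1)` is the read-start density per genomic
  copy. Under the repeat model the neighbors occur at `m` extra genomic
  copies, giving the mixture `sum_m q_m Poisson(m * lambda + rho)` with
  `q_m` renormalized from the fitted repeat weights. The 0.05 allowance
  and the exact functional forms are this package's reconstruction of a
  model whose published equations are not recoverable; they reproduce
  the intended contrast (`d` near zero without extra copies, near
  `m * lambda` with them) and are exposed as configuration.
* **Coverage balance.** `c_b` out of `n = c_a + c_b` is
  `Binomial(n, 1/2)` for variants (two alleles equally sampled),
  `Binomial(n, 0.05)` for errors (reads overwhelmingly support the true
  neighbor), and `BetaBinomial(n, 2, 2)` for repeats — mild
  overdispersion around 1/2 reflecting unknown copy-number
  configuration. The three constants (0.05, alpha = beta = 2) are
  likewise reconstructed defaults, adjustable via `classifier_params()`.

Posteriors (uniform prior, independence of the two observations) are
accumulated as *soft counts* per class over every k-mer instance of the
sampled reads, and rates are soft counts divided by `N_h`, the number of
homozygous instances checked. Instances, not distinct k-mers, are
counted, matching the sampling design. A rate whose soft count is below
2 is suppressed (reported `NA`), and a k whose fitted `lambda` is below
15 is skipped entirely: with that little coverage the error and variant
models are not distinguishable and variant branches are partly invisible.
Both thresholds are configuration, chosen conservatively.

The mixture is refit at every analyzed k rather than rescaled from
k = 31, because `lambda` depends on k through `l - k + 1` and the error
fraction grows with k. `branch_rates()` therefore takes the read set and
builds a transient k/(k+1) index per k, freeing each before the next —
this bounds memory on desk-scale hardware and is why it does not accept a
prebuilt index.

### The reference-graph oracle and a degeneracy worth knowing

`reference_branch_rates()` computes exact rates from a known diploid
genome: homozygous vertices are canonical k-mers with multiplicity
exactly one per haplotype; each is checked for suffix branches in both
orientations (`N_h` counts vertex–orientation pairs, mirroring the
read-based scan that checks each instance in its observed orientation); a
two-neighbor branch whose alternatives are genome-unique and
haplotype-specific is a variant, anything else a repeat.

A consequence of the homozygous filter that surfaced during development:
genomes whose repeat copies are *identical* produce no repeat branches at
homozygous vertices at all — every multi-way junction lies inside the
repeat, where multiplicity excludes the vertex — and the read-based
estimator agrees, since such vertices also fail the coverage posterior.
Real genomes show repeat branch signal because repeat families are
*diverged*: a k-mer containing a copy-specific difference is
genome-unique while its (k−1)-suffix is still shared. The simulator
therefore supports a per-family `divergence` rate (copies independently
mutated before planting), and repeat-rate validation uses diverged
families; with divergence, longer k-mers are more likely to contain a
discriminating site, which is exactly why the repeat branch rate falls
with k.

## Read-level metrics

**Per-base error rate.** For each sampled read, candidate overlaps are
found through shared 31-mer seeds (seeds occurring more than 200 times
are skipped as repetitive), aligned ungapped at the first seed's
diagonal, and kept at ≥ 50 bp overlap and ≥ 95% identity. Per column of
the resulting stack, the majority base is the consensus, with ties
resolved toward the assessed read's own base so a 50/50 column never
manufactures an error. A base is an error iff it differs from a
consensus supported by at least 3 reads while fewer than 4 reads support
it; columns with fewer than 4 reads are not assessed and are excluded
from the denominator. Ungapped alignment is a documented limitation: the
simulator's error model is substitution-only, and for substitution-rate
estimation at these identities gaps contribute negligibly; data with
appreciable indel error would bias this estimator.

**Fragment sizes.** For a sampled pair (X, Y), a greedy walk from X's
first 51-mer repeatedly takes the highest-coverage strand-validated
suffix neighbor until it reaches the first 51-mer of rc(Y)
(forward/reverse orientation assumed; a flag flips to forward/forward),
dead-ends, or exceeds 1500 steps. The emitted length is the distance
from X's start to Y's anchor plus Y's length — the full molecule span, a
convention calibrated by simulator round-trip and exposed as
configuration. Long fragments break more often at coverage gaps, so at
low coverage the estimate is biased short; the resolved fraction is
reported alongside.

**Coverage diagnostics.** The fixed-k (default 51) count histogram and a
2-D histogram of (GC fraction of the k-mer, combined count) over sampled
k-mer instances; under GC-unbiased coverage every GC column has the same
count distribution. GC is computed on the k-mer itself with 20
left-closed bins over [0, 1].

## Simulated assembly

Walks mimic an assembler that resolves error and variant branches but
not repeats: starts are first k-mers of sampled reads with homozygous
posterior ≥ 0.5; extension takes the highest-coverage neighbor,
continuing through branches whose posterior argmax is error or variant
and stopping at repeats, dead ends, within-walk revisits, or 50000
k-mers. Visited vertices go into a Bloom filter (four hashes, sized at
16 bits per expected element, false-positive rate well below 1%) and
starts already present are skipped; a false positive can only skip a
start, never corrupt a walk. Contig length is k-mers visited, and N50
per k summarizes the trade-off between repeat resolution (favoring large
k) and graph connectivity (favoring small k).

## What the simulator does and does not emulate

The generator produces: a uniform-random haploid sequence; planted
repeat families (identical or diverged copies, non-overlapping); a
second haplotype via per-base heterozygous substitutions; reads drawn
uniformly from a random haplotype and strand with Gaussian fragment
sizes, position-specific substitution errors, and constant Q30
qualities.

It does not emulate: indel errors, GC-dependent coverage bias,
instrument-specific quality profiles, nested or tandem repeat structure,
or chimeric fragments. Passing recovery tests on simulated data
therefore demonstrates correctness of the estimators under their own
model assumptions — uniform coverage, substitution-only errors, diploid
genomes — not robustness to every artifact of real instruments. The
quality-by-position summary, for instance, is exercised with explicitly
constructed quality strings because simulated qualities are constant.

## Numerical choices and problem sizes

* Zero-truncated Poisson evaluation is in log space
  (`dpois(log = TRUE) - log1p(-exp(-rate))`), stable to rates in the
  hundreds; the `lambda_e` M-step solves the truncated-mean equation
  `lambda / (1 - e^-lambda) = m` by `uniroot` to 1e-10.
* All randomness flows through R's RNG; C++ code receives pre-sampled
  read indices and is deterministic, so a single seed reproduces a run
  byte for byte. `run_all()` derives one substream seed per stage so
  disabling a metric does not perturb the others.
* Default full-scale sampling sizes are 50000 reads (histograms),
  100000 (error profile), 1000000 (branch scans), 100000 pairs
  (fragments) and 20000 walks per k; `preqc_config(scale = )` shrinks
  all of them proportionally. The bundled tests validate recovery at
  desk scale: genome-size and error-profile recovery on 100 kb genomes,
  fragment-size recovery on 200 kb, and branch-rate recovery against
  the exact reference-graph rates on a 1 Mb diploid genome at 40X with
  0.5% error — sizes chosen so the full suite and the acceptance script
  each run in minutes on one core while leaving the estimators' sampling
  noise well inside the stated tolerances.

## Known limitations

* Diploid assumption throughout; polyploid genomes would need more
  mixture components and a different balance model.
* Branch-model constants (balance probabilities, Beta-Binomial shape,
  posterior thresholds) are reconstructed, conservative defaults —
  calibrated qualitatively, not fitted to any external dataset.
* Short-insert paired-end only; mate-pair/long-insert libraries with
  different orientation conventions are out of scope beyond the
  forward/forward flag.
* The error-rate estimator undercounts when the same error recurs in
  four or more overlapping reads at one column (the support-4 shield),
  so rates at very high error densities are slightly conservative.
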