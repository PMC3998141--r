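# preqcr

Reference-free quality assessment and genome characterization from raw
whole-genome shotgun sequencing reads.

Before committing compute to a *de novo* assembly, one wants to know what
the reads say about the genome and about themselves: how big the genome
is, how heterozygous and how repetitive it is, how error-prone the reads
are, and whether the paired-end library matches its intended fragment
size. `preqcr` estimates all of these **without a reference genome**,
directly from a k-mer counting index of the reads, and bundles the
results into a versioned JSON report with companion plots. The intended
users are people planning or troubleshooting genome assemblies.

## The model

All metrics build on exact k-mer counting over the read set. For a
pattern *P*, `count(P)` is its occurrence count on the observed strand and
`count_rc(P) = count(P) + count(rc(P))` folds in the reverse complement.

**Count spectrum and genome size.** Sampled k-mer counts *c* are modeled
as a mixture of zero-truncated Poisson components,

    P(c) = sum_z  w_z * ZTP(c; lambda_z),    ZTP(c; λ) = Pois(c; λ) / (1 − e^−λ)

with ten components: sequencing errors (free rate λ_e), heterozygous
k-mers (λ/2), homozygous k-mers (λ), and seven repeat states at fixed
rates 2λ, …, 8λ. Only the weights **w** and λ_e are updated by EM; the
genomic rates are pinned to λ, the homozygous mean count. Since *n* reads
of length *l* contain *n(l − k + 1)* k-mers and a haploid genome of size
*G* contains about *G* distinct ones, λ = n(l − k + 1)/G, and correcting
the k-mer total for the error fraction w₀ gives

    G = (1 − w₀) · n (l − k + 1) / λ        (k = 31 by default)

**Branch classification.** In the de Bruijn graph, a homozygous k-mer
with two strand-validated suffix neighbors (counts c_a ≥ c_b) is a branch
caused by a sequencing error, an allelic variant, or a repeat. Two
statistics separate the three: the *excess-read count*
d = (c_a − c_ia) + (c_b − c_ib), where c_ia, c_ib count reads containing
both the vertex and the neighbor — small unless the neighbors have extra
genomic copies — and the *coverage balance* of c_b in c_a + c_b
(Binomial(1/2) for variants, Binomial(p≈0.05) for errors, Beta-Binomial
for repeats). Posteriors under a uniform prior are accumulated as soft
counts over the k-mers of sampled reads, giving per-k variant and repeat
branch rates; the same model guides simulated assembly walks whose
contig N50 versus k maps out the assembly's sweet spot.

**Read-level metrics.** Per-base error rates come from overlap consensus:
sampled reads are stacked with their seed-matched, ungapped overlaps
(≥ 50 bp, ≥ 95% identity) and a base is called an error when it differs
from a consensus supported by ≥ 3 reads while fewer than 4 reads agree
with it. Fragment sizes come from greedy highest-coverage walks through
the 51-mer graph from one mate to the other.

A synthetic diploid-genome and read simulator (tunable heterozygosity,
diverged repeat families, position-specific error rates, fragment-size
distribution) makes the whole pipeline testable end to end against known
truth.

## Worked example

```r
library(preqcr)

g  <- simulate_diploid_genome(100000, het_rate = 0.001, seed = 42)
rs <- simulate_reads(g, coverage = 40, read_len = 100,
                     error_rate_by_pos = 0.01, fragment_mean = 300,
                     fragment_sd = 30, paired = TRUE, seed = 7)

idx <- build_kmer_index(rs, 31, with_k_plus_1 = FALSE)
set.seed(1)
h <- sample_count_histogram(idx, 31, 50000)
m <- fit_mixture_em(h)
m
#> count_mixture (k = 31 ): lambda = 21 lambda_e = 0.1081
#>   weights: 0.268 0.013 0.719 5.47e-06 ...

estimate_genome_size(m, n_reads(rs), 100, k = 31)
#> genome size estimate: 97574 bp (lambda = 21.00, w0 = 0.268, k = 31)
```

The spectrum's homozygous peak sits at λ = 21 (40X coverage thinned by
the chance that a 31-mer is error-free, 0.99³¹ ≈ 0.73), w₀ says 27% of
sampled k-mer instances contain an error, and the corrected estimate
recovers the true 100 kb genome within 2.5%. The same index drives the
other metrics:

```r
idx51 <- build_kmer_index(rs, 51, with_k_plus_1 = FALSE)
set.seed(2)
estimate_fragment_sizes(idx51, n_pairs = 5000, k = 51)
#> fragment_sizes: 1518/5000 pairs resolved; mean 299.3 bp, sd 30.6 bp
```

matching the simulated fragment distribution (mean 300, sd 30). A full
run over every metric, written to JSON and rendered to PDF:

```r
report <- run_all(rs, preqc_config(seed = 1, scale = 0.05))
write_report_json(report, "report.json")
render_report(report, "report.pdf")
```

or from a shell, via the thin CLI in `inst/cli/`:

```sh
preqc run reads.fq.gz --paired --out report.json --seed 1 --scale 0.05
preqc report report.json -o report.pdf
```

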