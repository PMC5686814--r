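# TADclust

Unsupervised detection of topologically associating domains (TADs) in
Hi-C contact matrices by clustering per-bin contact profiles.

## The problem

A Hi-C contact matrix M records the interaction frequency M[i, j]
between every pair of fixed-width bins (i, j) of a chromosome. TADs —
contiguous regions whose bins interact far more with one another than
with the rest of the chromosome — appear as dense square blocks on the
main diagonal. TADclust is for computational biologists who want a TAD
annotation from a normalized intra-chromosomal matrix, a way to compare
two annotations, and a way to check boundary enrichment of ChIP-seq
marks, all scriptable from R or the shell.

## The method

Each diagonal bin i is represented by the concatenation of row i and
column i of M (a 2N-length interaction profile). Profiles are grouped
with K-means, agglomerative hierarchical clustering, or a
Gaussian-mixture EM, under Euclidean, city-block, or Pearson
correlation (1 − r) distance. Consecutive same-cluster bins are joined
into segments; segments of at least the minimum TAD size (default
180 kb) become TADs, shorter runs boundaries, zero-contact runs gaps.
Each TAD i is scored

    quality(i) = intra(i) − inter(i, j)

where intra(i) is the mean contact inside the domain block and
inter(i, j) the mean contact in the rectangle between domain i and its
adjacent domain(s). The number of clusters K is chosen either from the
rule-of-thumb window K = √(n/2) ± 10 with quality-based selection (the
default) or by the elbow of the percent-variance-explained curve; the
TAD set with the highest mean quality is returned. An iterative mode
re-clusters the largest clusters over several rounds to resolve
sub-TADs, and evaluation utilities compute annotation consistency
(exact-match / sub-TAD containment cases) and peak-enrichment profiles
at domain borders.

## Worked example

Simulate a 30-bin chromosome with five planted domains and call TADs
with the elbow policy:

```r
library(TADclust)
sp  <- plantedSpec(30, list(c(0, 7), c(8, 13), c(14, 19), c(20, 24), c(25, 29)),
                   noiseSd = 1, seed = 7)
gen <- generateBlockMatrix(sp)
res <- callTads(gen$matrix, kPolicy = "elbow", seed = 7)
res$best
#> TadSet: chrU - 5 TADs, 0 boundaries, 0 gaps (k = 5 )
#>   overall quality: 7.824
tadTable(res$best)
#>   startBin endBin label class  quality
#> 1        0      7     4   TAD 8.107315
#> 2        8     13     5   TAD 7.561148
#> 3       14     19     1   TAD 7.801023
#> 4       20     24     3   TAD 7.358962
#> 5       25     29     2   TAD 8.291029
res$elbow$kElbow
#> [1] 5
```

The elbow lands on K = 5, the five planted domains are recovered
exactly (0-based inclusive bins), and each domain's quality is its
within-block mean contact (~10) minus the mean contact to its
neighbors (~2), shrunk a little by noise. With a real matrix, pass a
file path and the resolution instead:

```r
res <- callTads("chr20_40kb.matrix", resolution = 40000, chrom = "chr20",
                outPrefix = "chr20")   # writes chr20.tads.bed + chr20.perK.tsv
```

The same pipeline is available from the shell via the installed
script (`exec/tadclust`): subcommands `call`, `compare`, `enrich`, and
`simulate`.

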