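# jointmds

Quantifying how chromosome 3D organization differs between two conditions
from paired Hi-C data.

Multidimensional scaling can turn a single normalized Hi-C contact matrix
into an ensemble-average 3D structure, but comparing two conditions by
embedding each matrix separately and superposing the results is unreliable:
MDS is stochastic, and two runs on the *same* matrix already disagree by a
nonzero aligned RMSD. `jointmds` embeds both matrices **simultaneously**,
minimizing the penalized joint stress

    sigma(X1, X2) = sum_{i<j} (d_ij(X1) - delta_ij1)^2
                  + sum_{i<j} (d_ij(X2) - delta_ij2)^2
                  + sum_i w_i * d_i(X1, X2)^2

by stress majorization (SMACOF), where `delta_ijc` are target distances
derived from contacts (`delta = c^(-1/4)` by default), and the similarity
weight `w` ties each locus's two embedded positions together. The output is
a pair of aligned structures in a common frame; the per-locus Euclidean
distance between them is the **relocalization distance**. Around this core
the package provides:

* preprocessing (shared-locus intersection, mean normalization, a mild
  distance-decay prior, contact-to-distance conversion);
* a data-driven similarity-weight selector (reproducibility plateau);
* the infer-then-align baseline (independent embeddings + Kabsch rigid
  superposition) for comparison;
* A/B compartment scores (PC1 of the observed/expected correlation
  matrix), a 3D compartment axis fitted by linear SVR, and the
  decomposition of relocalization along it;
* relocalization peak calling by continuous-wavelet-transform ridge lines,
  compartment-difference filtering, virtual 4C, and interval coverage
  enrichment;
* synthetic fixture generators with planted relocalizations, shifted
  domain boundaries, and compartment flips, so every claim is testable
  without external data.

Intended users: computational biologists analyzing differential genome
architecture (cell-type comparisons, condition responses) at the level of
binned intrachromosomal Hi-C matrices.

## Worked example

Simulate two conditions that share all interaction domains except one
boundary (bin 100 in condition A, bin 105 in condition B — a five-bin shift,
about 2.5% of the span, the same order as a 1 Mb boundary shift on a ~50 Mb
chromosome), then fit:

```r
library(jointmds)

sim <- make_boundary_pair(seed = 1)            # planted boundary: 100 vs 105
dp  <- prepare_distance_pair(sim$a, sim$b)     # intersect, normalize, prior, d = c^(-1/4)
fit <- joint_mds(dp$d1, dp$d2, weight = 0.05, seed = 1)
summary(fit)
#> Joint MDS fit over 200 loci (similarity weight 0.05)
#>   stress 22140.8 after 139 iterations
#>   embedding error: 0.7416 / 0.7502 (condition 1 / 2)
#>   relocalization magnitude (min / median / q90 / max):
#>     0.01648 / 0.1486 / 0.2833 / 0.6374

prof <- call_peaks(relocalization_profile(fit))
which.max(prof$magnitude)
#> [1] 100
```

The relocalization profile peaks exactly at the planted boundary: the loci
between the two boundary positions are the only ones whose contact
environment changed, and the strongest called peaks sit in or near bins
100–105 (e.g. the peak interval at 10.1–10.2 Mb is bin 102). The
infer-then-align baseline on the same inputs misses it:

```r
base <- independent_compare(dp$d1, dp$d2, seed = 1)
which.max(relocalization_profile(base)$magnitude)
#> [1] 1
```

The fit object also supports `print()`, `plot()` (magnitude vs position),
`coef()` (coordinate matrices), `fitted()` (embedded distance matrices) and
`residuals()` (distance residuals per condition). Structures and profiles
are written as TSV via `write_structure()` / `write_relocalization()`, and
a command-line wrapper is installed at
`system.file("scripts/jointmds", package = "jointmds")`:

```sh
jointmds run A.tsv B.tsv --res 100000 --weight 0.05 --seed 1 --out prefix
jointmds simulate boundary --out simdir --seed 1
```

For compartment-level analysis, `compartment_scores()` +
`fit_compartment_axis()` + `decompose_relocalization()` test whether
relocalization is concentrated along the A/B compartment axis, and
`filter_peaks_by_compartment()` separates within-compartment relocalization
peaks from outright compartment switches (|score difference| < 0.2).

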