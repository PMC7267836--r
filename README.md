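# riboloop

Reconstruction of full-length small-subunit (SSU, 16S/18S) rRNA gene
sequences from large paired-end total RNA meta-transcriptomic read sets,
with per-sample relative-abundance estimation.

## The problem and the method

Total RNA sequencing of a microbial community is dominated by rRNA, so the
reads carry a full taxonomic census — but tens of millions of short reads
cannot be assembled in one pass, and the conserved/variable block structure
of rRNA genes makes one-shot assembly both slow and error-prone. `riboloop`
reconstructs rRNA genes iteratively and subtractively. With `U` the pooled
unmapped read-pair set and `C` the accumulating contig set, each iteration:

1. draws a random subsample of `n` pairs from `U` (default `n = 100000`,
   seed `base_seed + t`);
2. assembles it against a reference database with an internal
   expectation-maximisation (EM) consensus assembler: candidate references
   receive read posteriors
   `z_rj ∝ π_j (1−ε)^matches (ε/3)^mismatches`, priors and per-position
   posterior-weighted consensus bases are re-estimated, collapsed
   candidates are pruned, and candidate pairs above 97% mutual identity
   are merged;
3. dereplicates the new contigs into `C` (greedy longest-first absorption
   at ≥ 99% identity with ≤ 5 indel columns);
4. maps all of `U` against `C` (k-mer seeded, glocal, search identity
   0.96, mapped/unmapped decision at 0.98, at most one indel, pairs must
   map concordantly) and removes every explained pair;
5. stops when the pool is exhausted (`|U| < n`), when an iteration adds
   fewer novel contigs than 1% of `|C|` (after one final double-size
   iteration), or at 11 iterations.

Post-processing drops contigs with mean coverage < 2 or covered fraction
< 80%, then re-maps each sample's raw reads to the kept contigs to build a
contig × sample relative-abundance ("OTU") table in which ambiguous read
mass is split `1/k` across tied contigs, so each column sums exactly to
the sample's mapping rate.

A synthetic-community module (conserved/variable-block reference pools,
log-normal communities, substitution-error paired reads, and the three
reference-database scenarios: sources present / 95–99% similar / absent)
and an evaluation module (precision-sensitivity-F1 threshold sweeps
against ground truth, abundance correlation) make the whole pipeline
benchmarkable end to end.

## Worked example

```r
library(riboloop)

pool      <- make_reference_pool(20, length = 1200, seed = 11)
community <- sample_community(pool, 6, seed = 12)
bundle    <- make_scenario("a", pool, community, n_pairs = 20000, seed = 13)

cfg    <- default_config(sampling_num = 5000, base_seed = 1)
result <- run_pipeline(bundle$reads, bundle$reference_db, cfg)
glance(result)
#> # A tibble: 1 × 6
#>   iterations contigs final_unmapped termination_reason kept_contigs dropped_contigs
#> 1          1       6             15 pool_exhausted                6               0

ev <- evaluate_contigs(result$kept, bundle$profile, result$abundance)
glance(ev)
#> # A tibble: 1 × 4
#>   precision_97 sensitivity_97 f1_97 pearson_r
#> 1            1              1     1     1.000

head(tidy(result))
#> # A tibble: 6 × 3
#>   contig_id sample abundance
#> 1 contig_1  S1       0.579
#> 2 contig_2  S1       0.178
#> 3 contig_3  S1       0.115
#> 4 contig_4  S1       0.0979
#> 5 contig_5  S1       0.0256
#> 6 contig_6  S1       0.00395
```

One iteration reconstructs all six sources exactly (precision and
sensitivity 1 at the 97% threshold), the pool collapses from 20000 to 15
unexplained pairs, and the estimated abundance column tracks the true
log-normal community (Pearson r ≈ 1; the column sums to the sample's
mapping rate). `autoplot(ev)` draws the precision/sensitivity/F1 sweep and
`autoplot(result$run)` the pool-shrinkage trace; `tidy()`/`glance()`
methods return every result as a tibble.

A thin command-line front end is installed as `exec/riboloop` with
`run --config FILE`, `simulate --scenario a|b|c --outdir DIR` and
`evaluate --contigs FASTA --sources FASTA` subcommands over the same
functions.

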