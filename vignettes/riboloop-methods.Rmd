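---
title: "Iterative reference-guided rRNA reconstruction: models and methods"
author: "riboloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative reference-guided rRNA reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Total RNA meta-transcriptomic sequencing captures the whole RNA pool of a
microbial community, of which 95–99% is rRNA. Reconstructing full-length
small-subunit (SSU, 16S/18S) rRNA genes from these short paired-end reads
gives both a taxonomic census and, through per-sample read mapping, relative
abundances — but assembling tens of millions of rRNA reads at once is
impractical, and the strong conserved/variable block structure of rRNA makes
naive assembly chimera-prone. `riboloop` addresses this with an iterative
subtractive strategy: assemble a small random subsample against a reference
database, remove every read explained by the resulting contigs, and repeat on
the shrinking unmapped pool, so that abundant taxa are reconstructed (and
their reads removed) in early rounds and rare taxa become reachable later —
the "rare biosphere" motivation for the design.

## The iterative loop

Let $U$ be the unmapped read-pair pool (initially all samples pooled) and $C$
the accumulated contig set (initially empty). Each iteration $t$:

1. **Subsample** $n$ pairs uniformly without replacement from $U$
   (default $n = 100\,000$; the RNG seed is `base_seed` $+ t$, so each
   iteration draws a fresh subsample and the whole run is a pure function of
   `base_seed`).
2. **Sub-assemble** the subsample with the EM assembler (below) against the
   reference database.
3. **Dereplicate** the new contigs into $C$: concatenate, sort by descending
   length, and greedily absorb any contig whose glocal alignment inside an
   accepted representative reaches $\ge 99\%$ identity with $\le 5$ indel
   columns (both criteria must hold, mirroring the conjunction semantics of
   overlap-based dereplication tools). Survivors are renamed `contig_<k>` in
   scan order; provenance (iteration of origin, original id) is retained.
4. **Map** all of $U$ against $C$ under the stringent contract below and
   shrink $U$ to the unmapped remainder. Because dereplication never edits
   an accepted representative, a pair left unmapped in earlier rounds can
   only be explained by this round's novel representatives; the
   implementation therefore maps $U$ against the novel representatives
   only, which yields the identical split at a fraction of the cost.
5. **Terminate** checking, in order: (ii) $|U| < n$ (pool exhausted);
   (iii) the iteration produced fewer novel representatives than 1% of
   $|C|$, in which case ONE extra iteration with subsample size $2n$ runs
   before stopping; (i) the cap of 11 iterations. The extra iteration is
   not itself eligible to trigger another, so at most `max_iterations + 1`
   iterations ever run. Exhaustion is checked first because it is decisive;
   the criteria list has no inherent order, so we fixed this one.

"n reads" is interpreted as $n$ read *pairs* — the loop operates on paired
data and pairs are never split across the subsample boundary.

## The EM assembler

The sub-assembler is a reference-guided expectation-maximisation consensus
caller. Read pairs are first overlap-merged (best-scoring overlap of
$\ge 20$ bases with mismatch rate $\le 5\%$; overlap bases resolved by the
higher quality, ties keeping mate 1's base); merged reads and the two mates
of unmerged pairs enter the model as independent observations — this avoids
modelling insert-size likelihoods. Candidates are the reference sequences
attracting at least one seeded, identity-qualified read alignment
($\ge 90\%$); priors $\pi_j$ start uniform.

* **E-step.** For read $r$ and candidate $j$, the likelihood from the best
  glocal alignment is
  $P(r \mid j) = (1-\varepsilon)^{\text{matches}} (\varepsilon/3)^{\text{mismatches}}$
  with $\varepsilon = 0.005$ by default, and
  $z_{rj} = \pi_j P(r\mid j) / \sum_{j'} \pi_{j'} P(r\mid j')$. Reads with
  no qualifying alignment are dropped and never re-admitted, so the
  retained-read count is monotone within one assembly.
* **M-step.** $\pi_j \leftarrow \sum_r z_{rj} / \sum_{r,j'} z_{rj'}$; each
  candidate's consensus is re-called per position as the posterior-weighted
  majority base over its aligned reads (ties keep the current base;
  positions without aligned mass are untouched). Consensus edits are
  substitution-only, keeping candidate coordinates stable. Candidates with
  $\pi_j < 10^{-4}$ are pruned and priors renormalised.
* **Merging.** Candidate pairs at $\ge 97\%$ mutual global identity are
  merged into the higher-prior candidate (priors summed), enforcing the
  assembler's documented resolution ceiling for near-identical variants.
* **Convergence.** The loop stops after 15 iterations or when the L1 change
  of the prior vector falls below $10^{-3}$; candidates with
  $\pi_j \ge 10^{-3}$ are reported, ids encoding the pipeline iteration.

All constants are configuration-exposed (`EM_*` keys). The EM internals are
this package's own design; no numeric equivalence with any external
implementation is claimed.

## Alignment and mapping semantics

Identity is defined everywhere as matches / alignment columns
(gap-inclusive), with linear scores match $+1$, mismatch $-1$, gap $-2$;
`N` never matches anything. The global aligner optimises the lexicographic
objective (score, then matches): maximising matches among co-optimal paths
makes the reported identity canonical — in particular symmetric under
argument swap — where a fixed traceback preference alone would not be.
Affine gaps are deliberately omitted: with at most 1 indel in mapping and 5
in dereplication, linear penalties lose nothing.

Mapping follows a two-threshold contract: k-mer seeding ($k = 13$, both
strands, at least `minhits = 2` distinct seed positions on a consistent
diagonal) proposes candidates; glocal alignment (read consumed end-to-end,
at most `maxindel = 1` indel column) scores them; candidates below
`minid = 0.96` are discarded during search; and a read unit is MAPPED iff
its best identity reaches `idfilter = 0.98`. The search-time/report-time
split mirrors the documented semantics of the two flags in short-read
mappers. An unmerged pair is MAPPED iff both mates map to the same contig
on opposite strands; a pair with exactly one mapping mate stays in $U$
(conservative: its information remains available to later iterations). A
mapped fragment's hit set is every contig tied with its best score;
ambiguous mass is split $1/k$ over the $k$ tied contigs, which conserves
read mass so abundance columns sum exactly to mapping rates. For
`maxindel <= 1` the glocal optimum is computed exactly by a per-diagonal
prefix-sum formulation (an alignment with one indel column is exactly a
prefix on one diagonal joined to a suffix on an adjacent one); the general
DP with a gap-count state handles larger bounds. Dereplication and
candidate merging precede alignment with a shared-k-mer prefilter: one edit
destroys at most $k$ k-mers, so a pair below the identity threshold by a
safe margin is provably rejected without alignment.

Coverage bookkeeping: `mean_coverage` counts aligned read bases
(match + mismatch columns) over the contig length; `covered_fraction` is
the fraction of positions with depth $\ge 1$. Ambiguously mapped fragments
contribute *fully* (unweighted) to every tied contig's coverage — the
$1/k$ split applies only to abundance mass. The rationale: coverage filters
ask "is this contig physically supported by reads", for which fractional
counting would understate support of genuinely present contigs sharing
conserved blocks.

## Post-processing

The pooled raw reads of all samples are mapped to the final contig set; a
contig is dropped when its mean coverage is below 2 **or** its covered
fraction below 80% (boundary values are kept — "below" is strict). Pooling
for the keep/drop decision avoids dropping contigs present in only one
sample. Each sample's raw reads are then re-mapped against the *kept*
contigs, and the abundance of contig $i$ in sample $s$ is
$(\text{unambig}_i + \text{ambig mass}_i) / \text{pairs}_s$, so each
column sums exactly to the sample's mapping rate. Rows are ordered by
descending pooled abundance. Whether abundance should be computed against
the filtered or unfiltered set was an open choice; re-mapping to the
filtered set was selected so that reported abundances refer to reported
contigs.

## The synthetic community generator

The simulator emulates the benchmark design used to validate this class of
tools, replacing a curated SSU database and an external read simulator with
a self-contained generator:

* **Reference pool** — one random template; 9 conserved blocks totalling
  40% of the length, evenly interleaved with 10 variable blocks; each
  species mutates variable-block bases independently at rate 0.12. This
  conserved/variable architecture is what produces ambiguous mapping, the
  phenomenon behind abundance over-estimation in conserved regions; the
  divergence keeps distinct pool members near 85–90% identity, comparable
  to distinct SSU genera.
* **Community** — sources drawn without replacement; abundances i.i.d.
  log-normal. The distribution family is standard for microbial
  communities; its parameters are not pinned by any external source, so we
  chose $\mu = 0, \sigma = 1.5$ once (a realistic dynamic range of roughly
  three orders of magnitude over 30 sources) and expose both.
* **Reads** — fragment start uniform, insert $\sim N(350, 35)$ clamped to
  $[\text{read len}, \text{source len}]$, 2×150 mates, substitution errors
  at 0.2% per base uniformly over the three other bases, constant Phred 30
  qualities, pair ids encoding the source and coordinates as ground truth.
  Errors are substitution-only by default: the mapper tolerates one indel
  and the evaluation is identity-based, so indel simulation (config flag,
  default off) adds little discrimination.
* **Scenarios** — (a) sources verbatim in the reference database; (b)
  sources replaced by mutated copies whose nearest-database global identity
  is verified by alignment to lie in [0.95, 0.99] (mutation rates
  rejection-sampled until the band is hit); (c) sources removed from the
  database.

What the simulator does **not** emulate: instrument-trained quality/error
profiles, chimeric fragments, intra-genomic rRNA operon variation, and
length variation among sources. Passing the synthetic benchmarks therefore
demonstrates the pipeline's correctness under substitution noise and
conserved-block ambiguity, not robustness to every artefact of real
libraries.

## Evaluation

Reconstructed contigs are compared to the true sources by global pairwise
alignment with a 90% identity floor, in both directions: each contig's best
source and each source's best contig. At a similarity threshold $t$:
TP = contigs whose best source similarity $\ge t$ (the boundary is closed —
"above the threshold" is ambiguous at equality and $\ge$ was fixed);
FP = all other contigs, *including* contigs with no $\ge 90\%$ hit at all
(the conservative choice); FN = sources with no contig at $\ge t$.
Precision, sensitivity and F1 follow. Abundance recovery pairs each matched
source's true abundance with its closest contig's estimated abundance and
reports Pearson's r on raw values (the log–log view is also reported, since
log-normal abundances span decades).

## Problem sizes and study conditions

The packaged benchmarks run a 100-reference pool of 1500-base sequences, a
30-source community, and 100 000 read pairs with pipeline subsample
$n = 10\,000$ — a desk-scale proxy (reference pools of ~1000 sequences and
5 million pairs behave identically in structure but not in wall-clock).
The reduced-depth filtering benchmark uses 5 000 pairs, a depth at which
rare sources fall below the mean-coverage threshold so the contig filter is
actually exercised. Unit tests use still smaller pools (4–12 references,
hundreds of pairs) and lengths of 400–1500 bases.

## Numerical and design notes

* Determinism: every stochastic step derives from an explicit seed
  (generators) or from `base_seed + iteration` (subsampling); reruns are
  byte-identical.
* The dereplication sort key is length desc, then iteration of origin asc,
  then id asc. The iteration key matters: without it, a verbatim duplicate
  arriving in a later iteration could displace (and be counted against) the
  existing representative purely through id renaming, breaking the
  "re-presenting the set yields zero novelty" contract that termination
  depends on.
* E-step weights are computed in plain probability space: with the 90%
  identity floor a read's log-likelihood is bounded below by roughly
  $-100$, far from double underflow, so no log-sum-exp machinery is needed.
* The EM's read-candidate graph is fixed at initialisation: consensus
  changes re-score each cached alignment at its recorded coordinates
  (exact for the substitution-only, coordinate-stable updates) rather than
  re-running the seeded search, and no read-candidate pair is added after
  initialisation. Re-weighting and polishing happen within the initial
  alignment graph, a deliberate simplification of iterative-remapping EM
  designs; hits whose identity falls below the 90% floor as a candidate
  drifts are discarded.
* The seed prefilter also applies an identity bound: an alignment at
  identity $\ge m$ can destroy at most $k$ k-mers per edit, so a candidate
  sharing fewer than $V - k\lfloor(1-m)(L+\text{maxindel})\rfloor$ of the
  read's $V$ valid k-mers is rejected without alignment; this never
  changes which hits are reported. For the pool-shrinking step, which
  consumes only the mapped/unmapped split, the search floor is raised to
  the idfilter (a hit below the idfilter cannot make a unit mapped), so
  the bound bites much earlier.
* Consensus ties keep the current base; among non-current bases the
  alphabetically first wins — an arbitrary but fixed order.
* Zero-read samples are an error in abundance estimation; empty read sets,
  empty contig sets, and fully pruned EM models short-circuit to empty
  results rather than erroring inside the loop.

## Known limitations

Reference-guided assembly cannot reconstruct sequence absent from both the
reads' coverage and the database: in scenario c the assembler reports
database relatives polished only where $\ge 90\%$-identity reads align, so
variable regions of absent taxa remain unresolved and sensitivity at high
thresholds approaches zero — the expected failure mode of this method
class, reproduced here deliberately. Abundances of contigs sharing long
conserved blocks are smoothed toward each other by the $1/k$ ambiguity
split. The mapper is a seeded heuristic: a true best target sharing fewer
than `minhits` seeds with the read (possible only at error rates far above
the simulator's) can be missed.
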