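---
title: "Incremental naive Bayes taxonomic classification: model and design notes"
author: "kmernb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental naive Bayes taxonomic classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmernb)
```

## The classifier

`kmernb` classifies shotgun metagenomic reads to species with a naive Bayes
model over k-mer features. A species class $y_i$ keeps the raw count
$f(x_j \mid y_i)$ of every k-mer $x_j$ seen in its training genomes and the
total $T_i = \sum_j f(x_j \mid y_i)$. Class-conditional probabilities are
Laplace (add-one) smoothed over the complete alphabet of $K = 4^k$ words:

$$P(x_j \mid y_i) = \frac{f(x_j \mid y_i) + 1}{T_i + K}$$

so unseen k-mers get a small positive probability and the distribution sums
to exactly 1 (the test suite checks this exhaustively for $k \le 6$). A read
$\mathbf{x}$ is scored in log space,
$L(\mathbf{x} \mid y_i) = \sum_j \log P(x_j \mid y_i)$, and assigned to the
class with the largest $L$. Three modelling choices deserve comment:

- **Uniform prior, dropped.** Without knowledge of the sampled environment
  there is no defensible species prior; the posterior denominator is
  class-independent and irrelevant to the argmax, so both are omitted.
  (`classify_batchwise(all_scores = TRUE)` exposes the full score matrix for
  users who want normalized posteriors via log-sum-exp.)
- **Distinct k-mers by default.** The default `"unique"` mode sums each
  distinct k-mer of the read once; `"multiplicity"` weights by occurrence
  count. For short reads (~100–300 bp) at $k \ge 8$ most k-mers occur once
  and the two modes rarely disagree; both are first-class and tested, the
  default is a documented convention rather than a claim about which is
  superior.
- **Natural log everywhere.** The base only rescales scores uniformly;
  fixing it makes worked examples exact.

Classification is species-level only. Genus through phylum results are
*traced back* through the taxonomy from the species call — there are no
higher-rank models. A consequence tested as a property: accuracy is
non-decreasing from species to phylum whenever lineages resolve, because a
correct species call forces a correct call at every rank above.

Every read receives a label; there is no "unclassified" bin or confidence
threshold. Ties (e.g. a read whose k-mers are all invalid, scoring 0 against
every class) are broken deterministically toward the smallest taxid.

## Incremental updates as exact arithmetic

The sufficient statistics are integer sums, and the store keeps them raw —
smoothing is applied at query time. Updating a class with new genomes adds
their counts; creating a class starts from the new counts; merging species
$A$ into $B$ (a taxonomy revision) sets $f_B \leftarrow f_B + f_A$ and
deletes $A$'s savefile. Because integer addition is associative and
commutative, *any* partition of the training genomes into update batches, in
any order, produces byte-identical savefiles — the package's strongest
invariant, asserted at the file level across 20 random partitions in the
acceptance tests. Storing raw counts rather than probabilities is what makes
the equivalence exact rather than approximate, and lets $K$ (hence all
probabilities) be recomputed if needed.

Savefiles are plain text: `#`-prefixed header (taxid, k, strand mode, genome
tally, total) then `kmer<TAB>count` lines sorted lexicographically. The
format is deliberately boring — deterministic bytes make the
incremental-equals-batch guarantee directly testable with a checksum, and
corrupted or truncated files fail a total-vs-sum integrity check on load.
Class deletion (a taxid retired from the reference taxonomy) is simply
savefile removal; removing a *single genome* from a class is out of scope,
as it would require per-genome count retention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 in examples; 1–31 accepted | k-mer length; $K = 4^k$ smoothing mass. Larger k sharpens species separation but dilutes counts; the `kmer_size_sweep` harness measures the trade-off. The cap of 31 keeps a 2-bit packing inside one 64-bit word for future optimisation; storage is string-keyed regardless. |
| `canonical` | `FALSE` | pool each k-mer with its reverse complement (lexicographic minimum as key). Off by default to count strands separately, matching the plain (non-`-C`) convention of k-mer counters; a flag rather than a fixed choice because either convention is defensible. Reads and models must use the same setting — the store enforces it. |
| `mode` | `"unique"` | see above. |
| `threads` (`-t`) | 1 | worker processes, each scoring one class at a time. Scheduling only: the per-class score vectors are combined in ascending-taxid order, so results are bit-identical at any thread count. |
| memory cap (`-m`) / batch size (`-n`) | unset (one batch) | mutually exclusive batch layouts. The cap is accounted in read bytes (sequence length); class savefiles are additional, roughly `threads × savefile size`. Greedy in input order; an oversized read forms a warned singleton batch. Also pure scheduling — tested bit-identical across layouts. |
| `threshold` (profiling) | 0.05 | abundance below which a taxon is pooled into "Others: New" (taxa first added in the latest training division) or "Others: Old". Mass is conserved to 1e-12. |

## Numerical and degenerate-input choices

- Windows containing anything outside A/C/G/T (N, IUPAC codes, gaps) are
  skipped, not errors: real assemblies contain them routinely. Input case is
  ignored; storage is uppercase.
- A read shorter than k, or made entirely of invalid windows, has an empty
  k-mer table and scores 0 against every class; the smallest-taxid tie-break
  then applies.
- Bray-Curtis is computed on relative abundances over the union of taxon
  labels, none pooled; the unresolved fraction (reads with no ancestor at
  the profiled rank) is not a taxon and is excluded. On unit-sum profiles
  the statistic equals half the L1 distance; the implementation is
  cross-checked against `vegan::vegdist` in the tests.
- Taxonomy lineages missing an intermediate rank resolve to "none" at that
  rank; evaluation drops such reads from that rank's denominator and reports
  them as unresolved. Merged taxids are resolved transitively at load time;
  deleted-taxid lists (delnodes) are ignored — a deleted class is handled
  explicitly by `delete_class` instead.
- Cross-validation folds are balanced (sizes differ by at most one) and
  seeded; the seed is a required argument and is recorded on the result.
- A genome belongs to exactly one year: the calendar year of its release
  date. Grouping years into coarser divisions is a matter of passing a
  different `years` vector to `snapshot_experiment`.

## What the synthetic data emulates — and what it does not

`simulate_dataset` builds a six-rank taxonomy (root → phylum → class →
order → family → genus → species) in the exact NCBI dump dialect, one
ancestral random sequence per genus, species mutated from it at
`species_divergence`, strain genomes mutated from the species sequence at
`strain_divergence`, release years assigned round-robin, and error-free
fixed-length reads at uniform random positions (forward strand by default;
a strand flag exists to exercise canonical counting). Defaults — 2 phyla ×
2 genera × 3 species × 2 strains, 20 kb genomes, 10% species / 1% strain
divergence, 100 × 150 bp reads per genome, years 2016–2019 — are chosen so
that strains cluster tightly within well-separated species: a realistic
*shape* for the classification problem at a size where every experiment
runs in seconds. The per-base independent substitution model gives a
closed-form expected strain-pair divergence
$p = 2d(1-d) + \tfrac{2}{3}d^2$, which the tests verify within binomial
tolerance.

What passing on this generator does **not** show: real genomes have shared
mobile elements, conserved operons, repeats and uneven genome sizes that
create asymmetric k-mer sharing between distant taxa; real databases are
heavily imbalanced in genomes per species, which biases naive Bayes toward
over-represented classes; and real reads carry errors. The synthetic
accuracies (at or near 1.0) are therefore a *correctness* check of the
pipeline and its invariants, not a forecast of accuracy on real data, which
is known to be substantially lower at species rank.

## Problem sizes used in the checks

The test suite and acceptance script run on the default 24-genome / 2400-read
dataset for the end-to-end checks (cross-validation, 20 update partitions,
yearly snapshots, profile drift) and on a reduced 3 kb-genome variant for
module-level tests; these sizes were chosen so the full suite completes in
well under five minutes while still exercising every code path at realistic
structure. The byte-identity and bit-identity invariants are scale-free —
they hold by arithmetic, not by statistics — so small fixtures lose nothing
there.

## Known limitations

- No read-level confidence or "unclassified" output; downstream rejection is
  intentionally out of scope.
- No paired-end logic and no quality-score handling (training genomes and
  the simulated reads are error-free).
- Memory accounting for batches counts sequence bytes only; class savefile
  residency is the user's `threads × savefile` allowance.
- Genome-level removal from a class is unsupported (raw counts are pooled
  per class).
- The dense $4^k$ enumeration used by the normalization test is exponential
  in k and only run for $k \le 6$; the classifier itself is sparse and
  handles any $k \le 31$.
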