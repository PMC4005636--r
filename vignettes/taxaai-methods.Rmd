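---
title: "taxaai: model, weights and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxaai: model, weights and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`taxaai` treats every gene on a query sequence as a classifier whose vote is
worth what the gene's reference cluster has earned offline. The offline stage
builds the currency; the online stage spends it.

**Offline.** All-vs-all protein matches between reference genomes are reduced
to reciprocal best matches (RBM: a pair of genes, each the other's
highest-bitscore match between its two genomes) after filtering at >40%
amino acid identity, ≥70% coverage of the shorter gene, and e-value <1e-12.
Connected components of the RBM graph become gene clusters; genes that joined
no RBM edge are compared once more against the clustered genes and merged
into the cluster of their best passing match (paralog merging), the remainder
staying singletons — the clusters always partition the gene catalog.
Genome-aggregate AAI is the arithmetic mean identity over all RBM genes of a
genome pair; the species tree is the average-linkage (UPGMA) tree on
`d = (100 − AAI)/100`.

Each cluster then receives, per rank `t ∈ {phylum, genus, species}`:

* `D_t(x)`: identities of all member-gene pairs from distinct genomes are
  split into *intra* (genomes share the taxon at `t`) and *inter* sets, each
  smoothed by a Gaussian KDE with Scott's-rule bandwidth
  `h = σ̂ n^(−1/5)`, and `D_t(x) = f_intra(x) / (f_intra(x) + f_inter(x))`.
* `M`: the fraction of genome triplets whose closest pair under the cluster's
  gene distances matches the closest pair under the species-tree patristic
  distances; exhaustive up to 5000 member genomes, Monte-Carlo (default
  10,000 seeded triplets, binomial standard error reported) beyond.

**Online.** Per query gene, the top `N = 5` matches each contribute
`bitscore × (w_D D_t(identity) + w_M M)` to the taxon of the matched genome.
Candidate likelihood at a rank is the taxon's share of the total
contribution; the top candidate is accepted iff its likelihood is ≥ the
score cutoff (0.5), descending phylum → genus → species and restricting
candidates to the accepted parent's subtree. On the first rejection the query
receives a novelty call from the mean identity of the hits supporting its
deepest accepted taxon: ≥95 known species, [60, 95) novel species of the
matched genus, [45, 60) novel genus, <45 novel phylum-level lineage.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_identity` | 40 | % AAI, exclusive | twilight-zone floor for orthology |
| `min_coverage` | 0.7 | fraction of shorter gene | excludes domain-only matches |
| `max_evalue` | 1e-12 | e-value, exclusive | significance floor |
| `top_n` | 5 | matches/gene | `N = 1` degenerates to weighted best-hit/LCA; large N costs memory for little accuracy |
| `score_cutoff` | 0.5 | likelihood, inclusive | majority support required to descend |
| `w_d` | 0.5 | — | uninformative midpoint; `grid_search_wd()` recalibrates (grid 0.05…0.95, 10 replicates of 10% subsamples) |
| species/genus/phylum bands | 95 / 60–80 / 45 | % AAI | rank-delineation cutoffs; 95 rather than the 85 typical of older species designations |
| KDE fallback bandwidth | 0.5 | % identity | used when a point set has zero variance |

## What the generator emulates — and what it does not

`simulate_reference_set()` evolves one root protein per family down the
taxonomy tree. Per-branch substitution probabilities are solved backwards
from per-node identity targets: if a pair diverging at a node should show
identity `T`, each lineage below that node accumulates substitutions with
probability `q = 1 − sqrt(T/100)`, and a branch from cumulative `q_above` to
`q_below` mutates each site with `p = 1 − (1−q_above)/(1−q_below)`.
Conservation classes (slow/medium/fast) sit at fixed fractions (0.85 / 0.5 /
0.15) inside each rank's band, so slow families remain alignable across phyla
(they are what gives distant genome pairs a defined AAI, as conserved genes
do in real data) while fast families fall below the 40% clustering cutoff
between phyla and split into per-phylum clusters. HGT is planted by replacing
a fraction `hgt_rate` (default 0.05) of genes with a lightly diverged copy
from a different genus, with ground-truth labels emitted.

The `"small"` preset is deliberately unbalanced, mirroring real reference
collections: one phylum carries a deep multi-species genus (the
novel-species hold-out), one is a breadth of six two-genome genera (the
novel-genus hold-out), one is filler. Genome "DNA" is a deterministic codon
rendering of the proteins with 30-bp spacers; fragments are uniform substrings
with independent per-base substitution errors (default 1%), and the
similarity search is emulated by adding Gaussian noise (sd 1%) to the true
planted identities with `bitscore = 2 × aligned_length × identity/100`.

Not emulated: indels and alignment-induced coverage variation, genuinely
novel gene content (every query gene has a reference family), rank
heterogeneity beyond three levels, chimeras, and composition signal. A green
end-to-end test therefore establishes that the weighting/likelihood machinery
recovers planted structure — not field performance against live databases.

## Numerical and design choices

* **D functional form.** The published description defines D through the
  difference between inter- and intra-group identity distributions without a
  printed formula; we use the normalized two-class posterior
  `f_intra/(f_intra + f_inter)` — bounded, monotone in the density
  difference, exact 1/0 in the pure-class limits — with the literal clamped
  difference available as `d_mode = "difference"`. Where both densities
  underflow, D is 0.5 (uninformative). No intra observations ⇒ D ≡ 0; no
  inter ⇒ D ≡ 1; neither ⇒ the hit falls back to M alone.
* **M per rank.** The available text defines no rank-dependent triplet
  restriction, so M is computed once per cluster against the species tree and
  stored under each rank; the weight-DB manifest flags this.
* **Triplet topology from distances.** At triplet scale the tree topology is
  fully determined by the three pairwise distances, so per-triplet alignment
  and tree building are replaced by closest-pair comparison of gene distances
  `(100 − identity)/100` against species-tree patristic distances. Ties in
  either triplet are scored concordant (benefit of the doubt).
* **Species tree.** UPGMA on AAI distances: deterministic, ultrametric, and
  sufficient for triplet extraction; `method = "nj"` is available. Undefined
  AAI pairs are an error, never imputed. With paralogs merged, a genome's
  representative in a cluster is its member with the highest mean identity to
  other genomes' members.
* **Band boundaries.** Half-open, lower-inclusive: [45, 60), [60, 95),
  [95, 100]. The printed genus band tops out at 80%, leaving 80–95 undefined;
  everything in [60, 95) is treated as a novel species of the matched genus,
  consistent with how intermediate-identity reads are handled in validation
  practice.
* **Likelihood denominator.** Matches outside the accepted parent's subtree
  stay in the denominator (they dilute the likelihood); renormalization
  within the subtree is available (`parent_renorm = TRUE`) but off by
  default, matching the "share of all matching taxa" definition.
* **Best-match AAI.** Mean identity of the hits supporting the deepest
  accepted taxon (robust to one spurious hit); `aai_summary = "max"` is
  available. With nothing accepted, the mean over all used hits.
* **Acceptance-gate metric.** "Correct lineage" for a known fragment means
  the phylum is resolved and every resolved rank matches the truth. Fragments
  carrying a planted HGT gene often stop, correctly, at the genus rank —
  that is a false negative at the species rank, not a wrong prediction, and
  the evaluation module keeps the two categories (FN vs WP) distinct exactly
  as the benchmarking framework does.
* **Ties.** Best-match selection orders by bitscore, then identity, then
  accession; grid-search ties resolve to the `w_d` nearest 0.5, then smaller;
  cluster ids derive from each component's smallest member accession. All
  results are independent of input row order.

## Known limitations

* Weight records live in memory; the database layout (TSV + JSON sidecar) is
  built for desk-scale reference sets, not millions of clusters.
* A novel-phylum query in a world with only two remaining phyla has a
  degenerate 50/50 likelihood split, so phylum-level hold-outs are exercised
  through the band probes rather than the end-to-end gate.
* Sn/Sp macro-averaging over taxa follows the "weighted performance over all
  taxa" reading; pooled micro-averaging is provided as an alternative mode.
* The classifier trusts the hit table's `pident` as amino-acid identity
  (protein-vs-protein searches); nucleotide searches are out of scope.
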