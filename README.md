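# taxaai

Gene-weighted taxonomic classification of metagenomic and genomic sequences,
built on genome-aggregate **average amino acid identity (AAI)**.

## The problem

Assigning metagenomic contigs to taxa from homology searches is dominated by
two failure modes: highly conserved genes (the 16S paradox — informative at
the phylum rank, useless at the species rank) and horizontally transferred
genes, whose phylogeny contradicts the genome's. `taxaai` addresses both by
pre-computing, for every reference gene cluster `c` and each rank
`t ∈ {phylum, genus, species}`, two classifying-power weights:

* **D** — how well sequence identity within the cluster separates intra-taxon
  from inter-taxon gene pairs. Both identity distributions are smoothed with
  Gaussian kernel densities (Scott's-rule bandwidths) and
  `D(x) = f_intra(x) / (f_intra(x) + f_inter(x))` scores a match at identity
  `x`.
* **M** — how consistent the cluster's gene phylogeny is with the species
  tree (approximated by the AAI distance tree), as the fraction of concordant
  genome triplets over all `C(n,3)` triplets (Monte-Carlo sampled for clusters
  with more than 5000 members). Low M flags HGT-prone genes.

A query contig's genes are searched against the reference (BLAST-style
tabular input); each of the top `N = 5` matches of each gene contributes

    bitscore × (w_D · D(identity) + w_M · M),      w_D + w_M = 1

to the taxon encoding the matched gene. Per rank, a candidate taxon's
**likelihood** is its share of the total contribution; the classifier descends
phylum → genus → species while the top candidate's likelihood clears the
score cutoff (default 0.5). When the descent stops, the query's **novelty
rank** is called from its best-match AAI: ≥95% known species, 60–95% novel
species of the matched genus, 45–60% novel genus, <45% a novel phylum-level
lineage.

The offline builder clusters reference genes by reciprocal-best-match (RBM)
graph connected components (identity >40%, coverage of the shorter gene
≥70%, e-value <1e-12), merges paralogs into their best-matching cluster, and
computes AAI as the arithmetic mean identity of all RBM genes per genome
pair.

Everything is testable offline: a seeded synthetic generator emulates a
three-rank taxonomy with realistic AAI bands (within-species 96–99%,
within-genus 65–80%, within-phylum 48–58%, between phyla 30–42%), planted
HGT, and mock metagenome fragments (100–2000 bp, 1% substitution error).

## Worked example

Simulate a 34-genome reference world, hold out one species and one genus,
build the weight database, classify 1000 mock fragments:

```r
library(taxaai); library(data.table)
tax <- preset_taxonomy("small")
ref <- simulate_reference_set(tax, seed = 101)
held <- tax[species == "p01_g01_s03" | genus == "p02_g06"]$genome_id
reference_genomes <- setdiff(tax$genome_id, held)

matches <- simulate_reference_matches(ref, reference_genomes, seed = 102)
genes   <- ref$genes[genome_id %in% reference_genomes, .(accession, genome_id)]
built   <- build_clusters(matches, genes)
aai     <- aai_matrix(built$edges, genome_ids = sort(reference_genomes))
tree    <- build_species_tree(aai)
db      <- build_weight_db(built$clusters, matches[, .(gene_a, gene_b, identity)],
                           tax, tree, seed = 103)
#> weight_db: 54 clusters, 1200 genes; ranks: phylum/genus/species

mg   <- simulate_metagenome(ref, fragment_spec(n_fragments = 1000), seed = 106)
hits <- simulate_hits(mg, ref, reference_genomes = reference_genomes, seed = 107)
out  <- classify_batch(mg$genes[, .(contig_id = fragment_id, gene_id)], hits, db, tax)
out$results[1:3, .(contig_id, species, species_score, lowest_rank, novelty_call)]
#>     contig_id     species species_score lowest_rank  novelty_call
#> 1: frag000001 p02_g03_s01     0.6453748     species known species
#> 2: frag000002 p01_g02_s01     0.6487434     species known species
#> 3: frag000003 p03_g03_s02     0.6022481     species known species
```

With this seed the run prints: resolved lineage correct for 99.0% of the 876
known fragments (91.4% carry a fully correct species-level lineage — most of
the rest stop, correctly labelled, at the genus rank because a planted HGT
gene genuinely supports two species), novelty rank correct for 85.5% of the
124 held-out fragments, and species-rank macro sensitivity/specificity
0.919/0.913. A `species_score` of 0.65 means that taxon received 65% of the
total bit-score-weighted support of all matching taxa; `novelty_call` for an
unresolved fragment reports the AAI band of its supporting hits.

## Command line

```sh
taxaai simulate --preset small --seed 42 --out fixtures/
taxaai build-db --matches fixtures/reference_matches.tsv \
                --taxonomy fixtures/reference/taxonomy.tsv --out weightdb/
taxaai classify --gff fixtures/metagenome/fragments.gff3 --hits fixtures/hits.tsv \
                --db weightdb/ --taxonomy fixtures/reference/taxonomy.tsv \
                --score-cutoff 0.5 --top-n 5 --out results.tsv --krona out.xml
taxaai evaluate --results results.tsv --truth truth.tsv --rank species --out outcomes.tsv
taxaai optimize-weights --gff ... --hits ... --db ... --taxonomy ... --truth ...
```

(the launcher script is installed at `inst/exec/taxaai`; equivalently call
`taxaai::taxaai_main(c("classify", ...))`).

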