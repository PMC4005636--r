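library(data.table)

# ---- tiny hand-built worlds -------------------------------------------------

# gene catalog: n genomes x m genes, accessions "<genome>|g<i>"
toy_genes <- function(genomes, per_genome = 1L) {
  rbindlist(lapply(genomes, function(g)
    data.table(accession = sprintf("%s|g%d", g, seq_len(per_genome)),
               genome_id = g, length = 100L,
               sequence = strrep("A", 100L))))
}

toy_match <- function(a, b, identity, coverage = 0.9, evalue = 1e-30,
                      bitscore = identity * 2) {
  data.table(gene_a = a, gene_b = b, identity = identity, coverage = coverage,
             evalue = evalue, bitscore = bitscore)
}

toy_taxonomy <- function(genomes, phylum, genus, species) {
  data.table(genome_id = genomes, phylum = phylum, genus = genus,
             species = species)
}

# symmetric AAI matrix object from a named value list
toy_aai <- function(ids, pairs) {
  n <- length(ids)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(v) <- 100
  for (p in pairs) {
    v[p[[1L]], p[[2L]]] <- p[[3L]]; v[p[[2L]], p[[1L]]] <- p[[3L]]
  }
  structure(list(genome_ids = ids, values = v,
                 n_shared = matrix(1L, n, n, dimnames = list(ids, ids))),
            class = "aai_matrix")
}

# ---- independent oracles ----------------------------------------------------

# brute-force best-hit-in-both-directions RBM oracle over a directed match table
oracle_rbm <- function(matches, genes) {
  gmap <- setNames(genes$genome_id, genes$accession)
  m <- as.data.table(matches)
  m <- rbind(m, m[, .(gene_a = gene_b, gene_b = gene_a, identity, coverage,
                      evalue, bitscore)])
  m <- m[gmap[gene_a] != gmap[gene_b]]
  m <- unique(m, by = c("gene_a", "gene_b"))
  best_of <- function(g, target_genome) {
    cand <- m[gene_a == g & gmap[gene_b] == target_genome]
    if (nrow(cand) == 0L) return(NA_character_)
    cand <- cand[order(-bitscore, -identity, gene_b)]
    cand$gene_b[1L]
  }
  out <- list()
  for (i in seq_len(nrow(m))) {
    a <- m$gene_a[i]; b <- m$gene_b[i]
    if (a >= b) next
    if (identical(best_of(a, gmap[[b]]), b) && identical(best_of(b, gmap[[a]]), a))
      out[[length(out) + 1L]] <- data.table(gene_a = a, gene_b = b)
  }
  if (!length(out)) return(data.table(gene_a = character(), gene_b = character()))
  setorder(rbindlist(out), gene_a, gene_b)[]
}

# naive O(n^3) average-linkage agglomeration returning merge order signatures
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric()
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    merges[[length(merges) + 1L]] <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# sets of tip labels under each internal node of a phylo tree
tree_clades <- function(phy) {
  n_tip <- length(phy$tip.label)
  lapply((n_tip + 1L):(n_tip + phy$Nnode), function(nd)
    sort(ape::extract.clade(phy, nd)$tip.label))
}

# minimal weight_db: one record per cluster applied to all three ranks.
# rec fields: intra/inter KDE point sets (possibly empty) and m.
toy_weight_db <- function(clusters, recs) {
  records <- lapply(recs, function(r) {
    base <- list(
      intra = as.numeric(r$intra %||% numeric()),
      inter = as.numeric(r$inter %||% numeric()),
      bw_intra = if (length(r$intra %||% numeric())) scott_bandwidth(r$intra) else NA_real_,
      bw_inter = if (length(r$inter %||% numeric())) scott_bandwidth(r$inter) else NA_real_,
      n_intra = length(r$intra %||% numeric()),
      n_inter = length(r$inter %||% numeric()),
      m = r$m %||% 1.0, m_se = 0, n_triplets = 0L, m_method = "exact")
    list(phylum = base, genus = base, species = base)
  })
  structure(list(clusters = as.data.table(clusters), records = records,
                 manifest = list(format_version = "1.0", n_clusters = length(records),
                                 n_genes = nrow(clusters),
                                 ranks = c("phylum", "genus", "species"))),
            class = "weight_db")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared toy reference: 2 phyla / 2 genera each / 2 species each, one genome
# per species, one cluster per "family"
toy_ref_world <- function() {
  genomes <- c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2")
  tax <- toy_taxonomy(genomes,
                      phylum = rep(c("P1", "P2"), each = 4L),
                      genus = rep(c("gA", "gB", "gC", "gD"), each = 2L),
                      species = paste0("s", genomes))
  clusters <- data.table(cluster_id = "GC000001",
                         accession = paste0(genomes, "|f1"),
                         genome_id = genomes)
  db <- toy_weight_db(clusters, list(GC000001 = list(m = 1.0)))
  list(tax = tax, db = db)
}

# one outfmt6-style hit row
toy_hit <- function(q, s, pident, bitscore = pident * 2) {
  data.table(qseqid = q, sseqid = s, pident = pident, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = 1e-50, bitscore = bitscore)
}

# ---- cached expensive world for acceptance-scale tests ----------------------

.world_cache <- new.env(parent = emptyenv())

# The "small" preset world: 34 genomes, hold-outs for novel-species and
# novel-genus experiments, full offline build. Built once per test run.
small_world <- function() {
  if (!is.null(.world_cache$w)) return(.world_cache$w)
  tax <- preset_taxonomy("small")
  ref <- simulate_reference_set(tax, seed = 101L)
  held_species <- tax[species == "p01_g01_s03"]$genome_id
  held_genus <- tax[genus == "p02_g06"]$genome_id
  reference_genomes <- setdiff(tax$genome_id, c(held_species, held_genus))
  matches <- simulate_reference_matches(ref, reference_genomes, seed = 102L)
  genes <- ref$genes[genome_id %in% reference_genomes, .(accession, genome_id)]
  built <- build_clusters(matches, genes)
  aai <- aai_matrix(built$edges, genome_ids = sort(reference_genomes))
  tree <- build_species_tree(aai)
  db <- build_weight_db(built$clusters, matches[, .(gene_a, gene_b, identity)],
                        tax, tree, seed = 103L)
  .world_cache$w <- list(tax = tax, ref = ref, held_species = held_species,
                         held_genus = held_genus,
                         reference_genomes = reference_genomes,
                         matches = matches, built = built, aai = aai,
                         tree = tree, db = db)
  .world_cache$w
}
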