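#' Filter all-vs-all matches down to ortholog candidates
#'
#' Keeps matches with percent identity strictly above `min_identity` (default
#' 40), coverage of the shorter gene at least `min_coverage` (default 0.7) and
#' e-value strictly below `max_evalue` (default 1e-12).
#'
#' @param matches pair-match table (`gene_a`, `gene_b`, `identity`, `coverage`,
#'   `evalue`, `bitscore`), e.g. from [as_pair_matches()].
#' @param thresholds an [ortholog_thresholds()].
#' @return the passing subset, same columns.
#' @export
filter_ortholog_candidates <- function(matches, thresholds = ortholog_thresholds()) {
  m <- data.table::as.data.table(matches)
  req <- c("gene_a", "gene_b", "identity", "coverage", "evalue", "bitscore")
  if (!all(req %in% names(m)))
    stop("matches must have columns ", paste(req, collapse = ", "))
  if (nrow(m) == 0L) return(m)
  bad <- which(m$identity < 0 | m$identity > 100 | m$coverage < 0 |
                 m$coverage > 1 | m$evalue < 0 | m$bitscore < 0)
  if (length(bad))
    stop("malformed match row(s): ", paste(head(bad, 5), collapse = ", "),
         " (identity must be in [0,100], coverage in [0,1], evalue/bitscore >= 0)")
  m[identity > thresholds$min_identity &
      coverage >= thresholds$min_coverage &
      evalue < thresholds$max_evalue]
}

# Symmetrize matches into a directed table over distinct-genome gene pairs,
# deduplicating unordered pairs by best (bitscore, identity) evidence.
directed_matches <- function(matches, genes) {
  m <- data.table::as.data.table(matches)
  gmap <- setNames(genes$genome_id, genes$accession)
  ga <- gmap[m$gene_a]; gb <- gmap[m$gene_b]
  if (anyNA(ga) || anyNA(gb))
    stop("match references gene absent from catalog: ",
         paste(head(unique(c(m$gene_a[is.na(ga)], m$gene_b[is.na(gb)])), 3),
               collapse = ", "))
  m[, `:=`(src_genome = ga, dst_genome = gb)]
  m <- m[src_genome != dst_genome & gene_a != gene_b]
  if (nrow(m) == 0L) return(m[, .(src = gene_a, dst = gene_b, src_genome,
                                  dst_genome, identity, bitscore)])
  # canonical unordered key, keep best evidence per gene pair
  key1 <- pmin(m$gene_a, m$gene_b); key2 <- pmax(m$gene_a, m$gene_b)
  m[, `:=`(k1 = key1, k2 = key2)]
  data.table::setorder(m, k1, k2, -bitscore, -identity)
  m <- unique(m, by = c("k1", "k2"))
  both <- data.table::rbindlist(list(
    m[, .(src = gene_a, dst = gene_b, src_genome, dst_genome, identity, bitscore)],
    m[, .(src = gene_b, dst = gene_a, src_genome = dst_genome,
          dst_genome = src_genome, identity, bitscore)]))
  both
}

#' Find reciprocal-best-match (RBM) edges between genomes
#'
#' For every genome pair (G1, G2) and gene g in G1, g's best match in G2 is
#' retained only if g is in turn the best match of that gene back in G1. "Best"
#' means highest bitscore, ties broken by higher identity then lexicographically
#' smaller accession, so results are independent of input row order.
#'
#' @param matches filtered pair matches (see [filter_ortholog_candidates()]).
#' @param genes gene catalog mapping accessions to genomes.
#' @return `data.table` of RBM edges: `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `genome_a`, `genome_b`, `identity`, `bitscore`.
#' @export
find_rbm_edges <- function(matches, genes) {
  d <- directed_matches(matches, genes)
  empty <- data.table::data.table(gene_a = character(), gene_b = character(),
                                  genome_a = character(), genome_b = character(),
                                  identity = numeric(), bitscore = numeric())
  if (nrow(d) == 0L) return(empty)
  data.table::setorder(d, src, dst_genome, -bitscore, -identity, dst)
  best <- unique(d, by = c("src", "dst_genome"))
  # an edge is RBM iff selected in both directions
  fwd <- best[, .(src, dst)]
  rev <- best[, .(src = dst, dst = src)]
  rbm <- merge(fwd, rev, by = c("src", "dst"))
  if (nrow(rbm) == 0L) return(empty)
  e <- merge(rbm, best, by = c("src", "dst"))
  e <- e[src < dst]
  out <- e[, .(gene_a = src, gene_b = dst, genome_a = src_genome,
               genome_b = dst_genome, identity, bitscore)]
  data.table::setorder(out, gene_a, gene_b)
  out[]
}

#' Group genes into clusters by RBM-graph connected components
#'
#' Every connected component of the RBM graph becomes one cluster; genes with
#' no RBM edge become singleton clusters, so the output partitions the catalog.
#' Cluster ids are `GC` + zero-padded index, assigned in order of each
#' cluster's lexicographically smallest member for determinism.
#'
#' @param edges RBM edges from [find_rbm_edges()].
#' @param genes gene catalog (all genes to be partitioned).
#' @return `data.table` with columns `cluster_id`, `accession`, `genome_id`.
#' @export
cluster_by_components <- function(edges, genes) {
  acc <- sort(genes$accession)
  n <- length(acc)
  parent <- seq_len(n)
  if (nrow(edges)) {
    ia <- match(edges$gene_a, acc); ib <- match(edges$gene_b, acc)
    if (anyNA(ia) || anyNA(ib)) stop("edge references gene absent from catalog")
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(i) { while (parent[i] != i) i <- parent[i]; i }, integer(1))
  # id clusters by smallest member accession (roots are minima by construction)
  comp <- match(root, sort(unique(root)))
  ids <- sprintf("GC%06d", comp)
  out <- data.table::data.table(cluster_id = ids, accession = acc)
  out <- merge(out, data.table::as.data.table(genes)[, .(accession, genome_id)],
               by = "accession", sort = TRUE)
  data.table::setcolorder(out, c("cluster_id", "accession", "genome_id"))
  data.table::setorder(out, cluster_id, accession)
  out[]
}

#' Merge paralog (non-RBM) genes into their best-matching cluster
#'
#' Paralogs — genes that took part in no RBM edge (singleton clusters unless
#' given explicitly) — are compared against clustered genes; each paralog whose
#' best match passes the ortholog thresholds joins the cluster of its
#' highest-bitscore matching gene (ties: higher identity, then smaller
#' accession). Paralogs without a passing match stay singletons.
#'
#' @param clusters partition from [cluster_by_components()].
#' @param matches paralog-vs-clustered-gene pair matches (unfiltered).
#' @param thresholds an [ortholog_thresholds()].
#' @param paralogs optional character vector of paralog accessions; defaults to
#'   all genes currently in singleton clusters.
#' @return updated cluster table (still a partition of the same genes).
#' @export
merge_paralogs <- function(clusters, matches, thresholds = ortholog_thresholds(),
                           paralogs = NULL) {
  cl <- data.table::copy(data.table::as.data.table(clusters))
  if (is.null(paralogs)) {
    sizes <- cl[, .N, by = cluster_id]
    paralogs <- cl[cluster_id %in% sizes[N == 1L]$cluster_id]$accession
  }
  if (length(paralogs) == 0L || nrow(matches) == 0L) return(cl)
  m <- filter_ortholog_candidates(matches, thresholds)
  if (nrow(m) == 0L) return(cl)
  # orient rows paralog -> clustered gene (accept either input orientation)
  para <- unique(paralogs)
  m2 <- data.table::rbindlist(list(
    m[, .(p = gene_a, g = gene_b, identity, bitscore)],
    m[, .(p = gene_b, g = gene_a, identity, bitscore)]))
  m2 <- m2[p %in% para & !(g %in% para)]
  if (nrow(m2) == 0L) return(cl)
  data.table::setorder(m2, p, -bitscore, -identity, g)
  best <- unique(m2, by = "p")
  target <- setNames(cl$cluster_id[match(best$g, cl$accession)], best$p)
  target <- target[!is.na(target)]
  if (length(target)) {
    i <- match(names(target), cl$accession)
    cl$cluster_id[i] <- unname(target)
  }
  data.table::setorder(cl, cluster_id, accession)
  cl[]
}

#' Build gene clusters end-to-end from matches
#'
#' Convenience wrapper: filter, RBM detection, connected components, paralog
#' merging.
#'
#' @inheritParams find_rbm_edges
#' @inheritParams merge_paralogs
#' @return list with `clusters` (partition table) and `edges` (RBM edges).
#' @export
build_clusters <- function(matches, genes, thresholds = ortholog_thresholds()) {
  flt <- filter_ortholog_candidates(matches, thresholds)
  edges <- find_rbm_edges(flt, genes)
  cl <- cluster_by_components(edges, genes)
  cl <- merge_paralogs(cl, matches, thresholds)
  list(clusters = cl, edges = edges)
}
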