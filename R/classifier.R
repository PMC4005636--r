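#' Trim similarity-search hits to the top N per query gene
#'
#' Hits are ranked per query gene by bitscore (descending), ties broken by
#' higher identity then lexicographically smaller subject accession, so the
#' selection is independent of input row order.
#'
#' @param hits table with at least `qseqid`, `sseqid`, `pident`, `bitscore`.
#' @param top_n matches to keep per gene (default 5; 1 gives the weighted
#'   best-hit/LCA degenerate case).
#' @return trimmed `data.table`.
#' @export
select_top_hits <- function(hits, top_n = 5L) {
  h <- data.table::as.data.table(hits)
  if (nrow(h) == 0L) return(h)
  data.table::setorder(h, qseqid, -bitscore, -pident, sseqid)
  h[, head(.SD, top_n), by = qseqid]
}

#' Raw weighted contribution of one or more hits at a rank
#'
#' `contribution = bitscore x (w_d D(identity) + w_m M)`; when the cluster has
#' no usable D at the rank (no intra and no inter observations) the hit
#' contributes with weight `M` alone.
#'
#' @param hits hit rows (`pident`, `bitscore`) all belonging to one cluster.
#' @param weights the cluster's weight record at the rank
#'   (from [weight_db_lookup()]).
#' @param cfg a [classifier_config()].
#' @return numeric vector of non-negative contributions.
#' @export
score_match <- function(hits, weights, cfg = classifier_config()) {
  d <- d_eval(weights, hits$pident, mode = cfg$d_mode)
  w <- ifelse(is.na(d), weights$m,
              combined_weight(d, weights$m, cfg$weight_cfg))
  hits$bitscore * w
}

#' Normalize per-taxon contributions into likelihoods at one rank
#'
#' Likelihood of a taxon = (sum of weighted contributions supporting it) /
#' (total over all matching taxa); likelihoods sum to 1. Multiple genes hitting
#' the same taxon raise its share.
#'
#' @param contributions table with `taxon` and `contrib` columns.
#' @return `data.table` of candidate scores: `taxon`, `raw_weight_sum`,
#'   `likelihood`, `supporting_matches`, sorted by decreasing likelihood;
#'   zero rows when total weight is 0 (rank unresolved).
#' @export
rank_likelihoods <- function(contributions) {
  co <- data.table::as.data.table(contributions)
  co <- co[!is.na(taxon) & contrib > 0]
  if (nrow(co) == 0L)
    return(data.table::data.table(taxon = character(), raw_weight_sum = numeric(),
                                  likelihood = numeric(),
                                  supporting_matches = integer()))
  agg <- co[, .(raw_weight_sum = sum(contrib), supporting_matches = .N), by = taxon]
  agg[, likelihood := raw_weight_sum / sum(raw_weight_sum)]
  data.table::setorder(agg, -likelihood, taxon)
  agg[]
}

#' Prepare a scored hit table for classification
#'
#' Joins hits to query contigs, trims to the top N per gene, resolves subject
#' accessions to clusters and reference lineages, and evaluates D and M per
#' rank. The result is independent of the weight vector `w_d`, so grid-search
#' re-classification under different weight configurations can reuse it.
#'
#' @param contig_genes gene calls (`contig_id`, `gene_id`) from [read_gff3()].
#' @param hits similarity-search hits from [read_hits()] (qseqid must match
#'   `gene_id`).
#' @param db a `weight_db`.
#' @param taxonomy reference taxonomy from [read_taxonomy()].
#' @param cfg a [classifier_config()].
#' @return `data.table`, one row per retained hit, with lineage columns
#'   (`phylum`, `genus`, `species`), `d_<rank>`/`m_<rank>` values, and a
#'   `n_unmatched` attribute counting hits whose subject was absent from the db.
#' @export
prepare_hit_table <- function(contig_genes, hits, db, taxonomy,
                              cfg = classifier_config()) {
  h <- data.table::as.data.table(hits)
  cg <- data.table::as.data.table(contig_genes)
  h <- merge(h, cg[, .(gene_id, contig_id)], by.x = "qseqid", by.y = "gene_id")
  i <- match(h$sseqid, db$clusters$accession)
  n_unmatched <- sum(is.na(i))
  h <- h[!is.na(i)]
  i <- i[!is.na(i)]
  h[, `:=`(cluster_id = db$clusters$cluster_id[i],
           subject_genome = db$clusters$genome_id[i])]
  if (length(cfg$exclude_genomes))
    h <- h[!subject_genome %in% cfg$exclude_genomes]
  h <- select_top_hits(h, cfg$top_n)
  for (rk in CLASSIFY_RANKS) {
    data.table::set(h, j = rk, value = if (nrow(h))
      taxon_at(taxonomy, h$subject_genome, rk) else character())
  }
  for (rk in CLASSIFY_RANKS) {
    dcol <- paste0("d_", rk); mcol <- paste0("m_", rk)
    data.table::set(h, j = dcol, value = NA_real_)
    data.table::set(h, j = mcol, value = NA_real_)
    if (nrow(h) == 0L) next
    for (cid in unique(h$cluster_id)) {
      rec <- db$records[[cid]][[rk]]
      rows <- which(h$cluster_id == cid)
      if (is.null(rec)) next
      data.table::set(h, i = rows, j = dcol,
                      value = d_eval(rec, h$pident[rows], mode = cfg$d_mode))
      data.table::set(h, i = rows, j = mcol, value = rec$m)
    }
  }
  data.table::setattr(h, "n_unmatched", n_unmatched)
  h[]
}

# Classify all contigs from a prepared hit table. Internal engine behind
# classify_contig / classify_batch / the grid-search optimizer.
classify_prepared <- function(prep, contig_ids, cfg = classifier_config()) {
  res <- data.table::data.table(
    contig_id = contig_ids,
    phylum = NA_character_, phylum_score = NA_real_,
    genus = NA_character_, genus_score = NA_real_,
    species = NA_character_, species_score = NA_real_,
    lowest_rank = "unclassified", novelty_call = NA_character_,
    best_match_aai = NA_real_, n_hits_used = 0L)
  if (nrow(prep) == 0L) return(res)
  p <- data.table::copy(prep)
  wcfg <- cfg$weight_cfg
  for (rk in CLASSIFY_RANKS) {
    d <- p[[paste0("d_", rk)]]; m <- p[[paste0("m_", rk)]]
    w <- data.table::fifelse(is.na(m), NA_real_,
           data.table::fifelse(is.na(d), m, wcfg$w_d * d + wcfg$w_m * m))
    data.table::set(p, j = paste0("contrib_", rk), value = p$bitscore * w)
  }
  used <- p[, .(n_hits_used = .N), by = contig_id]
  res[used, n_hits_used := i.n_hits_used, on = "contig_id"]

  accepted <- data.table::data.table(contig_id = unique(p$contig_id))
  state <- NULL  # per-contig accepted lineage so far
  for (ri in seq_along(CLASSIFY_RANKS)) {
    rk <- CLASSIFY_RANKS[ri]
    lineage_cols <- CLASSIFY_RANKS[seq_len(ri)]
    ccol <- paste0("contrib_", rk)
    cand <- p[!is.na(get(rk)) & !is.na(get(ccol)) & get(ccol) > 0,
              c("contig_id", lineage_cols, ccol), with = FALSE]
    if (nrow(cand) == 0L) break
    agg <- cand[, .(s = sum(get(ccol))), by = c("contig_id", lineage_cols)]
    tot <- agg[, .(tot = sum(s)), by = contig_id]
    if (!is.null(state)) {
      # restrict candidates to the accepted parent's subtree
      parent_cols <- CLASSIFY_RANKS[seq_len(ri - 1L)]
      agg <- merge(agg, state, by = c("contig_id", parent_cols))
      if (cfg$parent_renorm)
        tot <- agg[, .(tot = sum(s)), by = contig_id]
    }
    if (nrow(agg) == 0L) break
    agg <- merge(agg, tot, by = "contig_id")
    agg[, likelihood := s / tot]
    data.table::setorderv(agg, c("contig_id", "likelihood", rk),
                          order = c(1L, -1L, 1L))
    top <- unique(agg, by = "contig_id")
    acc <- top[likelihood >= cfg$score_cutoff]
    if (nrow(acc) == 0L) break
    res[acc, (rk) := get(paste0("i.", rk)), on = "contig_id"]
    res[acc, paste0(rk, "_score") := i.likelihood, on = "contig_id"]
    res[acc, lowest_rank := rk, on = "contig_id"]
    state <- acc[, c("contig_id", lineage_cols), with = FALSE]
  }

  # best-match AAI: mean (or max) identity of hits supporting the deepest
  # accepted taxon; with no accepted rank, over all usable hits
  summ <- if (identical(cfg$aai_summary, "max")) max else mean
  deepest <- res[n_hits_used > 0L,
                 .(contig_id, phylum, genus, species, lowest_rank)]
  for (k in seq_len(nrow(deepest))) {
    cid <- deepest$contig_id[k]
    lr <- deepest$lowest_rank[k]
    sub <- p[contig_id == cid]
    if (lr != "unclassified") {
      cols <- CLASSIFY_RANKS[seq_len(match(lr, CLASSIFY_RANKS))]
      for (cc in cols) sub <- sub[get(cc) == deepest[[cc]][k] & !is.na(get(cc))]
    }
    if (nrow(sub) == 0L) sub <- p[contig_id == cid]
    res[contig_id == cid, best_match_aai := summ(sub$pident)]
  }
  res[n_hits_used > 0L & lowest_rank == "species", novelty_call := "known species"]
  todo <- res$n_hits_used > 0L & res$lowest_rank != "species" &
    !is.na(res$best_match_aai)
  if (any(todo))
    res[todo, novelty_call := novelty_rank(pmin(pmax(best_match_aai, 0), 100),
                                           cfg$bands)]
  res[]
}

#' Classify one query contig
#'
#' Descends phylum, then genus, then species: at each rank the candidate taxa
#' within the accepted parent are scored by their share of the total weighted
#' support, and the top candidate is accepted iff its likelihood reaches the
#' score cutoff. On the first rejection the descent stops and the contig gets a
#' novelty call from its best-match AAI. A contig with no usable hits is
#' `"unclassified"`.
#'
#' @param contig_genes gene calls for the contig (`contig_id`, `gene_id`).
#' @param hits similarity-search hits for the contig's genes.
#' @param db a `weight_db`.
#' @param taxonomy reference taxonomy.
#' @param cfg a [classifier_config()].
#' @return one-row `data.table` (see [classify_batch()] for columns).
#' @export
classify_contig <- function(contig_genes, hits, db, taxonomy,
                            cfg = classifier_config()) {
  cg <- data.table::as.data.table(contig_genes)
  stopifnot(length(unique(cg$contig_id)) == 1L)
  classify_batch(cg, hits, db, taxonomy, cfg)$results
}

#' Classify a batch of query contigs
#'
#' @param contig_genes gene calls (`contig_id`, `gene_id`) from [read_gff3()].
#' @param hits similarity-search hits from [read_hits()].
#' @param db a `weight_db`.
#' @param taxonomy reference taxonomy.
#' @param cfg a [classifier_config()].
#' @return list with `results` (one row per contig, deterministic order:
#'   `contig_id`, per-rank taxon + likelihood, `lowest_rank`, `novelty_call`,
#'   `best_match_aai`, `n_genes`, `n_hits_used`) and `diagnostics`
#'   (`n_unmatched_hits`).
#' @export
classify_batch <- function(contig_genes, hits, db, taxonomy,
                           cfg = classifier_config()) {
  cg <- data.table::as.data.table(contig_genes)
  contig_ids <- sort(unique(cg$contig_id))
  prep <- prepare_hit_table(cg, hits, db, taxonomy, cfg)
  res <- classify_prepared(prep, contig_ids, cfg)
  n_genes <- cg[, .(n_genes = data.table::uniqueN(gene_id)), by = contig_id]
  res <- merge(res, n_genes, by = "contig_id", all.x = TRUE, sort = TRUE)
  data.table::setcolorder(res, c("contig_id", "phylum", "phylum_score", "genus",
                                 "genus_score", "species", "species_score",
                                 "lowest_rank", "novelty_call", "best_match_aai",
                                 "n_genes", "n_hits_used"))
  list(results = res[],
       diagnostics = list(n_unmatched_hits = attr(prep, "n_unmatched")))
}
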