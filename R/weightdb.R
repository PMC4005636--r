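WEIGHT_DB_VERSION <- "1.0"

# Drop genomes with undefined representative distances until the matrix is
# complete (greedy: remove the genome with most NAs first).
complete_distance_submatrix <- function(dm) {
  repeat {
    nas <- rowSums(is.na(dm))
    if (!any(nas > 0L) || nrow(dm) <= 2L) return(dm)
    worst <- which.max(nas)
    dm <- dm[-worst, -worst, drop = FALSE]
  }
}

#' Build the per-cluster classification weight database
#'
#' For every gene cluster and each rank (phylum, genus, species) computes the
#' discriminative KDE record for D and the triplet-concordance weight M
#' (computed once per cluster against the species tree and stored under every
#' rank; see the methods vignette).
#'
#' @param clusters cluster partition (`cluster_id`, `accession`, `genome_id`).
#' @param pair_identities gene-pair percent identities (`gene_a`, `gene_b`,
#'   `identity`); used for both D observations and triplet gene distances.
#' @param taxonomy table from [read_taxonomy()].
#' @param species_tree `phylo` AAI tree over the reference genomes.
#' @param ranks ranks to parameterize (default phylum/genus/species).
#' @param max_exhaustive,mc_samples,seed Monte-Carlo controls for M
#'   (see [m_weight()]).
#' @param fallback_bw zero-variance KDE fallback bandwidth (identity percent).
#' @return a `weight_db` object (clusters, per-cluster records, manifest).
#' @export
build_weight_db <- function(clusters, pair_identities, taxonomy, species_tree,
                            ranks = CLASSIFY_RANKS, max_exhaustive = 5000L,
                            mc_samples = 10000L, seed = NULL, fallback_bw = 0.5) {
  cl <- data.table::as.data.table(clusters)
  pi <- data.table::as.data.table(pair_identities)
  pi_by_gene <- NULL
  records <- list()
  split_cl <- split(cl, by = "cluster_id", keep.by = TRUE)
  for (cid in names(split_cl)) {
    mb <- split_cl[[cid]]
    sub <- pi[gene_a %in% mb$accession & gene_b %in% mb$accession]
    # M: once per cluster
    if (length(unique(mb$genome_id)) >= 3L && nrow(sub)) {
      dm <- complete_distance_submatrix(cluster_genome_distances(mb, sub))
      mres <- m_weight(dm, species_tree, max_exhaustive = max_exhaustive,
                       mc_samples = mc_samples, seed = seed)
    } else {
      mres <- list(m = 1.0, n_triplets = 0L, se = 0, method = "degenerate")
    }
    per_rank <- list()
    for (rk in ranks) {
      obs <- suppressWarnings(collect_identity_observations(mb, sub, taxonomy, rk))
      rec <- new_d_record(obs$identity[obs$category == "intra"],
                          obs$identity[obs$category == "inter"],
                          fallback_bw = fallback_bw)
      rec$m <- mres$m
      rec$m_se <- mres$se
      rec$n_triplets <- mres$n_triplets
      rec$m_method <- mres$method
      per_rank[[rk]] <- rec
    }
    records[[cid]] <- per_rank
  }
  manifest <- list(
    format_version = WEIGHT_DB_VERSION,
    ranks = ranks,
    max_exhaustive = max_exhaustive,
    mc_samples = mc_samples,
    fallback_bw = fallback_bw,
    d_form = "posterior f_intra/(f_intra+f_inter); difference mode at classify time",
    m_note = "M computed once per cluster vs the AAI species tree, stored per rank",
    n_clusters = length(records),
    n_genes = nrow(cl))
  structure(list(clusters = cl, records = records, manifest = manifest),
            class = "weight_db")
}

#' @export
print.weight_db <- function(x, ...) {
  cat("weight_db:", x$manifest$n_clusters, "clusters,",
      x$manifest$n_genes, "genes; ranks:",
      paste(x$manifest$ranks, collapse = "/"), "\n")
  invisible(x)
}

#' Look up the cluster and rank weights for a gene accession
#'
#' @param db a `weight_db`.
#' @param accession subject gene accession.
#' @return list with `cluster_id` and `ranks` (per-rank weight records), or
#'   `NULL` when the accession is unknown.
#' @export
weight_db_lookup <- function(db, accession) {
  i <- match(accession, db$clusters$accession)
  if (is.na(i)) return(NULL)
  cid <- db$clusters$cluster_id[i]
  list(cluster_id = cid, ranks = db$records[[cid]])
}

#' Write / read a weight database directory
#'
#' Layout: `clusters.tsv` (membership), `weights.tsv` (per cluster x rank
#' scalars), `kde.json` (intra/inter KDE point sets), `manifest.json`
#' (build parameters; byte-stable — no timestamps).
#'
#' @param db a `weight_db`.
#' @param dir target directory (created if needed).
#' @return `dir` (write) / `weight_db` (read).
#' @export
write_weight_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clusters_tsv(db$clusters, file.path(dir, "clusters.tsv"))
  rows <- list()
  kde <- list()
  for (cid in names(db$records)) {
    kde[[cid]] <- list()
    for (rk in names(db$records[[cid]])) {
      r <- db$records[[cid]][[rk]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        cluster_id = cid, rank_name = rk, n_intra = r$n_intra,
        n_inter = r$n_inter, bw_intra = r$bw_intra, bw_inter = r$bw_inter,
        m = r$m, m_se = r$m_se, n_triplets = r$n_triplets,
        m_method = r$m_method)
      kde[[cid]][[rk]] <- list(intra = r$intra, inter = r$inter)
    }
  }
  data.table::fwrite(data.table::rbindlist(rows), file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(kde, file.path(dir, "kde.json"), digits = NA)
  jsonlite::write_json(db$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_weight_db
#' @export
read_weight_db <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop("not a weight database (missing manifest.json): ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), WEIGHT_DB_VERSION))
    warning("weight-db format version ", manifest$format_version,
            " differs from supported ", WEIGHT_DB_VERSION)
  clusters <- read_clusters_tsv(file.path(dir, "clusters.tsv"))
  wt <- data.table::fread(file.path(dir, "weights.tsv"), sep = "\t", header = TRUE)
  kde <- jsonlite::read_json(file.path(dir, "kde.json"), simplifyVector = TRUE)
  records <- list()
  for (i in seq_len(nrow(wt))) {
    cid <- wt$cluster_id[i]; rk <- wt$rank_name[i]
    pts <- kde[[cid]][[rk]]
    records[[cid]][[rk]] <- list(
      intra = as.numeric(pts$intra %||% numeric()),
      inter = as.numeric(pts$inter %||% numeric()),
      bw_intra = wt$bw_intra[i], bw_inter = wt$bw_inter[i],
      n_intra = wt$n_intra[i], n_inter = wt$n_inter[i],
      m = wt$m[i], m_se = wt$m_se[i], n_triplets = wt$n_triplets[i],
      m_method = wt$m_method[i])
  }
  structure(list(clusters = data.table::as.data.table(clusters),
                 records = records, manifest = manifest),
            class = "weight_db")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
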