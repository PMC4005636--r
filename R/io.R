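#' Read a reference gene catalog from protein FASTA + gene-to-genome map
#'
#' The accession of each gene is the first whitespace-delimited token of its
#' FASTA header. The map is a two-column TSV (`accession`, `genome_id`) with a
#' header line.
#'
#' @param fasta_path protein FASTA file.
#' @param map_path gene-to-genome TSV.
#' @return `data.table` with columns `accession`, `genome_id`, `length`,
#'   `sequence`.
#' @export
read_gene_catalog <- function(fasta_path, map_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicate gene accession(s) in ", fasta_path, ": ",
         paste(unique(acc[duplicated(acc)])[1:3], collapse = ", "))
  map <- data.table::fread(map_path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!all(c("accession", "genome_id") %in% names(map)))
    stop("gene map must have columns 'accession' and 'genome_id': ", map_path)
  genes <- data.table::data.table(accession = acc,
                                  sequence = as.character(seqs),
                                  length = Biostrings::width(seqs))
  if (any(genes$length == 0L)) stop("zero-length gene sequence in ", fasta_path)
  genes <- merge(genes, map[, .(accession, genome_id)], by = "accession",
                 all.x = TRUE, sort = TRUE)
  if (anyNA(genes$genome_id))
    stop("gene(s) missing from genome map: ",
         paste(head(genes$accession[is.na(genes$genome_id)], 3), collapse = ", "))
  genes[, .(accession, genome_id, length, sequence)]
}

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular similarity-search result (BLAST outfmt-6 style)
#'
#' Expects 12 standard columns, optionally a 13th coverage column (fraction of
#' the shorter gene covered). Rows whose numeric fields fail to parse are
#' skipped and counted in the `n_skipped` attribute, never fatal.
#'
#' @param path TSV file without header.
#' @return `data.table` with outfmt-6 column names (plus `coverage` when a 13th
#'   column is present); attribute `n_skipped` counts dropped rows.
#' @export
read_hits <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = FALSE,
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) == 0L) {
    out <- data.table::as.data.table(
      c(list(qseqid = character(), sseqid = character()),
        lapply(setNames(nm = OUTFMT6_COLS[3:12]), function(.) numeric())))
    data.table::setattr(out, "n_skipped", 0L)
    return(out)
  }
  ncol_in <- ncol(raw)
  if (!ncol_in %in% c(12L, 13L))
    stop("hits file must have 12 or 13 tab-separated columns, found ",
         ncol_in, ": ", path)
  nm <- c(OUTFMT6_COLS, if (ncol_in == 13L) "coverage")
  data.table::setnames(raw, nm)
  num_cols <- setdiff(nm, c("qseqid", "sseqid"))
  for (cc in num_cols)
    data.table::set(raw, j = cc, value = suppressWarnings(as.numeric(raw[[cc]])))
  ok <- rowSums(is.na(as.matrix(raw[, num_cols, with = FALSE]))) == 0L
  out <- raw[ok]
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (cc in int_cols) data.table::set(out, j = cc, value = as.integer(out[[cc]]))
  data.table::setattr(out, "n_skipped", sum(!ok))
  out[]
}

#' Convert similarity-search hits to pairwise ortholog-candidate matches
#'
#' Attaches coverage when absent: `aln_length / min(qlen, slen)` from the gene
#' catalog lengths (aligned-column count over the shorter gene).
#'
#' @param hits table from [read_hits()].
#' @param genes gene catalog (for lengths, when no coverage column).
#' @return `data.table` with columns `gene_a`, `gene_b`, `identity`, `coverage`,
#'   `evalue`, `bitscore`.
#' @export
as_pair_matches <- function(hits, genes = NULL) {
  h <- data.table::as.data.table(hits)
  if (!"coverage" %in% names(h)) {
    if (is.null(genes))
      stop("hits lack a coverage column; a gene catalog is required to derive it")
    len <- setNames(genes$length, genes$accession)
    qlen <- len[h$qseqid]; slen <- len[h$sseqid]
    if (anyNA(qlen) || anyNA(slen))
      stop("hit references gene absent from catalog: ",
           paste(head(unique(c(h$qseqid[is.na(qlen)], h$sseqid[is.na(slen)])), 3),
                 collapse = ", "))
    h[, coverage := pmin(length / pmin(qlen, slen), 1)]
  }
  h[, .(gene_a = qseqid, gene_b = sseqid, identity = pident,
        coverage, evalue, bitscore)]
}

#' Read a genome taxonomy table
#'
#' Flat TSV with header; required columns `genome_id`, `phylum`, `genus`,
#' `species`; optional intermediate ranks (`class`, `order`, `family`) are kept.
#' Empty cells mean "unranked".
#'
#' @param path TSV file.
#' @return `data.table` keyed by `genome_id`.
#' @export
read_taxonomy <- function(path) {
  tx <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  req <- c("genome_id", "phylum", "genus", "species")
  if (!all(req %in% names(tx)))
    stop("taxonomy must have columns ", paste(req, collapse = ", "), ": ", path)
  if (anyDuplicated(tx$genome_id))
    stop("duplicate genome_id in taxonomy: ",
         paste(unique(tx$genome_id[duplicated(tx$genome_id)])[1:3], collapse = ", "))
  data.table::setkeyv(tx, "genome_id")
  tx[]
}

#' Look up the taxon of genomes at one rank
#'
#' @param taxonomy table from [read_taxonomy()].
#' @param genome_ids character vector.
#' @param rank one of `"phylum"`, `"genus"`, `"species"` (or an optional
#'   intermediate rank present in the table).
#' @return character vector; `NA` for unranked (empty) cells.
#' @export
taxon_at <- function(taxonomy, genome_ids, rank) {
  if (!rank %in% names(taxonomy)) stop("rank not in taxonomy: ", rank)
  i <- match(genome_ids, taxonomy$genome_id)
  if (anyNA(i))
    stop("genome(s) missing from taxonomy: ",
         paste(head(genome_ids[is.na(i)], 3), collapse = ", "))
  v <- taxonomy[[rank]][i]
  v[!nzchar(v)] <- NA_character_
  v
}

#' Read query gene calls from GFF3
#'
#' Keeps `gene` and `CDS` features, deduplicated by their `ID` attribute
#' (a gene annotated both as `gene` and `CDS` counts once). Coordinates are
#' 1-based inclusive as in the file.
#'
#' @param path GFF3 file.
#' @return `data.table` with columns `contig_id`, `gene_id`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import.gff3(path),
                 error = function(e) stop("failed to parse GFF3 ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("GFF3 gene/CDS records must carry an ID attribute: ", path)
  dt <- data.table::data.table(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(ids),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  dt <- unique(dt, by = "gene_id")
  if (any(dt$end < dt$start))
    stop("GFF3 record with end < start: ",
         paste(head(dt$gene_id[dt$end < dt$start], 3), collapse = ", "))
  if (anyDuplicated(dt[, .(contig_id, gene_id)]))
    stop("duplicate gene ids within a contig: ", path)
  data.table::setkeyv(dt, c("contig_id", "start"))
  dt[]
}

#' Write gene calls as GFF3
#'
#' @param genes table with `contig_id`, `gene_id`, `start`, `end`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  g <- data.table::as.data.table(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = ifelse(g$strand %in% c("+", "-"), g$strand, "*"))
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$source <- "taxaai"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write / read a gene-cluster table
#'
#' Columns: `cluster_id`, `accession`, `genome_id`. UTF-8, tab-only, no quoting.
#'
#' @param clusters cluster membership table.
#' @param path TSV path.
#' @return `path` (write) / `data.table` (read).
#' @export
write_clusters_tsv <- function(clusters, path) {
  data.table::fwrite(clusters[, .(cluster_id, accession, genome_id)], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
}

#' Write / read an AAI matrix in long TSV format
#'
#' Long format: `genome_a`, `genome_b`, `aai`, `n_rbm`, one row per unordered
#' genome pair with defined AAI.
#'
#' @param aai an `aai_matrix` object.
#' @param path TSV path.
#' @return `path` (write) / `aai_matrix` (read).
#' @export
write_aai_tsv <- function(aai, path) {
  ids <- aai$genome_ids
  idx <- which(upper.tri(aai$values), arr.ind = TRUE)
  dt <- data.table::data.table(
    genome_a = ids[idx[, 1L]], genome_b = ids[idx[, 2L]],
    aai = aai$values[idx], n_rbm = aai$n_shared[idx])
  dt <- dt[!is.na(aai)]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_aai_tsv
#' @export
read_aai_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- sort(unique(c(dt$genome_a, dt$genome_b)))
  n <- length(ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cnt <- matrix(0L, n, n, dimnames = list(ids, ids))
  i <- match(dt$genome_a, ids); j <- match(dt$genome_b, ids)
  vals[cbind(i, j)] <- dt$aai; vals[cbind(j, i)] <- dt$aai
  cnt[cbind(i, j)] <- dt$n_rbm; cnt[cbind(j, i)] <- dt$n_rbm
  diag(vals) <- 100
  new_aai_matrix(ids, vals, cnt)
}
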