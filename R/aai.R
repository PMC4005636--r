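new_aai_matrix <- function(genome_ids, values, n_shared) {
  structure(list(genome_ids = genome_ids, values = values, n_shared = n_shared),
            class = "aai_matrix")
}

#' @export
print.aai_matrix <- function(x, ...) {
  nundef <- sum(is.na(x$values[upper.tri(x$values)]))
  cat("aai_matrix:", length(x$genome_ids), "genomes;",
      nundef, "undefined pair(s)\n")
  invisible(x)
}

#' Genome-aggregate average amino acid identity from RBM edges
#'
#' AAI of a genome pair is the arithmetic mean of the percent identities of all
#' reciprocal-best-match genes shared by the two genomes. Pairs with fewer than
#' `min_rbm` shared RBM genes are undefined (`NA`), never silently 0; the
#' diagonal is 100 by definition.
#'
#' @param edges RBM edge table from [find_rbm_edges()] (columns `genome_a`,
#'   `genome_b`, `identity`).
#' @param genome_ids genomes to include (defaults to all genomes in `edges`).
#' @param min_rbm minimum shared RBM count for a defined AAI (default 1).
#' @return an `aai_matrix`: symmetric `values` matrix (percent), `n_shared`
#'   RBM-count matrix, `genome_ids`.
#' @export
aai_matrix <- function(edges, genome_ids = NULL, min_rbm = 1L) {
  e <- data.table::as.data.table(edges)
  if (is.null(genome_ids))
    genome_ids <- sort(unique(c(e$genome_a, e$genome_b)))
  n <- length(genome_ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(genome_ids, genome_ids))
  cnt <- matrix(0L, n, n, dimnames = list(genome_ids, genome_ids))
  if (nrow(e)) {
    ga <- pmin(e$genome_a, e$genome_b); gb <- pmax(e$genome_a, e$genome_b)
    agg <- data.table::data.table(ga = ga, gb = gb, identity = e$identity)[,
      .(aai = mean(identity), n = .N), by = .(ga, gb)]
    agg <- agg[ga %in% genome_ids & gb %in% genome_ids & ga != gb]
    i <- match(agg$ga, genome_ids); j <- match(agg$gb, genome_ids)
    ok <- agg$n >= min_rbm
    vals[cbind(i[ok], j[ok])] <- agg$aai[ok]
    vals[cbind(j[ok], i[ok])] <- agg$aai[ok]
    cnt[cbind(i, j)] <- agg$n; cnt[cbind(j, i)] <- agg$n
  }
  diag(vals) <- 100
  new_aai_matrix(genome_ids, vals, cnt)
}

#' AAI of a single genome pair
#'
#' @param edges RBM edge table.
#' @param genome_a,genome_b genome ids.
#' @param min_rbm minimum RBM count for a defined value.
#' @return list with `aai` (percent, `NA` if undefined) and `n_rbm`.
#' @export
compute_aai <- function(edges, genome_a, genome_b, min_rbm = 1L) {
  if (genome_a == genome_b) return(list(aai = 100, n_rbm = NA_integer_))
  e <- data.table::as.data.table(edges)
  sel <- (e$genome_a == genome_a & e$genome_b == genome_b) |
         (e$genome_a == genome_b & e$genome_b == genome_a)
  ids <- e$identity[sel]
  if (length(ids) < min_rbm) return(list(aai = NA_real_, n_rbm = length(ids)))
  list(aai = mean(ids), n_rbm = length(ids))
}

#' Build the species (AAI distance) tree
#'
#' The species phylogeny is approximated by a distance tree on
#' `d = (100 - AAI) / 100`. Default method is average-linkage agglomerative
#' clustering (UPGMA; deterministic and ultrametric), with neighbor-joining
#' available behind a flag. Undefined AAI pairs are an error, not imputed.
#'
#' @param aai an `aai_matrix` with all off-diagonal pairs defined.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return an [ape::read.tree] style `phylo` object with genome-id tip labels.
#' @export
build_species_tree <- function(aai, method = c("upgma", "nj")) {
  method <- match.arg(method)
  v <- aai$values
  und <- which(is.na(v) & upper.tri(v), arr.ind = TRUE)
  if (nrow(und))
    stop("AAI undefined for genome pair(s): ",
         paste(apply(head(und, 5), 1L, function(ij)
           paste(aai$genome_ids[ij], collapse = "/")), collapse = ", "))
  d <- stats::as.dist((100 - v) / 100)
  if (method == "nj") return(ape::nj(d))
  hc <- stats::hclust(d, method = "average")
  # as.phylo.hclust places tips at height/2, so patristic distance between two
  # leaves equals their average-linkage merge distance
  ape::as.phylo(hc)
}

#' Distribution of AAI values by lowest shared taxonomic rank
#'
#' For every genome pair, the lowest rank (species < genus < phylum) at which
#' the two lineages agree; pairs agreeing at no considered rank fall in the
#' `"none"` band. This reproduces the rank-band histogram data underpinning the
#' novelty cutoffs.
#'
#' @param aai an `aai_matrix`.
#' @param taxonomy table from [read_taxonomy()] covering all genomes.
#' @return `data.table` with `genome_a`, `genome_b`, `aai`,
#'   `lowest_shared_rank` (factor: species, genus, phylum, none).
#' @export
rank_band_analysis <- function(aai, taxonomy) {
  ids <- aai$genome_ids
  missing <- setdiff(ids, taxonomy$genome_id)
  if (length(missing))
    stop("genome(s) missing from taxonomy: ",
         paste(head(missing, 3), collapse = ", "))
  idx <- which(upper.tri(aai$values), arr.ind = TRUE)
  a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
  same <- function(rank) {
    ta <- taxon_at(taxonomy, a, rank); tb <- taxon_at(taxonomy, b, rank)
    !is.na(ta) & !is.na(tb) & ta == tb
  }
  band <- data.table::fcase(
    same("species"), "species",
    same("genus"), "genus",
    same("phylum"), "phylum",
    default = "none")
  data.table::data.table(
    genome_a = a, genome_b = b, aai = aai$values[idx],
    lowest_shared_rank = factor(band, levels = c("species", "genus", "phylum", "none")))
}

NOVELTY_LEVELS <- c("known species", "novel species", "novel genus", "novel phylum")

#' Call the novelty rank of a query from its best-match AAI
#'
#' Bands are half-open, lower-inclusive: AAI `>= species_min` (95) is a known
#' species; `[genus_low, species_min)` a novel species of the matched genus;
#' `[phylum_max, genus_low)` a novel genus within the matched phylum; below
#' `phylum_max` (45) a novel phylum-level lineage.
#'
#' @param best_match_aai numeric vector of percent AAI in `[0, 100]`.
#' @param bands a [rank_bands()].
#' @return character vector over
#'   `c("known species", "novel species", "novel genus", "novel phylum")`.
#' @export
novelty_rank <- function(best_match_aai, bands = rank_bands()) {
  x <- as.numeric(best_match_aai)
  if (anyNA(x) || any(x < 0 | x > 100))
    stop("best_match_aai must be in [0, 100]")
  data.table::fcase(
    x >= bands$species_min, "known species",
    x >= bands$genus_low, "novel species",
    x >= bands$phylum_max, "novel genus",
    default = "novel phylum")
}
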