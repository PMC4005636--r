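#' Scott's-rule bandwidth for a 1-D Gaussian KDE
#'
#' `h = sigma-hat * n^(-1/5)`. Degenerate inputs (a single point, or zero
#' variance) fall back to `fallback` identity-percent units.
#'
#' @param points numeric observations (percent identity).
#' @param fallback bandwidth used when the sample variance is zero (default 0.5).
#' @return bandwidth (positive scalar).
#' @export
scott_bandwidth <- function(points, fallback = 0.5) {
  n <- length(points)
  if (n == 0L) stop("at least one point required")
  s <- if (n > 1L) stats::sd(points) else 0
  if (!is.finite(s) || s <= 0) return(fallback)
  s * n^(-1 / 5)
}

#' Gaussian-kernel density estimate at arbitrary evaluation points
#'
#' Plain Gaussian KDE: `f(x) = mean_i dnorm(x, points_i, h)` with Scott's-rule
#' bandwidth by default. Stored point sets (not gridded curves) keep the
#' density evaluable at any identity without interpolation error.
#'
#' @param points numeric observations.
#' @param x evaluation points.
#' @param bw bandwidth; default [scott_bandwidth()] of `points`.
#' @return density values, same length as `x`.
#' @export
kde_density <- function(points, x, bw = NULL) {
  if (length(points) == 0L) stop("at least one point required")
  if (is.null(bw)) bw <- scott_bandwidth(points)
  stopifnot(bw > 0)
  if (length(x) == 0L) return(numeric())
  colMeans(matrix(stats::dnorm(outer(points, x, "-"), sd = bw),
                  nrow = length(points)))
}

#' Collect intra-/inter-group identity observations for one cluster
#'
#' Every unordered pair of member genes from two distinct genomes contributes
#' one observation, labelled `intra` when the two genomes share the taxon at
#' `rank` and `inter` otherwise. Genomes unranked at `rank` are skipped with a
#' warning.
#'
#' @param members cluster membership (`accession`, `genome_id`).
#' @param pair_identities gene-pair identity table (`gene_a`, `gene_b`,
#'   `identity`, percent); direction-free.
#' @param taxonomy table from [read_taxonomy()].
#' @param rank `"phylum"`, `"genus"` or `"species"`.
#' @return `data.table` with `gene_a`, `gene_b`, `identity`, `category`
#'   (`"intra"`/`"inter"`); zero rows when fewer than 2 eligible genes.
#' @export
collect_identity_observations <- function(members, pair_identities, taxonomy, rank) {
  mb <- data.table::as.data.table(members)
  tx <- taxon_at(taxonomy, mb$genome_id, rank)
  if (anyNA(tx)) {
    warning(sum(is.na(tx)), " member gene(s) skipped: genome unranked at ", rank)
    mb <- mb[!is.na(tx)]; tx <- tx[!is.na(tx)]
  }
  empty <- data.table::data.table(gene_a = character(), gene_b = character(),
                                  identity = numeric(), category = character())
  if (nrow(mb) < 2L) return(empty)
  pi <- data.table::as.data.table(pair_identities)
  pi <- pi[, .(gene_a = pmin(gene_a, gene_b), gene_b = pmax(gene_a, gene_b), identity)]
  pi <- unique(pi, by = c("gene_a", "gene_b"))
  gmap <- setNames(mb$genome_id, mb$accession)
  txmap <- setNames(tx, mb$accession)
  obs <- pi[gene_a %in% mb$accession & gene_b %in% mb$accession]
  if (nrow(obs) == 0L) return(empty)
  ga <- gmap[obs$gene_a]; gb <- gmap[obs$gene_b]
  obs <- obs[ga != gb]
  if (nrow(obs) == 0L) return(empty)
  obs[, category := data.table::fifelse(
    txmap[gene_a] == txmap[gene_b], "intra", "inter")]
  obs[]
}

# KDE parameter record for one cluster x rank D curve.
new_d_record <- function(intra, inter, fallback_bw = 0.5) {
  list(intra = as.numeric(intra), inter = as.numeric(inter),
       bw_intra = if (length(intra)) scott_bandwidth(intra, fallback_bw) else NA_real_,
       bw_inter = if (length(inter)) scott_bandwidth(inter, fallback_bw) else NA_real_,
       n_intra = length(intra), n_inter = length(inter))
}

# Evaluate a D record at identities x under the given mode.
d_eval <- function(rec, x, mode = "posterior") {
  if (rec$n_intra == 0L && rec$n_inter == 0L) return(rep(NA_real_, length(x)))
  if (rec$n_intra == 0L) return(rep(0, length(x)))
  if (rec$n_inter == 0L) return(rep(1, length(x)))
  fi <- kde_density(rec$intra, x, rec$bw_intra)
  fe <- kde_density(rec$inter, x, rec$bw_inter)
  if (mode == "difference") return(pmin(pmax(fi - fe, 0), 1))
  tot <- fi + fe
  out <- rep(0.5, length(x))  # both densities underflown: uninformative
  pos <- tot > .Machine$double.xmin
  out[pos] <- fi[pos] / tot[pos]
  pmin(pmax(out, 0), 1)
}

#' Discriminative weight D at given identities
#'
#' D quantifies how strongly an identity value separates intra-taxon from
#' inter-taxon gene pairs of a cluster: both categories are smoothed with
#' Gaussian KDEs (Scott's rule) and, under the default `"posterior"` mode,
#' `D(x) = f_intra(x) / (f_intra(x) + f_inter(x))`. With no intra observations
#' `D == 0` at the rank, with no inter observations `D == 1`; with neither, the
#' weight is unavailable (`NA`).
#'
#' @param obs observation table from [collect_identity_observations()].
#' @param x percent identities at which to evaluate.
#' @param mode `"posterior"` (default) or `"difference"` (clamped
#'   `f_intra - f_inter`).
#' @return numeric vector in `[0,1]` (or `NA` when unavailable).
#' @export
d_weight <- function(obs, x, mode = c("posterior", "difference")) {
  mode <- match.arg(mode)
  rec <- new_d_record(obs$identity[obs$category == "intra"],
                      obs$identity[obs$category == "inter"])
  d_eval(rec, x, mode)
}

#' Per-genome representative distances for a cluster
#'
#' When a genome contributes several members (merged paralogs), its
#' representative is the member with the highest mean identity to members of
#' the other genomes. Returns the genome-level distance matrix
#' `d = (100 - identity)/100` between representatives.
#'
#' @inheritParams collect_identity_observations
#' @return symmetric matrix with genome-id dimnames; `NA` where no identity is
#'   recorded between the two representatives.
#' @export
cluster_genome_distances <- function(members, pair_identities) {
  mb <- data.table::as.data.table(members)
  pi <- data.table::as.data.table(pair_identities)
  pi <- data.table::rbindlist(list(
    pi[, .(gene_a, gene_b, identity)],
    pi[, .(gene_a = gene_b, gene_b = gene_a, identity)]))
  pi <- pi[gene_a %in% mb$accession & gene_b %in% mb$accession]
  gmap <- setNames(mb$genome_id, mb$accession)
  pi[, `:=`(ga = gmap[gene_a], gb = gmap[gene_b])]
  genomes <- sort(unique(mb$genome_id))
  # representative = member with highest mean identity to other genomes' members
  rep_score <- pi[ga != gb, .(score = mean(identity)), by = .(ga, gene_a)]
  data.table::setorder(rep_score, ga, -score, gene_a)
  reps <- unique(rep_score, by = "ga")
  rep_of <- setNames(reps$gene_a, reps$ga)
  # genomes with a single member and no cross-genome identity still need a rep
  solo <- setdiff(genomes, names(rep_of))
  if (length(solo)) {
    first <- mb[genome_id %in% solo][order(accession)][!duplicated(genome_id)]
    rep_of <- c(rep_of, setNames(first$accession, first$genome_id))
  }
  n <- length(genomes)
  dm <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  diag(dm) <- 0
  if (n >= 2L) {
    pr <- pi[gene_a %in% rep_of & gene_b %in% rep_of & ga != gb]
    if (nrow(pr)) {
      i <- match(pr$ga, genomes); j <- match(pr$gb, genomes)
      dm[cbind(i, j)] <- (100 - pr$identity) / 100
    }
  }
  dm
}

# Cherry (closest pair) of a triplet given three pairwise distances.
# Returns 1L for (a,b), 2L for (a,c), 3L for (b,c); attribute "tie" when the
# minimum is not unique within tol.
triplet_cherry <- function(dab, dac, dbc, tol = 1e-12) {
  d <- c(dab, dac, dbc)
  k <- which.min(d)
  structure(k, tie = sum(d <= d[k] + tol) > 1L)
}

#' Concordance of one gene triplet with the species tree
#'
#' A triplet of genomes is concordant when the closest pair under the gene
#' distances equals the closest pair under the species-tree patristic
#' distances. Ties (in either tree) are resolved as concordant — benefit of
#' the doubt.
#'
#' @param gene_d 3x3 gene distance matrix with genome-id dimnames.
#' @param species_tree `phylo` species tree containing the three genomes.
#' @param triplet character vector of the 3 genome ids.
#' @return `TRUE` (concordant) or `FALSE` (discordant).
#' @export
triplet_concordance <- function(gene_d, species_tree, triplet) {
  stopifnot(length(triplet) == 3L)
  if (!all(triplet %in% species_tree$tip.label))
    stop("genome(s) absent from species tree: ",
         paste(setdiff(triplet, species_tree$tip.label), collapse = ", "))
  sd_full <- ape::cophenetic.phylo(species_tree)
  g <- gene_d[triplet, triplet]
  s <- sd_full[triplet, triplet]
  cg <- triplet_cherry(g[1, 2], g[1, 3], g[2, 3])
  cs <- triplet_cherry(s[1, 2], s[1, 3], s[2, 3])
  isTRUE(attr(cg, "tie")) || isTRUE(attr(cs, "tie")) || cg == cs
}

# Vectorized concordance over a matrix of triplet index rows (m x 3) into
# aligned distance matrices Dg, Ds.
concordance_many <- function(Dg, Ds, trip, tol = 1e-12) {
  i <- trip[, 1L]; j <- trip[, 2L]; k <- trip[, 3L]
  gd <- cbind(Dg[cbind(i, j)], Dg[cbind(i, k)], Dg[cbind(j, k)])
  sd <- cbind(Ds[cbind(i, j)], Ds[cbind(i, k)], Ds[cbind(j, k)])
  cg <- max.col(-gd, ties.method = "first")
  cs <- max.col(-sd, ties.method = "first")
  ming <- gd[cbind(seq_len(nrow(gd)), cg)]
  mins <- sd[cbind(seq_len(nrow(sd)), cs)]
  tie_g <- rowSums(gd <= ming + tol) > 1L
  tie_s <- rowSums(sd <= mins + tol) > 1L
  tie_g | tie_s | (cg == cs)
}

#' Phylogenetic-consistency weight M for a cluster
#'
#' M is the fraction of genome triplets whose gene-distance topology agrees
#' with the species (AAI) tree. Clusters with up to `max_exhaustive` member
#' genomes are enumerated exactly over all `C(n,3)` triplets; larger clusters
#' are estimated by Monte-Carlo sampling of `mc_samples` triplets (binomial
#' standard error reported). Clusters with fewer than 3 genomes default to
#' `M = 1` with `method = "degenerate"`.
#'
#' @param gene_d genome-level gene distance matrix
#'   (see [cluster_genome_distances()]).
#' @param species_tree `phylo` species tree covering the genomes.
#' @param max_exhaustive exhaustive-enumeration limit (default 5000 genomes).
#' @param mc_samples Monte-Carlo sample size (default 10000 triplets).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return list: `m` in `[0,1]`, `n_triplets`, `se` (0 for exact),
#'   `method` (`"exact"`, `"monte_carlo"` or `"degenerate"`).
#' @export
m_weight <- function(gene_d, species_tree, max_exhaustive = 5000L,
                     mc_samples = 10000L, seed = NULL) {
  genomes <- rownames(gene_d)
  genomes <- genomes[genomes %in% species_tree$tip.label]
  n <- length(genomes)
  if (n < 3L)
    return(list(m = 1.0, n_triplets = 0L, se = 0, method = "degenerate"))
  Ds <- ape::cophenetic.phylo(species_tree)[genomes, genomes]
  Dg <- gene_d[genomes, genomes]
  if (anyNA(Dg[upper.tri(Dg)]))
    stop("gene distances undefined for some genome pairs in cluster")
  if (n <= max_exhaustive && choose(n, 3) <= 2e6) {
    trip <- t(utils::combn(n, 3L))
    conc <- concordance_many(Dg, Ds, trip)
    m <- mean(conc)
    return(list(m = m, n_triplets = nrow(trip), se = 0, method = "exact"))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  trip <- t(replicate(mc_samples, sample.int(n, 3L)))
  conc <- concordance_many(Dg, Ds, trip)
  m <- mean(conc)
  list(m = m, n_triplets = mc_samples,
       se = sqrt(m * (1 - m) / mc_samples), method = "monte_carlo")
}

#' Combine D and M linearly
#'
#' `w = w_d * D + w_m * M`, a convex combination (the two coefficients sum
#' to 1).
#'
#' @param d,m numeric vectors in `[0,1]`.
#' @param cfg a [combined_weight_config()].
#' @return numeric vector in `[0,1]`.
#' @export
combined_weight <- function(d, m, cfg = combined_weight_config()) {
  stopifnot(inherits(cfg, "combined_weight_config"))
  cfg$w_d * d + cfg$w_m * m
}
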