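AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_BASES <- c("A", "C", "G", "T")
# one fixed codon per amino acid: protein-space simulation carries a
# deterministic nucleotide representation for fragment sampling
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
              H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
              P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
              W = "TGG", Y = "TAT")

# run fn() under set.seed(seed), restoring the caller's RNG state
with_preserved_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  if (!is.null(seed)) set.seed(seed)
  fn()
}

#' Target AAI bands for the synthetic taxonomy
#'
#' Pairwise identity targets by the lowest rank two genomes share:
#' within-species 96-99, within-genus 65-80, within-phylum 48-58, between-phyla
#' 30-42 percent. Band ordering mirrors the rank-band framework used for
#' novelty calls.
#'
#' @param species,genus,phylum,root length-2 `c(low, high)` percent bands.
#' @return named list of bands.
#' @export
aai_band_targets <- function(species = c(96, 99), genus = c(65, 80),
                             phylum = c(48, 58), root = c(30, 42)) {
  b <- list(species = species, genus = genus, phylum = phylum, root = root)
  lows <- vapply(b, `[`, numeric(1), 1L)
  his <- vapply(b, `[`, numeric(1), 2L)
  if (any(his <= lows) || any(diff(rev(lows)) <= 0))
    stop("band targets must be increasing intervals ordered root < phylum < genus < species")
  b
}

#' Build a balanced synthetic taxonomy table
#'
#' @param n_phyla,genera_per_phylum,species_per_genus,genomes_per_species
#'   counts at each level.
#' @return `data.table` with `genome_id`, `phylum`, `genus`, `species`.
#' @export
taxonomy_spec <- function(n_phyla = 2L, genera_per_phylum = 2L,
                          species_per_genus = 2L, genomes_per_species = 2L) {
  rows <- list()
  for (p in seq_len(n_phyla)) for (g in seq_len(genera_per_phylum))
    for (s in seq_len(species_per_genus)) for (i in seq_len(genomes_per_species)) {
      ph <- sprintf("p%02d", p)
      ge <- sprintf("%s_g%02d", ph, g)
      sp <- sprintf("%s_s%02d", ge, s)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        genome_id = sprintf("%s_i%02d", sp, i), phylum = ph, genus = ge, species = sp)
    }
  data.table::rbindlist(rows)
}

#' Preset synthetic taxonomies
#'
#' The `"small"` preset (34 genomes, 3 phyla) is deliberately unbalanced, like
#' real reference collections: one phylum with a deep multi-species genus
#' (novel-species hold-out experiments), one broad phylum of many small genera
#' (novel-genus hold-outs), one moderate filler phylum. `"tiny"` is a minimal
#' balanced 2x2x2x2 world for fast tests.
#'
#' @param name `"small"` or `"tiny"`.
#' @return taxonomy `data.table` as in [taxonomy_spec()].
#' @export
preset_taxonomy <- function(name = c("small", "tiny")) {
  name <- match.arg(name)
  if (name == "tiny") return(taxonomy_spec(2L, 2L, 2L, 2L))
  mk <- function(ph, genus_sizes) {
    rows <- list()
    for (g in seq_along(genus_sizes)) {
      ge <- sprintf("%s_g%02d", ph, g)
      for (s in seq_len(genus_sizes[[g]][1L])) {
        sp <- sprintf("%s_s%02d", ge, s)
        for (i in seq_len(genus_sizes[[g]][2L]))
          rows[[length(rows) + 1L]] <- data.table::data.table(
            genome_id = sprintf("%s_i%02d", sp, i),
            phylum = ph, genus = ge, species = sp)
      }
    }
    data.table::rbindlist(rows)
  }
  data.table::rbindlist(list(
    # p01: deep genus (3 species x 2 genomes) + companion genus (2 x 2)
    mk("p01", list(c(3L, 2L), c(2L, 2L))),
    # p02: six shallow genera, one 2-genome species each
    mk("p02", list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L))),
    # p03: moderate filler
    mk("p03", list(c(2L, 2L), c(2L, 2L), c(2L, 2L)))))
}

#' Gene-family simulation parameters
#'
#' @param n_families number of gene families (each yields one reference gene
#'   per genome).
#' @param class_fractions mix of conservation classes; slow families sit near
#'   the top of each identity band, fast near the bottom.
#' @param hgt_rate fraction of (genome, family) genes replaced by a copy
#'   transferred from a different genus (planted HGT), in `[0, 1)`.
#' @param length_range amino-acid length range families are drawn from.
#' @return an object of class `gene_family_spec`.
#' @export
gene_family_spec <- function(n_families = 40L,
                             class_fractions = c(slow = 0.25, medium = 0.5, fast = 0.25),
                             hgt_rate = 0.05, length_range = c(80L, 350L)) {
  stopifnot(n_families >= 1L, hgt_rate >= 0, hgt_rate < 1,
            abs(sum(class_fractions) - 1) < 1e-9,
            all(c("slow", "medium", "fast") %in% names(class_fractions)))
  structure(list(n_families = as.integer(n_families),
                 class_fractions = class_fractions, hgt_rate = hgt_rate,
                 length_range = as.integer(length_range)),
            class = "gene_family_spec")
}

#' Mock-metagenome fragment parameters
#'
#' @param lengths fragment lengths (bp) sampled uniformly per fragment;
#'   menu values 100/500/800/1000/1500/2000.
#' @param error_rate per-base substitution probability (default 0.01,
#'   emulating ~1% sequencing error); must be in `[0, 0.1]`.
#' @param n_fragments number of fragments.
#' @param min_gene_overlap_aa genes clipped below this many residues are
#'   dropped from the emitted gene calls.
#' @return an object of class `fragment_spec`.
#' @export
fragment_spec <- function(lengths = c(500L, 1000L, 1500L, 2000L),
                          error_rate = 0.01, n_fragments = 1000L,
                          min_gene_overlap_aa = 20L) {
  stopifnot(all(lengths > 0), error_rate >= 0, error_rate <= 0.1,
            n_fragments >= 1L)
  structure(list(lengths = as.integer(lengths), error_rate = error_rate,
                 n_fragments = as.integer(n_fragments),
                 min_gene_overlap_aa = as.integer(min_gene_overlap_aa)),
            class = "fragment_spec")
}

# draw a per-node identity target inside `band` for a conservation class
draw_band_target <- function(band, class_frac, n = 1L) {
  w <- band[2L] - band[1L]
  t <- band[1L] + class_frac * w + stats::runif(n, -0.05, 0.05) * w
  pmin(pmax(t, band[1L]), band[2L])
}

CLASS_BAND_FRAC <- c(slow = 0.85, medium = 0.5, fast = 0.15)

# substitute each site independently with probability p (to a different AA)
mutate_aa <- function(seq_vec, p) {
  hit <- stats::runif(length(seq_vec)) < p
  n <- sum(hit)
  if (n) {
    repl <- sample(AA_ALPHABET, n, replace = TRUE)
    # re-draw collisions with the current residue so p is the realized rate
    same <- repl == seq_vec[hit]
    while (any(same)) {
      repl[same] <- sample(AA_ALPHABET, sum(same), replace = TRUE)
      same <- repl == seq_vec[hit]
    }
    seq_vec[hit] <- repl
  }
  seq_vec
}

# branch substitution probability taking cumulative target q_above down to
# q_below (per-lineage, measured from the branching node to the leaves)
branch_prob <- function(q_above, q_below) {
  p <- 1 - (1 - q_above) / (1 - q_below)
  pmin(pmax(p, 0), 0.95)
}

q_of_target <- function(T_pct) 1 - sqrt(T_pct / 100)

#' Simulate a reference proteome set with planted taxonomy and AAI structure
#'
#' Per gene family, a root protein is evolved down the taxonomy tree with
#' per-branch substitution probabilities solved backwards from per-node
#' identity targets drawn inside the requested AAI bands, so pairwise
#' identities land in the band of the two genomes' lowest shared rank.
#' A fraction `hgt_rate` of genes is replaced by a copy from a different genus
#' (planted horizontal transfer), with ground-truth labels emitted. All output
#' (sequences, true pairwise identities, HGT labels) is deterministic under
#' `seed`.
#'
#' @param taxonomy taxonomy table ([taxonomy_spec()] / [preset_taxonomy()]).
#' @param fam a [gene_family_spec()].
#' @param bands an [aai_band_targets()].
#' @param seed RNG seed.
#' @return a `reference_set`: `genes` (accession `genome|family`, sequence,
#'   HGT flag), `taxonomy`, `families` (class, length), `pair_identities`
#'   (true percent identity per gene pair within each family), `identity_matrices`
#'   (per family, genome x genome), `hgt` labels, `bands`, `seed`.
#' @export
simulate_reference_set <- function(taxonomy, fam = gene_family_spec(),
                                   bands = aai_band_targets(), seed = 1L) {
  tax <- data.table::as.data.table(taxonomy)
  genomes <- tax$genome_id
  n <- length(genomes)
  stopifnot(n >= 2L)
  with_preserved_seed(seed, function() {
    fracs <- fam$class_fractions[c("slow", "medium", "fast")]
    counts <- diff(c(0L, round(cumsum(fracs) * fam$n_families)))
    classes <- rep(names(fracs), counts)
    fam_ids <- sprintf("F%04d", seq_len(fam$n_families))
    genes_rows <- list(); id_mats <- list(); hgt_rows <- list()
    for (j in seq_len(fam$n_families)) {
      cf <- CLASS_BAND_FRAC[[classes[j]]]
      L <- sample(seq(fam$length_range[1L], fam$length_range[2L]), 1L)
      root <- sample(AA_ALPHABET, L, replace = TRUE)
      q_root <- q_of_target(draw_band_target(bands$root, cf))
      mat <- matrix("", n, L)
      rownames(mat) <- genomes
      for (ph in unique(tax$phylum)) {
        q_ph <- q_of_target(draw_band_target(bands$phylum, cf))
        q_ph <- min(q_ph, q_root)  # keep cumulative targets monotone
        seq_ph <- mutate_aa(root, branch_prob(q_root, q_ph))
        tph <- tax[phylum == ph]
        for (ge in unique(tph$genus)) {
          q_ge <- min(q_of_target(draw_band_target(bands$genus, cf)), q_ph)
          seq_ge <- mutate_aa(seq_ph, branch_prob(q_ph, q_ge))
          tge <- tph[genus == ge]
          for (sp in unique(tge$species)) {
            q_sp <- min(q_of_target(draw_band_target(bands$species, cf)), q_ge)
            seq_sp <- mutate_aa(seq_ge, branch_prob(q_ge, q_sp))
            for (gm in tge[species == sp]$genome_id)
              mat[gm, ] <- mutate_aa(seq_sp, q_sp)
          }
        }
      }
      # planted HGT: replace genes with slightly diverged cross-genus copies
      if (fam$hgt_rate > 0) {
        pristine <- mat
        recipients <- genomes[stats::runif(n) < fam$hgt_rate]
        for (gm in recipients) {
          row <- tax[genome_id == gm]
          # prefer cross-genus transfer; degrade gracefully in small worlds
          donors <- tax[genus != row$genus]$genome_id
          if (!length(donors)) donors <- tax[species != row$species]$genome_id
          if (!length(donors)) donors <- setdiff(tax$genome_id, gm)
          if (!length(donors)) next
          donor <- sample(donors, 1L)
          mat[gm, ] <- mutate_aa(pristine[donor, ], 0.02)
          hgt_rows[[length(hgt_rows) + 1L]] <- data.table::data.table(
            genome_id = gm, family_id = fam_ids[j], donor_genome = donor)
        }
      }
      idm <- matrix(100, n, n, dimnames = list(genomes, genomes))
      for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        v <- 100 * mean(mat[a, ] == mat[b, ])
        idm[a, b] <- v; idm[b, a] <- v
      }
      id_mats[[fam_ids[j]]] <- idm
      genes_rows[[j]] <- data.table::data.table(
        accession = paste0(genomes, "|", fam_ids[j]),
        genome_id = genomes, family_id = fam_ids[j], length = L,
        sequence = apply(mat, 1L, paste, collapse = ""))
    }
    genes <- data.table::rbindlist(genes_rows)
    hgt <- if (length(hgt_rows)) data.table::rbindlist(hgt_rows) else
      data.table::data.table(genome_id = character(), family_id = character(),
                             donor_genome = character())
    genes[, hgt := paste(genome_id, family_id) %in% paste(hgt$genome_id, hgt$family_id)]
    pid_rows <- lapply(fam_ids, function(fid) {
      idm <- id_mats[[fid]]
      ij <- which(upper.tri(idm), arr.ind = TRUE)
      data.table::data.table(
        gene_a = paste0(genomes[ij[, 1L]], "|", fid),
        gene_b = paste0(genomes[ij[, 2L]], "|", fid),
        family_id = fid, identity = idm[ij])
    })
    structure(list(genes = genes, taxonomy = tax,
                   families = data.table::data.table(family_id = fam_ids,
                                                     class = classes,
                                                     length = genes[, length[1L], by = family_id]$V1),
                   pair_identities = data.table::rbindlist(pid_rows),
                   identity_matrices = id_mats, hgt = hgt, bands = bands,
                   seed = seed),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nrow(x$taxonomy), "genomes,",
      length(x$identity_matrices), "gene families,",
      nrow(x$hgt), "planted HGT gene(s)\n")
  invisible(x)
}

#' Write a reference set to disk (FASTA + TSVs)
#'
#' Emits `proteins.fasta`, `gene_map.tsv`, `taxonomy.tsv`,
#' `true_identities.tsv`, `families.tsv`, `hgt.tsv`.
#'
#' @param ref a `reference_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(setNames(ref$genes$sequence, ref$genes$accession))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  data.table::fwrite(ref$genes[, .(accession, genome_id)],
                     file.path(dir, "gene_map.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(ref$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(ref$pair_identities, file.path(dir, "true_identities.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(ref$families, file.path(dir, "families.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(ref$hgt, file.path(dir, "hgt.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

# deterministic nucleotide genomes: fixed codon per residue, genes separated
# by 30-bp spacers drawn from the seeded RNG
build_genome_dna <- function(ref, spacer_len = 30L) {
  out_seq <- character(0); out_genes <- list()
  for (gm in ref$taxonomy$genome_id) {
    gg <- ref$genes[genome_id == gm][order(accession)]
    parts <- character(0); pos <- 0L; rows <- list()
    for (k in seq_len(nrow(gg))) {
      spacer <- paste(sample(DNA_BASES, spacer_len, replace = TRUE), collapse = "")
      dna <- paste(CODON_OF[strsplit(gg$sequence[k], "")[[1]]], collapse = "")
      parts <- c(parts, spacer, dna)
      start <- pos + spacer_len + 1L
      end <- start + nchar(dna) - 1L
      pos <- end
      rows[[k]] <- data.table::data.table(
        genome_id = gm, accession = gg$accession[k], start = start, end = end)
    }
    out_seq[[gm]] <- paste(parts, collapse = "")
    out_genes[[gm]] <- data.table::rbindlist(rows)
  }
  list(dna = out_seq, gene_coords = data.table::rbindlist(out_genes))
}

#' Simulate a mock metagenome from reference genomes
#'
#' Fragments are sampled uniformly from deterministic nucleotide renderings of
#' the reference genomes (fixed codon per residue, 30-bp intergenic spacers),
#' with independent per-base substitution errors at `error_rate`. Gene calls
#' overlapping each fragment are clipped to its bounds and emitted with
#' 1-based coordinates; truth labels map every fragment to its source genome
#' and lineage.
#'
#' @param ref a `reference_set`.
#' @param frag a [fragment_spec()].
#' @param genome_ids genomes to sample from (default: all in `ref`).
#' @param seed RNG seed.
#' @return a `metagenome`: `fragments` (id, source genome/coords, sequence),
#'   `genes` (fragment gene calls with source accession and clipped
#'   amino-acid range), `truth` (fragment lineage), `genome_dna`, `spec`.
#' @export
simulate_metagenome <- function(ref, frag = fragment_spec(),
                                genome_ids = NULL, seed = 1L) {
  if (is.null(genome_ids)) genome_ids <- ref$taxonomy$genome_id
  with_preserved_seed(seed, function() {
    gd <- build_genome_dna(ref)
    glen <- nchar(gd$dna)
    feasible <- genome_ids[glen[genome_ids] >= max(frag$lengths)]
    if (!length(feasible)) stop("fragment length exceeds all genome lengths")
    frag_rows <- list(); gene_rows <- list()
    for (k in seq_len(frag$n_fragments)) {
      gm <- sample(feasible, 1L)
      flen <- if (length(frag$lengths) > 1L) sample(frag$lengths, 1L) else frag$lengths
      start <- sample.int(glen[[gm]] - flen + 1L, 1L)
      end <- start + flen - 1L
      seqv <- strsplit(substr(gd$dna[[gm]], start, end), "")[[1]]
      nerr <- 0L
      if (frag$error_rate > 0) {
        hit <- stats::runif(flen) < frag$error_rate
        nerr <- sum(hit)
        if (nerr) {
          repl <- sample(DNA_BASES, nerr, replace = TRUE)
          same <- repl == seqv[hit]
          while (any(same)) {
            repl[same] <- sample(DNA_BASES, sum(same), replace = TRUE)
            same <- repl == seqv[hit]
          }
          seqv[hit] <- repl
        }
      }
      fid <- sprintf("frag%06d", k)
      frag_rows[[k]] <- data.table::data.table(
        fragment_id = fid, genome_id = gm, source_start = start,
        source_end = end, length = flen, n_errors = nerr,
        sequence = paste(seqv, collapse = ""))
      ov <- gd$gene_coords[genome_id == gm]
      ov <- ov[ov$end >= start & ov$start <= end]
      if (nrow(ov)) {
        cl_start <- pmax(ov$start, start); cl_end <- pmin(ov$end, end)
        aa_from <- ceiling((cl_start - ov$start) / 3) + 1L
        aa_to <- aa_from + ((cl_end - cl_start + 1L) %/% 3L) - 1L
        keepg <- (aa_to - aa_from + 1L) >= frag$min_gene_overlap_aa
        if (any(keepg)) {
          ov <- ov[keepg]
          gene_rows[[length(gene_rows) + 1L]] <- data.table::data.table(
            fragment_id = fid,
            gene_id = sprintf("%s_g%02d", fid, seq_len(nrow(ov))),
            start = (cl_start[keepg] - start) + 1L,
            end = (cl_end[keepg] - start) + 1L,
            strand = "+",
            source_accession = ov$accession,
            aa_from = aa_from[keepg], aa_to = aa_to[keepg])
        }
      }
    }
    fragments <- data.table::rbindlist(frag_rows)
    genes <- if (length(gene_rows)) data.table::rbindlist(gene_rows) else
      data.table::data.table(fragment_id = character(), gene_id = character(),
                             start = integer(), end = integer(), strand = character(),
                             source_accession = character(), aa_from = integer(),
                             aa_to = integer())
    truth <- merge(fragments[, .(fragment_id, genome_id)], ref$taxonomy,
                   by = "genome_id")[, .(fragment_id, genome_id, phylum, genus, species)]
    data.table::setorder(truth, fragment_id)
    structure(list(fragments = fragments, genes = genes, truth = truth,
                   genome_dna = gd$dna, spec = frag, seed = seed),
              class = "metagenome")
  })
}

#' Recount the realized per-base error rate of a simulated metagenome
#'
#' Independent of the generator's bookkeeping: re-aligns every fragment to its
#' source coordinates on the stored genome sequence and counts mismatching
#' bases.
#'
#' @param mg a `metagenome`.
#' @return list: `mismatch_rate` (fraction), `n_bases`, `n_mismatches`.
#' @export
realized_error_rate <- function(mg) {
  tot <- 0L; mis <- 0L
  for (k in seq_len(nrow(mg$fragments))) {
    fr <- mg$fragments[k]
    src <- strsplit(substr(mg$genome_dna[[fr$genome_id]], fr$source_start,
                           fr$source_end), "")[[1]]
    emt <- strsplit(fr$sequence, "")[[1]]
    tot <- tot + length(src)
    mis <- mis + sum(src != emt)
  }
  list(mismatch_rate = mis / tot, n_bases = tot, n_mismatches = mis)
}

#' Write metagenome fixtures to disk (FASTA + GFF3 + truth TSV)
#'
#' @param mg a `metagenome`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_metagenome <- function(mg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(mg$fragments$sequence,
                                            mg$fragments$fragment_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "fragments.fasta"))
  write_gff3(mg$genes[, .(contig_id = fragment_id, gene_id, start, end, strand)],
             file.path(dir, "fragments.gff3"))
  data.table::fwrite(mg$truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

# shared scoring for simulated similarity searches
sim_bitscore <- function(pident, aa_len) round(2 * aa_len * pident / 100, 1)
sim_evalue <- function(bitscore) pmax(2^(-bitscore), 1e-180)

#' Simulate the similarity-search step for fragment genes
#'
#' Stands in for the external BLAST/BLAT search: for every gene called on a
#' fragment, emits outfmt-6-style rows against the reference genes of the same
#' family, with `pident` equal to the true planted identity plus Gaussian
#' noise (clamped to `[0, 100]`) and bitscore a monotone function of identity
#' times aligned length (`2 * aa_len * pident / 100`).
#'
#' @param mg a `metagenome`.
#' @param ref the `reference_set` the fragments came from.
#' @param reference_genomes subject genomes available in the reference database
#'   (default: all; pass a subset for hold-out experiments).
#' @param noise_sd identity noise standard deviation (percent, default 1).
#' @param top_k subject rows emitted per gene (default 10).
#' @param seed RNG seed.
#' @return hits `data.table` in outfmt-6 column layout.
#' @export
simulate_hits <- function(mg, ref, reference_genomes = NULL, noise_sd = 1,
                          top_k = 10L, seed = 1L) {
  if (is.null(reference_genomes)) reference_genomes <- ref$taxonomy$genome_id
  stopifnot(noise_sd >= 0)
  g <- mg$genes
  with_preserved_seed(seed, function() {
    rows <- vector("list", nrow(g))
    for (k in seq_len(nrow(g))) {
      src <- g$source_accession[k]
      parts <- strsplit(src, "|", fixed = TRUE)[[1]]
      gm <- parts[1L]; fid <- parts[2L]
      idm <- ref$identity_matrices[[fid]]
      subjects <- intersect(rownames(idm), reference_genomes)
      if (!length(subjects)) next
      true_id <- idm[gm, subjects]
      la <- g$aa_to[k] - g$aa_from[k] + 1L
      pid <- pmin(pmax(true_id + stats::rnorm(length(subjects), 0, noise_sd), 0), 100)
      ord <- order(-pid, subjects)
      keep <- ord[seq_len(min(top_k, length(ord)))]
      bs <- sim_bitscore(pid[keep], la)
      rows[[k]] <- data.table::data.table(
        qseqid = g$gene_id[k], sseqid = paste0(subjects[keep], "|", fid),
        pident = round(pid[keep], 2), length = la,
        mismatch = as.integer(round(la * (1 - pid[keep] / 100))), gapopen = 0L,
        qstart = 1L, qend = la, sstart = g$aa_from[k], send = g$aa_to[k],
        evalue = sim_evalue(bs), bitscore = bs)
    }
    out <- data.table::rbindlist(rows)
    if (nrow(out) == 0L)
      out <- data.table::as.data.table(sapply(OUTFMT6_COLS, function(.) character(), simplify = FALSE))
    out
  })
}

#' Simulate the all-vs-all reference search used for cluster building
#'
#' Emits one pair-match row per gene pair within each family (identity = true
#' planted identity + Gaussian noise, coverage 1, tiny e-value, bitscore
#' monotone in identity x length), mimicking an all-vs-all protein search whose
#' cross-family matches fall below reporting thresholds.
#'
#' @param ref a `reference_set`.
#' @param genome_ids reference genomes to include (default all).
#' @param noise_sd identity noise sd in percent (default 0.5).
#' @param seed RNG seed.
#' @return pair-match `data.table` (`gene_a`, `gene_b`, `identity`, `coverage`,
#'   `evalue`, `bitscore`).
#' @export
simulate_reference_matches <- function(ref, genome_ids = NULL, noise_sd = 0.5,
                                       seed = 1L) {
  if (is.null(genome_ids)) genome_ids <- ref$taxonomy$genome_id
  pi <- ref$pair_identities
  lens <- setNames(ref$families$length, ref$families$family_id)
  with_preserved_seed(seed, function() {
    ga_gm <- sub("\\|.*$", "", pi$gene_a); gb_gm <- sub("\\|.*$", "", pi$gene_b)
    sel <- ga_gm %in% genome_ids & gb_gm %in% genome_ids
    sub_pi <- pi[sel]
    idn <- pmin(pmax(sub_pi$identity + stats::rnorm(nrow(sub_pi), 0, noise_sd), 0), 100)
    la <- lens[sub_pi$family_id]
    bs <- sim_bitscore(idn, la)
    data.table::data.table(gene_a = sub_pi$gene_a, gene_b = sub_pi$gene_b,
                           identity = round(idn, 2), coverage = 1,
                           evalue = sim_evalue(bs), bitscore = bs)
  })
}
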