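test_that("top-N selection ranks by bitscore, identity, accession", {
  h <- rbindlist(lapply(1:8, function(i)
    toy_hit("q1", sprintf("S%d|f1", i), pident = 50 + i, bitscore = 100 + i)))
  got <- select_top_hits(h, 5L)
  expect_identical(nrow(got), 5L)
  expect_setequal(got$sseqid, sprintf("S%d|f1", 4:8))
  # fewer hits than N are all retained; N = 1 keeps the single best
  expect_identical(nrow(select_top_hits(h[1:2], 5L)), 2L)
  expect_identical(select_top_hits(h, 1L)$sseqid, "S8|f1")
  # tie on bitscore resolved by identity then accession
  ties <- rbind(toy_hit("q1", "Sa|f1", 90, bitscore = 100),
                toy_hit("q1", "Sb|f1", 95, bitscore = 100),
                toy_hit("q1", "Sc|f1", 95, bitscore = 100))
  expect_identical(select_top_hits(ties, 1L)$sseqid, "Sb|f1")
})

test_that("match scoring combines bitscore with the D/M weights", {
  rec <- list(intra = c(95, 96, 97), inter = c(60, 61, 62),
              bw_intra = scott_bandwidth(c(95, 96, 97)),
              bw_inter = scott_bandwidth(c(60, 61, 62)),
              n_intra = 3L, n_inter = 3L, m = 0.8)
  cfg <- classifier_config(weight_cfg = combined_weight_config(0.6))
  hits <- data.table(pident = c(96, 61, 80), bitscore = c(100, 100, 50))
  got <- score_match(hits, rec, cfg)
  # spreadsheet oracle: bitscore * (0.6 D + 0.4 M)
  d <- d_weight(rbind(data.table(identity = rec$intra, category = "intra"),
                      data.table(identity = rec$inter, category = "inter")),
                hits$pident)
  expect_equal(got, hits$bitscore * (0.6 * d + 0.4 * 0.8), tolerance = 1e-12)
  # zero combined weight kills the contribution regardless of bitscore
  rec0 <- list(intra = numeric(), inter = c(60), bw_intra = NA_real_,
               bw_inter = 0.5, n_intra = 0L, n_inter = 1L, m = 0)
  expect_equal(score_match(data.table(pident = 90, bitscore = 1e6), rec0,
                           classifier_config()), 0)
  # D=1, M=1, bitscore 100 -> 100
  rec1 <- list(intra = c(90), inter = numeric(), bw_intra = 0.5,
               bw_inter = NA_real_, n_intra = 1L, n_inter = 0L, m = 1)
  expect_equal(score_match(data.table(pident = 90, bitscore = 100), rec1,
                           classifier_config()), 100)
})

test_that("rank likelihoods normalize to 1 with grouped-sum equivalence", {
  co <- data.table(taxon = c("X", "X", "Y"), contrib = c(2, 1, 1))
  got <- rank_likelihoods(co)
  expect_equal(got[taxon == "X"]$likelihood, 0.75)
  expect_equal(got[taxon == "Y"]$likelihood, 0.25)
  expect_equal(sum(got$likelihood), 1, tolerance = 1e-9)
  # all contributions to one taxon -> 1.0
  expect_equal(rank_likelihoods(data.table(taxon = "Z", contrib = 5))$likelihood, 1.0)
  # 3 taxa x 4 genes toy equals the brute-force grouped-sum oracle
  set.seed(18)
  co2 <- data.table(taxon = sample(c("T1", "T2", "T3"), 12, TRUE),
                    contrib = runif(12))
  got2 <- rank_likelihoods(co2)
  orc <- sapply(split(co2$contrib, co2$taxon), sum)
  expect_equal(setNames(got2$likelihood, got2$taxon)[names(orc)],
               orc / sum(orc), tolerance = 1e-12)
  # zero total weight -> unresolved (no candidates)
  expect_identical(nrow(rank_likelihoods(data.table(taxon = "X", contrib = 0))), 0L)
})

test_that("a single high-identity hit resolves all three ranks", {
  w <- toy_ref_world()
  genes <- data.table(contig_id = "ctg1", gene_id = "ctg1_g1")
  hits <- toy_hit("ctg1_g1", "A1|f1", 99)
  res <- classify_contig(genes, hits, w$db, w$tax)
  expect_identical(res$phylum, "P1")
  expect_identical(res$genus, "gA")
  expect_identical(res$species, "sA1")
  expect_equal(res$species_score, 1.0)
  expect_identical(res$lowest_rank, "species")
  expect_identical(res$novelty_call, "known species")
})

test_that("the score cutoff is inclusive at the boundary", {
  w <- toy_ref_world()
  genes <- data.table(contig_id = "ctg1", gene_id = "ctg1_g1")
  # phylum shares 0.499 / 0.501: only the 0.501 side is acceptable
  h2 <- rbind(toy_hit("ctg1_g1", "A1|f1", 70, bitscore = 499),
              toy_hit("ctg1_g1", "C1|f1", 70, bitscore = 501))
  r2 <- classify_contig(genes, h2, w$db, w$tax)
  expect_identical(r2$phylum, "P2")
  expect_equal(r2$phylum_score, 0.501, tolerance = 1e-9)
  # an exact 0.500 share is accepted (cutoff uses >=)
  h3 <- rbind(toy_hit("ctg1_g1", "A1|f1", 70, bitscore = 500),
              toy_hit("ctg1_g1", "C1|f1", 70, bitscore = 500))
  r3 <- classify_contig(genes, h3, w$db, w$tax)
  expect_equal(r3$phylum_score, 0.5, tolerance = 1e-9)
  expect_false(is.na(r3$phylum))
})

test_that("a 0.499 top genus is rejected and the descent stops at phylum", {
  w <- toy_ref_world()
  genes <- data.table(contig_id = "ctg1", gene_id = "ctg1_g1")
  # genus shares within accepted P1: gA 0.499, gB 0.250; P2 hit dilutes (0.251)
  hits <- rbind(toy_hit("ctg1_g1", "A1|f1", 70, bitscore = 499),
                toy_hit("ctg1_g1", "B1|f1", 70, bitscore = 250),
                toy_hit("ctg1_g1", "C1|f1", 70, bitscore = 251))
  r <- classify_contig(genes, hits, w$db, w$tax)
  expect_identical(r$phylum, "P1")            # 0.749 at phylum
  expect_true(is.na(r$genus))                 # top candidate 0.499 < 0.5
  expect_identical(r$lowest_rank, "phylum")
  # novelty call from the AAI of the hits supporting the accepted phylum (70%)
  expect_identical(r$novelty_call, "novel species")
  expect_equal(r$best_match_aai, 70)
})

test_that("batch output maintains lineage consistency and normalization", {
  w <- toy_ref_world()
  set.seed(19)
  genes <- data.table(contig_id = rep(sprintf("c%02d", 1:20), each = 2L),
                      gene_id = sprintf("c%02d_g%d", rep(1:20, each = 2L), 1:2))
  subs <- paste0(sample(c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
                        120, TRUE), "|f1")
  hits <- rbindlist(lapply(seq_len(120), function(i)
    toy_hit(sample(genes$gene_id, 1L), subs[i], runif(1, 45, 99),
            bitscore = runif(1, 50, 500))))
  out <- classify_batch(genes, hits, w$db, w$tax)
  res <- out$results
  # lineage consistency: species implies genus implies phylum, and the
  # accepted species really lies under the accepted genus
  expect_true(all(is.na(res$species) | !is.na(res$genus)))
  expect_true(all(is.na(res$genus) | !is.na(res$phylum)))
  for (k in which(!is.na(res$species))) {
    row <- w$tax[species == res$species[k]]
    expect_identical(row$genus, res$genus[k])
    expect_identical(row$phylum, res$phylum[k])
  }
  # single-contig batch equals classify_contig
  one <- genes[contig_id == "c01"]
  expect_identical(classify_contig(one, hits, w$db, w$tax),
                   classify_batch(one, hits, w$db, w$tax)$results)
  # empty hits -> everything unclassified
  empty <- classify_batch(genes, hits[0], w$db, w$tax)$results
  expect_true(all(empty$lowest_rank == "unclassified"))
})

test_that("raising the cutoff never deepens a classification", {
  w <- toy_ref_world()
  set.seed(20)
  genes <- data.table(contig_id = rep(sprintf("m%02d", 1:15), each = 1L),
                      gene_id = sprintf("m%02d_g1", 1:15))
  hits <- rbindlist(lapply(genes$gene_id, function(g) {
    k <- sample(2:6, 1L)
    rbindlist(lapply(seq_len(k), function(.)
      toy_hit(g, paste0(sample(c("A1", "A2", "B1", "C1", "D1"), 1L), "|f1"),
              runif(1, 45, 99), bitscore = runif(1, 50, 500))))
  }))
  depth <- function(cutoff) {
    r <- classify_batch(genes, hits, w$db, w$tax,
                        classifier_config(score_cutoff = cutoff))$results
    match(r$lowest_rank, c("unclassified", "phylum", "genus", "species"))
  }
  d_low <- depth(0.3); d_mid <- depth(0.5); d_high <- depth(0.9)
  expect_true(all(d_mid <= d_low))
  expect_true(all(d_high <= d_mid))
})

test_that("top_n = 1 reduces to the weighted best-hit lineage", {
  w <- toy_ref_world()
  set.seed(22)
  genes <- data.table(contig_id = sprintf("n%02d", 1:10),
                      gene_id = sprintf("n%02d_g1", 1:10))
  hits <- rbindlist(lapply(genes$gene_id, function(g)
    rbindlist(lapply(1:4, function(.)
      toy_hit(g, paste0(sample(c("A1", "A2", "B1", "C1"), 1L), "|f1"),
              round(runif(1, 45, 99), 3), bitscore = round(runif(1, 50, 500), 3))))))
  res <- classify_batch(genes, hits, w$db, w$tax,
                        classifier_config(top_n = 1L))$results
  for (k in seq_len(nrow(res))) {
    hh <- hits[qseqid == paste0(res$contig_id[k], "_g1")]
    best <- hh[order(-bitscore, -pident, sseqid)][1L]
    src <- sub("\\|f1$", "", best$sseqid)
    expect_identical(res$phylum[k], w$tax[genome_id == src]$phylum)
    expect_identical(res$species[k], w$tax[genome_id == src]$species)
  }
})

test_that("unknown subjects are skipped and tallied, not fatal", {
  w <- toy_ref_world()
  genes <- data.table(contig_id = "ctg1", gene_id = "ctg1_g1")
  hits <- rbind(toy_hit("ctg1_g1", "A1|f1", 99),
                toy_hit("ctg1_g1", "NOTINDB|f9", 99))
  out <- classify_batch(genes, hits, w$db, w$tax)
  expect_identical(out$diagnostics$n_unmatched_hits, 1L)
  expect_identical(out$results$species, "sA1")
})
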