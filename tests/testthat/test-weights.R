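test_that("Gaussian KDE matches the closed form and the summation oracle", {
  # single point: fallback bandwidth, closed-form peak 1/(h sqrt(2 pi))
  h <- scott_bandwidth(90)
  expect_equal(h, 0.5)
  expect_equal(kde_density(90, 90), 1 / (h * sqrt(2 * pi)))

  # symmetric points give a symmetric density
  expect_equal(kde_density(c(80, 100), 85), kde_density(c(80, 100), 95))

  # 20 random points at 7 evaluation values vs direct kernel summation
  set.seed(12)
  pts <- runif(20, 40, 100)
  xs <- runif(7, 30, 110)
  hh <- sd(pts) * 20^(-1 / 5)
  oracle <- vapply(xs, function(x) sum(dnorm(x, pts, hh)) / 20, numeric(1))
  expect_equal(kde_density(pts, xs), oracle, tolerance = 1e-12)

  # zero-variance sample falls back, never a zero bandwidth
  expect_equal(scott_bandwidth(rep(50, 5)), 0.5)
})

test_that("identity observations are categorized by shared taxon at the rank", {
  tax <- toy_taxonomy(c("A", "B", "C"), phylum = c("P1", "P1", "P2"),
                      genus = c("g1", "g1", "g2"),
                      species = c("s1", "s1", "s2"))
  members <- data.table(accession = c("A|g1", "B|g1", "C|g1"),
                        genome_id = c("A", "B", "C"))
  pid <- data.table(gene_a = c("A|g1", "A|g1", "B|g1"),
                    gene_b = c("B|g1", "C|g1", "C|g1"),
                    identity = c(97, 55, 54))
  obs_sp <- collect_identity_observations(members, pid, tax, "species")
  expect_identical(obs_sp[identity == 97]$category, "intra")
  expect_identical(obs_sp[identity != 97]$category, c("inter", "inter"))

  # 3 genes from 3 phyla -> all inter at phylum rank
  tax3 <- toy_taxonomy(c("A", "B", "C"), paste0("P", 1:3), paste0("g", 1:3),
                       paste0("s", 1:3))
  expect_identical(collect_identity_observations(members, pid, tax3, "phylum")$category,
                   rep("inter", 3L))

  # single eligible gene -> empty
  expect_identical(nrow(collect_identity_observations(members[1], pid, tax, "species")), 0L)

  # 12-gene fixture equals the nested-loop lineage oracle
  set.seed(13)
  genomes <- sprintf("G%02d", 1:12)
  tax12 <- toy_taxonomy(genomes, phylum = rep(c("P1", "P2"), 6L),
                        genus = rep(sprintf("g%d", 1:4), 3L),
                        species = rep(sprintf("s%d", 1:6), 2L))
  mem12 <- data.table(accession = paste0(genomes, "|f"), genome_id = genomes)
  cmb <- t(combn(mem12$accession, 2L))
  pid12 <- data.table(gene_a = cmb[, 1L], gene_b = cmb[, 2L],
                      identity = runif(nrow(cmb), 30, 100))
  for (rk in c("phylum", "genus", "species")) {
    obs <- collect_identity_observations(mem12, pid12, tax12, rk)
    for (k in seq_len(nrow(obs))) {
      ga <- sub("\\|f$", "", obs$gene_a[k]); gb <- sub("\\|f$", "", obs$gene_b[k])
      want <- if (tax12[genome_id == ga][[rk]] == tax12[genome_id == gb][[rk]])
        "intra" else "inter"
      expect_identical(obs$category[k], want)
    }
  }
})

test_that("D weight hits its limit cases and the KDE-ratio oracle", {
  obs_intra <- data.table(identity = c(95, 96), category = "intra")
  obs_inter <- data.table(identity = c(60, 61), category = "inter")
  # pure intra -> 1, pure inter -> 0 at every x
  expect_equal(d_weight(obs_intra, c(50, 70, 95)), rep(1, 3))
  expect_equal(d_weight(obs_inter, c(50, 70, 95)), rep(0, 3))
  # both empty -> unavailable
  expect_true(all(is.na(d_weight(obs_intra[0], 80))))
  # equal densities -> 0.5
  both <- rbind(data.table(identity = c(79, 81), category = "intra"),
                data.table(identity = c(79, 81), category = "inter"))
  expect_equal(d_weight(both, 80), 0.5)
  # well-separated samples: D(95) > 0.99, D(60) < 0.01
  set.seed(14)
  sep <- rbind(data.table(identity = rnorm(40, 95, 1), category = "intra"),
               data.table(identity = rnorm(40, 60, 1), category = "inter"))
  expect_gt(d_weight(sep, 95), 0.99)
  expect_lt(d_weight(sep, 60), 0.01)
  # equals the direct KDE-ratio oracle
  fi <- kde_density(sep[category == "intra"]$identity, 80)
  fe <- kde_density(sep[category == "inter"]$identity, 80)
  expect_equal(d_weight(sep, 80), fi / (fi + fe), tolerance = 1e-12)
  # difference mode is the clamped density difference
  expect_equal(d_weight(sep, 94, mode = "difference"),
               min(max(kde_density(sep[category == "intra"]$identity, 94) -
                         kde_density(sep[category == "inter"]$identity, 94), 0), 1))
})

test_that("triplet concordance compares closest pairs against the species tree", {
  aai <- toy_aai(c("A", "B", "C"),
                 list(list("A", "B", 90), list("A", "C", 50), list("B", "C", 50)))
  tree <- build_species_tree(aai)
  # gene distances proportional to species distances -> concordant
  gd_ok <- (100 - aai$values) / 100 * 0.7
  expect_true(triplet_concordance(gd_ok, tree, c("A", "B", "C")))
  # gene cherry (A,C) where species cherry is (A,B) -> discordant
  gd_bad <- matrix(c(0, .5, .1, .5, 0, .5, .1, .5, 0), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_false(triplet_concordance(gd_bad, tree, c("A", "B", "C")))
  # ties go to concordant
  gd_tie <- matrix(0.4, 3, 3, dimnames = dimnames(gd_bad)); diag(gd_tie) <- 0
  expect_true(triplet_concordance(gd_tie, tree, c("A", "B", "C")))
  expect_error(triplet_concordance(gd_ok, tree, c("A", "B", "Z")), "absent")
})

test_that("M weight: exact enumeration, Monte-Carlo agreement and HGT recovery", {
  # gene tree identical to species tree -> M = 1
  set.seed(15)
  n <- 12L
  ids <- sprintf("G%02d", 1:n)
  base <- matrix(runif(n * n, 0.2, 0.8), n, n, dimnames = list(ids, ids))
  base <- (base + t(base)) / 2; diag(base) <- 0
  aai_obj <- structure(list(genome_ids = ids, values = 100 - base * 100,
                            n_shared = base * 0 + 1L), class = "aai_matrix")
  tree <- build_species_tree(aai_obj)
  patr <- ape::cophenetic.phylo(tree)[ids, ids]
  expect_equal(m_weight(patr, tree)$m, 1.0)

  # 3 genomes, planted discordant triplet -> M = 0
  t3 <- build_species_tree(toy_aai(c("A", "B", "C"),
                                   list(list("A", "B", 90), list("A", "C", 50),
                                        list("B", "C", 50))))
  gd_bad <- matrix(c(0, .5, .1, .5, 0, .5, .1, .5, 0), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(m_weight(gd_bad, t3)$m, 0.0)

  # fewer than 3 genomes: degenerate default 1
  expect_identical(m_weight(gd_bad[1:2, 1:2], t3)$method, "degenerate")

  # Monte-Carlo within 3 SE of exhaustive enumeration on a 12-genome cluster
  noisy <- patr + matrix(runif(n * n, 0, 0.35), n, n)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  exact <- m_weight(noisy, tree)
  expect_identical(exact$method, "exact")
  expect_identical(exact$n_triplets, as.integer(choose(n, 3L)))
  mc <- m_weight(noisy, tree, max_exhaustive = 5L, mc_samples = 2000L, seed = 77L)
  expect_identical(mc$method, "monte_carlo")
  expect_lt(abs(mc$m - exact$m), 3 * max(mc$se, 1e-3))

  # Monte-Carlo mean over seeds converges to the exact value (unbiasedness)
  ms <- vapply(1:10, function(s)
    m_weight(noisy, tree, max_exhaustive = 5L, mc_samples = 1000L, seed = s)$m,
    numeric(1))
  se_mean <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - exact$m), 4 * se_mean + 1e-3)
})

test_that("planted HGT discordance is recovered by M", {
  # world with a known transfer fraction; expected discordance comes from an
  # independent enumeration over the planted gene distances
  ref <- simulate_reference_set(taxonomy_spec(2L, 2L, 2L, 2L),
                                gene_family_spec(n_families = 10L, hgt_rate = 0.15),
                                seed = 55L)
  A <- Reduce(`+`, ref$identity_matrices) / length(ref$identity_matrices)
  aai <- structure(list(genome_ids = rownames(A), values = A,
                        n_shared = A * 0L + 1L), class = "aai_matrix")
  tree <- build_species_tree(aai)
  patr <- ape::cophenetic.phylo(tree)
  fams_hgt <- unique(ref$hgt$family_id)
  expect_gt(length(fams_hgt), 0L)
  for (fid in fams_hgt[seq_len(min(3L, length(fams_hgt)))]) {
    gd <- (100 - ref$identity_matrices[[fid]]) / 100
    got <- m_weight(gd, tree)$m
    # oracle: manual loop over all genome triplets with triplet_concordance
    ids <- rownames(gd)
    trips <- combn(ids, 3L)
    conc <- vapply(seq_len(ncol(trips)), function(k)
      triplet_concordance(gd, tree, trips[, k]), logical(1))
    expect_equal(got, mean(conc))
    expect_lt(got, 1.0)  # transfers must show up as discordance
  }
  # q = 0 world: every family fully concordant, M = 1 downstream
  ref0 <- simulate_reference_set(taxonomy_spec(2L, 2L, 1L, 2L),
                                 gene_family_spec(n_families = 5L, hgt_rate = 0),
                                 seed = 56L)
  A0 <- Reduce(`+`, ref0$identity_matrices) / length(ref0$identity_matrices)
  aai0 <- structure(list(genome_ids = rownames(A0), values = A0,
                         n_shared = A0 * 0L + 1L), class = "aai_matrix")
  tree0 <- build_species_tree(aai0)
  for (fid in names(ref0$identity_matrices)) {
    gd0 <- (100 - ref0$identity_matrices[[fid]]) / 100
    expect_equal(m_weight(gd0, tree0)$m, 1.0)
  }
})

test_that("combined weight is the stated convex combination", {
  expect_equal(combined_weight(0.3, 0.9, combined_weight_config(1)), 0.3)
  expect_equal(combined_weight(0.5, 1.0, combined_weight_config(0.6)), 0.7)
  for (v in c(0, 0.25, 1)) # D = M = v -> v under any w_d
    expect_equal(combined_weight(v, v, combined_weight_config(0.37)), v)
  # never exceeds max(D, M)
  set.seed(16)
  d <- runif(50); m <- runif(50)
  w <- combined_weight(d, m, combined_weight_config(0.42))
  expect_true(all(w <= pmax(d, m) + 1e-12 & w >= pmin(d, m) - 1e-12))
})

test_that("a conserved '16S-like' family discriminates phyla better than species", {
  # tiny intra/inter-species divergence but clear phylum separation
  genomes <- sprintf("G%d", 1:8)
  tax <- toy_taxonomy(genomes, phylum = rep(c("P1", "P2"), each = 4L),
                      genus = rep(c("g1", "g2"), each = 4L),
                      species = rep(c("s1", "s2", "s3", "s4"), each = 2L))
  mem <- data.table(accession = paste0(genomes, "|rrs"), genome_id = genomes)
  cmb <- t(combn(genomes, 2L))
  same_ph <- tax$phylum[match(cmb[, 1], tax$genome_id)] ==
    tax$phylum[match(cmb[, 2], tax$genome_id)]
  set.seed(17)
  pid <- data.table(gene_a = paste0(cmb[, 1], "|rrs"),
                    gene_b = paste0(cmb[, 2], "|rrs"),
                    identity = ifelse(same_ph, runif(nrow(cmb), 98, 99.5),
                                      runif(nrow(cmb), 88, 90)))
  obs_ph <- collect_identity_observations(mem, pid, tax, "phylum")
  obs_sp <- collect_identity_observations(mem, pid, tax, "species")
  # at a conserved-gene identity typical of same-phylum pairs, phylum D is
  # informative while species D is ambiguous
  expect_gt(d_weight(obs_ph, 99), 0.9)
  expect_lt(d_weight(obs_sp, 99), d_weight(obs_ph, 99))
})
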