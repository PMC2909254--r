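test_that("Yule simulation is ultrametric, seeded, and matches the
           analytic expected root age", {
  t2 <- simulate_yule_tree(2, seed = 4)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(attr(check_ultrametric(t2), "pass"))
  expect_identical(ape::write.tree(simulate_yule_tree(9, seed = 3)),
                   ape::write.tree(simulate_yule_tree(9, seed = 3)))
  expect_error(simulate_yule_tree(1), "n_tips")

  root_age <- function(tr) max(ecmphylo:::node_depths(tr)[
    seq_len(ape::Ntip(tr))])
  expected <- function(n, lambda = 1) sum(1 / (lambda * 2:n))
  set.seed(99)
  m4 <- mean(replicate(200, root_age(simulate_yule_tree(4))))
  m64 <- mean(replicate(200, root_age(simulate_yule_tree(64))))
  expect_gt(m64, m4)
  expect_lt(abs(m4 - expected(4)), 0.15)    # E = 0.78, MC se ~ 0.05
  expect_lt(abs(m64 - expected(64)), 0.25)  # E = 3.18, MC se ~ 0.06
})

test_that("sequence evolution honours rates and the ITS/LSU ratio", {
  tr <- simulate_yule_tree(8, seed = 2, normalize = TRUE)
  cfg0 <- synthetic_config(lsu_rate = 0, seq_len_its = 60, seq_len_lsu = 60)
  s0 <- evolve_sequences(tr, "ITS", cfg0, seed = 1)
  expect_length(unique(s0$residues), 1)  # rate 0: all equal the root

  expect_error(
    evolve_sequences(tr, "ITS",
                     synthetic_config(seq_len_its = 0), seed = 1),
    "zero-length")

  # rho = 1: both markers drift at the same speed
  cfg1 <- synthetic_config(its_rate_ratio = 1, lsu_rate = 0.15,
                           seq_len_its = 1500, seq_len_lsu = 1500)
  set.seed(7)
  ratio <- replicate(20, {
    mean_pdist(evolve_sequences(tr, "ITS", cfg1)$residues) /
      mean_pdist(evolve_sequences(tr, "LSU", cfg1)$residues)
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)

  # rho = 3: ITS p-distance exceeds LSU on every pair
  cfg3 <- synthetic_config(its_rate_ratio = 3, lsu_rate = 0.1,
                           seq_len_its = 1500, seq_len_lsu = 1500)
  set.seed(8)
  its <- evolve_sequences(tr, "ITS", cfg3)$residues
  lsu <- evolve_sequences(tr, "LSU", cfg3)$residues
  sp_i <- strsplit(its, ""); sp_l <- strsplit(lsu, "")
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_gt(mean(sp_i[[i]] != sp_i[[j]]), mean(sp_l[[i]] != sp_l[[j]]))
    }
  }
})

test_that("assembly models behave as specified", {
  cfg <- synthetic_config(n_species_pool = 32, filter_strength = 0,
                          n_forests_per_habitat = 1,
                          n_samples_per_forest = 10)
  tr <- simulate_yule_tree(32, seed = 5, normalize = TRUE)
  # filter_strength 0 reduces exactly to the random model
  f0 <- assemble_communities(tr, cfg, "serpentine", seed = 11,
                             model = "filtered")
  r0 <- assemble_communities(tr, cfg, "serpentine", seed = 11,
                             model = "random")
  expect_identical(f0$x, r0$x)

  # infinite strength confines every cube to the focal clade
  cfgI <- synthetic_config(n_species_pool = 32, filter_strength = Inf,
                           n_forests_per_habitat = 1,
                           n_samples_per_forest = 10)
  fI <- assemble_communities(tr, cfgI, "serpentine", seed = 3,
                             model = "filtered")
  focal <- attr(fI, "truth")$focal_clade
  expect_true(all(colnames(fI$x) %in% focal))
  expect_gte(length(focal), 12)  # smallest clade with >= 2 x max richness

  # uniform inclusion under the random model (chi-square GOF, 1e4 draws)
  cfgU <- synthetic_config(n_species_pool = 16,
                           n_forests_per_habitat = 1,
                           n_samples_per_forest = 2500)
  trU <- simulate_yule_tree(16, seed = 6, normalize = TRUE)
  ru <- assemble_communities(trU, cfgU, "serpentine", seed = 13,
                             model = "random")
  counts <- colSums(ru$x)
  expect_gte(sum(counts), 1e4 * 0.7)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)

  # overdispersed cubes spread further over the tree than filtered ones
  dm <- patristic_distances(trU)
  cfgD <- synthetic_config(n_species_pool = 16, filter_strength = 5,
                           n_forests_per_habitat = 1,
                           n_samples_per_forest = 30)
  ov <- assemble_communities(trU, cfgD, "serpentine", seed = 14,
                             model = "overdispersed")
  fl <- assemble_communities(trU, cfgD, "serpentine", seed = 14,
                             model = "filtered")
  mpd_rows <- function(cm) {
    mean(apply(cm$x, 1, function(r) {
      s <- colnames(cm$x)[r > 0]
      mean_phylo_distances(s, dm)["mpd"]
    }))
  }
  expect_gt(mpd_rows(ov), mpd_rows(fl))
})

test_that("soil table generation follows the summaries", {
  g <- data.frame(parameter = c("Ni", "Ni"),
                  group = c("serpentine", "non_serpentine"),
                  mean = c(29.8, 1.0), sd = c(0, 0))
  t0 <- generate_soil_table(g, n_reps = 4, seed = 1)
  expect_equal(t0$value, rep(c(29.8, 1.0), each = 4))  # sd 0: exact means
  expect_error(generate_soil_table(transform(g, sd = -1)), "negative sd")
  t1 <- generate_soil_table(soil_reference(), n_reps = 4, seed = 9)
  t2 <- generate_soil_table(soil_reference(), n_reps = 4, seed = 9)
  expect_identical(t1, t2)
})

test_that("generate_study assembles the full design deterministically", {
  cfg <- synthetic_config(seed = 21, n_species_pool = 32,
                          seq_len_its = 120, seq_len_lsu = 150)
  st <- generate_study(cfg)
  n_samp <- nrow(st$matrices$serpentine$x) +
    nrow(st$matrices$non_serpentine$x)
  expect_equal(n_samp, 80)  # 2 habitats x 2 forests x 20 cubes
  expect_true(all(colnames(st$matrices$serpentine$x) %in%
                    st$true_tree$tip.label))
  expect_true(all(colnames(st$matrices$non_serpentine$x) %in%
                    st$true_tree$tip.label))
  st2 <- generate_study(cfg)
  expect_identical(ape::write.tree(st$true_tree),
                   ape::write.tree(st2$true_tree))
  expect_identical(st$matrices$serpentine$x, st2$matrices$serpentine$x)
  expect_identical(st$tip_records, st2$tip_records)
  expect_identical(st$soil_table, st2$soil_table)
  # marker trees carry the right scales and outgroups
  expect_equal(tree_scale(st$backbone_subs), "substitutions")
  for (g in names(st$its_genus_trees)) {
    expect_true(any(startsWith(st$its_genus_trees[[g]]$tip.label, "OUT_")))
  }
})

test_that("random-vs-random habitats overlap like hypergeometric draws;
           filtered serpentine is more clustered than random", {
  # scenario B: shared species count matches the hypergeometric mean
  cfg <- synthetic_config(n_species_pool = 32, seq_len_its = 2,
                          seq_len_lsu = 2, n_forests_per_habitat = 1,
                          n_samples_per_forest = 10,
                          assembly_model = "random")
  set.seed(31)
  dev <- replicate(20, {
    tr <- simulate_yule_tree(32, normalize = TRUE)
    a <- assemble_communities(tr, cfg, "serpentine", model = "random")
    b <- assemble_communities(tr, cfg, "non_serpentine", model = "random")
    sh <- length(intersect(colnames(a$x), colnames(b$x)))
    sh - ncol(a$x) * ncol(b$x) / 32
  })
  expect_lt(abs(mean(dev)), 3 * stats::sd(dev) / sqrt(length(dev)) + 1e-9)

  # scenario A: filtered serpentine NRI stochastically above random
  cfgA <- synthetic_config(n_species_pool = 32, filter_strength = 5,
                           tips_per_sample_mean = 6,
                           tips_per_sample_range = c(6, 6),
                           n_forests_per_habitat = 1,
                           n_samples_per_forest = 20)
  set.seed(32)
  nri <- replicate(15, {
    tr <- simulate_yule_tree(32, normalize = TRUE)
    one <- function(model, hab) {
      cm <- assemble_communities(tr, cfgA, hab, model = model)
      comstruct(cm, tr, null_model_spec("phylogeny_shuffle", 199))$nri
    }
    c(filtered = one("filtered", "serpentine"),
      random = one("random", "non_serpentine"))
  })
  expect_gt(mean(nri["filtered", ] > nri["random", ]), 0.8)
  expect_gt(median(nri["filtered", ]), median(nri["random", ]))
})
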