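test_that("scale factors on constructed tree pairs are exact", {
  its <- ape::read.tree(text = "((s1:1,s2:1):1,OUT_x:2);")
  bb <- ape::read.tree(text = "(G1:2,OG:2);")
  sf <- estimate_scale_factor(its, bb, "G1", "OG")
  expect_equal(sf$s_g, 1.0)   # identical distances
  expect_equal(sf$P_its, 4)   # both ingroup tips at distance 4

  its2 <- its
  its2$edge.length <- its$edge.length * 2
  expect_equal(estimate_scale_factor(its2, bb, "G1", "OG")$s_g, 0.5)

  expect_error(estimate_scale_factor(its, bb, "G9", "OG"), "G9")
  noout <- ape::read.tree(text = "(s1:1,s2:1);")
  expect_error(estimate_scale_factor(noout, bb, "G1", "OG"), "outgroup")
})

test_that("grafting constructed case gives exact crown ages", {
  bb <- set_tree_scale(
    ape::read.tree(text = "((G1:0.4,G2:0.4):0.6,G3:1);"), "relative_time")
  crown <- ape::read.tree(text = "(s1:1,s2:1);")
  pl <- list(G1 = list(genus = "G1", s_g = 1, f_g = 0.5, a_g = 0.4,
                       capped = FALSE))
  st <- graft(bb, list(G1 = crown, G2 = "x2", G3 = "x3"), pl)
  expect_true(attr(check_ultrametric(st, 1e-8), "pass"))
  ages <- ecmphylo:::node_ages(st)
  crown_node <- ape::getMRCA(st, c("s1", "s2"))
  expect_equal(unname(ages[crown_node]), 0.2)      # f_g * a_g
  stem <- st$edge.length[st$edge[, 2] == crown_node]
  expect_equal(stem, 0.2)                           # a_g - crown age
  expect_equal(sort(st$tip.label), c("s1", "s2", "x2", "x3"))

  # all genera single species: topology is the backbone
  st2 <- graft(bb, list(G1 = "x1", G2 = "x2", G3 = "x3"), list())
  expect_equal(ape::dist.topo(
    ape::unroot(st2),
    ape::unroot(ape::read.tree(text = "((x1:0.4,x2:0.4):0.6,x3:1);"))), 0,
    ignore_attr = TRUE)

  # missing plan for a multi-species genus errors
  expect_error(graft(bb, list(G1 = crown, G2 = "x2", G3 = "x3"), list()),
               "plan")
  # non-ultrametric species tree errors
  bad <- ape::read.tree(text = "(s1:1,s2:2);")
  expect_error(graft(bb, list(G1 = bad, G2 = "x2", G3 = "x3"), pl),
               "ultrametric")
})

test_that("crown fractions above the cap are capped with a warning", {
  bb_sub <- ape::read.tree(text = "((G1:0.05,G2:0.05):0.65,G3:0.7);")
  bb_time <- nprs_smooth(bb_sub)$tree
  # ITS crown much deeper than the tiny stem -> uncapped f_g ~ 0.98
  its <- ape::read.tree(text = "((s1:0.5,s2:0.5):0.01,OUT_g:0.51);")
  expect_warning(
    pl <- graft_plan(bb_sub, bb_time, list(G1 = its), c(G1 = "G2")),
    "capped")
  expect_equal(pl$G1$f_g, 0.9)
  expect_true(pl$G1$capped)
  crown <- ape::read.tree(text = "(s1:1,s2:1);")
  st <- graft(bb_time, list(G1 = crown, G2 = "x2", G3 = "x3"), pl)
  expect_true(attr(check_ultrametric(st, 1e-8), "pass"))
  # stem keeps at least (1 - beta) of the attachment age
  crown_node <- ape::getMRCA(st, c("s1", "s2"))
  stem <- st$edge.length[st$edge[, 2] == crown_node]
  expect_gte(stem, 0.1 * pl$G1$a_g - 1e-12)
})

test_that("increasing s_g stretches within-genus, not between-genus,
           distances", {
  bb_sub <- ape::read.tree(text = "((G1:0.3,G2:0.3):0.3,G3:0.6);")
  bb_time <- nprs_smooth(bb_sub)$tree
  crown <- ape::read.tree(text = "(s1:1,s2:1);")
  mk <- function(f) {
    pl <- list(G1 = list(genus = "G1", s_g = f, f_g = f, a_g = 0.5,
                         capped = FALSE))
    graft(bb_time, list(G1 = crown, G2 = "x2", G3 = "x3"), pl)
  }
  d1 <- patristic_distances(mk(0.3))
  d2 <- patristic_distances(mk(0.6))
  expect_gt(d2["s1", "s2"], d1["s1", "s2"])
  expect_equal(d2["s1", "x3"], d1["s1", "x3"])
  expect_equal(d2["x2", "x3"], d1["x2", "x3"])
})

test_that("prune(graft(x)) recovers the backbone for synthetic studies", {
  for (seed in c(101, 202)) {
    st <- generate_study(synthetic_config(
      seed = seed, n_species_pool = 24, seq_len_its = 2, seq_len_lsu = 2))
    built <- build_supertree(st)
    expect_lte(as.numeric(check_ultrametric(built$supertree)), 1e-8)
    expect_equal(ape::Ntip(built$supertree), 24)  # sum of genus richness
    pruned <- prune_to_backbone(built$supertree, st$genus_map)
    expect_equal(ape::dist.topo(ape::unroot(pruned),
                                ape::unroot(built$backbone_time)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("prune_to_backbone is representative-independent on a toy", {
  st <- generate_study(synthetic_config(
    seed = 303, n_species_pool = 16, seq_len_its = 2, seq_len_lsu = 2))
  built <- build_supertree(st)
  gm <- st$genus_map
  genera <- unique(unname(gm))
  ref <- NULL
  # exhaustively vary the representative of the largest genus
  big <- genera[which.max(table(gm[built$supertree$tip.label]))]
  cands <- names(gm)[gm == big & names(gm) %in% built$supertree$tip.label]
  others <- vapply(setdiff(genera, big), function(g)
    names(gm)[gm == g & names(gm) %in% built$supertree$tip.label][1],
    character(1))
  for (cand in cands) {
    reps <- c(setNames(cand, big), others)[genera]
    names(reps) <- genera
    tr <- prune_to_backbone(built$supertree, gm, representatives = reps)
    if (is.null(ref)) ref <- tr
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(prune_to_backbone(built$supertree, character(0)), "empty")
  expect_error(prune_to_backbone(built$supertree, gm[-1]), "missing")
})
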