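#' Configuration of a synthetic two-habitat study
#'
#' Describes the simulated world used to exercise the pipeline end to end:
#' a Yule regional species pool, two nuclear ribosomal markers evolved at
#' different rates on the same species tree (fast ITS, slow LSU), two
#' habitats each sampled in `n_forests_per_habitat` forests with
#' `n_samples_per_forest` soil cubes, about four root tips per cube
#' (range 3-6), per-habitat community assembly rules, and a two-group
#' soil-chemistry table.
#'
#' @param n_species_pool size of the regional species pool (>= 4).
#' @param birth_rate per-lineage speciation rate of the Yule simulation.
#' @param kappa HKY85 transition/transversion rate ratio.
#' @param base_freqs equilibrium base frequencies (A,C,G,T), summing to 1.
#' @param lsu_rate expected LSU substitutions/site per unit tree depth.
#' @param its_rate_ratio rho, ITS rate divided by LSU rate (> 1 expected).
#' @param seq_len_its,seq_len_lsu simulated sequence lengths.
#' @param n_forests_per_habitat forests per habitat (default 2).
#' @param n_samples_per_forest soil cubes per forest (default 20).
#' @param tips_per_sample_mean,tips_per_sample_range mean and range of the
#'   per-cube richness distribution (default mean 4, range 3-6; drawn as
#'   `lo + Binomial(hi - lo, (mean - lo)/(hi - lo))`).
#' @param assembly_model per-habitat assembly rule(s); a single value is
#'   recycled to both habitats. Defaults to habitat filtering on
#'   serpentine and random assembly on non-serpentine soil.
#' @param filter_strength log-weight given to focal-clade membership under
#'   `filtered` (and to scaled nearest-taxon distance under
#'   `overdispersed`).
#' @param seed master seed; every stochastic step of [generate_study()]
#'   draws from the single stream it initialises.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species_pool = 64,
                             birth_rate = 1,
                             kappa = 2,
                             base_freqs = c(0.25, 0.25, 0.25, 0.25),
                             lsu_rate = 0.1,
                             its_rate_ratio = 3,
                             seq_len_its = 600L,
                             seq_len_lsu = 900L,
                             n_forests_per_habitat = 2L,
                             n_samples_per_forest = 20L,
                             tips_per_sample_mean = 4,
                             tips_per_sample_range = c(3L, 6L),
                             assembly_model = c(serpentine = "filtered",
                                                non_serpentine = "random"),
                             filter_strength = 5,
                             seed = 1L) {
  if (n_species_pool < 4) stop_ecm("n_species_pool must be >= 4")
  if (abs(sum(base_freqs) - 1) > 1e-12)
    stop_ecm("base_freqs must sum to 1")
  if (its_rate_ratio <= 0) stop_ecm("its_rate_ratio must be > 0")
  if (filter_strength < 0) stop_ecm("filter_strength must be >= 0")
  models <- rep_len(assembly_model, 2L)
  if (is.null(names(models)) || !all(nzchar(names(models))))
    names(models) <- c("serpentine", "non_serpentine")
  bad <- setdiff(models, c("filtered", "random", "overdispersed"))
  if (length(bad)) stop_ecm("unknown assembly model: ", bad[1])
  rng <- as.integer(tips_per_sample_range)
  if (rng[1] > rng[2] || tips_per_sample_mean < rng[1] ||
      tips_per_sample_mean > rng[2])
    stop_ecm("tips_per_sample_mean must lie within tips_per_sample_range")
  structure(list(
    n_species_pool = as.integer(n_species_pool), birth_rate = birth_rate,
    kappa = kappa, base_freqs = base_freqs, lsu_rate = lsu_rate,
    its_rate_ratio = its_rate_ratio,
    seq_len_its = as.integer(seq_len_its),
    seq_len_lsu = as.integer(seq_len_lsu),
    n_forests_per_habitat = as.integer(n_forests_per_habitat),
    n_samples_per_forest = as.integer(n_samples_per_forest),
    tips_per_sample_mean = tips_per_sample_mean,
    tips_per_sample_range = rng,
    assembly_model = models, filter_strength = filter_strength,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: two lineages from the root, exponential waits with
#' rate `birth_rate * k` while `k` lineages are extant, a uniformly chosen
#' lineage splitting at each event. The simulation stops when `n_tips`
#' lineages exist and extends all pendant branches by the final
#' `Exp(n_tips * birth_rate)` wait, so the expected root age is
#' `sum_{k=2}^{n} 1/(birth_rate * k)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional seed (see [with_seed()]); `NULL` draws from the
#'   current stream.
#' @param normalize rescale so the root age is exactly 1 and mark the tree
#'   as relative time.
#' @return an ultrametric `phylo` tree with tips `sp001`, `sp002`, ... in
#'   order of appearance.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               normalize = FALSE) {
  if (n_tips < 2) stop_ecm("n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  tree <- with_seed(seed, {
    birth <- c(0, 0)
    split_at <- rep(NA_real_, 2L)
    kids <- list(NULL, NULL)
    active <- c(1L, 2L)
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + rexp(1, birth_rate * k)
      pick <- sample.int(k, 1L)
      i <- active[pick]
      a <- length(birth) + 1L
      b <- a + 1L
      birth[c(a, b)] <- t
      split_at[i] <- t
      split_at[c(a, b)] <- NA_real_
      kids[[i]] <- c(a, b)
      kids[c(a, b)] <- list(NULL, NULL)
      active <- c(active[-pick], a, b)
    }
    t_end <- t + rexp(1, birth_rate * n_tips)
    tipc <- 0L
    fmt <- function(x) sprintf("%.15g", x)
    build <- function(i) {
      if (is.null(kids[[i]])) {
        tipc <<- tipc + 1L
        paste0(sprintf("sp%03d", tipc), ":", fmt(t_end - birth[i]))
      } else {
        paste0("(", build(kids[[i]][1]), ",", build(kids[[i]][2]), "):",
               fmt((if (is.na(split_at[i])) t_end else split_at[i]) - birth[i]))
      }
    }
    ape::read.tree(text = paste0("(", build(1L), ",", build(2L), ");"))
  })
  if (normalize) {
    depth <- max(node_depths(tree)[seq_len(n_tips)])
    tree$edge.length <- tree$edge.length / depth
    tree <- set_tree_scale(tree, "relative_time")
  }
  tree
}

# HKY85 rate matrix, scaled to one expected substitution per unit time
hky_rate_matrix <- function(kappa, freqs) {
  transitions <- matrix(c(1, 3, 2, 4), 2, byrow = TRUE)  # A<->G, C<->T
  Q <- outer(rep(1, 4), freqs)
  for (r in 1:2) {
    i <- transitions[r, 1]; j <- transitions[r, 2]
    Q[i, j] <- Q[i, j] * kappa
    Q[j, i] <- Q[j, i] * kappa
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(freqs * -diag(Q))
}

# eigen machinery for matrix-exponential transition probabilities;
# symmetrised with sqrt(pi) for numerical stability
hky_eigen <- function(kappa, freqs) {
  Q <- hky_rate_matrix(kappa, freqs)
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       left = diag(1 / s) %*% e$vectors,
       right = t(e$vectors) %*% diag(s))
}

hky_pmat <- function(eig, t) {
  P <- eig$left %*% (exp(eig$values * t) * eig$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve marker sequences on a tree under HKY85
#'
#' Site-independent HKY85 simulation by matrix-exponential transition
#' probabilities (4x4 eigen decomposition, exact for any branch length).
#' The LSU marker evolves at `lsu_rate` expected substitutions/site per
#' unit of tree depth; ITS at `its_rate_ratio` times that.
#'
#' @param tree ultrametric `phylo` tree (depth 1 assumed for the rates to
#'   have their stated units).
#' @param marker `"ITS"` or `"LSU"`.
#' @param config a [synthetic_config()].
#' @param seed optional seed.
#' @return a data.frame of sequence records (one per tip) as in
#'   [read_fasta()].
#' @export
evolve_sequences <- function(tree, marker = c("ITS", "LSU"), config,
                             seed = NULL) {
  marker <- match.arg(marker)
  len <- if (marker == "ITS") config$seq_len_its else config$seq_len_lsu
  if (len < 1) stop_ecm("requested zero-length sequences")
  rate <- config$lsu_rate *
    (if (marker == "ITS") config$its_rate_ratio else 1)
  eig <- hky_eigen(config$kappa, config$base_freqs)
  bases <- c("A", "C", "G", "T")
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  with_seed(seed, {
    store <- vector("list", n + tree$Nnode)
    store[[n + 1L]] <- sample.int(4L, len, replace = TRUE,
                                  prob = config$base_freqs)
    for (i in seq_len(nrow(tr$edge))) {
      p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      P <- hky_pmat(eig, tr$edge.length[i] * rate)
      cp <- t(apply(P, 1, cumsum))
      s <- store[[p]]
      new <- s
      for (b in 1:4) {
        idx <- which(s == b)
        if (length(idx)) {
          u <- runif(length(idx))
          new[idx] <- 1L + (u > cp[b, 1]) + (u > cp[b, 2]) + (u > cp[b, 3])
        }
      }
      store[[ch]] <- new
    }
    data.frame(
      id = tree$tip.label,
      marker = marker,
      residues = vapply(seq_len(n),
                        function(i) paste(bases[store[[i]]], collapse = ""),
                        character(1)),
      sample_id = NA_character_, forest_id = NA_character_,
      habitat = NA_character_, stringsAsFactors = FALSE
    )
  })
}

# smallest clade with >= min_size tips (first in node order on ties);
# falls back to the root when no proper clade is large enough
choose_focal_clade <- function(tree, min_size) {
  n <- ape::Ntip(tree)
  sizes <- vapply((n + 1L):(n + tree$Nnode), function(nd)
    length(tip_indices_below(tree, nd)), integer(1))
  cand <- which(sizes >= min_size)
  node <- if (length(cand)) {
    cand[which.min(sizes[cand])] + n
  } else n + 1L
  tree$tip.label[tip_indices_below(tree, node)]
}

tip_indices_below <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  out <- integer(0)
  todo <- node
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n])
    todo <- c(todo, ch[ch > n])
  }
  sort(out)
}

#' Assemble presence/absence communities on a species pool
#'
#' Emulates one habitat's soil-cube sampling across its forests. Richness
#' per cube is drawn from the configured 3-6 tips distribution; species
#' are then drawn without replacement according to the assembly rule:
#'
#' * `filtered` — weights `exp(filter_strength * I(species in focal clade))`
#'   for a focal clade chosen as the smallest clade with at least twice the
#'   maximum cube richness, giving phylogenetically clustered cubes;
#' * `random` — the same machinery with zero weights (uniform draws);
#' * `overdispersed` — sequential draws up-weighting species far from the
#'   ones already in the cube
#'   (`exp(filter_strength * d_min / mean pairwise distance)`).
#'
#' @param pool_tree ultrametric pool tree whose tips are the species pool.
#' @param config a [synthetic_config()].
#' @param habitat_label `"serpentine"` or `"non_serpentine"`.
#' @param seed optional seed.
#' @param model override of the configured assembly model for this habitat.
#' @return a [community_matrix()] (only observed species retained) with a
#'   `truth` attribute recording the model and focal clade.
#' @export
assemble_communities <- function(pool_tree, config, habitat_label,
                                 seed = NULL, model = NULL) {
  species <- pool_tree$tip.label
  model <- model %||% unname(config$assembly_model[habitat_label])
  if (is.na(model)) model <- unname(config$assembly_model[1])
  lo <- config$tips_per_sample_range[1]
  hi <- config$tips_per_sample_range[2]
  pbin <- if (hi > lo) (config$tips_per_sample_mean - lo) / (hi - lo) else 0
  strength <- config$filter_strength

  focal <- NULL
  logw <- rep(0, length(species))
  if (model %in% c("filtered", "random")) {
    if (model == "filtered") {
      focal <- choose_focal_clade(pool_tree, 2L * hi)
      if (length(focal) < hi)
        stop_ecm("focal filter clade (", length(focal), " tips) is smaller ",
                 "than the maximum sample richness (", hi, "); lower ",
                 "tips_per_sample_range or enlarge the pool")
      if (is.infinite(strength)) {
        logw <- ifelse(species %in% focal, 0, -Inf)
      } else {
        logw <- strength * (species %in% focal)
      }
    }
  } else {
    dm <- patristic_distances(pool_tree)[species, species]
    dbar <- mean(dm[upper.tri(dm)])
  }

  draw_sample <- function() {
    r <- lo + rbinom(1L, hi - lo, pbin)
    if (model %in% c("filtered", "random")) {
      w <- exp(logw - max(logw))
      sample(species, r, prob = w)
    } else {
      chosen <- sample(species, 1L)
      while (length(chosen) < r) {
        rest <- setdiff(species, chosen)
        dmin <- apply(dm[rest, chosen, drop = FALSE], 1, min)
        w <- exp(pmin(strength * dmin / dbar, 700))
        chosen <- c(chosen, sample(rest, 1L, prob = w))
      }
      chosen
    }
  }

  nf <- config$n_forests_per_habitat
  ns <- config$n_samples_per_forest
  with_seed(seed, {
    rows <- list(); forest <- character(0); snames <- character(0)
    for (f in seq_len(nf)) {
      fid <- sprintf("%s_f%d", habitat_label, f)
      for (s in seq_len(ns)) {
        sp <- draw_sample()
        rows[[length(rows) + 1L]] <- as.integer(species %in% sp)
        forest <- c(forest, fid)
        snames <- c(snames, sprintf("%s_c%02d", fid, s))
      }
    }
    x <- do.call(rbind, rows)
    dimnames(x) <- list(snames, species)
    x <- x[, colSums(x) > 0, drop = FALSE]
    cm <- community_matrix(x, forest = forest,
                           habitat = rep(habitat_label, length(snames)))
    attr(cm, "truth") <- list(model = model, focal_clade = focal,
                              filter_strength = strength)
    cm
  })
}

#' Bundled serpentine / non-serpentine soil chemistry profile
#'
#' Printed mean (sd) summaries of topsoil chemistry for a serpentine and a
#' neighbouring non-serpentine oak forest (4 composite samples per group):
#' low Ca/Mg ratio, high Mg/Ni/Cr and high CEC on serpentine. Used as the
#' default parameterisation of [generate_soil_table()] and as summary
#' input for [compare_soils()].
#'
#' @return data.frame with columns `parameter`, `units`, `group`, `mean`,
#'   `sd`, `n`.
#' @export
soil_reference <- function() {
  p <- function(parameter, units, m1, s1, m2, s2)
    data.frame(parameter = parameter, units = units,
               group = c("serpentine", "non_serpentine"),
               mean = c(m1, m2), sd = c(s1, s2), n = 4L,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    p("Al", "ppm", 12.3, 5.4, 28.8, 0.7),
    p("B", "ppm", 1.1, 0.1, 0.3, 0.0),
    p("C", "%", 10.7, 1.6, 1.6, 0.2),
    p("Ca_BS", "%BS", 15.9, 2.0, 42.9, 3.3),
    p("Ca", "ppm", 1014.3, 89.5, 1349.8, 83.4),
    p("Ca_Mg", "ratio", 0.4, 0.0, 2.0, 0.0),
    p("CEC", "meq/100g", 32.3, 2.1, 16.6, 0.9),
    p("Cd", "ppm", 0.38, 0.1, 0, 0.0),
    p("Cr", "ppm", 0.5, 0.1, 0.2, 0.1),
    p("Cu", "ppm", 0.1, 0.1, 0.4, 0.1),
    p("Fe", "ppm", 23.3, 4.8, 6.9, 0.8),
    p("K_BS", "%BS", 0.7, 0.2, 2.6, 0.4),
    p("K", "ppm", 81.3, 21.7, 154.5, 26.2),
    p("Mg_BS", "%BS", 60.4, 5.7, 22.4, 8.6),
    p("Mg", "ppm", 2378.8, 327.6, 430.5, 171.8),
    p("Mn", "ppm", 180.6, 44.0, 117.8, 7.1),
    p("N", "%", 0.5, 0.1, 0.2, 0.0),
    p("Ni", "ppm", 29.8, 8.1, 1.0, 0.4),
    p("NO3_N", "ppm", 7.8, 3.3, 1.3, 0.0),
    p("P", "ppm", 27.3, 3.9, 7.5, 2.1),
    p("Pb", "ppm", 31.7, 0.3, 30.5, 0.0),
    p("pH", "pH", 6.1, 0.1, 5.3, 0.1),
    p("Zn", "ppm", 1.9, 0.9, 1.1, 0.5)
  ))
}

#' Draw raw soil replicates from per-group summaries
#'
#' Normal draws per parameter per group; concentrations cannot be
#' negative, so negative draws are clipped to 0 (with a warning counting
#' the clips).
#'
#' @param group_means_sds data.frame with columns `parameter`, `group`,
#'   `mean`, `sd` (defaults to [soil_reference()]).
#' @param n_reps replicates per parameter per group (default 4 composite
#'   soil samples per forest).
#' @param seed optional seed.
#' @return data.frame with columns `parameter`, `group`, `replicate`,
#'   `value`.
#' @export
generate_soil_table <- function(group_means_sds = soil_reference(),
                                n_reps = 4L, seed = NULL) {
  g <- group_means_sds
  stopifnot(all(c("parameter", "group", "mean", "sd") %in% names(g)))
  if (any(g$sd < 0)) stop_ecm("negative sd in soil summaries")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      data.frame(parameter = g$parameter[i], group = g$group[i],
                 replicate = seq_len(n_reps),
                 value = rnorm(n_reps, g$mean[i], g$sd[i]),
                 stringsAsFactors = FALSE)))
    nneg <- sum(out$value < 0)
    if (nneg) {
      warning(nneg, " negative soil draws clipped to 0", call. = FALSE)
      out$value[out$value < 0] <- 0
    }
    out
  })
}

# one genus per lineage crossing `genus_age` (time before present);
# returns named vector tip -> genus label
assign_genera <- function(tree, genus_age = 0.5) {
  ages <- node_ages(tree)
  cross <- which(ages[tree$edge[, 1]] > genus_age &
                   ages[tree$edge[, 2]] <= genus_age)
  genus_map <- setNames(rep(NA_character_, ape::Ntip(tree)), tree$tip.label)
  for (k in seq_along(cross)) {
    tips <- tip_indices_below(tree, tree$edge[cross[k], 2])
    genus_map[tips] <- sprintf("G%02d", k)
  }
  stopifnot(!anyNA(genus_map))
  genus_map
}

# first tip label under the sibling clade of each backbone tip
backbone_sisters <- function(backbone) {
  out <- setNames(character(ape::Ntip(backbone)), backbone$tip.label)
  for (i in seq_len(ape::Ntip(backbone))) {
    p <- backbone$edge[backbone$edge[, 2] == i, 1]
    sibs <- setdiff(tip_indices_below(backbone, p), i)
    if (!length(sibs)) {  # parent is root of a 2-tip tree etc.
      sibs <- setdiff(seq_len(ape::Ntip(backbone)), i)
    }
    out[i] <- backbone$tip.label[sibs[1]]
  }
  out
}

#' Generate a complete synthetic two-habitat study
#'
#' Draws, from the single configured seed: the regional pool tree (Yule,
#' depth normalised to 1); a genus partition of the pool (lineages
#' crossing age 0.5); per-species ITS and LSU sequences (HKY85, ITS
#' `its_rate_ratio` times faster); per-habitat community matrices across
#' forests under the configured assembly rules; per-root-tip ITS records
#' (one per soil-cube presence); unanimous 20-hit taxonomy tables; marker
#' trees for the supertree stage (substitution-scale genus backbone from
#' LSU, per-genus ITS trees with a sister-genus outgroup, prefixed
#' `OUT_`); and a raw soil-chemistry table.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_study`; see the methods vignette for
#'   the component-by-component description.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species_pool, config$birth_rate,
                             normalize = TRUE)
  genus_map <- assign_genera(tree)
  its <- evolve_sequences(tree, "ITS", config)
  lsu <- evolve_sequences(tree, "LSU", config)

  habs <- c("serpentine", "non_serpentine")
  matrices <- lapply(setNames(habs, habs), function(h)
    assemble_communities(tree, config, h))

  # root-tip ITS records: one sequenced tip per (cube, species) presence
  its_by_sp <- setNames(its$residues, its$id)
  tip_records <- do.call(rbind, lapply(habs, function(h) {
    cm <- matrices[[h]]
    idx <- which(cm$x == 1L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(
      id = paste(rownames(cm$x)[idx[, 1]], colnames(cm$x)[idx[, 2]],
                 sep = "."),
      marker = "ITS",
      residues = unname(its_by_sp[colnames(cm$x)[idx[, 2]]]),
      sample_id = rownames(cm$x)[idx[, 1]],
      forest_id = cm$samples$forest[idx[, 1]],
      habitat = h, stringsAsFactors = FALSE
    )
  }))
  tip_records <- tip_records[order(tip_records$id), , drop = FALSE]
  rownames(tip_records) <- NULL

  # genus backbone (LSU, substitution scale) and per-genus ITS trees
  genera <- unique(genus_map[tree$tip.label])
  reps <- vapply(genera, function(g)
    tree$tip.label[genus_map[tree$tip.label] == g][1], character(1))
  backbone <- ape::keep.tip(tree, unname(reps))
  backbone$tip.label <- names(reps)[match(backbone$tip.label, reps)]
  backbone_subs <- backbone
  backbone_subs$edge.length <- backbone$edge.length * config$lsu_rate
  backbone_subs <- set_tree_scale(backbone_subs, "substitutions")

  sisters <- backbone_sisters(backbone)
  its_rate <- config$lsu_rate * config$its_rate_ratio
  multi <- genera[vapply(genera, function(g)
    sum(genus_map == g) > 1L, logical(1))]
  its_trees <- lapply(setNames(multi, multi), function(g) {
    tips <- names(genus_map)[genus_map == g]
    og <- unname(reps[sisters[g]])
    tr <- ape::keep.tip(tree, c(tips, og))
    tr$tip.label[tr$tip.label == og] <- paste0("OUT_", og)
    tr$edge.length <- tr$edge.length * its_rate
    set_tree_scale(tr, "substitutions")
  })
  outgroup_map <- setNames(unname(sisters[multi]), multi)

  hits <- lapply(setNames(tree$tip.label, tree$tip.label), function(sp)
    rep(unname(genus_map[sp]), 20L))

  soil <- generate_soil_table(soil_reference(), n_reps = 4L)

  structure(list(
    config = config,
    true_tree = tree,
    genus_map = genus_map,
    genus_reps = reps,
    backbone_subs = backbone_subs,
    its_genus_trees = its_trees,
    outgroup_map = outgroup_map,
    its_seqs = its, lsu_seqs = lsu,
    tip_records = tip_records,
    matrices = matrices,
    taxonomy_hits = hits,
    soil_table = soil,
    truth = list(
      assembly = lapply(matrices, attr, "truth"),
      its_rate_ratio = config$its_rate_ratio
    )
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", ape::Ntip(x$true_tree), "species pool,",
      nrow(x$matrices$serpentine$x) + nrow(x$matrices$non_serpentine$x),
      "soil cubes,", nrow(x$tip_records), "root-tip ITS records\n")
  invisible(x)
}
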