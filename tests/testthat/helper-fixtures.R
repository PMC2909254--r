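# shared fixtures and independent oracles, all built in code

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
star4 <- function() ape::read.tree(text = "(A:1,B:1,C:1,D:1);")

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

# independent patristic oracle: Floyd-Warshall on the tree graph
fw_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  d <- matrix(Inf, nn, nn)
  diag(d) <- 0
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    d[a, b] <- d[b, a] <- tree$edge.length[i]
  }
  for (k in seq_len(nn)) {
    for (i in seq_len(nn)) {
      dk <- d[i, k]
      if (is.finite(dk)) {
        cand <- dk + d[k, ]
        upd <- cand < d[i, ]
        d[i, upd] <- cand[upd]
      }
    }
  }
  out <- d[seq_len(n), seq_len(n)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# brute-force MPD / MNTD by explicit loops over pairs
brute_mpd_mntd <- function(species, dm) {
  k <- length(species)
  tot <- 0; np <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tot <- tot + dm[species[i], species[j]]
      np <- np + 1
    }
  }
  nt <- vapply(seq_len(k), function(i)
    min(dm[species[i], species[-i]]), numeric(1))
  c(mpd = tot / np, mntd = mean(nt))
}

# closed-form sample-based rarefaction (Mao tau) for the mean curve
mao_tau <- function(x, k) {
  n <- nrow(x)
  f <- colSums(x > 0)
  sum(1 - choose(n - f, k) / choose(n, k))
}

# random binary community matrix with no empty species or samples
random_cm <- function(n_samples, n_species, p = 0.3, seed = 1,
                      habitat = NULL) {
  set.seed(seed)
  repeat {
    x <- matrix(rbinom(n_samples * n_species, 1, p), n_samples)
    if (all(colSums(x) > 0) && all(rowSums(x) > 0)) break
  }
  dimnames(x) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("sp%02d", seq_len(n_species)))
  community_matrix(x, habitat = habitat)
}

# random nucleotide string
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate a sequence at k random positions (guaranteed substitutions)
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# records data.frame from bare sequences
seq_records <- function(residues, sample_id = NA_character_) {
  data.frame(id = sprintf("q%03d", seq_along(residues)), marker = "ITS",
             residues = residues,
             sample_id = rep_len(sample_id, length(residues)),
             forest_id = NA_character_, habitat = NA_character_,
             stringsAsFactors = FALSE)
}

# partition of record ids from an OTU list
otu_partition <- function(otus) {
  lapply(otus, function(o) sort(o$member_ids))
}

# does partition q refine partition p (every q-block inside one p-block)?
refines <- function(q, p) {
  all(vapply(q, function(blk) {
    any(vapply(p, function(big) all(blk %in% big), logical(1)))
  }, logical(1)))
}

# mean pairwise raw p-distance of a set of equal-length sequences
mean_pdist <- function(seqs) {
  n <- length(seqs)
  sp <- strsplit(seqs, "")
  v <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- c(v, mean(sp[[i]] != sp[[j]]))
    }
  }
  mean(v)
}

# combined two-habitat community matrix from a synthetic study
combined_matrix <- function(study) {
  a <- study$matrices$serpentine
  b <- study$matrices$non_serpentine
  sp <- union(colnames(a$x), colnames(b$x))
  fill <- function(m) {
    y <- matrix(0L, nrow(m$x), length(sp),
                dimnames = list(rownames(m$x), sp))
    y[, colnames(m$x)] <- m$x
    y
  }
  community_matrix(rbind(fill(a), fill(b)),
                   forest = c(a$samples$forest, b$samples$forest),
                   habitat = c(a$samples$habitat, b$samples$habitat))
}

# smooth ITS genus trees, prune outgroups, assemble supertree for a study
build_supertree <- function(study, beta = 0.9) {
  backbone_time <- nprs_smooth(study$backbone_subs)$tree
  plans <- suppressWarnings(
    graft_plan(study$backbone_subs, backbone_time,
               study$its_genus_trees, study$outgroup_map, beta))
  species_time <- lapply(study$its_genus_trees, function(tr) {
    og <- tr$tip.label[startsWith(tr$tip.label, "OUT_")]
    ape::drop.tip(nprs_smooth(tr)$tree, og)
  })
  singles <- setdiff(backbone_time$tip.label, names(study$its_genus_trees))
  sp <- names(study$genus_map)
  single_map <- lapply(setNames(singles, singles),
                       function(g) sp[study$genus_map == g][1])
  list(backbone_time = backbone_time, plans = plans,
       supertree = graft(backbone_time, c(species_time, single_map), plans))
}
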