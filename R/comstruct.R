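#' Null-model specification for community phylogenetic structure
#'
#' @param model `"independent_swap"` (checkerboard swaps preserving both
#'   matrix margins — the classic "randomization method 3"),
#'   `"phylogeny_shuffle"` (permute tip identities on the phylogeny), or
#'   `"pool_draw"` (equal-richness random draws from the tree's tips).
#' @param n_runs number of null replicates (default 999).
#' @param swap_burnin trial swaps before the first sample (default 10x the
#'   number of matrix cells).
#' @param swaps_between trial swaps between successive samples (default
#'   the number of matrix cells).
#' @param seed optional seed.
#' @param exhaustive for `pool_draw` only: enumerate all equal-richness
#'   subsets instead of sampling (population sd used; feasible small
#'   cases only).
#' @return list of class `null_model_spec`.
#' @export
null_model_spec <- function(model = c("independent_swap",
                                      "phylogeny_shuffle", "pool_draw"),
                            n_runs = 999L, swap_burnin = NULL,
                            swaps_between = NULL, seed = NULL,
                            exhaustive = FALSE) {
  model <- match.arg(model)
  if (n_runs < 1) stop_ecm("n_runs must be >= 1")
  structure(list(model = model, n_runs = as.integer(n_runs),
                 swap_burnin = swap_burnin, swaps_between = swaps_between,
                 seed = seed, exhaustive = exhaustive),
            class = "null_model_spec")
}

#' Independent-swap randomization of a binary matrix
#'
#' Repeatedly samples random 2x2 submatrices and flips checkerboards,
#' conserving row and column sums exactly (asserted on every draw). A
#' matrix admitting no checkerboard is returned unchanged with a message.
#'
#' @param m a [community_matrix()] or binary matrix.
#' @param n_trial_swaps number of trial swaps.
#' @param seed optional seed.
#' @return object of the same type as `m`, with attribute `n_accepted`.
#' @export
independent_swap <- function(m, n_trial_swaps, seed = NULL) {
  x <- if (inherits(m, "community_matrix")) m$x else m
  res <- with_seed(seed, swap_chain_cpp(x, n_trial_swaps))
  y <- res$matrix
  dimnames(y) <- dimnames(x)
  stopifnot(identical(rowSums(y), rowSums(x)),
            identical(colSums(y), colSums(x)))
  if (res$accepted == 0 && n_trial_swaps > 0)
    message("no checkerboard found; matrix returned unchanged")
  out <- if (inherits(m, "community_matrix")) {
    m$x <- y
    m
  } else y
  attr(out, "n_accepted") <- res$accepted
  out
}

#' Mean pairwise and mean nearest-taxon distance of a species set
#'
#' MPD is the mean patristic distance over unordered pairs; MNTD the mean
#' over members of the distance to the nearest other member
#' (presence/absence weighting).
#'
#' @param species character vector of at least 2 species.
#' @param dm patristic distance matrix containing them.
#' @return named numeric vector `c(mpd =, mntd =)`.
#' @export
mean_phylo_distances <- function(species, dm) {
  if (length(species) < 2)
    stop_ecm("MPD/MNTD undefined for fewer than 2 species")
  missing <- setdiff(species, rownames(dm))
  if (length(missing))
    stop_ecm("species missing from distance matrix: ",
             paste(missing, collapse = ", "))
  sub <- dm[species, species]
  c(mpd = mean(sub[upper.tri(sub)]),
    mntd = mean(apply(sub + diag(Inf, length(species)), 1, min)))
}

community_species_sets <- function(m, by = c("habitat", "sample")) {
  by <- match.arg(by)
  if (by == "habitat") {
    habs <- unique(m$samples$habitat)
    habs <- habs[!is.na(habs)]
    if (!length(habs)) stop_ecm("matrix has no habitat labels")
    lapply(setNames(habs, habs), function(h) {
      rows <- which(m$samples$habitat == h)
      colnames(m$x)[colSums(m$x[rows, , drop = FALSE]) > 0]
    })
  } else {
    sets <- apply(m$x, 1, function(r) colnames(m$x)[r > 0],
                  simplify = FALSE)
    setNames(sets, rownames(m$x))
  }
}

#' Community phylogenetic structure (NRI / NTI) under a null model
#'
#' Computes observed MPD and MNTD for each community (by default the
#' pooled species list of each habitat; per-sample with `by = "sample"`),
#' a null distribution of each under the requested randomization, and the
#' standardized effect sizes
#' `NRI = -(MPD_obs - mean_null) / sd_null` and
#' `NTI = -(MNTD_obs - mean_null) / sd_null`, sign-flipped so that
#' phylogenetic clustering gives positive values. One-tailed p-values
#' toward clustering use `(1 + #\{null <= obs\}) / (n_runs + 1)` (ties
#' counted as <=); a two-tailed variant is reported alongside.
#'
#' For `independent_swap` the whole matrix is randomized by a single
#' burnt-in, thinned chain and each community's species pool is recomputed
#' from every randomized matrix. `phylogeny_shuffle` permutes tip
#' identities (a community equal to the entire pool is therefore invariant
#' and gets index 0). `pool_draw` draws equal-richness species sets from
#' the tree's tips, with optional exhaustive enumeration.
#'
#' Null sd is the sample standard deviation of the replicates (population
#' sd under exhaustive enumeration). A degenerate null (sd 0) with
#' observed equal to the null mean yields index 0 and p 1.
#'
#' @param m a [community_matrix()]; all species must be tips of `tree`.
#' @param tree phylogeny (typically the grafted supertree).
#' @param spec a [null_model_spec()].
#' @param by `"habitat"` (pooled, default) or `"sample"`.
#' @return data.frame of class `comstruct_result`, one row per community.
#' @export
comstruct <- function(m, tree, spec = null_model_spec(), by = "habitat") {
  stopifnot(inherits(m, "community_matrix"),
            inherits(spec, "null_model_spec"))
  missing <- setdiff(colnames(m$x), tree$tip.label)
  if (length(missing))
    stop_ecm("species missing from tree: ", paste(missing, collapse = ", "))
  dm <- patristic_distances(tree)
  comms <- community_species_sets(m, by)
  comms <- comms[vapply(comms, length, integer(1)) >= 2]
  if (!length(comms)) stop_ecm("no community with >= 2 species")
  obs <- vapply(comms, mean_phylo_distances, numeric(2), dm = dm)

  ncells <- length(m$x)
  burnin <- spec$swap_burnin %||% (10 * ncells)
  thin <- spec$swaps_between %||% ncells

  null_arr <- with_seed(spec$seed, {
    switch(spec$model,
      independent_swap = {
        x <- swap_chain_cpp(m$x, burnin)$matrix
        vapply(seq_len(spec$n_runs), function(i) {
          x <<- swap_chain_cpp(x, thin)$matrix
          mm <- m; mm$x <- x; dimnames(mm$x) <- dimnames(m$x)
          sets <- community_species_sets(mm, by)[names(comms)]
          vapply(sets, function(s)
            if (length(s) >= 2) mean_phylo_distances(s, dm)
            else c(mpd = NA_real_, mntd = NA_real_), numeric(2))
        }, obs)
      },
      phylogeny_shuffle = {
        vapply(seq_len(spec$n_runs), function(i) {
          perm <- setNames(sample(rownames(dm)), rownames(dm))
          vapply(comms, function(s)
            mean_phylo_distances(unname(perm[s]), dm), numeric(2))
        }, obs)
      },
      pool_draw = {
        pool <- rownames(dm)
        vapply(seq_len(spec$n_runs), function(i) {
          vapply(comms, function(s)
            mean_phylo_distances(sample(pool, length(s)), dm), numeric(2))
        }, obs)
      })
  })
  # null_arr: 2 (mpd,mntd) x n_comms x n_runs
  if (length(comms) == 1L && length(dim(null_arr)) == 2L)
    dim(null_arr) <- c(2L, 1L, spec$n_runs)

  exhaustive <- isTRUE(spec$exhaustive) && spec$model == "pool_draw"
  if (exhaustive) {
    pool <- rownames(dm)
    null_list <- lapply(comms, function(s) {
      sets <- combn(pool, length(s), simplify = FALSE)
      vapply(sets, mean_phylo_distances, numeric(2), dm = dm)
    })
  }

  rows <- lapply(seq_along(comms), function(ci) {
    stats_for <- function(metric, mi) {
      o <- obs[mi, ci]
      nulls <- if (exhaustive) null_list[[ci]][mi, ] else null_arr[mi, ci, ]
      nulls <- nulls[!is.na(nulls)]
      mu <- mean(nulls)
      sdv <- if (exhaustive) {
        sqrt(mean((nulls - mu)^2))
      } else sd(nulls)
      idx <- if (sdv > 0) -(o - mu) / sdv else if (abs(o - mu) < 1e-12) 0
        else -sign(o - mu) * Inf
      n <- length(nulls)
      p_lo <- (1 + sum(nulls <= o)) / (n + 1)
      p_hi <- (1 + sum(nulls >= o)) / (n + 1)
      list(obs = o, mu = mu, sd = sdv, idx = idx,
           p1 = p_lo, p2 = min(1, 2 * min(p_lo, p_hi)))
    }
    a <- stats_for("mpd", 1L)
    b <- stats_for("mntd", 2L)
    data.frame(community = names(comms)[ci],
               n_taxa = length(comms[[ci]]),
               mpd_obs = a$obs, mpd_null_mean = a$mu, mpd_null_sd = a$sd,
               nri = a$idx, p_mpd_one = a$p1, p_mpd_two = a$p2,
               mntd_obs = b$obs, mntd_null_mean = b$mu,
               mntd_null_sd = b$sd,
               nti = b$idx, p_mntd_one = b$p1, p_mntd_two = b$p2,
               n_runs = spec$n_runs, model = spec$model,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comstruct_result", "data.frame")
  out
}
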