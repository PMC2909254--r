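#' Species rank/frequency curve
#'
#' Frequency is the number of samples containing the species; species are
#' ranked by descending frequency with ties broken by species id.
#'
#' @param m a [community_matrix()].
#' @return data.frame `rank`, `species`, `frequency`, with attribute
#'   `singleton_fraction` (fraction of species found in a single sample).
#' @export
rank_frequency <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (!ncol(m$x)) stop_ecm("empty matrix")
  f <- colSums(m$x)
  ord <- order(-f, colnames(m$x))
  out <- data.frame(rank = seq_along(f), species = colnames(m$x)[ord],
                    frequency = unname(f[ord]), stringsAsFactors = FALSE)
  attr(out, "singleton_fraction") <- mean(f == 1)
  out
}

#' Sample-based species accumulation curve with bootstrap interval
#'
#' The mean curve is the expected richness of `k` samples drawn without
#' replacement, averaged over `n_perm` random sample orderings (the
#' Monte-Carlo counterpart of analytic sample-based rarefaction). The 95%
#' interval at each depth is the 2.5/97.5 percentile over `n_boot`
#' bootstrap resamples of the sample set (with replacement, one random
#' ordering each), clamped to contain the mean curve (the raw percentile
#' bootstrap is biased low at deep k; see the methods vignette).
#'
#' @param m a [community_matrix()] with at least 2 samples.
#' @param n_boot bootstrap replicates (default 1000; must be >= 2).
#' @param seed optional seed.
#' @param n_perm permutations for the mean curve (default 100).
#' @return data.frame `k`, `mean`, `lower`, `upper`.
#' @export
accumulation_curve <- function(m, n_boot = 1000L, seed = NULL,
                               n_perm = 100L) {
  stopifnot(inherits(m, "community_matrix"))
  n <- nrow(m$x)
  if (n < 2) stop_ecm("need at least 2 samples")
  if (n_boot < 2) stop_ecm("n_boot must be >= 2")
  X <- m$x > 0
  richness_path <- function(ord) {
    # first row (within ord) at which each species appears
    first <- apply(X[ord, , drop = FALSE], 2, function(col) {
      w <- which(col)
      if (length(w)) w[1] else NA_integer_
    })
    cumsum(tabulate(first[!is.na(first)], nbins = n))
  }
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i)
      richness_path(sample.int(n)), numeric(n))
    mean_curve <- rowMeans(perm)
    boot <- vapply(seq_len(n_boot), function(i)
      richness_path(sample.int(n, replace = TRUE)), numeric(n))
    lo <- apply(boot, 1, quantile, probs = 0.025, names = FALSE)
    hi <- apply(boot, 1, quantile, probs = 0.975, names = FALSE)
    data.frame(k = seq_len(n), mean = mean_curve,
               lower = pmin(lo, mean_curve),
               upper = pmax(hi, mean_curve))
  })
}

#' Species overlap between two habitats
#'
#' @param a,b [community_matrix()] objects or character vectors of species.
#' @return list `n_A`, `n_B`, `n_shared`, `jaccard_pct`
#'   (shared/union x 100) and `sorensen_pct`.
#' @export
overlap <- function(a, b) {
  sp <- function(x) if (inherits(x, "community_matrix")) colnames(x$x) else x
  A <- unique(sp(a)); B <- unique(sp(b))
  shared <- length(intersect(A, B))
  uni <- length(union(A, B))
  list(n_A = length(A), n_B = length(B), n_shared = shared,
       jaccard_pct = if (uni) 100 * shared / uni else 100,
       sorensen_pct = if (length(A) + length(B))
         100 * 2 * shared / (length(A) + length(B)) else 100)
}

#' Bray-Curtis dissimilarity on presence/absence
#'
#' On binary data this is `1 - 2 * shared / (s_i + s_j)`, the complement
#' of the Sorensen index.
#'
#' @param m a [community_matrix()]; all-zero samples are an error (filter
#'   them upstream).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  X <- m$x
  s <- rowSums(X)
  if (any(s == 0))
    stop_ecm("all-zero sample row(s): ",
             paste(rownames(X)[s == 0], collapse = ", "))
  shared <- X %*% t(X)
  d <- 1 - 2 * shared / outer(s, s, "+")
  diag(d) <- 0
  d
}

#' Keep the largest connected component of a dissimilarity graph
#'
#' Samples are connected when their dissimilarity is below 1 (they share
#' at least one species). Low-frequency communities produce disconnected
#' graphs that NMDS cannot embed, so only the largest component is kept;
#' ties between equal-sized components are broken in favour of the one
#' containing the earliest sample.
#'
#' @param dissim symmetric dissimilarity matrix.
#' @return list `kept` (sample ids), `n_discarded`.
#' @export
connectivity_filter <- function(dissim) {
  n <- nrow(dissim)
  adj <- dissim < 1
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      todo <- i
      while (length(todo)) {
        v <- todo[1]; todo <- todo[-1]
        if (comp[v] == 0L) {
          comp[v] <- cid
          todo <- c(todo, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))[1]  # first-encountered wins ties
  kept <- which(comp == best)
  list(kept = rownames(dissim)[kept] %||% kept,
       n_discarded = n - length(kept))
}

kruskal_stress <- function(d, dhat, denom) sqrt(sum((d - dhat)^2) / denom)

#' Kruskal stress-1 of a given configuration
#'
#' Evaluates the stress (percent) of an arbitrary configuration against a
#' dissimilarity matrix, using the same isotonic fit as [nmds()]. Useful
#' for checking invariances (stress is unchanged by rotation, reflection
#' and uniform scaling of the configuration).
#'
#' @param dissim symmetric dissimilarity matrix.
#' @param points numeric matrix of coordinates (rows match `dissim`).
#' @return stress-1 x 100.
#' @export
nmds_stress <- function(dissim, points) {
  dissim <- as.matrix(dissim)
  lower <- which(lower.tri(dissim))
  ord <- order(dissim[lower])
  d <- as.matrix(dist(points))[lower]
  dhat <- numeric(length(d))
  dhat[ord] <- isoreg(d[ord])$yf
  100 * kruskal_stress(d, dhat, sum(d^2))
}

# one Kruskal NMDS run from a given configuration
nmds_run <- function(X, dissim_order, max_iter, tol) {
  n <- nrow(X)
  lower <- which(lower.tri(matrix(0, n, n)))
  config_d <- function(X) as.matrix(dist(X))[lower]
  stress_of <- function(d) {
    dhat <- numeric(length(d))
    dhat[dissim_order] <- isoreg(d[dissim_order])$yf
    list(stress = kruskal_stress(d, dhat, sum(d^2)), dhat = dhat)
  }
  d <- config_d(X)
  st <- stress_of(d)
  trace <- st$stress
  for (it in seq_len(max_iter)) {
    # Guttman transform toward the fitted disparities
    dm <- matrix(0, n, n)
    dm[lower] <- pmax(d, 1e-12)
    dm <- dm + t(dm)
    ratio <- matrix(0, n, n)
    ratio[lower] <- st$dhat
    ratio <- (ratio + t(ratio)) / pmax(dm, 1e-12)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- -colSums(B)
    Xg <- B %*% X / n
    # step halving guarantees monotone stress
    alpha <- 1
    improved <- FALSE
    for (h in 1:20) {
      Xtry <- X + alpha * (Xg - X)
      dtry <- config_d(Xtry)
      if (!any(dtry > 0)) { alpha <- alpha / 2; next }
      sttry <- stress_of(dtry)
      if (sttry$stress <= trace[length(trace)] + 1e-12) {
        X <- Xtry; d <- dtry; st <- sttry
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    trace <- c(trace, st$stress)
    if (!improved ||
        trace[length(trace) - 1] - trace[length(trace)] < tol) break
  }
  list(X = X, stress = st$stress, trace = trace,
       converged = length(trace) > 1 &&
         trace[length(trace) - 1] - trace[length(trace)] < tol)
}

#' Non-metric multidimensional scaling (Kruskal)
#'
#' Kruskal's stress-1 NMDS: the first start is the classical (metric)
#' scaling configuration, followed by `n_restarts - 1` random starts;
#' within each run, isotonic (pool-adjacent-violators) regression of
#' configuration distances on dissimilarity ranks alternates with Guttman
#' configuration updates (step-halved so stress never increases) until
#' the stress change falls below `tol` or `max_iter` iterations. The best
#' run is returned; stress is reported as stress-1 x 100 (percent).
#'
#' @param dissim symmetric dissimilarity matrix of a connected sample set.
#' @param k embedding dimension (default 2; must be < n - 1).
#' @param n_restarts number of starts (default 20).
#' @param seed optional seed.
#' @param max_iter,tol iteration cap and stress-change tolerance.
#' @return list of class `nmds_result`: `points` (centred coordinates),
#'   `stress` (percent), `stress_by_restart`, `converged` (best two
#'   restarts agree within 1% relative stress), `n_restarts`.
#' @export
nmds <- function(dissim, k = 2L, n_restarts = 20L, seed = NULL,
                 max_iter = 500L, tol = 1e-6) {
  dissim <- as.matrix(dissim)
  n <- nrow(dissim)
  if (!all(is.finite(dissim))) stop_ecm("non-finite dissimilarity")
  if (k >= n - 1) stop_ecm("k must be < n_samples - 1")
  lower <- which(lower.tri(dissim))
  dvec <- dissim[lower]
  dissim_order <- order(dvec)
  with_seed(seed, {
    runs <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      X0 <- if (r == 1L) {
        cs <- suppressWarnings(cmdscale(dissim, k = k))
        if (ncol(cs) < k)
          cs <- cbind(cs, matrix(rnorm(n * (k - ncol(cs)), 0, 1e-3), n))
        cs
      } else {
        matrix(rnorm(n * k), n, k)
      }
      runs[[r]] <- nmds_run(X0, dissim_order, max_iter, tol)
    }
    stresses <- vapply(runs, `[[`, numeric(1), "stress")
    best <- which.min(stresses)
    pts <- runs[[best]]$X
    pts <- sweep(pts, 2, colMeans(pts))
    rownames(pts) <- rownames(dissim)
    srt <- sort(stresses)
    structure(list(points = pts, stress = 100 * stresses[best],
                   stress_by_restart = 100 * stresses,
                   trace = runs[[best]]$trace,
                   converged = length(srt) > 1 &&
                     (srt[2] - srt[1]) <= 0.01 * max(srt[1], 1e-12),
                   n_restarts = n_restarts, k = k),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS:", nrow(x$points), "samples in", x$k, "dimensions; stress =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}
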