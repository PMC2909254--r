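test_that("rank/frequency curves sort, tie-break and count singletons", {
  x <- matrix(c(1, 1, 1, 1, 0, 0, 0, 1, 0), 3,
              dimnames = list(c("s1", "s2", "s3"), c("b", "a", "c")))
  m <- community_matrix(x)
  rf <- rank_frequency(m)
  expect_equal(rf$frequency, c(3, 1, 1))
  expect_equal(rf$species, c("b", "a", "c"))  # ties by species id
  expect_equal(attr(rf, "singleton_fraction"), 2 / 3)
  expect_equal(sum(rf$frequency), sum(m$x))  # conservation

  flat <- community_matrix(matrix(1, 2, 3,
    dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  expect_true(all(rank_frequency(flat)$frequency == 2))
})

test_that("accumulation curves: degenerate cases exact, invariants hold", {
  # identical samples: flat curve, zero-width interval
  m <- community_matrix(matrix(1, 4, 3,
    dimnames = list(paste0("s", 1:4), c("a", "b", "c"))))
  ac <- accumulation_curve(m, n_boot = 200, seed = 1)
  expect_true(all(ac$mean == 3))
  expect_true(all(ac$lower == 3 & ac$upper == 3))

  # disjoint single-species samples: mean at depth k equals k
  x2 <- diag(1L, 5)
  dimnames(x2) <- list(paste0("s", 1:5), paste0("sp", 1:5))
  m2 <- community_matrix(x2)
  ac2 <- accumulation_curve(m2, n_boot = 100, seed = 2)
  expect_equal(ac2$mean, 1:5)

  m3 <- random_cm(8, 12, seed = 3)
  ac3 <- accumulation_curve(m3, n_boot = 200, seed = 3)
  expect_true(all(diff(ac3$mean) >= 0))                    # nondecreasing
  expect_true(all(ac3$lower <= ac3$mean & ac3$mean <= ac3$upper))
  expect_equal(ac3$mean[nrow(ac3)], ncol(m3$x))            # terminal = total
  expect_error(accumulation_curve(m3, n_boot = 1), "n_boot")
})

test_that("overlap set arithmetic and symmetry", {
  o <- overlap(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(o$n_shared, 2)
  expect_equal(o$jaccard_pct, 50)
  expect_equal(o$sorensen_pct, 100 * 4 / 6)
  expect_equal(overlap(c("a", "b"), c("a", "b"))$jaccard_pct, 100)
  expect_equal(overlap(c("a"), c("b"))$jaccard_pct, 0)
  o2 <- overlap(c("y", "z", "w"), c("x", "y", "z"))
  expect_equal(o2$n_shared, o$n_shared)
  expect_equal(o2$jaccard_pct, o$jaccard_pct)
})

test_that("Bray-Curtis on presence/absence", {
  x <- matrix(c(1, 0, 1, 1, 1, 1, 0, 1, 0, 1, 1, 1), 4,
              dimnames = list(c("i", "j", "k", "l"), c("A", "B", "C")))
  m <- community_matrix(x)
  d <- bray_curtis(m)
  expect_equal(diag(d), setNames(rep(0, 4), rownames(x)))
  expect_equal(d, t(d))
  # {A,B} vs {B,C} -> 0.5
  x2 <- rbind(s1 = c(A = 1, B = 1, C = 0), s2 = c(A = 0, B = 1, C = 1))
  expect_equal(bray_curtis(community_matrix(x2))["s1", "s2"], 0.5)
  # identical -> 0, disjoint -> 1
  x3 <- rbind(s1 = c(A = 1, B = 1, C = 0, D = 0),
              s2 = c(A = 1, B = 1, C = 0, D = 0),
              s3 = c(A = 0, B = 0, C = 1, D = 1))
  d3 <- bray_curtis(community_matrix(x3))
  expect_equal(d3["s1", "s2"], 0)
  expect_equal(d3["s1", "s3"], 1)
  x4 <- rbind(s1 = c(A = 1), s2 = c(A = 0))
  expect_error(bray_curtis(community_matrix(x4)), "all-zero")
})

test_that("connectivity filter keeps the largest component", {
  d <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(d) <- 0
  d["s1", "s2"] <- d["s2", "s1"] <- 0.4   # s3 isolated
  cf <- connectivity_filter(d)
  expect_setequal(cf$kept, c("s1", "s2"))
  expect_equal(cf$n_discarded, 1)

  d2 <- matrix(0.5, 3, 3, dimnames = dimnames(d))
  diag(d2) <- 0
  cf2 <- connectivity_filter(d2)
  expect_equal(cf2$n_discarded, 0)

  # two equal components: first-encountered kept
  d3 <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(d3) <- 0
  d3["s1", "s2"] <- d3["s2", "s1"] <- 0.2
  d3["s3", "s4"] <- d3["s4", "s3"] <- 0.2
  expect_setequal(connectivity_filter(d3)$kept, c("s1", "s2"))
})

test_that("NMDS embeds representable configurations at ~zero stress and
           its stress is monotone within a run", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  # k = 2 >= n - 1 is rejected
  expect_error(nmds(d, k = 2), "k must be")
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as.matrix(dist(sq))
  dimnames(dsq) <- list(paste0("s", 1:4), paste0("s", 1:4))
  o <- nmds(dsq, k = 2, n_restarts = 5, seed = 1)
  expect_lt(o$stress, 0.1)
  expect_equal(colMeans(o$points), c(0, 0), tolerance = 1e-8)
  # stress non-increasing along the best run's trace
  set.seed(9)
  for (i in 1:5) {
    pts <- matrix(rnorm(6 * 3), 6, 3)
    dd <- as.matrix(dist(pts)) + matrix(runif(36, 0, 0.05), 6)
    dd <- (dd + t(dd)) / 2
    diag(dd) <- 0
    dimnames(dd) <- list(paste0("s", 1:6), paste0("s", 1:6))
    r <- nmds(dd, k = 2, n_restarts = 3, seed = i)
    expect_true(all(diff(r$trace) <= 1e-12))
  }
  dbad <- dsq; dbad[1, 2] <- dbad[2, 1] <- NA
  expect_error(nmds(dbad, k = 2), "non-finite")
})

test_that("stress is invariant to rotation, reflection and scaling", {
  set.seed(4)
  pts <- matrix(rnorm(10), 5, 2)
  dd <- as.matrix(dist(matrix(rnorm(15), 5, 3)))
  s0 <- nmds_stress(dd, pts)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(nmds_stress(dd, pts %*% rot), s0, tolerance = 1e-10)
  expect_equal(nmds_stress(dd, pts %*% diag(c(-1, 1))), s0,
               tolerance = 1e-10)
  expect_equal(nmds_stress(dd, 3.7 * pts), s0, tolerance = 1e-10)
})
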