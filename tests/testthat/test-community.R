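test_that("Hellinger transform takes square-rooted row proportions", {
  expect_equal(hellinger(matrix(c(1, 1), 1)), matrix(sqrt(c(0.5, 0.5)), 1))
  expect_equal(hellinger(matrix(c(4, 0, 0), 1)), matrix(c(1, 0, 0), 1))
  expect_equal(hellinger(matrix(c(1, 3), 1)), matrix(c(0.5, sqrt(0.75)), 1))
  m <- matrix(rpois(60, 5) + 1, 10, 6)
  expect_equal(rowSums(hellinger(m)^2), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("r1", "r2"), NULL))
  expect_error(hellinger(bad), "r2")
})

test_that("PCA matches an eigendecomposition oracle and flags degeneracy", {
  expect_error(comm_pca(matrix(1, 3, 2)), "zero total variance")

  line <- cbind(1:5, 2 * (1:5))
  p <- comm_pca(line)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)

  set.seed(10)
  m <- matrix(runif(12), 4, 3)
  p <- comm_pca(m)
  ev <- eigen(stats::cov(m))
  expect_equal(sort(p$variance_explained, decreasing = TRUE),
               ev$values / sum(ev$values), tolerance = 1e-10)
  # scores reproduce centered data projected on the eigenvectors (up to sign)
  ctr <- scale(m, scale = FALSE)
  for (j in 1:3) {
    ref <- drop(ctr %*% ev$vectors[, j])
    expect_lt(min(sum((p$scores[, j] - ref)^2),
                  sum((p$scores[, j] + ref)^2)), 1e-10)
  }
  # deterministic sign: the dominant loading of each axis is positive
  dom <- apply(p$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(dom > 0))
})

test_that("PERMANOVA partitions the distance matrix into unit R2", {
  set.seed(2)
  m <- matrix(runif(48), 12, 4)
  site <- rep(c("A", "B", "C"), each = 4)
  transect <- rep(rep(c("t1", "t2"), each = 2), 3)
  tp <- rep(c("T1", "T3"), 6)
  r <- permanova(dist(m), site, transect, tp, n_perm = 49, seed = 1)
  expect_lt(abs(sum(r$terms$R2) - 1), 1e-10)
  expect_equal(r$terms$term,
               c("site", "transect_within_site", "time_point", "residual"))
  expect_equal(sum(r$terms$df), 11)
})

test_that("PERMANOVA agrees with vegan::adonis2 on the SS partition", {
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(runif(40), 10, 4)
  site <- rep(c("A", "B"), each = 5)
  ours <- permanova(dist(m), site, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dist(m) ~ site, data = data.frame(site = site),
                        permutations = 99)
  expect_equal(ours$terms$ss[1], ref$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(ours$terms$R2[1], ref$R2[1], tolerance = 1e-10)
  expect_equal(ours$terms$pseudo_F[1], ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA permutation p is seed-reproducible and matches enumeration", {
  set.seed(4)
  m <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 3), 3))
  site <- rep(c("A", "B"), each = 3)
  r1 <- permanova(dist(m), site, n_perm = 199, seed = 9)
  r2 <- permanova(dist(m), site, n_perm = 199, seed = 9)
  expect_identical(r1$terms$p, r2$terms$p)

  ex <- permanova(dist(m), site, exact = TRUE)
  expect_equal(ex$n_perm, factorial(6))
  # enumeration over all 720 row permutations: 6!/(3!3!) label splits x
  # within-group shuffles; separation means only the 2 site-respecting
  # splits reach the observed F
  expect_equal(ex$terms$p[1], 2 / 20)
  se <- sqrt(ex$terms$p[1] * (1 - ex$terms$p[1]) / 199)
  expect_lt(abs(r1$terms$p[1] - ex$terms$p[1]), 3 * se + 1 / 200)
})

test_that("structureless distances give p near 1 and tiny site R2 signal", {
  n <- 8
  D <- matrix(1, n, n) - diag(n)
  site <- rep(c("A", "B"), each = 4)
  r <- permanova(as.dist(D), site, n_perm = 99, seed = 2)
  expect_gt(r$terms$p[1], 0.9)
  expect_error(permanova(as.dist(D), c("A", rep("B", n - 1))), "at least two rows")
})

test_that("SIMPER decomposes Bray-Curtis dissimilarity exactly", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2")))
  s <- simper(m, c("A", "B"))
  expect_equal(s$mean_dissimilarity, 1)
  expect_equal(s$contributions$contribution_pct, c(50, 50))
  expect_equal(max(s$contributions$cumulative_pct), 100)

  same <- matrix(rep(c(0.2, 0.8), 4), 4, 2, byrow = TRUE)
  s0 <- simper(same, c("A", "A", "B", "B"))
  expect_equal(s0$mean_dissimilarity, 0)

  onediff <- matrix(c(0.5, 0.5, 0, 0.5, 0.3, 0.2), 2, 3, byrow = TRUE,
                    dimnames = list(NULL, c("g1", "g2", "g3")))
  s1 <- simper(onediff, c("A", "B"))
  expect_error(simper(onediff, c("A", "A")), "two groups")
})

test_that("SIMPER conservation matches vegan's mean dissimilarity", {
  skip_if_not_installed("vegan")
  set.seed(5)
  counts <- matrix(rpois(48, 6) + 1, 8, 6,
                   dimnames = list(NULL, paste0("g", 1:6)))
  m <- relative_abundance(counts)
  grp <- rep(c("A", "B"), each = 4)
  s <- simper(m, grp)
  bc <- as.matrix(vegan::vegdist(m, method = "bray"))
  between <- bc[1:4, 5:8]
  expect_equal(s$mean_dissimilarity, mean(between), tolerance = 1e-10)
  expect_equal(sum(s$contributions$average), s$mean_dissimilarity,
               tolerance = 1e-12)
})

test_that("Hill numbers match hand values and vegan indices", {
  h1 <- hill_numbers(c(5))
  expect_equal(c(h1$N0, h1$N1, h1$N2), c(1, 1, 1))
  h4 <- hill_numbers(rep(3, 4))
  expect_equal(c(h4$N0, h4$N1, h4$N2), c(4, 4, 4))
  h <- hill_numbers(c(2, 1, 1))
  expect_equal(h$N1, exp(-sum(c(.5, .25, .25) * log(c(.5, .25, .25)))))
  expect_equal(h$N2, 1 / 0.375)

  skip_if_not_installed("vegan")
  set.seed(6)
  x <- rpois(10, 4) + 1
  h <- hill_numbers(x)
  expect_equal(h$N1, exp(vegan::diversity(x, "shannon")), tolerance = 1e-12)
  expect_equal(h$N2, vegan::diversity(x, "invsimpson"), tolerance = 1e-12)

  expect_error(hill_numbers(c(0, 0)), "zero total")
  expect_error(hill_numbers(c(-1, 2)), "non-negative")
})

test_that("community matrix counts live colonies at baseline time points", {
  ds <- simulate_fate_tracking(small_config(seed = 19))
  cm <- community_matrix(ds$colony_table, time_points = c(1L, 3L))
  meta <- attr(cm, "meta")
  expect_equal(nrow(cm), nrow(meta))
  expect_true(all(meta$time_point %in% c("T1", "T3")))
  alive13 <- ds$colony_table[ds$colony_table$time_point %in% c(1, 3) &
                               ds$colony_table$mortality_state == "alive", ]
  expect_equal(sum(cm), nrow(alive13))
})
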