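test_that("distance matrices match closed forms and validate input", {
  disjoint <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.matrix(distance_matrix(disjoint, "bray"))[1, 2], 1.0)

  same <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(as.matrix(distance_matrix(same, "bray"))[1, 2], 0.0)

  pair <- rbind(c(0.2, 0.8), c(0.4, 0.6))
  expect_equal(as.matrix(distance_matrix(pair, "bray"))[1, 2], 0.2,
               tolerance = 1e-12)

  expect_error(distance_matrix(rbind(c(-1, 2), c(1, 1)), "bray"), "non-negative")

  chem <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(distance_matrix(chem, "euclidean"), "zero-variance")
  m <- as.matrix(distance_matrix(chem[, "a", drop = FALSE], "euclidean"))
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  expect_equal(m, t(m))
})

test_that("pseudo-F matches the naive sum-of-squares oracle on small data", {
  set.seed(41)
  cases <- list(
    list(n = 6, g = rep(c("a", "b"), each = 3)),
    list(n = 6, g = c("a", "a", "b", "b", "c", "c")),
    list(n = 8, g = rep(c("a", "b"), each = 4)),
    list(n = 8, g = rep(c("a", "b", "c", "d"), each = 2)),
    list(n = 7, g = c("a", "a", "a", "b", "b", "b", "b"))
  )
  for (cs in cases) {
    x <- matrix(abs(rnorm(cs$n * 5)), cs$n)
    ra <- x / rowSums(x)
    d <- distance_matrix(ra, "bray")
    fit <- permanova(d, data.frame(g = cs$g), n_perm = 19, seed = 1)
    expect_equal(fit$F[1], naive_permanova_F(d, cs$g), tolerance = 1e-10)
  }
})

test_that("exhaustive permutation p equals full-enumeration oracle", {
  # two well-separated pairs: only 3 distinct partitions, p = 2/6
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rownames(pts) <- sprintf("s%d", 1:4)
  d <- dist(pts)
  g <- data.frame(g = c("a", "a", "b", "b"))
  fit <- permanova(d, g, exhaustive = TRUE)
  expect_equal(fit$p[1], 2 / 6, tolerance = 1e-12)
  expect_equal(fit$p[1], enumerate_permanova_p(d, g$g), tolerance = 1e-12)

  # a less structured case still matches the oracle exactly
  set.seed(13)
  x <- matrix(abs(rnorm(6 * 4)), 6)
  d2 <- distance_matrix(x / rowSums(x), "bray")
  g2 <- c("a", "a", "b", "b", "b", "a")
  fit2 <- permanova(d2, data.frame(g = g2), exhaustive = TRUE)
  expect_equal(fit2$p[1], enumerate_permanova_p(d2, g2), tolerance = 1e-12)
})

test_that("sequential multi-factor partitioning agrees with vegan", {
  set.seed(7)
  x <- matrix(abs(rnorm(24 * 12)), 24)
  ra <- x / rowSums(x)
  f <- data.frame(a = rep(c("u", "v"), each = 12),
                  b = rep(c("p", "q", "r"), 8))
  d <- distance_matrix(ra, "bray")
  mine <- permanova(d, f, terms = c("a", "b"), n_perm = 99, seed = 5)
  ref <- vegan::adonis2(d ~ a + b, data = f, permutations = 99, by = "terms")
  expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(mine$F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$R2[1:2], ref$R2[1:2], tolerance = 1e-10)
})

test_that("duplicating samples preserves R2 and rescales F by its dfs", {
  set.seed(2)
  x <- matrix(abs(rnorm(8 * 5)), 8)
  ra <- x / rowSums(x)
  g <- rep(c("u", "v"), each = 4)
  f1 <- permanova(distance_matrix(ra, "bray"), data.frame(g = g),
                  n_perm = 9, seed = 1)
  ra2 <- ra[rep(1:8, each = 2), ]
  f2 <- permanova(distance_matrix(ra2, "bray"),
                  data.frame(g = rep(g, each = 2)), n_perm = 9, seed = 1)
  expect_equal(f2$R2[1], f1$R2[1], tolerance = 1e-10)
  expect_equal(f2$F[1], f1$F[1] * (16 - 2) / (8 - 2), tolerance = 1e-10)
})

test_that("permanova is reproducible, and degenerate designs error", {
  set.seed(9)
  x <- matrix(abs(rnorm(12 * 6)), 12)
  d <- distance_matrix(x / rowSums(x), "bray")
  f <- data.frame(g = rep(c("a", "b", "c"), each = 4))
  r1 <- permanova(d, f, n_perm = 99, seed = 42)
  r2 <- permanova(d, f, n_perm = 99, seed = 42)
  expect_identical(r1$p, r2$p)

  f2 <- data.frame(g = f$g, h = f$g)  # h adds nothing after g
  expect_error(permanova(d, f2, terms = c("g", "h")), "confounded")
  expect_error(permanova(d, data.frame(g = factor(1:12))), "residual degrees")
})

test_that("strata restrict permutations to within-block shuffles", {
  set.seed(30)
  x <- matrix(abs(rnorm(12 * 6)), 12)
  d <- distance_matrix(x / rowSums(x), "bray")
  f <- data.frame(g = rep(c("a", "b"), 6))
  blocks <- rep(c("t1", "t2", "t3"), each = 4)
  fit <- permanova(d, f, n_perm = 49, seed = 3, strata = blocks)
  expect_true(fit$p[1] > 0 && fit$p[1] <= 1)
})

test_that("pairwise permanova flags nothing on an equidistant community", {
  ra <- diag(6)  # mutually disjoint compositions: all distances 1
  rownames(ra) <- sprintf("s%d", 1:6)
  d <- distance_matrix(ra, "bray")
  g <- rep(c("a", "b", "c"), each = 2)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 1)
  expect_true(all(pw$p_raw == 1))
  expect_true(all(pw$p_adj == 1))

  pw_none <- pairwise_permanova(d, g, n_perm = 99, seed = 1, adjust = "none")
  expect_equal(pw_none$p_adj, pw_none$p_raw)

  expect_error(pairwise_permanova(d, c("a", rep("b", 5))), "fewer than two")
})

test_that("mantel statistic honours rank invariance and exact enumeration", {
  set.seed(11)
  pts <- matrix(rnorm(10 * 3), 10)
  d1 <- dist(pts)
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$r, 1.0)
  # monotone transform leaves the Spearman statistic at 1
  d_sq <- as.dist(as.matrix(d1)^2)
  expect_equal(mantel_test(d1, d_sq, n_perm = 9, seed = 1)$r, 1.0)

  # exhaustive n = 5 equals the 120-permutation brute-force oracle exactly
  m1 <- as.matrix(dist(matrix(rnorm(5 * 2), 5)))
  m2 <- as.matrix(dist(matrix(rnorm(5 * 2), 5)))
  mine <- mantel_test(m1, m2, exhaustive = TRUE)
  oracle <- enumerate_mantel(m1, m2)
  expect_equal(mine$r, oracle$r, tolerance = 1e-12)
  expect_equal(mine$p, oracle$p, tolerance = 1e-12)
  expect_equal(mine$n_perm, 120L)

  # agreement with the ecology toolkit's statistic
  ref <- vegan::mantel(d1, d_sq, method = "spearman", permutations = 9)
  expect_equal(mantel_test(d1, d_sq, n_perm = 9, seed = 2)$r, ref$statistic,
               tolerance = 1e-12, ignore_attr = TRUE)

  r1 <- mantel_test(m1, m2, n_perm = 199, seed = 8)
  r2 <- mantel_test(m1, m2, n_perm = 199, seed = 8)
  expect_identical(r1$p, r2$p)

  expect_error(mantel_test(matrix(0, 5, 5), m2), "constant lower triangle")
  expect_error(mantel_test(m1, m2[1:4, 1:4]), "differ in size")
})

test_that("RDA matches the regression-R2 oracle in the noiseless case", {
  n <- 12
  ph <- seq(4, 6, length.out = n)
  set.seed(14)
  Y <- cbind(otu1 = 0.1 + 0.04 * ph,
             otu2 = abs(rnorm(n, 0.2, 0.02)),
             otu3 = abs(rnorm(n, 0.3, 0.02)))
  Y <- Y / rowSums(Y)
  fit <- rda_analysis(Y, data.frame(pH = ph), n_perm = 999, seed = 1)

  # oracle: summed fitted SS over per-column linear regressions
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_fit <- sum(sapply(seq_len(ncol(Yc)), function(j) {
    sum(lm.fit(cbind(1, ph), Yc[, j])$fitted.values^2)
  }))
  expect_equal(fit$axis_props[1], ss_fit / sum(Yc^2), tolerance = 1e-9)
  expect_equal(fit$constrained_prop, ss_fit / sum(Yc^2), tolerance = 1e-9)
  expect_lte(fit$p, 0.01)

  # eigenvalue proportions agree with the ecology toolkit
  ref <- vegan::rda(Yc ~ ., data = data.frame(pH = scale(ph)))
  expect_equal(unname(fit$axis_props),
               unname(ref$CCA$eig / ref$tot.chi), tolerance = 1e-9)
})

test_that("RDA on an orthogonal environment explains nothing", {
  set.seed(15)
  n <- 10
  Y <- matrix(abs(rnorm(n * 4)), n)
  Y <- Y / rowSums(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  z <- rnorm(n)
  x_orth <- lm.fit(cbind(1, Yc), z)$residuals  # exactly orthogonal to Yc
  fit <- rda_analysis(Y, data.frame(x = x_orth), n_perm = 99, seed = 2)
  expect_lt(fit$constrained_prop, 1e-9)
  expect_gt(fit$p, 0.05)
})

test_that("RDA variance partition closes and guards collinearity", {
  set.seed(16)
  Y <- matrix(abs(rnorm(15 * 6)), 15)
  Y <- Y / rowSums(Y)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  fit <- rda_analysis(Y, X, n_perm = 49, seed = 3)
  expect_equal(sum(fit$axis_props) + sum(fit$unconstrained_props), 1,
               tolerance = 1e-9)
  expect_equal(fit$first_two_axes_prop, sum(fit$axis_props[1:2]),
               tolerance = 1e-12)

  X_coll <- data.frame(a = X$a, b = 2 * X$a + 1)
  expect_error(rda_analysis(Y, X_coll), "collinear")
  expect_error(rda_analysis(Y, data.frame(a = rep(1, 15))), "zero-variance")
})

test_that("per-OTU environment correlations flag strong monotone signals", {
  n <- 14
  ph <- seq(4, 6, length.out = n)
  set.seed(18)
  # columns are per-sample proportions of three OTUs; no renormalisation so
  # each column's association with pH is exactly as constructed
  Y <- cbind(tracks_ph = seq(0.1, 0.3, length.out = n),
             flat = rep(c(0.2, 0.21), n / 2),
             noise = runif(n, 0.1, 0.2))
  fit <- rda_analysis(Y, data.frame(pH = ph), n_perm = 199, seed = 4)
  tab <- fit$otu_env
  expect_true(tab$flagged[tab$otu_id == "tracks_ph"])
  expect_equal(tab$r[tab$otu_id == "tracks_ph"], 1, tolerance = 1e-9)
  expect_false(tab$flagged[tab$otu_id == "flat"])
  expect_lte(tab$p[tab$otu_id == "tracks_ph"], 0.01)
})

test_that("NMDS recovers a planted two-dimensional configuration", {
  set.seed(19)
  true_xy <- matrix(rnorm(10 * 2), 10)
  d <- dist(true_xy)
  fit <- nmds_ordination(d, k = 2, restarts = 10, seed = 5)
  expect_lt(fit$stress, 0.01)
  proc <- vegan::procrustes(true_xy, fit$points, symmetric = TRUE)
  expect_lt(proc$ss, 0.01)  # matches up to rotation/reflection/scale

  # best-of-restarts stress is monotone in the number of restarts
  one <- nmds_ordination(d, k = 2, restarts = 1, seed = 5)
  many <- nmds_ordination(d, k = 2, restarts = 20, seed = 5)
  expect_gte(one$stress, many$stress)

  expect_error(nmds_ordination(dist(matrix(rnorm(6), 3)), k = 2), "k \\+ 2")
})
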