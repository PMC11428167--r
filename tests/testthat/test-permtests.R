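euclid_dist <- function(coords, ids = sprintf("s%d", seq_len(nrow(coords)))) {
  rownames(coords) <- ids
  stats::dist(coords)
}

test_that("ANOSIM reaches R = 1 under complete separation", {
  # two tight, far-apart clusters: every between-distance beats every within
  set.seed(1)
  coords <- rbind(matrix(rnorm(8, 0, 0.01), 4),
                  matrix(rnorm(8, 100, 0.01), 4))
  res <- anosim(euclid_dist(coords), rep(c("a", "b"), each = 4),
                n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("ANOSIM R agrees with vegan and is rank-invariant", {
  ft <- random_table(25, 12, seed = 6)
  dm <- bray_curtis(ft)
  g <- rep(c("a", "b", "c"), each = 4)
  ours <- anosim(dm, g, n_perm = 49, seed = 1)
  ref <- vegan::anosim(dm, g, permutations = 49)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # invariance under a monotone transform of the dissimilarities
  sq <- stats::as.dist(as.matrix(dm)^2)
  expect_equal(anosim(sq, g, n_perm = 9, seed = 1)$statistic, ours$statistic)
  expect_error(anosim(dm, c(g[-1], "d"), n_perm = 9), "fewer than 2")
})

test_that("exhaustive two-group ANOSIM matches the brute-force oracle exactly", {
  set.seed(9)
  coords <- rbind(matrix(rnorm(6, 0, 1), 3), matrix(rnorm(6, 2, 1), 3))
  dm <- euclid_dist(coords)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(dm, g, exhaustive = TRUE)
  orc <- oracle_anosim(dm, g)
  expect_equal(res$statistic, orc$r, tolerance = 1e-14)
  expect_equal(res$p_value, orc$p, tolerance = 1e-14)
  expect_equal(res$n_permutations, choose(6, 3))
})

test_that("permutation tests reproduce exactly under a fixed seed", {
  ft <- random_table(20, 14, seed = 2)
  dm <- bray_curtis(ft)
  g <- rep(c("a", "b"), 7)
  a1 <- anosim(dm, g, n_perm = 199, seed = 42)
  a2 <- anosim(dm, g, n_perm = 199, seed = 42)
  expect_identical(a1$p_value, a2$p_value)
  b1 <- betadisper(dm, g, n_perm = 199, seed = 42)
  b2 <- betadisper(dm, g, n_perm = 199, seed = 42)
  expect_identical(b1$p_value, b2$p_value)
  p1 <- permanova(dm, data.frame(g = g), n_perm = 199, seed = 42)
  p2 <- permanova(dm, data.frame(g = g), n_perm = 199, seed = 42)
  expect_identical(p1$p_values, p2$p_values)
})

test_that("betadisper dispersions match vegan on a semimetric input", {
  ft <- random_table(30, 15, seed = 13)
  dm <- bray_curtis(ft)
  g <- rep(c("a", "b", "c"), each = 5)
  ours <- betadisper(dm, g, n_perm = 49, seed = 1)
  ref <- vegan::betadisper(dm, g, type = "centroid")
  expect_equal(unname(ours$dispersions), unname(ref$distances),
               tolerance = 1e-10)
  expect_equal(ours$statistic, unname(anova(ref)$`F value`[1]),
               tolerance = 1e-10)
})

test_that("betadisper on Euclidean input equals plain distances to group means", {
  set.seed(4)
  coords <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  ours <- betadisper(euclid_dist(coords), g, n_perm = 49, seed = 1)
  direct <- numeric(12)
  for (gr in c("a", "b")) {
    ix <- g == gr
    ctr <- colMeans(coords[ix, ])
    direct[ix] <- sqrt(rowSums(sweep(coords[ix, ], 2, ctr)^2))
  }
  expect_equal(unname(ours$dispersions), direct, tolerance = 1e-10)
})

test_that("betadisper flags an extreme dispersion contrast", {
  set.seed(5)
  tight <- matrix(rep(c(0, 0), each = 8), 8, 2) +
    matrix(rnorm(16, 0, 1e-4), 8, 2)
  loose <- matrix(rnorm(16, 0, 5), 8, 2)
  res <- betadisper(euclid_dist(rbind(tight, loose)),
                    rep(c("tight", "loose"), each = 8),
                    n_perm = 199, seed = 1)
  expect_gt(res$statistic, 20)
  expect_lt(res$p_value, 0.05)
})

test_that("single-factor PERMANOVA on Euclidean distances equals ANOVA R2", {
  set.seed(3)
  y <- matrix(rnorm(20 * 2), 20, 2)
  g <- rep(c("a", "b"), each = 10)
  y[g == "b", ] <- y[g == "b", ] + 1
  res <- permanova(euclid_dist(y), data.frame(g = g), n_perm = 99, seed = 1)
  sst <- sum(scale(y, scale = FALSE)^2)
  sse <- sum(unlist(lapply(c("a", "b"), function(gr)
    sum(scale(y[g == gr, ], scale = FALSE)^2))))
  expect_equal(unname(res$r_squared["g"]), 1 - sse / sst, tolerance = 1e-9)
})

test_that("sequential PERMANOVA matches adonis2 and partitions to one", {
  ft <- random_table(30, 18, seed = 21)
  dm <- bray_curtis(ft)
  dat <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                    h = rep(c("x", "y"), 9))
  ours <- permanova(dm, dat, c("g", "h"), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dm ~ g + h, data = dat, by = "terms",
                        permutations = 99)
  expect_equal(unname(ours$r_squared), ref$R2[1:3], tolerance = 1e-10)
  expect_equal(unname(ours$f), ref$F[1:2], tolerance = 1e-10)
  expect_equal(sum(ours$r_squared), 1, tolerance = 1e-9)
  expect_error(permanova(dm, cbind(dat, g2 = dat$g), c("g", "g2"),
                         n_perm = 9),
               "collinear")
})

test_that("identical groups separated from distinct groups give first-term R2 = 1", {
  # 3 groups of 4 identical points each
  coords <- rbind(matrix(rep(c(0, 0), 4), ncol = 2, byrow = TRUE),
                  matrix(rep(c(5, 5), 4), ncol = 2, byrow = TRUE),
                  matrix(rep(c(9, 0), 4), ncol = 2, byrow = TRUE))
  g <- rep(c("a", "b", "c"), each = 4)
  res <- permanova(euclid_dist(coords), data.frame(g = g), n_perm = 49,
                   seed = 1)
  expect_equal(unname(res$r_squared["g"]), 1, tolerance = 1e-9)
})

test_that("the homogeneity gate controls reporting", {
  ft <- random_table(20, 10, seed = 31)
  dm <- bray_curtis(ft)
  g <- rep(c("a", "b"), 5)
  bd <- betadisper(dm, g, n_perm = 99, seed = 1)
  an <- anosim(dm, g, n_perm = 99, seed = 1)

  fake_bd <- bd
  fake_bd$p_value <- 0.5
  ok <- gated_report(fake_bd, an, alpha = 0.01)
  expect_true(ok$homogeneity_ok)
  expect_equal(ok$report, "report")

  fake_bd$p_value <- 0.001
  bad <- gated_report(fake_bd, an, alpha = 0.01)
  expect_false(bad$homogeneity_ok)
  expect_match(bad$report, "heterogeneous")

  # the gate honors alpha at the boundary
  fake_bd$p_value <- 0.02
  expect_true(gated_report(fake_bd, an, alpha = 0.01)$homogeneity_ok)
  expect_false(gated_report(fake_bd, an, alpha = 0.05)$homogeneity_ok)

  other <- anosim(bray_curtis(random_table(20, 8, seed = 5)),
                  rep(c("a", "b"), 4), n_perm = 9, seed = 1)
  expect_error(gated_report(bd, other), "mismatched sample sets")
})
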