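test_that("rarefaction subsamples exactly and preserves expected proportions", {
  x <- rbind(a = c(10, 0), b = c(30, 20), c = c(2, 1))
  fm <- feature_matrix(x)
  r <- rarefy(fm, depth = 5, seed = 1)
  expect_equal(attr(r, "dropped"), "c")                 # below depth: dropped
  expect_equal(unname(r$intensities["a", ]), c(5, 0))   # forced outcome
  expect_true(all(rowSums(r$intensities) == 5))
  # a row already at depth is unchanged
  same <- rarefy(feature_matrix(rbind(a = c(3, 2))), depth = 5, seed = 1)
  expect_equal(unname(same$intensities[1, ]), c(3, 2))
  expect_error(rarefy(fm, depth = 0), "positive")
  # deterministic given seed
  expect_identical(rarefy(fm, 5, seed = 2)$intensities,
                   rarefy(fm, 5, seed = 2)$intensities)
  # expected rarefied count equals the hypergeometric mean depth * k / n
  row <- c(6, 4, 10)
  draws <- t(vapply(1:1000, function(s)
    rarefy(feature_matrix(rbind(r1 = row)), depth = 10, seed = s)$intensities[1, ],
    numeric(3)))
  exp_mean <- 10 * row / sum(row)
  se <- sqrt(10 * (row / sum(row)) * (1 - row / sum(row)) *
               (sum(row) - 10) / (sum(row) - 1) / 1000)
  expect_true(all(abs(colMeans(draws) - exp_mean) < 4 * se))
})

test_that("Bray-Curtis follows the formula and its boundary cases", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 4 / 12)        # hand computation
  expect_equal(d["a", "c"], 0)             # identical rows
  disj <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 2, 3))
  expect_equal(bray_curtis(disj)["a", "b"], 1)   # disjoint supports
  expect_error(bray_curtis(rbind(a = c(1, 2), b = c(0, 0))), "b")
  # random tables: symmetric, in [0,1], equal to the elementwise oracle,
  # and invariant to feature order
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(rpois(8 * 12, 20), 8, 12)
    d <- unclass(bray_curtis(m))
    oracle <- matrix(0, 8, 8)
    for (p in 1:8) for (q in 1:8)
      oracle[p, q] <- sum(abs(m[p, ] - m[q, ])) / sum(m[p, ] + m[q, ])
    expect_equal(d, oracle, ignore_attr = TRUE)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    perm <- sample(12)
    expect_equal(unclass(bray_curtis(m[, perm])), d, ignore_attr = TRUE)
  }
})

test_that("Bray-Curtis agrees with the community-ecology reference", {
  set.seed(9)
  m <- matrix(rpois(10 * 30, 15), 10, 30)
  expect_equal(unclass(bray_curtis(m))[lower.tri(diag(10))],
               as.numeric(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12)
})

test_that("PCoA recovers a planted Euclidean configuration", {
  set.seed(10)
  pts <- cbind(rnorm(9, sd = 3), rnorm(9))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  expect_length(ord$negative_eigenvalues, 0)
  # Procrustes alignment: recovered coordinates match up to rotation
  A <- scale(pts, scale = FALSE)
  B <- ord$coordinates[, 1:2]
  B <- scale(B, scale = FALSE)
  sv <- svd(crossprod(A, B))
  rot <- sv$v %*% t(sv$u)
  expect_lt(max(abs(B %*% rot - A)), 1e-8)
  # distances recomputed from full-rank coordinates reproduce the input
  dd <- as.matrix(dist(ord$coordinates))
  expect_equal(dd, d, tolerance = 1e-8, ignore_attr = TRUE)
  # identical points collapse to the origin
  d0 <- matrix(0, 4, 4)
  expect_equal(ncol(pcoa(d0)$coordinates), 0)
  # explained fractions are sorted and account for all positive variance
  bc <- bray_curtis(matrix(rpois(60, 10), 6, 10))
  o2 <- pcoa(bc)
  expect_true(all(diff(o2$explained) <= 1e-12))
  expect_equal(sum(o2$explained), 1)
})

test_that("PERMANOVA partitions distances and matches the reference and the exact null", {
  # degenerate: zero within-group distance, distinct groups -> R2 = 1
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 1), c(9, 1))
  d <- as.matrix(dist(pts))
  r <- permanova(d, c("g1", "g1", "g2", "g2", "g3", "g3"),
                 n_permutations = 19, seed = 1)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # F and R2 agree with the reference implementation on random data
  set.seed(11)
  m <- matrix(rpois(9 * 20, 12), 9, 20)
  g <- rep(c("a", "b", "c"), each = 3)
  bc <- bray_curtis(m)
  mine <- permanova(bc, g, n_permutations = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(bc) ~ grp, data = data.frame(grp = g),
                        permutations = 99)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  # R2 invariant to group relabeling
  relab <- c(a = "x", b = "y", c = "z")[g]
  expect_equal(permanova(bc, relab, n_permutations = 19, seed = 1)$r_squared,
               mine$r_squared)
  # exhaustive p on 2 groups of 3 equals a brute-force enumeration oracle
  set.seed(12)
  m6 <- matrix(runif(6 * 4, 1, 10), 6, 4)
  d6 <- bray_curtis(m6)
  g6 <- rep(c("a", "b"), each = 3)
  ex <- permanova(d6, g6, n_permutations = "exhaustive")
  expect_equal(ex$n_permutations, choose(6, 3))
  f_for <- function(idx_a) {
    gg <- ifelse(seq_len(6) %in% idx_a, "a", "b")
    permanova(d6, gg, n_permutations = 1, seed = 1)$pseudo_f
  }
  f_all <- apply(utils::combn(6, 3), 2, f_for)
  expect_equal(ex$p_value, mean(f_all >= ex$pseudo_f - 1e-12))
  # sampled p converges to the exhaustive p
  samp <- permanova(d6, g6, n_permutations = 9999, seed = 3)
  expect_lt(abs(samp$p_value - ex$p_value), 0.05)
  expect_gte(samp$p_value, 1 / 10000)
  expect_error(permanova(d6, rep("a", 6)), "2 groups")
})
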