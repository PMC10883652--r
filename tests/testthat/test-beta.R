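test_that("Hellinger distance matches closed forms under both conventions", {
  a <- c(0.5, 0.5)
  expect_equal(hellinger_distance(a, a), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(hellinger_distance(c(0.5, 0.5), c(1, 0)),
               sqrt((sqrt(0.5) - 1)^2 + 0.5))
  expect_equal(round(hellinger_distance(c(0.5, 0.5), c(1, 0)), 5), 0.76537)

  # the scaled convention divides by sqrt(2)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1), scaled = TRUE), 1)
  expect_error(hellinger_distance(c(0.7, 0.7), a), "sum to 1")
})

test_that("Hellinger distance is a metric on random compositions", {
  set.seed(12)
  for (i in 1:25) {
    m <- sample(3:30, 1)
    a <- random_composition(m)
    b <- random_composition(m)
    cc <- random_composition(m)
    dab <- hellinger_distance(a, b)
    expect_equal(dab, hellinger_distance(b, a))
    expect_lte(dab, hellinger_distance(a, cc) + hellinger_distance(cc, b) + 1e-9)
    expect_lte(dab, sqrt(2) + 1e-12)
  }
})

test_that("pairwise distances agree with the community-ecology reference", {
  skip_if_not_installed("vegan")
  set.seed(33)
  comp <- replicate(6, random_composition(15))
  colnames(comp) <- sprintf("s%d", 1:6)
  rownames(comp) <- sprintf("f%02d", 1:15)
  ours <- hellinger_dist(comp)
  ref <- dist(vegan::decostand(t(comp), "hellinger"))
  expect_equal(as.vector(ours), as.vector(ref), tolerance = 1e-12)

  # duplicated sample has zero off-diagonal distance
  comp2 <- cbind(comp, dup = comp[, 1])
  dm <- as.matrix(hellinger_dist(comp2))
  expect_equal(dm["s1", "dup"], 0)
})

test_that("PCoA reconstructs planted Euclidean configurations", {
  set.seed(4)
  pts <- cbind(runif(8, -3, 3), runif(8, -3, 3))
  rownames(pts) <- sprintf("p%d", 1:8)
  d <- dist(pts)
  res <- pcoa(d, n_axes = 2)
  expect_equal(as.vector(dist(res$coordinates)), as.vector(d),
               tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9)) # sorted descending

  # collinear points: one dominant axis
  line <- cbind(1:6, 2 * (1:6))
  resl <- suppressWarnings(pcoa(dist(line), n_axes = 2))
  expect_gt(resl$proportion[1], 0.999)

  # duplicated samples are coincident
  dup <- rbind(pts, p9 = pts[1, ])
  resd <- pcoa(dist(dup), n_axes = 2)
  expect_equal(resd$coordinates["p9", ], resd$coordinates["p1", ],
               tolerance = 1e-8)
})

test_that("PCoA of Hellinger distances has no meaningful negative eigenvalues", {
  set.seed(9)
  comp <- replicate(10, random_composition(25))
  colnames(comp) <- sprintf("s%d", 1:10)
  res <- pcoa(hellinger_dist(comp), n_axes = 3)
  expect_true(all(res$eigenvalues > -1e-9))
})

test_that("ANOSIM gives R = 1 for complete separation and valid p-values", {
  # two tight clusters far apart: every between-distance beats every within
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5),
               matrix(rnorm(10, 100, 0.01), 5))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 5)
  res <- anosim(d, g, n_permutations = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)

  expect_error(anosim(d, rep(c("a", "b", "c"), c(5, 4, 1)),
                      n_permutations = 199), "at least 2 samples")
})

test_that("ANOSIM statistic matches vegan and exact p matches enumeration", {
  skip_if_not_installed("vegan")
  set.seed(55)
  for (sizes in list(c(2, 2), c(3, 3))) {
    n <- sum(sizes)
    pts <- matrix(rnorm(n * 3), n)
    d <- dist(pts)
    g <- rep(c("a", "b"), sizes)

    ref <- vegan::anosim(d, factor(g), permutations = 0)
    ours <- anosim(d, g, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)

    # brute-force oracle: score every label assignment with vegan's statistic
    combos <- combn(n, sizes[1])
    r_all <- apply(combos, 2, function(idx) {
      gg <- rep("b", n)
      gg[idx] <- "a"
      unname(vegan::anosim(d, factor(gg), permutations = 0)$statistic)
    })
    p_exact <- mean(r_all >= unname(ref$statistic) - 1e-12)
    expect_equal(ours$p_value, p_exact)
    expect_gt(ours$p_value, 0)
  }
})

test_that("ANOSIM is invariant to the Hellinger convention and null-centered", {
  set.seed(77)
  comp <- replicate(12, random_composition(20))
  colnames(comp) <- sprintf("s%d", 1:12)
  g <- rep(c("a", "b"), each = 6)
  r1 <- anosim(hellinger_dist(comp), g, n_permutations = 199, seed = 5)
  r2 <- anosim(hellinger_dist(comp, scaled = TRUE), g,
               n_permutations = 199, seed = 5)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  # random labels: mean R near zero
  set.seed(88)
  rs <- replicate(200, {
    cc <- replicate(8, random_composition(15))
    colnames(cc) <- sprintf("s%d", 1:8)
    anosim(hellinger_dist(cc), sample(rep(c("a", "b"), each = 4)),
           exact = TRUE)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)
})
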