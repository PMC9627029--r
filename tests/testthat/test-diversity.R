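test_that("Shannon diversity matches hand-computed values", {
  expect_equal(shannon(c(5, 5)), log(2), tolerance = 1e-12)
  expect_equal(shannon(c(10, 0, 0)), 0)
  ## frozen against an independent evaluation of -sum p log p
  expect_equal(shannon(c(1, 2, 3)), 1.01140426, tolerance = 1e-7)
  expect_equal(shannon(c(1, 2, 3), base = 2), 1.01140426 / log(2),
               tolerance = 1e-7)
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("Shannon is maximized by the uniform vector at fixed richness", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    x <- rgamma(k, 1)
    expect_lte(shannon(x), shannon(rep(1, k)) + 1e-12)
  }
})

test_that("Bray-Curtis matches the definition on hand cases", {
  m <- matrix(c(2, 4, 0,
                2, 0, 4), nrow = 3,
              dimnames = list(paste0("A", 1:3), c("S1", "S2")))
  d <- bray_curtis(asv_table(m))
  expect_equal(d["S1", "S2"], 8 / 12, tolerance = 1e-12)
  same <- matrix(c(1, 2, 1, 2), nrow = 2,
                 dimnames = list(c("A1", "A2"), c("S1", "S2")))
  expect_equal(bray_curtis(asv_table(same))["S1", "S2"], 0)
  disj <- matrix(c(3, 0, 0, 5), nrow = 2,
                 dimnames = list(c("A1", "A2"), c("S1", "S2")))
  expect_equal(bray_curtis(asv_table(disj))["S1", "S2"], 1)
})

test_that("weighted UniFrac reproduces the two-branch hand computation", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(10, 0, 0, 5), nrow = 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  raw <- weighted_unifrac(asv_table(m), tree)
  expect_equal(raw["S1", "S2"], 2, tolerance = 1e-12)
  norm <- weighted_unifrac(asv_table(m), tree, normalized = TRUE)
  expect_equal(norm["S1", "S2"], 1, tolerance = 1e-12)
  same <- matrix(c(3, 7, 6, 14), nrow = 2,
                 dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_equal(weighted_unifrac(asv_table(same), tree)["S1", "S2"], 0,
               tolerance = 1e-12)
  bad <- matrix(c(1, 1), nrow = 2, dimnames = list(c("A", "Z"), "S1"))
  expect_error(weighted_unifrac(asv_table(cbind(bad, S2 = c(1L, 0L))), tree),
               "Z")
})

test_that("weighted UniFrac equals the branch-enumeration oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    tree <- ape::rtree(8, br = stats::rexp)
    m <- matrix(sample.int(30, 8 * 3, replace = TRUE) - 1L, 8, 3,
                dimnames = list(tree$tip.label, c("S1", "S2", "S3")))
    m[1, colSums(m) == 0] <- 1L
    tab <- asv_table(m)
    for (normalized in c(FALSE, TRUE)) {
      got <- weighted_unifrac(tab, tree, normalized = normalized)
      want <- oracle_unifrac(m, tree, normalized = normalized)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("PCoA reproduces simple geometries", {
  ## three equidistant points: two equal positive eigenvalues, distances 1
  dm <- matrix(1, 3, 3) - diag(3)
  dimnames(dm) <- list(paste0("S", 1:3), paste0("S", 1:3))
  fit <- pcoa(dm, axes = 2)
  eig <- fit$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  emb <- as.matrix(dist(fit$coordinates))
  expect_equal(unname(emb[upper.tri(emb)]), rep(1, 3), tolerance = 1e-6)
  ## duplicated sample lands on identical coordinates
  dm4 <- rbind(cbind(dm, S4 = dm[, 3]), S4 = c(dm[3, ], 0))
  rownames(dm4) <- colnames(dm4) <- c(paste0("S", 1:3), "S4")
  fit4 <- suppressWarnings(pcoa(dm4, axes = 2))
  expect_equal(fit4$coordinates["S3", ], fit4$coordinates["S4", ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit4$eigenvalues) < 1e-9))   # sorted descending
})

test_that("PCoA embeddings reconstruct Euclidean-realizable distances", {
  set.seed(7)
  x <- matrix(rnorm(5 * 3), 5)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("S", 1:5), paste0("S", 1:5))
  fit <- pcoa(dm, axes = 3)
  expect_equal(as.matrix(dist(fit$coordinates)), dm, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lte(sum(fit$proportion_explained), 1 + 1e-9)
  expect_warning(pcoa(dm, axes = 10), "truncated")
})

test_that("ANOSIM attains R = 1 under complete separation and matches vegan", {
  set.seed(11)
  x <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 10), 4))
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("S", 1:8), paste0("S", 1:8))
  groups <- rep(c("a", "b"), each = 4)
  res <- anosim(dm, groups, n_permutations = 99, seed = 1)
  expect_equal(res$R, 1, tolerance = 1e-12)
  ## R statistic cross-checked against the reference implementation
  set.seed(2)
  y <- matrix(rnorm(8 * 4), 8)
  dmy <- as.matrix(dist(y))
  dimnames(dmy) <- list(paste0("S", 1:8), paste0("S", 1:8))
  ref <- vegan::anosim(stats::as.dist(dmy), factor(groups), permutations = 0)
  got <- anosim(dmy, groups, n_permutations = 19, seed = 1)
  expect_equal(got$R, unname(ref$statistic), tolerance = 1e-9)
})

test_that("ANOSIM p is exact for 4 samples in 2 groups of 2", {
  set.seed(5)
  x <- matrix(rnorm(4 * 2), 4)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("S", 1:4), paste0("S", 1:4))
  groups <- c("a", "a", "b", "b")
  res <- anosim(dm, groups, n_permutations = 999, seed = 1)
  expect_true(res$exhaustive)
  ## independent exhaustive oracle over the 3 distinct pair partitions
  stat <- function(g) {
    r <- rank(dm[upper.tri(dm)])
    pr <- which(upper.tri(dm), arr.ind = TRUE)
    w <- g[pr[, 1]] == g[pr[, 2]]
    (mean(r[!w]) - mean(r[w])) / (length(r) / 2)
  }
  labelings <- list(c("a", "a", "b", "b"), c("a", "b", "a", "b"),
                    c("a", "b", "b", "a"))
  stats_all <- vapply(labelings, stat, numeric(1))
  p_oracle <- mean(stats_all >= stats_all[1] - 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_error(anosim(dm, c("a", "a", "a", "b")), "size 1")
})

test_that("nearest neighbour recovers planted pairs and breaks ties", {
  set.seed(9)
  dm <- as.matrix(dist(matrix(rnorm(12), 6)))
  ids <- paste0("S", 1:6)
  dimnames(dm) <- list(ids, ids)
  dm["S2", "S5"] <- dm["S5", "S2"] <- 1e-6       # planted closest pair
  expect_equal(nearest_neighbor(dm, "S2"), "S5")
  expect_equal(nearest_neighbor(dm, "S5"), "S2")
  ## brute-force scan agreement on every query
  for (q in ids) {
    d <- dm[q, setdiff(ids, q)]
    expect_equal(nearest_neighbor(dm, q), names(d)[which.min(d)])
  }
  tie <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3,
                dimnames = list(c("S1", "S2", "S3"), c("S1", "S2", "S3")))
  expect_warning(nn <- nearest_neighbor(tie, "S1"), "tie")
  expect_equal(nn, "S2")
  expect_error(nearest_neighbor(dm, "missing"), "absent")
})
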