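two_bird_meta <- function() {
  as_sample_metadata(data.frame(
    sample_id = c("B1_colon", "B1_cloacal_swab", "B2_colon",
                  "B2_cloacal_swab", "B1_crop", "B2_crop"),
    bird_id = rep(c("B1", "B1", "B2", "B2", "B1", "B2")),
    site = c("colon", "cloacal_swab", "colon", "cloacal_swab", "crop",
             "crop")))
}

test_that("distance-to-swab profiles average within birds then across birds", {
  ids <- c("B1_colon", "B1_cloacal_swab", "B2_colon", "B2_cloacal_swab",
           "B1_crop", "B2_crop")
  dm <- matrix(0.5, 6, 6, dimnames = list(ids, ids))
  diag(dm) <- 0
  dm["B1_colon", "B1_cloacal_swab"] <- dm["B1_cloacal_swab", "B1_colon"] <- 0.1
  dm["B2_colon", "B2_cloacal_swab"] <- dm["B2_cloacal_swab", "B2_colon"] <- 0.3
  dm["B1_crop", "B1_cloacal_swab"] <- dm["B1_cloacal_swab", "B1_crop"] <- 0.8
  dm["B2_crop", "B2_cloacal_swab"] <- dm["B2_cloacal_swab", "B2_crop"] <- 0.6
  prof <- distance_to_swab(dm, two_bird_meta())
  expect_equal(prof$mean_distance_to_swab[prof$site == "colon"], 0.2)
  expect_equal(prof$mean_distance_to_swab[prof$site == "crop"], 0.7)
  expect_equal(prof$sd[prof$site == "colon"], sd(c(0.1, 0.3)))
  ## swab identical to colon: colon mean distance 0
  dm0 <- dm
  dm0["B1_colon", "B1_cloacal_swab"] <- dm0["B1_cloacal_swab", "B1_colon"] <- 0
  dm0["B2_colon", "B2_cloacal_swab"] <- dm0["B2_cloacal_swab", "B2_colon"] <- 0
  expect_equal(distance_to_swab(dm0, two_bird_meta())$mean_distance_to_swab[
    prof$site == "colon"], 0)
  ## a bird without a swab is an error
  meta_noswab <- two_bird_meta()[-2, ]
  expect_error(distance_to_swab(dm[-2, -2], meta_noswab), "B1")
})

test_that("distance-to-swab means are invariant to sample order", {
  fl <- small_flock(51)
  meta <- fl$metadata[!fl$metadata$is_negative, ]
  tab <- true_subtable(fl)
  dm <- bray_curtis(css_normalize(tab)$table)
  prof <- distance_to_swab(dm, meta)
  perm <- sample(nrow(dm))
  prof2 <- distance_to_swab(dm[perm, perm], meta)
  expect_equal(prof, prof2)
})

test_that("family correlation matches the closed-form t-test", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1.5, 4, 3.5, 5)
  ## pipeline values computed through a toy 5-bird flock at two sites
  meta <- as_sample_metadata(data.frame(
    sample_id = c(paste0("B", 1:5, "_colon"), paste0("B", 1:5, "_cloacal_swab")),
    bird_id = rep(paste0("B", 1:5), 2),
    site = rep(c("colon", "cloacal_swab"), each = 5)))
  m <- matrix(0, 2, 10, dimnames = list(c("E1", "OTHER"), meta$sample_id))
  m[1, 1:5] <- x; m[1, 6:10] <- y
  m[2, ] <- 5
  tax <- toy_taxonomy(c("E1", "OTHER"), kingdom = "Bacteria",
                      family = c("Enterobacteriaceae", "Lachnospiraceae"))
  out <- family_correlation(asv_table(m, normalized = TRUE), tax, meta)
  ## frozen against an independent Pearson evaluation of the toy vectors
  expect_equal(out$r[out$site == "colon"], 0.87811408, tolerance = 1e-7)
  expect_equal(out$p[out$site == "colon"], 0.05013723, tolerance = 1e-6)
  ## perfect copy and reflection
  m2 <- m; m2[1, 1:5] <- y
  out2 <- family_correlation(asv_table(m2, normalized = TRUE), tax, meta)
  expect_equal(out2$r[out2$site == "colon"], 1, tolerance = 1e-12)
  m3 <- m; m3[1, 1:5] <- 2 * mean(y) - y
  out3 <- family_correlation(asv_table(m3, normalized = TRUE), tax, meta)
  expect_equal(out3$r[out3$site == "colon"], -1, tolerance = 1e-12)
  ## zero variance is reported as NA, not an error
  m4 <- m; m4[1, 1:5] <- 3
  out4 <- family_correlation(asv_table(m4, normalized = TRUE), tax, meta)
  expect_true(is.na(out4$r[out4$site == "colon"]))
})

test_that("the least-squares core matches hand arithmetic", {
  fit <- gutsampler:::ls_fit(c(1, 2, 3), c(0.9, 0.7, 0.5))
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.1, tolerance = 1e-12)
})

test_that("perfect distance decay is detected at the permutation floor", {
  ## similarity strictly decreasing in ordinal gap
  sites <- c("crop", "duodenum", "ileum", "colon", "cloacal_swab")
  ids <- paste0("B1_", sites)
  meta <- as_sample_metadata(data.frame(
    sample_id = ids, bird_id = "B1", site = sites))
  ords <- meta$ordinal
  dm <- outer(ords, ords, function(a, b) 0.1 * abs(a - b))
  dimnames(dm) <- list(ids, ids)
  fit <- distance_decay(dm, meta, "B1", n_permutations = 999, seed = 1)
  expect_lt(fit$r, 0)
  expect_lt(fit$slope, 0)
  expect_true(fit$exhaustive)
  expect_equal(fit$p, 1 / fit$n_permutations, tolerance = 1e-12)
  expect_equal(fit$n_pairs, choose(5, 2))
  expect_error(distance_decay(dm[1:3, 1:3], meta[1:3, ], "B1"), "4")
})

test_that("distance-decay p matches exhaustive enumeration for 4 sites", {
  set.seed(23)
  sites <- c("crop", "jejunum", "colon", "cloacal_swab")
  ids <- paste0("B1_", sites)
  meta <- as_sample_metadata(data.frame(sample_id = ids, bird_id = "B1",
                                        site = sites))
  dm <- as.matrix(dist(matrix(rnorm(8), 4))) / 10
  dimnames(dm) <- list(ids, ids)
  fit <- distance_decay(dm, meta, "B1", n_permutations = 999, seed = 2)
  ## independent enumeration of all 4! ordinal relabelings
  ords <- meta$ordinal
  ut <- upper.tri(dm)
  pr <- which(ut, arr.ind = TRUE)
  sim <- 1 - dm[ut]
  r_for <- function(o) cor(abs(o[pr[, 1]] - o[pr[, 2]]), sim)
  perms <- gutsampler:::all_orderings(4)
  rs <- apply(perms, 1, function(ix) r_for(ords[ix]))
  expect_equal(fit$p, mean(rs <= rs[1] + 1e-12), tolerance = 1e-12)
})

test_that("cecal enrichment calls planted folds and respects BH monotonicity", {
  set.seed(31)
  n_cec <- 6; n_non <- 10
  ids <- c(paste0("C", 1:n_cec), paste0("N", 1:n_non))
  meta <- as_sample_metadata(data.frame(
    sample_id = ids,
    bird_id = ids,
    site = c(rep("cecum", n_cec), rep("ileum", n_non)),
    pouch = c(rep(c("left", "right"), 3), rep(NA, n_non))))
  m <- matrix(rpois(20 * 16, 50), 20, 16,
              dimnames = list(sprintf("A%02d", 1:20), ids))
  m[1, 1:n_cec] <- rpois(n_cec, 400)          # planted enriched
  m[2, ] <- 0                                  # absent everywhere
  tab <- asv_table(m, normalized = TRUE)
  expect_warning(res <- cecal_enrichment(tab, meta, alpha = 0.05,
                                         n_permutations = 499, seed = 3),
                 "absent")
  expect_false("A02" %in% res$feature_id)
  a1 <- res[res$feature_id == "A01", ]
  expect_equal(a1$status, "enriched")
  expect_gt(a1$log2_fold_change, 2)
  ## exact 2x ratio with negligible pseudocount gives LFC near 1
  m5 <- matrix(1000, 2, 16, dimnames = list(c("F1", "F2"), ids))
  m5[1, 1:n_cec] <- 2000
  res5 <- cecal_enrichment(asv_table(m5, normalized = TRUE), meta,
                           n_permutations = 99, seed = 1)
  expect_equal(res5$log2_fold_change[res5$feature_id == "F1"], 1,
               tolerance = 0.01)
  expect_equal(res5$log2_fold_change[res5$feature_id == "F2"], 0,
               tolerance = 1e-9)
  expect_equal(res5$status[res5$feature_id == "F2"], "ns")
  ## q-values are monotone in p-values
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  ## status is consistent with q and the fold-change sign
  expect_true(all((res$status != "ns") == (res$q < 0.05)))
  expect_true(all(res$log2_fold_change[res$status == "enriched"] > 0))
  expect_true(all(res$log2_fold_change[res$status == "depleted"] < 0))
})
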