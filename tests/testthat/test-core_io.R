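test_that("ASV table TSV round-trip is the identity on counts and ids", {
  for (seed in 1:5) {
    tab <- rand_int_table(20, 6, seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_asv_table(tab, path)
    back <- read_asv_table(path)
    expect_identical(unname(dim(back)), unname(dim(tab)))
    expect_identical(rownames(back), rownames(tab))
    expect_identical(colnames(back), colnames(tab))
    expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  }
})

test_that("table validation names the offending id or cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "ASV_1\t1\t2", "ASV_1\t3\t4"), path)
  expect_error(read_asv_table(path), "ASV_1")
  writeLines(c("feature_id\tS1\tS2", "ASV_1\t1\t2", "ASV_2\t-3\t4"), path)
  expect_error(read_asv_table(path), "negative")
  writeLines(c("feature_id\tS1\tS2", "ASV_1\t1\tx", "ASV_2\t3\t4"), path)
  expect_error(read_asv_table(path), "non-numeric")
  m <- tiny_counts()
  m[1, 1] <- 1.5
  expect_error(asv_table(m), "non-integer")
  expect_silent(asv_table(m, normalized = TRUE))
})

test_that("metadata ordinals follow the anatomical convention", {
  df <- data.frame(sample_id = c("S1", "S2", "S3"),
                   bird_id = "B1",
                   site = c("cecum", "crop", "cloacal_swab"),
                   pouch = c("left", NA, NA))
  meta <- as_sample_metadata(df)
  expect_equal(meta$ordinal, c(7L, 1L, 9L))
  expect_false(any(meta$is_negative))
})

test_that("metadata validation rejects malformed rows", {
  base <- data.frame(sample_id = "S1", bird_id = "B1", site = "crop")
  bad_site <- base; bad_site$site <- "unknown_site"
  expect_error(as_sample_metadata(bad_site), "crop.*cecum|allowed")
  no_pouch <- base; no_pouch$site <- "cecum"
  expect_error(as_sample_metadata(no_pouch), "pouch")
  stray_pouch <- base; stray_pouch$pouch <- "left"
  expect_error(as_sample_metadata(stray_pouch), "non-cecum")
  neg_conc <- base; neg_conc$dna_conc <- -1
  expect_error(as_sample_metadata(neg_conc), "dna_conc")
  ## samples in the table but not in metadata are a hard error
  tab <- asv_table(tiny_counts())
  meta <- as_sample_metadata(data.frame(sample_id = "S1", bird_id = "B1",
                                        site = "crop"))
  expect_error(gutsampler:::align_metadata(tab, meta), "S2")
})

test_that("relative abundance sums to one and drops empty samples", {
  tab <- asv_table(tiny_counts())
  rel <- to_relative_abundance(tab)
  expect_equal(unname(colSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(unclass(rel)[, "S2"]), c(0, 0.25, 0.75))
  m <- tiny_counts(); m[, 2] <- 0
  expect_warning(rel2 <- to_relative_abundance(asv_table(m)), "S2")
  expect_equal(colnames(rel2), "S1")
  expect_error(to_relative_abundance(asv_table(m[, 0, drop = FALSE])))
})

test_that("taxonomy readers accept wide and lineage-string dialects", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("feature_id", "kingdom", "phylum", "class", "order",
                       "family", "genus", "species"), collapse = "\t"),
               "ASV_1\tBacteria\tFirmicutes\tBacilli\tLactobacillales\tLactobacillaceae\tLactobacillus\t",
               "ASV_2\tBacteria\t\t\t\t\t\t"), wide)
  gg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tTaxon",
               "ASV_1\tk__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus; s__",
               "ASV_2\tk__Bacteria"), gg)
  tw <- read_taxonomy(wide)
  tg <- read_taxonomy(gg)
  expect_equal(tw$family, tg$family)
  expect_equal(tw$kingdom, tg$kingdom)
  expect_true(is.na(tg$species[1]))
})

test_that("aggregation by rank is additive, conserving, and idempotent", {
  m <- matrix(c(3, 4, 5,
                2, 1, 7), nrow = 3,
              dimnames = list(c("ASV_1", "ASV_2", "ASV_3"), c("S1", "S2")))
  tab <- asv_table(m)
  tax <- toy_taxonomy(c("ASV_1", "ASV_2", "ASV_3"),
                      kingdom = "Bacteria",
                      family = c("Enterobacteriaceae", "Enterobacteriaceae", NA),
                      species = c("sp1", "sp2", "sp3"))
  fam <- aggregate_by_rank(tab, tax, "family")
  expect_equal(unclass(fam)["Enterobacteriaceae", "S1"], 7)
  expect_true("unclassified_Bacteria" %in% rownames(fam))
  expect_equal(colSums(fam), colSums(tab))
  ## species-level then family-level equals direct family aggregation
  sp <- aggregate_by_rank(tab, tax, "species")
  tax_sp <- toy_taxonomy(rownames(sp),
                         kingdom = "Bacteria",
                         family = c("Enterobacteriaceae",
                                    "Enterobacteriaceae", NA)[
                           match(rownames(sp), c("sp1", "sp2", "sp3"))])
  fam2 <- aggregate_by_rank(sp, tax_sp, "family")
  common <- intersect(rownames(fam), rownames(fam2))
  expect_equal(unclass(fam)["Enterobacteriaceae", ],
               unclass(fam2)["Enterobacteriaceae", ])
  expect_error(aggregate_by_rank(tab, tax, "clade"), "unknown rank")
})

test_that("tree and distance-matrix round-trips preserve structure", {
  set.seed(42)
  tree <- ape::rtree(8, br = stats::rexp)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, path)
  back <- read_tree(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
  dm <- as.matrix(dist(matrix(rnorm(12), 4)))
  dimnames(dm) <- list(paste0("S", 1:4), paste0("S", 1:4))
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, dpath)
  expect_equal(read_distance_matrix(dpath), dm, tolerance = 1e-9)
})
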