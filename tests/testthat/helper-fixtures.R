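## Shared fixtures and independent oracles, all built in code.

tiny_counts <- function() {
  m <- matrix(c(2, 2, 4,
                0, 10, 30), nrow = 3,
              dimnames = list(c("ASV_1", "ASV_2", "ASV_3"), c("S1", "S2")))
  m
}

rand_int_table <- function(n_feat, n_samp, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1, n_feat * n_samp, replace = TRUE) - 1L,
              n_feat, n_samp,
              dimnames = list(sprintf("ASV_%03d", seq_len(n_feat)),
                              sprintf("S%02d", seq_len(n_samp))))
  ## keep every sample non-empty
  m[1, colSums(m) == 0] <- 1L
  asv_table(m)
}

toy_taxonomy <- function(feature_id, ...) {
  extra <- list(...)
  df <- data.frame(feature_id = feature_id, stringsAsFactors = FALSE)
  for (r in c("kingdom", "phylum", "class", "order", "family", "genus",
              "species"))
    df[[r]] <- if (!is.null(extra[[r]])) extra[[r]] else NA_character_
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

## independent weighted-UniFrac oracle: enumerate every branch and its
## descendant leaf set by recursive descent (no postorder accumulation)
oracle_unifrac <- function(counts, tree, normalized = FALSE) {
  n_tip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  props <- sweep(counts, 2, colSums(counts), "/")
  S <- ncol(props)
  d <- matrix(0, S, S, dimnames = list(colnames(counts), colnames(counts)))
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tree$tip.label[desc_tips(tree$edge[e, 2])]
      pa <- sum(props[rownames(props) %in% tips, a])
      pb <- sum(props[rownames(props) %in% tips, b])
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    d[a, b] <- d[b, a] <- if (normalized) num / den else num
  }
  d
}

## independent accumulation oracle: plain set arithmetic over one ordering
oracle_accumulate <- function(sets, ord) {
  seen <- character(0)
  new <- cumulative <- uni <- integer(length(ord))
  for (k in seq_along(ord)) {
    s <- sets[[ord[k]]]
    new[k] <- length(setdiff(s, seen))
    seen <- union(seen, s)
    cumulative[k] <- length(seen)
    tallies <- table(unlist(sets[ord[seq_len(k)]]))
    uni[k] <- sum(tallies == 1)
  }
  list(new = new, cumulative = cumulative, unique = uni)
}

random_flock_meta <- function(table) {
  ## metadata for tables whose columns are named like B<i>_<site>[_pouch]
  ids <- colnames(table)
  parts <- strsplit(ids, "_")
  df <- data.frame(sample_id = ids,
                   bird_id = vapply(parts, `[`, "", 1),
                   site = vapply(parts, function(p)
                     paste(p[-1][!p[-1] %in% c("l", "r")], collapse = "_"), ""),
                   stringsAsFactors = FALSE)
  df
}

small_flock <- function(seed, ...) {
  generate_flock(flock_model(seed = seed, n_birds = 4, n_features = 150,
                             depth_mean = 4000, n_contaminants = 4,
                             n_planted_enriched = 4, ...))
}

true_subtable <- function(flock) {
  meta <- flock$metadata
  keep <- meta$sample_id[!meta$is_negative]
  asv_table(unclass(flock$table)[, keep, drop = FALSE])
}
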