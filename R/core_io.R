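#' @keywords internal
"_PACKAGE"

## Anatomical ordinal convention for the broiler alimentary tract.
## The flow order (proventriculus before gizzard) is used; both cecal pouches
## share one ordinal and the cloacal swab sits most aborad.
SITE_ORDINALS <- c(
  crop = 1L, proventriculus = 2L, gizzard = 3L, duodenum = 4L,
  jejunum = 5L, ileum = 6L, cecum = 7L, colon = 8L, cloacal_swab = 9L
)

SITE_LEVELS <- c(names(SITE_ORDINALS), "negative_control")

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

#' Anatomical site labels and their ordinals
#'
#' Returns the named integer vector mapping each alimentary-tract site to its
#' anatomical ordinal (crop = 1 ... cloacal_swab = 9). Both cecal pouches
#' share ordinal 7. Negative controls carry no ordinal.
#'
#' @return Named integer vector.
#' @export
site_ordinals <- function() SITE_ORDINALS

#' Construct a validated ASV count table
#'
#' The central object of the pipeline: a features x samples matrix of
#' non-negative read counts (or normalized abundances) with unique feature and
#' sample identifiers.
#'
#' @param counts Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param normalized Logical; `FALSE` for raw integer counts (enforced),
#'   `TRUE` after normalization.
#' @return An object of class `asv_table` (a matrix with a `normalized`
#'   attribute).
#' @export
asv_table <- function(counts, normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("`counts` must carry feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (nrow(counts) > 0) validate_ids(rownames(counts), "feature")
  if (ncol(counts) > 0) validate_ids(colnames(counts), "sample")
  if (anyNA(counts))
    stop("count matrix contains missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (!normalized && any(abs(counts - round(counts)) > 1e-9)) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s' in a raw table",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  structure(counts, normalized = normalized,
            class = c("asv_table", class(counts)))
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("empty or missing %s id", what), call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated %s id(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d features x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw counts"))
  cat(sprintf("  total reads/abundance: %s\n",
              format(sum(x), big.mark = ",")))
  invisible(x)
}

is_normalized <- function(table) isTRUE(attr(table, "normalized"))

## Rebuild an asv_table from a plain matrix derived from `template`.
as_asv <- function(counts, normalized) {
  asv_table(as.matrix(counts), normalized = normalized)
}

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file with the first column holding feature ids and
#' the header row holding sample ids (or the transpose, per `orientation`).
#'
#' @param path Path to a TSV file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param normalized Logical flag recorded on the returned table.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(path,
                           orientation = c("features_in_rows", "samples_in_rows"),
                           normalized = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("ASV table must have an id column plus at least one data column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  validate_ids(ids, if (orientation == "features_in_rows") "feature" else "sample")
  validate_ids(colnames(df)[-1],
               if (orientation == "features_in_rows") "sample" else "feature")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
    mode(mat) <- "numeric"
  }
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  asv_table(mat, normalized = normalized)
}

#' Write an ASV table to TSV
#'
#' Features in rows, samples in columns; inverse of [read_asv_table()].
#'
#' @param table An [asv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Requires columns `sample_id`, `bird_id`, `site`; accepts optional `pouch`
#' (cecum only), `dna_conc`, `is_negative` and `ordinal`. When no `ordinal`
#' column is supplied, ordinals are assigned from the anatomical convention
#' ([site_ordinals()]).
#'
#' @param path Path to a TSV file.
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_sample_metadata(df)
}

#' Validate a metadata data frame
#'
#' @param df Data frame with at least `sample_id`, `bird_id`, `site`.
#' @return A validated `sample_metadata` data frame with columns `sample_id`,
#'   `bird_id`, `site`, `pouch`, `ordinal`, `dna_conc`, `is_negative`.
#' @export
as_sample_metadata <- function(df) {
  required <- c("sample_id", "bird_id", "site")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    bird_id = as.character(df$bird_id),
    site = as.character(df$site),
    stringsAsFactors = FALSE
  )
  validate_ids(out$sample_id, "sample")
  bad_site <- setdiff(unique(out$site), SITE_LEVELS)
  if (length(bad_site))
    stop(sprintf("unknown site label(s): %s; allowed: %s",
                 paste(bad_site, collapse = ", "),
                 paste(SITE_LEVELS, collapse = ", ")), call. = FALSE)
  pouch <- if ("pouch" %in% colnames(df)) as.character(df$pouch) else
    rep(NA_character_, nrow(df))
  pouch[!is.na(pouch) & !nzchar(pouch)] <- NA_character_
  bad_pouch <- setdiff(stats::na.omit(unique(pouch)), c("left", "right"))
  if (length(bad_pouch))
    stop("pouch must be 'left' or 'right', got: ",
         paste(bad_pouch, collapse = ", "), call. = FALSE)
  if (any(out$site == "cecum" & is.na(pouch)))
    stop("cecum sample(s) without a pouch label: ",
         paste(out$sample_id[out$site == "cecum" & is.na(pouch)], collapse = ", "),
         call. = FALSE)
  if (any(out$site != "cecum" & !is.na(pouch)))
    stop("pouch label on non-cecum sample(s): ",
         paste(out$sample_id[out$site != "cecum" & !is.na(pouch)], collapse = ", "),
         call. = FALSE)
  out$pouch <- pouch
  if ("ordinal" %in% colnames(df)) {
    out$ordinal <- as.integer(df$ordinal)
  } else {
    out$ordinal <- unname(SITE_ORDINALS[out$site])
  }
  if (any(is.na(out$ordinal) & out$site != "negative_control"))
    stop("ordinal undefined for non-negative-control sample(s)", call. = FALSE)
  out$dna_conc <- if ("dna_conc" %in% colnames(df))
    as.numeric(df$dna_conc) else rep(NA_real_, nrow(df))
  if (any(!is.na(out$dna_conc) & out$dna_conc <= 0))
    stop("dna_conc must be positive where present", call. = FALSE)
  is_neg <- if ("is_negative" %in% colnames(df))
    as.logical(df$is_negative) else out$site == "negative_control"
  if (any(is_neg != (out$site == "negative_control")))
    stop("is_negative flag inconsistent with site == 'negative_control'",
         call. = FALSE)
  out$is_negative <- is_neg
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## Align metadata rows to a table's samples; error on mismatch.
align_metadata <- function(table, meta) {
  idx <- match(colnames(table), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) present in the table but absent from metadata: ",
         paste(colnames(table)[is.na(idx)], collapse = ", "), call. = FALSE)
  meta[idx, , drop = FALSE]
}

#' Read a taxonomy table
#'
#' Accepts two dialects: one column per canonical rank
#' (kingdom ... species), or a single lineage-string column in the
#' Greengenes style (`k__Bacteria; p__Firmicutes; ...`). Empty rank labels
#' become `NA`.
#'
#' @param path Path to a TSV with a `feature_id` (or first) column.
#' @return A `taxonomy_table` data frame: `feature_id` plus the seven ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- if ("feature_id" %in% colnames(df)) "feature_id" else colnames(df)[1]
  feature_id <- as.character(df[[id_col]])
  validate_ids(feature_id, "feature")
  rest <- df[, setdiff(colnames(df), id_col), drop = FALSE]
  if (all(TAXONOMY_RANKS %in% tolower(colnames(rest)))) {
    colnames(rest) <- tolower(colnames(rest))
    ranks <- rest[, TAXONOMY_RANKS, drop = FALSE]
  } else if (ncol(rest) >= 1) {
    ranks <- parse_lineage_strings(as.character(rest[[1]]))
  } else {
    stop("taxonomy file needs rank columns or a lineage column", call. = FALSE)
  }
  out <- data.frame(feature_id = feature_id, ranks, stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS) {
    v <- as.character(out[[r]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    out[[r]] <- v
  }
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

parse_lineage_strings <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  mat <- matrix(NA_character_, nrow = length(x), ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  for (i in seq_along(parts)) {
    for (piece in trimws(parts[[i]])) {
      hit <- which(startsWith(piece, prefixes))
      if (length(hit) == 1) {
        label <- substring(piece, 4)
        if (nzchar(label)) mat[i, hit] <- label
      }
    }
  }
  as.data.frame(mat, stringsAsFactors = FALSE)
}

#' Write a taxonomy table (wide rank columns)
#' @param taxonomy A `taxonomy_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(as.data.frame(taxonomy), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a rooted phylogenetic tree with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the distance
#' computations rely on: unique leaf labels and non-negative branch lengths
#' present on every edge.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are required", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  validate_ids(tree$tip.label, "tree leaf")
  invisible(tree)
}

#' Read/write a square distance matrix as TSV
#'
#' @param path Path to a square TSV with sample ids on both axes.
#' @return A validated symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ids
  validate_distance_matrix(mat)
  mat
}

#' @rdname read_distance_matrix
#' @param dm A square distance matrix with dimnames.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), as.data.frame(dm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(dm, tol = 1e-9) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(dm)) || is.null(colnames(dm)) ||
      !identical(rownames(dm), colnames(dm)))
    stop("distance matrix must have matching row/column sample ids", call. = FALSE)
  if (any(dm < -tol)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(dm - t(dm))) > tol)
    stop("distance matrix not symmetric within tolerance", call. = FALSE)
  if (any(abs(diag(dm)) > tol))
    stop("distance matrix diagonal not zero", call. = FALSE)
  invisible(dm)
}

#' Convert counts to per-sample relative abundance
#'
#' Each sample column is divided by its total so columns sum to one. Samples
#' with zero total are dropped with a warning.
#'
#' @param table An [asv_table()].
#' @return A normalized [asv_table()] of relative abundances.
#' @export
to_relative_abundance <- function(table) {
  if (nrow(table) == 0 || ncol(table) == 0)
    stop("empty ASV table", call. = FALSE)
  totals <- colSums(table)
  if (any(totals == 0)) {
    warning("dropping all-zero sample(s): ",
            paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
    table <- table[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
    if (ncol(table) == 0) stop("no samples with positive counts", call. = FALSE)
  }
  as_asv(sweep(unclass(table), 2, totals, "/"), normalized = TRUE)
}

#' Aggregate an ASV table at a taxonomic rank
#'
#' Features sharing the rank label are summed. Features unassigned at that
#' rank are pooled into `unclassified_<parent>` buckets named after the
#' deepest assigned ancestor label, so per-sample totals are conserved
#' exactly.
#'
#' @param table An [asv_table()].
#' @param taxonomy A `taxonomy_table` covering the table's features.
#' @param rank One of the seven canonical ranks.
#' @return An [asv_table()] with one row per rank label / unclassified bucket.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank) {
  if (!rank %in% TAXONOMY_RANKS)
    stop(sprintf("unknown rank '%s'; must be one of: %s", rank,
                 paste(TAXONOMY_RANKS, collapse = ", ")), call. = FALSE)
  idx <- match(rownames(table), taxonomy$feature_id)
  depth <- match(rank, TAXONOMY_RANKS)
  labels <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    ti <- idx[i]
    if (is.na(ti)) { labels[i] <- "unclassified_unknown"; next }
    lab <- taxonomy[[rank]][ti]
    if (!is.na(lab)) { labels[i] <- lab; next }
    parent <- NA_character_
    for (d in rev(seq_len(depth - 1))) {
      cand <- taxonomy[[TAXONOMY_RANKS[d]]][ti]
      if (!is.na(cand)) { parent <- cand; break }
    }
    labels[i] <- paste0("unclassified_",
                        if (is.na(parent)) "unknown" else parent)
  }
  agg <- rowsum(unclass(table), group = labels)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  as_asv(agg, normalized = is_normalized(table))
}
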