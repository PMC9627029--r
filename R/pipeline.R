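#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its documented default,
#' validating each against its domain before any computation. Inputs are
#' either file paths (`inputs`) or an in-memory [generate_flock()] result
#' (`flock`).
#'
#' @param out_dir Output directory for all stage outputs and the run
#'   manifest.
#' @param inputs Named list of paths: `table`, `metadata`, `taxonomy`,
#'   `tree` (tree optional).
#' @param flock Alternative to `inputs`: a `flock` object.
#' @param decontam_threshold Contaminant flagging threshold in (0, 1).
#' @param decontam_permutations Permutations for the contaminant frequency
#'   test.
#' @param css_quantile CSS quantile in (0, 1).
#' @param css_scale CSS rescale factor.
#' @param remove_taxa Data frame (`rank`, `label`) of taxa to drop; defaults
#'   to the two Lactobacillus species flagged in negative controls.
#' @param accumulation_thresholds New-ASV fractions for the sufficiency
#'   analysis.
#' @param n_orderings Orderings per accumulation curve.
#' @param metric `"bray"` or `"wunifrac"` for the distance-based stages.
#' @param alpha Global significance level.
#' @param enrichment_alpha Significance level of the cecal enrichment
#'   contrast.
#' @param family Family for the swab-correlation analysis.
#' @param n_permutations Permutation budget for ANOSIM, distance decay and
#'   enrichment.
#' @param seed Integer seed; required (every stochastic stage derives its
#'   stream from it).
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       inputs = NULL,
                       flock = NULL,
                       decontam_threshold = 0.1,
                       decontam_permutations = 1000,
                       css_quantile = 0.5,
                       css_scale = 1000,
                       remove_taxa = data.frame(
                         rank = c("species", "species"),
                         label = c("L. acidipiscis", "L. helveticus"),
                         stringsAsFactors = FALSE),
                       accumulation_thresholds = c(0.10, 0.01),
                       n_orderings = 100,
                       metric = c("bray", "wunifrac"),
                       alpha = 0.05,
                       enrichment_alpha = 0.01,
                       family = "Enterobacteriaceae",
                       n_permutations = 999,
                       seed) {
  metric <- match.arg(metric)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (is.null(inputs) && is.null(flock))
    stop("either `inputs` paths or a `flock` must be given", call. = FALSE)
  check01 <- function(x, name) {
    if (!is.numeric(x) || any(x <= 0) || any(x >= 1))
      stop(sprintf("%s must lie in (0, 1); got %s", name,
                   paste(x, collapse = ", ")), call. = FALSE)
  }
  check01(decontam_threshold, "decontam_threshold")
  check01(css_quantile, "css_quantile")
  check01(accumulation_thresholds, "accumulation_thresholds")
  check01(alpha, "alpha")
  check01(enrichment_alpha, "enrichment_alpha")
  stopifnot(css_scale > 0, n_orderings >= 1, n_permutations >= 1,
            decontam_permutations >= 1)
  structure(list(
    out_dir = out_dir, inputs = inputs, flock = flock,
    decontam_threshold = decontam_threshold,
    decontam_permutations = decontam_permutations,
    css_quantile = css_quantile, css_scale = css_scale,
    remove_taxa = remove_taxa,
    accumulation_thresholds = accumulation_thresholds,
    n_orderings = n_orderings, metric = metric, alpha = alpha,
    enrichment_alpha = enrichment_alpha, family = family,
    n_permutations = n_permutations, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; `remove_taxa` is a
#' list of `rank: label` maps.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$remove_taxa))
    y$remove_taxa <- do.call(rbind, lapply(y$remove_taxa, function(x)
      data.frame(rank = x$rank, label = x$label, stringsAsFactors = FALSE)))
  if (!is.null(y$accumulation_thresholds))
    y$accumulation_thresholds <- as.numeric(y$accumulation_thresholds)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full sampling-diagnostics pipeline
#'
#' Stages run in dependency order: organelle/kingdom filtering, contaminant
#' scoring and removal, named-taxon removal, CSS normalization, diversity
#' (Shannon, distances, PCoA, ANOSIM by site), sufficiency curves, cecal
#' pair report, and the swab-proxy / distance-decay / enrichment contrasts.
#' Every output file is listed in a JSON run manifest together with the full
#' parameter echo and per-stage feature/sample counts; rerunning with the
#' same configuration and seed reproduces every output byte-identically.
#'
#' @param config A [run_config()] (or a path to a YAML accepted by
#'   [read_run_config()]).
#' @return The run manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s", stage, msg))
    log[[length(log) + 1]] <<- list(stage = stage, note = msg)
  }

  ## ---- load ----
  if (!is.null(config$flock)) {
    fl <- config$flock
    table <- fl$table; meta <- fl$metadata
    taxonomy <- fl$taxonomy; tree <- fl$tree
  } else {
    table <- read_asv_table(config$inputs$table)
    meta <- read_metadata(config$inputs$metadata)
    taxonomy <- read_taxonomy(config$inputs$taxonomy)
    tree <- if (!is.null(config$inputs$tree)) read_tree(config$inputs$tree)
  }
  meta <- align_metadata(table, meta)
  note("load", "%d features x %d samples", nrow(table), ncol(table))

  ## ---- preprocessing ----
  table <- filter_nonbacterial(table, taxonomy)
  note("filter", "%d features after organelle/kingdom filter", nrow(table))
  if (any(meta$is_negative)) {
    report <- decontam_combo(table, meta,
                             threshold = config$decontam_threshold,
                             n_permutations = config$decontam_permutations,
                             seed = config$seed + 1L)
    outputs <- c(outputs, write_tsv(report,
                                    file.path(config$out_dir, "contaminants.tsv")))
    flagged <- report$feature_id[report$flagged]
    table <- as_asv(unclass(table)[!rownames(table) %in% flagged, ,
                                   drop = FALSE], normalized = FALSE)
    note("decontam", "%d feature(s) flagged and removed", length(flagged))
  } else {
    note("decontam", "no negative controls; stage skipped")
  }
  table <- suppressWarnings(remove_named_taxa(table, taxonomy,
                                              config$remove_taxa))
  note("remove_taxa", "%d features remain", nrow(table))
  ## negatives leave the analysis after contaminant scoring
  keep <- meta$sample_id[!meta$is_negative]
  raw <- as_asv(unclass(table)[, keep, drop = FALSE], normalized = FALSE)
  raw <- as_asv(unclass(raw)[rowSums(raw) > 0, , drop = FALSE],
                normalized = FALSE)
  meta_true <- meta[!meta$is_negative, , drop = FALSE]
  css <- css_normalize(raw, quantile_l = config$css_quantile,
                       scale = config$css_scale)
  norm <- css$table
  outputs <- c(outputs,
               write_tsv(css$factors, file.path(config$out_dir, "css_factors.tsv")))
  outputs <- c(outputs, write_asv_table(norm,
                                        file.path(config$out_dir, "normalized_table.tsv")))
  note("css", "normalized %d samples (quantile %.2f)", ncol(norm),
       config$css_quantile)

  ## ---- diversity ----
  sh <- apply(unclass(norm), 2, shannon)
  alpha_df <- data.frame(sample_id = names(sh), shannon = unname(sh),
                         site = meta_true$site[match(names(sh),
                                                     meta_true$sample_id)])
  outputs <- c(outputs, write_tsv(alpha_df,
                                  file.path(config$out_dir, "alpha_diversity.tsv")))
  dm <- if (config$metric == "bray") bray_curtis(norm) else
    weighted_unifrac(norm, tree)
  outputs <- c(outputs, write_distance_matrix(dm,
                                              file.path(config$out_dir, "distance_matrix.tsv")))
  ord <- pcoa(dm, axes = 2)
  outputs <- c(outputs, write_tsv(
    data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
    file.path(config$out_dir, "pcoa_coordinates.tsv")))
  an <- anosim(dm, meta_true$site[match(rownames(dm), meta_true$sample_id)],
               n_permutations = config$n_permutations,
               seed = config$seed + 2L)
  note("diversity", "ANOSIM by site: R = %.4f, p = %.4g", an$R, an$p)

  ## ---- sufficiency ----
  suff <- flock_sufficiency(raw, meta_true,
                            thresholds = config$accumulation_thresholds,
                            n_orderings = config$n_orderings,
                            seed = config$seed + 3L)
  curve_df <- do.call(rbind, lapply(suff$curves, function(cv)
    data.frame(site = cv$site, cv$steps)))
  outputs <- c(outputs, write_tsv(curve_df,
                                  file.path(config$out_dir, "accumulation_curves.tsv")))
  outputs <- c(outputs, write_tsv(suff$summary,
                                  file.path(config$out_dir, "sample_size_summary.tsv")))

  ## ---- cecal pairs ----
  pairs <- pair_report(norm, meta_true, dm)
  outputs <- c(outputs, write_tsv(pairs$birds,
                                  file.path(config$out_dir, "cecal_pairs.tsv")))

  ## ---- site contrasts ----
  proxy <- distance_to_swab(dm, meta_true, metric = config$metric)
  outputs <- c(outputs, write_tsv(proxy,
                                  file.path(config$out_dir, "distance_to_swab.tsv")))
  famcor <- family_correlation(norm, taxonomy, meta_true,
                               family = config$family)
  outputs <- c(outputs, write_tsv(famcor,
                                  file.path(config$out_dir, "family_correlation.tsv")))
  birds <- sort(unique(meta_true$bird_id))
  decay <- do.call(rbind, lapply(seq_along(birds), function(i) {
    fit <- distance_decay(dm, meta_true, birds[i],
                          n_permutations = config$n_permutations,
                          seed = config$seed + 10L + i)
    data.frame(bird_id = fit$bird_id, slope = fit$slope,
               intercept = fit$intercept, r = fit$r, p = fit$p,
               n_pairs = fit$n_pairs)
  }))
  outputs <- c(outputs, write_tsv(decay,
                                  file.path(config$out_dir, "distance_decay.tsv")))
  enrich <- suppressWarnings(
    cecal_enrichment(norm, meta_true, alpha = config$enrichment_alpha,
                     n_permutations = config$n_permutations,
                     seed = config$seed + 4L))
  outputs <- c(outputs, write_tsv(enrich,
                                  file.path(config$out_dir, "cecal_enrichment.tsv")))
  note("contrasts", "%d enriched, %d depleted at alpha %.3g",
       sum(enrich$status == "enriched"), sum(enrich$status == "depleted"),
       config$enrichment_alpha)

  ## ---- summary + manifest ----
  summary <- list(
    n_features = nrow(raw), n_samples = ncol(raw),
    anosim = list(R = an$R, p = an$p),
    sample_size = suff$summary,
    pair_summary = pairs$summary,
    family_correlation = famcor,
    n_enriched = sum(enrich$status == "enriched"),
    n_depleted = sum(enrich$status == "depleted"),
    decay_negative_slopes = sum(decay$slope < 0),
    decay_at_floor = sum(decay$p <= 1 / (config$n_permutations + 1) + 1e-12)
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  outputs <- c(outputs, summary_path)
  cfg_echo <- unclass(config)
  cfg_echo$flock <- if (!is.null(config$flock))
    list(regenerated_from_seed = config$flock$model$seed) else NULL
  manifest <- list(parameters = cfg_echo, seed = config$seed,
                   log = log, outputs = outputs)
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  manifest$outputs <- c(outputs, manifest_path)
  invisible(manifest)
}
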