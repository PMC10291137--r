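## Umbrella pipeline: simulate a cohort (or consume user tables), run every
## stage with the configured thresholds, write TSV outputs and a JSON
## manifest with parameter values and output checksums. Identical
## configuration and seed give identical checksums.

default_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_patients = 8L, n_genes = 2000L, n_me_genes = 200L,
                  n_variants_shared = 10L, n_variants_relapse_gained = 5L,
                  n_variants_pdx_private = 3L, fusion_tool_count = 5L),
    xenosplit = list(enabled = TRUE, k = 21L, n_pairs = 400L,
                     genome_length = 20000L, shared_fraction = 0.1,
                     read_length = 80L),
    variants = list(min_alt_reads = 5L, min_vaf = 0.05, max_popaf = 0.01,
                    fail_fraction = 0.1),
    cna = list(focal_threshold = 5e6, neutral_cn = 2L, as_printed = FALSE),
    fusions = list(min_tools = 3L),
    deconv = list(alpha = 0.05, min_fold = 4, absent_max_mean = 3),
    components = list(min_var = 0.05, alpha = 0.05, n_perm = 200L),
    proteomics = list(max_missing = 0.34, rank = 2L, n_proteins = 400L),
    growth = list(td_days = 5, v0 = 150, noise_cv = 0.05, n_mice = 8L,
                  window = c(200, 400))
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste0(path, nm), call. = FALSE)
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]], paste0(path, nm, "$"))
    else override[[nm]]
  }
  base
}

#' Pipeline configuration
#'
#' Returns the full default configuration, optionally overridden by a nested
#' list; unknown keys are rejected. Every threshold documented on the stage
#' functions appears here under its stage block.
#'
#' @param ... named top-level overrides (e.g. `seed = 7`, `variants =
#'   list(min_vaf = 0.1)`).
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  structure(merge_config(default_config(), list(...)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with (partial) configuration.
#' @export
read_pipeline_config <- function(path) {
  structure(merge_config(default_config(), yaml::read_yaml(path)),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates every input with the configured cohort, then executes read
#' partitioning (optional), variant filtering + Jaccard + conservation,
#' copy-number categorization + Jaccard, fusion consensus + validation +
#' conservation, tumor/ME expression deconvolution, component selection with
#' loading enrichment, proteomics filtering + imputation, and doubling-time
#' estimation. All outputs are TSV/JSON under `out_dir`; `manifest.json`
#' records the configuration and the MD5 checksum of every output file.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `config`, `files`,
#'   `checksums`, plus headline `summary` numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("pdxplore_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  summary <- list()

  ## --- xenosplit ---------------------------------------------------------
  if (isTRUE(config$xenosplit$enabled)) {
    xs <- config$xenosplit
    sim <- simulate_two_species_reads(xs$genome_length, xs$genome_length,
                                      xs$shared_fraction, xs$n_pairs,
                                      read_length = xs$read_length,
                                      seed = config$seed)
    idx <- build_kmer_index(sim$genomes["graft"], sim$genomes["host"], k = xs$k)
    res <- classify_pairs(sim$r1, sim$r2, idx, out_prefix = p("xenosplit"))
    acc <- mean(res$pairs$class == sim$truth$class)
    write_tsv(cbind(sim$truth, assigned = res$pairs$class), p("xenosplit_truth.tsv"))
    summary$xenosplit_accuracy <- acc
  }

  ## --- somatic variants --------------------------------------------------
  vc <- simulate_variant_cohort(spec, config$variants$fail_fraction)
  write_tsv(vc$calls, p("variants_calls.tsv"))
  fl <- filter_variants(vc$calls, config$variants$min_alt_reads,
                        config$variants$min_vaf, config$variants$max_popaf)
  write_tsv(fl$kept, p("variants_kept.tsv"))
  write_tsv(fl$rejected, p("variants_rejected.tsv"))
  sets <- variant_sets(vc$calls)
  jm <- pairwise_jaccard_matrix(sets)
  write_tsv(data.frame(sample = rownames(jm), jm, check.names = FALSE),
            p("variants_jaccard.tsv"))
  cons <- do.call(rbind, lapply(split(vc$calls, vc$calls$patient_id),
                                classify_conservation))
  rownames(cons) <- NULL
  write_tsv(cons, p("variants_conservation.tsv"))
  gain <- mutation_gain_ratio(vc$calls, "diagnosis", "relapse")
  write_tsv(gain$per_patient, p("variants_gain_ratio.tsv"))
  summary$mutation_gain_ratio_mean <- gain$mean

  ## --- copy number -------------------------------------------------------
  cna <- simulate_cna_profiles(spec)
  seg <- classify_segments(cna$segments, config$cna$focal_threshold,
                           config$cna$neutral_cn, config$cna$as_printed)
  write_tsv(seg, p("cna_segments.tsv"))
  cna_sets <- cna_alteration_sets(seg, cna$gene_intervals)
  cjm <- pairwise_jaccard_matrix(cna_sets)
  write_tsv(data.frame(sample = rownames(cjm), cjm, check.names = FALSE),
            p("cna_jaccard.tsv"))

  ## --- fusions -----------------------------------------------------------
  fu <- simulate_fusion_calls(spec, min_tools = config$fusions$min_tools)
  write_tsv(fu$calls, p("fusion_calls.tsv"))
  cand <- consensus_filter(fu$calls, config$fusions$min_tools,
                           tool_set = paste0("tool", seq_len(spec$fusion_tool_count)))
  write_tsv(cand, p("fusion_consensus.tsv"))
  val <- validate_breakpoints(cand, fu$evidence)
  write_tsv(val, p("fusion_validated.tsv"))
  fc <- fusion_conservation_counts(val)
  write_tsv(fc$per_fusion, p("fusion_conservation.tsv"))
  recovered <- sort(unique(val$key[val$validated]))
  summary$fusion_survivors_recovered <- length(recovered)
  summary$fusion_survivor_exact_match <-
    as.integer(setequal(recovered, fu$ground_truth$survivor_keys))

  ## --- expression deconvolution -----------------------------------------
  ex <- simulate_expression_cohort(spec)
  meta <- ex$sample_meta
  pat <- ex$human_counts[, meta$sample[meta$fraction == "patient"], drop = FALSE]
  pdxh <- ex$human_counts[, meta$sample[meta$fraction == "pdx_human"], drop = FALSE]
  me <- identify_me_genes(pat, pdxh, config$deconv$alpha,
                          config$deconv$min_fold, config$deconv$absent_max_mean)
  write_tsv(me$stats, p("deconv_me_stats.tsv"))
  tm <- build_tumor_matrix(ex$human_counts, me$me_genes)
  write_count_matrix(tm$matrix, p("deconv_tumor_counts.tsv"))
  truth_me <- ex$ground_truth$me_gene_ids
  summary$me_genes_removed <- tm$n_removed
  summary$me_recall <- length(intersect(me$me_genes, truth_me)) /
    max(length(truth_me), 1)
  summary$me_precision <- if (length(me$me_genes))
    length(intersect(me$me_genes, truth_me)) / length(me$me_genes) else NA_real_
  if (length(me$me_genes)) {
    xsme <- build_cross_species_me_matrix(
      ex$human_counts[me$me_genes, colnames(pat), drop = FALSE],
      ex$mouse_counts, ex$ortholog_map)
    write_tsv(data.frame(gene = rownames(xsme$matrix), xsme$matrix,
                         check.names = FALSE), p("deconv_cross_species.tsv"))
    write_tsv(xsme$dropped, p("deconv_dropped_genes.tsv"))
  }

  ## --- component analysis ------------------------------------------------
  logmat <- log1p(cpm(tm$matrix))
  dec <- decompose_expression(logmat)
  grp <- setNames(ifelse(meta$fraction[match(colnames(logmat), meta$sample)] ==
                           "patient", "patient", "pdx"), colnames(logmat))
  dec <- select_components(dec, grp, config$components$min_var,
                           config$components$alpha)
  write_tsv(dec$selection, p("components_selection.tsv"))
  write_tsv(data.frame(sample = rownames(dec$scores), dec$scores,
                       check.names = FALSE), p("components_scores.tsv"))
  summary$n_components_selected <- sum(dec$selected)
  gmt <- system.file("extdata", "toy_gene_sets.gmt", package = "pdxplore")
  if (nzchar(gmt) && any(dec$selected)) {
    comp1 <- which(dec$selected)[1]
    enr <- loading_enrichment(dec$loadings[, comp1], read_gmt(gmt),
                              n_perm = config$components$n_perm,
                              seed = config$seed)
    if (!is.null(enr$results))
      write_tsv(enr$results, p("components_enrichment.tsv"))
  }

  ## --- proteomics --------------------------------------------------------
  pm <- simulate_protein_matrix(n_proteins = config$proteomics$n_proteins,
                                seed = config$seed)
  filt <- filter_by_missingness(pm$observed, config$proteomics$max_missing)
  imp <- pca_impute(filt$matrix, rank = config$proteomics$rank)
  write_tsv(data.frame(protein = rownames(imp$matrix), imp$matrix,
                       check.names = FALSE), p("proteomics_imputed.tsv"))
  summary$proteins_kept <- filt$n_kept

  ## --- growth ------------------------------------------------------------
  g <- config$growth
  curves <- do.call(rbind, lapply(seq_len(g$n_mice), function(i) {
    cv <- simulate_growth_curve(g$v0, g$td_days, g$noise_cv, 0:30,
                                seed = config$seed * 1000L + i)
    data.frame(mouse_id = sprintf("mouse%02d", i), cv)
  }))
  write_tsv(curves, p("growth_volumes.tsv"))
  td <- doubling_time_table(curves, g$window)
  write_tsv(td, p("growth_td.tsv"))
  summary$td_mean_days <- mean(td$td_days, na.rm = TRUE)

  ## --- ground truth + manifest -------------------------------------------
  jsonlite::write_json(
    list(me_gene_ids = ex$ground_truth$me_gene_ids,
         variant_sets_per_sample = vc$ground_truth$variant_sets_per_sample,
         fusion_survivors = fu$ground_truth$survivor_keys,
         td_days = g$td_days),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(package = "pdxplore",
                   config = unclass(config),
                   summary = summary,
                   files = files,
                   checksums = checksums)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
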