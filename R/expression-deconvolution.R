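## Tumor / microenvironment expression deconvolution.
##
## In a PDX the human fraction of the reads comes from the tumor cells and
## the mouse fraction from the microenvironment (ME). Genes expressed in
## patient tumors but absent from the PDX human fraction are therefore
## ME-derived in the patient and are removed to isolate the tumor-cell
## program; their mouse orthologs, expressed in the PDX mouse fraction, form
## the cross-species ME matrix.

#' Identify microenvironment genes from patient vs PDX-human-fraction counts
#'
#' A gene is called ME iff (a) its library-size-normalized mean in the PDX
#' human fraction is at most `absent_max_mean` counts, and (b) a two-group
#' negative-binomial rate comparison (method-of-moments dispersion, Wald
#' test on the log-rate difference, Benjamini-Hochberg correction across
#' genes) rejects equality at `alpha` with a patient/PDX fold change of at
#' least `min_fold`. All-zero genes are excluded from testing and reported.
#'
#' @param patient_counts,pdx_human_counts gene x sample count matrices over
#'   a shared gene universe, >= 2 samples each.
#' @param alpha BH-adjusted significance level.
#' @param min_fold minimum patient/PDX normalized fold change.
#' @param absent_max_mean maximum normalized mean count in the PDX human
#'   fraction for a gene to count as absent there.
#' @return list with `me_genes` (character), `stats` (per-gene decision
#'   trace: means, fold, p, adjusted p, decision), `excluded` (all-zero
#'   genes).
#' @export
identify_me_genes <- function(patient_counts, pdx_human_counts,
                              alpha = 0.05, min_fold = 4,
                              absent_max_mean = 3) {
  genes <- intersect(rownames(patient_counts), rownames(pdx_human_counts))
  if (!length(genes)) stop("no shared genes", call. = FALSE)
  if (ncol(patient_counts) < 2 || ncol(pdx_human_counts) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  pa <- normalize_counts(patient_counts)[genes, , drop = FALSE]
  px <- normalize_counts(pdx_human_counts)[genes, , drop = FALSE]
  all_zero <- rowSums(pa) == 0 & rowSums(px) == 0
  test_genes <- genes[!all_zero]
  a <- pa[test_genes, , drop = FALSE]
  x <- px[test_genes, , drop = FALSE]
  na <- ncol(a); nx <- ncol(x)
  mu_a <- rowMeans(a); mu_x <- rowMeans(x)
  ## pooled method-of-moments NB dispersion: var = mu + phi mu^2
  phi_of <- function(m) {
    mu <- rowMeans(m); v <- apply(m, 1, var)
    pmax((v - mu) / pmax(mu^2, 1e-12), 0)
  }
  phi <- pmax(phi_of(a), phi_of(x))
  ## Wald statistic on log(mu_a) - log(mu_x); delta method:
  ## Var(log mean) ~ (1/mu + phi) / n, with a half-count floor on the mean
  floor_a <- 0.5 / na; floor_x <- 0.5 / nx
  la <- log(pmax(mu_a, floor_a)); lx <- log(pmax(mu_x, floor_x))
  se <- sqrt((1 / pmax(mu_a, floor_a) + phi) / na +
             (1 / pmax(mu_x, floor_x) + phi) / nx)
  z <- (la - lx) / se
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")
  fold <- pmax(mu_a, floor_a) / pmax(mu_x, floor_x)
  absent <- mu_x <= absent_max_mean
  is_me <- absent & padj < alpha & fold >= min_fold & mu_a > mu_x
  stats <- data.frame(gene = test_genes, mean_patient = mu_a,
                      mean_pdx_human = mu_x, dispersion = phi, fold = fold,
                      p_value = p, p_adj = padj, absent_in_pdx = absent,
                      is_me = is_me, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(me_genes = test_genes[is_me], stats = stats,
       excluded = genes[all_zero])
}

#' Remove ME genes to obtain the tumor expression matrix
#'
#' @param counts gene x sample count matrix (patient + PDX human fraction).
#' @param me_genes genes to remove; must be a subset of the gene universe.
#' @return list with `matrix` (counts without ME genes) and `n_removed`.
#' @export
build_tumor_matrix <- function(counts, me_genes) {
  if (!all(me_genes %in% rownames(counts)))
    stop("me_genes must be a subset of the gene universe", call. = FALSE)
  keep <- setdiff(rownames(counts), me_genes)
  if (!length(keep)) warning("all genes removed; tumor matrix is empty")
  list(matrix = counts[keep, , drop = FALSE],
       n_removed = length(intersect(me_genes, rownames(counts))))
}

#' Genes absent from the PDX mouse fraction
#'
#' A mouse gene is absent iff it has fewer than `max_reads` reads in every
#' mouse-fraction sample (a gene reaching the boundary in even one sample is
#' not absent).
#'
#' @param pdx_mouse_counts gene x sample counts of the mouse fraction.
#' @param max_reads threshold (default 3; the rule is strictly fewer).
#' @return character vector of absent gene ids.
#' @export
mouse_absent_genes <- function(pdx_mouse_counts, max_reads = 3) {
  rownames(pdx_mouse_counts)[apply(pdx_mouse_counts < max_reads, 1, all)]
}

#' Cross-species microenvironment expression matrix
#'
#' Maps ME genes to their mouse orthologs (only 1:1 pairs are kept; genes in
#' many-to-many relationships are dropped and reported), then merges patient
#' samples with PDX mouse-fraction samples on one gene axis. Each sample
#' group is library-size normalized (counts per million, log1p) and then
#' per-gene standardized within its group before merging, so the two
#' platforms/species are scaled by the nature of the samples.
#'
#' @param patient_me_counts ME-gene x patient-sample counts (human gene ids).
#' @param pdx_mouse_counts mouse-gene x mouse-fraction-sample counts.
#' @param ortholog_map data.frame with `human_gene`, `mouse_gene`.
#' @return list with `matrix` (rows = human gene ids of retained ME genes,
#'   columns = patient then mouse samples), `dropped` (data.frame: gene,
#'   reason in no_ortholog/many_to_many/absent_in_mouse_matrix) and
#'   `groups` (column group labels: patient / pdx_mouse).
#' @export
build_cross_species_me_matrix <- function(patient_me_counts, pdx_mouse_counts,
                                          ortholog_map) {
  genes <- rownames(patient_me_counts)
  dup_h <- ortholog_map$human_gene[duplicated(ortholog_map$human_gene)]
  dup_m <- ortholog_map$mouse_gene[duplicated(ortholog_map$mouse_gene)]
  one2one <- ortholog_map[!(ortholog_map$human_gene %in% dup_h) &
                            !(ortholog_map$mouse_gene %in% dup_m), , drop = FALSE]
  drop_rows <- function(g, reason) if (length(g))
    data.frame(gene = g, reason = reason, stringsAsFactors = FALSE) else NULL
  dropped <- rbind(
    drop_rows(setdiff(genes, ortholog_map$human_gene), "no_ortholog"),
    drop_rows(intersect(genes, unique(c(dup_h,
      ortholog_map$human_gene[ortholog_map$mouse_gene %in% dup_m]))),
      "many_to_many"))
  keep <- one2one[one2one$human_gene %in% genes, , drop = FALSE]
  in_mouse <- keep$mouse_gene %in% rownames(pdx_mouse_counts)
  dropped <- rbind(dropped,
                   drop_rows(keep$human_gene[!in_mouse], "absent_in_mouse_matrix"))
  if (is.null(dropped))
    dropped <- data.frame(gene = character(0), reason = character(0))
  keep <- keep[in_mouse, , drop = FALSE]
  if (!nrow(keep))
    stop("no ME gene has a retained 1:1 ortholog in the mouse matrix",
         call. = FALSE)
  norm <- function(m) row_standardize(log1p(cpm(m)))
  hm <- norm(patient_me_counts[keep$human_gene, , drop = FALSE])
  mm <- norm(pdx_mouse_counts[keep$mouse_gene, , drop = FALSE])
  rownames(mm) <- keep$human_gene
  merged <- cbind(hm, mm)
  rownames(dropped) <- NULL
  list(matrix = merged, dropped = dropped,
       groups = setNames(rep(c("patient", "pdx_mouse"),
                             c(ncol(hm), ncol(mm))), colnames(merged)))
}
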