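## Somatic-variant filtering and longitudinal set comparison.
##
## Filter defaults follow the standard exome practice for tumor cohorts:
## alterations with fewer than 5 supporting reads, a variant allele fraction
## below 5%, or a population allele frequency above 1% in either of two
## population databases are removed. Boundary values (exactly 5 reads,
## exactly 1% population frequency, exactly 5% VAF) are kept.

TIMEPOINTS <- c("diagnosis", "relapse", "pdx_sc", "pdx_pt")

#' Filter somatic variant calls
#'
#' Keeps a call iff `alt_reads >= min_alt_reads` AND `vaf >= min_vaf` AND
#' both population allele frequencies are `<= max_popaf`. Dropped calls are
#' returned with the rule(s) that fired. Calls with missing evidence fields
#' are rejected with reason `incomplete` (never silently kept); missing
#' population frequencies are treated as 0 unless `strict_missing = TRUE`.
#'
#' @param calls data.frame with at least `alt_reads`, `depth`, `vaf`,
#'   `popaf_1000g`, `popaf_kaviar`.
#' @param min_alt_reads minimum alt-supporting reads (kept at the boundary).
#' @param min_vaf minimum variant allele fraction (kept at the boundary).
#' @param max_popaf maximum population allele frequency in either database
#'   (kept at the boundary).
#' @param strict_missing treat missing population frequencies as failures
#'   instead of 0.
#' @return list with `kept` (data.frame), `rejected` (data.frame with an
#'   added `failed_rules` column, comma-separated).
#' @export
filter_variants <- function(calls, min_alt_reads = 5L, min_vaf = 0.05,
                            max_popaf = 0.01, strict_missing = FALSE) {
  if (min_vaf <= 0 || min_vaf > 1 || max_popaf <= 0 || max_popaf > 1)
    stop("proportion thresholds must be in (0, 1]", call. = FALSE)
  n <- nrow(calls)
  pop1 <- calls$popaf_1000g
  pop2 <- calls$popaf_kaviar
  if (!strict_missing) {
    pop1[is.na(pop1)] <- 0
    pop2[is.na(pop2)] <- 0
  }
  incomplete <- is.na(calls$alt_reads) | is.na(calls$vaf) |
    (strict_missing & (is.na(pop1) | is.na(pop2)))
  fail_support <- !is.na(calls$alt_reads) & calls$alt_reads < min_alt_reads
  fail_vaf <- !is.na(calls$vaf) & calls$vaf < min_vaf
  fail_pop <- (!is.na(pop1) & pop1 > max_popaf) |
    (!is.na(pop2) & pop2 > max_popaf)
  rules <- cbind(incomplete = incomplete, support = fail_support,
                 vaf = fail_vaf, population = fail_pop)
  keep <- rowSums(rules) == 0
  rejected <- calls[!keep, , drop = FALSE]
  rejected$failed_rules <- apply(rules[!keep, , drop = FALSE], 1, function(r)
    paste(colnames(rules)[r], collapse = ","))
  rownames(rejected) <- NULL
  kept <- calls[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Jaccard distance between two sets
#'
#' `1 - |A intersect B| / |A union B|`; the distance between two empty sets
#' is defined as 0.
#'
#' @param set_a,set_b vectors treated as sets (duplicates ignored).
#' @return distance in \[0, 1\].
#' @export
jaccard_distance <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Pairwise Jaccard distance matrix
#'
#' @param sets named list mapping sample id to a vector of set elements
#'   (variant keys, (gene, category) pairs, ...).
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_jaccard_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two samples", call. = FALSE)
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- jaccard_distance(sets[[i]], sets[[j]])
    m[i, j] <- d; m[j, i] <- d
  }
  m
}

#' Variant keys of a call table
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_keys <- function(calls) {
  if (!nrow(calls)) return(character(0))
  variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
}

#' Per-sample variant-key sets of a call table
#'
#' @param calls data.frame with `sample` plus key columns.
#' @return named list of key sets.
#' @export
variant_sets <- function(calls) {
  split(variant_keys(calls), calls$sample)
}

#' Classify longitudinal conservation of variants
#'
#' For each variant of a patient: `diagnosis-conserved` iff present at
#' diagnosis and in at least one PDX; `relapse-emergent` iff absent at
#' diagnosis, present at relapse and in at least one PDX; `pdx-private` iff
#' present only in PDX sample(s); everything else is `other` (e.g. present
#' only in patient samples). The origins partition the variants: each
#' variant gets exactly one.
#'
#' @param calls data.frame for one patient with `timepoint` plus key columns
#'   (`chrom`, `pos`, `ref`, `alt`, optionally `gene`).
#' @return data.frame with `key`, `gene`, `present_in` (comma-separated),
#'   `origin`.
#' @export
classify_conservation <- function(calls) {
  if (!all(calls$timepoint %in% TIMEPOINTS))
    stop("unknown timepoint label", call. = FALSE)
  if (length(unique(calls$timepoint)) < 2)
    stop("need at least two timepoints", call. = FALSE)
  key <- variant_keys(calls)
  gene <- if ("gene" %in% names(calls)) calls$gene else NA_character_
  present <- tapply(calls$timepoint, key, function(x) sort(unique(x)),
                    simplify = FALSE)
  genes <- tapply(gene, key, `[[`, 1L)
  pdx <- c("pdx_sc", "pdx_pt")
  origin <- vapply(present, function(p) {
    in_pdx <- any(p %in% pdx)
    if ("diagnosis" %in% p && in_pdx) "diagnosis-conserved"
    else if (!("diagnosis" %in% p) && "relapse" %in% p && in_pdx) "relapse-emergent"
    else if (all(p %in% pdx)) "pdx-private"
    else "other"
  }, "")
  data.frame(key = names(present),
             gene = as.character(genes[names(present)]),
             present_in = vapply(present, paste, "", collapse = ","),
             origin = unname(origin),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutation gain ratio between two timepoints
#'
#' Ratio of variant counts at the later timepoint over the earlier one, per
#' patient, with a cohort mean and standard deviation.
#'
#' @param calls cohort call table with `patient_id`, `timepoint` and key
#'   columns.
#' @param earlier,later timepoint labels to compare.
#' @return list with `per_patient` (data.frame: patient_id, n_earlier,
#'   n_later, ratio) and `mean`, `sd` over patients with a defined ratio.
#' @export
mutation_gain_ratio <- function(calls, earlier = "diagnosis", later = "relapse") {
  per <- lapply(split(calls, calls$patient_id), function(p) {
    ne <- length(unique(variant_keys(p[p$timepoint == earlier, , drop = FALSE])))
    nl <- length(unique(variant_keys(p[p$timepoint == later, , drop = FALSE])))
    data.frame(patient_id = p$patient_id[1], n_earlier = ne, n_later = nl,
               ratio = if (ne > 0) nl / ne else NA_real_)
  })
  per <- do.call(rbind, per); rownames(per) <- NULL
  ok <- !is.na(per$ratio)
  list(per_patient = per,
       mean = if (any(ok)) mean(per$ratio[ok]) else NA_real_,
       sd = if (sum(ok) > 1) sd(per$ratio[ok]) else NA_real_)
}

#' Gene x sample alteration (oncoprint) table
#'
#' Joins mutation, copy-number and fusion records on (gene, sample) for a
#' gene panel; each cell lists the alteration classes present,
#' comma-separated, empty if none.
#'
#' @param mutations data.frame with `gene`, `sample` (one row per mutation);
#'   NULL allowed.
#' @param cna_calls data.frame with `gene`, `sample`, `category`; NULL
#'   allowed.
#' @param fusions data.frame with `gene`, `sample`; NULL allowed.
#' @param gene_panel nonempty character vector of panel genes (rows).
#' @param samples column order; defaults to all samples seen.
#' @return character matrix gene x sample.
#' @export
oncoprint_table <- function(mutations = NULL, cna_calls = NULL, fusions = NULL,
                            gene_panel, samples = NULL) {
  if (!length(gene_panel)) stop("gene panel must be nonempty", call. = FALSE)
  recs <- rbind(
    if (!is.null(mutations) && nrow(mutations))
      data.frame(gene = mutations$gene, sample = mutations$sample,
                 class = "mutation", stringsAsFactors = FALSE),
    if (!is.null(cna_calls) && nrow(cna_calls))
      data.frame(gene = cna_calls$gene, sample = cna_calls$sample,
                 class = cna_calls$category, stringsAsFactors = FALSE),
    if (!is.null(fusions) && nrow(fusions))
      data.frame(gene = fusions$gene, sample = fusions$sample,
                 class = "fusion", stringsAsFactors = FALSE))
  if (is.null(samples))
    samples <- if (is.null(recs)) character(0) else sort(unique(recs$sample))
  out <- matrix("", length(gene_panel), length(samples),
                dimnames = list(gene_panel, samples))
  if (!is.null(recs)) {
    recs <- recs[recs$gene %in% gene_panel & recs$sample %in% samples, , drop = FALSE]
    if (nrow(recs)) {
      agg <- aggregate(class ~ gene + sample, data = recs,
                       FUN = function(x) paste(sort(unique(x)), collapse = ","))
      out[cbind(agg$gene, agg$sample)] <- agg$class
    }
  }
  out
}
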