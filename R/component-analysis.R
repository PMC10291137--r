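## PCA decomposition of deconvolved expression matrices, component selection
## (variance and species-separation rules), loading-based preranked gene-set
## enrichment, and the proteomics missingness filter + iterative-PCA
## imputation.

#' PCA decomposition of a gene x sample matrix
#'
#' Standard PCA on gene-centered data (the input is expected to be
#' log-normalized). The decomposition is deterministic up to component sign;
#' signs are fixed so the largest-magnitude loading of each component is
#' positive (ties broken by gene order).
#'
#' @param mat gene x sample numeric matrix.
#' @param n_components number of components to retain (default: all).
#' @return object of class `component_decomposition`: `scores` (sample x
#'   component), `loadings` (gene x component, orthonormal), `var_fraction`
#'   (over all components, non-increasing), `center` (per-gene means),
#'   `selected`/`rejection_reason` placeholders filled by
#'   [select_components()].
#' @export
decompose_expression <- function(mat, n_components = NULL) {
  if (ncol(mat) < 2) stop("need at least two samples", call. = FALSE)
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 var_fraction = var_fraction[seq_len(k)],
                 var_fraction_all = var_fraction,
                 center = pc$center,
                 selected = rep(NA, k),
                 rejection_reason = rep(NA_character_, k)),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("PCA decomposition: %d components over %d genes x %d samples\n",
              ncol(x$scores), nrow(x$loadings), nrow(x$scores)))
  cat("variance fractions:",
      paste(sprintf("%.3f", head(x$var_fraction, 8)), collapse = " "),
      if (length(x$var_fraction) > 8) "...\n" else "\n")
  invisible(x)
}

#' Select components by variance contribution and group separation
#'
#' A component is rejected if it contributes no more than `min_var` of the
#' overall variance (reason `low_variance`; "more than 5%" is strict, so a
#' component at exactly 5% is rejected). Surviving components are rejected
#' if their scores separate the two sample groups (patient vs PDX, or human
#' vs mouse) at BH-adjusted `alpha` in a two-sided rank-sum test (reason
#' `species_separation`); the remaining components are selected.
#'
#' @param dec a [decompose_expression()] result.
#' @param groups named character/factor vector over the score rows with two
#'   levels; with a single level the separation test is skipped (noted in
#'   the result).
#' @param min_var variance-fraction threshold (default 0.05).
#' @param alpha BH-adjusted level for the separation test.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return `dec` with `selected`, `rejection_reason` and a `selection`
#'   data.frame (component, var_fraction, p_separation, p_adj, selected,
#'   rejection_reason) filled in.
#' @export
select_components <- function(dec, groups, min_var = 0.05, alpha = 0.05,
                              test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(dec, "component_decomposition"))
  groups <- groups[rownames(dec$scores)]
  if (any(is.na(groups))) stop("groups must cover all samples", call. = FALSE)
  k <- ncol(dec$scores)
  reason <- rep("none", k)
  reason[dec$var_fraction <= min_var] <- "low_variance"
  p_sep <- rep(NA_real_, k)
  lv <- unique(as.character(groups))
  test_skipped <- length(lv) < 2
  idx <- which(reason == "none")
  if (!test_skipped && length(idx)) {
    for (j in idx) {
      s <- dec$scores[, j]
      p_sep[j] <- if (test == "wilcoxon")
        suppressWarnings(wilcox.test(s[groups == lv[1]],
                                     s[groups == lv[2]])$p.value)
      else t.test(s[groups == lv[1]], s[groups == lv[2]])$p.value
    }
    p_adj <- rep(NA_real_, k)
    p_adj[idx] <- p.adjust(p_sep[idx], method = "BH")
    reason[!is.na(p_adj) & p_adj < alpha] <- "species_separation"
  } else p_adj <- rep(NA_real_, k)
  dec$selected <- reason == "none"
  dec$rejection_reason <- reason
  dec$selection <- data.frame(
    component = seq_len(k), var_fraction = dec$var_fraction,
    p_separation = p_sep, p_adj = p_adj,
    selected = dec$selected, rejection_reason = reason,
    stringsAsFactors = FALSE)
  dec$separation_test_skipped <- test_skipped
  dec
}

#' Top contributing genes of a component
#'
#' The `n` genes of largest absolute loading, tagged with the loading sign;
#' ties are broken by gene id, lexicographically.
#'
#' @param dec a [decompose_expression()] result (or a gene-named loading
#'   vector).
#' @param component component index (ignored when `dec` is a vector).
#' @param n number of genes.
#' @return data.frame with `gene`, `loading`, `sign` (+/-), strongest first.
#' @export
top_contributors <- function(dec, component = 1L, n = 10L) {
  l <- if (inherits(dec, "component_decomposition"))
    dec$loadings[, component] else dec
  if (n > length(l)) stop("n exceeds the gene count", call. = FALSE)
  ord <- order(-abs(l), names(l))
  sel <- ord[seq_len(n)]
  data.frame(gene = names(l)[sel], loading = unname(l[sel]),
             sign = ifelse(l[sel] >= 0, "+", "-"),
             stringsAsFactors = FALSE, row.names = NULL)
}

## weighted Kolmogorov-Smirnov running-sum enrichment score for a set of hit
## positions within a ranked list; weights are |stat| at the hits.
## The running sum is piecewise linear, so its extrema lie just before or at
## hit positions; both candidate sets are examined.
gsea_es <- function(abs_stat, hit_pos) {
  n <- length(abs_stat); m <- length(hit_pos)
  if (m == 0 || m >= n) return(0)
  hit_pos <- sort(hit_pos)
  w <- abs_stat[hit_pos]
  W <- sum(w)
  if (W <= 0) return(0)
  miss <- (hit_pos - seq_len(m)) / (n - m)
  cw <- cumsum(w) / W
  after <- cw - miss
  before <- (cw - w / W) - miss
  cand <- as.vector(rbind(before, after))  # in running-sum order
  cand[which.max(abs(cand))]
}

#' Loading-based preranked gene-set enrichment for one component
#'
#' Genes are ranked by signed loading; the enrichment score is the extremum
#' of a weighted Kolmogorov-Smirnov running sum (weight = absolute loading,
#' the preranked-GSEA form). The null is gene-label permutation:
#' p = (1 + #\{|ES_perm| >= |ES_obs|\}) / (1 + n_perm), so the minimum
#' attainable p is 1/(n_perm + 1). P-values are BH-corrected across sets and
#' the direction is the ES sign.
#'
#' @param loadings named numeric vector (one component's gene loadings).
#' @param gene_sets named list of character vectors.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @param min_size sets with fewer than this many genes in the universe are
#'   skipped (reported in `skipped`).
#' @return list with `results` (data.frame: gene_set, size, es, p_value,
#'   p_adj, direction) and `skipped`.
#' @export
loading_enrichment <- function(loadings, gene_sets, n_perm = 1000L,
                               seed = NULL, min_size = 5L) {
  ord <- order(-loadings, names(loadings))
  ranked_genes <- names(loadings)[ord]
  abs_stat <- abs(loadings[ord])
  n <- length(ranked_genes)
  sizes <- vapply(gene_sets, function(s)
    length(intersect(s, ranked_genes)), integer(1))
  skipped <- names(gene_sets)[sizes < min_size | sizes >= n]
  use <- setdiff(names(gene_sets), skipped)
  res <- with_seed(seed, {
    do.call(rbind, lapply(use, function(nm) {
      hits <- which(ranked_genes %in% gene_sets[[nm]])
      es <- gsea_es(abs_stat, hits)
      m <- length(hits)
      es_perm <- vapply(seq_len(n_perm), function(i)
        gsea_es(abs_stat, sample.int(n, m)), numeric(1))
      p <- (1 + sum(abs(es_perm) >= abs(es))) / (1 + n_perm)
      data.frame(gene_set = nm, size = m, es = es, p_value = p,
                 direction = if (es >= 0) "positive" else "negative",
                 stringsAsFactors = FALSE)
    }))
  })
  if (!is.null(res)) {
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    res <- res[, c("gene_set", "size", "es", "p_value", "p_adj", "direction")]
    rownames(res) <- NULL
  }
  list(results = res, skipped = skipped)
}

#' Filter proteins by missing rate
#'
#' Keeps rows whose missing fraction is strictly below `max_missing` (a
#' protein missing 34% or more of its samples is dropped).
#'
#' @param mat protein x sample matrix with NA for missing values.
#' @param max_missing maximum tolerated missing fraction (default 0.34).
#' @return list with `matrix` (kept rows), `dropped` (row names), counts.
#' @export
filter_by_missingness <- function(mat, max_missing = 0.34) {
  frac <- rowMeans(is.na(mat))
  keep <- frac < max_missing
  list(matrix = mat[keep, , drop = FALSE],
       dropped = rownames(mat)[!keep],
       n_kept = sum(keep), n_dropped = sum(!keep))
}

#' Iterative low-rank (PCA) imputation of missing values
#'
#' Missing cells are initialized at row means, then the matrix is repeatedly
#' completed with its rank-`rank` PCA reconstruction (row-centered SVD) until
#' the largest change at a missing cell falls below `tol` or `max_iter` is
#' reached. Observed cells are never modified.
#'
#' @param mat matrix with NA for missing cells (rows should already pass the
#'   missingness filter).
#' @param rank reconstruction rank.
#' @param max_iter,tol convergence controls.
#' @return list with `matrix` (complete), `iterations`, `converged`.
#' @export
pca_impute <- function(mat, rank = 2L, max_iter = 1000L, tol = 1e-5) {
  miss <- is.na(mat)
  if (!any(miss)) return(list(matrix = mat, iterations = 0L, converged = TRUE))
  m <- mat
  rmeans <- rowMeans(mat, na.rm = TRUE)
  rmeans[is.nan(rmeans)] <- mean(mat, na.rm = TRUE)
  m[miss] <- rmeans[row(mat)[miss]]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- rowMeans(m)
    sv <- svd(m - mu, nu = rank, nv = rank)
    recon <- mu + sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- max(abs(recon[miss] - m[miss]))
    m[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("pca_impute did not converge in ", max_iter,
                          " iterations")
  list(matrix = m, iterations = it, converged = converged)
}
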