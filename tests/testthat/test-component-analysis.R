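test_that("PCA decomposition satisfies its algebraic identities", {
  set.seed(81)
  # rank-1 matrix: first component carries (essentially) all variance
  u <- rnorm(100); v <- rnorm(10)
  m1 <- outer(u, v)
  dimnames(m1) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10))
  dec1 <- decompose_expression(m1)
  expect_gt(dec1$var_fraction[1], 1 - 1e-6)
  expect_lt(sum(dec1$var_fraction[-1]), 1e-6)

  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:8)))
  dec <- decompose_expression(m)
  # reconstruction with all components reproduces the centered matrix
  recon <- dec$scores %*% t(dec$loadings)
  expect_lt(norm(recon - (t(m) - rep(1, 8) %o% dec$center), "F"), 1e-8)
  # orthonormal loadings
  gram <- t(dec$loadings) %*% dec$loadings
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # variance fractions: in [0,1], non-increasing, sum to 1 over all components
  expect_true(all(diff(dec$var_fraction_all) <= 1e-12))
  expect_equal(sum(dec$var_fraction_all), 1)
  # sign convention: largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(dec$loadings)))
    expect_gte(dec$loadings[which.max(abs(dec$loadings[, j])), j], 0)
  expect_error(decompose_expression(m[, 1, drop = FALSE]), "two samples")
})

test_that("a planted 3-factor structure is recovered in the top score subspace", {
  set.seed(82)
  n_genes <- 400; n_samp <- 16
  load <- matrix(rnorm(n_genes * 3), n_genes, 3)
  fact <- matrix(rnorm(n_samp * 3), n_samp, 3)
  m <- load %*% t(fact) * 3 + matrix(rnorm(n_genes * n_samp, 0, 0.5),
                                     n_genes, n_samp)
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:n_samp))
  dec <- decompose_expression(m, n_components = 3)
  cc <- stats::cancor(dec$scores, fact)$cor
  expect_true(all(cc > 0.95))
})

test_that("component selection applies variance then separation, boundaries strict", {
  mk_dec <- function(vf, scores) {
    k <- length(vf)
    structure(list(scores = scores, loadings = NULL, var_fraction = vf,
                   var_fraction_all = vf, center = NULL,
                   selected = rep(NA, k),
                   rejection_reason = rep(NA_character_, k)),
              class = "component_decomposition")
  }
  sc <- matrix(rnorm(16 * 3), 16, 3,
               dimnames = list(sprintf("s%02d", 1:16), NULL))
  groups <- setNames(rep(c("patient", "pdx"), each = 8), rownames(sc))
  # a perfectly separating component
  sc[, 1] <- c(rnorm(8, 5), rnorm(8, -5))
  dec <- select_components(mk_dec(c(0.30, 0.20, 0.049), sc), groups)
  expect_identical(dec$rejection_reason, c("species_separation", "none",
                                           "low_variance"))
  expect_identical(dec$selected, c(FALSE, TRUE, FALSE))
  # exactly 5% is NOT "more than 5%": rejected
  dec2 <- select_components(mk_dec(c(0.90, 0.05, 0.05), sc), groups)
  expect_identical(dec2$rejection_reason[2:3], rep("low_variance", 2))
  # degenerate limit: min_var = 0 and a single group selects everything
  one_group <- setNames(rep("all", 16), rownames(sc))
  dec3 <- select_components(mk_dec(c(0.6, 0.3, 0.1), sc), one_group, min_var = 0)
  expect_true(all(dec3$selected))
  expect_true(dec3$separation_test_skipped)
  expect_error(select_components(mk_dec(c(0.6, 0.4), sc[, 1:2]),
                                 groups[1:3]), "cover")
})

test_that("top contributors sort by |loading| with lexicographic tie-break", {
  l <- setNames(c(0.9, -0.8, 0.1), c("g1", "g2", "g3"))
  tc <- top_contributors(l, n = 2)
  expect_identical(tc$gene, c("g1", "g2"))
  expect_identical(tc$sign, c("+", "-"))
  # tie on magnitude: gene id decides
  l2 <- setNames(c(0.5, -0.5, 0.2), c("zz", "aa", "mm"))
  expect_identical(top_contributors(l2, n = 2)$gene, c("aa", "zz"))
  # random loadings: equals a brute-force sort
  set.seed(83)
  lr <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  want <- names(lr)[order(-abs(lr), names(lr))][1:10]
  expect_identical(top_contributors(lr, n = 10)$gene, want)
  expect_error(top_contributors(lr, n = 100), "exceeds")
})

test_that("enrichment score matches a brute-force running sum", {
  brute_es <- function(abs_stat, hits) {
    n <- length(abs_stat); m <- length(hits)
    w <- numeric(n); w[hits] <- abs_stat[hits]
    step <- ifelse(seq_len(n) %in% hits, w / sum(w), -1 / (n - m))
    D <- cumsum(step)
    D[which.max(abs(D))]
  }
  set.seed(84)
  for (i in 1:200) {
    n <- sample(30:80, 1); m <- sample(3:10, 1)
    st <- abs(rnorm(n)); h <- sample(n, m)
    a <- pdxplore:::gsea_es(st, h)
    b <- brute_es(st, h)
    expect_equal(abs(a), abs(b), tolerance = 1e-12)
  }
})

test_that("loading enrichment finds planted sets and respects its permutation floor", {
  set.seed(85)
  l <- setNames(rnorm(500), sprintf("G%04d", 1:500))
  top20 <- names(sort(-l))[1:20]
  res <- loading_enrichment(l, list(planted = top20), n_perm = 1000, seed = 1)
  expect_gt(res$results$es, 0)
  expect_lte(res$results$p_value, 0.01)
  # minimum attainable p-value is 1/(n_perm + 1)
  expect_gte(res$results$p_value, 1 / 1001)
  expect_identical(res$results$direction, "positive")
  # antisymmetry on a tie-free planted case: ES flips sign exactly
  res_rev <- loading_enrichment(-l, list(planted = top20), n_perm = 10, seed = 1)
  expect_equal(res_rev$results$es, -res$results$es)
  # sets below the size floor are skipped and reported
  res_small <- loading_enrichment(l, list(tiny = top20[1:3]), n_perm = 10)
  expect_identical(res_small$skipped, "tiny")
  expect_null(res_small$results)
})

test_that("enrichment score agrees with an independent preranked implementation", {
  set.seed(86)
  l <- setNames(rnorm(300), sprintf("G%04d", 1:300))
  ord <- order(-l, names(l))
  stats_sorted <- l[ord]
  for (i in 1:20) {
    hits <- sort(sample(300, 15))
    mine <- pdxplore:::gsea_es(abs(stats_sorted), hits)
    ref <- fgsea::calcGseaStat(stats_sorted, selectedStats = hits, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("missingness filter drops proteins at or above the threshold", {
  m <- matrix(1, 3, 8, dimnames = list(c("full", "a", "b"), paste0("s", 1:8)))
  m["a", 1:3] <- NA   # 37.5% missing: dropped
  m["b", 1:2] <- NA   # 25%: kept
  f <- filter_by_missingness(m)
  expect_setequal_chr(rownames(f$matrix), c("full", "b"))
  expect_identical(f$dropped, "a")
  expect_identical(f$n_kept + f$n_dropped, 3L)
  # exactly 34% missing is dropped ("less than 34%")
  m2 <- matrix(1, 1, 50); m2[1, 1:17] <- NA
  expect_identical(filter_by_missingness(m2)$n_kept, 0L)
})

test_that("pca imputation preserves observed cells and beats row means on low rank", {
  pm <- simulate_protein_matrix(n_proteins = 200, n_samples = 8, seed = 87)
  f <- filter_by_missingness(pm$observed)
  imp <- pca_impute(f$matrix, rank = 2)
  expect_true(imp$converged)
  obs <- !is.na(f$matrix)
  expect_identical(imp$matrix[obs], f$matrix[obs])
  # identity when nothing is missing
  full <- matrix(rnorm(40), 8, 5)
  expect_identical(pca_impute(full, rank = 2)$matrix, full)
  # held-out RMSE better than row-mean imputation across seeds
  wins <- 0L
  for (s in 88:92) {
    pm <- simulate_protein_matrix(n_proteins = 200, n_samples = 8, seed = s)
    f <- filter_by_missingness(pm$observed)
    miss <- is.na(f$matrix)
    truth <- pm$complete[rownames(f$matrix), ]
    imp <- pca_impute(f$matrix, rank = 2)
    base <- f$matrix
    base[miss] <- rowMeans(f$matrix, na.rm = TRUE)[row(base)[miss]]
    rmse <- function(x) sqrt(mean((x[miss] - truth[miss])^2))
    wins <- wins + (rmse(imp$matrix) < rmse(base))
  }
  expect_gte(wins, 4L)
})
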