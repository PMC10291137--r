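base_call <- function(alt_reads = 50, depth = 200, vaf = 0.3,
                      p1 = 0, p2 = 0) {
  data.frame(sample = "s", chrom = "chr1", pos = 100, ref = "A", alt = "T",
             alt_reads = alt_reads, depth = depth, vaf = vaf,
             popaf_1000g = p1, popaf_kaviar = p2, stringsAsFactors = FALSE)
}

test_that("filter keeps boundary values and rejects strictly below/above", {
  # fewer than five supporting reads are removed; exactly five are kept
  expect_identical(nrow(filter_variants(base_call(alt_reads = 4))$kept), 0L)
  expect_identical(nrow(filter_variants(base_call(alt_reads = 5))$kept), 1L)
  # population frequency above 1% removed, exactly 1% kept
  r <- filter_variants(base_call(p1 = 0.02))
  expect_identical(nrow(r$kept), 0L)
  expect_match(r$rejected$failed_rules, "population")
  expect_identical(nrow(filter_variants(base_call(p1 = 0.01, p2 = 0.01))$kept), 1L)
  expect_identical(nrow(filter_variants(base_call(p2 = 0.011))$kept), 0L)
  # VAF below 5% removed, exactly 5% kept
  expect_identical(nrow(filter_variants(base_call(vaf = 0.049))$kept), 0L)
  expect_identical(nrow(filter_variants(base_call(vaf = 0.05))$kept), 1L)
  # several rules can fire at once
  r2 <- filter_variants(base_call(alt_reads = 2, vaf = 0.01, p1 = 0.5))
  expect_identical(r2$rejected$failed_rules, "support,vaf,population")
})

test_that("missing evidence is never silently kept", {
  r <- filter_variants(base_call(vaf = NA))
  expect_identical(nrow(r$kept), 0L)
  expect_match(r$rejected$failed_rules, "incomplete")
  # missing population AF defaults to 0 (kept), strict mode rejects
  expect_identical(nrow(filter_variants(base_call(p1 = NA))$kept), 1L)
  expect_identical(nrow(filter_variants(base_call(p1 = NA),
                                        strict_missing = TRUE)$kept), 0L)
})

test_that("filter agrees with an independent predicate oracle and is idempotent", {
  calls <- random_calls(1000, seed = 31)
  res <- filter_variants(calls)
  oracle_keep <- vapply(seq_len(nrow(calls)), function(i) {
    c <- calls[i, ]
    isTRUE(c$alt_reads >= 5) && isTRUE(c$vaf >= 0.05) &&
      isTRUE(c$popaf_1000g <= 0.01) && isTRUE(c$popaf_kaviar <= 0.01)
  }, logical(1))
  expect_identical(nrow(res$kept), sum(oracle_keep))
  expect_setequal_chr(
    paste(variant_keys(res$kept), res$kept$sample),
    paste(variant_keys(calls), calls$sample)[oracle_keep])
  # idempotence: filtering the kept set changes nothing
  res2 <- filter_variants(res$kept)
  expect_identical(res2$kept, res$kept)
  expect_identical(nrow(res2$rejected), 0L)
})

test_that("jaccard distance matches its definition on hand cases", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(c("v1", "v2", "v3"), c("v2", "v3", "v4")), 0.5)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  expect_equal(jaccard_distance(c("a", "a", "b"), c("b", "a")), 0)  # sets
})

test_that("pairwise jaccard matrix is symmetric, zero-diagonal, in [0,1]", {
  set.seed(7)
  sets <- lapply(1:10, function(i) sample(letters, sample(3:15, 1)))
  names(sets) <- paste0("s", 1:10)
  m <- pairwise_jaccard_matrix(sets)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  for (i in 1:10) for (j in 1:10)
    expect_equal(m[i, j], jaccard_distance(sets[[i]], sets[[j]]))
  # triangle inequality (Jaccard distance is a metric)
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  expect_error(pairwise_jaccard_matrix(sets[1]), "two samples")
})

test_that("planted cohort Jaccard follows closed-form set arithmetic", {
  spec <- cohort_spec(n_patients = 1, n_variants_shared = 10,
                      n_variants_relapse_gained = 6,
                      n_variants_pdx_private = 0, seed = 12)
  sets <- simulate_variant_cohort(spec)$ground_truth$variant_sets_per_sample
  # diagnosis (10) vs relapse (16): intersection 10, union 16
  expect_equal(jaccard_distance(sets$M01_Pat_D, sets$M01_Pat_R), 1 - 10 / 16)
  # relapse vs PDX identical sets
  expect_equal(jaccard_distance(sets$M01_Pat_R, sets$M01_PDX_sc), 0)
  # diagnosis-relapse distance exceeds relapse-PDX distance
  expect_gt(jaccard_distance(sets$M01_Pat_D, sets$M01_Pat_R),
            jaccard_distance(sets$M01_Pat_R, sets$M01_PDX_pt))
})

test_that("conservation origins follow the presence rules and partition", {
  mk <- function(tps) data.frame(sample = tps, timepoint = tps, chrom = "chr1",
                                 pos = 1, ref = "A", alt = "T", gene = "G1")
  expect_identical(classify_conservation(
    mk(c("diagnosis", "relapse", "pdx_sc", "pdx_pt")))$origin,
    "diagnosis-conserved")
  expect_identical(classify_conservation(mk(c("relapse", "pdx_sc")))$origin,
                   "relapse-emergent")
  expect_identical(classify_conservation(mk(c("pdx_pt", "pdx_sc")))$origin,
                   "pdx-private")
  expect_identical(classify_conservation(mk(c("diagnosis", "relapse")))$origin,
                   "other")
  expect_error(classify_conservation(mk(c("dx", "relapse"))), "timepoint")
  # each variant gets exactly one origin
  spec <- cohort_spec(n_patients = 2, seed = 14)
  vc <- simulate_variant_cohort(spec)
  for (p in split(vc$calls, vc$calls$patient_id)) {
    rec <- classify_conservation(p)
    expect_identical(anyDuplicated(rec$key), 0L)
    expect_true(all(rec$origin %in% c("diagnosis-conserved", "relapse-emergent",
                                      "pdx-private", "other")))
    expect_identical(nrow(rec), length(unique(variant_keys(p))))
  }
})

test_that("mutation gain ratio is count arithmetic with cohort summary", {
  calls <- rbind(
    data.frame(sample = "p_D", patient_id = "p", timepoint = "diagnosis",
               chrom = "chr1", pos = 1:10, ref = "A", alt = "T"),
    data.frame(sample = "p_R", patient_id = "p", timepoint = "relapse",
               chrom = "chr1", pos = 1:15, ref = "A", alt = "T"))
  r <- mutation_gain_ratio(calls)
  expect_equal(r$per_patient$ratio, 1.5)
  # identical sets give 1.0
  calls2 <- calls[calls$pos <= 10, ]
  expect_equal(mutation_gain_ratio(calls2)$per_patient$ratio, 1.0)
  # planted cohort: shared = 10, relapse-gained = 5, no losses -> 1.5 always
  spec <- cohort_spec(n_patients = 4, n_variants_shared = 10,
                      n_variants_relapse_gained = 5,
                      n_variants_pdx_private = 3, seed = 20)
  g <- mutation_gain_ratio(simulate_variant_cohort(spec)$calls)
  expect_true(all(g$per_patient$ratio == 1.5))
  expect_equal(g$mean, 1.5)
  # empty earlier set -> missing ratio
  calls3 <- calls[calls$timepoint == "relapse", ]
  expect_true(is.na(mutation_gain_ratio(calls3)$per_patient$ratio))
})

test_that("oncoprint table equals a brute-force (gene, sample) join", {
  panel <- c("G1", "G2", "G3")
  empty <- oncoprint_table(gene_panel = panel, samples = c("s1", "s2"))
  expect_identical(dim(empty), c(3L, 2L))
  expect_true(all(empty == ""))
  one <- oncoprint_table(mutations = data.frame(gene = "G2", sample = "s1"),
                         gene_panel = panel)
  expect_identical(sum(one != ""), 1L)
  expect_identical(one["G2", "s1"], "mutation")

  set.seed(41)
  mut <- data.frame(gene = sample(paste0("G", 1:5), 20, TRUE),
                    sample = sample(c("s1", "s2", "s3"), 20, TRUE))
  cnv <- data.frame(gene = sample(paste0("G", 1:5), 10, TRUE),
                    sample = sample(c("s1", "s2", "s3"), 10, TRUE),
                    category = sample(c("gain", "deletion"), 10, TRUE))
  fus <- data.frame(gene = sample(paste0("G", 1:5), 6, TRUE),
                    sample = sample(c("s1", "s2", "s3"), 6, TRUE))
  tab <- oncoprint_table(mut, cnv, fus, gene_panel = paste0("G", 1:4))
  for (g in paste0("G", 1:4)) for (s in colnames(tab)) {
    want <- sort(unique(c(
      if (any(mut$gene == g & mut$sample == s)) "mutation",
      cnv$category[cnv$gene == g & cnv$sample == s],
      if (any(fus$gene == g & fus$sample == s)) "fusion")))
    expect_identical(tab[g, s], paste(want, collapse = ","))
  }
  expect_error(oncoprint_table(gene_panel = character(0)), "nonempty")
})
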