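test_that("index construction validates inputs", {
  expect_error(build_kmer_index("ACGT", "ACGT", k = 20), "odd")
  expect_error(build_kmer_index("ACGT", "ACGT", k = 9), "odd|\\[11")
  expect_error(build_kmer_index(character(0), "ACGTACGT", k = 15), "empty")
})

test_that("index separates, shares and canonicalizes k-mers correctly", {
  graft <- strrep("A", 100)
  host <- strrep("C", 100)
  idx <- build_kmer_index(graft, host, k = 15)
  expect_length(idx$shared, 0)
  expect_identical(idx$graft_only, strrep("A", 15))
  # canonical form: CCCC... stays (C < G)
  expect_identical(idx$host_only, strrep("C", 15))

  same <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  idx2 <- build_kmer_index(same, same, k = 15)
  expect_length(idx2$graft_only, 0)
  expect_length(idx2$host_only, 0)
  expect_gt(length(idx2$shared), 0)
  # three sets pairwise disjoint
  expect_length(intersect(idx2$shared, c(idx2$graft_only, idx2$host_only)), 0)
})

test_that("a block copied into both genomes yields exactly its k-mers as shared", {
  set.seed(21)
  block <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  g_rest <- strrep("A", 200)
  h_rest <- strrep("C", 200)
  idx <- build_kmer_index(paste0(block, g_rest), paste0(block, h_rest), k = 15)
  # brute-force enumeration of the block's canonical 15-mers (30 - 15 + 1 = 16)
  brute <- vapply(1:16, function(i) substr(block, i, i + 14), "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(brute)))
  brute_canon <- unique(ifelse(brute <= rc, brute, rc))
  expect_length(brute_canon, 16)
  # boundary k-mers spanning block/rest junctions may add shared k-mers only
  # if they coincide across genomes; with disjoint homopolymer tails they don't
  expect_setequal_chr(intersect(idx$shared, brute_canon), brute_canon)
  expect_length(setdiff(idx$shared, brute_canon), 0)
})

test_that("read classification follows the five-class evidence rule", {
  graft <- paste(rep("ACGGT", 40), collapse = "")   # periodic, distinct content
  host <- paste(rep("TTGCA", 40), collapse = "")
  idx <- build_kmer_index(graft, host, k = 11)
  expect_identical(classify_read(substr(graft, 1, 40), idx)$klass, "graft")
  expect_identical(classify_read(substr(host, 1, 40), idx)$klass, "host")
  mixed <- paste0(substr(graft, 1, 20), substr(host, 1, 20))
  expect_identical(classify_read(mixed, idx)$klass, "ambiguous")
  expect_identical(classify_read(strrep("N", 40), idx)$klass, "neither")
  # shared-only content
  shared_block <- "GATTACAGATTACAGATTACA"
  idx2 <- build_kmer_index(paste0(shared_block, strrep("A", 100)),
                           paste0(shared_block, strrep("C", 100)), k = 11)
  expect_identical(classify_read(shared_block, idx2)$klass, "both")
  # shorter than k -> neither, counted
  res <- classify_reads(c("ACGT", substr(graft, 1, 40)), idx)
  expect_identical(res$klass, c("neither", "graft"))
  expect_identical(attr(res, "n_too_short"), 1L)
})

test_that("per-read k-mer counts sum to read_length - k + 1", {
  sim <- simulate_two_species_reads(5000, 5000, 0.3, 100, read_length = 60,
                                    seed = 13)
  idx <- build_kmer_index(sim$genomes["graft"], sim$genomes["host"], k = 21)
  res <- classify_reads(sim$r1$seq, idx)
  tot <- res$n_graft_kmers + res$n_host_kmers + res$n_shared_kmers +
    res$n_absent_kmers
  expect_true(all(tot == 60 - 21 + 1))
})

test_that("pair resolution matches an independent rule statement, exhaustively", {
  classes <- c("graft", "host", "both", "neither", "ambiguous")
  grid <- expand.grid(c1 = classes, c2 = classes, stringsAsFactors = FALSE)
  # independent re-statement of the contract
  oracle <- function(c1, c2) {
    if (c1 == "ambiguous" || c2 == "ambiguous") return("ambiguous")
    if (setequal(c(c1, c2), c("graft", "host"))) return("ambiguous")
    if ("graft" %in% c(c1, c2)) return("graft")
    if ("host" %in% c(c1, c2)) return("host")
    if ("both" %in% c(c1, c2)) return("both")
    "neither"
  }
  expected <- mapply(oracle, grid$c1, grid$c2)
  expect_identical(combine_pair_classes(grid$c1, grid$c2), unname(expected))
  expect_error(combine_pair_classes("graft", "weird"), "unknown")
})

test_that("pair classification partitions input and respects canonicalization", {
  sim <- simulate_two_species_reads(20000, 20000, 0.15, 400, read_length = 80,
                                    seed = 17)
  idx <- build_kmer_index(sim$genomes["graft"], sim$genomes["host"], k = 21)
  res <- classify_pairs(sim$r1, sim$r2, idx)
  expect_identical(sum(res$summary$n_pairs), 400L)
  expect_gt(mean(res$pairs$class == sim$truth$class), 0.99)
  # reverse-complementing every read leaves classifications unchanged
  rc <- function(df) {
    df$seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(df$seq)))
    df
  }
  res_rc <- classify_pairs(rc(sim$r1), rc(sim$r2), idx)
  expect_identical(res$pairs$class1, res_rc$pairs$class1)
  expect_identical(res$pairs$class, res_rc$pairs$class)
})

test_that("classify_pairs writes five FASTQ pairs plus a summary", {
  sim <- simulate_two_species_reads(5000, 5000, 0.2, 60, read_length = 50,
                                    seed = 19)
  idx <- build_kmer_index(sim$genomes["graft"], sim$genomes["host"], k = 21)
  pre <- file.path(tempdir(), "xs_test")
  res <- classify_pairs(sim$r1, sim$r2, idx, out_prefix = pre)
  for (cl in c("graft", "host", "both", "neither", "ambiguous")) {
    r1 <- read_fastq(sprintf("%s_%s_1.fastq", pre, cl))
    r2 <- read_fastq(sprintf("%s_%s_2.fastq", pre, cl))
    expect_identical(nrow(r1), res$summary$n_pairs[res$summary$class == cl])
    expect_identical(r1$id, r2$id)
  }
  expect_error(classify_pairs(sim$r1, sim$r2[-1, ], idx), "different numbers")
})
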