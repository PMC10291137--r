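# Shared fixtures built in code.

# random variant-call table spanning the filter-threshold boundaries
random_calls <- function(n, seed) {
  set.seed(seed)
  alt <- sample(c(0:10, 20, 50), n, replace = TRUE)
  depth <- alt + sample(0:200, n, replace = TRUE)
  data.frame(
    sample = sample(c("s1", "s2"), n, replace = TRUE),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = "A", alt = "T",
    alt_reads = alt, depth = depth,
    vaf = sample(c(0, 0.01, 0.049, 0.05, 0.051, round(runif(20), 3)), n,
                 replace = TRUE),
    popaf_1000g = sample(c(0, 0.005, 0.01, 0.0101, 0.02, 0.5), n, replace = TRUE),
    popaf_kaviar = sample(c(0, 0.005, 0.01, 0.0101, 0.02, 0.5), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# two-exon toy gene models for fusion typing
toy_gene_models <- function() {
  list(
    # "+" strand, coding span 1000 bases across two 500-base exons
    GP = list(strand = "+", exons = data.frame(start = c(1000, 3000),
                                               end = c(1500, 3500))),
    GQ = list(strand = "+", exons = data.frame(start = c(5000, 7000),
                                               end = c(5500, 7500))),
    # "-" strand gene: transcript direction runs from high to low coordinates
    GR = list(strand = "-", exons = data.frame(start = c(9000, 11000),
                                               end = c(9500, 11500))),
    GS = list(strand = "+", exons = data.frame(start = c(100, 400),
                                               end = c(300, 900)))
  )
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
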