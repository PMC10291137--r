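## Readers and writers for the plain-text interchange formats the pipeline
## uses. TSVs carry documented headers; FASTA/FASTQ go through Biostrings
## for reading, and FASTQ records are written with a constant Phred+33
## quality so outputs are byte-reproducible.

#' Read / write FASTQ
#'
#' @param path file path.
#' @return `read_fastq`: data.frame with `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = unname(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with `id`, `seq`.
#' @param qual_char constant quality character (Phred+33).
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  if (nrow(reads)) {
    qual <- strrep(qual_char, nchar(reads$seq))
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a minimal VCF into the variant-call table layout
#'
#' Accepts a plain VCF with `AD` (alt-supporting reads), `DP` (depth), `AF`
#' (variant allele fraction) and optionally `POPAF1`/`POPAF2` keys in INFO;
#' returns the same columns as [simulate_variant_cohort()] calls tables
#' (without cohort metadata).
#'
#' @param path VCF path.
#' @param sample sample id to stamp on the rows.
#' @return data.frame of variant calls.
#' @export
read_variants_vcf <- function(path, sample = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      alt_reads = integer(0), depth = integer(0),
                      vaf = numeric(0), popaf_1000g = numeric(0),
                      popaf_kaviar = numeric(0)))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    out <- rep(NA_character_, length(info))
    out[m != -1L] <- sub(paste0(".*", key, "="), "", regmatches(info, m))
    suppressWarnings(as.numeric(out))
  }
  info <- f[[8]]
  data.frame(sample = sample, chrom = f[[1]], pos = as.integer(f[[2]]),
             ref = f[[4]], alt = f[[5]],
             alt_reads = as.integer(info_get(info, "AD")),
             depth = as.integer(info_get(info, "DP")),
             vaf = info_get(info, "AF"),
             popaf_1000g = info_get(info, "POPAF1"),
             popaf_kaviar = info_get(info, "POPAF2"),
             stringsAsFactors = FALSE)
}

#' @rdname read_variants_vcf
#' @param calls variant-call data.frame.
#' @export
write_variants_vcf <- function(calls, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
              "##INFO=<ID=POPAF1,Number=1,Type=Float,Description=\"Population AF, db 1\">",
              "##INFO=<ID=POPAF2,Number=1,Type=Float,Description=\"Population AF, db 2\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAD=%d;DP=%d;AF=%g;POPAF1=%g;POPAF2=%g",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  calls$alt_reads, calls$depth, calls$vaf,
                  calls$popaf_1000g, calls$popaf_kaviar)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene x sample count matrix with its sidecar metadata
#'
#' The counts TSV has a `gene` column followed by one column per sample; the
#' metadata TSV has columns `sample`, `species`, `fraction`, `patient`,
#' `timepoint`.
#'
#' @param counts_path,meta_path file paths.
#' @return list with `counts` (integer matrix) and `sample_meta`.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  ct <- read_tsv(counts_path)
  genes <- ct$gene
  mat <- as.matrix(ct[, -1])
  rownames(mat) <- genes
  meta <- as.data.frame(read_tsv(meta_path))
  if (!all(colnames(mat) %in% meta$sample))
    stop("metadata does not cover all samples", call. = FALSE)
  list(counts = mat, sample_meta = meta)
}

#' @rdname read_count_matrix
#' @param counts gene x sample matrix.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated (name, description,
#' members...).
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nchar(lines) > 0]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  writeLines(vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
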