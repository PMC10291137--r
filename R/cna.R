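## Copy-number segment categorization and gene-level annotation.
##
## Categories follow the integer-copy-number convention: deletion (= 0),
## loss (= 1), gain (>= 2 and < 7), amplification (>= 7 copies), focal
## amplification (>= 7 copies on less than 5 Mb). Read literally the gain
## rule includes the diploid-neutral state, which would call every normal
## segment a gain; by default copy number equal to `neutral_cn` (2) is
## labeled neutral and excluded from alteration sets, and `as_printed = TRUE`
## restores the literal rule.

CNA_CATEGORIES <- c("focal_amplification", "amplification", "gain",
                    "neutral", "loss", "deletion")

#' Categorize copy-number segments
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based,
#'   half-open: inclusive start, exclusive end) and `total_cn` (integer >= 0).
#' @param focal_threshold segment length (bases) below which a >= 7-copy
#'   segment is focal; the boundary is strict (a segment of exactly 5 Mb is
#'   an amplification).
#' @param neutral_cn copy number labeled neutral (default 2).
#' @param as_printed if TRUE, `neutral_cn` segments are labeled gain (the
#'   literal ">= 2 and < 7" rule).
#' @return `segments` with an added `category` column; every segment gets
#'   exactly one label.
#' @export
classify_segments <- function(segments, focal_threshold = 5e6,
                              neutral_cn = 2L, as_printed = FALSE) {
  cn <- segments$total_cn
  if (any(is.na(cn)) || any(cn < 0) || any(cn != floor(cn)))
    stop("total_cn must be non-negative integers", call. = FALSE)
  if (any(segments$start >= segments$end))
    stop("segments must satisfy start < end", call. = FALSE)
  len <- segments$end - segments$start
  category <- ifelse(cn == 0, "deletion",
              ifelse(cn == 1, "loss",
              ifelse(cn >= 7 & len < focal_threshold, "focal_amplification",
              ifelse(cn >= 7, "amplification",
              ifelse(!as_printed & cn == neutral_cn, "neutral", "gain")))))
  segments$category <- category
  segments
}

#' @rdname classify_segments
#' @param seg a single-segment list/data.frame row.
#' @return `classify_segment`: the category label.
#' @export
classify_segment <- function(seg, focal_threshold = 5e6, neutral_cn = 2L,
                             as_printed = FALSE) {
  classify_segments(as.data.frame(seg), focal_threshold, neutral_cn,
                    as_printed)$category
}

#' Gene-level copy-number calls from segments
#'
#' A gene inherits the category of any overlapping non-neutral segment
#' (overlap = at least one shared base under half-open intervals). When
#' several segments overlap one gene, the most extreme category per
#' direction wins (focal_amplification > amplification > gain;
#' deletion > loss); a gene spanning segments of both directions yields one
#' call per direction. Output is independent of segment input order.
#'
#' @param segments categorized segments (see [classify_segments()]) for one
#'   sample, columns `chrom`, `start`, `end`, `category`.
#' @param gene_intervals data.frame with `gene`, `chrom`, `start`, `end`
#'   (same half-open convention).
#' @return data.frame with `gene`, `category` (zero rows if no gene overlaps
#'   an altered segment), sorted by gene then category.
#' @export
annotate_genes <- function(segments, gene_intervals) {
  alt <- segments[segments$category != "neutral", , drop = FALSE]
  out <- data.frame(gene = character(0), category = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(alt) && nrow(gene_intervals)) {
    hits <- lapply(unique(alt$chrom), function(ch) {
      a <- alt[alt$chrom == ch, , drop = FALSE]
      g <- gene_intervals[gene_intervals$chrom == ch, , drop = FALSE]
      if (!nrow(g)) return(NULL)
      ## half-open intervals: convert to closed for IRanges (end - 1)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(g$start, g$end - 1L),
        IRanges::IRanges(a$start, a$end - 1L))
      if (!length(ov)) return(NULL)
      data.frame(gene = g$gene[S4Vectors::queryHits(ov)],
                 category = a$category[S4Vectors::subjectHits(ov)],
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (!is.null(hits) && nrow(hits)) {
      hits$direction <- ifelse(hits$category %in% c("deletion", "loss"),
                               "del", "amp")
      sev <- c(focal_amplification = 1, amplification = 2, gain = 3,
               deletion = 1, loss = 2)
      picked <- lapply(split(hits, paste(hits$gene, hits$direction)), function(h)
        h[which.min(sev[h$category]), c("gene", "category"), drop = FALSE])
      out <- do.call(rbind, picked)
    }
  }
  out <- out[order(out$gene, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample copy-number alteration sets
#'
#' Builds the set elements used for CNA Jaccard distances. Default
#' resolution is gene-level `(gene, category)` pairs; the `bin` alternative
#' uses fixed-width genomic bins labeled with the segment category.
#'
#' @param segments cohort segment table with a `sample` column (categorized;
#'   [classify_segments()] is applied if `category` is absent).
#' @param gene_intervals required for `resolution = "gene"`.
#' @param resolution `"gene"` or `"bin"`.
#' @param bin_width bin width in bases for `resolution = "bin"`.
#' @param ... passed to [classify_segments()].
#' @return named list mapping sample to a character set.
#' @export
cna_alteration_sets <- function(segments, gene_intervals = NULL,
                                resolution = c("gene", "bin"),
                                bin_width = 1e6, ...) {
  resolution <- match.arg(resolution)
  if (!"category" %in% names(segments))
    segments <- classify_segments(segments, ...)
  lapply(split(segments, segments$sample), function(s) {
    alt <- s[s$category != "neutral", , drop = FALSE]
    if (resolution == "gene") {
      if (is.null(gene_intervals))
        stop("gene_intervals required for gene resolution", call. = FALSE)
      calls <- annotate_genes(alt, gene_intervals)
      if (!nrow(calls)) return(character(0))
      paste(calls$gene, calls$category, sep = "|")
    } else {
      if (!nrow(alt)) return(character(0))
      bins <- unlist(lapply(seq_len(nrow(alt)), function(i) {
        b <- seq(floor((alt$start[i] - 1) / bin_width),
                 floor((alt$end[i] - 2) / bin_width))
        paste0(alt$chrom[i], ":", b, "|", alt$category[i])
      }))
      unique(bins)
    }
  })
}

#' Jaccard distance between two samples' CNA alteration sets
#'
#' Same contract as [jaccard_distance()], on the set elements produced by
#' [cna_alteration_sets()].
#'
#' @param set_a,set_b alteration sets.
#' @return distance in \[0, 1\].
#' @export
cna_jaccard <- function(set_a, set_b) jaccard_distance(set_a, set_b)
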