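## Multi-caller gene-fusion consensus, junction-read validation and
## longitudinal conservation.
##
## A fusion key is the ordered pair (gene5, gene3): A::B and B::A are
## different fusions because the 5'/3' roles matter. Per-tool breakpoint
## coordinates may disagree, so keys match on the gene pair only and the
## reported breakpoint is the median position per side.

#' Consensus filter over multi-tool fusion calls
#'
#' Groups calls by (sample, gene5, gene3) and keeps keys reported by at
#' least `min_tools` distinct tools in that sample; a tool reporting the
#' same key twice counts once. Output is invariant to input row order and to
#' duplicated rows.
#'
#' @param calls data.frame with `tool`, `sample`, `gene5`, `gene3`,
#'   optionally `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`, `strand3`,
#'   `junction_reads`.
#' @param min_tools minimum number of distinct supporting tools (default 3).
#' @param tool_set declared set of caller names; an unknown tool name in
#'   `calls` is an error.
#' @return data.frame of candidate consensus fusions: `sample`, `gene5`,
#'   `gene3`, `key`, `n_tools`, `supporting_tools` (comma-separated), median
#'   breakpoints where available.
#' @export
consensus_filter <- function(calls, min_tools = 3L,
                             tool_set = paste0("tool", 1:5)) {
  if (!all(calls$tool %in% tool_set))
    stop("unknown tool name: ",
         paste(setdiff(unique(calls$tool), tool_set), collapse = ", "),
         call. = FALSE)
  if (anyNA(calls$gene5) || anyNA(calls$gene3) ||
      any(calls$gene5 == "") || any(calls$gene3 == ""))
    stop("gene5/gene3 must be nonempty", call. = FALSE)
  dt <- as.data.table(calls)
  has_bp <- all(c("pos5", "pos3") %in% names(dt))
  grp <- dt[, {
    tl <- sort(unique(tool))
    c(list(n_tools = length(tl),
           supporting_tools = paste(tl, collapse = ",")),
      if (has_bp) list(pos5 = as.double(median(pos5)),
                       pos3 = as.double(median(pos3))))
  }, by = .(sample, gene5, gene3)]
  out <- grp[n_tools >= min_tools]
  out[, key := paste(gene5, gene3, sep = "::")]
  out <- out[order(sample, key)]
  as.data.frame(out)
}

#' Validate consensus fusions by junction-read evidence
#'
#' A candidate is validated iff the evidence table shows at least one read
#' covering its breakpoint in that sample (a key missing from the table
#' counts as 0 reads). The evidence search also rescues presence: a key
#' validated anywhere in a patient is looked up in every sample's evidence,
#' and samples with >= 1 junction read are marked present even when no tool
#' called the fusion there. Rescue never adds new keys cohort-wide.
#'
#' @param candidates output of [consensus_filter()] (any table with
#'   `sample`, `gene5`, `gene3`).
#' @param evidence data.frame with `gene5`, `gene3`, `sample`,
#'   `junction_reads`.
#' @return data.frame with `key`, `gene5`, `gene3`, `sample`,
#'   `junction_reads`, `validated` (logical), `rescued` (TRUE where presence
#'   comes from evidence alone), one row per (key, sample) with support.
#' @export
validate_breakpoints <- function(candidates, evidence) {
  if (!nrow(candidates))
    return(data.frame(key = character(0), gene5 = character(0),
                      gene3 = character(0), sample = character(0),
                      junction_reads = integer(0), validated = logical(0),
                      rescued = logical(0)))
  cand <- unique(data.frame(gene5 = candidates$gene5, gene3 = candidates$gene3,
                            sample = candidates$sample,
                            stringsAsFactors = FALSE))
  cand$key <- paste(cand$gene5, cand$gene3, sep = "::")
  ev <- data.frame(key = paste(evidence$gene5, evidence$gene3, sep = "::"),
                   sample = evidence$sample,
                   junction_reads = evidence$junction_reads,
                   stringsAsFactors = FALSE)
  jr <- function(key, sample) {
    i <- match(paste(key, sample), paste(ev$key, ev$sample))
    ifelse(is.na(i), 0L, as.integer(ev$junction_reads[i]))
  }
  cand$junction_reads <- jr(cand$key, cand$sample)
  cand$validated <- cand$junction_reads >= 1L
  cand$rescued <- FALSE
  ## re-search: every validated key is looked up in all samples of the
  ## evidence table; evidence-only hits are added as rescued presences
  valid_keys <- unique(cand$key[cand$validated])
  extra <- ev[ev$key %in% valid_keys & ev$junction_reads >= 1L, , drop = FALSE]
  extra <- extra[!(paste(extra$key, extra$sample) %in%
                     paste(cand$key, cand$sample)), , drop = FALSE]
  if (nrow(extra)) {
    parts <- do.call(rbind, strsplit(extra$key, "::", fixed = TRUE))
    cand <- rbind(cand, data.frame(
      gene5 = parts[, 1], gene3 = parts[, 2], sample = extra$sample,
      key = extra$key, junction_reads = as.integer(extra$junction_reads),
      validated = TRUE, rescued = TRUE, stringsAsFactors = FALSE))
  }
  cand <- cand[order(cand$key, cand$sample),
               c("key", "gene5", "gene3", "sample", "junction_reads",
                 "validated", "rescued")]
  rownames(cand) <- NULL
  cand
}

#' Annotate a fusion's alteration category from toy gene models
#'
#' Categories: `truncated` if the 3' breakpoint falls within the 3' partner's
#' last exon (the remaining span has no downstream coding continuation);
#' otherwise `5'-altered` vs `3'-altered` by which partner loses the larger
#' fraction of its coding span (a partner losing at least `loss_threshold`
#' of its span decides directly; ties go to `3'-altered`). These definitions
#' are a declared interpretation of the three labels.
#'
#' @param fusions data.frame with `gene5`, `gene3` and breakpoint positions
#'   `pos5`, `pos3`.
#' @param gene_models named list: gene -> list(strand = "+"/"-",
#'   exons = matrix/data.frame with columns start, end (half-open)).
#' @param loss_threshold fraction of coding span lost that decides a side
#'   directly (default 0.5).
#' @return character vector of categories; `unclassified` when a partner is
#'   absent from the models.
#' @export
annotate_fusion_type <- function(fusions, gene_models, loss_threshold = 0.5) {
  span_lost <- function(gene, pos, side) {
    gm <- gene_models[[gene]]
    if (is.null(gm)) return(NA_real_)
    ex <- as.data.frame(gm$exons)
    total <- sum(ex$end - ex$start)
    ## coding bases retained by the fusion product, strand-aware:
    ## the 5' partner keeps sequence upstream of the breakpoint in transcript
    ## direction, the 3' partner keeps sequence downstream of it
    upstream <- sum(pmax(0, pmin(ex$end, pos) - ex$start))
    retained <- if ((side == "5'") == (gm$strand == "+")) upstream
                else total - upstream
    1 - retained / total
  }
  in_last_exon <- function(gene, pos) {
    gm <- gene_models[[gene]]
    if (is.null(gm)) return(NA)
    ex <- as.data.frame(gm$exons)
    last <- if (gm$strand == "+") ex[which.max(ex$start), ] else
      ex[which.min(ex$start), ]
    pos >= last$start && pos < last$end
  }
  vapply(seq_len(nrow(fusions)), function(i) {
    g5 <- fusions$gene5[i]; g3 <- fusions$gene3[i]
    if (is.null(gene_models[[g5]]) || is.null(gene_models[[g3]]))
      return("unclassified")
    if (isTRUE(in_last_exon(g3, fusions$pos3[i]))) return("truncated")
    lost5 <- span_lost(g5, fusions$pos5[i], "5'")
    lost3 <- span_lost(g3, fusions$pos3[i], "3'")
    if (lost5 >= loss_threshold && lost5 > lost3) return("5'-altered")
    if (lost3 >= loss_threshold) return("3'-altered")
    if (lost5 > lost3) "5'-altered" else "3'-altered"
  }, "")
}

#' Longitudinal conservation counts of validated fusions
#'
#' Applies the same origin rules as [classify_conservation()] to validated
#' fusion presences and tallies, per patient and for the cohort:
#' diagnosis-to-PDX conserved, relapse-to-PDX conserved, PDX-private, and
#' non-conserved (patient-only) fusions.
#'
#' @param validated output of [validate_breakpoints()] (validated rows are
#'   used), with samples named `<model>_<Pat|PDX>_<D|R|sc|pt>`; or any table
#'   with `key`, `patient_id`, `timepoint`.
#' @return list with `per_fusion` (key, patient_id, present_in, origin) and
#'   `counts` (cohort totals by origin).
#' @export
fusion_conservation_counts <- function(validated) {
  ok <- if ("validated" %in% names(validated)) validated$validated
        else rep(TRUE, nrow(validated))
  v <- validated[ok, , drop = FALSE]
  if (!("timepoint" %in% names(v))) {
    code <- sub("^(M[0-9]+|[^_]+)_", "", v$sample)
    map <- c(Pat_D = "diagnosis", Pat_R = "relapse",
             PDX_sc = "pdx_sc", PDX_pt = "pdx_pt")
    v$timepoint <- unname(map[code])
    v$patient_id <- sub("_(Pat|PDX)_.*$", "", v$sample)
  }
  per <- lapply(split(v, paste(v$patient_id, v$key)), function(x) {
    p <- sort(unique(x$timepoint))
    pdx <- c("pdx_sc", "pdx_pt")
    origin <- if ("diagnosis" %in% p && any(p %in% pdx)) "diagnosis-conserved"
      else if (!("diagnosis" %in% p) && "relapse" %in% p && any(p %in% pdx))
        "relapse-emergent"
      else if (all(p %in% pdx)) "pdx-private"
      else "not-conserved"
    data.frame(key = x$key[1], patient_id = x$patient_id[1],
               present_in = paste(p, collapse = ","), origin = origin,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per); rownames(per) <- NULL
  lv <- c("diagnosis-conserved", "relapse-emergent", "pdx-private",
          "not-conserved")
  counts <- setNames(vapply(lv, function(o) sum(per$origin == o), integer(1)), lv)
  list(per_fusion = per, counts = counts)
}
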