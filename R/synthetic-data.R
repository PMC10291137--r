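#' Cohort specification for the synthetic-data generators
#'
#' Describes a longitudinal PDX cohort: patients sampled at diagnosis and
#' relapse, each with a subcutaneous and a paratibial xenograft. The
#' generators in this package consume a `cohort_spec` and emit tables plus a
#' recorded ground truth, so every downstream stage can be tested against
#' known planted structure.
#'
#' @param n_patients number of patients (models).
#' @param timepoints ordered unique timepoint labels.
#' @param n_genes number of human genes in the expression universe.
#' @param n_me_genes number of planted microenvironment (ME) genes; must be
#'   smaller than `n_genes`.
#' @param n_variants_shared per-patient somatic variants present at every
#'   timepoint.
#' @param n_variants_relapse_gained per-patient variants absent at diagnosis,
#'   present at relapse and in both PDX.
#' @param n_variants_pdx_private per-patient variants present in exactly one
#'   PDX sample.
#' @param fusion_tool_count number of fusion callers emulated (default 5).
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_patients = 8L,
                        timepoints = c("diagnosis", "relapse", "pdx_sc", "pdx_pt"),
                        n_genes = 2000L,
                        n_me_genes = 200L,
                        n_variants_shared = 10L,
                        n_variants_relapse_gained = 5L,
                        n_variants_pdx_private = 3L,
                        fusion_tool_count = 5L,
                        seed = 1L) {
  counts <- c(n_patients = n_patients, n_genes = n_genes,
              n_me_genes = n_me_genes, n_variants_shared = n_variants_shared,
              n_variants_relapse_gained = n_variants_relapse_gained,
              n_variants_pdx_private = n_variants_pdx_private,
              fusion_tool_count = fusion_tool_count)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (n_me_genes >= n_genes) stop("n_me_genes must be < n_genes", call. = FALSE)
  if (anyDuplicated(timepoints)) stop("timepoints must be unique", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 timepoints = timepoints,
                 n_genes = as.integer(n_genes),
                 n_me_genes = as.integer(n_me_genes),
                 n_variants_shared = as.integer(n_variants_shared),
                 n_variants_relapse_gained = as.integer(n_variants_relapse_gained),
                 n_variants_pdx_private = as.integer(n_variants_pdx_private),
                 fusion_tool_count = as.integer(fusion_tool_count),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

model_ids <- function(spec) sprintf("M%02d", seq_len(spec$n_patients))

## sample naming convention: <model>_<Pat|PDX>_<D|R|sc|pt>
sample_name <- function(model, timepoint) {
  code <- c(diagnosis = "Pat_D", relapse = "Pat_R",
            pdx_sc = "PDX_sc", pdx_pt = "PDX_pt")[timepoint]
  paste(model, code, sep = "_")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate paired reads from a two-species (graft/host) mixture
#'
#' Builds two random genomes; when `shared_fraction > 0` a sequence block is
#' copied verbatim into both genomes, and "both"-class read pairs are drawn
#' entirely from inside that block. Graft/host pairs are drawn from the
#' block-free remainder of the respective genome, so every pair's true class
#' is known by construction.
#'
#' @param graft_genome_length,host_genome_length genome lengths in bases.
#' @param shared_fraction expected fraction of pairs drawn from the shared
#'   block, in \[0, 1\].
#' @param n_pairs number of read pairs.
#' @param read_length read length in bases.
#' @param seed integer seed.
#' @param insert_gap unsequenced bases between the two mates of a fragment.
#' @return list with `genomes` (named character vectors `graft`, `host`),
#'   `r1`/`r2` (data.frames with `id`, `seq`), and `truth` (data.frame with
#'   `pair_id`, `class` in graft/host/both).
#' @export
simulate_two_species_reads <- function(graft_genome_length, host_genome_length,
                                       shared_fraction, n_pairs,
                                       read_length = 100L, seed = 1L,
                                       insert_gap = 20L) {
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  frag_len <- 2L * read_length + insert_gap
  if (graft_genome_length < frag_len || host_genome_length < frag_len)
    stop("genome shorter than the fragment length implied by read_length",
         call. = FALSE)
  with_seed(seed, {
    block_len <- if (shared_fraction > 0) max(frag_len, 2L * frag_len) else 0L
    if (block_len > 0 &&
        (graft_genome_length < 2L * block_len || host_genome_length < 2L * block_len))
      stop("genomes too short to host the shared block and unique regions",
           call. = FALSE)
    block <- if (block_len > 0) random_dna(block_len) else ""
    graft <- paste0(block, random_dna(graft_genome_length - block_len))
    host  <- paste0(block, random_dna(host_genome_length - block_len))

    classes <- if (shared_fraction >= 1) rep("both", n_pairs)
      else sample(c("graft", "host", "both"), n_pairs, replace = TRUE,
                  prob = c((1 - shared_fraction) / 2,
                           (1 - shared_fraction) / 2, shared_fraction))
    start_lo <- ifelse(classes == "both", 1L, block_len + 1L)
    start_hi <- ifelse(classes == "both", block_len - frag_len + 1L,
                ifelse(classes == "graft",
                       graft_genome_length - frag_len + 1L,
                       host_genome_length - frag_len + 1L))
    starts <- start_lo + floor(runif(n_pairs) * (start_hi - start_lo + 1L))
    src <- ifelse(classes == "host", host, graft)
    frags <- substr(src, starts, starts + frag_len - 1L)
    r1 <- substr(frags, 1L, read_length)
    r2_fwd <- substr(frags, frag_len - read_length + 1L, frag_len)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2_fwd)))
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    list(genomes = c(graft = graft, host = host),
         r1 = data.frame(id = ids, seq = r1, stringsAsFactors = FALSE),
         r2 = data.frame(id = ids, seq = r2, stringsAsFactors = FALSE),
         truth = data.frame(pair_id = ids, class = classes,
                            stringsAsFactors = FALSE))
  })
}

variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Simulate a longitudinal somatic-variant cohort
#'
#' Plants three variant strata per patient: shared variants present at all
#' timepoints, relapse-gained variants present at relapse and in both PDX,
#' and PDX-private variants present in a single PDX sample. Evidence fields
#' are drawn so that a configurable fraction of rows fails each filter rule
#' (read support, variant allele fraction, population frequency).
#'
#' @param spec a [cohort_spec()].
#' @param fail_fraction fraction of rows drawn to fail a (randomly chosen)
#'   filter rule.
#' @return list with `calls` (one row per variant per sample; columns
#'   `sample`, `patient_id`, `timepoint`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `alt_reads`, `depth`, `vaf`, `popaf_1000g`, `popaf_kaviar`) and
#'   `ground_truth` (planted per-sample variant-key sets, per-variant origin,
#'   per-row planted filter fate).
#' @export
simulate_variant_cohort <- function(spec, fail_fraction = 0.1) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    all_calls <- list()
    origin_rows <- list()
    sets <- list()
    for (m in model_ids(spec)) {
      n_var <- spec$n_variants_shared + spec$n_variants_relapse_gained +
        spec$n_variants_pdx_private
      if (n_var == 0) {
        for (tp in spec$timepoints) sets[[sample_name(m, tp)]] <- character(0)
        next
      }
      chrom <- paste0("chr", sample(1:22, n_var, replace = TRUE))
      pos <- sample(1e6:5e7, n_var, replace = FALSE)
      ref <- sample(bases, n_var, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      gene <- sprintf("G%04d", sample(seq_len(max(spec$n_genes, n_var)), n_var))
      origin <- rep(c("shared", "relapse_gained", "pdx_private"),
                    c(spec$n_variants_shared, spec$n_variants_relapse_gained,
                      spec$n_variants_pdx_private))
      private_site <- sample(c("pdx_sc", "pdx_pt"), n_var, replace = TRUE)
      key <- variant_key(chrom, pos, ref, alt)
      origin_rows[[m]] <- data.frame(patient_id = m, key = key, gene = gene,
                                     origin = origin, stringsAsFactors = FALSE)
      for (tp in spec$timepoints) {
        present <- switch(tp,
          diagnosis = origin == "shared",
          relapse   = origin %in% c("shared", "relapse_gained"),
          origin %in% c("shared", "relapse_gained") |
            (origin == "pdx_private" & private_site == tp))
        idx <- which(present)
        sm <- sample_name(m, tp)
        sets[[sm]] <- key[idx]
        if (!length(idx)) next
        n <- length(idx)
        fate <- sample(c("pass", "support", "vaf", "popaf"), n, replace = TRUE,
                       prob = c(1 - fail_fraction, rep(fail_fraction / 3, 3)))
        alt_reads <- ifelse(fate == "support", sample(0:4, n, replace = TRUE),
                            5L + stats::rpois(n, 25))
        vaf <- ifelse(fate == "vaf", runif(n, 0.005, 0.049),
                      runif(n, 0.10, 0.60))
        depth <- pmax(alt_reads, ceiling(alt_reads / pmax(vaf, 1e-3)))
        vaf <- ifelse(depth > 0, alt_reads / depth, 0)
        ## a support-failure row may still have vaf >= 0.05; fate records the
        ## rule that was planted, pass/fail truth is re-derived below
        pop1 <- runif(n, 0, 0.009)
        pop2 <- runif(n, 0, 0.009)
        which_db <- sample(1:2, n, replace = TRUE)
        pop1[fate == "popaf" & which_db == 1] <-
          runif(sum(fate == "popaf" & which_db == 1), 0.011, 0.2)
        pop2[fate == "popaf" & which_db == 2] <-
          runif(sum(fate == "popaf" & which_db == 2), 0.011, 0.2)
        all_calls[[paste(m, tp)]] <- data.frame(
          sample = sm, patient_id = m, timepoint = tp,
          chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt[idx],
          gene = gene[idx], alt_reads = as.integer(alt_reads),
          depth = as.integer(depth), vaf = round(vaf, 6),
          popaf_1000g = round(pop1, 6), popaf_kaviar = round(pop2, 6),
          stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(all_calls)) do.call(rbind, all_calls) else
      data.frame(sample = character(0))
    rownames(calls) <- NULL
    passes <- with(calls, alt_reads >= 5 & vaf >= 0.05 &
                     popaf_1000g <= 0.01 & popaf_kaviar <= 0.01)
    list(calls = calls,
         ground_truth = list(
           variant_sets_per_sample = sets,
           origins = do.call(rbind, origin_rows),
           passes_filter = passes))
  })
}

#' Simulate gene-by-sample expression for patients and PDX fractions
#'
#' Draws counts from a negative-binomial low-rank model. Planted ME genes are
#' expressed in patient samples (mean 50-500) and hard-zero in the PDX human
#' fraction (optionally with leakage); their mouse orthologs follow the same
#' per-patient program in the PDX mouse fraction. One latent factor loads
#' only by species group (patient vs PDX), and one biological factor is
#' shared per patient across all of that patient's samples.
#'
#' @param spec a [cohort_spec()].
#' @param dispersion negative-binomial dispersion (variance = mu + phi mu^2).
#' @param species_amplitude score magnitude of the planted species factor
#'   (0 disables it).
#' @param bio_loading_sd,species_loading_sd log-scale loading spreads of the
#'   two planted factors.
#' @param me_leakage mean count of ME genes in the PDX human fraction
#'   (default 0: hard zeros).
#' @param both_pdx_sites also emit paratibial PDX samples (default: one
#'   subcutaneous PDX per patient, so patient and PDX groups are the same
#'   size).
#' @param n_mouse_absent number of mouse ortholog genes planted as absent
#'   (< 3 reads in every mouse-fraction sample).
#' @return list with `human_counts` (gene x sample), `mouse_counts`,
#'   `sample_meta` (sample, species, fraction, patient, timepoint),
#'   `ortholog_map` (human_gene, mouse_gene) and `ground_truth`.
#' @export
simulate_expression_cohort <- function(spec, dispersion = 0.2,
                                       species_amplitude = 1,
                                       bio_loading_sd = 0.5,
                                       species_loading_sd = 0.3,
                                       me_leakage = 0,
                                       both_pdx_sites = FALSE,
                                       n_mouse_absent = 50L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    me_genes <- sprintf("G%04d", seq_len(spec$n_me_genes))  # first block planted as ME
    models <- model_ids(spec)
    pdx_tp <- if (both_pdx_sites) c("pdx_sc", "pdx_pt") else "pdx_sc"

    meta <- do.call(rbind, lapply(models, function(m) {
      rbind(
        data.frame(sample = sample_name(m, "relapse"), species = "human",
                   fraction = "patient", patient = m, timepoint = "relapse"),
        do.call(rbind, lapply(pdx_tp, function(tp) rbind(
          data.frame(sample = paste0(sample_name(m, tp), "_h"),
                     species = "human", fraction = "pdx_human",
                     patient = m, timepoint = tp),
          data.frame(sample = paste0(sample_name(m, tp), "_m"),
                     species = "mouse", fraction = "pdx_mouse",
                     patient = m, timepoint = tp)))))
    }))
    rownames(meta) <- NULL

    base_mu <- rlnorm(spec$n_genes, meanlog = log(100), sdlog = 1)
    bio_load <- rnorm(spec$n_genes, 0, bio_loading_sd)
    sp_load <- rnorm(spec$n_genes, 0, species_loading_sd)
    bio_score <- setNames(rnorm(spec$n_patients), models)
    me_mu <- runif(spec$n_me_genes, 50, 500)
    ## per-patient ME program: a rank-3 signature shared between the patient
    ## sample and the mouse fraction of that patient's PDX
    me_rank <- 3L
    me_load <- matrix(rnorm(spec$n_me_genes * me_rank, 0, bio_loading_sd),
                      spec$n_me_genes, me_rank)
    me_score <- matrix(rnorm(spec$n_patients * me_rank), spec$n_patients,
                       me_rank, dimnames = list(models, NULL))

    is_me <- genes %in% me_genes
    human_samples <- meta$sample[meta$fraction != "pdx_mouse"]
    human_counts <- matrix(0L, spec$n_genes, length(human_samples),
                           dimnames = list(genes, human_samples))
    size <- if (dispersion > 0) 1 / dispersion else Inf
    draw <- function(mu) {
      if (is.finite(size)) rnbinom(length(mu), mu = mu, size = size)
      else stats::rpois(length(mu), mu)
    }
    for (s in human_samples) {
      i <- match(s, meta$sample)
      pat <- meta$patient[i]
      sp_score <- if (meta$fraction[i] == "patient") 1 else -1
      mu <- base_mu * exp(bio_load * bio_score[pat] +
                          sp_load * sp_score * species_amplitude)
      mu[is_me] <- if (meta$fraction[i] == "patient")
        me_mu * exp(drop(me_load %*% me_score[pat, ])) else me_leakage
      cnt <- draw(mu)
      if (meta$fraction[i] != "patient" && me_leakage == 0) cnt[is_me] <- 0L
      human_counts[, s] <- cnt
    }

    ## ortholog map: 1:1 for most genes; a few ME genes lack an ortholog and
    ## a couple of rows are many-to-many (dropped by the 1:1 filter)
    mouse_of <- setNames(sprintf("Gm%04d", seq_len(spec$n_genes)), genes)
    no_orth <- if (spec$n_me_genes >= 4) me_genes[seq_len(2)] else character(0)
    map <- data.frame(human_gene = setdiff(genes, no_orth),
                      mouse_gene = mouse_of[setdiff(genes, no_orth)],
                      stringsAsFactors = FALSE)
    if (spec$n_genes > spec$n_me_genes + 4) {
      dup_h <- genes[spec$n_me_genes + 1L]   # one human gene -> two mouse genes
      map <- rbind(map, data.frame(human_gene = dup_h,
                                   mouse_gene = "Gm_dup1"))
    }
    rownames(map) <- NULL

    mouse_genes <- sort(unique(map$mouse_gene))
    mouse_samples <- meta$sample[meta$fraction == "pdx_mouse"]
    mouse_counts <- matrix(0L, length(mouse_genes), length(mouse_samples),
                           dimnames = list(mouse_genes, mouse_samples))
    absent_pool <- setdiff(mouse_genes, c(mouse_of[me_genes], "Gm_dup1"))
    mouse_absent <- sort(sample(absent_pool, min(n_mouse_absent, length(absent_pool))))
    me_idx_of_mouse <- match(mouse_genes, mouse_of[me_genes])  # NA if not ME ortholog
    for (s in mouse_samples) {
      i <- match(s, meta$sample)
      pat <- meta$patient[i]
      mu <- rep(80, length(mouse_genes))
      is_meo <- !is.na(me_idx_of_mouse)
      mu[is_meo] <- me_mu[me_idx_of_mouse[is_meo]] *
        exp(drop(me_load[me_idx_of_mouse[is_meo], , drop = FALSE] %*%
                   me_score[pat, ]))
      mu[mouse_genes %in% mouse_absent] <- 0.2
      mouse_counts[, s] <- draw(mu)
    }

    list(human_counts = human_counts, mouse_counts = mouse_counts,
         sample_meta = meta, ortholog_map = map,
         ground_truth = list(
           me_gene_ids = me_genes,
           no_ortholog_me_genes = no_orth,
           bio_factor_scores = bio_score,
           me_program_scores = me_score,
           species_scores = setNames(
             ifelse(meta$fraction[match(human_samples, meta$sample)] == "patient", 1, -1),
             human_samples),
           species_amplitude = species_amplitude,
           mouse_absent_genes = mouse_absent))
  })
}

#' Simulate copy-number segment profiles
#'
#' Builds a toy genome (5 chromosomes x 50 Mb, 20 evenly spaced genes per
#' chromosome) and plants per-patient alteration profiles: conserved
#' alterations present at all timepoints plus PDX-private ones. Unaltered
#' stretches are emitted as neutral (copy number 2) segments so each sample
#' has a full, non-overlapping segmentation.
#'
#' @param spec a [cohort_spec()].
#' @param n_conserved,n_pdx_private planted alterations per patient.
#' @return list with `segments` (sample, chrom, start, end, total_cn),
#'   `gene_intervals` (gene, chrom, start, end) and `ground_truth` (per
#'   sample, the planted (gene, category) pairs).
#' @export
simulate_cna_profiles <- function(spec, n_conserved = 6L, n_pdx_private = 2L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1L, {
    chroms <- paste0("chr", 1:5)
    chrom_len <- 5e7
    genes_per_chrom <- 20L
    gi <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      starts <- (seq_len(genes_per_chrom) - 1L) * 2.5e6 + 1e6 + 1
      data.frame(gene = sprintf("CG%03d", (ci - 1L) * genes_per_chrom +
                                  seq_len(genes_per_chrom)),
                 chrom = chroms[ci], start = starts, end = starts + 5e4,
                 stringsAsFactors = FALSE)
    }))
    cats <- c("focal_amplification", "amplification", "gain", "loss", "deletion")
    seg_for <- function(g, category) {
      row <- gi[gi$gene == g, ]
      half <- switch(category, focal_amplification = 1e6,
                     amplification = 3e6, 2e6)
      cn <- switch(category, focal_amplification = sample(7:10, 1),
                   amplification = sample(7:10, 1), gain = sample(3:6, 1),
                   loss = 1L, deletion = 0L)
      mid <- (row$start + row$end) / 2
      data.frame(chrom = row$chrom,
                 start = max(1, floor(mid - half)),
                 end = min(chrom_len, floor(mid + half)),
                 total_cn = cn, gene = g, category = category,
                 stringsAsFactors = FALSE)
    }
    segments <- list(); truth <- list()
    for (m in model_ids(spec)) {
      ## pick altered genes spaced >= 4 apart on the index grid so planted
      ## segments never overlap
      n_alt <- n_conserved + n_pdx_private
      pick <- sort(sample(seq(1, nrow(gi), by = 4), n_alt))
      alt_genes <- gi$gene[pick]
      alt_cat <- sample(cats, n_alt, replace = TRUE)
      private_idx <- if (n_pdx_private > 0)
        tail(seq_len(n_alt), n_pdx_private) else integer(0)
      private_site <- sample(c("pdx_sc", "pdx_pt"), n_alt, replace = TRUE)
      for (tp in spec$timepoints) {
        sm <- sample_name(m, tp)
        keep <- vapply(seq_len(n_alt), function(i) {
          if (!(i %in% private_idx)) TRUE
          else tp == private_site[i]
        }, logical(1))
        alt <- do.call(rbind, lapply(which(keep), function(i)
          seg_for(alt_genes[i], alt_cat[i])))
        ## fill the rest of each chromosome with neutral segments
        full <- do.call(rbind, lapply(chroms, function(ch) {
          a <- alt[alt$chrom == ch, , drop = FALSE]
          a <- a[order(a$start), , drop = FALSE]
          neut <- list(); cur <- 1
          for (j in seq_len(nrow(a))) {
            if (a$start[j] > cur)
              neut[[length(neut) + 1L]] <- data.frame(
                chrom = ch, start = cur, end = a$start[j], total_cn = 2L,
                gene = NA_character_, category = "neutral")
            cur <- a$end[j]
          }
          if (cur < chrom_len)
            neut[[length(neut) + 1L]] <- data.frame(
              chrom = ch, start = cur, end = chrom_len, total_cn = 2L,
              gene = NA_character_, category = "neutral")
          rbind(a, do.call(rbind, neut))
        }))
        full <- full[order(full$chrom, full$start), ]
        segments[[sm]] <- data.frame(sample = sm,
                                     full[, c("chrom", "start", "end", "total_cn")],
                                     stringsAsFactors = FALSE)
        truth[[sm]] <- data.frame(sample = sm,
                                  gene = alt$gene, category = alt$category,
                                  stringsAsFactors = FALSE)
      }
    }
    seg <- do.call(rbind, segments); rownames(seg) <- NULL
    tru <- do.call(rbind, truth); rownames(tru) <- NULL
    list(segments = seg, gene_intervals = gi,
         ground_truth = list(planted_calls = tru))
  })
}

#' Simulate multi-caller fusion tables with planted consensus survivors
#'
#' Each planted fusion is assigned a longitudinal origin (present at a set of
#' timepoints), a random subset of the emulated callers, and junction-read
#' evidence. Survivors are fusions called by at least `min_tools` distinct
#' tools in some sample and carrying at least one junction read; the
#' generator also plants non-survivors of each kind (too few tools; zero
#' junction reads) and rescue cases (evidence present in a sample where no
#' tool called the fusion).
#'
#' @param spec a [cohort_spec()].
#' @param n_fusions_per_patient planted fusions per patient.
#' @param min_tools consensus threshold used for the bookkeeping (default 3).
#' @return list with `calls` (tool, sample, patient_id, timepoint, gene5,
#'   gene3, chrom5, pos5, strand5, chrom3, pos3, strand3, junction_reads),
#'   `evidence` (validator-style table: gene5, gene3, sample, junction_reads)
#'   and `ground_truth` (per-fusion origin, presence, survivor keys).
#' @export
simulate_fusion_calls <- function(spec, n_fusions_per_patient = 8L,
                                  min_tools = 3L) {
  stopifnot(inherits(spec, "cohort_spec"))
  tools <- paste0("tool", seq_len(spec$fusion_tool_count))
  with_seed(spec$seed + 2L, {
    calls <- list(); evid <- list(); truth <- list()
    for (m in model_ids(spec)) {
      g5 <- sprintf("F%s_%02dA", m, seq_len(n_fusions_per_patient))
      g3 <- sprintf("F%s_%02dB", m, seq_len(n_fusions_per_patient))
      origin <- sample(c("diagnosis_conserved", "relapse_emergent",
                         "pdx_private", "patient_only"),
                       n_fusions_per_patient, replace = TRUE)
      kind <- sample(c("survivor", "few_tools", "no_reads"),
                     n_fusions_per_patient, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
      for (i in seq_len(n_fusions_per_patient)) {
        present <- switch(origin[i],
          diagnosis_conserved = c("diagnosis", "relapse",
                                  sample(c("pdx_sc", "pdx_pt"), sample(1:2, 1))),
          relapse_emergent = c("relapse",
                               sample(c("pdx_sc", "pdx_pt"), sample(1:2, 1))),
          pdx_private = sample(c("pdx_sc", "pdx_pt"), 1),
          patient_only = sample(c("diagnosis", "relapse"), 1))
        present <- intersect(spec$timepoints, unique(present))
        n_tools <- if (kind[i] == "few_tools")
          sample(seq_len(min_tools - 1L), 1)
        else sample(seq(min_tools, spec$fusion_tool_count), 1)
        chrom5 <- paste0("chr", sample(1:22, 1)); pos5 <- sample(1e6:9e7, 1)
        chrom3 <- paste0("chr", sample(1:22, 1)); pos3 <- sample(1e6:9e7, 1)
        ## rescue case: drop the tool calls (not the evidence) in one
        ## present sample when the fusion is present in >= 2 samples
        rescue_tp <- if (kind[i] == "survivor" && length(present) >= 2 &&
                         runif(1) < 0.3) sample(present, 1) else NA_character_
        for (tp in present) {
          sm <- sample_name(m, tp)
          jr <- if (kind[i] == "no_reads") 0L else sample(1:40, 1)
          evid[[length(evid) + 1L]] <- data.frame(
            gene5 = g5[i], gene3 = g3[i], sample = sm,
            junction_reads = jr, stringsAsFactors = FALSE)
          if (identical(tp, rescue_tp)) next
          toolset <- sample(tools, n_tools)
          for (tl in toolset) {
            calls[[length(calls) + 1L]] <- data.frame(
              tool = tl, sample = sm, patient_id = m, timepoint = tp,
              gene5 = g5[i], gene3 = g3[i],
              chrom5 = chrom5, pos5 = pos5 + sample(-5:5, 1), strand5 = "+",
              chrom3 = chrom3, pos3 = pos3 + sample(-5:5, 1), strand3 = "+",
              junction_reads = max(0L, jr + sample(-2:2, 1)),
              stringsAsFactors = FALSE)
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = m, gene5 = g5[i], gene3 = g3[i], origin = origin[i],
          kind = kind[i], present_in = paste(present, collapse = ","),
          rescue_timepoint = rescue_tp, stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, calls); rownames(calls) <- NULL
    evid <- do.call(rbind, evid); rownames(evid) <- NULL
    tru <- do.call(rbind, truth); rownames(tru) <- NULL
    ## survivors: >= min_tools distinct tools in some sample AND >= 1 read;
    ## with >= 2 present samples a single rescue drop cannot erase consensus
    surv <- tru$kind == "survivor"
    list(calls = calls, evidence = evid,
         ground_truth = list(
           fusions = tru,
           survivor_keys = paste(tru$gene5[surv], tru$gene3[surv], sep = "::")))
  })
}

#' Simulate a low-rank protein abundance matrix with missing values
#'
#' Gaussian low-rank signal on the log-intensity scale plus noise, with
#' missing-completely-at-random holes. A fraction of proteins is planted
#' with high missingness so the missing-rate filter has work to do.
#'
#' @param n_proteins,n_samples matrix dimensions.
#' @param rank rank of the planted signal.
#' @param noise_sd residual standard deviation.
#' @param missing_rate per-cell MCAR missingness probability for ordinary
#'   proteins.
#' @param high_missing_fraction fraction of proteins given a per-cell
#'   missingness of 0.6 (these should fall to the <34% filter).
#' @param seed integer seed.
#' @return list with `observed` (matrix with NA), `complete`, `mask`
#'   (logical, TRUE = missing).
#' @export
simulate_protein_matrix <- function(n_proteins = 600L, n_samples = 8L,
                                    rank = 2L, noise_sd = 0.3,
                                    missing_rate = 0.2,
                                    high_missing_fraction = 0.15,
                                    seed = 1L) {
  with_seed(seed, {
    u <- matrix(rnorm(n_proteins * rank), n_proteins, rank)
    v <- matrix(rnorm(n_samples * rank), n_samples, rank)
    mu <- rnorm(n_proteins, 25, 2)  # log2 LFQ-like baseline per protein
    complete <- mu + u %*% t(v) + matrix(rnorm(n_proteins * n_samples, 0, noise_sd),
                                         n_proteins, n_samples)
    dimnames(complete) <- list(sprintf("P%04d", seq_len(n_proteins)),
                               sprintf("S%02d", seq_len(n_samples)))
    rate <- rep(missing_rate, n_proteins)
    n_high <- floor(high_missing_fraction * n_proteins)
    if (n_high > 0) rate[sample(n_proteins, n_high)] <- 0.6
    mask <- matrix(runif(n_proteins * n_samples), n_proteins, n_samples) <
      matrix(rate, n_proteins, n_samples)
    ## never blank out a full row
    full <- rowSums(!mask) == 0
    mask[full, 1] <- FALSE
    observed <- complete
    observed[mask] <- NA_real_
    dimnames(mask) <- dimnames(complete)
    list(observed = observed, complete = complete, mask = mask)
  })
}

#' Simulate an exponential tumor growth curve
#'
#' Volumes follow \eqn{V(t) = v_0 \cdot 2^{t / T_d}} with multiplicative
#' lognormal noise of coefficient of variation `noise_cv` (mean-one noise, so
#' the expected volume is the noiseless curve).
#'
#' @param v0 starting volume (mm3), > 0.
#' @param td_days true doubling time (days), > 0.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param t_grid measurement days.
#' @param seed integer seed.
#' @return data.frame with `day`, `volume_mm3`.
#' @export
simulate_growth_curve <- function(v0, td_days, noise_cv, t_grid, seed = 1L) {
  if (v0 <= 0 || td_days <= 0) stop("v0 and td_days must be > 0", call. = FALSE)
  with_seed(seed, {
    v <- v0 * 2^(t_grid / td_days)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      v <- v * rlnorm(length(t_grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    data.frame(day = t_grid, volume_mm3 = v)
  })
}
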