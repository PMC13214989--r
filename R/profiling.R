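## The core pipeline: read preprocessing, a dereplication-based ASV
## surrogate, tiered identity classification, per-sample composition,
## prevalence/richness summaries, and the cohort exclusion cascade.

#' Pipeline filter thresholds
#'
#' All quality and detection thresholds used by the pipeline, with the
#' study defaults: 23-base 3' trim (index removal), >=250 bp ASVs,
#' >=10,000 reads per sample, >=1% genus-level relative abundance for
#' cohort inclusion, 600-4,000 kcal/day caloric range, 0.5% detection
#' threshold for prevalence/richness, and the minor-label rule (median
#' <1% or prevalence <10%).
#'
#' @param trim_3prime bases trimmed from each read's 3' end.
#' @param min_asv_len minimum retained read/ASV length (bp).
#' @param min_sample_reads minimum retained reads per sample.
#' @param genus_min_relab minimum 16S genus-level relative abundance
#'   (fraction) for cohort inclusion.
#' @param kcal_range accepted daily caloric intake range (kcal).
#' @param detection_relab detection threshold (fraction) for prevalence
#'   and species richness.
#' @param minor_median,minor_prevalence minor-label thresholds
#'   (fractions).
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(trim_3prime = 23L, min_asv_len = 250L,
                              min_sample_reads = 10000L,
                              genus_min_relab = 0.01,
                              kcal_range = c(600, 4000),
                              detection_relab = 0.005,
                              minor_median = 0.01,
                              minor_prevalence = 0.10) {
  stopifnot(trim_3prime >= 0, min_asv_len > 0, min_sample_reads > 0,
            kcal_range[1] < kcal_range[2])
  structure(list(trim_3prime = as.integer(trim_3prime),
                 min_asv_len = as.integer(min_asv_len),
                 min_sample_reads = as.integer(min_sample_reads),
                 genus_min_relab = genus_min_relab,
                 kcal_range = kcal_range,
                 detection_relab = detection_relab,
                 minor_median = minor_median,
                 minor_prevalence = minor_prevalence),
            class = "filter_thresholds")
}

#' Labels used by the tiered classifier
#'
#' `Group 1` .. `Group 12`, `Other Faecalibacterium` (95-98% identity) and
#' `Others` (<95%).
#'
#' @return Character vector of the 14 labels.
#' @export
profile_labels <- function() {
  c(paste("Group", 1:12), "Other Faecalibacterium", "Others")
}

#' Preprocess amplicon reads
#'
#' Trims `trim_3prime` bases from the 3' end of each read (index
#' removal), strips the forward primer prefix and the
#' reverse-complemented reverse primer suffix when present (degenerate
#' match, <=1 mismatch, no 3' protection), and drops reads shorter than
#' `min_asv_len`.
#'
#' @param reads character vector of merged/single-end reads for one
#'   sample.
#' @param pair `primer_pair` (default [meta_rpoa_primers()]); `NULL`
#'   skips primer stripping.
#' @param th `filter_thresholds`.
#' @return List: `reads` (retained, trimmed), `stats` (n_input,
#'   n_trimmed, n_primer_stripped, n_dropped_short, n_retained).
#' @export
preprocess_reads <- function(reads, pair = meta_rpoa_primers(),
                             th = filter_thresholds()) {
  n_input <- length(reads)
  if (n_input == 0L) {
    return(list(reads = character(),
                stats = list(n_input = 0L, n_trimmed = 0L,
                             n_primer_stripped = 0L, n_dropped_short = 0L,
                             n_retained = 0L)))
  }
  reads <- toupper(reads)
  lens <- nchar(reads)
  keep_len <- pmax(lens - th$trim_3prime, 0L)
  reads <- substr(reads, 1L, keep_len)
  n_trimmed <- sum(lens > keep_len)

  n_stripped <- 0L
  if (!is.null(pair)) {
    fwd <- pair$fwd$seq
    rev_rc <- reverse_complement(pair$rev$seq)
    Lf <- nchar(fwd); Lr <- nchar(rev_rc)
    lens <- nchar(reads)
    hit_f <- lens >= Lf &
      .mismatch_counts(fwd, substr(reads, 1L, Lf)) <= 1L
    reads[hit_f] <- substr(reads[hit_f], Lf + 1L, lens[hit_f])
    lens <- nchar(reads)
    hit_r <- lens >= Lr &
      .mismatch_counts(rev_rc, substr(reads, lens - Lr + 1L, lens)) <= 1L
    reads[hit_r] <- substr(reads[hit_r], 1L, lens[hit_r] - Lr)
    n_stripped <- sum(hit_f | hit_r)
  }
  keep <- nchar(reads) >= th$min_asv_len
  list(reads = reads[keep],
       stats = list(n_input = n_input, n_trimmed = n_trimmed,
                    n_primer_stripped = n_stripped,
                    n_dropped_short = sum(!keep),
                    n_retained = sum(keep)))
}

#' Dereplication-based ASV surrogate caller
#'
#' Exact-sequence dereplication across samples with singleton removal: a
#' deliberately simple stand-in for model-based denoising that keeps the
#' classification layer fully testable. Sequences with total count 1 and
#' sequences shorter than `min_asv_len` are discarded. ASV ids are
#' assigned deterministically by (total count descending, sequence
#' lexicographic).
#'
#' @param batches named list: sample_id -> character vector of
#'   preprocessed reads.
#' @param th `filter_thresholds`.
#' @return List of class `asv_table`: `asv` (data frame: asv_id, seq,
#'   length, total_count) and `counts` (integer matrix, ASVs x samples).
#' @export
call_asvs <- function(batches, th = filter_thresholds()) {
  stopifnot(is.list(batches), !is.null(names(batches)),
            !anyDuplicated(names(batches)))
  samples <- names(batches)
  all_reads <- unlist(batches, use.names = FALSE)
  if (length(all_reads) == 0L) {
    asv <- data.frame(asv_id = character(), seq = character(),
                      length = integer(), total_count = integer())
    counts <- matrix(0L, 0L, length(samples),
                     dimnames = list(NULL, samples))
    return(structure(list(asv = asv, counts = counts), class = "asv_table"))
  }
  sample_of <- rep(samples, lengths(batches))
  seq_f <- factor(all_reads)
  counts <- table(seq_f, factor(sample_of, levels = samples))
  counts <- matrix(as.integer(counts), nrow = nlevels(seq_f),
                   dimnames = list(levels(seq_f), samples))
  total <- rowSums(counts)
  keep <- total > 1L & nchar(rownames(counts)) >= th$min_asv_len
  counts <- counts[keep, , drop = FALSE]
  total <- total[keep]
  ord <- order(-total, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  total <- total[ord]
  asv <- data.frame(
    asv_id = sprintf("ASV%05d", seq_len(nrow(counts))),
    seq = rownames(counts),
    length = nchar(rownames(counts)),
    total_count = as.integer(total),
    stringsAsFactors = FALSE)
  rownames(counts) <- asv$asv_id
  structure(list(asv = asv, counts = counts), class = "asv_table")
}

#' Tiered identity classification of ASVs against a reference library
#'
#' Each ASV is assigned by its best end-gap-free identity across the
#' library's amplicon regions: >=98% to the species group of the best
#' reference, 95% to <98% to "Other Faecalibacterium", below 95% to
#' "Others". When several references in *different* groups attain the
#' best identity at >=98%, the earliest record in library order wins and
#' `tie_flag` is set.
#'
#' @param seqs character vector of ASV sequences (named by asv_id), or an
#'   `asv_table`.
#' @param lib amplicon-extracted `ref_library`.
#' @return Data frame: `asv_id`, `best_identity`, `label`, `tie_flag`,
#'   `best_ref`.
#' @export
classify_asvs <- function(seqs, lib) {
  if (inherits(seqs, "asv_table")) {
    s <- seqs$asv$seq; names(s) <- seqs$asv$asv_id; seqs <- s
  }
  stopifnot(inherits(lib, "ref_library"))
  lib <- lib[!is.na(lib$amplicon_seq), , drop = FALSE]
  if (nrow(lib) == 0L) stop("empty library (no amplicons)", call. = FALSE)
  if (length(seqs) == 0L) {
    return(data.frame(asv_id = character(), best_identity = numeric(),
                      label = character(), tie_flag = logical(),
                      best_ref = character()))
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("ASV%05d", seq_along(seqs))
  idm <- identity_matrix(unname(seqs), lib$amplicon_seq)

  best <- numeric(length(seqs)); label <- character(length(seqs))
  tie <- logical(length(seqs)); best_ref <- character(length(seqs))
  for (i in seq_along(seqs)) {
    v <- idm[i, ]
    b <- max(v)
    hits <- which(abs(v - b) < 1e-9)
    first <- hits[1L]          # earliest record in library order
    best[i] <- b
    best_ref[i] <- lib$record_id[first]
    if (b >= 98) {
      label[i] <- paste("Group", lib$group_id[first])
      tie[i] <- length(unique(lib$group_id[hits])) > 1L
    } else if (b >= 95) {
      label[i] <- "Other Faecalibacterium"
    } else {
      label[i] <- "Others"
    }
  }
  data.frame(asv_id = ids, best_identity = best, label = label,
             tie_flag = tie, best_ref = best_ref, stringsAsFactors = FALSE)
}

#' Per-sample relative-abundance profiles
#'
#' Label abundance = summed counts of ASVs carrying that label divided by
#' the sample's total retained counts (the denominator includes
#' "Other Faecalibacterium" and "Others"). Samples below
#' `min_sample_reads` total are excluded and reported.
#'
#' @param asvs `asv_table`.
#' @param classifications output of [classify_asvs()].
#' @param th `filter_thresholds`.
#' @return List of class `sample_profiles`: `rel_abundance` (matrix,
#'   retained samples x the 14 labels), `total_reads` (named vector over
#'   all input samples), `excluded_samples`.
#' @export
build_profiles <- function(asvs, classifications, th = filter_thresholds()) {
  stopifnot(inherits(asvs, "asv_table"))
  stopifnot(all(asvs$asv$asv_id %in% classifications$asv_id))
  labels <- profile_labels()
  lab <- classifications$label[match(asvs$asv$asv_id,
                                     classifications$asv_id)]
  lab <- factor(lab, levels = labels)
  agg <- rowsum(asvs$counts, group = lab)   # labels x samples (present only)
  full <- matrix(0, nrow = length(labels), ncol = ncol(asvs$counts),
                 dimnames = list(labels, colnames(asvs$counts)))
  full[rownames(agg), ] <- agg
  totals <- colSums(full)
  keep <- totals >= th$min_sample_reads
  rel <- t(full[, keep, drop = FALSE]) / totals[keep]
  structure(list(rel_abundance = rel,
                 total_reads = totals,
                 excluded_samples = colnames(asvs$counts)[!keep]),
            class = "sample_profiles")
}

#' Cohort-level composition summary
#'
#' Per label: median and Q1-Q3 of relative abundance, prevalence
#' (fraction of samples at or above the detection threshold), and a
#' minor-label flag (median below `minor_median` or prevalence below
#' `minor_prevalence`). Per sample: species richness, the number of
#' Groups 1-12 detected at or above the detection threshold.
#'
#' @param profiles `sample_profiles` or a samples x labels relative
#'   abundance matrix.
#' @param th `filter_thresholds`.
#' @return List of class `cohort_summary`: `per_label` data frame and
#'   `richness` named vector.
#' @export
summarize_cohort <- function(profiles, th = filter_thresholds()) {
  rel <- if (inherits(profiles, "sample_profiles")) profiles$rel_abundance
         else profiles
  stopifnot(nrow(rel) >= 1L)
  labels <- colnames(rel)
  qs <- apply(rel, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  prevalence <- colMeans(rel >= th$detection_relab)
  per_label <- data.frame(
    label = labels,
    median = qs[2, ], q1 = qs[1, ], q3 = qs[3, ],
    prevalence = prevalence,
    minor = qs[2, ] < th$minor_median | prevalence < th$minor_prevalence,
    stringsAsFactors = FALSE, row.names = NULL)
  group_cols <- grep("^Group ", labels)
  richness <- rowSums(rel[, group_cols, drop = FALSE] >= th$detection_relab)
  structure(list(per_label = per_label, richness = richness,
                 detection_relab = th$detection_relab),
            class = "cohort_summary")
}

#' Cohort exclusion cascade
#'
#' Applies the enrolment exclusions in fixed order, each sample removed at
#' the first applicable stage only: (1) 16S genus-level relative
#' abundance of Faecalibacterium below `genus_min_relab`; (2) cancer
#' history; (3) caloric intake outside `kcal_range`; (4) fewer than
#' `min_sample_reads` amplicon reads. With the study's stage counts
#' (55/13/3/9 among 660 enrolled) the final population is 580.
#'
#' @param cohort data frame with columns `sample_id`, `genus_relab_16S`,
#'   `cancer_history` (logical), `kcal`.
#' @param total_reads named numeric vector of per-sample read totals
#'   (e.g. `sample_profiles$total_reads`); must cover every cohort sample.
#' @param th `filter_thresholds`.
#' @return List of class `cascade_report`: `retained` (sample ids),
#'   `stages` (data frame: stage, n_removed), `n_enrolled`, `n_final`.
#' @export
apply_cohort_cascade <- function(cohort, total_reads,
                                 th = filter_thresholds()) {
  stopifnot(all(c("sample_id", "genus_relab_16S", "cancer_history",
                  "kcal") %in% names(cohort)))
  missing_ids <- setdiff(cohort$sample_id, names(total_reads))
  if (length(missing_ids)) {
    stop("samples without read totals: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  reads <- total_reads[cohort$sample_id]
  active <- rep(TRUE, nrow(cohort))
  stage_defs <- list(
    low_genus_abundance = cohort$genus_relab_16S < th$genus_min_relab,
    cancer_history = as.logical(cohort$cancer_history),
    caloric_outlier = cohort$kcal < th$kcal_range[1] |
                      cohort$kcal > th$kcal_range[2],
    low_read_count = reads < th$min_sample_reads
  )
  removed <- integer(length(stage_defs))
  names(removed) <- names(stage_defs)
  for (s in seq_along(stage_defs)) {
    hit <- active & stage_defs[[s]] & !is.na(stage_defs[[s]])
    removed[s] <- sum(hit)
    active <- active & !hit
  }
  structure(list(
    retained = cohort$sample_id[active],
    stages = data.frame(stage = names(removed), n_removed = unname(removed),
                        stringsAsFactors = FALSE),
    n_enrolled = nrow(cohort),
    n_final = sum(active)
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Cohort cascade: %d enrolled -> %d retained\n",
              x$n_enrolled, x$n_final))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  - %s: %d removed\n",
                x$stages$stage[i], x$stages$n_removed[i]))
  }
  invisible(x)
}
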