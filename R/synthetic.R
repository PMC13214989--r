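## Mock-community and cohort simulators. Everything is a pure function of
## (config, seed): identical inputs give bit-identical outputs, and every
## generated artifact is traceable through the returned truth manifest.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 12 species groups, 106
#' reference sequences, a 283-bp amplicon core flanked by the 21-bp
#' primer sites (325-bp primer-inclusive amplicons), inter-group
#' divergence of at least 6% of core positions and intra-group strain
#' divergence of at most 3 core substitutions (keeping cross-group
#' amplicon identity below 94% and within-group identity above 98%), a
#' 0.1% per-base substitution error rate, and a 660-participant cohort
#' with disjoint exclusion-category counts 55/13/3/9.
#'
#' @param seed mandatory RNG seed.
#' @param n_groups number of species groups.
#' @param refs_per_group integer vector (length `n_groups`) of records
#'   per group; the default sums to 106.
#' @param core_len amplicon core length between the primer sites (bp).
#' @param inter_group_divergence fraction of core positions carrying a
#'   group-specific substitution (>= 0.06).
#' @param intra_group_muts maximum strain substitutions from the group
#'   ancestor.
#' @param flank_len random flanking sequence on each side of the
#'   amplicon in full-length records (bp).
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param reads_per_sample reads drawn per sample.
#' @param tail_len index-tail length appended to reads (exercises the 3'
#'   trim).
#' @param dirichlet_alpha per-label Dirichlet concentration for cohort
#'   compositions (named, over [profile_labels()] groups; default mimics
#'   a community dominated by Groups 3 and 4 with intermediate Groups 1,
#'   6 and 11).
#' @param cohort_size enrolled participants.
#' @param exclusion_counts named counts for the four exclusion
#'   categories (`low_genus_abundance`, `cancer_history`,
#'   `caloric_outlier`, `low_read_count`); disjoint by default.
#' @param overlap_exclusions if TRUE, exclusion categories may overlap
#'   (stress-tests first-stage-wins counting).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_groups = 12L,
                       refs_per_group = c(9L, 9L, 9L, 9L, 9L, 9L, 9L, 9L,
                                          9L, 9L, 8L, 8L),
                       core_len = 283L,
                       inter_group_divergence = 0.06,
                       intra_group_muts = 3L,
                       flank_len = 60L,
                       error_rate = 0.001,
                       reads_per_sample = 50000L,
                       tail_len = 23L,
                       dirichlet_alpha = NULL,
                       cohort_size = 660L,
                       exclusion_counts = c(low_genus_abundance = 55L,
                                            cancer_history = 13L,
                                            caloric_outlier = 3L,
                                            low_read_count = 9L),
                       overlap_exclusions = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(refs_per_group) == n_groups,
            inter_group_divergence >= 0.02,
            intra_group_muts >= 0,
            sum(exclusion_counts) <= cohort_size)
  n_sig <- ceiling(inter_group_divergence * core_len)
  if (n_groups * n_sig > core_len) {
    stop("divergence constraints unsatisfiable: ", n_groups, " groups x ",
         n_sig, " signature positions exceed the ", core_len, "-bp core",
         call. = FALSE)
  }
  if (is.null(dirichlet_alpha)) {
    w <- c(0.05, 0.005, 0.30, 0.20, 0.005, 0.09, 0.005, 0.005, 0.005,
           0.005, 0.09, 0.005)[seq_len(n_groups)]
    w <- w / sum(w)
    dirichlet_alpha <- stats::setNames(w * 8, paste("Group",
                                                    seq_len(n_groups)))
  }
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 refs_per_group = as.integer(refs_per_group),
                 core_len = as.integer(core_len),
                 inter_group_divergence = inter_group_divergence,
                 intra_group_muts = as.integer(intra_group_muts),
                 flank_len = as.integer(flank_len),
                 error_rate = error_rate,
                 reads_per_sample = as.integer(reads_per_sample),
                 tail_len = as.integer(tail_len),
                 dirichlet_alpha = dirichlet_alpha,
                 cohort_size = as.integer(cohort_size),
                 exclusion_counts = exclusion_counts,
                 overlap_exclusions = overlap_exclusions),
            class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_at <- function(letters, positions) {
  for (p in positions) {
    letters[p] <- sample(setdiff(c("A", "C", "G", "T"), letters[p]), 1L)
  }
  letters
}

#' Simulate a group-annotated rpoA reference library
#'
#' One random ancestor core; each group receives a disjoint set of
#' signature positions (a fraction `inter_group_divergence` of the core)
#' mutated away from the ancestor, so any two groups differ at >= twice
#' that many core positions; strains within a group add at most
#' `intra_group_muts` further substitutions. Full-length records embed
#' the amplicon (random forward-primer expansion + core + reverse
#' complement of a random reverse-primer expansion) between random
#' flanks, so primer-inclusive amplicons are 21 + core + 21 bp.
#'
#' @param cfg `sim_config`.
#' @param pair `primer_pair` providing the primer sites.
#' @return List: `library` (a `ref_library` with `amplicon_seq` already
#'   populated from the generator), `manifest` (true group of every
#'   record, signature positions, seed).
#' @export
simulate_reference_library <- function(cfg, pair = meta_rpoa_primers()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxa <- faecalibacterium_taxonomy()
  core_len <- cfg$core_len
  n_sig <- ceiling(cfg$inter_group_divergence * core_len)
  ancestor <- strsplit(.random_dna(core_len), "")[[1]]
  sig_pool <- sample.int(core_len, cfg$n_groups * n_sig)
  fwd_variants <- expand_degenerate(pair$fwd$seq)
  rev_variants <- expand_degenerate(pair$rev$seq)

  seqs <- character(); ids <- character()
  manifest_rows <- list()
  for (g in seq_len(cfg$n_groups)) {
    sig <- sig_pool[((g - 1L) * n_sig + 1L):(g * n_sig)]
    group_core <- .mutate_at(ancestor, sig)
    species <- taxa$species[taxa$group_id == g]
    ## primer-site variants are fixed per group: varying them across
    ## strains would erode the within-group identity floor
    fwd_site <- sample(fwd_variants, 1L)
    rev_site <- sample(rev_variants, 1L)
    for (s in seq_len(cfg$refs_per_group[g])) {
      strain_core <- group_core
      n_mut <- if (s == 1L) 0L else sample.int(cfg$intra_group_muts, 1L)
      mut_pos <- if (n_mut > 0L) sample.int(core_len, n_mut) else integer()
      strain_core <- .mutate_at(strain_core, mut_pos)
      amplicon <- paste0(fwd_site, paste(strain_core, collapse = ""),
                         reverse_complement(rev_site))
      full <- paste0(.random_dna(cfg$flank_len), amplicon,
                     .random_dna(cfg$flank_len))
      strain <- sprintf("SYN%02d-%02d", g, s)
      id <- sprintf("Group%d|%s|%s", g, species, strain)
      ids <- c(ids, id); seqs <- c(seqs, full)
      manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
        record_id = id, group_id = g, strain = strain,
        amplicon_seq = amplicon, n_strain_muts = n_mut,
        stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- ids
  lib <- as_ref_library(seqs)
  lib$amplicon_seq <- vapply(manifest_rows, `[[`, character(1),
                             "amplicon_seq")
  list(library = lib,
       manifest = list(records = do.call(rbind, manifest_rows),
                       signature_positions = split(
                         sig_pool, rep(seq_len(cfg$n_groups), each = n_sig)),
                       seed = cfg$seed))
}

.add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    letters <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(letters), n_err[i])
    letters <- .mutate_at(letters, pos)
    reads[i] <- paste(letters, collapse = "")
  }
  reads
}

#' Simulate amplicon reads for one sample
#'
#' Reads are drawn multinomially across groups according to
#' `composition`, uniformly across each group's reference amplicons,
#' subjected to per-base substitution errors, and given a random
#' `tail_len`-base index tail (removed later by the 3' trim). Reads are
#' generated pre-merged.
#'
#' @param lib amplicon-populated `ref_library`.
#' @param composition named numeric vector (group label -> fraction,
#'   e.g. `c("Group 3" = 0.5, ...)`), summing to 1.
#' @param cfg `sim_config`.
#' @param sample_seed seed for this sample (defaults to `cfg$seed`).
#' @return List: `reads` (character vector), `manifest` (true per-group
#'   read counts and error settings).
#' @export
simulate_sample_reads <- function(lib, composition, cfg,
                                  sample_seed = cfg$seed) {
  stopifnot(inherits(lib, "ref_library"), length(composition) > 0L,
            abs(sum(composition) - 1) < 1e-8)
  set.seed(sample_seed)
  gids <- as.integer(sub("^Group ", "", names(composition)))
  stopifnot(!any(is.na(gids)))
  counts <- as.integer(stats::rmultinom(1L, cfg$reads_per_sample,
                                        composition)[, 1])
  reads <- character(0)
  for (k in seq_along(gids)) {
    if (counts[k] == 0L) next
    pool <- lib$amplicon_seq[lib$group_id == gids[k]]
    pool <- pool[!is.na(pool)]
    stopifnot(length(pool) > 0L)
    reads <- c(reads, sample(pool, counts[k], replace = TRUE))
  }
  reads <- sample(reads)   # shuffle group blocks
  reads <- .add_read_errors(reads, cfg$error_rate)
  if (cfg$tail_len > 0L && length(reads) > 0L) {
    tl <- matrix(sample(c("A", "C", "G", "T"),
                        length(reads) * cfg$tail_len, replace = TRUE),
                 nrow = length(reads))
    tails <- do.call(paste0, as.data.frame(tl, stringsAsFactors = FALSE))
    reads <- paste0(reads, tails)
  }
  list(reads = reads,
       manifest = list(true_counts = stats::setNames(counts,
                                                     names(composition)),
                       error_rate = cfg$error_rate,
                       seed = sample_seed))
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a cohort with metadata, compositions and exclusion labels
#'
#' Generates `cohort_size` participants with host metadata (age, sex,
#' BMI, caloric intake, defecation frequency, exercise habit, region,
#' 16S genus-level relative abundance, cancer history, 18 diet-category
#' intakes), Dirichlet species compositions, and the four exclusion
#' categories at the configured counts (disjoint by default, so the
#' cascade arithmetic is exact). An optional exposure effect of known
#' log-linear magnitude can be injected into one group's composition.
#'
#' @param cfg `sim_config`.
#' @param inject_effect optional list `list(exposure =, label =, beta =)`:
#'   the label's abundance is scaled by `exp(beta * z(exposure))` and
#'   renormalized.
#' @return List: `cohort` (data frame), `compositions` (samples x labels
#'   matrix of true relative abundances), `total_reads` (named vector;
#'   below threshold for the `low_read_count` category),
#'   `manifest` (true exclusion labels per sample, injected effect).
#' @export
simulate_cohort <- function(cfg, inject_effect = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$cohort_size
  ids <- sprintf("S%04d", seq_len(n))

  ## exclusion assignment
  excl <- rep("none", n)
  counts <- cfg$exclusion_counts
  if (cfg$overlap_exclusions) {
    flags <- sapply(names(counts), function(nm) {
      f <- rep(FALSE, n); f[sample.int(n, counts[[nm]])] <- TRUE; f
    })
  } else {
    pick <- sample.int(n, sum(counts))
    flags <- matrix(FALSE, n, length(counts),
                    dimnames = list(NULL, names(counts)))
    off <- 0L
    for (j in seq_along(counts)) {
      if (counts[[j]] > 0L)
        flags[pick[(off + 1L):(off + counts[[j]])], j] <- TRUE
      off <- off + counts[[j]]
    }
  }

  age <- sample(21:83, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.18, 0.82))
  bmi <- round(stats::rnorm(n, 22, 3), 1)
  kcal <- round(stats::rnorm(n, 1900, 420))
  kcal <- pmin(pmax(kcal, 650), 3900)          # in-range baseline
  kcal[flags[, "caloric_outlier"]] <-
    sample(c(400, 450, 500, 4200, 4500), sum(flags[, "caloric_outlier"]),
           replace = TRUE)
  genus <- stats::rbeta(n, 2, 18)              # typically 5-15%
  genus <- pmax(genus, 0.011)
  genus[flags[, "low_genus_abundance"]] <-
    stats::runif(sum(flags[, "low_genus_abundance"]), 0, 0.009)
  cancer <- flags[, "cancer_history"]
  defecation <- sample(c("daily", "every_2_3_days", "less_often"), n,
                       replace = TRUE, prob = c(0.6, 0.3, 0.1))
  exercise <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
  region <- sample(c("urban", "rural"), n, replace = TRUE,
                   prob = c(0.7, 0.3))

  diet_categories <- c("RICE", "CRL", "POT", "SGR", "BEAN", "VEG", "FRT",
                       "FISH", "MEAT", "EGG", "MILK", "OIL", "SWT", "BEV",
                       "SEA", "SOY", "FUNGI", "SPICE")
  diet <- sapply(diet_categories, function(cat)
    round(stats::rlnorm(n, meanlog = 3.5, sdlog = 0.6), 1))
  colnames(diet) <- diet_categories

  labels <- paste("Group", seq_len(cfg$n_groups))
  comp <- .rdirichlet(n, cfg$dirichlet_alpha)
  colnames(comp) <- labels
  rownames(comp) <- ids

  cohort <- data.frame(sample_id = ids, age = age, sex = sex, BMI = bmi,
                       kcal = kcal, defecation = defecation,
                       exercise = exercise, region = region,
                       genus_relab_16S = genus, cancer_history = cancer,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(diet))

  if (!is.null(inject_effect)) {
    stopifnot(all(c("exposure", "label", "beta") %in% names(inject_effect)),
              inject_effect$exposure %in% names(cohort),
              inject_effect$label %in% labels)
    z <- as.numeric(scale(cohort[[inject_effect$exposure]]))
    comp[, inject_effect$label] <-
      comp[, inject_effect$label] * exp(inject_effect$beta * z)
    comp <- comp / rowSums(comp)
  }

  total_reads <- rep(cfg$reads_per_sample, n)
  total_reads[flags[, "low_read_count"]] <-
    sample(1000:9999, sum(flags[, "low_read_count"]), replace = TRUE)
  names(total_reads) <- ids

  for (j in rev(seq_along(counts))) excl[flags[, j]] <- names(counts)[j]

  list(cohort = cohort, compositions = comp, total_reads = total_reads,
       manifest = list(exclusion = stats::setNames(excl, ids),
                       flags = flags,
                       injected_effect = inject_effect,
                       seed = cfg$seed))
}
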