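test_that("read preprocessing trims tails, strips primers and drops short reads", {
  pair <- meta_rpoa_primers()
  set.seed(41)
  amp <- paste0(expand_degenerate(pair$fwd$seq)[1], random_dna(283),
                reverse_complement(expand_degenerate(pair$rev$seq)[1]))
  read <- paste0(amp, random_dna(23))   # 325 + index tail
  expect_equal(nchar(read), 348)
  pp <- preprocess_reads(read, pair)
  expect_equal(pp$stats$n_retained, 1)
  expect_equal(nchar(pp$reads), 283)    # tail and both primers removed
  expect_identical(pp$reads, substr(amp, 22, 304))

  ## a read whose trimmed length falls below 250 is dropped
  short <- paste0(random_dna(260))
  pp2 <- preprocess_reads(short, pair = NULL)
  expect_equal(pp2$stats$n_dropped_short, 1)
  expect_equal(length(pp2$reads), 0)

  ## 300-nt read without primer content: plain 23-base trim
  plain <- random_dna(300)
  pp3 <- preprocess_reads(plain, pair = NULL)
  expect_equal(nchar(pp3$reads), 277)

  ## empty batch
  pp4 <- preprocess_reads(character())
  expect_equal(pp4$stats$n_input, 0)
  expect_length(pp4$reads, 0)
})

test_that("ASV calling dereplicates, drops singletons and orders deterministically", {
  set.seed(42)
  s <- random_dna(260); s2 <- plant_substitutions(s, 1)
  batches <- list(A = c(rep(s, 1000), s2), B = rep(s, 500))
  asvs <- call_asvs(batches)
  expect_equal(nrow(asvs$asv), 1)          # singleton s2 dropped
  expect_equal(asvs$asv$total_count, 1500)
  expect_equal(unname(asvs$counts[1, ]), c(1000L, 500L))

  ## short sequences are discarded even when abundant
  shorty <- random_dna(100)
  asvs2 <- call_asvs(list(A = c(rep(s, 10), rep(shorty, 50))))
  expect_equal(nrow(asvs2$asv), 1)

  ## deterministic ordering: count desc then lexicographic
  t1 <- random_dna(260); t2 <- random_dna(260)
  asvs3 <- call_asvs(list(A = c(rep(t1, 5), rep(t2, 5), rep(s, 9))))
  expect_equal(asvs3$asv$total_count, c(9L, 5L, 5L))
  expect_equal(asvs3$asv$seq[2:3], sort(c(t1, t2)))
  expect_equal(asvs3$asv$asv_id, sprintf("ASV%05d", 1:3))
})

test_that("tiered classification assigns groups by identity thresholds", {
  sim <- small_library(seed = 43, groups = 5L, per_group = 1L)
  lib <- sim$library
  ref4 <- lib$amplicon_seq[lib$group_id == 4][1]

  ## exact match
  cls <- classify_asvs(c(a1 = ref4), lib)
  expect_equal(cls$best_identity, 100)
  expect_equal(cls$label, "Group 4")
  expect_false(cls$tie_flag)

  set.seed(44)
  ## 9 substitutions in a 250-mer core: identity vs its own reference is
  ## >= 95 and < 98; 25 substitutions fall below 95 (values verified by
  ## the planted-mutation arithmetic on the end-gap-free contract)
  core250 <- substr(ref4, 22, 271)
  mid <- plant_substitutions(core250, 9)    # 241/250 = 96.4%
  far <- plant_substitutions(core250, 25)   # 225/250 = 90%
  cls2 <- classify_asvs(c(mid = mid, far = far), lib)
  expect_equal(cls2$label, c("Other Faecalibacterium", "Others"))
  expect_equal(cls2$best_identity[1], 100 * 241 / 250)

  ## boundary inclusive: exactly 98.0% stays in the species group
  b98 <- plant_substitutions(core250, 5)    # 245/250 = 98.0%
  cls3 <- classify_asvs(c(b = b98), lib)
  expect_equal(cls3$best_identity, 98)
  expect_equal(cls3$label, "Group 4")

  ## tie across groups at >= 98: earliest library record wins, flagged
  twin <- lib[c(1, 1), ]
  twin$record_id <- c("Group1|F. prausnitzii|a", "Group2|F. langellae|b")
  twin$group_id <- c(1L, 2L)
  class(twin) <- class(lib)
  cls4 <- classify_asvs(c(q = twin$amplicon_seq[1]), twin)
  expect_true(cls4$tie_flag)
  expect_equal(cls4$label, "Group 1")
  expect_equal(cls4$best_ref, "Group1|F. prausnitzii|a")

  expect_error(classify_asvs(c(a = "ACGT"),
                             structure(data.frame(), class = c("ref_library",
                                                               "data.frame"))))
})

test_that("classification tiers match a brute-force identity oracle", {
  ## short-amplicon library keeps the quadratic R oracle affordable
  cfg <- sim_config(seed = 45, n_groups = 4L, refs_per_group = rep(2L, 4L),
                    core_len = 80L)
  lib <- simulate_reference_library(cfg)$library
  set.seed(46)
  queries <- character(20)
  for (i in seq_len(20)) {
    ref <- sample(lib$amplicon_seq, 1)
    queries[i] <- plant_substitutions(substr(ref, 10, 109),
                                      sample(0:15, 1))
  }
  cls <- classify_asvs(setNames(queries, paste0("q", 1:20)), lib)
  for (i in seq_len(20)) {
    ids <- vapply(lib$amplicon_seq, function(r)
      oracle_align_identity(queries[i], r)$identity_pct, numeric(1))
    best <- max(ids)
    expect_equal(cls$best_identity[i], best, tolerance = 1e-9)
    want <- if (best >= 98) paste("Group", lib$group_id[which.max(ids)])
            else if (best >= 95) "Other Faecalibacterium" else "Others"
    expect_equal(cls$label[i], want)
  }
})

test_that("profiles normalize counts per sample and apply the read floor", {
  sim <- small_library(seed = 47, groups = 3L, per_group = 1L)
  lib <- sim$library
  r1 <- lib$amplicon_seq[1]; r2 <- lib$amplicon_seq[2]
  batches <- list(S1 = rep(r1, 10000),
                  S2 = c(rep(r1, 7500), rep(r2, 2500)),
                  S3 = rep(r1, 9999))
  asvs <- call_asvs(batches)
  cls <- classify_asvs(asvs, lib)
  prof <- build_profiles(asvs, cls)
  expect_equal(prof$excluded_samples, "S3")
  expect_equal(rownames(prof$rel_abundance), c("S1", "S2"))
  expect_equal(prof$rel_abundance["S1", "Group 1"], 1.0)
  expect_equal(unname(prof$rel_abundance["S2", c("Group 1", "Group 2")]),
               c(0.75, 0.25))
  ## conservation: abundances sum to 1 per retained sample
  expect_equal(unname(rowSums(prof$rel_abundance)), c(1, 1),
               tolerance = 1e-9)
})

test_that("cohort summary computes prevalence, richness and minor flags", {
  labels <- profile_labels()
  rel <- matrix(0, nrow = 10, ncol = length(labels),
                dimnames = list(paste0("S", 1:10), labels))
  rel[, "Group 4"] <- 0.9
  rel[, "Group 3"] <- 0.096
  rel[, "Others"] <- 0.004   # below 0.5% everywhere
  summ <- summarize_cohort(rel)
  pl <- summ$per_label
  expect_equal(pl$prevalence[pl$label == "Group 4"], 1.0)
  expect_equal(pl$prevalence[pl$label == "Others"], 0.0)
  expect_true(all(summ$richness == 2))
  expect_false(pl$minor[pl$label == "Group 4"])
  expect_true(pl$minor[pl$label == "Group 7"])

  ## monotonicity: raising the detection threshold never raises
  ## prevalence or richness
  set.seed(48)
  rel2 <- matrix(stats::runif(140, 0, 0.2), nrow = 10,
                 dimnames = list(paste0("S", 1:10), labels))
  rel2 <- rel2 / rowSums(rel2)
  th_lo <- filter_thresholds(detection_relab = 0.005)
  th_hi <- filter_thresholds(detection_relab = 0.02)
  s_lo <- summarize_cohort(rel2, th_lo)
  s_hi <- summarize_cohort(rel2, th_hi)
  expect_true(all(s_hi$per_label$prevalence <= s_lo$per_label$prevalence))
  expect_true(all(s_hi$richness <= s_lo$richness))
})

test_that("exclusion cascade removes each sample at its first applicable stage", {
  ## hand-built 10-row table with one overlapping sample
  cohort <- data.frame(
    sample_id = paste0("P", 1:10),
    genus_relab_16S = c(0.005, rep(0.05, 9)),
    cancer_history = c(TRUE, TRUE, rep(FALSE, 8)),    # P1 overlaps stage 1
    kcal = c(2000, 2000, 500, rep(2000, 7)),
    stringsAsFactors = FALSE)
  reads <- setNames(c(rep(20000, 9), 500), cohort$sample_id)
  rep1 <- apply_cohort_cascade(cohort, reads)
  expect_equal(rep1$stages$n_removed, c(1L, 1L, 1L, 1L))
  expect_equal(rep1$n_final, 6)
  expect_equal(sum(rep1$stages$n_removed), rep1$n_enrolled - rep1$n_final)

  ## study-scale synthetic cohort: 660 enrolled, 55/13/3/9 -> 580
  cohsim <- simulate_cohort(sim_config(seed = 49))
  rep2 <- apply_cohort_cascade(cohsim$cohort, cohsim$total_reads)
  expect_equal(rep2$n_enrolled, 660)
  expect_equal(rep2$stages$n_removed, c(55L, 13L, 3L, 9L))
  expect_equal(rep2$n_final, 580)

  ## no exclusions triggered
  clean <- cohort[4:9, ]
  rep3 <- apply_cohort_cascade(clean, reads[4:9])
  expect_equal(rep3$n_final, nrow(clean))

  expect_error(apply_cohort_cascade(cohort, reads[1:3]), "without read")
})
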