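## Independent oracles and fixture builders shared across the suite.

## Pure-R dynamic-programming oracle for end-gap-free alignment identity.
## Same contract as the package kernel (match +1, mismatch -1, gap -2;
## identity over columns excluding terminal gaps; among co-optimal
## alignments the one with most matches, then fewest columns) but
## implemented independently with explicit full matrices over the
## (score, matches, columns) triple.
oracle_align_identity <- function(a, b) {
  al <- strsplit(toupper(a), "")[[1]]
  bl <- strsplit(toupper(b), "")[[1]]
  m <- length(al); n <- length(bl)
  S <- matrix(0L, m + 1L, n + 1L)
  M <- matrix(0L, m + 1L, n + 1L)
  C <- matrix(0L, m + 1L, n + 1L)
  pick <- function(cands) {
    ## cands: list of c(score, matches, columns)
    best <- cands[[1]]
    for (k in seq_along(cands)[-1]) {
      x <- cands[[k]]
      if (x[1] > best[1] ||
          (x[1] == best[1] && (x[2] > best[2] ||
                               (x[2] == best[2] && x[3] < best[3])))) {
        best <- x
      }
    }
    best
  }
  for (i in 1:m) {
    for (j in 1:n) {
      sub <- if (al[i] == bl[j] && al[i] %in% c("A", "C", "G", "T")) 1L else -1L
      b3 <- pick(list(
        c(S[i, j] + sub, M[i, j] + (sub == 1L), C[i, j] + 1L),
        c(S[i, j + 1L] - 2L, M[i, j + 1L], C[i, j + 1L] + 1L),
        c(S[i + 1L, j] - 2L, M[i + 1L, j], C[i + 1L, j] + 1L)))
      S[i + 1L, j + 1L] <- b3[1]; M[i + 1L, j + 1L] <- b3[2]
      C[i + 1L, j + 1L] <- b3[3]
    }
  }
  border <- list(c(0L, 0L, 0L))
  for (i in 0:m) border[[length(border) + 1L]] <-
    c(S[i + 1L, n + 1L], M[i + 1L, n + 1L], C[i + 1L, n + 1L])
  for (j in 0:n) border[[length(border) + 1L]] <-
    c(S[m + 1L, j + 1L], M[m + 1L, j + 1L], C[m + 1L, j + 1L])
  best <- pick(border)
  list(matches = best[2], columns = best[3], score = best[1],
       identity_pct = if (best[3] > 0) 100 * best[2] / best[3] else 0)
}

## Exact two-sided Mann-Whitney p-value by full enumeration of all
## C(n_x + n_y, n_x) group assignments (no-ties case).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  obs <- u_stat(x, y)
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2L, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  paste(sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N"), n, replace = TRUE),
        collapse = "")
}

## Plant exactly k substitutions into a sequence (no indels), at interior
## positions: a substitution at the very first/last base would be clipped
## by the free terminal gaps and the (L - k)/L identity arithmetic would
## no longer apply.
plant_substitutions <- function(seq, k) {
  letters <- strsplit(seq, "")[[1]]
  stopifnot(k <= length(letters) - 2L)
  pos <- if (k > 0L) sample(2:(length(letters) - 1L), k) else integer()
  for (p in pos) {
    letters[p] <- sample(setdiff(c("A", "C", "G", "T"), letters[p]), 1L)
  }
  paste(letters, collapse = "")
}

## Small reference library fixture: `groups` groups, `per_group` strains,
## built through the package generator at a fixed seed.
small_library <- function(seed = 101L, groups = 5L, per_group = 1L) {
  cfg <- sim_config(seed = seed, n_groups = groups,
                    refs_per_group = rep(per_group, groups))
  simulate_reference_library(cfg)
}

## The staggered five-species mock community used for composition
## recovery: one strain per species at 30/25/20/15/10%.
mock_composition <- function() {
  stats::setNames(c(0.30, 0.25, 0.20, 0.15, 0.10), paste("Group", 1:5))
}

run_mock_pipeline <- function(seed, reads = 50000L, error_rate = 0.001) {
  sim <- small_library(seed = 1000L + seed, groups = 5L, per_group = 1L)
  cfg <- sim_config(seed = seed, n_groups = 5L,
                    refs_per_group = rep(1L, 5L),
                    reads_per_sample = reads, error_rate = error_rate)
  comp <- mock_composition()
  rr <- simulate_sample_reads(sim$library, comp, cfg, sample_seed = seed)
  pp <- preprocess_reads(rr$reads)
  asvs <- call_asvs(list(S1 = pp$reads))
  cls <- classify_asvs(asvs, sim$library)
  prof <- build_profiles(asvs, cls)
  est <- prof$rel_abundance[1, ]
  true_p <- rr$manifest$true_counts / sum(rr$manifest$true_counts)
  l1 <- sum(abs(est[names(true_p)] - true_p)) +
    sum(est[setdiff(names(est), names(true_p))])
  list(l1 = l1, est = est, true_p = true_p, n_asvs = nrow(asvs$asv))
}
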