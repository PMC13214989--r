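## Degenerate primer design from a multiple alignment, in-silico PCR,
## specificity screening, and the synthetic-construct copy-number
## arithmetic used in primer validation.

#' The meta-rpoA primer pair
#'
#' The degenerate primer pair targeting the conserved flanks of the
#' 325-bp rpoA region that resolves human-origin *Faecalibacterium* at the
#' species level: forward `CACCCCBGTKCTCAAGGTGAA` (degeneracy 6) and
#' reverse `CCSARRTTRCGRACYTTCATC` (degeneracy 64), both written 5'->3'
#' on their own strand.
#'
#' @param min_product,max_product accepted product-length range in bp.
#' @return A `primer_pair` object.
#' @export
meta_rpoa_primers <- function(min_product = 100L, max_product = 1000L) {
  primer_pair(
    fwd = degenerate_primer("meta-rpoA-F", "CACCCCBGTKCTCAAGGTGAA", "forward"),
    rev = degenerate_primer("meta-rpoA-R", "CCSARRTTRCGRACYTTCATC", "reverse"),
    min_product = min_product, max_product = max_product
  )
}

#' Construct a degenerate primer
#'
#' @param name primer name.
#' @param seq IUPAC string, 5'->3'. Reverse primers are stored 5'->3' on
#'   the reverse strand (the oligo as synthesized).
#' @param direction `"forward"` or `"reverse"`.
#' @return A `degenerate_primer` object.
#' @export
degenerate_primer <- function(name, seq, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  .check_iupac(seq)
  structure(list(name = name, seq = toupper(seq), direction = direction,
                 degeneracy = degeneracy(seq)),
            class = "degenerate_primer")
}

#' Construct a primer pair
#'
#' @param fwd,rev `degenerate_primer` objects.
#' @param min_product,max_product product-length range (bp), primer-inclusive.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(fwd, rev, min_product = 100L, max_product = 1000L) {
  stopifnot(inherits(fwd, "degenerate_primer"),
            inherits(rev, "degenerate_primer"),
            min_product <= max_product)
  structure(list(fwd = fwd, rev = rev,
                 min_product = as.integer(min_product),
                 max_product = as.integer(max_product)),
            class = "primer_pair")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("%s (%s): 5'-%s-3' [degeneracy %d]\n",
              x$name, x$direction, x$seq, x$degeneracy))
  invisible(x)
}

#' @export
print.primer_pair <- function(x, ...) {
  print(x$fwd); print(x$rev)
  cat(sprintf("product range: %d-%d bp\n", x$min_product, x$max_product))
  invisible(x)
}

## --- consensus codes from a multiple alignment -------------------------

.code_for_bases <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(map)[vapply(map, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = "") == key, logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for base set: ", key)
  hit
}

#' Per-column minimal IUPAC consensus codes of an alignment
#'
#' For each column, the minimal IUPAC code covering every base whose
#' frequency among the rows is at least `min_base_freq`; rare alleles
#' (typically sequencing errors) below that threshold do not inflate
#' primer degeneracy. Columns containing gap characters are flagged
#' unusable for primer placement.
#'
#' @param msa character vector of equal-length aligned sequences (>= 2 rows;
#'   `-` or `.` as gaps).
#' @param min_base_freq minimum base frequency for inclusion (default 0.05).
#' @return Data frame with one row per column: `code`, `usable`,
#'   `degeneracy`.
#' @export
column_base_sets <- function(msa, min_base_freq = 0.05) {
  stopifnot(length(msa) >= 2L)
  msa <- toupper(msa)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("ragged alignment", call. = FALSE)
  mat <- do.call(rbind, strsplit(msa, ""))
  ncols <- ncol(mat)
  code <- character(ncols); usable <- logical(ncols); degen <- integer(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    if (any(col %in% c("-", "."))) {
      code[j] <- NA_character_; usable[j] <- FALSE; degen[j] <- NA_integer_
      next
    }
    tab <- table(col) / length(col)
    keep <- names(tab)[tab >= min_base_freq]
    if (length(keep) == 0L) keep <- names(tab)
    ## expand any degenerate letters present in the rows themselves
    bases <- unique(unlist(lapply(keep, iupac_bases)))
    code[j] <- .code_for_bases(bases)
    usable[j] <- TRUE
    degen[j] <- length(bases)
  }
  data.frame(column = seq_len(ncols), code = code, usable = usable,
             degeneracy = degen, stringsAsFactors = FALSE)
}

#' Design ranked degenerate primer pairs from a multiple alignment
#'
#' Enumerates alignment windows whose consensus degeneracy stays within
#' `degeneracy_cap` and which perfectly match (0 mismatches) at least
#' `n_rows - max_missed_targets` rows; pairs forward/reverse windows whose
#' primer-inclusive product length lies in the product range. Pairs are
#' ranked by coverage (descending), total degeneracy (ascending), product
#' length (descending), with ties broken by leftmost forward start.
#'
#' @param msa character vector of aligned sequences.
#' @param primer_length integer vector of allowed primer lengths
#'   (default 20:22).
#' @param degeneracy_cap maximum consensus degeneracy per primer
#'   (default 64).
#' @param product_range length-2 vector, accepted product lengths in bp.
#' @param max_missed_targets rows a window may fail to match (default 0).
#' @param min_base_freq passed to [column_base_sets()].
#' @return Data frame of ranked pairs (fwd_seq, rev_seq, coordinates,
#'   coverage, degeneracies, product length). When no window qualifies, an
#'   empty data frame carrying a per-window diagnostic report in
#'   `attr(, "window_report")`.
#' @export
design_primer_pairs <- function(msa, primer_length = 20:22,
                                degeneracy_cap = 64,
                                product_range = c(100L, 1000L),
                                max_missed_targets = 0L,
                                min_base_freq = 0.05) {
  msa <- toupper(msa)
  cols <- column_base_sets(msa, min_base_freq)
  n_rows <- length(msa)
  ncols <- nrow(cols)
  rows_mat <- do.call(rbind, strsplit(msa, ""))

  windows <- list(); report <- list()
  for (L in sort(unique(as.integer(primer_length)))) {
    if (L > ncols) next
    for (s in seq_len(ncols - L + 1L)) {
      span <- s:(s + L - 1L)
      if (!all(cols$usable[span])) next
      deg <- prod(cols$degeneracy[span])
      if (deg > degeneracy_cap) {
        report[[length(report) + 1L]] <-
          data.frame(start = s, length = L, degeneracy = deg,
                     reason = "degeneracy above cap")
        next
      }
      consensus <- paste(cols$code[span], collapse = "")
      cov <- sum(vapply(seq_len(n_rows), function(r) {
        w <- paste(rows_mat[r, span], collapse = "")
        degenerate_match(consensus, w, max_mismatch = 0L,
                         protect_3prime = 0L)$match
      }, logical(1)))
      if (cov < n_rows - max_missed_targets) {
        report[[length(report) + 1L]] <-
          data.frame(start = s, length = L, degeneracy = deg,
                     reason = "coverage below requirement")
        next
      }
      windows[[length(windows) + 1L]] <-
        data.frame(start = s, end = s + L - 1L, length = L,
                   consensus = consensus, degeneracy = deg, coverage = cov,
                   stringsAsFactors = FALSE)
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(start = integer(), length = integer(),
               degeneracy = numeric(), reason = character())
  if (length(windows) == 0L) {
    out <- data.frame()
    attr(out, "window_report") <- report
    return(out)
  }
  win <- do.call(rbind, windows)

  pairs <- list()
  for (i in seq_len(nrow(win))) {
    for (j in seq_len(nrow(win))) {
      if (win$start[j] <= win$end[i]) next
      plen <- win$end[j] - win$start[i] + 1L
      if (plen < product_range[1] || plen > product_range[2]) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        fwd_start = win$start[i], fwd_end = win$end[i],
        rev_start = win$start[j], rev_end = win$end[j],
        fwd_seq = win$consensus[i],
        rev_seq = reverse_complement(win$consensus[j]),
        fwd_degeneracy = win$degeneracy[i],
        rev_degeneracy = win$degeneracy[j],
        total_degeneracy = win$degeneracy[i] + win$degeneracy[j],
        coverage = min(win$coverage[i], win$coverage[j]),
        product_length = plen,
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0L) {
    out <- data.frame()
    attr(out, "window_report") <- report
    return(out)
  }
  out <- do.call(rbind, pairs)
  ord <- order(-out$coverage, out$total_degeneracy, -out$product_length,
               out$fwd_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_report") <- report
  out
}

## --- in-silico PCR ------------------------------------------------------

## Scan a concrete template for all positions where `primer` (IUPAC,
## left-to-right) matches under max_mismatch with `protect` protected
## positions at the stated side ("right" = primer 3' end at window end).
.scan_sites <- function(primer, template, max_mismatch, protect,
                        protect_side = c("right", "left")) {
  protect_side <- match.arg(protect_side)
  pl <- strsplit(primer, "")[[1]]
  tl <- strsplit(template, "")[[1]]
  L <- length(pl); n <- length(tl)
  if (n < L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  allowed <- .primer_allowed_matrix(pl)
  tcode <- match(tl, c("A", "C", "G", "T"))
  tcode[is.na(tcode)] <- 5L
  npos <- n - L + 1L
  mm <- integer(npos); mm_prot <- integer(npos)
  prot_idx <- if (protect_side == "right") (L - protect + 1L):L
              else seq_len(protect)
  if (protect == 0L) prot_idx <- integer()
  for (k in seq_len(L)) {
    miss <- !allowed[k, ][tcode[k:(k + npos - 1L)]]
    ## N or unknown template letters never match
    miss[tcode[k:(k + npos - 1L)] == 5L] <- TRUE
    mm <- mm + miss
    if (k %in% prot_idx) mm_prot <- mm_prot + miss
  }
  ok <- mm <= max_mismatch & mm_prot == 0L
  data.frame(start = which(ok), mismatches = mm[ok])
}

.pcr_one_strand <- function(pair, template, max_mismatch, protect_3prime) {
  fwd <- pair$fwd$seq
  rev_rc <- reverse_complement(pair$rev$seq)  # reverse site on this strand
  Lf <- nchar(fwd); Lr <- nchar(rev_rc)
  fsites <- .scan_sites(fwd, template, max_mismatch, protect_3prime, "right")
  ## rev primer anneals to this strand's complement; its 3' end maps to the
  ## *left* end of the rc(rev) site on this strand
  rsites <- .scan_sites(rev_rc, template, max_mismatch, protect_3prime, "left")
  out <- list()
  for (i in seq_len(nrow(fsites))) {
    for (j in seq_len(nrow(rsites))) {
      s <- fsites$start[i]
      e <- rsites$start[j] + Lr - 1L
      plen <- e - s + 1L
      if (rsites$start[j] < s + Lf) next
      if (plen < pair$min_product || plen > pair$max_product) next
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, product_length = plen,
        fwd_mismatches = fsites$mismatches[i],
        rev_mismatches = rsites$mismatches[j],
        product_seq = substr(template, s, e),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(),
               product_length = integer(), fwd_mismatches = integer(),
               rev_mismatches = integer(), product_seq = character())
}

#' In-silico PCR of a degenerate primer pair against a template
#'
#' Scans both strands for forward-primer sites and reverse-complemented
#' reverse-primer sites under degenerate matching with 3'-end protection,
#' and emits every primer-inclusive product whose length falls in the
#' pair's product range. Coordinates are reported 0-based half-open on
#' the template's forward strand; minus-strand products are reported in
#' product orientation.
#'
#' @param pair `primer_pair`.
#' @param template concrete template sequence (character) or named vector
#'   of length 1.
#' @param max_mismatch tolerated mismatches per primer site (default 3).
#' @param protect_3prime protected 3' positions (default 3).
#' @param template_id label used in the output (default the vector name or
#'   `"template"`).
#' @return Data frame of amplicons: `template_id`, `start`, `end`,
#'   `strand`, `product_length`, `fwd_mismatches`, `rev_mismatches`,
#'   `product_seq`. Zero rows when no site pair is found.
#' @export
in_silico_pcr <- function(pair, template, max_mismatch = 3L,
                          protect_3prime = 3L, template_id = NULL) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.null(template_id)) {
    template_id <- if (!is.null(names(template))) names(template)[1]
                   else "template"
  }
  template <- toupper(unname(template[1]))
  if (nchar(template) == 0L) stop("empty template", call. = FALSE)

  plus <- .pcr_one_strand(pair, template, max_mismatch, protect_3prime)
  if (nrow(plus)) plus$strand <- "+"
  rc_t <- reverse_complement(template)
  minus <- .pcr_one_strand(pair, rc_t, max_mismatch, protect_3prime)
  n <- nchar(template)
  if (nrow(minus)) {
    minus$strand <- "-"
    ## map coordinates back to the forward strand
    s_fwd <- n - minus$end + 1L
    e_fwd <- n - minus$start + 1L
    minus$start <- s_fwd; minus$end <- e_fwd
  }
  out <- rbind(plus, minus)
  if (nrow(out) == 0L) {
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      product_length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer(), product_seq = character()))
  }
  ## convert to 0-based half-open
  out$start <- out$start - 1L
  data.frame(template_id = template_id, start = out$start, end = out$end,
             strand = out$strand, product_length = out$product_length,
             fwd_mismatches = out$fwd_mismatches,
             rev_mismatches = out$rev_mismatches,
             product_seq = out$product_seq, stringsAsFactors = FALSE)
}

#' Primer specificity and sensitivity screen
#'
#' Runs [in_silico_pcr()] over on-target and off-target reference sets and
#' summarizes: sensitivity = amplified on-targets / on-targets;
#' specificity = 1 - amplified off-targets / off-targets.
#'
#' @param pair `primer_pair`.
#' @param on_targets,off_targets named character vectors of sequences.
#' @param max_mismatch,protect_3prime matching tolerances.
#' @return List with `per_sequence` (data frame: id, set, amplified,
#'   product_length) and `summary` (sensitivity, specificity, counts).
#' @export
specificity_screen <- function(pair, on_targets, off_targets,
                               max_mismatch = 3L, protect_3prime = 3L) {
  stopifnot(length(on_targets) > 0L, length(off_targets) > 0L)
  screen_one <- function(seqs, set) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0(set, "_", seq_along(seqs))
    rows <- lapply(seq_along(seqs), function(i) {
      amp <- in_silico_pcr(pair, seqs[i], max_mismatch, protect_3prime,
                           template_id = ids[i])
      data.frame(id = ids[i], set = set, amplified = nrow(amp) > 0L,
                 product_length = if (nrow(amp)) amp$product_length[1]
                                  else NA_integer_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  per_seq <- rbind(screen_one(on_targets, "on_target"),
                   screen_one(off_targets, "off_target"))
  n_on <- sum(per_seq$set == "on_target")
  n_off <- sum(per_seq$set == "off_target")
  amp_on <- sum(per_seq$amplified[per_seq$set == "on_target"])
  amp_off <- sum(per_seq$amplified[per_seq$set == "off_target"])
  list(per_sequence = per_seq,
       summary = list(sensitivity = amp_on / n_on,
                      specificity = 1 - amp_off / n_off,
                      n_on_targets = n_on, n_off_targets = n_off,
                      amplified_on = amp_on, amplified_off = amp_off))
}

#' log10 copy number of a synthetic DNA construct
#'
#' Copies = mass\[g\] * Avogadro / (total length * 650 g/mol/bp), the
#' standard dsDNA arithmetic used to convert a mass of plasmid construct
#' (vector + insert) into gene copies for qPCR standards. 100 pg of a
#' 3,440-bp construct gives 7.43 log10 copies.
#'
#' @param mass_pg construct mass in picograms.
#' @param vector_len,insert_len construct component lengths in bp (their
#'   sum is the molecule length).
#' @return log10 of the copy number.
#' @examples
#' log10_copies(100, vector_len = 2450, insert_len = 990)  # 7.43
#' @export
log10_copies <- function(mass_pg, vector_len, insert_len = 0) {
  total_len <- vector_len + insert_len
  if (mass_pg <= 0) stop("mass must be positive", call. = FALSE)
  if (total_len <= 0) stop("construct length must be positive", call. = FALSE)
  avogadro <- 6.02214076e23
  copies <- (mass_pg * 1e-12) * avogadro / (total_len * 650)
  log10(copies)
}
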