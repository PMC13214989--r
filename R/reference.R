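## Curation, validation and serialization of the group-annotated rpoA
## reference library (12 species-level groups, 106 sequences by default)
## and its taxonomy table.

#' Species-level taxonomy of human-origin Faecalibacterium groups
#'
#' The twelve species-level phylogroups used throughout the package, with
#' the type (or representative, for yet-unclassified groups) strain of
#' each: named species such as *F. prausnitzii* (Group 1), *F. taiwanense*
#' (Group 3), *F. longum* (Group 4) and *F. duncaniae* (Group 6), plus
#' four yet-to-be-classified groups (5, 8, 11, 12).
#'
#' @return Data frame with `group_id`, `species`, `strain`,
#'   `representative` (TRUE when the strain is a representative rather
#'   than a type strain).
#' @export
faecalibacterium_taxonomy <- function() {
  data.frame(
    group_id = 1:12,
    species = c("F. prausnitzii", "F. langellae", "F. taiwanense",
                "F. longum", "unclassified", "F. duncaniae", "F. hattorii",
                "unclassified", "F. butyricigenerans", "F. wellingii",
                "unclassified", "unclassified"),
    strain = c("ATCC 27768", "CNCM I-4541", "HLW 78", "CM 04-06",
               "APC942/8-14-2", "A2-165", "APC922/41-1",
               "MGYG-HGUT-00195", "AF52-21", "HTF-F", "UMGS183", "UMGS253"),
    representative = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                       TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

.parse_ref_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !grepl("^Group[0-9]+$", parts[1])) {
    stop("malformed reference header (expected 'Group{n}|{species}|{strain}'): ",
         header, call. = FALSE)
  }
  gid <- as.integer(sub("^Group", "", parts[1]))
  list(group_id = gid, species = parts[2], strain = parts[3])
}

#' Load a group-annotated rpoA reference library from FASTA
#'
#' Headers must follow the `>Group{n}|{species}|{strain}` dialect; every
#' record is bound to a row of [faecalibacterium_taxonomy()] and duplicate
#' record ids are rejected.
#'
#' @param path FASTA path.
#' @return A `ref_library` data frame: `record_id`, `group_id`, `species`,
#'   `strain`, `full_seq`, `amplicon_seq` (NA until
#'   [extract_amplicons()] is run).
#' @export
load_library <- function(path) {
  seqs <- read_seqs(path)
  as_ref_library(seqs)
}

#' Build a `ref_library` from a named vector of sequences
#'
#' @param seqs named character vector; names follow the header dialect of
#'   [load_library()].
#' @return A `ref_library` data frame.
#' @export
as_ref_library <- function(seqs) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  meta <- lapply(ids, .parse_ref_header)
  gids <- vapply(meta, `[[`, integer(1), "group_id")
  known <- faecalibacterium_taxonomy()$group_id
  bad <- setdiff(unique(gids), known)
  if (length(bad)) {
    stop("unknown group id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lib <- data.frame(
    record_id = ids,
    group_id = gids,
    species = vapply(meta, `[[`, character(1), "species"),
    strain = vapply(meta, `[[`, character(1), "strain"),
    full_seq = toupper(unname(seqs)),
    amplicon_seq = NA_character_,
    stringsAsFactors = FALSE
  )
  class(lib) <- c("ref_library", "data.frame")
  lib
}

#' Write a reference library back to FASTA
#'
#' Inverse of [load_library()]; the round trip is bit-exact on records.
#'
#' @param lib `ref_library`.
#' @param path output FASTA path.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "ref_library"))
  seqs <- lib$full_seq
  names(seqs) <- lib$record_id
  write_fasta(seqs, path)
}

#' Populate library amplicon regions by in-silico PCR
#'
#' Runs [in_silico_pcr()] on each record's full sequence and stores the
#' primer-inclusive product. Records yielding no product are flagged with
#' a warning and excluded from downstream classification (partial genes
#' are tolerated, not fatal). When several products arise, the leftmost
#' is taken.
#'
#' @param lib `ref_library`.
#' @param pair `primer_pair` (default [meta_rpoa_primers()]).
#' @param max_mismatch,protect_3prime matching tolerances.
#' @return The library with `amplicon_seq` populated and an
#'   `attr(, "failed_records")` character vector of excluded ids.
#' @export
extract_amplicons <- function(lib, pair = meta_rpoa_primers(),
                              max_mismatch = 3L, protect_3prime = 3L) {
  stopifnot(inherits(lib, "ref_library"))
  failed <- character()
  for (i in seq_len(nrow(lib))) {
    amp <- in_silico_pcr(pair, lib$full_seq[i], max_mismatch,
                         protect_3prime, template_id = lib$record_id[i])
    if (nrow(amp) == 0L) {
      failed <- c(failed, lib$record_id[i])
      lib$amplicon_seq[i] <- NA_character_
    } else {
      amp <- amp[order(amp$start), , drop = FALSE]
      lib$amplicon_seq[i] <- amp$product_seq[1]
    }
  }
  if (length(failed)) {
    warning("no amplicon for record(s): ", paste(failed, collapse = ", "),
            "; excluded from classification", call. = FALSE)
  }
  attr(lib, "failed_records") <- failed
  lib
}

#' Validate intra-/inter-group identity separation of a library
#'
#' Computes all-pairs end-gap-free identity over amplicon regions and
#' checks that within-group pairs stay at or above `intra_min` and
#' cross-group pairs at or below `inter_max` (the species groups are
#' separated by <94% inter-group nucleotide identity while strains within
#' a species stay >=98%).
#'
#' @param lib amplicon-extracted `ref_library`.
#' @param intra_min minimum tolerated within-group identity (default 98).
#' @param inter_max maximum tolerated cross-group identity (default 94).
#' @return List of class `library_validation`: `intra` (per-group min /
#'   mean identity), `inter` (per group-pair max identity), `flags`
#'   (violating record pairs), `n_records`.
#' @export
validate_separation <- function(lib, intra_min = 98, inter_max = 94) {
  stopifnot(inherits(lib, "ref_library"))
  lib <- lib[!is.na(lib$amplicon_seq), , drop = FALSE]
  if (nrow(lib) == 0L) stop("empty library", call. = FALSE)
  idm <- identity_matrix(lib$amplicon_seq, lib$amplicon_seq)
  n <- nrow(lib)
  gids <- lib$group_id

  flags <- list()
  intra_rows <- list()
  for (g in sort(unique(gids))) {
    idx <- which(gids == g)
    vals <- numeric()
    if (length(idx) >= 2L) {
      pr <- utils::combn(idx, 2L)
      vals <- idm[cbind(pr[1, ], pr[2, ])]
      low <- which(vals < intra_min)
      for (k in low) {
        flags[[length(flags) + 1L]] <- data.frame(
          record_a = lib$record_id[pr[1, k]],
          record_b = lib$record_id[pr[2, k]],
          identity_pct = vals[k], type = "intra_below_min",
          stringsAsFactors = FALSE)
      }
    }
    intra_rows[[length(intra_rows) + 1L]] <- data.frame(
      group_id = g, n_records = length(idx),
      min_identity = if (length(vals)) min(vals) else NA_real_,
      mean_identity = if (length(vals)) mean(vals) else NA_real_)
  }

  inter_rows <- list()
  groups <- sort(unique(gids))
  if (length(groups) >= 2L) {
    gp <- utils::combn(groups, 2L)
    for (k in seq_len(ncol(gp))) {
      ia <- which(gids == gp[1, k]); ib <- which(gids == gp[2, k])
      sub <- idm[ia, ib, drop = FALSE]
      mx <- max(sub)
      inter_rows[[length(inter_rows) + 1L]] <- data.frame(
        group_a = gp[1, k], group_b = gp[2, k], max_identity = mx)
      if (mx > inter_max) {
        w <- which(sub == mx, arr.ind = TRUE)[1, ]
        flags[[length(flags) + 1L]] <- data.frame(
          record_a = lib$record_id[ia[w[1]]],
          record_b = lib$record_id[ib[w[2]]],
          identity_pct = mx, type = "inter_above_max",
          stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    intra = do.call(rbind, intra_rows),
    inter = if (length(inter_rows)) do.call(rbind, inter_rows) else
      data.frame(group_a = integer(), group_b = integer(),
                 max_identity = numeric()),
    flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(record_a = character(), record_b = character(),
                 identity_pct = numeric(), type = character()),
    n_records = n, intra_min = intra_min, inter_max = inter_max
  ), class = "library_validation")
}

#' @export
print.library_validation <- function(x, ...) {
  cat(sprintf("Reference library validation: %d records, %d groups\n",
              x$n_records, nrow(x$intra)))
  cat(sprintf("  flags: %d (intra_min=%g, inter_max=%g)\n",
              nrow(x$flags), x$intra_min, x$inter_max))
  invisible(x)
}
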