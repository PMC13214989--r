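## Sequence primitives shared by every other module: the IUPAC degenerate
## alphabet, degenerate matching, and end-gap-free pairwise identity.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Base set of an IUPAC nucleotide code
#'
#' @param code single IUPAC letter.
#' @return Character vector of the concrete bases the code stands for.
#' @examples
#' iupac_bases("B")  # C G T
#' @export
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    stop("invalid IUPAC letter: ", code, call. = FALSE)
  }
  strsplit(map[[code]], "")[[1]]
}

.check_iupac <- function(seq) {
  letters <- strsplit(toupper(seq), "")[[1]]
  if (length(letters) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(letters), IUPAC_LETTERS)
  if (length(bad) > 0L) {
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  letters
}

.check_nuc <- function(seq) {
  letters <- strsplit(toupper(seq), "")[[1]]
  if (length(letters) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(letters), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid nucleotide letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  letters
}

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the per-letter base-set sizes.
#'
#' @param seq IUPAC nucleotide string.
#' @return Integer degeneracy (>= 1).
#' @export
degeneracy <- function(seq) {
  letters <- .check_iupac(seq)
  prod(nchar(Biostrings::IUPAC_CODE_MAP[letters]))
}

#' Expand a degenerate IUPAC string into all concrete sequences
#'
#' @param seq IUPAC nucleotide string.
#' @return Character vector of every A/C/G/T realization; its length equals
#'   `degeneracy(seq)`.
#' @examples
#' expand_degenerate("CACCCCBGTKCTCAAGGTGAA")  # 6 variants
#' @export
expand_degenerate <- function(seq) {
  letters <- .check_iupac(seq)
  sets <- lapply(letters, iupac_bases)
  out <- do.call(expand.grid,
                 c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- rev(out)
  apply(as.matrix(out), 1L, paste, collapse = "")
}

#' Reverse complement of an IUPAC string
#'
#' Complements degenerate codes as well (R<->Y, B<->V, ...); an involution.
#'
#' @param seq IUPAC nucleotide string.
#' @return Reverse-complemented IUPAC string.
#' @export
reverse_complement <- function(seq) {
  .check_iupac(seq)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

## Lookup table: for a primer letter, which of A/C/G/T/N are accepted.
## N in the *template* matches nothing (low-quality bases never inflate
## identity); N in the primer accepts A/C/G/T.
.primer_allowed_matrix <- function(primer_letters) {
  n <- length(primer_letters)
  allowed <- matrix(FALSE, nrow = n, ncol = 5,
                    dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (k in seq_len(n)) {
    allowed[k, iupac_bases(primer_letters[k])] <- TRUE
  }
  allowed
}

## Vectorized mismatch counts of one primer against many same-length
## windows (no 3' protection; used by bulk read preprocessing).
.mismatch_counts <- function(primer, windows) {
  pl <- strsplit(toupper(primer), "")[[1]]
  mm <- integer(length(windows))
  for (k in seq_along(pl)) {
    ch <- substr(windows, k, k)
    mm <- mm + !(ch %in% iupac_bases(pl[k]))
  }
  mm
}

#' Match a degenerate primer against a same-length template window
#'
#' Position i matches when the template base is a member of the primer
#' letter's base set. The match succeeds when the total number of
#' mismatches is at most `max_mismatch` *and* no mismatch falls within the
#' last `protect_3prime` positions (the primer's 3' end, where a mismatch
#' blocks polymerase extension).
#'
#' @param primer IUPAC string (5'->3').
#' @param window concrete A/C/G/T/N string of the same length.
#' @param max_mismatch maximum tolerated mismatches outside the protected
#'   3' positions.
#' @param protect_3prime number of 3'-terminal positions in which any
#'   mismatch is disqualifying (default 3).
#' @return List with `match` (logical) and `mismatches` (count).
#' @export
degenerate_match <- function(primer, window, max_mismatch = 0L,
                             protect_3prime = 3L) {
  pl <- .check_iupac(primer)
  wl <- .check_nuc(window)
  if (length(pl) != length(wl)) {
    stop("primer and window lengths differ (", length(pl), " vs ",
         length(wl), ")", call. = FALSE)
  }
  allowed <- .primer_allowed_matrix(pl)
  hit <- allowed[cbind(seq_along(pl), match(wl, colnames(allowed)))]
  mm <- sum(!hit)
  protect <- min(protect_3prime, length(pl))
  tail_ok <- protect == 0L ||
    all(hit[(length(pl) - protect + 1L):length(pl)])
  list(match = (mm <= max_mismatch) && tail_ok, mismatches = mm)
}

#' End-gap-free pairwise identity
#'
#' Global alignment with free terminal gaps on both sequences (overlap
#' alignment; match +1, mismatch -1, gap -2). Identity is
#' `100 * matches / aligned_columns`, where aligned columns exclude
#' terminal-gap runs but count internal gap columns as mismatching. A read
#' that is an exact substring of a reference therefore scores 100%. Among
#' co-optimal alignments the one with most matches, then fewest columns,
#' defines the reported identity, which makes the result exactly
#' symmetric in its arguments.
#'
#' @param a,b A/C/G/T/N strings.
#' @return List of class `pairwise_identity` with `matches`,
#'   `aligned_columns`, `identity_pct` and the alignment `score`.
#' @examples
#' align_identity("ACGTACGT", "ACGTACGT")$identity_pct  # 100
#' @export
align_identity <- function(a, b) {
  .check_nuc(a)
  .check_nuc(b)
  res <- .align_endsfree_cpp(toupper(a), toupper(b))
  structure(res, class = "pairwise_identity")
}

#' Percent-identity matrix between two sets of sequences
#'
#' Vectorized [align_identity()] over all query x reference pairs.
#'
#' @param queries,refs character vectors of A/C/G/T/N sequences.
#' @return Numeric matrix `length(queries)` x `length(refs)` of percent
#'   identities.
#' @export
identity_matrix <- function(queries, refs) {
  stopifnot(length(queries) > 0L, length(refs) > 0L)
  m <- .identity_matrix_cpp(toupper(queries), toupper(refs))
  dimnames(m) <- list(names(queries), names(refs))
  m
}

#' Read sequences from FASTA or FASTQ
#'
#' Sequences are upper-cased and U is mapped to T on ingest.
#'
#' @param path file path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Named character vector of sequences.
#' @export
read_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::readBStringSet(path, format = format)
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- names(ss)
  seqs
}

#' Write sequences to FASTA
#'
#' Unwrapped dialect (one line per sequence) so that read/write round
#' trips are bit-exact.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 20001L)
  invisible(path)
}
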