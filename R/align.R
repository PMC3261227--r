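# Flank extraction and pairwise global alignment with percent identity,
# for cross-species conservation reports around regulatory modules.

#' Extract flanks around a module
#'
#' Slices `flank_bp` of sequence on either side of a module interval, the
#' standard window for cross-species comparison of a regulatory domain.
#' Flanks are truncated (and flagged) at contig ends; the concatenation
#' `left_flank + core + right_flank` always reconstructs the contiguous
#' genomic slice.
#'
#' @param module_start,module_end Module interval (1-based inclusive).
#' @param contig Contig sequence (any form accepted by [scan_pattern()]).
#' @param flank_bp Flank width in bp (default 200).
#' @return Object of class `flanked_module`: list with `left_flank`, `core`,
#'   `right_flank`, `slice_start`, `slice_end`, `flank_bp`,
#'   `left_truncated`, `right_truncated`.
#' @export
extract_flanks <- function(module_start, module_end, contig,
                           flank_bp = 200) {
  seq <- toupper(.contig_seq(contig))
  len <- nchar(seq)
  if (module_start < 1L || module_end > len || module_start > module_end) {
    stop("module interval outside contig bounds")
  }
  s <- max(1L, module_start - flank_bp)
  e <- min(len, module_end + flank_bp)
  structure(list(
    left_flank = substring(seq, s, module_start - 1L),
    core = substring(seq, module_start, module_end),
    right_flank = substring(seq, module_end + 1L, e),
    slice_start = as.integer(s), slice_end = as.integer(e),
    flank_bp = flank_bp,
    left_truncated = (module_start - flank_bp) < 1L,
    right_truncated = (module_end + flank_bp) > len
  ), class = "flanked_module")
}

#' Full slice of a flanked module
#'
#' @param x A [extract_flanks()] result.
#' @return `left_flank + core + right_flank` as one string.
#' @export
flank_slice <- function(x) {
  paste0(x$left_flank, x$core, x$right_flank)
}

#' Global alignment with affine gaps and percent identity
#'
#' Optimal Needleman-Wunsch/Gotoh global alignment via
#' [Biostrings::pairwiseAlignment()]. The cost of a gap run of length L is
#' `gap_open + gap_extend * L`. Percent identity is reported in two
#' flavours: over all alignment columns including gap columns
#' (`percent_identity`) and over gap-free columns only
#' (`percent_identity_ungapped`); the two bracket the plausible definitions
#' used in the literature.
#'
#' @param a,b DNA sequences (character strings).
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend Affine gap penalties as non-negative costs
#'   (defaults 5 and 1).
#' @param block_min Minimum run length for [conserved_blocks()] reporting
#'   (default 10).
#' @return Object of class `pairwise_conservation`: list with `score`,
#'   `aligned_a`, `aligned_b`, `alignment_length`, `matches`,
#'   `percent_identity`, `percent_identity_ungapped`, `blocks` (data frame
#'   of maximal identical runs of length >= `block_min`, in sequence-a
#'   coordinates).
#' @examples
#' al <- global_align("ACGTACGT", "ACGAACGT")
#' al$percent_identity
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1, block_min = 10) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1L]]
  ident <- ca == cb & ca != "-"
  gap_free <- ca != "-" & cb != "-"
  structure(list(
    score = as.numeric(Biostrings::score(pa)),
    aligned_a = al_a, aligned_b = al_b,
    alignment_length = length(ca),
    matches = sum(ident),
    percent_identity = 100 * sum(ident) / length(ca),
    percent_identity_ungapped =
      if (any(gap_free)) 100 * sum(ident) / sum(gap_free) else NA_real_,
    blocks = conserved_blocks(al_a, al_b, k = block_min),
    scoring = list(match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_extend = gap_extend)
  ), class = "pairwise_conservation")
}

#' @export
print.pairwise_conservation <- function(x, width = 60, ...) {
  cat(sprintf(
    "Global alignment: %d columns, %d identical (%.1f%%; %.1f%% gap-free), score %.1f\n",
    x$alignment_length, x$matches, x$percent_identity,
    x$percent_identity_ungapped, x$score))
  n <- nchar(x$aligned_a)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    ca <- substring(x$aligned_a, s, e)
    cb <- substring(x$aligned_b, s, e)
    marks <- paste(ifelse(strsplit(ca, "")[[1L]] == strsplit(cb, "")[[1L]] &
                            strsplit(ca, "")[[1L]] != "-", "|", " "),
                   collapse = "")
    cat(sprintf("a %6d %s\n         %s\nb %6d %s\n\n", s, ca, marks, s, cb))
  }
  invisible(x)
}

#' Maximal conserved blocks of an alignment
#'
#' Maximal runs of identical (non-gap) aligned columns of length at least
#' `k`, reported in sequence-a coordinates.
#'
#' @param aligned_a,aligned_b Aligned strings (equal length, `-` for gaps),
#'   or a single `pairwise_conservation` object as `aligned_a`.
#' @param k Minimum run length.
#' @return Data frame `a_start`, `a_end`, `length` (ordered, disjoint).
#' @export
conserved_blocks <- function(aligned_a, aligned_b = NULL, k = 10) {
  if (inherits(aligned_a, "pairwise_conservation")) {
    aligned_b <- aligned_a$aligned_b
    aligned_a <- aligned_a$aligned_a
  }
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  ident <- ca == cb & ca != "-"
  a_pos <- cumsum(ca != "-")  # sequence-a coordinate of each column
  r <- rle(ident)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  data.frame(
    a_start = a_pos[starts[keep]],
    a_end = a_pos[ends[keep]],
    length = r$lengths[keep]
  )
}
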