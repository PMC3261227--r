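# Degenerate IUPAC pattern compilation and exhaustive both-strand scanning.

# Per-code literal expansions (DNA alphabet).
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.validate_iupac <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) < 1L) stop(what, " must be non-empty", call. = FALSE)
  codes <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- which(!codes %in% names(IUPAC_EXPANSION))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of %s '%s'",
                 codes[bad[1L]], bad[1L], what, x), call. = FALSE)
  }
  codes
}

#' Compile a degenerate IUPAC pattern
#'
#' Builds a matcher for a degenerate DNA motif such as the Su(H) consensus
#' `YGTGRGAA` or the proneural A box `RCAGSTG`. The matcher accepts exactly
#' the Cartesian expansion of the IUPAC codes and is case-insensitive on the
#' scanned sequence.
#'
#' @param iupac Single string over the 15-letter IUPAC DNA alphabet.
#' @param name Short label used in hit tables; defaults to the pattern itself.
#'
#' @return An object of class `DegeneratePattern`: a list with elements
#'   `name`, `iupac`, `length`, `n_expansions` and (for patterns with at most
#'   4096 expansions) the sorted character vector `expansions`.
#'
#' @examples
#' p <- compile_pattern("YGTGRGAA", "SuH")
#' p$n_expansions       # 4
#' p$expansions
#' @export
compile_pattern <- function(iupac, name = iupac) {
  codes <- .validate_iupac(iupac, "pattern")
  deg <- vapply(IUPAC_EXPANSION[codes], length, integer(1L))
  n_exp <- prod(deg)
  expansions <- NULL
  if (n_exp <= 4096) {
    grid <- expand.grid(IUPAC_EXPANSION[codes],
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    expansions <- sort(do.call(paste0, grid))
  }
  structure(
    list(name = name, iupac = paste(codes, collapse = ""),
         length = length(codes), n_expansions = n_exp,
         expansions = expansions),
    class = "DegeneratePattern"
  )
}

#' @export
print.DegeneratePattern <- function(x, ...) {
  cat(sprintf("DegeneratePattern '%s': %s (%d bp, %d literal expansion%s)\n",
              x$name, x$iupac, x$length, x$n_expansions,
              if (x$n_expansions == 1L) "" else "s"))
  invisible(x)
}

#' Enumerate the literal expansions of a degenerate pattern
#'
#' @param iupac IUPAC string (or a compiled [compile_pattern()] object).
#' @return Sorted character vector of all literal ACGT words matching the
#'   pattern.
#' @examples
#' iupac_expand("RCAGSTG")   # 4 words
#' @export
iupac_expand <- function(iupac) {
  if (inherits(iupac, "DegeneratePattern")) {
    if (!is.null(iupac$expansions)) return(iupac$expansions)
    iupac <- iupac$iupac
  }
  p <- compile_pattern(iupac)
  if (is.null(p$expansions)) {
    stop("pattern has too many expansions to enumerate (", p$n_expansions, ")")
  }
  p$expansions
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements degenerate codes correctly (R<->Y, S<->S, K<->M, N<->N) and is
#' an involution. Vectorised over its input.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements (uppercase).
#' @examples
#' revcomp("YGTGRGAA")  # "TTCYCACR"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq) || anyNA(seq)) {
    stop("seq must be a character vector without NAs", call. = FALSE)
  }
  for (s in seq) .validate_iupac(s)
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
}

.contig_seq <- function(contig) {
  if (inherits(contig, "synthetic_contig")) return(contig$seq)
  if (methods::is(contig, "DNAString")) return(as.character(contig))
  if (methods::is(contig, "DNAStringSet")) {
    if (length(contig) != 1L) stop("expected a single contig")
    return(as.character(contig[[1L]]))
  }
  if (is.character(contig) && length(contig) == 1L) return(contig)
  stop("contig must be a single DNA sequence (character, DNAString or ",
       "synthetic_contig)")
}

.contig_id <- function(contig, default = "contig") {
  if (inherits(contig, "synthetic_contig")) return(contig$contig_id)
  nm <- names(contig)
  if (methods::is(contig, "DNAStringSet") && !is.null(names(contig))) {
    return(sub("\\s.*$", "", names(contig)[1L]))
  }
  if (is.character(contig) && !is.null(nm) && nzchar(nm[1L])) return(nm[1L])
  default
}

.empty_hits <- function() {
  data.frame(pattern = character(), seqid = character(),
             start = integer(), end = integer(), strand = character(),
             matched_seq = character(), site_seq = character(),
             stringsAsFactors = FALSE)
}

#' Scan both strands of a contig for a degenerate pattern
#'
#' Reports every match of the pattern on the plus and minus strands,
#' including overlapping and nested matches. Coordinates are 1-based
#' inclusive on the plus strand of the contig. `matched_seq` is always the
#' plus-strand slice; `site_seq` is the motif-oriented sequence
#' (reverse-complemented for minus-strand hits) and therefore always matches
#' the pattern literally. Non-ACGT characters in the contig (e.g. `N`) never
#' match a literal code.
#'
#' @param contig A single DNA sequence: character string (optionally named),
#'   `DNAString`, single-sequence `DNAStringSet`, or a
#'   [generate_contig()] result.
#' @param pattern A [compile_pattern()] object (a plain IUPAC string is
#'   compiled on the fly).
#' @param contig_id Label for the `seqid` column; defaults to the sequence
#'   name when available.
#' @param exclude_softmasked If `TRUE`, hits overlapping lowercase
#'   (soft-masked) positions of a character input are dropped. Default
#'   `FALSE`: masking case is ignored.
#'
#' @return A data frame of hits sorted by `start` with columns `pattern`,
#'   `seqid`, `start`, `end`, `strand`, `matched_seq`, `site_seq`. An empty
#'   data frame is a valid result.
#'
#' @examples
#' suh <- compile_pattern("YGTGRGAA", "SuH")
#' scan_pattern("AACGTGAGAATT", suh)
#' @export
scan_pattern <- function(contig, pattern, contig_id = NULL,
                         exclude_softmasked = FALSE) {
  if (!inherits(pattern, "DegeneratePattern")) {
    pattern <- compile_pattern(pattern)
  }
  raw <- .contig_seq(contig)
  if (is.null(contig_id)) contig_id <- .contig_id(contig)
  if (nchar(raw) == 0L) stop("contig is empty")
  up <- toupper(raw)
  if (nchar(up) < pattern$length) return(.empty_hits())
  subj <- Biostrings::DNAString(up)

  one_strand <- function(iupac, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(iupac), subj,
                                  fixed = "subject")
    if (length(m) == 0L) return(.empty_hits())
    st <- BiocGenerics::start(m)
    en <- BiocGenerics::end(m)
    matched <- substring(up, st, en)
    data.frame(pattern = pattern$name, seqid = contig_id,
               start = st, end = en, strand = strand,
               matched_seq = matched,
               site_seq = if (strand == "+") matched else revcomp(matched),
               stringsAsFactors = FALSE)
  }

  hits <- rbind(one_strand(pattern$iupac, "+"),
                one_strand(revcomp(pattern$iupac), "-"))
  if (exclude_softmasked && nrow(hits)) {
    chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
    masked <- which(chars %in% letters)
    if (length(masked)) {
      keep <- vapply(seq_len(nrow(hits)), function(i) {
        !any(masked >= hits$start[i] & masked <= hits$end[i])
      }, logical(1L))
      hits <- hits[keep, , drop = FALSE]
    }
  }
  hits <- hits[order(hits$start, hits$end, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a contig with a set of motifs
#'
#' @param contig As in [scan_pattern()].
#' @param patterns A list of compiled patterns (e.g. [espl_motifs()]).
#' @param ... Passed to [scan_pattern()].
#' @return Row-bound hit table across all patterns, sorted by start.
#' @export
scan_motifs <- function(contig, patterns = espl_motifs(), ...) {
  hits <- do.call(rbind, lapply(patterns, function(p) {
    scan_pattern(contig, p, ...)
  }))
  if (is.null(hits)) return(.empty_hits())
  hits <- hits[order(hits$start, hits$end, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Restrict hits to a set of intervals
#'
#' Keeps only hits lying entirely within one of the given intervals
#' (typically the non-coding regions from [noncoding_regions()]).
#'
#' @param hits Hit table from [scan_pattern()].
#' @param regions Data frame with columns `start`, `end` (1-based inclusive).
#' @return Filtered hit table.
#' @export
restrict_hits <- function(hits, regions) {
  if (nrow(hits) == 0L || is.null(regions) || nrow(regions) == 0L) {
    return(hits[integer(0), , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$start[i] >= regions$start & hits$end[i] <= regions$end)
  }, logical(1L))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a motif configuration table
#'
#' The format is a two-column tab-separated file with a header line
#' `name<TAB>iupac`, one motif per row. The motif set shipped with the
#' package ([espl_motifs()]) is in this format under
#' `system.file("extdata", "motifs.tsv", package = "spsarch")`.
#'
#' @param path Path to the motif file.
#' @return Named list of [compile_pattern()] objects.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "iupac") %in% names(tab))) {
    stop("motif file must have columns 'name' and 'iupac'")
  }
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    compile_pattern(tab$iupac[i], tab$name[i])
  })
  names(pats) <- tab$name
  pats
}

#' The default Enhancer-of-split motif set
#'
#' Five degenerate consensi: the Su(H) binding site `YGTGRGAA`, the proneural
#' A box `RCAGSTG`, and the three 3' UTR boxes Brd (`AGCTTTA`), GY
#' (`GTCTTCC`) and K (`TGTGAT`).
#'
#' @return Named list of compiled patterns
#'   (`SuH`, `Abox`, `Brd`, `GY`, `K`).
#' @export
espl_motifs <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "spsarch")
  if (!nzchar(path)) {
    # fall back to the built-in definitions (e.g. during load_all)
    return(list(
      SuH = compile_pattern("YGTGRGAA", "SuH"),
      Abox = compile_pattern("RCAGSTG", "Abox"),
      Brd = compile_pattern("AGCTTTA", "Brd"),
      GY = compile_pattern("GTCTTCC", "GY"),
      K = compile_pattern("TGTGAT", "K")
    ))
  }
  read_motifs(path)
}

#' Motifs scanned in 3' UTR windows
#'
#' @return The Brd/GY/K subset of [espl_motifs()].
#' @export
utr_motifs <- function() {
  espl_motifs()[c("Brd", "GY", "K")]
}

#' Expected number of background hits for a degenerate pattern
#'
#' Closed-form expectation of the both-strand hit count for a pattern on an
#' i.i.d. background of length `length` with the given GC fraction
#' (bases A/T each with probability `(1-gc)/2`, C/G each `gc/2`). On a
#' uniform background (`gc = 0.5`) this reduces to
#' `2 * (L - m + 1) * n_expansions / 4^m`.
#'
#' @param pattern Compiled pattern or IUPAC string.
#' @param length Contig length in bp.
#' @param gc Background GC fraction.
#' @return Expected hit count (double).
#' @export
expected_background_hits <- function(pattern, length, gc = 0.5) {
  if (!inherits(pattern, "DegeneratePattern")) {
    pattern <- compile_pattern(pattern)
  }
  m <- pattern$length
  if (length < m) return(0)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  word_prob <- function(words) {
    sum(vapply(strsplit(words, "", fixed = TRUE), function(w) {
      prod(p[w])
    }, numeric(1L)))
  }
  fwd <- word_prob(iupac_expand(pattern))
  rev <- word_prob(vapply(iupac_expand(pattern), revcomp, character(1L)))
  (length - m + 1) * (fwd + rev)
}
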