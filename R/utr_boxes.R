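# 3' UTR Brd/GY/K box profiling and cross-species organization comparison.
# The boxes are mRNA-level miRNA-binding elements, so scanning is
# sense-strand only; offsets are 0-based distances from the UTR window
# start (the number of bases preceding the box).

#' Scan a 3' UTR window for Brd/GY/K boxes
#'
#' @param window_seq UTR sequence in gene (sense) orientation.
#' @param motifs Named list of compiled patterns (default [utr_motifs()]).
#' @param gene_id,species Labels carried into the profile.
#' @param source Window provenance label (e.g. `"transcript"` or
#'   `"stop+1000"`).
#' @param truncated Whether the window was truncated (shorter than the
#'   nominal length); carried through to [compare_organization()] so that
#'   absence of boxes in a partial window can be flagged rather than
#'   over-interpreted.
#'
#' @return An object of class `utr_profile`: list with `gene_id`, `species`,
#'   `boxes` (data frame `box_type`, `offset`, `match`, ordered by offset;
#'   overlapping boxes of different types are all reported),
#'   `window_length`, `source`, `truncated`.
#' @export
scan_utr <- function(window_seq, motifs = utr_motifs(), gene_id = NA,
                     species = NA, source = "stop+1000",
                     truncated = FALSE) {
  stopifnot(is.character(window_seq), length(window_seq) == 1L)
  wlen <- nchar(window_seq)
  rows <- lapply(motifs, function(p) {
    if (wlen < p$length) return(NULL)
    m <- Biostrings::matchPattern(Biostrings::DNAString(p$iupac),
                                  Biostrings::DNAString(toupper(window_seq)),
                                  fixed = "subject")
    if (length(m) == 0L) return(NULL)
    st <- BiocGenerics::start(m)
    data.frame(box_type = p$name, offset = st - 1L,
               match = substring(toupper(window_seq), st,
                                 BiocGenerics::end(m)),
               stringsAsFactors = FALSE)
  })
  boxes <- do.call(rbind, rows)
  if (is.null(boxes)) {
    boxes <- data.frame(box_type = character(), offset = integer(),
                        match = character(), stringsAsFactors = FALSE)
  }
  boxes <- boxes[order(boxes$offset, boxes$box_type), , drop = FALSE]
  rownames(boxes) <- NULL
  structure(list(gene_id = gene_id, species = species, boxes = boxes,
                 window_length = wlen, source = source,
                 truncated = truncated),
            class = "utr_profile")
}

#' @export
print.utr_profile <- function(x, ...) {
  cat(sprintf("3' UTR profile%s%s: [%s] over %d bp (%s%s)\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              paste(x$boxes$box_type, collapse = ", "),
              x$window_length, x$source,
              if (isTRUE(x$truncated)) ", truncated" else ""))
  invisible(x)
}

# Longest common subsequence with traceback over two character vectors.
# Returns list(length, pairs = data.frame(i, j)) of matched index pairs.
box_lcs <- function(x, y) {
  m <- length(x); n <- length(y)
  L <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      L[i + 1L, j + 1L] <- if (x[i] == y[j]) L[i, j] + 1L
                           else max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  i <- m; j <- n
  pi <- integer(0); pj <- integer(0)
  while (i > 0L && j > 0L) {
    if (x[i] == y[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(length = L[m + 1L, n + 1L],
       pairs = data.frame(i = pi, j = pj))
}

#' Compare 3' UTR box organization between two profiles
#'
#' Conservation of organization is judged on the ordered strings of box
#' types (offsets are ignored): matched boxes form the longest common
#' subsequence of the two type strings. The conservation class is
#' `identical` when the strings are equal and non-empty, `identical-empty`
#' when both are empty (a real state: some genes carry no boxes in either
#' species), `none` when the LCS is empty but at least one profile is not,
#' and `partial` otherwise. The classification is symmetric in its
#' arguments.
#'
#' @param a,b [scan_utr()] profiles.
#' @return Object of class `organization_comparison`: list with
#'   `profile_a`, `profile_b`, `pairs` (matched box indices), `lcs_length`,
#'   `conservation_class`, `truncated` (TRUE if either window was
#'   truncated).
#' @export
compare_organization <- function(a, b) {
  stopifnot(inherits(a, "utr_profile"), inherits(b, "utr_profile"))
  sa <- a$boxes$box_type
  sb <- b$boxes$box_type
  lcs <- box_lcs(sa, sb)
  cls <- if (length(sa) == 0L && length(sb) == 0L) {
    "identical-empty"
  } else if (length(sa) == length(sb) && all(sa == sb)) {
    "identical"
  } else if (lcs$length == 0L) {
    "none"
  } else {
    "partial"
  }
  structure(list(profile_a = a, profile_b = b, pairs = lcs$pairs,
                 lcs_length = lcs$length, conservation_class = cls,
                 truncated = isTRUE(a$truncated) || isTRUE(b$truncated)),
            class = "organization_comparison")
}

#' @export
print.organization_comparison <- function(x, ...) {
  cat(organization_diagram(x), sep = "\n")
  invisible(x)
}

#' Plain-text organization diagram for a gene pair
#'
#' A Fig-6-style, text-only rendering: each species' ordered box string with
#' conserved (LCS-matched) boxes marked by `*`.
#'
#' @param cmp A [compare_organization()] result.
#' @return Character vector of lines.
#' @export
organization_diagram <- function(cmp) {
  mark <- function(types, matched) {
    if (!length(types)) return("(none)")
    lab <- ifelse(seq_along(types) %in% matched,
                  paste0("[", types, "]*"), paste0("[", types, "]"))
    paste(lab, collapse = "--")
  }
  gene <- cmp$profile_a$gene_id
  c(sprintf("gene %s: %s", if (is.na(gene)) "?" else gene,
            cmp$conservation_class),
    sprintf("  %-10s %s",
            ifelse(is.na(cmp$profile_a$species), "a", cmp$profile_a$species),
            mark(cmp$profile_a$boxes$box_type, cmp$pairs$i)),
    sprintf("  %-10s %s",
            ifelse(is.na(cmp$profile_b$species), "b", cmp$profile_b$species),
            mark(cmp$profile_b$boxes$box_type, cmp$pairs$j)),
    if (cmp$truncated) "  (window truncated; absence calls are weak)")
}
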