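# Inverted Su(H) pair construction and SPS / SPS+A module classification.

.empty_pairs <- function() {
  data.frame(pair_id = character(), seqid = character(),
             left_start = integer(), left_end = integer(),
             left_strand = character(), left_site = character(),
             right_start = integer(), right_end = integer(),
             right_strand = character(), right_site = character(),
             spacer_bp = integer(), orientation = character(),
             canonical = logical(), variant_label = character(),
             stringsAsFactors = FALSE)
}

#' Find inverted Su(H) pairs among motif hits
#'
#' Enumerates every pair of opposite-strand, non-overlapping hits whose
#' spacer (the number of bases strictly between the two motif intervals)
#' falls in `[spacer_min, spacer_max]`. When a hit participates in several
#' candidate pairs, a greedy pass keeps the pair whose spacer is closest to
#' the canonical 17 bp (ties broken toward the smaller spacer) and discards
#' alternatives sharing either site. An SPS (Su(H) Paired Sites) element is
#' canonically an inverted pair separated by 17 bp; 15 bp and 7 bp variants
#' occur and are labelled through `variant_label`.
#'
#' @param hits Hit table from [scan_pattern()], all on one contig.
#' @param spacer_min,spacer_max Allowed spacer window in bp (default 0-30,
#'   wide enough to capture the 7, 15 and 17 bp architectures).
#' @param canonical_spacer The spacer that sets `canonical = TRUE`
#'   (default 17) and anchors the greedy tie-break.
#'
#' @return Data frame of pairs with the left site (smaller start) first:
#'   coordinates, strands and motif-oriented site sequences of both sites,
#'   `spacer_bp`, `orientation` (`convergent` when the left site is on the
#'   plus strand, `divergent` otherwise), `canonical` and `variant_label`
#'   (the spacer as a string for non-canonical pairs, `NA` otherwise).
#' @export
find_inverted_pairs <- function(hits, spacer_min = 0, spacer_max = 30,
                                canonical_spacer = 17) {
  stopifnot(spacer_min >= 0, spacer_max >= spacer_min)
  if (nrow(hits) < 2L) return(.empty_pairs())
  if (length(unique(hits$seqid)) > 1L) {
    stop("hits must come from a single contig")
  }
  h <- hits[order(hits$start, hits$end), , drop = FALSE]
  n <- nrow(h)
  li <- integer(0); ri <- integer(0); sp <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      gap <- h$start[j] - h$end[i] - 1L
      if (gap > spacer_max) break  # starts are sorted; no later j can qualify
      if (h$strand[j] == h$strand[i]) next
      if (h$start[j] <= h$end[i]) next  # overlapping intervals
      if (gap < spacer_min) next
      li <- c(li, i); ri <- c(ri, j); sp <- c(sp, gap)
    }
  }
  if (!length(li)) return(.empty_pairs())

  # greedy deduplication: closest-to-canonical spacer wins, ties -> smaller
  # spacer, then leftmost pair
  ord <- order(abs(sp - canonical_spacer), sp, h$start[li], h$start[ri])
  used <- rep(FALSE, n)
  keep <- logical(length(li))
  for (k in ord) {
    if (used[li[k]] || used[ri[k]]) next
    keep[k] <- TRUE
    used[li[k]] <- TRUE
    used[ri[k]] <- TRUE
  }
  li <- li[keep]; ri <- ri[keep]; sp <- sp[keep]
  ord2 <- order(h$start[li])
  li <- li[ord2]; ri <- ri[ord2]; sp <- sp[ord2]

  data.frame(
    pair_id = sprintf("%s:%d-%d", h$seqid[li], h$start[li], h$end[ri]),
    seqid = h$seqid[li],
    left_start = h$start[li], left_end = h$end[li],
    left_strand = h$strand[li], left_site = h$site_seq[li],
    right_start = h$start[ri], right_end = h$end[ri],
    right_strand = h$strand[ri], right_site = h$site_seq[ri],
    spacer_bp = sp,
    orientation = ifelse(h$strand[li] == "+", "convergent", "divergent"),
    canonical = sp == canonical_spacer,
    variant_label = ifelse(sp == canonical_spacer, NA_character_,
                           as.character(sp)),
    stringsAsFactors = FALSE
  )
}

#' Attach proneural A boxes to Su(H) pairs
#'
#' Classifies each pair as `SPS+A` (at least one A box within `max_dist` of
#' either pair edge, and inside `region` when given) or bare `SPS`. The
#' distance of an A box is the number of bases strictly between the box and
#' the pair span (0 when they touch or overlap). The default `max_dist` of
#' 500 bp accommodates the distal A boxes observed in real modules (232 bp
#' and 405 bp away from the pair).
#'
#' @param pairs Pair table from [find_inverted_pairs()].
#' @param abox_hits A-box hit table from [scan_pattern()] on the same contig.
#' @param max_dist Maximum A-box distance in bp (default 500).
#' @param region Optional data frame of intervals (`start`, `end`); every
#'   pair must lie inside one of them (otherwise an error is raised) and
#'   A boxes outside them are ignored.
#'
#' @return The pair table extended with `module_id`, `module_class`
#'   (`"SPS+A"` or `"SPS"`), `n_aboxes`, and a list column `aboxes` holding
#'   one data frame per module (`start`, `end`, `strand`, `site_seq`,
#'   `distance_bp`).
#' @export
associate_aboxes <- function(pairs, abox_hits, max_dist = 500,
                             region = NULL) {
  stopifnot(max_dist >= 0)
  out <- pairs
  out$module_id <- pairs$pair_id
  out$module_class <- character(nrow(pairs))
  out$n_aboxes <- integer(nrow(pairs))
  boxes <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$left_start[i]; e <- pairs$right_end[i]
    if (!is.null(region) && nrow(region) > 0L &&
        !any(s >= region$start & e <= region$end)) {
      stop(sprintf("pair %s lies outside the supplied region",
                   pairs$pair_id[i]))
    }
    ab <- abox_hits[abox_hits$seqid == pairs$seqid[i], , drop = FALSE]
    if (!is.null(region) && nrow(ab)) {
      keep <- vapply(seq_len(nrow(ab)), function(k) {
        any(ab$start[k] >= region$start & ab$end[k] <= region$end)
      }, logical(1L))
      ab <- ab[keep, , drop = FALSE]
    }
    if (nrow(ab)) {
      d <- ifelse(ab$end < s, s - ab$end - 1L,
                  ifelse(ab$start > e, ab$start - e - 1L, 0L))
      ab$distance_bp <- as.integer(d)
      ab <- ab[ab$distance_bp <= max_dist, , drop = FALSE]
      ab <- ab[order(ab$distance_bp, ab$start), , drop = FALSE]
    } else {
      ab$distance_bp <- integer(0)
    }
    rownames(ab) <- NULL
    boxes[[i]] <- ab[, c("start", "end", "strand", "site_seq",
                         "distance_bp"), drop = FALSE]
    out$n_aboxes[i] <- nrow(ab)
    out$module_class[i] <- if (nrow(ab)) "SPS+A" else "SPS"
  }
  out$aboxes <- boxes
  out
}

#' Assign Y-position characters to modules
#'
#' The "Y" position is the first (degenerate C/T) base of the motif-oriented
#' Su(H) site sequence. Once a module is assigned to a gene, the
#' gene-upstream site is the pair site farther from the gene along the
#' gene's reading orientation (the left site for a plus-strand gene, the
#' right site for a minus-strand gene). The canonical configuration has a T
#' in the upstream site and a C in the downstream site.
#'
#' @param modules Module table from [associate_aboxes()] (a plain pair table
#'   also works).
#' @param gene_strand Character vector (recycled) of the regulated gene's
#'   strand per module, `"+"` or `"-"`; `NA` leaves the Y fields unassigned.
#'
#' @return `modules` with columns `y_upstream`, `y_downstream` and
#'   `y_canonical` added.
#' @export
assign_y_positions <- function(modules, gene_strand) {
  n <- nrow(modules)
  gs <- rep_len(as.character(gene_strand), n)
  left_y <- substr(modules$left_site, 1L, 1L)
  right_y <- substr(modules$right_site, 1L, 1L)
  y_up <- ifelse(is.na(gs), NA_character_,
                 ifelse(gs == "+", left_y, right_y))
  y_down <- ifelse(is.na(gs), NA_character_,
                   ifelse(gs == "+", right_y, left_y))
  modules$y_upstream <- y_up
  modules$y_downstream <- y_down
  modules$y_canonical <- ifelse(is.na(gs), NA,
                                y_up == "T" & y_down == "C")
  modules
}
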