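# Gene-model geometry: non-coding masking, module-to-gene assignment,
# upstream distances and 3' UTR windows. All coordinates 1-based inclusive.

#' Construct a gene model
#'
#' A minimal CDS-based gene model: ordered, non-overlapping CDS intervals on
#' one strand. The first base of the start codon is the lowest CDS
#' coordinate for a plus-strand gene and the highest for a minus-strand
#' gene; `stop_end` is the last base of the stop codon (highest coordinate
#' on plus, lowest on minus).
#'
#' @param gene_id Gene label.
#' @param strand `"+"` or `"-"`.
#' @param cds Data frame with columns `start`, `end`, or a numeric
#'   `c(start, end)` for a single-interval CDS.
#' @param seqid Contig label.
#' @return One-row data frame with a list column `cds` and derived columns
#'   `span_start`, `span_end`, `start_codon`, `stop_end`.
#' @export
gene_model <- function(gene_id, strand, cds, seqid = "contig") {
  if (is.numeric(cds)) cds <- data.frame(start = cds[1L], end = cds[2L])
  stopifnot(all(c("start", "end") %in% names(cds)), nrow(cds) >= 1L)
  if (any(cds$start > cds$end)) stop("malformed CDS interval (start > end)")
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(cds) > 1L && any(cds$start[-1L] <= cds$end[-nrow(cds)])) {
    stop("CDS intervals of one gene must not overlap")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  span_start <- min(cds$start); span_end <- max(cds$end)
  data.frame(
    gene_id = gene_id, seqid = seqid, strand = strand,
    span_start = span_start, span_end = span_end,
    start_codon = if (strand == "+") span_start else span_end,
    stop_end = if (strand == "+") span_end else span_start,
    cds = I(list(cds[, c("start", "end"), drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Read gene models from a GFF3 file
#'
#' Collects `CDS` features grouped by their gene (via the `Parent` or
#' `gene_id`/`ID` attribute) into [gene_model()] rows.
#'
#' @param path GFF3 file path.
#' @return Data frame of gene models (one row per gene).
#' @export
genes_from_gff <- function(path) {
  gr <- rtracklayer::import(path)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features found in ", path)
  key <- if (!is.null(cds$Parent) && all(lengths(cds$Parent) > 0)) {
    vapply(cds$Parent, function(p) as.character(p)[1L], character(1L))
  } else if (!is.null(cds$gene_id)) {
    as.character(cds$gene_id)
  } else {
    as.character(cds$ID)
  }
  key <- sub("^(gene|mRNA|transcript)[:.]", "", key)
  rows <- lapply(split(seq_along(cds), key), function(idx) {
    sub <- cds[idx]
    gene_model(
      gene_id = key[idx[1L]],
      strand = as.character(BiocGenerics::strand(sub))[1L],
      cds = data.frame(start = BiocGenerics::start(sub),
                       end = BiocGenerics::end(sub)),
      seqid = as.character(GenomicRanges::seqnames(sub))[1L]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Non-coding regions of a contig
#'
#' The complement of the union of all CDS intervals: intergenic and intronic
#' sequence are both retained (the non-coding mask is non-CDS, not
#' non-genic).
#'
#' @param contig_length Contig length in bp.
#' @param genes Gene-model table (from [gene_model()] rows or
#'   [genes_from_gff()]); `NULL` or empty means the whole contig is
#'   non-coding.
#' @return Data frame of intervals `start`, `end`, `width` partitioning the
#'   contig together with the CDS union.
#' @export
noncoding_regions <- function(contig_length, genes = NULL) {
  stopifnot(contig_length >= 1)
  whole <- IRanges::IRanges(1L, as.integer(contig_length))
  if (is.null(genes) || nrow(genes) == 0L) {
    out <- as.data.frame(whole)[, c("start", "end", "width")]
    return(out)
  }
  cds <- do.call(rbind, genes$cds)
  if (any(cds$start < 1L) || any(cds$end > contig_length)) {
    stop("CDS intervals outside contig bounds")
  }
  mask <- IRanges::reduce(IRanges::IRanges(cds$start, cds$end))
  nc <- IRanges::setdiff(whole, mask)
  as.data.frame(nc)[, c("start", "end", "width")]
}

#' Assign modules to the genes they are upstream of
#'
#' For each module, every gene whose start codon lies downstream of the
#' module in that gene's reading orientation is a candidate (side
#' `upstream`); candidates are reported nearest first, so a module sitting
#' between two divergently transcribed genes lists both. If no gene has the
#' module upstream, the nearest gene is reported with side `internal`
#' (module overlapping the gene span) or `downstream`. Distances run from
#' the module edge nearest the start codon to the first base of the start
#' codon, exclusive of both (so a module ending at 4447 with a plus-strand
#' start codon at 5001 is 553 bp upstream).
#'
#' @param modules Module (or pair) table with `left_start` and `right_end`
#'   columns, or any table with `start`/`end`.
#' @param genes Gene-model table on the same contig.
#' @return Data frame with one row per (module, candidate gene):
#'   `module_id`, `gene_id`, `side`, `distance_bp`, `rank` (1 = assigned
#'   gene). Zero rows when `genes` is empty.
#' @export
assign_module_to_gene <- function(modules, genes) {
  ms <- if ("left_start" %in% names(modules)) modules$left_start else modules$start
  me <- if ("right_end" %in% names(modules)) modules$right_end else modules$end
  mid <- if ("module_id" %in% names(modules)) modules$module_id
         else if ("pair_id" %in% names(modules)) modules$pair_id
         else as.character(seq_len(nrow(modules)))
  empty <- data.frame(module_id = character(), gene_id = character(),
                      side = character(), distance_bp = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0L || nrow(modules) == 0L) {
    return(empty)
  }
  res <- list()
  for (i in seq_len(nrow(modules))) {
    s <- ms[i]; e <- me[i]
    side <- character(nrow(genes)); dist <- integer(nrow(genes))
    for (g in seq_len(nrow(genes))) {
      sc <- genes$start_codon[g]
      g1 <- genes$span_start[g]; g2 <- genes$span_end[g]
      if (s <= g2 && e >= g1) {
        side[g] <- "internal"
        dist[g] <- if (sc >= s && sc <= e) 0L
                   else as.integer(min(abs(s - sc), abs(e - sc)) - 1L)
      } else if (genes$strand[g] == "+") {
        if (e < sc) { side[g] <- "upstream"; dist[g] <- sc - e - 1L }
        else { side[g] <- "downstream"; dist[g] <- s - sc - 1L }
      } else {
        if (s > sc) { side[g] <- "upstream"; dist[g] <- s - sc - 1L }
        else { side[g] <- "downstream"; dist[g] <- sc - e - 1L }
      }
    }
    up <- which(side == "upstream")
    if (length(up)) {
      ord <- up[order(dist[up])]
    } else {
      ord <- which.min(dist)
    }
    res[[i]] <- data.frame(
      module_id = mid[i], gene_id = genes$gene_id[ord],
      side = side[ord], distance_bp = dist[ord],
      rank = seq_along(ord), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' 3' UTR search window for a gene
#'
#' If a transcript-defined UTR interval is supplied it is returned as-is
#' (source `"transcript"`); otherwise the window is the `utr_bp` bases
#' immediately 3' of the stop codon in gene orientation (source
#' `"stop+1000"` for the 1000 bp default), truncated at the contig ends.
#'
#' @param gene One-row gene-model data frame.
#' @param contig_length Contig length for truncation.
#' @param utr_bp Window length in bp (default 1000).
#' @param transcript_utr Optional list or data frame with `start`, `end`.
#' @return List with `start`, `end`, `strand`, `width`, `source`,
#'   `truncated`.
#' @export
utr_window <- function(gene, contig_length, utr_bp = 1000,
                       transcript_utr = NULL) {
  if (!is.null(transcript_utr)) {
    s <- transcript_utr$start; e <- transcript_utr$end
    return(list(start = s, end = e, strand = gene$strand,
                width = e - s + 1L, source = "transcript",
                truncated = FALSE))
  }
  if (gene$strand == "+") {
    s <- gene$stop_end + 1L
    e <- min(gene$stop_end + utr_bp, contig_length)
    truncated <- (gene$stop_end + utr_bp) > contig_length
  } else {
    e <- gene$stop_end - 1L
    s <- max(gene$stop_end - utr_bp, 1L)
    truncated <- (gene$stop_end - utr_bp) < 1L
  }
  if (e < s) stop("gene has no room for a 3' UTR window on this contig")
  list(start = as.integer(s), end = as.integer(e), strand = gene$strand,
       width = as.integer(e - s + 1L),
       source = sprintf("stop+%d", utr_bp), truncated = truncated)
}

#' Gene-oriented sequence of a UTR window
#'
#' @param window A [utr_window()] result.
#' @param contig Contig sequence (any form accepted by [scan_pattern()]).
#' @return Character string in gene (sense) orientation.
#' @export
utr_seq <- function(window, contig) {
  seq <- toupper(.contig_seq(contig))
  s <- substring(seq, window$start, window$end)
  if (window$strand == "-") s <- revcomp(s)
  s
}
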