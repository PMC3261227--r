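# Synthetic-contig generator: plants whole regulatory architectures
# (SPS/SPS+A modules, proneural A boxes, 3' UTR box strings) over an i.i.d.
# background with a ground-truth record, so every pipeline stage can be
# tested for recall and false positives without any external data.

.SUH_CORE <- "GTGAGAA"   # YGTGRGAA with R realised as A; prepend the Y char
.ABOX_SEQ <- "ACAGCTG"   # RCAGSTG with R = A, S = C
.BOX_SEQS <- c(Brd = "AGCTTTA", GY = "GTCTTCC", K = "TGTGAT")

#' Specify one module to plant
#'
#' @param module_id Label.
#' @param gene_id Target gene (must exist in the spec's gene table).
#' @param upstream_distance Bases strictly between the module edge nearest
#'   the start codon and the first base of the start codon.
#' @param spacer Bases strictly between the two Su(H) sites (canonical 17).
#' @param y_upstream,y_downstream Y-position characters of the gene-upstream
#'   and gene-downstream sites; must be `"C"` or `"T"` (the Y code) so the
#'   planted site matches the consensus.
#' @param abox_offsets Integer vector of A-box placements: the gap in bp
#'   between the A box and the module span, negative values to the left of
#'   the module, non-negative to the right. Empty vector plants a bare SPS.
#' @return One-row data frame (list column `abox_offsets`).
#' @export
module_spec <- function(module_id, gene_id, upstream_distance,
                        spacer = 17, y_upstream = "T", y_downstream = "C",
                        abox_offsets = integer(0)) {
  stopifnot(upstream_distance >= 0, spacer >= 0)
  if (!y_upstream %in% c("C", "T") || !y_downstream %in% c("C", "T")) {
    stop("Y-position characters must be 'C' or 'T'")
  }
  data.frame(module_id = module_id, gene_id = gene_id,
             upstream_distance = as.integer(upstream_distance),
             spacer = as.integer(spacer),
             y_upstream = y_upstream, y_downstream = y_downstream,
             abox_offsets = I(list(as.integer(abox_offsets))),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic contig with planted architectures
#'
#' @param length Contig length in bp.
#' @param genes Data frame with columns `gene_id`, `strand`, `cds_start`,
#'   `cds_end` (single-interval CDS per gene).
#' @param modules Row-bound [module_spec()] rows, or `NULL`.
#' @param utr_boxes Named list (by `gene_id`); each element either a
#'   character vector of box types (`"Brd"`, `"GY"`, `"K"`; offsets are then
#'   laid out automatically at 10, 40, 70, ... bp into the window) or a data
#'   frame with columns `box_type`, `offset` (0-based offset into the
#'   gene-oriented UTR window).
#' @param gc Background GC fraction (default 0.40, fly-like intergenic DNA).
#' @param utr_bp UTR window length used for box planting (default 1000).
#' @param clean_background If `TRUE` (default), background windows that
#'   accidentally spawn unplanted motif matches are re-drawn so recall and
#'   false-positive counts are exact by construction.
#' @param seed Optional RNG seed applied by [generate_contig()].
#' @param contig_id Contig label.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(length, genes, modules = NULL, utr_boxes = NULL,
                       gc = 0.4, utr_bp = 1000, clean_background = TRUE,
                       seed = NULL, contig_id = "synthetic_contig") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  need <- c("gene_id", "strand", "cds_start", "cds_end")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns ", paste(need, collapse = ", "))
  }
  if (any(!genes$strand %in% c("+", "-"))) stop("gene strand must be +/-")
  if (any(genes$cds_start < 1) || any(genes$cds_end > length) ||
      any(genes$cds_end - genes$cds_start < 5)) {
    stop("infeasible packing: CDS outside contig or shorter than 6 bp")
  }
  if (!is.null(modules)) {
    bad <- setdiff(modules$gene_id, genes$gene_id)
    if (length(bad)) stop("modules target unknown genes: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(utr_boxes)) {
    bad <- setdiff(names(utr_boxes), genes$gene_id)
    if (length(bad)) stop("utr_boxes name unknown genes: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(length = as.integer(length), genes = genes,
                 modules = modules, utr_boxes = utr_boxes, gc = gc,
                 utr_bp = as.integer(utr_bp),
                 clean_background = isTRUE(clean_background),
                 seed = seed, contig_id = contig_id),
            class = "plant_spec")
}

.norm_boxes <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("box_type", "offset") %in% names(x)))
    return(x[, c("box_type", "offset"), drop = FALSE])
  }
  if (!length(x)) {
    return(data.frame(box_type = character(), offset = integer()))
  }
  data.frame(box_type = as.character(x),
             offset = 10L + 30L * (seq_along(x) - 1L))
}

.draw_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# compute planted footprints for a spec (coordinates, strands, sequences)
.plan_footprints <- function(spec) {
  genes <- spec$genes
  fp <- list()
  add <- function(id, kind, pattern, start, end, strand, site_seq,
                  module_id = NA, gene_id = NA, role = NA, extra = NA) {
    fp[[length(fp) + 1L]] <<- data.frame(
      id = id, kind = kind, pattern = pattern,
      start = as.integer(start), end = as.integer(end), strand = strand,
      site_seq = site_seq, module_id = module_id, gene_id = gene_id,
      role = role, extra = extra, stringsAsFactors = FALSE)
  }
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    s <- genes$cds_start[g]; e <- genes$cds_end[g]
    if (genes$strand[g] == "+") {
      add(paste0(gid, "_start"), "codon", NA, s, s + 2L, "+", "ATG",
          gene_id = gid)
      add(paste0(gid, "_stop"), "codon", NA, e - 2L, e, "+", "TAA",
          gene_id = gid)
    } else {
      add(paste0(gid, "_start"), "codon", NA, e - 2L, e, "-", "ATG",
          gene_id = gid)
      add(paste0(gid, "_stop"), "codon", NA, s, s + 2L, "-", "TAA",
          gene_id = gid)
    }
  }
  if (!is.null(spec$modules)) {
    for (m in seq_len(nrow(spec$modules))) {
      mm <- spec$modules[m, ]
      g <- genes[genes$gene_id == mm$gene_id, ]
      sp <- mm$spacer
      if (g$strand == "+") {
        sc <- g$cds_start
        mod_end <- sc - mm$upstream_distance - 1L
        mod_start <- mod_end - (16L + sp) + 1L
        up_seq <- paste0(mm$y_upstream, .SUH_CORE)
        down_seq <- paste0(mm$y_downstream, .SUH_CORE)
        add(paste0(mm$module_id, "_S_up"), "suh_site", "SuH",
            mod_start, mod_start + 7L, "+", up_seq,
            module_id = mm$module_id, gene_id = mm$gene_id,
            role = "upstream")
        add(paste0(mm$module_id, "_S_down"), "suh_site", "SuH",
            mod_end - 7L, mod_end, "-", down_seq,
            module_id = mm$module_id, gene_id = mm$gene_id,
            role = "downstream")
      } else {
        sc <- g$cds_end
        mod_start <- sc + mm$upstream_distance + 1L
        mod_end <- mod_start + (16L + sp) - 1L
        add(paste0(mm$module_id, "_S_down"), "suh_site", "SuH",
            mod_start, mod_start + 7L, "+",
            paste0(mm$y_downstream, .SUH_CORE),
            module_id = mm$module_id, gene_id = mm$gene_id,
            role = "downstream")
        add(paste0(mm$module_id, "_S_up"), "suh_site", "SuH",
            mod_end - 7L, mod_end, "-",
            paste0(mm$y_upstream, .SUH_CORE),
            module_id = mm$module_id, gene_id = mm$gene_id,
            role = "upstream")
      }
      offs <- mm$abox_offsets[[1L]]
      for (k in seq_along(offs)) {
        d <- offs[k]
        if (d >= 0) {
          ab_s <- mod_end + d + 1L
        } else {
          ab_s <- mod_start + d - 7L  # end = mod_start + d - 1, width 7
        }
        add(paste0(mm$module_id, "_A", k), "abox", "Abox",
            ab_s, ab_s + 6L, "+", .ABOX_SEQ,
            module_id = mm$module_id, gene_id = mm$gene_id,
            extra = abs(d))
      }
    }
  }
  if (!is.null(spec$utr_boxes)) {
    for (gid in names(spec$utr_boxes)) {
      g <- genes[genes$gene_id == gid, ]
      boxes <- .norm_boxes(spec$utr_boxes[[gid]])
      for (k in seq_len(nrow(boxes))) {
        bt <- boxes$box_type[k]
        if (!bt %in% names(.BOX_SEQS)) stop("unknown box type ", bt)
        w <- nchar(.BOX_SEQS[[bt]])
        o <- boxes$offset[k]
        if (g$strand == "+") {
          bs <- g$cds_end + 1L + o
          be <- bs + w - 1L
          strand <- "+"
        } else {
          be <- g$cds_start - 1L - o
          bs <- be - w + 1L
          strand <- "-"
        }
        add(paste0(gid, "_", bt, "_", k), "utr_box", bt, bs, be, strand,
            .BOX_SEQS[[bt]], gene_id = gid, extra = o)
      }
    }
  }
  out <- do.call(rbind, fp)
  rownames(out) <- NULL
  out
}

.plus_slice <- function(fp_row) {
  if (fp_row$strand == "+") fp_row$site_seq else revcomp(fp_row$site_seq)
}

#' Generate a synthetic contig with planted ground truth
#'
#' Draws an i.i.d. background at the requested GC fraction, plants start and
#' stop codons for every gene, whole SPS/SPS+A modules (two inverted Su(H)
#' sites with the requested spacer and Y-position characters, plus A boxes
#' at the requested gaps) and 3' UTR box strings, all verbatim. In
#' clean-background mode any accidental, unplanted match of the five motifs
#' (either strand) is removed by re-drawing the background bases it uses, so
#' scanning the output recovers exactly the planted architecture. Output is
#' deterministic given the spec's seed.
#'
#' @param spec A [plant_spec()].
#' @return Object of class `synthetic_contig`: list with `contig_id`, `seq`
#'   (character), `genes` (gene-model table), `truth` (lists `sites`,
#'   `aboxes`, `modules`, `utr_boxes`, `genes`), `footprints`, `spec`.
#' @export
generate_contig <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  len <- spec$length
  fp <- .plan_footprints(spec)
  if (any(fp$start < 1L) || any(fp$end > len)) {
    stop("infeasible packing: planted element outside contig bounds")
  }
  ord <- order(fp$start)
  if (any(fp$start[ord][-1L] <= fp$end[ord][-length(ord)])) {
    i <- which(fp$start[ord][-1L] <= fp$end[ord][-length(ord)])[1L]
    stop(sprintf("infeasible packing: '%s' overlaps '%s'",
                 fp$id[ord][i + 1L], fp$id[ord][i]))
  }
  # planted elements must not sit inside any CDS (they would be masked)
  non_codon <- fp[fp$kind %in% c("suh_site", "abox"), , drop = FALSE]
  for (g in seq_len(nrow(spec$genes))) {
    hit <- non_codon$start <= spec$genes$cds_end[g] &
      non_codon$end >= spec$genes$cds_start[g]
    if (any(hit)) {
      stop(sprintf("infeasible packing: '%s' overlaps CDS of %s",
                   non_codon$id[which(hit)[1L]], spec$genes$gene_id[g]))
    }
  }

  seqv <- .draw_bases(len, spec$gc)
  planted_pos <- integer(0)
  for (i in seq_len(nrow(fp))) {
    slice <- strsplit(.plus_slice(fp[i, ]), "", fixed = TRUE)[[1L]]
    seqv[fp$start[i]:fp$end[i]] <- slice
    planted_pos <- c(planted_pos, fp$start[i]:fp$end[i])
  }
  is_planted <- rep(FALSE, len)
  is_planted[planted_pos] <- TRUE

  if (spec$clean_background) {
    motifs <- espl_motifs()
    planted_keys <- with(fp[!is.na(fp$pattern), ],
                         paste(pattern, start, end, strand))
    for (iter in seq_len(100L)) {
      contig <- paste(seqv, collapse = "")
      hits <- scan_motifs(contig, motifs, contig_id = spec$contig_id)
      keys <- paste(hits$pattern, hits$start, hits$end, hits$strand)
      stray <- hits[!keys %in% planted_keys, , drop = FALSE]
      if (nrow(stray) == 0L) break
      redraw <- unique(unlist(lapply(seq_len(nrow(stray)), function(k) {
        pos <- stray$start[k]:stray$end[k]
        pos[!is_planted[pos]]
      })))
      if (!length(redraw)) {
        stop("cannot clean background: an unplanted match lies entirely ",
             "inside planted elements")
      }
      seqv[redraw] <- .draw_bases(length(redraw), spec$gc)
      if (iter == 100L) stop("clean-background rejection did not converge")
    }
  }
  contig <- paste(seqv, collapse = "")

  genes <- do.call(rbind, lapply(seq_len(nrow(spec$genes)), function(g) {
    gene_model(spec$genes$gene_id[g], spec$genes$strand[g],
               c(spec$genes$cds_start[g], spec$genes$cds_end[g]),
               seqid = spec$contig_id)
  }))

  sites <- fp[fp$kind == "suh_site", c("id", "module_id", "gene_id",
                                       "pattern", "start", "end", "strand",
                                       "site_seq", "role")]
  names(sites)[names(sites) == "id"] <- "site_id"
  sites$degraded <- rep(FALSE, nrow(sites))
  aboxes <- fp[fp$kind == "abox", c("id", "module_id", "gene_id", "start",
                                    "end", "strand", "site_seq", "extra")]
  names(aboxes)[names(aboxes) == "id"] <- "abox_id"
  names(aboxes)[names(aboxes) == "extra"] <- "distance_bp"
  aboxes$degraded <- rep(FALSE, nrow(aboxes))
  utr_truth <- fp[fp$kind == "utr_box", c("id", "gene_id", "pattern",
                                          "start", "end", "strand",
                                          "extra")]
  names(utr_truth)[names(utr_truth) == "id"] <- "box_id"
  names(utr_truth)[names(utr_truth) == "pattern"] <- "box_type"
  names(utr_truth)[names(utr_truth) == "extra"] <- "offset"
  utr_truth$degraded <- rep(FALSE, nrow(utr_truth))

  modules <- NULL
  if (!is.null(spec$modules)) {
    modules <- do.call(rbind, lapply(seq_len(nrow(spec$modules)),
                                     function(m) {
      mm <- spec$modules[m, ]
      ss <- sites[sites$module_id == mm$module_id, ]
      data.frame(module_id = mm$module_id, gene_id = mm$gene_id,
                 start = min(ss$start), end = max(ss$end),
                 spacer = mm$spacer,
                 module_class = if (length(mm$abox_offsets[[1L]])) "SPS+A"
                                else "SPS",
                 y_upstream = mm$y_upstream,
                 y_downstream = mm$y_downstream,
                 y_canonical = mm$y_upstream == "T" &
                   mm$y_downstream == "C",
                 n_aboxes = length(mm$abox_offsets[[1L]]),
                 upstream_distance = mm$upstream_distance,
                 degraded = FALSE, stringsAsFactors = FALSE)
    }))
  }
  rownames(sites) <- rownames(aboxes) <- rownames(utr_truth) <- NULL
  if (!is.null(modules)) rownames(modules) <- NULL

  structure(list(contig_id = spec$contig_id, seq = contig, genes = genes,
                 truth = list(sites = sites, aboxes = aboxes,
                              modules = modules, utr_boxes = utr_truth),
                 footprints = fp, spec = spec),
            class = "synthetic_contig")
}

#' @export
print.synthetic_contig <- function(x, ...) {
  nmod <- if (is.null(x$truth$modules)) 0L else nrow(x$truth$modules)
  cat(sprintf(
    "synthetic contig '%s': %d bp, %d genes, %d planted modules, %d UTR boxes\n",
    x$contig_id, nchar(x$seq), nrow(x$genes), nmod,
    nrow(x$truth$utr_boxes)))
  invisible(x)
}

.shift_coords <- function(df, cols, pos, delta) {
  for (cl in cols) {
    v <- df[[cl]]
    df[[cl]] <- ifelse(v > pos, v + delta, v)
  }
  df
}

#' Mutate a planted site and update the ground truth
#'
#' Applies a single-base edit to a planted Su(H) site, A box or UTR box.
#' Substitutions that leave the site matching its degenerate consensus
#' (e.g. flipping the Y-position T to C) are accepted and the truth record
#' is updated (Y characters and `y_canonical` follow the new sequence);
#' substitutions that break the consensus mark the site (and any module
#' depending on it) as degraded, so expected recall drops accordingly. A
#' deletion must break the consensus; edits that leave the contig unchanged
#' are rejected as no-ops.
#'
#' @param sim A [generate_contig()] result.
#' @param site_id Identifier from `sim$truth$sites`, `sim$truth$aboxes` or
#'   `sim$truth$utr_boxes`.
#' @param edit `list(op = "substitute", pos = <1-based position within the
#'   motif-oriented site>, base = <new base>)` or
#'   `list(op = "delete", pos = <position>)`.
#' @return The updated `synthetic_contig`.
#' @export
degrade_site <- function(sim, site_id, edit) {
  stopifnot(inherits(sim, "synthetic_contig"))
  tr <- sim$truth
  tab <- NULL; row <- NULL
  for (nm in c("sites", "aboxes", "utr_boxes")) {
    idcol <- c(sites = "site_id", aboxes = "abox_id",
               utr_boxes = "box_id")[[nm]]
    k <- which(tr[[nm]][[idcol]] == site_id)
    if (length(k)) { tab <- nm; row <- k; break }
  }
  if (is.null(tab)) stop("unknown site_id: ", site_id)
  rec <- tr[[tab]][row, ]
  pat_name <- if (tab == "aboxes") "Abox" else
    if (tab == "sites") "SuH" else rec$box_type
  pattern <- espl_motifs()[[pat_name]]
  width <- rec$end - rec$start + 1L
  if (edit$pos < 1L || edit$pos > width) stop("edit position outside site")
  gpos <- if (rec$strand == "+") rec$start + edit$pos - 1L
          else rec$end - edit$pos + 1L
  seqv <- strsplit(sim$seq, "", fixed = TRUE)[[1L]]

  if (edit$op == "substitute") {
    newb <- toupper(edit$base)
    gbase <- if (rec$strand == "+") newb else revcomp(newb)
    if (seqv[gpos] == gbase) stop("edit is a no-op")
    seqv[gpos] <- gbase
    new_slice <- paste(seqv[rec$start:rec$end], collapse = "")
    new_site <- if (rec$strand == "+") new_slice else revcomp(new_slice)
    still <- new_site %in% iupac_expand(pattern)
    if (tab == "utr_boxes") tr$utr_boxes$degraded[row] <- !still
    if (tab == "sites") {
      tr$sites$site_seq[row] <- new_site
      if (!still) {
        tr$sites$degraded[row] <- TRUE
        mid <- tr$sites$module_id[row]
        tr$modules$degraded[tr$modules$module_id == mid] <- TRUE
      } else if (edit$pos == 1L) {
        mid <- tr$sites$module_id[row]
        mrow <- which(tr$modules$module_id == mid)
        ych <- substr(new_site, 1L, 1L)
        if (tr$sites$role[row] == "upstream") {
          tr$modules$y_upstream[mrow] <- ych
        } else {
          tr$modules$y_downstream[mrow] <- ych
        }
        tr$modules$y_canonical[mrow] <-
          tr$modules$y_upstream[mrow] == "T" &
          tr$modules$y_downstream[mrow] == "C"
      }
    }
    if (tab == "aboxes") {
      tr$aboxes$site_seq[row] <- new_site
      if (!still) {
        tr$aboxes$degraded[row] <- TRUE
        mid <- tr$aboxes$module_id[row]
        if (all(tr$aboxes$degraded[tr$aboxes$module_id == mid])) {
          mrow <- which(tr$modules$module_id == mid)
          tr$modules$module_class[mrow] <- "SPS"
          tr$modules$n_aboxes[mrow] <- 0L
        }
      }
    }
  } else if (edit$op == "delete") {
    seqv <- seqv[-gpos]
    # shift every coordinate strictly beyond the deleted base
    tr$sites <- .shift_coords(tr$sites, c("start", "end"), gpos, -1L)
    tr$aboxes <- .shift_coords(tr$aboxes, c("start", "end"), gpos, -1L)
    tr$utr_boxes <- .shift_coords(tr$utr_boxes, c("start", "end"), gpos, -1L)
    if (!is.null(tr$modules)) {
      tr$modules <- .shift_coords(tr$modules, c("start", "end"), gpos, -1L)
    }
    sim$genes <- .shift_coords(sim$genes,
                               c("span_start", "span_end", "start_codon",
                                 "stop_end"), gpos, -1L)
    sim$genes$cds <- I(lapply(sim$genes$cds, .shift_coords,
                              cols = c("start", "end"), pos = gpos,
                              delta = -1L))
    # the edited record keeps its start; its interval is now one base short
    rec2 <- tr[[tab]][row, ]
    new_slice <- paste(seqv[rec2$start:(rec2$start + width - 1L)],
                       collapse = "")
    new_site <- if (rec2$strand == "+") new_slice else revcomp(new_slice)
    if (new_site %in% iupac_expand(pattern)) {
      stop("deletion leaves the site still matching its consensus")
    }
    tr[[tab]]$degraded[row] <- TRUE
    if (tab == "sites") {
      mid <- tr$sites$module_id[row]
      tr$modules$degraded[tr$modules$module_id == mid] <- TRUE
    }
    if (tab == "aboxes") {
      mid <- tr$aboxes$module_id[row]
      if (all(tr$aboxes$degraded[tr$aboxes$module_id == mid])) {
        mrow <- which(tr$modules$module_id == mid)
        tr$modules$module_class[mrow] <- "SPS"
        tr$modules$n_aboxes[mrow] <- 0L
      }
    }
  } else {
    stop("edit$op must be 'substitute' or 'delete'")
  }
  sim$seq <- paste(seqv, collapse = "")
  sim$truth <- tr
  sim
}

#' Generate a diverged ortholog of a synthetic contig
#'
#' Derives a second contig from the first under a per-base substitution
#' model (and optionally a geometric-length indel model). Planted elements
#' (and gene start/stop codons) are protected from mutation when
#' `protect = TRUE`, emulating conserved regulatory modules over diverged
#' background; with `protect = FALSE` the planted architecture is exposed
#' to mutation. With no indels the expected flank identity between the two
#' contigs is `100 * (1 - divergence)`.
#'
#' @param spec_a [plant_spec()] for the reference contig.
#' @param divergence Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base indel initiation probability (default 0).
#' @param indel_mean Mean geometric indel length (default 2).
#' @param protect Protect planted elements from mutation (default `TRUE`).
#' @param seed Optional seed for the mutation step.
#' @return List with `a` and `b` (`synthetic_contig` objects; `b` carries
#'   coordinate-mapped truth), `divergence`, `indel_rate`, `protect`, and
#'   `expected_utr_class` (per-gene expectation: `"identical"` or
#'   `"identical-empty"` under protection, `NA` otherwise).
#' @export
generate_ortholog_pair <- function(spec_a, divergence, indel_rate = 0,
                                   indel_mean = 2, protect = TRUE,
                                   seed = NULL) {
  stopifnot(divergence >= 0, divergence < 1, indel_rate >= 0)
  a <- generate_contig(spec_a)
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(a$seq)
  seqv <- strsplit(a$seq, "", fixed = TRUE)[[1L]]
  prot <- rep(FALSE, len)
  if (protect) {
    for (i in seq_len(nrow(a$footprints))) {
      prot[a$footprints$start[i]:a$footprints$end[i]] <- TRUE
    }
  }
  # substitutions
  sub_idx <- which(!prot & stats::runif(len) < divergence)
  if (length(sub_idx)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    seqv[sub_idx] <- vapply(seqv[sub_idx], function(b) {
      k <- sample.int(3L, 1L)
      substr(alt[[b]], k, k)
    }, character(1L), USE.NAMES = FALSE)
  }
  # indels
  ins_pos <- integer(0); ins_len <- integer(0); ins_seq <- character(0)
  del_pos <- logical(len)
  if (indel_rate > 0) {
    ev <- which(!prot & stats::runif(len) < indel_rate)
    for (p in ev) {
      L <- stats::rgeom(1L, 1 / indel_mean) + 1L
      if (stats::runif(1L) < 0.5) {
        ins_pos <- c(ins_pos, p); ins_len <- c(ins_len, L)
        ins_seq <- c(ins_seq,
                     paste(.draw_bases(L, spec_a$gc), collapse = ""))
      } else {
        run <- p
        while (length(run) < L && (p + length(run)) <= len &&
               !prot[p + length(run)] && !del_pos[p + length(run)]) {
          run <- c(run, p + length(run))
        }
        del_pos[run] <- TRUE
      }
    }
  }
  # build contig b and the old->new coordinate map
  keep <- !del_pos
  ins_at <- integer(len + 1L)  # inserted bases immediately after position i
  if (length(ins_pos)) {
    for (k in seq_along(ins_pos)) {
      ins_at[ins_pos[k] + 1L] <- ins_at[ins_pos[k] + 1L] + ins_len[k]
    }
  }
  # new coordinate of old position x = kept bases up to x plus all bases
  # inserted before x's slot (ins_at[i] = bases inserted just before i)
  new_pos <- cumsum(ins_at[seq_len(len)]) + cumsum(as.integer(keep))
  map <- function(x) new_pos[x]

  if (!length(ins_pos) && !any(del_pos)) {
    seq_b <- paste(seqv, collapse = "")
  } else {
    chunks <- character(len)
    for (i in seq_len(len)) {
      pre <- if (ins_at[i] > 0) {
        k <- which(ins_pos == i - 1L)
        paste(ins_seq[k], collapse = "")
      } else ""
      chunks[i] <- paste0(pre, if (keep[i]) seqv[i] else "")
    }
    tail_ins <- if (ins_at[len + 1L] > 0) {
      paste(ins_seq[ins_pos == len], collapse = "")
    } else ""
    seq_b <- paste0(paste(chunks, collapse = ""), tail_ins)
  }

  b <- a
  b$contig_id <- paste0(a$contig_id, "_b")
  b$seq <- seq_b
  remap <- function(df, cols) {
    for (cl in cols) df[[cl]] <- map(df[[cl]])
    df
  }
  b$truth$sites <- remap(b$truth$sites, c("start", "end"))
  b$truth$aboxes <- remap(b$truth$aboxes, c("start", "end"))
  b$truth$utr_boxes <- remap(b$truth$utr_boxes, c("start", "end"))
  if (!is.null(b$truth$modules)) {
    b$truth$modules <- remap(b$truth$modules, c("start", "end"))
  }
  b$footprints <- remap(b$footprints, c("start", "end"))
  b$genes <- remap(b$genes, c("span_start", "span_end", "start_codon",
                              "stop_end"))
  b$genes$cds <- I(lapply(b$genes$cds, remap, cols = c("start", "end")))
  b$genes$seqid <- b$contig_id

  expected <- vapply(a$genes$gene_id, function(gid) {
    if (!protect) return(NA_character_)
    n <- sum(a$truth$utr_boxes$gene_id == gid)
    if (n == 0L) "identical-empty" else "identical"
  }, character(1L))
  list(a = a, b = b, divergence = divergence, indel_rate = indel_rate,
       protect = protect, expected_utr_class = expected)
}

#' Write a synthetic contig bundle to disk
#'
#' Emits `<prefix>.fasta` (contig), `<prefix>.gff3` (gene and CDS features,
#' GFF3 version 3, 1-based inclusive) and `<prefix>.truth.json`
#' (machine-readable ground truth).
#'
#' @param sim A [generate_contig()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix (defaults to the contig id).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic <- function(sim, dir, prefix = sim$contig_id) {
  stopifnot(inherits(sim, "synthetic_contig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  tj <- file.path(dir, paste0(prefix, ".truth.json"))
  ss <- Biostrings::DNAStringSet(sim$seq)
  names(ss) <- sim$contig_id
  Biostrings::writeXStringSet(ss, fa)

  g <- sim$genes
  gene_gr <- GenomicRanges::GRanges(
    seqnames = sim$contig_id,
    ranges = IRanges::IRanges(g$span_start, g$span_end),
    strand = g$strand, type = "gene", phase = NA_integer_,
    ID = g$gene_id)
  cds_gr <- GenomicRanges::GRanges(
    seqnames = sim$contig_id,
    ranges = IRanges::IRanges(g$span_start, g$span_end),
    strand = g$strand, type = "CDS",
    phase = 0L,
    ID = paste0(g$gene_id, ".cds"), Parent = g$gene_id)
  rtracklayer::export(c(gene_gr, cds_gr), gff, format = "gff3")

  truth <- sim$truth
  truth$genes <- sim$genes[, c("gene_id", "seqid", "strand", "span_start",
                               "span_end", "start_codon", "stop_end")]
  jsonlite::write_json(truth, tj, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fasta = fa, gff3 = gff, truth = tj))
}
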