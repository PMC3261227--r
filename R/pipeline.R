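# Orchestration: scan a contig for SPS/SPS+A modules, profile 3' UTR
# windows, and compare two species' outputs (module classes, flank
# identities, UTR organization).

.resolve_contig <- function(contig) {
  if (is.character(contig) && length(contig) == 1L &&
      nchar(contig) < 4096 && file.exists(contig)) {
    ss <- Biostrings::readDNAStringSet(contig)
    if (length(ss) == 0L || sum(Biostrings::width(ss)) == 0L) {
      stop("no sequence found in ", contig)
    }
    if (length(ss) > 1L) stop("expected a single contig in ", contig)
    return(ss)
  }
  contig
}

.resolve_genes <- function(genes, contig) {
  if (is.null(genes)) {
    if (inherits(contig, "synthetic_contig")) return(contig$genes)
    return(NULL)
  }
  if (is.character(genes) && length(genes) == 1L) {
    return(genes_from_gff(genes))
  }
  genes
}

#' Scan a contig for SPS / SPS+A modules
#'
#' The end-to-end module census: masks coding sequence, scans the
#' non-coding DNA on both strands for Su(H) sites and proneural A boxes,
#' builds inverted pairs within the spacer window, attaches A boxes within
#' `abox_max_dist`, assigns every module to the gene(s) it is upstream of,
#' and types the Y positions from the assigned gene's orientation.
#'
#' @param contig Contig sequence: FASTA path, character string, `DNAString`
#'   or a [generate_contig()] result (whose gene models are then the
#'   default annotation).
#' @param genes Gene models: data frame of [gene_model()] rows, GFF3 path,
#'   or `NULL` (no masking or assignment).
#' @param motifs Motif set (default [espl_motifs()]).
#' @param spacer_min,spacer_max,canonical_spacer Pair-builder window, see
#'   [find_inverted_pairs()].
#' @param abox_max_dist A-box association radius, see [associate_aboxes()].
#' @param noncoding_only Restrict hits to non-CDS sequence (default TRUE).
#' @param out_dir If non-NULL, write `modules.tsv`, `hits.tsv` and
#'   `modules.gff3` there.
#'
#' @return List of class `sps_scan`: `hits`, `pairs`, `modules` (with
#'   assignment and Y columns merged), `assignments`, `noncoding`,
#'   `summary` (named counts), `files` (paths written or NULL).
#' @export
run_scan <- function(contig, genes = NULL, motifs = espl_motifs(),
                     spacer_min = 0, spacer_max = 30,
                     canonical_spacer = 17, abox_max_dist = 500,
                     noncoding_only = TRUE, out_dir = NULL) {
  contig <- .resolve_contig(contig)
  genes <- .resolve_genes(genes, contig)
  seq <- .contig_seq(contig)
  contig_id <- .contig_id(contig)
  len <- nchar(seq)

  nc <- noncoding_regions(len, genes)
  hits <- scan_motifs(contig, motifs[c("SuH", "Abox")])
  if (noncoding_only && !is.null(genes) && nrow(genes)) {
    hits <- restrict_hits(hits, nc)
  }
  suh <- hits[hits$pattern == "SuH", , drop = FALSE]
  abox <- hits[hits$pattern == "Abox", , drop = FALSE]

  pairs <- find_inverted_pairs(suh, spacer_min = spacer_min,
                               spacer_max = spacer_max,
                               canonical_spacer = canonical_spacer)
  modules <- associate_aboxes(pairs, abox, max_dist = abox_max_dist)
  assignments <- assign_module_to_gene(modules, genes)

  if (nrow(modules)) {
    top <- assignments[assignments$rank == 1L, , drop = FALSE]
    idx <- match(modules$module_id, top$module_id)
    modules$gene_id <- top$gene_id[idx]
    modules$side <- top$side[idx]
    modules$distance_bp <- top$distance_bp[idx]
    gstrand <- genes$strand[match(modules$gene_id, genes$gene_id)]
    modules <- assign_y_positions(modules, gstrand)
  }

  spacers <- table(modules$spacer_bp)
  summary <- list(
    contig_id = contig_id, contig_length = len,
    n_suh_hits = nrow(suh), n_abox_hits = nrow(abox),
    n_pairs = nrow(pairs),
    n_sps_a = sum(modules$module_class == "SPS+A"),
    n_sps = sum(modules$module_class == "SPS"),
    spacer_counts = stats::setNames(as.integer(spacers), names(spacers))
  )
  files <- NULL
  if (!is.null(out_dir)) {
    files <- .write_scan(modules, hits, contig_id, len, out_dir)
  }
  structure(list(hits = hits, pairs = pairs, modules = modules,
                 assignments = assignments, noncoding = nc,
                 summary = summary, files = files),
            class = "sps_scan")
}

#' @export
print.sps_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "SPS scan of %s (%d bp): %d Su(H) hits, %d A-box hits -> %d pairs (%d SPS+A, %d SPS)\n",
    s$contig_id, s$contig_length, s$n_suh_hits, s$n_abox_hits, s$n_pairs,
    s$n_sps_a, s$n_sps))
  if (length(s$spacer_counts)) {
    cat("  spacers:",
        paste(sprintf("%s bp x%d", names(s$spacer_counts),
                      s$spacer_counts), collapse = ", "), "\n")
  }
  invisible(x)
}

.module_flat <- function(modules) {
  if (!nrow(modules)) {
    return(data.frame(module_id = character(), seqid = character(),
                      start = integer(), end = integer()))
  }
  data.frame(
    module_id = modules$module_id, seqid = modules$seqid,
    start = modules$left_start, end = modules$right_end,
    spacer_bp = modules$spacer_bp, orientation = modules$orientation,
    canonical = modules$canonical, module_class = modules$module_class,
    n_aboxes = modules$n_aboxes,
    abox_distances = vapply(modules$aboxes, function(d) {
      paste(d$distance_bp, collapse = ",")
    }, character(1L)),
    gene_id = if ("gene_id" %in% names(modules)) modules$gene_id else NA,
    side = if ("side" %in% names(modules)) modules$side else NA,
    distance_bp = if ("distance_bp" %in% names(modules))
      modules$distance_bp else NA,
    y_upstream = if ("y_upstream" %in% names(modules))
      modules$y_upstream else NA,
    y_downstream = if ("y_downstream" %in% names(modules))
      modules$y_downstream else NA,
    y_canonical = if ("y_canonical" %in% names(modules))
      modules$y_canonical else NA,
    stringsAsFactors = FALSE
  )
}

.write_scan <- function(modules, hits, contig_id, len, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- .module_flat(modules)
  mod_tsv <- file.path(out_dir, "modules.tsv")
  hit_tsv <- file.path(out_dir, "hits.tsv")
  gff <- file.path(out_dir, "modules.gff3")
  utils::write.table(flat, mod_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hits, hit_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(modules)) {
    parent <- GenomicRanges::GRanges(
      seqnames = contig_id,
      ranges = IRanges::IRanges(modules$left_start, modules$right_end),
      strand = "*", type = "regulatory_region",
      ID = modules$module_id, class = modules$module_class,
      spacer = as.character(modules$spacer_bp))
    kids <- list()
    for (i in seq_len(nrow(modules))) {
      kids[[length(kids) + 1L]] <- GenomicRanges::GRanges(
        seqnames = contig_id,
        ranges = IRanges::IRanges(
          c(modules$left_start[i], modules$right_start[i]),
          c(modules$left_end[i], modules$right_end[i])),
        strand = c(modules$left_strand[i], modules$right_strand[i]),
        type = "TF_binding_site",
        ID = paste0(modules$module_id[i], c("_S1", "_S2")),
        class = "SuH", spacer = NA_character_,
        Parent = modules$module_id[i])
      ab <- modules$aboxes[[i]]
      if (nrow(ab)) {
        kids[[length(kids) + 1L]] <- GenomicRanges::GRanges(
          seqnames = contig_id,
          ranges = IRanges::IRanges(ab$start, ab$end),
          strand = ab$strand, type = "TF_binding_site",
          ID = paste0(modules$module_id[i], "_A", seq_len(nrow(ab))),
          class = "Abox", spacer = NA_character_,
          Parent = modules$module_id[i])
      }
    }
    gr <- c(parent, do.call(c, kids))
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  c(modules = mod_tsv, hits = hit_tsv, gff3 = gff)
}

#' Profile the 3' UTR windows of all genes
#'
#' @param contig Contig (as in [run_scan()]).
#' @param genes Gene models (as in [run_scan()]).
#' @param species Species label carried into the profiles.
#' @param utr_bp Window length 3' of the stop codon (default 1000) used
#'   when no transcript UTR is available.
#' @param transcript_utrs Optional named list (by gene) of
#'   `list(start, end)` transcript-defined UTR intervals.
#' @param motifs Box motifs (default [utr_motifs()]).
#' @return List of class `utr_scan`: `profiles` (named list of
#'   [scan_utr()] objects) and `table` (one row per gene: box string,
#'   offsets, window source, truncation flag).
#' @export
run_utr <- function(contig, genes = NULL, species = NA, utr_bp = 1000,
                    transcript_utrs = NULL, motifs = utr_motifs()) {
  contig <- .resolve_contig(contig)
  genes <- .resolve_genes(genes, contig)
  if (is.null(genes) || nrow(genes) == 0L) stop("gene models are required")
  seq <- .contig_seq(contig)
  len <- nchar(seq)
  profiles <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    tr <- if (!is.null(transcript_utrs)) transcript_utrs[[gid]] else NULL
    win <- utr_window(genes[g, ], len, utr_bp = utr_bp,
                      transcript_utr = tr)
    profiles[[gid]] <- scan_utr(utr_seq(win, seq), motifs = motifs,
                                gene_id = gid, species = species,
                                source = win$source,
                                truncated = win$truncated)
  }
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(gene_id = p$gene_id, species = p$species,
               boxes = paste(p$boxes$box_type, collapse = ","),
               offsets = paste(p$boxes$offset, collapse = ","),
               window_length = p$window_length, source = p$source,
               truncated = p$truncated, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(profiles = profiles, table = tab), class = "utr_scan")
}

.module_for_gene <- function(scan, gene_id) {
  m <- scan$modules
  if (!nrow(m) || !"gene_id" %in% names(m)) return(NULL)
  m <- m[!is.na(m$gene_id) & m$gene_id == gene_id, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m[which.min(m$distance_bp), , drop = FALSE]
}

#' Compare two species' module and UTR architecture
#'
#' Per ortholog pair: SPS class concordance, spacer lengths, percent
#' identity of the module region with `flank_bp` of sequence on either side
#' (global affine-gap alignment; both the all-columns and the gap-excluded
#' identity are reported), and the 3' UTR organization class.
#'
#' @param scan_a,scan_b [run_scan()] results for the two species.
#' @param utr_a,utr_b [run_utr()] results.
#' @param contig_a,contig_b The two contig sequences.
#' @param ortholog_map Two-column data frame (`gene_a`, `gene_b`); defaults
#'   to pairing genes with equal ids.
#' @param flank_bp Flank width around the module for alignment (default
#'   200).
#' @param out_dir If non-NULL, write `comparison.tsv` and
#'   `utr_diagrams.txt` there.
#' @return List of class `sps_comparison`: `table` (per-gene rows),
#'   `summary` (counts), `alignments`, `utr_comparisons`, `files`.
#' @export
run_compare <- function(scan_a, scan_b, utr_a, utr_b, contig_a, contig_b,
                        ortholog_map = NULL, flank_bp = 200,
                        out_dir = NULL) {
  contig_a <- .resolve_contig(contig_a)
  contig_b <- .resolve_contig(contig_b)
  if (is.null(ortholog_map)) {
    shared <- intersect(names(utr_a$profiles), names(utr_b$profiles))
    ortholog_map <- data.frame(gene_a = shared, gene_b = shared,
                               stringsAsFactors = FALSE)
  }
  rows <- list(); alns <- list(); cmps <- list()
  for (i in seq_len(nrow(ortholog_map))) {
    ga <- ortholog_map$gene_a[i]; gb <- ortholog_map$gene_b[i]
    ma <- .module_for_gene(scan_a, ga)
    mb <- .module_for_gene(scan_b, gb)
    class_a <- if (is.null(ma)) NA_character_ else ma$module_class
    class_b <- if (is.null(mb)) NA_character_ else mb$module_class
    pid <- pid_ungapped <- NA_real_
    if (!is.null(ma) && !is.null(mb)) {
      fa <- extract_flanks(ma$left_start, ma$right_end, contig_a,
                           flank_bp = flank_bp)
      fb <- extract_flanks(mb$left_start, mb$right_end, contig_b,
                           flank_bp = flank_bp)
      al <- global_align(flank_slice(fa), flank_slice(fb))
      alns[[ga]] <- al
      pid <- al$percent_identity
      pid_ungapped <- al$percent_identity_ungapped
    }
    pa <- utr_a$profiles[[ga]]; pb <- utr_b$profiles[[gb]]
    utr_class <- NA_character_
    if (!is.null(pa) && !is.null(pb)) {
      cmp <- compare_organization(pa, pb)
      cmps[[ga]] <- cmp
      utr_class <- cmp$conservation_class
    }
    rows[[i]] <- data.frame(
      gene_a = ga, gene_b = gb, class_a = class_a, class_b = class_b,
      class_concordant = !is.na(class_a) & !is.na(class_b) &
        class_a == class_b,
      spacer_a = if (is.null(ma)) NA_integer_ else ma$spacer_bp,
      spacer_b = if (is.null(mb)) NA_integer_ else mb$spacer_bp,
      flank_identity = pid, flank_identity_ungapped = pid_ungapped,
      utr_class = utr_class, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  summary <- list(
    n_genes = nrow(tab),
    n_modules_both = sum(!is.na(tab$class_a) & !is.na(tab$class_b)),
    n_class_concordant = sum(tab$class_concordant),
    n_utr_identical = sum(tab$utr_class %in%
                            c("identical", "identical-empty")),
    utr_class_counts = table(tab$utr_class)
  )
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cmp_tsv <- file.path(out_dir, "comparison.tsv")
    utils::write.table(tab, cmp_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    diag_txt <- file.path(out_dir, "utr_diagrams.txt")
    writeLines(unlist(lapply(cmps, organization_diagram)), diag_txt)
    files <- c(comparison = cmp_tsv, diagrams = diag_txt)
  }
  structure(list(table = tab, summary = summary, alignments = alns,
                 utr_comparisons = cmps, files = files),
            class = "sps_comparison")
}

#' @export
print.sps_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Ortholog comparison: %d genes, %d with modules in both, %d class-concordant, %d UTR-identical\n",
    s$n_genes, s$n_modules_both, s$n_class_concordant, s$n_utr_identical))
  invisible(x)
}
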