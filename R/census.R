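# Shipped census fixture: a two-species synthetic contig pair whose planted
# architecture reproduces, by construction, the structure of the
# Enhancer-of-split regulatory census in an acalyptrate fly versus
# Drosophila: 11 genes, 7 SPS+A modules and 4 bare SPS pairs (one pair with
# the 15 bp spacer variant), the documented upstream distances and distal
# A boxes, the four genes with a C in the upstream Y position, and a 3' UTR
# box organization that is identical for 6 of the 11 orthologs (one of them
# as the empty-empty state).

.census_gene_ids <- c("mdelta", "mgamma", "mbeta", "m3", "malpha", "m2",
                      "m4", "m5", "m6", "m7", "m8")

.census_genes <- function() {
  n <- length(.census_gene_ids)
  start <- 6000L + 9000L * (seq_len(n) - 1L)
  data.frame(
    gene_id = .census_gene_ids,
    strand = ifelse(.census_gene_ids %in% c("m4", "m6"), "-", "+"),
    cds_start = start, cds_end = start + 899L,
    stringsAsFactors = FALSE
  )
}

.census_modules <- function(species) {
  # upstream distances differ between the two species for the four genes
  # with documented values (4970/553/469/338 vs 1419/353/761/275); the
  # distal A box sits 232 bp from the pair in species a and 405 bp in b
  d <- if (species == "a") {
    c(mdelta = 4970L, mgamma = 553L, m7 = 469L, m8 = 338L)
  } else {
    c(mdelta = 1419L, mgamma = 353L, m7 = 761L, m8 = 275L)
  }
  m7_abox <- if (species == "a") 232L else 405L
  rbind(
    module_spec("mdelta_sps", "mdelta", d[["mdelta"]], spacer = 15,
                abox_offsets = -40L),
    module_spec("mgamma_sps", "mgamma", d[["mgamma"]],
                abox_offsets = 25L),
    module_spec("cns1_sps", "mgamma", 1200L, abox_offsets = 30L),
    module_spec("mbeta_sps", "mbeta", 450L, y_upstream = "C"),
    module_spec("m3_sps", "m3", 500L),
    module_spec("malpha_sps", "malpha", 350L, y_upstream = "C"),
    module_spec("m2_sps", "m2", 300L, y_upstream = "C",
                abox_offsets = 30L),
    module_spec("m4_sps", "m4", 300L),
    module_spec("m5_sps", "m5", 400L, y_upstream = "C",
                abox_offsets = 40L),
    module_spec("m7_sps", "m7", d[["m7"]], abox_offsets = m7_abox),
    module_spec("m8_sps", "m8", d[["m8"]],
                abox_offsets = c(-25L, 25L))
  )
}

.census_utr_boxes <- function(species) {
  if (species == "a") {
    list(
      mgamma = c("Brd", "GY", "K"),
      malpha = c("Brd", "K"),
      m2 = c("GY", "K"),
      m8 = c("Brd", "GY", "GY", "K"),
      m3 = c("GY"),
      mdelta = c("Brd", "GY", "K"),
      m4 = c("GY", "K"),
      m5 = c("Brd", "GY"),
      mbeta = c("Brd"),
      m7 = c("K")
    )
  } else {
    list(
      mgamma = c("Brd", "GY", "K"),
      malpha = c("Brd", "K"),
      m2 = c("GY", "K"),
      m8 = c("Brd", "GY", "GY", "K"),
      m3 = c("GY"),
      mdelta = c("Brd", "K"),
      m4 = c("K"),
      m5 = c("GY"),
      mbeta = c("GY")
    )
  }
}

#' Census fixture specs for two synthetic species
#'
#' Builds a pair of [plant_spec()] objects (species `a` and `b`) encoding
#' the regulatory census structure of an 11-gene Enhancer-of-split-like
#' complex: species `a` carries 7 SPS+A modules and 4 bare SPS pairs, one
#' of the pairs has the 15 bp spacer variant, four genes have a C in the
#' upstream Y position, and the two species' 3' UTR box strings realize 5
#' identical organizations, one identical-empty (a gene with no boxes in
#' either species), 3 partial and 2 with nothing in common. Running
#' [run_scan()]/[run_utr()]/[run_compare()] on the generated contigs
#' recovers these counts exactly, verifying the end-to-end plumbing.
#'
#' @param seed Seed for the two backgrounds (species `b` uses `seed + 1`).
#' @return List with elements `a` and `b`.
#' @export
census_specs <- function(seed = 20230) {
  list(
    a = plant_spec(100000L, .census_genes(),
                   modules = .census_modules("a"),
                   utr_boxes = .census_utr_boxes("a"),
                   gc = 0.4, clean_background = TRUE, seed = seed,
                   contig_id = "census_a"),
    b = plant_spec(100000L, .census_genes(),
                   modules = .census_modules("b"),
                   utr_boxes = .census_utr_boxes("b"),
                   gc = 0.4, clean_background = TRUE, seed = seed + 1L,
                   contig_id = "census_b")
  )
}
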