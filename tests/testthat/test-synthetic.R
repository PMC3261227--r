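test_that("generation is deterministic given the seed", {
  spec <- simple_spec(seed = 99, utr = c("Brd", "GY"))
  s1 <- generate_contig(spec)
  s2 <- generate_contig(spec)
  expect_identical(s1$seq, s2$seq)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_contig(simple_spec(seed = 100, utr = c("Brd", "GY")))
  expect_false(identical(s1$seq, s3$seq))
})

test_that("a planted canonical SPS+A is recovered exactly by the pipeline", {
  sim <- generate_contig(simple_spec(seed = 7, spacer = 17,
                                     upstream_distance = 100,
                                     abox_offsets = -30L))
  res <- run_scan(sim)
  expect_equal(nrow(res$modules), 1)
  m <- res$modules
  tr <- sim$truth$modules
  expect_equal(m$left_start, tr$start)
  expect_equal(m$right_end, tr$end)
  expect_equal(m$spacer_bp, 17)
  expect_true(m$canonical)
  expect_equal(m$module_class, "SPS+A")
  expect_equal(m$aboxes[[1]]$distance_bp, 30)
  expect_equal(m$gene_id, "g1")
  expect_equal(m$side, "upstream")
  expect_equal(m$distance_bp, 100)
  expect_equal(m$y_upstream, "T")
  expect_equal(m$y_downstream, "C")
  expect_true(m$y_canonical)
})

test_that("planted UTR box strings are recovered in order", {
  sim <- generate_contig(simple_spec(seed = 21, utr = c("GY", "Brd", "K")))
  utr <- run_utr(sim, species = "x")
  expect_equal(utr$profiles$g1$boxes$box_type, c("GY", "Brd", "K"))
  tr <- sim$truth$utr_boxes
  expect_equal(utr$profiles$g1$boxes$offset, tr$offset)
})

test_that("infeasible packings are rejected with an explanation", {
  genes <- data.frame(gene_id = "g1", strand = "+", cds_start = 2000L,
                      cds_end = 2899L)
  # module would hang off the left contig edge
  expect_error(generate_contig(
    plant_spec(4000L, genes,
               modules = module_spec("m", "g1", 1990L), seed = 1)),
    "infeasible")
  # two A boxes on the same spot collide
  expect_error(generate_contig(
    plant_spec(4000L, genes,
               modules = module_spec("m", "g1", 100L,
                                     abox_offsets = c(-30L, -32L)),
               seed = 1)),
    "overlaps")
  # A box inside the CDS of another gene
  genes2 <- rbind(genes, data.frame(gene_id = "g0", strand = "+",
                                    cds_start = 1000L, cds_end = 1500L))
  expect_error(generate_contig(
    plant_spec(4000L, genes2,
               modules = module_spec("m", "g1", 300L,
                                     abox_offsets = -200L), seed = 1)),
    "CDS")
})

test_that("deleting a base in a planted site removes its pair from the scan", {
  sim <- generate_contig(simple_spec(seed = 33))
  before <- run_scan(sim)
  expect_equal(nrow(before$pairs), 1)
  mut <- degrade_site(sim, "mod1_S_up", list(op = "delete", pos = 4))
  after <- run_scan(mut)
  expect_equal(nrow(after$pairs), 0)
  expect_true(mut$truth$sites$degraded[mut$truth$sites$site_id == "mod1_S_up"])
  expect_true(mut$truth$modules$degraded)
  expect_equal(nchar(mut$seq), nchar(sim$seq) - 1)
})

test_that("a Y-position substitution keeps the pair but flips y_canonical", {
  sim <- generate_contig(simple_spec(seed = 35, y_upstream = "T"))
  mut <- degrade_site(sim, "mod1_S_up",
                      list(op = "substitute", pos = 1, base = "C"))
  expect_false(mut$truth$modules$degraded)
  expect_equal(mut$truth$modules$y_upstream, "C")
  expect_false(mut$truth$modules$y_canonical)
  res <- run_scan(mut)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$modules$y_upstream, "C")
  expect_false(res$modules$y_canonical)
})

test_that("no-op edits are rejected", {
  sim <- generate_contig(simple_spec(seed = 37, y_upstream = "T"))
  expect_error(degrade_site(sim, "mod1_S_up",
                            list(op = "substitute", pos = 1, base = "T")),
               "no-op")
  expect_error(degrade_site(sim, "nonexistent",
                            list(op = "substitute", pos = 1, base = "C")),
               "unknown")
})

test_that("a consensus-breaking substitution degrades the site", {
  sim <- generate_contig(simple_spec(seed = 39))
  # position 2 of YGTGRGAA must be G; A breaks the consensus
  mut <- degrade_site(sim, "mod1_S_down",
                      list(op = "substitute", pos = 2, base = "A"))
  expect_true(mut$truth$sites$degraded[
    mut$truth$sites$site_id == "mod1_S_down"])
  expect_true(mut$truth$modules$degraded)
  expect_equal(nrow(run_scan(mut)$pairs), 0)
})

test_that("ortholog pairs at divergence 0 are identical over every flank", {
  op <- generate_ortholog_pair(simple_spec(seed = 51, utr = c("Brd", "K")),
                               divergence = 0, seed = 52)
  expect_identical(op$a$seq, op$b$seq)
  m <- op$a$truth$modules
  al <- global_align(
    flank_slice(extract_flanks(m$start, m$end, op$a)),
    flank_slice(extract_flanks(m$start, m$end, op$b)))
  expect_equal(al$percent_identity, 100)
})

test_that("protected UTR boxes stay identical across the ortholog pair", {
  op <- generate_ortholog_pair(simple_spec(seed = 61,
                                           utr = c("Brd", "GY", "K")),
                               divergence = 0.15, protect = TRUE,
                               seed = 62)
  pa <- run_utr(op$a, species = "a")$profiles$g1
  pb <- run_utr(op$b, species = "b")$profiles$g1
  cmp <- compare_organization(pa, pb)
  expect_equal(cmp$conservation_class, "identical")
  expect_equal(op$expected_utr_class[["g1"]], "identical")

  # protected module still scans as a canonical SPS+A in the ortholog
  rb <- run_scan(op$b)
  expect_equal(nrow(rb$pairs), 1)
  expect_equal(rb$modules$module_class, "SPS+A")
})

test_that("indel-bearing orthologs keep a consistent coordinate map", {
  op <- generate_ortholog_pair(simple_spec(seed = 71, utr = c("GY")),
                               divergence = 0.05, indel_rate = 0.005,
                               indel_mean = 2, protect = TRUE, seed = 72)
  # every protected footprint must carry its exact sequence at the mapped
  # coordinates in contig b
  fp <- op$b$footprints
  seqb <- op$b$seq
  for (i in seq_len(nrow(fp))) {
    slice <- substring(seqb, fp$start[i], fp$end[i])
    want <- if (fp$strand[i] == "+") fp$site_seq[i] else revcomp(fp$site_seq[i])
    expect_equal(slice, want, info = fp$id[i])
  }
  rb <- run_scan(op$b)
  expect_equal(nrow(rb$pairs), 1)
})

test_that("clean background mode leaves no stray motif matches", {
  set.seed(81)
  for (rep in 1:5) {
    sim <- generate_contig(random_recall_spec(rep * 7L))
    hits <- scan_motifs(sim$seq, espl_motifs(), contig_id = sim$contig_id)
    planted <- with(sim$footprints[!is.na(sim$footprints$pattern), ],
                    paste(pattern, start, end, strand))
    keys <- paste(hits$pattern, hits$start, hits$end, hits$strand)
    expect_true(all(keys %in% planted))
    expect_true(all(planted %in% keys))
  }
})
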