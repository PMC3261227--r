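test_that("non-coding regions are the complement of the CDS union", {
  g <- gene_model("g1", "+", c(101, 400))
  nc <- noncoding_regions(1000, g)
  expect_equal(nc$start, c(1, 401))
  expect_equal(nc$end, c(100, 1000))

  # no genes: the whole contig is non-coding
  all_nc <- noncoding_regions(1000, NULL)
  expect_equal(all_nc$start, 1)
  expect_equal(all_nc$end, 1000)

  expect_error(noncoding_regions(300, gene_model("g", "+", c(100, 400))),
               "bounds")
  expect_error(gene_model("g", "+", c(400, 100)), "malformed")
})

test_that("non-coding plus CDS partitions the contig, even with overlapping genes", {
  set.seed(5)
  for (rep in 1:10) {
    L <- sample(500:2000, 1)
    n <- sample(1:4, 1)
    genes <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample.int(L - 20, 1)
      gene_model(paste0("g", i), sample(c("+", "-"), 1),
                 c(s, min(L, s + sample(10:200, 1))))
    }))
    nc <- noncoding_regions(L, genes)
    cds <- do.call(rbind, genes$cds)
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(cds))) covered[cds$start[i]:cds$end[i]] <- TRUE
    nc_covered <- rep(FALSE, L)
    for (i in seq_len(nrow(nc))) {
      expect_false(any(nc_covered[nc$start[i]:nc$end[i]]))  # disjoint
      nc_covered[nc$start[i]:nc$end[i]] <- TRUE
    }
    expect_false(any(nc_covered & covered))
    expect_true(all(nc_covered | covered))
  }
})

test_that("modules are assigned to the gene they are upstream of", {
  # plus-strand gene with start codon at 5001, module ending at 4447:
  # 553 intervening bases
  g <- gene_model("mg", "+", c(5001, 5900))
  mod <- data.frame(module_id = "m1", left_start = 4414, right_end = 4447)
  asn <- assign_module_to_gene(mod, g)
  expect_equal(asn$side, "upstream")
  expect_equal(asn$distance_bp, 553)
  expect_equal(asn$rank, 1)

  # minus-strand gene: a module at higher coordinates is upstream
  gm <- gene_model("gm", "-", c(1000, 1900))
  modm <- data.frame(module_id = "m2", left_start = 2200, right_end = 2233)
  asnm <- assign_module_to_gene(modm, gm)
  expect_equal(asnm$side, "upstream")
  expect_equal(asnm$distance_bp, 2200 - 1900 - 1)

  # module inside the gene span (an intron) is internal
  gi <- gene_model("gi", "+", data.frame(start = c(100, 900),
                                         end = c(200, 1500)))
  modi <- data.frame(module_id = "m3", left_start = 400, right_end = 433)
  asni <- assign_module_to_gene(modi, gi)
  expect_equal(asni$side, "internal")

  # no genes -> unassigned (zero rows)
  expect_equal(nrow(assign_module_to_gene(mod, NULL)), 0)
})

test_that("a module between divergent genes reports both candidates, nearest first", {
  left_gene <- gene_model("gl", "-", c(100, 1000))    # reads leftward
  right_gene <- gene_model("gr", "+", c(2000, 2900))  # reads rightward
  genes <- rbind(left_gene, right_gene)
  mod <- data.frame(module_id = "m", left_start = 1200, right_end = 1233)
  asn <- assign_module_to_gene(mod, genes)
  expect_equal(nrow(asn), 2)
  expect_equal(asn$side, c("upstream", "upstream"))
  # gl start codon at 1000: distance 199; gr start codon 2000: distance 766
  expect_equal(asn$gene_id[asn$rank == 1], "gl")
  expect_equal(asn$distance_bp, c(199, 766))
})

test_that("UTR windows run 1000 bp 3' of the stop codon in gene orientation", {
  gp <- gene_model("gp", "+", c(1001, 2000))
  w <- utr_window(gp, 5000)
  expect_equal(c(w$start, w$end), c(2001, 3000))
  expect_equal(w$source, "stop+1000")
  expect_false(w$truncated)

  gm <- gene_model("gm", "-", c(2000, 3000))
  wm <- utr_window(gm, 5000)
  expect_equal(c(wm$start, wm$end), c(1000, 1999))
  expect_equal(wm$strand, "-")

  # truncation at the contig end
  gt <- gene_model("gt", "+", c(1001, 2000))
  wt <- utr_window(gt, 2200)
  expect_equal(c(wt$start, wt$end), c(2001, 2200))
  expect_true(wt$truncated)

  # transcript-defined UTR takes precedence
  wtr <- utr_window(gp, 5000, transcript_utr = list(start = 2001, end = 2350))
  expect_equal(c(wtr$start, wtr$end), c(2001, 2350))
  expect_equal(wtr$source, "transcript")
})

test_that("UTR sequence is reported in gene orientation", {
  contig <- paste0(strrep("A", 100), "GTCTTCC", strrep("A", 100))
  gp <- gene_model("gp", "+", c(1, 100))
  sp <- utr_seq(utr_window(gp, nchar(contig), utr_bp = 50), contig)
  expect_equal(substr(sp, 1, 7), "GTCTTCC")

  # on the minus strand the same genomic box reads reverse-complemented
  gm <- gene_model("gm", "-", c(108, 207))
  sm <- utr_seq(utr_window(gm, nchar(contig), utr_bp = 50), contig)
  expect_equal(substr(sm, 1, 7), revcomp("GTCTTCC"))
})

test_that("distances are invariant under contig reverse-complementation", {
  L <- 10000
  g <- gene_model("g", "+", c(5001, 5900))
  mod <- data.frame(module_id = "m", left_start = 4414, right_end = 4447)
  d1 <- assign_module_to_gene(mod, g)$distance_bp
  # flip everything
  gflip <- gene_model("g", "-", c(L - 5900 + 1, L - 5001 + 1))
  modflip <- data.frame(module_id = "m", left_start = L - 4447 + 1,
                        right_end = L - 4414 + 1)
  d2 <- assign_module_to_gene(modflip, gflip)$distance_bp
  expect_equal(d1, d2)
})
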