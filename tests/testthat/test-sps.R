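suh <- espl_motifs()$SuH
abox_pat <- espl_motifs()$Abox

# helper: a contig with an inverted Su(H) pair at a given spacer
pair_contig <- function(spacer, left = "TGTGAGAA", right = "CGTGGGAA",
                        pad = 20) {
  set.seed(spacer + 1000)
  paste0(random_dna(pad, gc = 0.2), left,
         random_dna(spacer, gc = 0.2), revcomp(right),
         random_dna(pad, gc = 0.2))
}

test_that("planted inverted pairs are found with the right spacer", {
  for (sp in c(17L, 15L, 7L)) {
    hits <- scan_pattern(pair_contig(sp), suh)
    pairs <- find_inverted_pairs(hits)
    expect_equal(nrow(pairs), 1, info = sp)
    expect_equal(pairs$spacer_bp, sp)
    expect_equal(pairs$canonical, sp == 17L)
    expect_equal(pairs$variant_label,
                 if (sp == 17L) NA_character_ else as.character(sp))
    expect_equal(pairs$orientation, "convergent")
    expect_equal(pairs$left_site, "TGTGAGAA")
    expect_equal(pairs$right_site, "CGTGGGAA")
  }
})

test_that("same-strand site pairs are never emitted", {
  contig <- paste0("CC", "TGTGAGAA", strrep("C", 17), "TGTGAGAA", "CC")
  hits <- scan_pattern(contig, suh)
  expect_equal(nrow(hits), 2)
  expect_equal(nrow(find_inverted_pairs(hits)), 0)
})

test_that("spacers outside the window are rejected", {
  hits <- scan_pattern(pair_contig(31L), suh)
  expect_equal(nrow(find_inverted_pairs(hits)), 0)
  expect_equal(nrow(find_inverted_pairs(hits, spacer_max = 40)), 1)
})

test_that("pair building matches a brute-force double loop with greedy dedup", {
  set.seed(23)
  for (rep in 1:20) {
    # synthesise a random hit table (up to 50 hits, 8 bp sites)
    n <- sample(2:50, 1)
    starts <- sort(sample.int(2000, n))
    hits <- data.frame(
      pattern = "SuH", seqid = "c",
      start = starts, end = starts + 7L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      matched_seq = "NNNNNNNN", site_seq = "NNNNNNNN",
      stringsAsFactors = FALSE)
    got <- find_inverted_pairs(hits)
    want <- brute_pairs(hits)
    expect_equal(got[, c("left_start", "right_start", "spacer_bp")],
                 want, ignore_attr = TRUE)
  }
})

test_that("pair building is symmetric under contig reverse-complementation", {
  set.seed(31)
  for (rep in 1:5) {
    contig <- paste0(pair_contig(17), random_dna(500, gc = 0.5),
                     pair_contig(15))
    fwd_pairs <- find_inverted_pairs(scan_pattern(contig, suh))
    rev_pairs <- find_inverted_pairs(scan_pattern(revcomp(contig), suh))
    expect_equal(nrow(fwd_pairs), nrow(rev_pairs))
    expect_setequal(fwd_pairs$spacer_bp, rev_pairs$spacer_bp)
    L <- nchar(contig)
    expect_setequal(L - fwd_pairs$right_end + 1L, rev_pairs$left_start)
  }
})

test_that("A boxes within range and inside the region define SPS+A", {
  # A-padding: C/T neighbours of the A box would create a legitimate
  # minus-strand shadow match (RCAGSTG's reverse complement is CASCTGY)
  mk <- function(abox_gap) {
    paste0(strrep("A", 10), "ACAGCTG", strrep("A", abox_gap),
           "TGTGAGAA", strrep("A", 17), revcomp("CGTGGGAA"),
           strrep("A", 10))
  }
  for (gap in c(10L, 232L)) {
    contig <- mk(gap)
    pairs <- find_inverted_pairs(scan_pattern(contig, suh))
    aboxes <- scan_pattern(contig, abox_pat)
    mod <- associate_aboxes(pairs, aboxes, max_dist = 500)
    expect_equal(mod$module_class, "SPS+A", info = gap)
    expect_equal(mod$n_aboxes, 1)
    expect_equal(mod$aboxes[[1]]$distance_bp, gap)
  }
  # beyond max_dist the module is a bare SPS
  contig <- mk(600L)
  pairs <- find_inverted_pairs(scan_pattern(contig, suh))
  aboxes <- scan_pattern(contig, abox_pat)
  mod <- associate_aboxes(pairs, aboxes, max_dist = 500)
  expect_equal(mod$module_class, "SPS")
  expect_equal(mod$n_aboxes, 0)
})

test_that("a pair outside the supplied region is rejected", {
  contig <- pair_contig(17)
  pairs <- find_inverted_pairs(scan_pattern(contig, suh))
  region <- data.frame(start = 1, end = 10)
  no_aboxes <- scan_pattern("AAAAAAA", abox_pat)  # empty hit table
  expect_error(associate_aboxes(pairs, no_aboxes, region = region),
               "outside")
})

test_that("Y positions follow gene orientation", {
  contig <- pair_contig(17, left = "TGTGAGAA", right = "CGTGGGAA")
  pairs <- find_inverted_pairs(scan_pattern(contig, suh))
  mod <- associate_aboxes(pairs, scan_pattern(contig, abox_pat))

  plus <- assign_y_positions(mod, "+")   # gene to the right: left site is upstream
  expect_equal(plus$y_upstream, "T")
  expect_equal(plus$y_downstream, "C")
  expect_true(plus$y_canonical)

  minus <- assign_y_positions(mod, "-")  # upstream/downstream swap
  expect_equal(minus$y_upstream, "C")
  expect_equal(minus$y_downstream, "T")
  expect_false(minus$y_canonical)

  una <- assign_y_positions(mod, NA)
  expect_true(is.na(una$y_upstream))
  expect_true(is.na(una$y_canonical))

  # the flagged class: C in the upstream Y position
  contig2 <- pair_contig(17, left = "CGTGAGAA", right = "CGTGGGAA")
  mod2 <- assign_y_positions(
    find_inverted_pairs(scan_pattern(contig2, suh)), "+")
  expect_equal(mod2$y_upstream, "C")
  expect_false(mod2$y_canonical)

  # both sites starting with T is not canonical either
  contig3 <- pair_contig(17, left = "TGTGAGAA", right = "TGTGGGAA")
  mod3 <- assign_y_positions(
    find_inverted_pairs(scan_pattern(contig3, suh)), "+")
  expect_false(mod3$y_canonical)
})
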