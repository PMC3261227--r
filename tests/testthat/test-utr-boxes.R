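test_that("UTR windows are scanned sense-strand only, with 0-based offsets", {
  p <- scan_utr("AAAGCTTTAAA")
  expect_equal(nrow(p$boxes), 1)
  expect_equal(p$boxes$box_type, "Brd")
  expect_equal(p$boxes$offset, 2)

  # ordering across box types
  p2 <- scan_utr(paste0("AA", "GTCTTCC", "AAAA", "TGTGAT", "AA"))
  expect_equal(p2$boxes$box_type, c("GY", "K"))
  expect_true(all(diff(p2$boxes$offset) > 0))

  # a window with no motifs yields an empty profile
  p3 <- scan_utr(strrep("A", 200))
  expect_equal(nrow(p3$boxes), 0)

  # an antisense box is not reported
  p4 <- scan_utr(paste0("AAA", revcomp("AGCTTTA"), "AAA"))
  expect_equal(nrow(p4$boxes), 0)
})

test_that("a profile equals the union of per-motif sense scans", {
  set.seed(13)
  for (rep in 1:10) {
    w <- random_dna(400, gc = runif(1, 0.3, 0.6))
    prof <- scan_utr(w)
    per <- do.call(rbind, lapply(utr_motifs(), function(p) {
      m <- naive_scan(w, p$iupac)
      m <- m[m$strand == "+", , drop = FALSE]
      if (nrow(m)) data.frame(box_type = p$name, offset = m$start - 1L)
    }))
    if (is.null(per)) per <- data.frame(box_type = character(),
                                        offset = integer())
    per <- per[order(per$offset, per$box_type), , drop = FALSE]
    expect_equal(prof$boxes[, c("box_type", "offset")], per,
                 ignore_attr = TRUE)
  }
})

test_that("organization comparison classifies identity, partial overlap and absence", {
  mk <- function(types) {
    boxes <- if (length(types)) {
      paste0(vapply(types, function(t) {
        c(Brd = "AGCTTTA", GY = "GTCTTCC", K = "TGTGAT")[[t]]
      }, character(1)), collapse = strrep("A", 10))
    } else ""
    scan_utr(paste0("AAAA", boxes, "AAAA"))
  }
  expect_equal(compare_organization(mk(c("Brd", "GY", "K")),
                                    mk(c("Brd", "GY", "K")))$conservation_class,
               "identical")
  expect_equal(compare_organization(mk(character(0)),
                                    mk(character(0)))$conservation_class,
               "identical-empty")
  cmp <- compare_organization(mk(c("Brd", "GY", "K", "K")),
                              mk(c("Brd", "K")))
  expect_equal(cmp$conservation_class, "partial")
  expect_equal(cmp$lcs_length, 2)
  expect_equal(compare_organization(mk("Brd"), mk("GY"))$conservation_class,
               "none")
  expect_equal(compare_organization(mk("K"),
                                    mk(character(0)))$conservation_class,
               "none")
})

test_that("LCS matching equals exhaustive subsequence enumeration", {
  types <- c("Brd", "GY", "K")
  set.seed(17)
  for (rep in 1:30) {
    x <- sample(types, sample(0:8, 1), replace = TRUE)
    y <- sample(types, sample(0:8, 1), replace = TRUE)
    got <- spsarch:::box_lcs(x, y)
    expect_equal(got$length, lcs_enum(x, y),
                 info = paste(paste(x, collapse = ""), "vs",
                              paste(y, collapse = "")))
    # the traceback is a genuine common subsequence
    if (nrow(got$pairs)) {
      expect_true(all(diff(got$pairs$i) > 0))
      expect_true(all(diff(got$pairs$j) > 0))
      expect_equal(x[got$pairs$i], y[got$pairs$j])
      expect_equal(nrow(got$pairs), got$length)
    }
  }
})

test_that("the conservation class is symmetric in its arguments", {
  types <- c("Brd", "GY", "K")
  set.seed(19)
  for (rep in 1:20) {
    mk <- function(ts) {
      prof <- scan_utr(strrep("A", 10))
      prof$boxes <- data.frame(box_type = ts,
                               offset = seq_along(ts) * 10L,
                               match = ts)
      prof
    }
    a <- mk(sample(types, sample(0:5, 1), replace = TRUE))
    b <- mk(sample(types, sample(0:5, 1), replace = TRUE))
    expect_equal(compare_organization(a, b)$conservation_class,
                 compare_organization(b, a)$conservation_class)
  }
})

test_that("truncated windows are flagged through to the comparison", {
  a <- scan_utr("AAAGCTTTAAA", truncated = TRUE)
  b <- scan_utr("AAAGCTTTAAA")
  cmp <- compare_organization(a, b)
  expect_true(cmp$truncated)
  expect_equal(cmp$conservation_class, "identical")
  expect_true(any(grepl("truncated", organization_diagram(cmp))))
})
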