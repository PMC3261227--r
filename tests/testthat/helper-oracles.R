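# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations (per-offset enumeration, double loops,
# textbook DP, exhaustive subsequence search) kept separate from the package
# code paths they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# complement without Biostrings
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "", fixed = TRUE)[[1L]]]),
        collapse = "")
}

# enumerate literal expansions of an IUPAC string without the package
oracle_expand <- function(iupac) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  out <- ""
  for (code in strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]) {
    out <- as.vector(outer(out, tab[[code]], paste0))
  }
  sort(out)
}

# test every offset on both strands against every literal expansion
naive_scan <- function(seq, iupac) {
  seq <- toupper(seq)
  m <- nchar(iupac)
  L <- nchar(seq)
  fwd <- oracle_expand(iupac)
  rev <- vapply(fwd, oracle_revcomp, character(1L), USE.NAMES = FALSE)
  out <- data.frame(start = integer(), end = integer(),
                    strand = character())
  if (L >= m) {
    starts <- seq_len(L - m + 1L)
    words <- substring(seq, starts, starts + m - 1L)
    fs <- starts[words %in% fwd]
    rs <- starts[words %in% rev]
    out <- rbind(
      data.frame(start = fs, end = fs + m - 1L,
                 strand = rep("+", length(fs))),
      data.frame(start = rs, end = rs + m - 1L,
                 strand = rep("-", length(rs))))
  }
  out[order(out$start, out$end, match(out$strand, c("+", "-"))), ,
      drop = FALSE]
}

# double loop over all hit pairs with the pairing constraints, then the
# greedy closest-to-17 deduplication, re-derived from scratch
brute_pairs <- function(hits, spacer_min = 0, spacer_max = 30,
                        canonical = 17) {
  n <- nrow(hits)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (hits$start[i] >= hits$start[j]) next  # i is the left site
      if (hits$strand[i] == hits$strand[j]) next
      if (hits$start[j] <= hits$end[i]) next
      sp <- hits$start[j] - hits$end[i] - 1L
      if (sp < spacer_min || sp > spacer_max) next
      cand[[length(cand) + 1L]] <- c(i = i, j = j, sp = sp)
    }
  }
  if (!length(cand)) {
    return(data.frame(left_start = integer(), right_start = integer(),
                      spacer_bp = integer()))
  }
  cand <- as.data.frame(do.call(rbind, cand))
  used <- rep(FALSE, n)
  keep <- rep(FALSE, nrow(cand))
  repeat {
    avail <- which(!keep & !used[cand$i] & !used[cand$j])
    if (!length(avail)) break
    score <- abs(cand$sp[avail] - canonical)
    best <- avail[order(score, cand$sp[avail], hits$start[cand$i[avail]],
                        hits$start[cand$j[avail]])][1L]
    keep[best] <- TRUE
    used[cand$i[best]] <- TRUE
    used[cand$j[best]] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(hits$start[out$i]), , drop = FALSE]
  data.frame(left_start = hits$start[out$i],
             right_start = hits$start[out$j],
             spacer_bp = out$sp)
}

# textbook three-state Gotoh DP, written against the alignment definition
# (gap run of length L costs open + ext * L), independent of Biostrings
gotoh_score <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # last column is a substitution
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (b consumed)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext,
                               Y[i, j + 1L] - open - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext,
                               X[i + 1L, j] - open - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# plain recursive enumeration of every global alignment (no memoisation);
# used at tiny lengths to validate gotoh_score itself
enum_align_score <- function(a, b, match = 1, mismatch = -1, open = 5,
                             ext = 1) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  rec <- function(i, j, prev) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(x)) {
      g <- ext + if (prev == "X") 0 else open
      best <- max(best, -g + rec(i + 1L, j, "X"))
    }
    if (j <= length(y)) {
      g <- ext + if (prev == "Y") 0 else open
      best <- max(best, -g + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# longest common subsequence length by exhaustive subsequence enumeration
lcs_enum <- function(x, y) {
  if (!length(x)) return(0L)
  is_subseq <- function(s, t) {
    j <- 1L
    for (el in t) {
      if (j <= length(s) && s[j] == el) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^length(x) - 1L)) {
    sub <- x[bitwAnd(mask, 2^(seq_along(x) - 1L)) > 0]
    if (length(sub) > best && is_subseq(sub, y)) best <- length(sub)
  }
  best
}

# run-length scan for identical alignment columns
naive_blocks <- function(al_a, al_b, k) {
  ca <- strsplit(al_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1L]]
  apos <- cumsum(ca != "-")
  res <- list()
  run <- integer(0)
  for (c in seq_along(ca)) {
    if (ca[c] == cb[c] && ca[c] != "-") {
      run <- c(run, c)
    } else {
      if (length(run) >= k) res[[length(res) + 1L]] <- run
      run <- integer(0)
    }
  }
  if (length(run) >= k) res[[length(res) + 1L]] <- run
  do.call(rbind, lapply(res, function(r) {
    data.frame(a_start = apos[r[1L]], a_end = apos[r[length(r)]],
               length = length(r))
  }))
}

# small convenience fixtures ------------------------------------------------

# one plus-strand gene with a single planted module and optional UTR boxes
simple_spec <- function(seed = 1, spacer = 17, upstream_distance = 100,
                        abox_offsets = c(-30L), y_upstream = "T",
                        y_downstream = "C", utr = NULL, length = 4000L,
                        clean_background = TRUE, gc = 0.4) {
  genes <- data.frame(gene_id = "g1", strand = "+", cds_start = 2000L,
                      cds_end = 2899L)
  plant_spec(length, genes,
             modules = module_spec("mod1", "g1", upstream_distance,
                                   spacer = spacer,
                                   y_upstream = y_upstream,
                                   y_downstream = y_downstream,
                                   abox_offsets = abox_offsets),
             utr_boxes = if (is.null(utr)) NULL else list(g1 = utr),
             gc = gc, clean_background = clean_background, seed = seed)
}

# random multi-module spec over two genes, used for recall sweeps
random_recall_spec <- function(seed) {
  set.seed(seed)
  genes <- data.frame(gene_id = c("gA", "gB"), strand = c("+", "-"),
                      cds_start = c(2500L, 6500L),
                      cds_end = c(3399L, 7399L))
  # A boxes are planted on the side of the module facing away from the
  # gene, on a 10 bp grid so footprints never collide
  mods <- rbind(
    module_spec("modA", "gA", sample(50:600, 1),
                spacer = sample(c(7L, 15L, 17L), 1),
                y_upstream = sample(c("C", "T"), 1),
                abox_offsets = if (runif(1) < 0.5) {
                  sample(seq(-400L, -10L, by = 10L), sample(1:2, 1))
                } else integer(0)),
    module_spec("modB", "gB", sample(50:600, 1),
                spacer = sample(c(7L, 15L, 17L), 1),
                abox_offsets = if (runif(1) < 0.5) {
                  sample(seq(10L, 400L, by = 10L), 1)
                } else integer(0))
  )
  utr <- list(gA = sample(c("Brd", "GY", "K"), sample(0:3, 1),
                          replace = TRUE))
  if (!length(utr$gA)) utr$gA <- NULL
  plant_spec(9000L, genes, modules = mods,
             utr_boxes = if (length(utr)) utr else NULL,
             gc = 0.4, clean_background = TRUE, seed = seed + 1000L)
}
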