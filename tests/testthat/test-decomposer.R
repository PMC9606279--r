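test_that("decomposition labels simple motif runs exactly", {
  d <- decompose_motifs("TGGAATGGAATAGAA", c("TGGAA", "TAGAA"))
  expect_equal(d$units$label, c("TGGAA", "TGGAA", "TAGAA"))
  expect_equal(d$other_bp, 0L)
  expect_equal(unname(d$composition), c(2L, 1L))

  d2 <- decompose_motifs(paste0(strrep("CAG", 4), "CAACAG", strrep("CCG", 2)),
                         c("CAG", "CAACAG", "CCG"))
  expect_equal(as.list(d2$composition), list(CAG = 4L, CAACAG = 1L, CCG = 2L))

  # one mismatched base inside a pentanucleotide unit, cost from the oracle
  d3 <- decompose_motifs("TGGAATGGTATGGAA", "TGGAA", max_mismatch_per_unit = 1)
  expect_equal(d3$units$label, rep("TGGAA", 3))
  expect_equal(sum(d3$units$mismatches), 1L)
  expect_equal(d3$cost, oracle_decompose_cost("TGGAATGGTATGGAA", "TGGAA"))
})

test_that("DP cost equals the exhaustive oracle on random short instances", {
  set.seed(77)
  motif_pairs <- list(c("TGGAA", "TAGAA"), c("CAG", "CAACAG"), c("AAGGG", "AAGG"))
  for (rep in 1:60) {
    motifs <- motif_pairs[[sample.int(3, 1)]]
    n <- sample(1:30, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    d <- decompose_motifs(s, motifs)
    expect_equal(d$cost, oracle_decompose_cost(s, motifs), info = s)
    # partition invariant: unit slices reconstruct the sequence exactly
    slices <- substring(s, d$units$start + 1, d$units$end)
    expect_equal(paste(slices, collapse = ""), s, info = s)
    # unit bp + OTHER bp accounts for every base
    unit_bp <- sum(nchar(d$units$label[d$units$label != "OTHER"]))
    expect_equal(unit_bp + d$other_bp, nchar(s), info = s)
  }
})

test_that("decomposition is reverse-complement symmetric in composition", {
  set.seed(12)
  motifs <- c("AAGGG", "AAGG")
  for (rep in 1:10) {
    comp <- c(sample(5:15, 1), sample(0:4, 1))
    s <- paste0(strrep("AAGGG", comp[1]), strrep("AAGG", comp[2]),
                paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = ""))
    d1 <- decompose_motifs(s, motifs)
    d2 <- decompose_motifs(revcomp(s), revcomp(motifs))
    expect_equal(unname(d1$composition), unname(d2$composition))
    expect_equal(d1$other_bp, d2$other_bp)
  }
})

test_that("tie-breaking prefers earlier-listed (pathogenic-first) motifs", {
  # TGGAA and TAGAA both fit with one mismatch against TGGTA; the
  # earlier-listed motif must win
  d <- decompose_motifs("TGGTA", c("TGGAA", "TAGAA"))
  expect_equal(d$units$label, "TGGAA")
  # trinucleotides get no mismatch tolerance
  d2 <- decompose_motifs("CAT", "CAG")
  expect_equal(d2$units$label, "OTHER")
})

test_that("consensus recovers the true tract from noisy reads", {
  truth <- strrep("CAG", 42)
  expect_equal(build_consensus(truth)$sequence, truth)
  set.seed(5)
  reads <- replicate(7, {
    x <- strsplit(truth, "")[[1]]
    i <- which(runif(length(x)) < 0.01)
    if (length(i)) x[i] <- sample(c("A", "C", "G", "T"), length(i), TRUE)
    paste(x, collapse = "")
  })
  cons <- build_consensus(reads)
  expect_equal(cons$sequence, truth)
  expect_equal(cons$n_reads_used, 7L)
  # 5 identical error-free copies
  cons2 <- build_consensus(rep(strrep("TGGAA", 10), 5))
  expect_equal(cons2$sequence, strrep("TGGAA", 10))
  # single read: returned unchanged
  one <- build_consensus("ACGTACGT", ids = "rX")
  expect_equal(one$sequence, "ACGTACGT")
  expect_equal(one$n_reads_used, 1L)
  expect_equal(one$medoid_read_id, "rX")
  expect_error(build_consensus(character(0)), class = "repscreen_validation_error")
})

test_that("waterfall rows group by allele length and sort by unit count", {
  reads <- c(replicate(5, strrep("GGC", 19)), replicate(5, strrep("GGC", 185)))
  w <- waterfall_matrix(reads, "GGC")
  expect_equal(sort(unique(w$reads$n_units)), c(19L, 185L))
  expect_equal(w$reads$n_units, sort(w$reads$n_units, decreasing = TRUE))
  expect_equal(ncol(w$matrix), 185L)
  expect_equal(nrow(waterfall_matrix(character(0), "GGC")$matrix), 0L)
  # minus-strand molecule sequences are reverse-complemented into repeat
  # orientation before decomposition
  plus <- strrep("AAGGG", 10)
  minus_mol <- revcomp(plus)
  w2 <- waterfall_matrix(c(plus, minus_mol), "AAGGG", strand = c("+", "-"))
  expect_equal(w2$reads$n_units, c(10L, 10L))
})

test_that("interruption calls report position relative to the pathogenic block", {
  cat_ <- default_catalog()
  htt <- catalog_locus(cat_, "HTT")
  d <- decompose_motifs(paste0(strrep("CAG", 42), "CAACAG"),
                        locus_motifs(htt))
  calls <- detect_interruptions(d, htt)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$motif, "CAACAG")
  expect_equal(calls$n_units, 1L)
  expect_equal(calls$position, "3prime")

  pure <- decompose_motifs(strrep("CAG", 42), locus_motifs(htt))
  expect_equal(nrow(detect_interruptions(pure, htt)), 0L)

  sca8 <- catalog_locus(cat_, "ATXN8OS")
  d8 <- decompose_motifs(paste0(strrep("CTA", 9), strrep("CTG", 86)),
                         locus_motifs(sca8))
  calls8 <- detect_interruptions(d8, sca8)
  expect_equal(calls8$motif, "CTA")
  expect_equal(calls8$n_units, 9L)
  expect_equal(calls8$position, "5prime")
})
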