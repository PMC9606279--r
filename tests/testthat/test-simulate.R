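test_that("mini genome has the expected contig structure and is seed-deterministic", {
  cat_ <- sub_catalog("CSTB")  # ref 3 units x 12 bp
  g1 <- build_mini_genome(cat_, flank_bp = 2000, seed = 5)
  expect_equal(unname(Biostrings::width(g1)), 2000L + 36L + 2000L)
  expect_equal(as.character(Biostrings::subseq(g1[["CSTB"]], 2001, 2036)),
               strrep("CCCCGCCCCGCG", 3))
  g2 <- build_mini_genome(cat_, flank_bp = 2000, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- build_mini_genome(cat_, flank_bp = 2000, seed = 6)
  expect_false(identical(as.character(g1), as.character(g3)))
  expect_error(build_mini_genome(cat_, flank_bp = 0),
               class = "repscreen_validation_error")
})

test_that("error-free reads carry the exact expansion as a tract-anchored insertion", {
  cat_ <- sub_catalog("RFC1")
  spec <- sim_spec(cat_, alleles = list(RFC1 = list(11, 622)), depth = 12,
                   flank_bp = 2000, read_len_mean = 8000,
                   sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 11)
  sim <- simulate_reads(spec)
  locus <- catalog_locus(sim$catalog, "RFC1")
  meas <- measure_reads(sim$sam, locus)
  sp <- merge(meas[meas$spans_tract, ], sim$truth, by = "read_id")
  expect_gt(nrow(sp), 0)
  # net insertion equals (units - 11) x 5 exactly, per allele
  expect_equal(sp$net_bp_change, ifelse(sp$allele_index == 1L, 611L * 5L, 0L))
  expect_equal(sp$copy_change, sp$true_copy_change)
  # strand invariance of the measurement on error-free molecules
  for (ai in 0:1) {
    cc <- split(sp$copy_change[sp$allele_index == ai], sp$strand.x[sp$allele_index == ai])
    if (length(cc) == 2L) expect_equal(unique(cc[["+"]]), unique(cc[["-"]]))
  }
})

test_that("simulation is deterministic per seed and conserves read counts", {
  cat_ <- sub_catalog(c("HTT", "CSTB"))
  spec <- sim_spec(cat_, depth = 6, flank_bp = 2000, read_len_mean = 6000, seed = 3)
  s1 <- simulate_reads(spec)
  s2 <- simulate_reads(spec)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$truth, s2$truth)
  # conservation: one SAM record and one truth record per FASTQ read
  expect_equal(nrow(s1$reads), nrow(s1$sam))
  expect_equal(sort(s1$reads$read_id), sort(s1$truth$read_id))
  f1 <- file.path(tempdir(), "a.fastq"); f2 <- file.path(tempdir(), "b.fastq")
  write_sim_fastq(s1, f1); write_sim_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("motif miscall corrupts whole units on the specified strand only", {
  cat_ <- sub_catalog("RFC1")
  spec <- sim_spec(cat_, alleles = list(RFC1 = list(622, 622)), depth = 14,
                   flank_bp = 2000, read_len_mean = 9000,
                   sub_rate = 0, ins_rate = 0, del_rate = 0,
                   motif_miscall = list(source = "AAGGG", corrupt = "AAGG",
                                        prob = 0.3, strand = "-"),
                   seed = 21)
  sim <- simulate_reads(spec)
  meas <- measure_reads(sim$sam, catalog_locus(sim$catalog, "RFC1"))
  sp <- meas[meas$spans_tract & !is.na(meas$tract_sequence), ]
  counts <- vapply(seq_len(nrow(sp)), function(i) {
    d <- decompose_motifs(sp$tract_sequence[i], c("AAGGG", "AAGG"))
    d$composition[["AAGG"]]
  }, integer(1))
  expect_true(all(counts[sp$strand == "+"] == 0L))
  expect_true(all(counts[sp$strand == "-"] > 0L))
  # ~30% of 622 units corrupted
  expect_gt(mean(counts[sp$strand == "-"]), 0.15 * 622)
  expect_lt(mean(counts[sp$strand == "-"]), 0.45 * 622)
})

test_that("realized read lengths track the lognormal mean", {
  cat_ <- sub_catalog("RFC1")
  spec <- sim_spec(cat_, depth = 35, flank_bp = 20000, read_len_mean = 3000,
                   read_len_min = 500, seed = 9)
  sim <- simulate_reads(spec)
  expect_gte(nrow(sim$reads), 200)
  expect_lt(abs(mean(nchar(sim$reads$seq)) - 3000) / 3000, 0.1)
})

test_that("simulated controls stay within the jitter band", {
  cat_ <- default_catalog()
  ctl <- simulate_controls(cat_, n = 27, jitter_units = 3, seed = 4)
  expect_equal(nrow(ctl), 27L * 2L * 13L)
  per_locus <- table(ctl$locus_id)
  expect_true(all(per_locus == 54L))  # 54 alleles per locus from 27 controls
  expect_true(all(abs(ctl$copy_change) <= 3L))
  expect_true(all(ctl$allele_units >= 0L))
  ctl0 <- simulate_controls(cat_, n = 5, jitter_units = 0, seed = 4)
  expect_true(all(ctl0$copy_change == 0L))
  expect_error(simulate_controls(cat_, n = 0), class = "repscreen_validation_error")
  expect_identical(simulate_controls(cat_, 27, 3, seed = 4), ctl)
})

test_that("simulated methylation probabilities follow per-allele profiles", {
  cat_ <- sub_catalog("NOTCH2NLC")  # GGC repeats carry CpGs
  spec <- sim_spec(cat_, alleles = list(NOTCH2NLC = list(26, 510)), depth = 10,
                   flank_bp = 2000, read_len_mean = 8000,
                   sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 8)
  sim <- simulate_reads(spec)
  meth <- simulate_methylation(sim$reads, sim$truth, c(0.05, 0.9), seed = 8)
  by_allele <- split(meth$prob,
                     sim$truth$allele_index[match(meth$read_id, sim$truth$read_id)])
  expect_gte(length(by_allele[["0"]]), 50)
  expect_gte(length(by_allele[["1"]]), 50)
  expect_lt(abs(mean(by_allele[["0"]]) - 0.05), 0.1)
  expect_lt(abs(mean(by_allele[["1"]]) - 0.9), 0.1)
  # fully unmethylated profile never emits a probability above 0.2
  meth0 <- simulate_methylation(sim$reads, sim$truth, c(0, 0), seed = 9)
  expect_true(all(meth0$prob <= 0.2))
  # sequences without CpG yield an empty table
  no_cpg <- data.frame(read_id = "r1", locus_id = "NOTCH2NLC", seq = "ATATATAT")
  truth1 <- data.frame(read_id = "r1", allele_index = 0L)
  expect_equal(nrow(simulate_methylation(no_cpg, truth1, c(0.5, 0.5), seed = 1)), 0L)
})
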