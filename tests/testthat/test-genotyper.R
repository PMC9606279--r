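test_that("copy-change measurement handles deletions, clipping and skips", {
  locus <- toy_locus()  # CAG x21 at ctg:2000-2063
  # 15-bp deletion fully inside the tract: net -15, copy change -5
  del <- aln_record(pos = 1801L, cigar = "220M15D245M", seq = strrep("A", 465))
  m <- measure_read_copy_change(del, locus)
  expect_equal(m$net_bp_change, -15L)
  expect_equal(m$copy_change, -5L)
  expect_true(m$spans_tract)
  # read clipped into the tract is measured but does not span
  clip <- aln_record(pos = 2021L, cigar = "100S300M", seq = strrep("A", 400))
  m2 <- measure_read_copy_change(clip, locus)
  expect_false(m2$spans_tract)
  # insertion anchored within one motif of the boundary counts; beyond it, not
  ins_near <- aln_record(pos = 1801L, cigar = "261M30I202M", seq = strrep("A", 493))
  expect_equal(measure_read_copy_change(ins_near, locus)$copy_change, 10L)
  ins_far <- aln_record(pos = 1801L, cigar = "100M30I363M", seq = strrep("A", 493))
  expect_equal(measure_read_copy_change(ins_far, locus)$copy_change, 0L)
  # unmapped and secondary records are skipped, wrong contig is an error
  expect_null(suppressMessages(
    measure_read_copy_change(aln_record(flag = 4L), locus)))
  expect_null(suppressMessages(
    measure_read_copy_change(aln_record(flag = 256L), locus)))
  expect_error(measure_read_copy_change(aln_record(chrom = "other"), locus),
               class = "repscreen_data_error")
})

test_that("two-allele genotyping matches the exhaustive-partition oracle", {
  locus <- toy_locus(ref_units = 11L, motif = "AAGGG", end = 2055L)
  mk <- function(cc) data.frame(read_id = paste0("r", seq_along(cc)),
                                locus_id = "L1", strand = "+",
                                net_bp_change = cc * 5L, copy_change = cc,
                                spans_tract = TRUE, map_qual = 60L,
                                tract_sequence = NA_character_,
                                stringsAsFactors = FALSE)
  g <- genotype_locus(mk(c(0L, 0L, 1L, 160L, 158L, 161L)), locus)
  expect_equal(g$status, "ok")
  expect_false(g$homozygous)
  expect_equal(g$allele_copy_change, c(0L, 160L))
  expect_equal(g$allele_units, c(11L, 171L))
  expect_equal(lengths(g$supporting_reads), c(3L, 3L))
  # the chosen split has the same WSS as the exhaustive 2^n partition oracle
  or <- oracle_two_cluster(c(0, 0, 1, 160, 158, 161))
  expect_equal(sort(or$left), c(0, 0, 1))

  hom <- genotype_locus(mk(c(610L, 611L, 611L, 612L)), locus)
  expect_true(hom$homozygous)
  expect_equal(hom$allele_copy_change, c(611L, 611L))

  expect_equal(genotype_locus(mk(c(0L, 5L)), locus)$status, "undetermined")
  # a heterozygous split with a thin minor cluster cannot be trusted
  thin <- genotype_locus(mk(c(0L, 0L, 0L, 0L, 200L, 201L)), locus)
  expect_equal(thin$status, "undetermined")
  expect_equal(thin$reason, "allele-support")
  expect_error(genotype_locus(rbind(mk(1L),
                                    transform(mk(2L), locus_id = "L2")), locus),
               class = "repscreen_data_error")
})

test_that("random two-cluster instances agree with the brute-force oracle", {
  locus <- toy_locus(ref_units = 1L, motif = "CAG", end = 2003L)
  set.seed(404)
  for (rep in 1:20) {
    a <- sample(0:30, 1); b <- a + sample(10:300, 1)
    n1 <- sample(c(3L, 5L), 1); n2 <- sample(c(3L, 5L), 1)  # odd: integral medians
    cc <- c(a + sample(-1:1, n1, TRUE), b + sample(-1:1, n2, TRUE))
    m <- data.frame(read_id = paste0("r", seq_along(cc)), locus_id = "L1",
                    strand = "+", net_bp_change = cc * 3L, copy_change = cc,
                    spans_tract = TRUE, map_qual = 60L,
                    tract_sequence = NA_character_, stringsAsFactors = FALSE)
    g <- genotype_locus(m, locus)
    or <- oracle_two_cluster(cc)
    expect_equal(g$allele_copy_change,
                 c(round(median(or$left)), round(median(or$right))))
  }
})

test_that("error-free heterozygous simulations are recovered exactly", {
  cat_ <- sub_catalog(c("HTT", "BEAN1"))
  spec <- sim_spec(cat_, alleles = list(HTT = list(18, 42),
                                        BEAN1 = list(c(TAAAA = 13L), c(TGGAA = 373L))),
                   depth = 14, flank_bp = 2000, read_len_mean = 8000,
                   sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 35)
  sim <- simulate_reads(spec)
  meas <- measure_catalog(sim$sam, sim$catalog)
  for (lid in c("HTT", "BEAN1")) {
    g <- genotype_locus(meas[meas$locus_id == lid, ], catalog_locus(sim$catalog, lid))
    expect_equal(g$status, "ok")
  }
  expect_equal(genotype_locus(meas[meas$locus_id == "HTT", ],
                              catalog_locus(sim$catalog, "HTT"))$allele_units,
               c(18L, 42L))
  expect_equal(genotype_locus(meas[meas$locus_id == "BEAN1", ],
                              catalog_locus(sim$catalog, "BEAN1"))$allele_copy_change,
               c(0L, 360L))  # 373x5 bp tract vs 13 reference units
})

test_that("unit-count arithmetic from tract lengths", {
  expect_equal(units_from_length(2756, 5), 551L)
  expect_equal(units_from_length(2915, 5), 583L)
  expect_equal(units_from_length(0, 5), 0L)
  expect_error(units_from_length(10, 0), class = "repscreen_validation_error")
})

test_that("histogram table conserves spanning counts per strand", {
  m <- data.frame(read_id = paste0("r", 1:6), locus_id = "L1",
                  strand = c("+", "-", "+", "+", "-", "+"),
                  net_bp_change = 0L, copy_change = c(0L, 0L, 1L, 160L, 158L, 161L),
                  spans_tract = c(rep(TRUE, 5), FALSE), map_qual = 60L,
                  tract_sequence = NA_character_, stringsAsFactors = FALSE)
  h <- histogram_table(m)
  expect_equal(sum(h$count), 5L)
  h2 <- histogram_table(transform(m, copy_change = 7L))
  expect_equal(nrow(h2), 2L)  # one x-value, two strand colors
  expect_equal(nrow(histogram_table(m[0, ])), 0L)
})

test_that("a SAM file round-trips through Rsamtools to identical measurements", {
  cat_ <- sub_catalog("HTT")
  spec <- sim_spec(cat_, alleles = list(HTT = list(18, 42)), depth = 6,
                   flank_bp = 2000, read_len_mean = 6000, seed = 12)
  sim <- simulate_reads(spec)
  sam <- file.path(tempdir(), "rt.sam")
  write_sim_sam(sim, sam)
  aln <- read_alignments(sam)
  locus <- catalog_locus(sim$catalog, "HTT")
  m_file <- measure_reads(aln, locus)
  m_mem <- measure_reads(sim$sam, locus)
  m_file <- m_file[order(m_file$read_id), ]
  m_mem <- m_mem[order(m_mem$read_id), ]
  rownames(m_file) <- rownames(m_mem) <- NULL
  expect_equal(m_file, m_mem)
})
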