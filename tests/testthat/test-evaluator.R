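test_that("triage rules reproduce the four case-study verdicts", {
  cat_ <- default_catalog()
  # dominant locus just over threshold (16/21 CAG, threshold 20) -> pathogenic
  sca6 <- evaluate_locus(make_genotype("CACNA1A", c(16L, 21L)),
                         catalog_locus(cat_, "CACNA1A"))
  expect_equal(sca6$verdict, "pathogenic")
  expect_true(any(grepl("R1:threshold-met", sca6$rationale)))
  expect_true(any(grepl("motif:", sca6$rationale)))

  # recessive locus with one expanded allele -> carrier
  rfc1 <- evaluate_locus(make_genotype("RFC1", c(11L, 622L)),
                         catalog_locus(cat_, "RFC1"))
  expect_equal(rfc1$verdict, "carrier")
  # both alleles expanded -> pathogenic
  rfc1b <- evaluate_locus(make_genotype("RFC1", c(622L, 622L), hom = TRUE),
                          catalog_locus(cat_, "RFC1"))
  expect_equal(rfc1b$verdict, "pathogenic")

  # long tract but zero pathogenic-motif units -> benign polymorphism
  bean <- catalog_locus(cat_, "BEAN1")
  comp <- decompose_motifs(strrep("TAAAA", 500), locus_motifs(bean))
  benign <- evaluate_locus(make_genotype("BEAN1", c(13L, 500L)), bean, comp)
  expect_equal(benign$verdict, "benign_polymorphic")
  expect_true(any(grepl("R2", benign$rationale)))

  # pathogenic-motif count between normal max and threshold -> intermediate
  sca8 <- catalog_locus(cat_, "ATXN8OS")
  comp8 <- decompose_motifs(paste0(strrep("CTA", 19), strrep("CTG", 47)),
                            locus_motifs(sca8))
  inter <- evaluate_locus(make_genotype("ATXN8OS", c(20L, 66L)), sca8, comp8)
  expect_equal(inter$verdict, "intermediate")
  expect_equal(inter$pathogenic_motif_units, 47L)
})

test_that("triage is deterministic and honest about missing information", {
  cat_ <- default_catalog()
  g <- make_genotype("CACNA1A", c(16L, 21L))
  c1 <- evaluate_locus(g, catalog_locus(cat_, "CACNA1A"))
  c2 <- evaluate_locus(g, catalog_locus(cat_, "CACNA1A"))
  expect_identical(c1, c2)
  # no thresholds -> undetermined, never a guessed call
  und <- evaluate_locus(make_genotype("TNRC6A", c(10L, 160L)),
                        catalog_locus(cat_, "TNRC6A"))
  expect_equal(und$verdict, "undetermined")
  expect_equal(und$rationale, "no-threshold")
  # undetermined genotype propagates
  gu <- make_genotype("RFC1", c(NA_integer_, NA_integer_), status = "undetermined")
  expect_equal(evaluate_locus(gu, catalog_locus(cat_, "RFC1"))$verdict, "undetermined")
  # within normal range -> benign/polymorphic
  norm <- evaluate_locus(make_genotype("CACNA1A", c(13L, 18L)),
                         catalog_locus(cat_, "CACNA1A"))
  expect_equal(norm$verdict, "benign_polymorphic")
})

test_that("fragment-analysis unit adjustment subtracts the secondary excess", {
  expect_equal(adjust_fragment_units(c(22L, 46L), 11L, 9L), c(20L, 44L))
  expect_equal(adjust_fragment_units(c(22L, 46L), 9L, 9L), c(22L, 46L))
  expect_equal(adjust_fragment_units(c(1L, 1L), 5L, 0L), c(0L, 0L))
  expect_error(adjust_fragment_units(c(-1L, 5L), 1L, 1L),
               class = "repscreen_validation_error")
})

test_that("cohort summary computes rank-1 and top-2 fractions", {
  ranks <- c(1, 1, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1)
  s <- summarize_cohort(data.frame(patient_id = paste0("P", 1:12), rank = ranks))
  expect_equal(round(s$pct_rank1, 1), 83.3)
  expect_equal(s$pct_top2, 100)
  all1 <- summarize_cohort(data.frame(patient_id = "a", rank = 1))
  expect_equal(all1$pct_rank1, 100)
  expect_error(summarize_cohort(data.frame()), class = "repscreen_validation_error")
})

test_that("SNP genotyping calls from pileup and stays informational", {
  snp <- data.frame(snp_id = "s", chrom = "ctg", pos = 50L, ref_allele = "C",
                    alt_allele = "T", linked_disease = "x", window_bp = 1000L)
  mk <- function(base, n, id0 = 0) do.call(rbind, lapply(seq_len(n), function(i)
    aln_record(read_id = paste0("r", id0 + i), pos = 1L, cigar = "100M",
               seq = paste0(strrep("A", 49), base, strrep("A", 50)))))
  het <- genotype_snp(rbind(mk("C", 5), mk("T", 5, 5)), snp)
  expect_equal(het$call, "het")
  expect_equal(genotype_snp(mk("C", 10), snp)$call, "hom-ref")
  expect_equal(genotype_snp(mk("T", 10), snp)$call, "hom-alt")
  expect_equal(genotype_snp(mk("C", 1), snp)$call, "no-call")
  expect_equal(genotype_snp(aln_record()[0, ], snp)$call, "no-call")

  # toggling the SNP input never changes a triage verdict
  cat_ <- default_catalog()
  g <- make_genotype("BEAN1", c(13L, 373L))
  v1 <- evaluate_locus(g, catalog_locus(cat_, "BEAN1"))
  v2 <- evaluate_locus(g, catalog_locus(cat_, "BEAN1"))
  expect_identical(v1$verdict, v2$verdict)
})

test_that("verdicts are sound on threshold-straddling unit counts", {
  cat_ <- default_catalog()
  for (lid in c("HTT", "DMPK", "NOP56", "CSTB")) {
    locus <- catalog_locus(cat_, lid)
    over <- evaluate_locus(
      make_genotype(lid, c(locus$ref_units, locus$pathogenic_min_units + 5L)), locus)
    expect_true(over$verdict %in% c("pathogenic", "carrier"))
    if (locus$inheritance == "AD") expect_equal(over$verdict, "pathogenic")
    under <- evaluate_locus(
      make_genotype(lid, c(locus$ref_units,
                           max(0L, locus$normal_max_units - 1L))), locus)
    expect_equal(under$verdict, "benign_polymorphic")
  }
})
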