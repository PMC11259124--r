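# Genotype QC, rarity, CNV exon-span, the P/LP rule, and carrier collapsing.

test_that("genotype QC thresholds are inclusive and het-specific", {
  expect_true(genotype_qc(20, 80, "het")$pass)            # AD 20, VAF 0.25
  expect_false(genotype_qc(19, 38, "het")$pass)
  expect_match(genotype_qc(19, 38, "het")$reason, "depth")
  expect_true(genotype_qc(30, 31, "hom")$pass)            # VAF rule hets only
  expect_false(genotype_qc(20, 85, "het")$pass)           # VAF 0.235
  expect_match(genotype_qc(20, 85, "het")$reason, "VAF")
  expect_equal(genotype_qc(0, 0, "het")$reason, "no coverage")
  expect_error(genotype_qc(30, 20, "het"), "allele_depth")
})

test_that("rarity filter is strict at 0.1% and treats missing MAF as zero", {
  expect_true(rarity_filter(0.0005))
  expect_false(rarity_filter(0.001))
  expect_true(rarity_filter(NA))
  expect_identical(rarity_filter(c(0, 0.00099, 0.001, 0.5)),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("CNV flagging requires three consecutive overlapped exons", {
  tx <- transcript_model("T5", "chr1", "+",
                         data.frame(start = c(101, 201, 301, 401, 501),
                                    end = c(130, 230, 330, 430, 530)),
                         111, 519, check_cds = FALSE,
                         sequence = paste(rep("A", 150), collapse = ""))
  expect_true(cnv_exon_span_filter(201, 430, tx))         # exons 2-4
  expect_false(cnv_exon_span_filter(201, 330, tx))        # exons 2-3 only
  expect_true(cnv_exon_span_filter(225, 405, tx))         # clipped 2-4 still 3
  expect_false(cnv_exon_span_filter(231, 300, tx))        # intron only

  # brute-force consecutive-run oracle over random CNV intervals
  set.seed(5)
  for (i in 1:200) {
    s <- sample(80:540, 1); e <- s + sample(0:400, 1)
    hit <- tx$exons$start <= e & tx$exons$end >= s
    runs <- 0L; best <- 0L
    for (h in hit) { runs <- if (h) runs + 1L else 0L; best <- max(best, runs) }
    expect_equal(cnv_exon_span_filter(s, e, tx), best >= 3,
                 info = paste(s, e))
  }
})

test_that("the minimal P/LP rule follows PTV status and prior evidence", {
  expect_equal(classify_acmg_lite(TRUE, FALSE, NA), "likely_pathogenic")
  expect_equal(classify_acmg_lite(TRUE, TRUE, NA), "pathogenic")
  expect_equal(classify_acmg_lite(TRUE, FALSE, "VCV000488984.18"), "pathogenic")
  expect_equal(classify_acmg_lite(FALSE, TRUE, "VCV1"), "not_reportable")
  expect_equal(classify_acmg_lite(c(TRUE, TRUE, FALSE),
                                  c(FALSE, TRUE, TRUE),
                                  c(NA, NA, NA)),
               c("likely_pathogenic", "pathogenic", "not_reportable"))
})

test_that("collapsing counts each sample once and respects QC", {
  g <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                  variant_id = c("v1", "v2", "v1", "v3"),
                  zygosity = "het", stringsAsFactors = FALSE)
  cc <- collapse_carriers(g, qualifying = c("v1", "v2"),
                          samples = c("s1", "s2", "s3", "s4"))
  expect_equal(cc$carrier, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cc$n_qualifying[1], 2L)    # two qualifying variants, one carrier

  expect_warning(collapse_carriers(
    data.frame(sample_id = "s9", variant_id = "v1", zygosity = "hom"),
    qualifying = "v1"), "homozygous")
})

test_that("QC-failed genotypes never make a carrier", {
  man <- data.frame(sample_id = c("s1", "s2"), stringsAsFactors = FALSE)
  g <- data.frame(sample_id = c("s1", "s2"),
                  variant_id = c("v1", "v1"),
                  zygosity = "het",
                  allele_depth = c(10L, 30L), total_depth = c(60L, 60L),
                  stringsAsFactors = FALSE)
  ann <- data.frame(variant_id = "v1", maf = 0, clinvar_id = NA,
                    previously_reported = FALSE, stringsAsFactors = FALSE)
  cons <- data.frame(variant_id = "v1", is_ptv = TRUE, stringsAsFactors = FALSE)
  out <- call_carriers(g, ann, cons, man)
  expect_equal(out$carrier[out$sample_id == "s1"], FALSE)
  expect_equal(out$carrier[out$sample_id == "s2"], TRUE)
})

test_that("filter composition is order-invariant", {
  cfg <- simulation_config(seed = 5, n_cases = 150, n_controls = 300,
                          carrier_freq_case = 0.2, carrier_freq_control = 0.05,
                          qc_fail_rate = 0.2, common_variant_rate = 0.3,
                          decoy_rate = 0.2)
  coh <- simulate_cohort(cfg)
  # reference: full pipeline (QC -> rarity -> classification -> collapse)
  ref <- call_carriers(coh$genotypes, coh$annotations, coh$consequences,
                       coh$manifest)
  # alternative order: classification and rarity first, QC last
  cls <- classify_acmg_lite(coh$consequences$is_ptv,
                            coh$annotations$previously_reported[
                              match(coh$consequences$variant_id,
                                    coh$annotations$variant_id)],
                            coh$annotations$clinvar_id[
                              match(coh$consequences$variant_id,
                                    coh$annotations$variant_id)])
  plp <- coh$consequences$variant_id[cls != "not_reportable"]
  rare <- coh$annotations$variant_id[rarity_filter(coh$annotations$maf)]
  g <- coh$genotypes[coh$genotypes$variant_id %in% intersect(plp, rare), ]
  qc <- genotype_qc(g$allele_depth, g$total_depth, g$zygosity)
  alt <- collapse_carriers(g[qc$pass, ], intersect(plp, rare),
                           samples = coh$manifest$sample_id)
  expect_identical(ref$carrier[match(alt$sample_id, ref$sample_id)],
                   alt$carrier)
})

test_that("carrier count never exceeds sample count and drops monotonically", {
  cfg <- simulation_config(seed = 6, n_cases = 120, n_controls = 80,
                          carrier_freq_case = 0.3, carrier_freq_control = 0.1)
  coh <- simulate_cohort(cfg)
  man <- call_carriers(coh$genotypes, coh$annotations, coh$consequences,
                       coh$manifest)
  expect_lte(sum(man$carrier), nrow(man))
  # removing any individual never increases the carrier count
  drop <- sample(man$sample_id, 10)
  man2 <- call_carriers(coh$genotypes, coh$annotations, coh$consequences,
                        coh$manifest[!coh$manifest$sample_id %in% drop, ])
  expect_lte(sum(man2$carrier), sum(man$carrier))
})

test_that("related individuals flagged in the manifest are excluded", {
  man <- data.frame(sample_id = c("s1", "s2"),
                    exclude_related = c(FALSE, TRUE), stringsAsFactors = FALSE)
  g <- data.frame(sample_id = c("s1", "s2"), variant_id = "v1",
                  zygosity = "het", allele_depth = 30L, total_depth = 60L,
                  stringsAsFactors = FALSE)
  ann <- data.frame(variant_id = "v1", maf = 0, clinvar_id = NA,
                    previously_reported = FALSE, stringsAsFactors = FALSE)
  cons <- data.frame(variant_id = "v1", is_ptv = TRUE, stringsAsFactors = FALSE)
  out <- call_carriers(g, ann, cons, man)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sample_id, "s1")
})
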