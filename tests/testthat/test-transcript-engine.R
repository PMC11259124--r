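# Transcript coordinate projection, edit application, and consequence
# classification, checked against independent brute-force oracles.

toy_tx <- function() {
  transcript_model("TOY1", "chr1", "+", data.frame(start = 101, end = 109),
                   101, 109, sequence = "ATGAAATAG")
}

toy_tx_intron <- function() {
  # exon1 101..109 (c.1-9), intron 110..209, exon2 210..215
  transcript_model("TOY2", "chr1", "+",
                   data.frame(start = c(101, 210), end = c(109, 215)),
                   101, 215, sequence = "ATGAAACCCTGATAA")
}

test_that("coding-coordinate projection handles CDS, introns, UTRs and outside", {
  tx <- toy_tx()
  expect_equal(project_to_cds(tx, 104)$label, "4")
  expect_equal(project_to_cds(tx, 104)$cds_pos, 4L)

  tx2 <- toy_tx_intron()
  d <- project_to_cds(tx2, 111)
  expect_equal(d$label, "9+2")
  expect_equal(d$kind, "intron")
  expect_equal(project_to_cds(tx2, 208)$label, "10-2")

  # outside the transcript span is a descriptor, not an error
  expect_equal(project_to_cds(tx2, 50)$kind, "outside")
  expect_equal(project_to_cds(tx2, variant_record("chr1", 50, "A", "T"))$kind,
               "outside")
})

test_that("projection agrees with an exhaustive position-mapping oracle", {
  set.seed(101)
  for (strand in c("+", "-")) {
    for (seed in c(3, 4)) {
      tx <- simulate_transcript(seed = seed, n_exons = 4,
                                exon_len = c(60, 120), intron_len = c(20, 60),
                                strand = strand)
      gp <- oracle_tx_positions(tx)
      cds_lo <- match(if (strand == "+") tx$cds_start else tx$cds_end, gp)
      cds_hi <- match(if (strand == "+") tx$cds_end else tx$cds_start, gp)
      idx <- seq_along(gp)
      expected <- ifelse(idx < cds_lo, paste0("-", cds_lo - idx),
                         ifelse(idx > cds_hi, paste0("*", idx - cds_hi),
                                as.character(idx - cds_lo + 1L)))
      got <- vapply(gp, function(g) project_to_cds(tx, g)$label, character(1))
      expect_identical(got, expected)
    }
  }
})

test_that("edit application and translation match direct string surgery", {
  tx <- toy_tx()
  expect_equal(apply_and_translate(tx, variant_record("chr1", 104, "A", "T"))$peptide,
               "M*")

  # 1-bp deletion in codon 2: frameshifted peptide equals independent
  # re-translation of the edited string
  tx3 <- transcript_model("TOY3", "chr1", "+",
                          data.frame(start = 101, end = 112), 101, 112,
                          sequence = "ATGAAAGGGTAG")
  v <- variant_record("chr1", 103, "GA", "G")   # deletes the A at c.4
  got <- apply_and_translate(tx3, v)
  edited <- paste0(substr("ATGAAAGGGTAG", 1, 3), substr("ATGAAAGGGTAG", 5, 12))
  expect_equal(got$peptide, oracle_translate(edited))
  expect_equal(got$cds, substr(edited, 1, 11))

  # identity edits are rejected at the variant-record level
  expect_error(variant_record("chr1", 101, "ATG", "ATG"), "differ")
})

test_that("classification follows the stop/frameshift/splice rules", {
  tx4 <- transcript_model("TOY4", "chr1", "+",
                          data.frame(start = 101, end = 112), 101, 112,
                          sequence = "ATGAAACCCTAG")
  expect_true(classify_consequence(tx4, variant_record("chr1", 104, "A", "T"))$is_ptv)
  expect_equal(classify_consequence(tx4, variant_record("chr1", 104, "A", "T"))$consequence,
               "stop_gain")

  del2 <- suppressWarnings(classify_consequence(tx4, variant_record("chr1", 103, "GAA", "G")))
  expect_equal(del2$consequence, "frameshift")
  expect_true(del2$is_ptv)

  del3 <- classify_consequence(tx4, variant_record("chr1", 103, "GAAA", "G"))
  expect_equal(del3$consequence, "inframe_indel")
  expect_false(del3$is_ptv)

  tx2 <- toy_tx_intron()
  # canonical donor +2 vs deep intronic
  expect_equal(classify_consequence(tx2, variant_record("chr1", 111, "T", "G"))$consequence,
               "canonical_splice")
  expect_equal(classify_consequence(tx2, variant_record("chr1", 150, "A", "G"))$consequence,
               "intronic")
  expect_false(classify_consequence(tx2, variant_record("chr1", 150, "A", "G"))$is_ptv)
  # acceptor -1
  acc <- classify_consequence(tx2, variant_record("chr1", 209, "G", "A"))
  expect_equal(acc$consequence, "canonical_splice")
  expect_equal(acc$hgvs_p, "p.?")
})

test_that("consequence classes agree with the edit-and-translate oracle on random variants", {
  set.seed(2024)
  for (strand in c("+", "-")) {
    tx <- simulate_transcript(seed = 8, n_exons = 5, strand = strand)
    for (i in 1:150) {
      v <- random_edit(tx)
      cl <- classify_consequence(tx, v, name = FALSE)
      expect_equal(cl$is_ptv, oracle_is_ptv(tx, v),
                   info = sprintf("%s strand %s", v$id, strand))
      f <- oracle_facts(tx, v)
      if (cl$consequence == "frameshift")
        expect_true(f$cds_overlap && f$net %% 3 != 0, info = v$id)
      if (cl$consequence == "stop_gain")
        expect_true(f$premature_stop, info = v$id)
    }
  }
})

test_that("mirrored transcripts give identical classes for mirrored variants", {
  txp <- simulate_transcript(seed = 21, n_exons = 4, strand = "+")
  txm <- simulate_transcript(seed = 21, n_exons = 4, strand = "-")
  L <- nchar(txp$contig_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(55)
  span <- min(txp$exons$start):max(txp$exons$end)
  for (i in 1:80) {
    g <- sample(span, 1)
    ref <- substr(txp$contig_seq, g, g)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cp <- classify_consequence(txp, variant_record("chrSim", g, ref, alt),
                               name = FALSE)
    cm <- classify_consequence(txm, variant_record("chrSim", L - g + 1L,
                                                   comp[[ref]], comp[[alt]]),
                               name = FALSE)
    expect_equal(cp$consequence, cm$consequence, info = paste("pos", g))
  }
})

test_that("in-frame indels fully inside the CDS are never frameshift", {
  tx <- simulate_transcript(seed = 13, n_exons = 3)
  gp <- oracle_tx_positions(tx)
  cds_g <- gp[(tx$cds_lo + 3L):(tx$cds_hi - 6L)]
  set.seed(77)
  for (i in 1:60) {
    g <- sample(cds_g, 1)
    len <- sample(c(3L, 6L), 1)
    ex <- which(tx$exons$start <= g & g <= tx$exons$end)
    if (g + len - 1L > tx$exons$end[ex] || !(g - 1L) %in% gp) next
    v <- variant_record(tx$contig, g - 1L,
                        substr(tx$contig_seq, g - 1L, g + len - 1L),
                        substr(tx$contig_seq, g - 1L, g - 1L))
    expect_false(classify_consequence(tx, v, name = FALSE)$consequence ==
                   "frameshift", info = v$id)
  }
})

test_that("transcript models enforce their structural invariants", {
  expect_error(transcript_model("T", "c", "+",
                                data.frame(start = c(1, 5), end = c(6, 9)),
                                1, 9, sequence = "AAAAAAAAA"),
               "overlap")
  expect_error(transcript_model("T", "c", "+", data.frame(start = 1, end = 8),
                                1, 8, sequence = "ATGAAATA"),
               "multiple of 3")
  expect_error(transcript_model("T", "c", "+", data.frame(start = 1, end = 9),
                                1, 9, sequence = "ATTAAATAG"),
               "ATG")
  expect_error(transcript_model("T", "c", "+", data.frame(start = 1, end = 9),
                                1, 9, sequence = "ATGAAAAAG"),
               "stop")
})
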