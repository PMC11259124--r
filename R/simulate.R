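# Synthetic transcripts, variant pools and case-control cohorts with known
# truth, so every pipeline stage can be exercised without external data.
#
# The generator emulates the cohort structure the burden analysis assumes:
# unrelated individuals, heterozygous carriers of one qualifying PTV drawn
# from a fixed pool, non-PTV decoy variants, genotypes that fail QC at a
# configurable rate, and pool variants that fail the rarity filter at a
# configurable rate. Defaults mirror a large resequencing study of
# hypertrophic cardiomyopathy: 2,366 cases with carrier frequency 1.52%
# against 22,448 controls at 0.071%, ages from a truncated normal
# (mean 53, SD 17.1, minimum 17).

RNG_BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(RNG_BASES, n, replace = TRUE),
                                collapse = "")

#' Simulation configuration for synthetic case-control cohorts
#'
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param n_cases,n_controls Panel sizes.
#' @param carrier_freq_case,carrier_freq_control Per-panel probabilities of
#'   being a true PTV carrier.
#' @param qc_fail_rate Fraction of carrier genotypes corrupted to fail QC
#'   (allele depth < 20 or VAF < 0.25, chosen uniformly).
#' @param common_variant_rate Fraction of pool variants assigned a
#'   population MAF >= 0.1% (so they fail the rarity filter).
#' @param decoy_rate Probability that an individual carries one decoy
#'   (non-PTV) variant.
#' @param multi_variant_rate Fraction of carriers given a second distinct
#'   pool variant, to exercise collapsing.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age model, years.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L, n_cases = 2366L, n_controls = 22448L,
                              carrier_freq_case = 0.0152,
                              carrier_freq_control = 0.00071,
                              qc_fail_rate = 0, common_variant_rate = 0,
                              decoy_rate = 0.05, multi_variant_rate = 0,
                              age_mean = 53, age_sd = 17.1,
                              age_min = 17, age_max = 99) {
  stopifnot(n_cases > 0, n_controls > 0,
            carrier_freq_case >= 0, carrier_freq_case <= 1,
            carrier_freq_control >= 0, carrier_freq_control <= 1,
            qc_fail_rate >= 0, qc_fail_rate <= 1,
            common_variant_rate >= 0, common_variant_rate <= 1,
            decoy_rate >= 0, decoy_rate <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a valid transcript model
#'
#' Generates a multi-exon transcript on a synthetic contig: exon and intron
#' lengths drawn from the given ranges, introns with canonical GT..AG
#' boundaries on the transcript strand, a CDS beginning with ATG, free of
#' internal in-frame stop codons and ending with a stop codon. Minus-strand
#' transcripts are produced by mirroring the contig.
#'
#' @param seed Integer seed (byte-identical transcript on re-run).
#' @param n_exons Number of exons (>= 1; a single exon gives an intronless
#'   transcript with no splice sites).
#' @param exon_len,intron_len Length ranges `c(min, max)`.
#' @param utr5_len 5' UTR length in the spliced transcript.
#' @param strand `"+"` or `"-"`.
#' @param contig,id Names for the synthetic contig and transcript.
#' @return A [transcript_model()] carrying its `contig_seq`.
#' @export
simulate_transcript <- function(seed = 1L, n_exons = 5L,
                                exon_len = c(120L, 300L),
                                intron_len = c(60L, 200L),
                                utr5_len = 30L, strand = "+",
                                contig = "chrSim", id = "SIMTX1") {
  stopifnot(n_exons >= 1, exon_len[1] >= 30, intron_len[1] >= 10,
            exon_len[2] >= exon_len[1], intron_len[2] >= intron_len[1])
  set.seed(seed)
  widths <- sample(exon_len[1]:exon_len[2], n_exons, replace = TRUE)
  total <- sum(widths)
  utr3_min <- 25L
  cds_nt <- total - utr5_len - utr3_min
  cds_nt <- cds_nt - (cds_nt %% 3L)
  if (cds_nt < 30L) stop("infeasible length constraints: CDS would be < 10 codons")
  utr3_len <- total - utr5_len - cds_nt

  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  m <- cds_nt / 3L
  cds <- paste0("ATG",
                paste(sample(non_stop, m - 2L, replace = TRUE), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  spliced <- paste0(random_seq(utr5_len), cds, random_seq(utr3_len))

  intr_w <- if (n_exons > 1)
    sample(intron_len[1]:intron_len[2], n_exons - 1L, replace = TRUE)
  else integer(0)
  introns <- vapply(intr_w, function(w)
    paste0("GT", random_seq(w - 4L), "AG"), character(1))

  flank <- 50L
  pieces <- character(0)
  exon_start <- integer(n_exons); exon_end <- integer(n_exons)
  pos <- flank + 1L
  offs <- cumsum(c(0L, widths))
  for (i in seq_len(n_exons)) {
    exon_start[i] <- pos
    exon_end[i] <- pos + widths[i] - 1L
    pieces <- c(pieces, substr(spliced, offs[i] + 1L, offs[i + 1L]))
    pos <- exon_end[i] + 1L
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      pos <- pos + intr_w[i]
    }
  }
  contig_seq <- paste0(random_seq(flank), paste(pieces, collapse = ""),
                       random_seq(flank))

  # genomic positions of CDS bounds on the plus-strand layout
  s2g <- function(sp) {          # spliced index -> genomic (plus layout)
    i <- findInterval(sp, offs + 1L)
    exon_start[i] + (sp - offs[i] - 1L)
  }
  cds_start <- s2g(utr5_len + 1L)
  cds_end <- s2g(utr5_len + cds_nt)

  if (strand == "-") {
    L <- nchar(contig_seq)
    contig_seq <- revcomp(contig_seq)
    new_start <- L - exon_end + 1L
    new_end <- L - exon_start + 1L
    exons <- data.frame(start = rev(new_start), end = rev(new_end))
    cds <- c(L - cds_end + 1L, L - cds_start + 1L)
    cds_start <- cds[1]; cds_end <- cds[2]
  } else {
    exons <- data.frame(start = exon_start, end = exon_end)
  }
  transcript_model(id, contig, strand, exons, cds_start, cds_end,
                   sequence = spliced, contig_seq = contig_seq)
}

contig_base <- function(t, g) substr(t$contig_seq, g, g)

# VCF-style deletion record of `len` bases starting at genomic position g
vcf_deletion <- function(t, g, len) {
  a <- g - 1L
  variant_record(t$contig, a, substr(t$contig_seq, a, g + len - 1L),
                 contig_base(t, a))
}

vcf_insertion <- function(t, g_after, ins) {
  variant_record(t$contig, g_after, contig_base(t, g_after),
                 paste0(contig_base(t, g_after), ins))
}

#' Sample PTV and decoy variant pools on a synthetic transcript
#'
#' Uses rejection sampling against [classify_consequence()] to build a pool
#' of verified stop-gain, frameshift and canonical-splice variants, and a
#' decoy pool of missense, synonymous and deep-intronic variants.
#'
#' @param t A [transcript_model()] with `contig_seq`.
#' @param n_stop,n_frameshift,n_splice PTV pool composition.
#' @param n_decoy Decoy pool size.
#' @param seed Integer seed.
#' @return List with elements `ptv` and `decoy`, each a list of
#'   [variant_record()]s, plus `calls` (a [consequence_table()] for all of
#'   them).
#' @export
sample_variant_pool <- function(t, n_stop = 3, n_frameshift = 3,
                                n_splice = 2, n_decoy = 6, seed = 1L) {
  set.seed(seed)
  stopifnot(!is.null(t$contig_seq))
  cds_g <- t2g(t, seq(t$cds_lo + 3L, t$cds_hi - 3L))   # interior CDS
  draw <- function(n, want, gen) {
    out <- list(); tries <- 0L
    while (length(out) < n && tries < 20000L) {
      tries <- tries + 1L
      v <- gen()
      if (is.null(v)) next
      cl <- try(classify_consequence(t, v, name = FALSE), silent = TRUE)
      if (inherits(cl, "try-error")) next
      if (cl$consequence %in% want &&
          !v$id %in% vapply(out, `[[`, "", "id")) out <- c(out, list(v))
    }
    if (length(out) < n) stop("could not sample enough ", want[1], " variants")
    out
  }
  snv_at <- function(g) {
    ref <- contig_base(t, g)
    variant_record(t$contig, g, ref, sample(setdiff(RNG_BASES, ref), 1))
  }
  stops <- draw(n_stop, "stop_gain", function() snv_at(sample(cds_g, 1)))
  fs <- draw(n_frameshift, "frameshift", function() {
    g <- sample(cds_g, 1)
    if (stats::runif(1) < 0.5) vcf_deletion(t, g, sample(1:2, 1))
    else vcf_insertion(t, g, random_seq(sample(1:2, 1)))
  })
  canon <- canonical_splice_positions(t)
  spl <- if (n_splice > 0) {
    if (!length(canon)) stop("transcript has no canonical splice sites")
    draw(n_splice, "canonical_splice", function() snv_at(sample(canon, 1)))
  } else list()
  intr <- intron_frame(t)
  deep <- if (!is.null(intr)) unlist(lapply(seq_len(nrow(intr)), function(j)
    (intr$gstart[j] + 10L):(intr$gend[j] - 10L))) else integer(0)
  decoys <- draw(n_decoy, c("missense", "synonymous", "intronic"), function() {
    g <- if (length(deep) && stats::runif(1) < 0.3) sample(deep, 1)
         else sample(cds_g, 1)
    snv_at(g)
  })
  all_v <- c(stops, fs, spl, decoys)
  calls <- consequence_table(lapply(all_v, function(v)
    classify_consequence(t, v)))
  list(ptv = c(stops, fs, spl), decoy = decoys, calls = calls)
}

truncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

# AD/DP pairs guaranteed to pass QC for heterozygous calls
passing_depths <- function(n) {
  dp <- sample(40:80, n, replace = TRUE)
  ad <- stats::rbinom(n, dp, 0.5)
  bad <- ad < 20 | ad / dp < 0.25
  while (any(bad)) {
    ad[bad] <- stats::rbinom(sum(bad), dp[bad], 0.5)
    bad <- ad < 20 | ad / dp < 0.25
  }
  data.frame(allele_depth = ad, total_depth = dp)
}

#' Simulate a case-control cohort over a transcript
#'
#' Each individual is independently a carrier with its panel's carrier
#' frequency; carriers receive one PTV drawn uniformly from the pool as a
#' heterozygous genotype with depths drawn to pass QC, unless selected for
#' QC corruption. Decoy (non-PTV) genotypes and common pool variants are
#' interspersed per the configured rates. A truth table records the
#' generated states before any corruption.
#'
#' @param cfg A [simulation_config()].
#' @param t A [transcript_model()]; defaults to
#'   `simulate_transcript(seed = cfg$seed)`.
#' @param pool Optional pool list as from [sample_variant_pool()].
#' @return Object of class `"synthetic_cohort"`: list with `manifest`
#'   (sample_id, panel, age, sex, exclude_related, true_carrier),
#'   `genotypes`, `annotations`, `consequences`, `pool`, `transcript`,
#'   `truth` (true carrier vector and the true odds ratio implied by the
#'   generating frequencies) and `config`.
#' @export
simulate_cohort <- function(cfg, t = NULL, pool = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(t)) t <- simulate_transcript(seed = cfg$seed)
  if (is.null(pool)) pool <- sample_variant_pool(t, seed = cfg$seed)
  set.seed(cfg$seed + 1L)

  n <- cfg$n_cases + cfg$n_controls
  panel <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  manifest <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    panel = panel,
    age = truncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max),
    sex = ifelse(stats::runif(n) <
                   ifelse(panel == "case", 0.66, 0.5), "male", "female"),
    exclude_related = FALSE,
    stringsAsFactors = FALSE)
  p <- ifelse(panel == "case", cfg$carrier_freq_case,
              cfg$carrier_freq_control)
  manifest$true_carrier <- stats::runif(n) < p

  ptv_ids <- vapply(pool$ptv, `[[`, "", "id")
  decoy_ids <- vapply(pool$decoy, `[[`, "", "id")

  carriers <- which(manifest$true_carrier)
  gt <- data.frame(sample_id = character(0), variant_id = character(0),
                   zygosity = character(0), allele_depth = integer(0),
                   total_depth = integer(0), stringsAsFactors = FALSE)
  if (length(carriers)) {
    vid <- sample(ptv_ids, length(carriers), replace = TRUE)
    dep <- passing_depths(length(carriers))
    gt <- data.frame(sample_id = manifest$sample_id[carriers],
                     variant_id = vid, zygosity = "het",
                     allele_depth = dep$allele_depth,
                     total_depth = dep$total_depth,
                     stringsAsFactors = FALSE)
    if (cfg$multi_variant_rate > 0 && length(ptv_ids) > 1) {
      extra <- which(stats::runif(length(carriers)) < cfg$multi_variant_rate)
      if (length(extra)) {
        vid2 <- vapply(vid[extra], function(v)
          sample(setdiff(ptv_ids, v), 1), character(1))
        dep2 <- passing_depths(length(extra))
        gt <- rbind(gt, data.frame(sample_id = manifest$sample_id[carriers[extra]],
                                   variant_id = vid2, zygosity = "het",
                                   allele_depth = dep2$allele_depth,
                                   total_depth = dep2$total_depth,
                                   stringsAsFactors = FALSE))
      }
    }
    # QC corruption: allele depth < 20 or VAF < 0.25, chosen uniformly
    corrupt <- which(stats::runif(nrow(gt)) < cfg$qc_fail_rate)
    for (i in corrupt) {
      if (stats::runif(1) < 0.5) {
        gt$allele_depth[i] <- sample(0:19, 1)
      } else {
        gt$allele_depth[i] <-
          max(0L, floor(gt$total_depth[i] * stats::runif(1, 0.02, 0.24)))
      }
    }
  }
  if (cfg$decoy_rate > 0 && length(decoy_ids)) {
    with_decoy <- which(stats::runif(n) < cfg$decoy_rate)
    if (length(with_decoy)) {
      dep <- passing_depths(length(with_decoy))
      gt <- rbind(gt, data.frame(sample_id = manifest$sample_id[with_decoy],
                                 variant_id = sample(decoy_ids,
                                                     length(with_decoy),
                                                     replace = TRUE),
                                 zygosity = "het",
                                 allele_depth = dep$allele_depth,
                                 total_depth = dep$total_depth,
                                 stringsAsFactors = FALSE))
    }
  }

  all_ids <- c(ptv_ids, decoy_ids)
  n_common <- round(cfg$common_variant_rate * length(ptv_ids))
  common <- if (n_common > 0) sample(ptv_ids, n_common) else character(0)
  known <- stats::runif(length(all_ids)) < 0.5
  annotations <- data.frame(
    variant_id = all_ids,
    maf = ifelse(all_ids %in% common, stats::runif(length(all_ids), 0.001, 0.01),
                 ifelse(known, stats::runif(length(all_ids), 0, 5e-4), 0)),
    clinvar_id = ifelse(known, sprintf("VCV%07d.1", seq_along(all_ids)),
                        NA_character_),
    previously_reported = known,
    stringsAsFactors = FALSE)

  odds <- function(q) q / (1 - q)
  structure(list(manifest = manifest, genotypes = gt,
                 annotations = annotations, consequences = pool$calls,
                 pool = pool, transcript = t,
                 truth = list(carrier = manifest$true_carrier,
                              true_or = odds(cfg$carrier_freq_case) /
                                        odds(cfg$carrier_freq_control)),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d cases + %d controls, ",
                     "%d true carriers, %d genotype rows\n"),
              x$config$n_cases, x$config$n_controls,
              sum(x$manifest$true_carrier), nrow(x$genotypes)))
  invisible(x)
}

#' Run the filtering/collapsing/burden pipeline on a synthetic cohort
#'
#' Convenience wrapper: [call_carriers()] on the cohort's genotype,
#' annotation and consequence tables, split by panel, then [burden_test()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param ... Thresholds passed to [call_carriers()].
#' @return A `"ptv_burden"` fit; the carrier manifest is attached as
#'   attribute `"manifest"`.
#' @export
estimate_burden <- function(cohort, ...) {
  man <- call_carriers(cohort$genotypes, cohort$annotations,
                       cohort$consequences, cohort$manifest, ...)
  fit <- burden_test(build_2x2(man[man$panel == "case", ],
                               man[man$panel == "control", ]))
  attr(fit, "manifest") <- man
  fit
}
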