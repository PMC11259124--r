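# Multi-sample VCF emission and reading for synthetic cohorts.
#
# The writer produces plain-text VCF 4.2 with GT:AD:DP per-sample fields;
# reading goes through vcfR. writer -> reader is the identity on the
# non-reference genotype table.

#' Write a synthetic cohort to VCF + TSV side files
#'
#' Emits a multi-sample VCF (GT:AD:DP), the variant annotation TSV, the
#' sample manifest TSV and the truth-table TSV.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the four file paths.
#' @export
emit_vcf <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- cohort$transcript
  vars <- c(cohort$pool$ptv, cohort$pool$decoy)
  vars <- vars[order(vapply(vars, `[[`, 0L, "pos"))]
  ids <- vapply(vars, `[[`, "", "id")
  samples <- cohort$manifest$sample_id

  gt <- cohort$genotypes
  key <- paste(gt$sample_id, gt$variant_id, sep = "\r")
  cell <- matrix("0/0:30,0:30", nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  if (nrow(gt)) {
    gtf <- ifelse(gt$zygosity == "hom", "1/1", "0/1")
    val <- sprintf("%s:%d,%d:%d", gtf,
                   gt$total_depth - gt$allele_depth, gt$allele_depth,
                   gt$total_depth)
    cell[cbind(match(gt$variant_id, ids), match(gt$sample_id, samples))] <- val
  }

  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", t$contig),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(vars), function(i) {
    v <- vars[[i]]
    paste(c(v$contig, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
            "GT:AD:DP", cell[i, ]), collapse = "\t")
  }, character(1))

  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             annotations = file.path(dir, paste0(prefix, "_annotations.tsv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  writeLines(c(header, body), paths["vcf"])
  utils::write.table(cohort$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$manifest[, setdiff(names(cohort$manifest),
                                               "true_carrier")],
                     paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = cohort$manifest$sample_id,
                                true_carrier = cohort$manifest$true_carrier),
                     paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read per-sample genotypes from a multi-sample VCF
#'
#' Parses GT:AD:DP fields via \pkg{vcfR} and returns the long-format
#' genotype table used by the filtering pipeline (non-reference genotypes
#' only).
#'
#' @param path VCF file.
#' @return Data frame: `sample_id`, `variant_id` (chrom-pos-ref-alt token),
#'   `zygosity` (`het`/`hom`), `allele_depth`, `total_depth`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = "-")
  gtm <- vcfR::extract.gt(v, element = "GT")
  adm <- vcfR::extract.gt(v, element = "AD")
  dpm <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  rownames(gtm) <- rownames(adm) <- rownames(dpm) <- ids

  nonref <- which(!is.na(gtm) & !gtm %in% c("0/0", "0|0", "./."),
                  arr.ind = TRUE)
  if (!nrow(nonref))
    return(data.frame(sample_id = character(0), variant_id = character(0),
                      zygosity = character(0), allele_depth = integer(0),
                      total_depth = integer(0), stringsAsFactors = FALSE))
  gts <- gtm[nonref]
  alleles <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
  zyg <- vapply(alleles, function(a)
    if (all(a == "1")) "hom" else "het", character(1))
  ad_alt <- vapply(strsplit(adm[nonref], ",", fixed = TRUE),
                   function(x) as.integer(x[2]), integer(1))
  out <- data.frame(sample_id = colnames(gtm)[nonref[, 2]],
                    variant_id = ids[nonref[, 1]],
                    zygosity = zyg,
                    allele_depth = ad_alt,
                    total_depth = as.integer(dpm[nonref]),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$variant_id), , drop = FALSE]
}
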