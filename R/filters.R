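# Genotype- and variant-level filters, the P/LP rule, and carrier collapsing.

#' Genotype-level quality control
#'
#' A genotype passes when the alternate allele depth is at least `min_ad`
#' (default 20) and, for heterozygous calls only, the variant allele
#' fraction is at least `min_vaf` (default 0.25). Both thresholds are
#' inclusive. Zero total depth fails with reason `"no coverage"`.
#'
#' @param allele_depth Integer vector: alt-supporting read count.
#' @param total_depth Integer vector: total read depth.
#' @param zygosity Character vector: `"het"`, `"hom"` or `"hemi"`.
#' @param min_ad,min_vaf Inclusive thresholds.
#' @return Data frame with columns `pass` (logical) and `reason`
#'   (`NA` when passing).
#' @examples
#' genotype_qc(20, 80, "het")    # passes: AD 20, VAF 0.25
#' genotype_qc(19, 38, "het")    # fails on depth
#' @export
genotype_qc <- function(allele_depth, total_depth, zygosity,
                        min_ad = 20, min_vaf = 0.25) {
  n <- max(length(allele_depth), length(total_depth), length(zygosity))
  allele_depth <- rep_len(allele_depth, n)
  total_depth <- rep_len(total_depth, n)
  zygosity <- rep_len(zygosity, n)
  if (any(allele_depth < 0 | total_depth < 0, na.rm = TRUE) ||
      any(allele_depth > total_depth, na.rm = TRUE))
    stop("require 0 <= allele_depth <= total_depth")
  vaf <- ifelse(total_depth > 0, allele_depth / total_depth, NA_real_)
  reason <- rep(NA_character_, n)
  reason[total_depth == 0] <- "no coverage"
  low_ad <- total_depth > 0 & allele_depth < min_ad
  reason[low_ad] <- sprintf("allele depth < %d", min_ad)
  low_vaf <- total_depth > 0 & !low_ad & zygosity == "het" & vaf < min_vaf
  reason[low_vaf] <- sprintf("VAF < %s for heterozygous call", min_vaf)
  data.frame(pass = is.na(reason), reason = reason, vaf = vaf,
             stringsAsFactors = FALSE)
}

#' Population-rarity filter
#'
#' Passes when the minor allele frequency in the matched population is
#' strictly below `max_maf` (default 0.001, i.e. 0.1%). A missing MAF is
#' treated as 0, so that variants absent from the reference panel (novel
#' variants) survive the filter.
#'
#' @param maf Numeric vector of population MAFs; `NA` treated as 0.
#' @param max_maf Strict upper bound.
#' @return Logical vector.
#' @export
rarity_filter <- function(maf, max_maf = 0.001) {
  maf[is.na(maf)] <- 0
  if (any(maf < 0 | maf > 1)) stop("MAF must lie in [0, 1]")
  maf < max_maf
}

#' Flag CNVs spanning at least k consecutive exons
#'
#' A copy-number call is flagged when its interval overlaps `min_exons`
#' (default 3) *consecutive* exons of the transcript. Overlapping exons 1
#' and 3 but not 2 does not qualify.
#'
#' @param cnv_start,cnv_end Genomic span of the CNV call.
#' @param t A [transcript_model()].
#' @param min_exons Minimum length of a consecutive run of overlapped exons.
#' @return `TRUE` when flagged.
#' @export
cnv_exon_span_filter <- function(cnv_start, cnv_end, t, min_exons = 3) {
  stopifnot(cnv_start <= cnv_end)
  hit <- t$exons$start <= cnv_end & t$exons$end >= cnv_start
  if (!any(hit)) return(FALSE)
  runs <- rle(hit)
  any(runs$lengths[runs$values] >= min_exons)
}

#' Minimal P/LP classification for PTVs
#'
#' A deliberately minimal PVS1+PM2-style surrogate for the full ACMG
#' framework: a rare PTV already reported (in ClinVar or the literature) is
#' `"pathogenic"`; a rare novel PTV is `"likely_pathogenic"`; anything that
#' is not a PTV is `"not_reportable"`. Callers should apply
#' [rarity_filter()] first.
#'
#' @param is_ptv Logical vector.
#' @param previously_reported Logical vector: reported in the literature
#'   (beyond the study at hand).
#' @param clinvar_id Character vector; `NA` or `""` means no ClinVar entry.
#' @return Character vector of classifications.
#' @export
classify_acmg_lite <- function(is_ptv, previously_reported = FALSE,
                               clinvar_id = NA_character_) {
  n <- max(length(is_ptv), length(previously_reported), length(clinvar_id))
  is_ptv <- rep_len(is_ptv, n)
  previously_reported <- rep_len(previously_reported, n)
  clinvar_id <- rep_len(clinvar_id, n)
  known <- (!is.na(previously_reported) & previously_reported) |
    (!is.na(clinvar_id) & nzchar(clinvar_id) & clinvar_id != "-")
  ifelse(!is_ptv, "not_reportable",
         ifelse(known, "pathogenic", "likely_pathogenic"))
}

#' Collapse qualifying genotypes to per-sample carrier status
#'
#' A sample is a carrier when it harbours at least one qualifying genotype
#' (P/LP PTV passing all upstream filters); multiple qualifying variants in
#' one sample count once. Homozygous qualifying genotypes are counted as
#' carriers with a warning, since the burden contrast is carrier versus
#' non-carrier of at least one allele.
#'
#' @param genotypes Data frame with columns `sample_id`, `variant_id`,
#'   `zygosity`; typically already restricted to QC-passing calls.
#' @param qualifying Character vector of qualifying variant ids (P/LP PTVs).
#' @param samples Optional character vector of all sample ids (so that
#'   samples with no genotype rows appear as non-carriers).
#' @return Data frame with columns `sample_id`, `carrier`, `n_qualifying`,
#'   `variants` (comma-separated qualifying variant ids).
#' @export
collapse_carriers <- function(genotypes, qualifying, samples = NULL) {
  g <- genotypes[genotypes$variant_id %in% qualifying, , drop = FALSE]
  if (nrow(g) && any(g$zygosity == "hom"))
    warning("homozygous qualifying genotype(s) counted as carriers: ",
            paste(unique(g$sample_id[g$zygosity == "hom"]), collapse = ", "))
  if (is.null(samples)) samples <- unique(genotypes$sample_id)
  tab <- if (nrow(g)) split(g$variant_id, g$sample_id) else list()
  n_q <- vapply(samples, function(s) length(unique(tab[[s]])), integer(1))
  vars <- vapply(samples, function(s)
    paste(unique(tab[[s]]), collapse = ","), character(1))
  data.frame(sample_id = samples, carrier = n_q > 0, n_qualifying = n_q,
             variants = vars, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full variant-to-carrier pipeline
#'
#' Applies, in order-invariant composition: genotype QC, the population
#' rarity filter, the P/LP PTV rule, and per-sample collapsing. Individuals
#' flagged `exclude_related` in the manifest are dropped before collapsing.
#'
#' @param genotypes Data frame: `sample_id`, `variant_id`, `zygosity`,
#'   `allele_depth`, `total_depth`.
#' @param annotations Data frame: `variant_id`, `maf`, `clinvar_id`,
#'   `previously_reported`.
#' @param consequences Data frame: `variant_id`, `is_ptv` (e.g. from
#'   [consequence_table()] with variant ids).
#' @param manifest Data frame with `sample_id` and optionally
#'   `exclude_related`; defines the sample universe.
#' @param min_ad,min_vaf,max_maf Filter thresholds (defaults 20, 0.25,
#'   0.001).
#' @return The manifest with columns `carrier`, `n_qualifying`, `variants`
#'   appended.
#' @export
call_carriers <- function(genotypes, annotations, consequences, manifest,
                          min_ad = 20, min_vaf = 0.25, max_maf = 0.001) {
  stopifnot(!anyDuplicated(manifest$sample_id))
  if ("exclude_related" %in% names(manifest)) {
    manifest <- manifest[!manifest$exclude_related, , drop = FALSE]
  }
  qc <- genotype_qc(genotypes$allele_depth, genotypes$total_depth,
                    genotypes$zygosity, min_ad = min_ad, min_vaf = min_vaf)
  g <- genotypes[qc$pass & genotypes$sample_id %in% manifest$sample_id, ,
                 drop = FALSE]
  ann <- annotations
  rare <- ann$variant_id[rarity_filter(ann$maf, max_maf = max_maf)]
  cls <- classify_acmg_lite(
    consequences$is_ptv,
    if ("previously_reported" %in% names(ann))
      ann$previously_reported[match(consequences$variant_id, ann$variant_id)]
    else FALSE,
    if ("clinvar_id" %in% names(ann))
      ann$clinvar_id[match(consequences$variant_id, ann$variant_id)]
    else NA_character_)
  plp <- consequences$variant_id[cls %in% c("pathogenic", "likely_pathogenic")]
  qualifying <- intersect(plp, rare)
  cc <- collapse_carriers(g, qualifying, samples = manifest$sample_id)
  merge(manifest, cc, by = "sample_id", sort = FALSE)
}
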