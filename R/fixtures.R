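# Packaged study fixtures: TSV transcriptions of the published carrier,
# variant, clinical and control-panel tables, and the 2x2 cell counts of the
# four control-panel comparisons.
#
# The carrier and variant tables are transcribed verbatim and are known to
# disagree in two places (one variant present in the carrier table but
# absent from the variant table; one recurrence count off by one); the
# loader surfaces this as a validation warning rather than silently
# resolving it.

fixture_path <- function(name) {
  system.file("extdata", name, package = "ptvburden", mustWork = TRUE)
}

read_fixture_tsv <- function(name) {
  utils::read.delim(fixture_path(name), stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Load the PTV-carrier patient table fixture
#'
#' One row per carrier patient: HGVS c./p. names of the qualifying variant,
#' age, sex and phenotype flags.
#'
#' @param warn_consistency Cross-check recurrence counts against the unique
#'   variant table and warn on discrepancies (default `TRUE`).
#' @return Data frame with 36 rows.
#' @export
load_patient_table <- function(warn_consistency = TRUE) {
  t1 <- read_fixture_tsv("table1_patients.tsv")
  if (warn_consistency) {
    t2 <- load_variant_table()
    validate_fixture_tables(t1, t2)
  }
  t1
}

#' Load the unique-variant table fixture
#'
#' One row per unique qualifying variant: GRCh37 `chrom-pos-ref-alt` token,
#' HGVS names, consequence class, recurrence count, prior-report and ClinVar
#' status, and the P/LP classification.
#'
#' @return Data frame with 14 rows; `consequence` holds the normalised enum
#'   (`stop_gain`, `frameshift`, `canonical_splice`) next to the verbatim
#'   `consequence_label`.
#' @export
load_variant_table <- function() {
  t2 <- read_fixture_tsv("table2_variants.tsv")
  map <- c("Stop gain" = "stop_gain", "Frameshift" = "frameshift",
           "Canonical splice site" = "canonical_splice")
  t2$consequence_label <- t2$consequence
  t2$consequence <- unname(map[t2$consequence_label])
  t2$previously_reported <-
    !(is.na(t2$previous_report) | t2$previous_report %in% c("-", "This study"))
  t2$clinvar_id[t2$clinvar_id %in% "-"] <- NA_character_
  t2$is_ptv <- t2$consequence %in% PTV_CLASSES
  t2
}

# cross-check per-variant recurrence counts between the two transcriptions
validate_fixture_tables <- function(t1, t2) {
  counts1 <- table(t1$hgvs_c)
  msgs <- character(0)
  only1 <- setdiff(names(counts1), t2$hgvs_c)
  if (length(only1))
    msgs <- c(msgs, paste0("variant(s) in the patient table missing from the ",
                           "variant table: ", paste(only1, collapse = ", ")))
  both <- intersect(t2$hgvs_c, names(counts1))
  n1 <- as.integer(counts1[both])
  n2 <- t2$n_patients[match(both, t2$hgvs_c)]
  off <- both[n1 != n2]
  if (length(off))
    msgs <- c(msgs, paste0("recurrence count mismatch for ",
                           paste(sprintf("%s (%d vs %d)", off,
                                         n1[n1 != n2], n2[n1 != n2]),
                                 collapse = ", ")))
  if (length(msgs))
    warning("fixture tables transcribed verbatim disagree: ",
            paste(msgs, collapse = "; "), call. = FALSE)
  invisible(msgs)
}

#' Load the clinical-features table fixture
#'
#' Echocardiographic follow-up for the subset of carriers with clinical
#' records: LVH morphology, maximum wall thickness (mm) and left
#' ventricular ejection fraction (%).
#'
#' @return Data frame with 24 rows.
#' @export
load_clinical_table <- function() {
  read_fixture_tsv("table3_clinical.tsv")
}

#' Load the control-panel variant table fixture
#'
#' Per-variant carrier counts in the case cohort and the four control
#' panels (blank cells read as 0).
#'
#' @return Data frame, one row per variant.
#' @export
load_control_table <- function() {
  t4 <- read_fixture_tsv("table4_controls.tsv")
  for (cl in c("hcmp_n", "gnomad_eas_n", "koges_n", "kova2_n", "exome_n"))
    t4[[cl]][is.na(t4[[cl]])] <- 0L
  t4
}

#' Load the 2x2 cell counts of the published control-panel comparisons
#'
#' @return Named list of [contingency_2x2()] tables: `gnomad_eas`,
#'   `koges_kova2`, `internal_exomes`, `combined`.
#' @export
load_comparison_counts <- function() {
  x <- jsonlite::read_json(fixture_path("comparison_counts.json"),
                           simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(x)), function(i)
    contingency_2x2(x$case_carriers[i], x$case_n[i],
                    x$control_carriers[i], x$control_n[i],
                    labels = c(x$case_label[i], x$control_label[i])))
  names(out) <- x$name
  out
}

#' Deterministic cohort manifest reproducing the study's diagnostic tallies
#'
#' Builds a 2,366-row manifest matching the published demographic and
#' diagnostic-yield summary: 1,564 male patients, 482 with a reported
#' cardiovascular-gene diagnosis (18 of whom carry findings in two genes),
#' with per-gene counts of 196 MYBPC3, 120 MYH7, 59 TNNI3 and the remainder
#' aggregated as OTHER. Construction is deterministic (no RNG); ages are not
#' part of this summary and are left `NA`.
#'
#' @return Data frame: `sample_id`, `sex`, `reported_genes`
#'   (semicolon-separated, `""` when undiagnosed).
#' @export
hcmp_diagnostic_manifest <- function() {
  n <- 2366L; n_male <- 1564L
  genes <- c(rep("MYBPC3;MYH7", 18L),          # dual-gene reports
             rep("MYBPC3", 196L - 18L),
             rep("MYH7", 120L - 18L),
             rep("TNNI3", 59L),
             rep("OTHER", 482L - 196L - 120L - 59L + 18L))
  stopifnot(length(genes) == 482L)
  data.frame(sample_id = sprintf("HCM%04d", seq_len(n)),
             sex = rep(c("male", "female"), c(n_male, n - n_male)),
             reported_genes = c(genes, rep("", n - 482L)),
             stringsAsFactors = FALSE)
}
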