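# Annotation driver and report serialisation.

#' Annotate variants against a transcript model
#'
#' Runs the consequence engine over a set of variants: a list of
#' [variant_record()]s, a character vector of `chrom-pos-ref-alt` tokens, or
#' a VCF path (multi-allelic sites are decomposed to biallelic records
#' first, so the output has one row per alternate allele).
#'
#' @param variants Variants in any of the accepted forms.
#' @param t A [transcript_model()].
#' @return A [consequence_table()] data frame, one row per (decomposed)
#'   variant.
#' @export
annotate_variants <- function(variants, t) {
  if (is.character(variants) && length(variants) == 1 &&
      file.exists(variants)) {
    variants <- read_vcf_sites(variants)
  } else if (is.character(variants)) {
    variants <- parse_variant_token(variants)
    if (inherits(variants, "variant_record")) variants <- list(variants)
  } else if (inherits(variants, "variant_record")) {
    variants <- list(variants)
  }
  if (!length(variants))
    return(consequence_table(list()))
  consequence_table(lapply(variants, function(v) classify_consequence(t, v)))
}

#' Serialise burden results to JSON (unrounded) and a rounded report
#'
#' All computation is kept at full precision; rounding happens only here,
#' at serialisation: odds ratios and interval bounds to 2 decimals, carrier
#' frequencies to the given digits. The JSON sidecar always carries the
#' unrounded values.
#'
#' @param results List of `"ptv_burden"` fits.
#' @param json Path for the JSON output (`NULL` to skip).
#' @param markdown Path for the human-readable markdown report (`NULL` to
#'   skip).
#' @param digits Decimals for ORs/CIs in the markdown report.
#' @return The forest table, invisibly.
#' @export
burden_report <- function(results, json = NULL, markdown = NULL, digits = 2) {
  ft <- forest_table(results)
  if (!is.null(json)) {
    payload <- lapply(seq_len(nrow(ft)), function(i) {
      list(label = ft$label[i],
           cells = list(a = ft$a[i], b = ft$b[i], c = ft$c[i], d = ft$d[i]),
           or = ft$or[i], ci_low = ft$ci_low[i], ci_high = ft$ci_high[i],
           carrier_freq_case_pct = ft$freq_case_pct[i],
           carrier_freq_control_pct = ft$freq_control_pct[i])
    })
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(markdown)) {
    lines <- c("# Carrier-burden results", "",
               "| comparison | carriers (cases) | carriers (controls) | OR | 95% CI |",
               "|---|---|---|---|---|")
    if (nrow(ft)) {
      lines <- c(lines, sprintf(
        "| %s | %d/%d (%.2f%%) | %d/%d (%.2f%%) | %.*f | %.*f-%.*f |",
        ft$label, ft$a, ft$a + ft$b, ft$freq_case_pct,
        ft$c, ft$c + ft$d, ft$freq_control_pct,
        digits, ft$or, digits, ft$ci_low, digits, ft$ci_high))
    }
    writeLines(lines, markdown)
  }
  invisible(ft)
}

#' Machine-readable provenance block for a pipeline run
#'
#' @param config Named list of run parameters.
#' @param seed Integer seed used for any randomness.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return List with config, seed, package version, R version and input
#'   digests; write it with `jsonlite::write_json()`.
#' @export
provenance_block <- function(config = list(), seed = NA_integer_,
                             inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "ptvburden",
       version = as.character(utils::packageVersion("ptvburden")),
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = seed, config = config, input_md5 = digests)
}
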