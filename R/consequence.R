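# Consequence classification and HGVS naming.
#
# PTV (premature terminating variant) classes are stop_gain, frameshift and
# canonical_splice: the loss-of-function classes counted by gene-burden
# testing. Canonical splice sites are the +/-1 and +/-2 intronic
# dinucleotides (GT donor / AG acceptor) of introns flanking a coding exon;
# deeper intronic positions are never PTVs here.

CONSEQUENCES <- c("stop_gain", "frameshift", "canonical_splice",
                  "inframe_indel", "missense", "synonymous",
                  "start_loss", "stop_loss", "intronic", "utr")
PTV_CLASSES <- c("stop_gain", "frameshift", "canonical_splice")

# genomic positions of canonical splice bases for introns flanking CDS exons
canonical_splice_positions <- function(t) {
  intr <- intron_frame(t)
  if (is.null(intr)) return(integer(0))
  ef <- exon_frame(t)
  cds_exon <- ef$t_start <= t$cds_hi & ef$t_end >= t$cds_lo
  out <- integer(0)
  for (j in seq_len(nrow(intr))) {
    if (!(cds_exon[j] || cds_exon[j + 1])) next
    i <- intr[j, ]
    if (i$gend - i$gstart + 1L < 2L) next
    out <- c(out,
             i$donor_edge_g + i$step * c(1L, 2L),
             i$acceptor_edge_g - i$step * c(1L, 2L))
  }
  sort(unique(out))
}

#' Classify the molecular consequence of a variant on a transcript
#'
#' Applies the edit-and-translate machinery and a canonical-splice-site rule
#' to assign one of: `stop_gain`, `frameshift`, `canonical_splice`,
#' `inframe_indel`, `missense`, `synonymous`, `start_loss`, `stop_loss`,
#' `intronic`, `utr`. `is_ptv` is `TRUE` exactly for the first three classes.
#'
#' Rules: a variant touching a +/-1 or +/-2 intronic base of an intron
#' flanking a coding exon is `canonical_splice` (protein effect `"p.?"`); an
#' indel whose net coding length change is not a multiple of 3 is
#' `frameshift`; an in-frame substitution or indel that introduces a stop
#' codon upstream of the expected stop is `stop_gain`. Variants spanning an
#' exon/intron junction without touching a canonical base are classified by
#' the length of CDS sequence they remove. Deep intronic variants are
#' `intronic` and never PTVs.
#'
#' @param t A [transcript_model()].
#' @param v A [variant_record()].
#' @param name If `TRUE` (default) populate HGVS c./p. names via
#'   [hgvs_name()].
#' @return An object of class `"consequence_call"`: list with `variant`,
#'   `transcript_id`, `consequence`, `is_ptv`, `hgvs_c`, `hgvs_p`,
#'   `annotation`.
#' @examples
#' tx <- transcript_model("TX1", "chr1", "+",
#'                        exons = data.frame(start = 101, end = 112),
#'                        cds_start = 101, cds_end = 112,
#'                        sequence = "ATGAAACCCTAG")
#' classify_consequence(tx, variant_record("chr1", 104, "A", "T"))$consequence
#' @export
classify_consequence <- function(t, v, name = TRUE) {
  stopifnot(inherits(t, "transcript_model"), inherits(v, "variant_record"))
  if (!identical(v$contig, t$contig))
    stop("variant contig does not match transcript contig")
  ed <- map_edit(t, v)
  canon <- canonical_splice_positions(t)
  annotation <- NA_character_

  hit_canonical <- FALSE
  if (length(canon)) {
    if (ed$status %in% c("intronic", "junction") ||
        (ed$status == "exonic" && ed$type != "ins")) {
      hit_canonical <- any(ed$span_g %in% canon)
    } else if (!is.null(ed$type) && ed$type == "ins") {
      hit_canonical <- all(ed$span_g %in% canon)   # inserted inside a dinucleotide
    }
  }

  ctx <- list(edit = ed)
  if (hit_canonical) {
    consequence <- "canonical_splice"
  } else if (ed$status == "outside") {
    consequence <- "intronic"
    annotation <- "outside transcript span"
  } else if (ed$status == "intronic") {
    consequence <- "intronic"
  } else if (ed$status == "junction") {
    net <- nchar(if (is.null(ed$ins)) "" else ed$ins) - ed$cds_del_len
    consequence <- if (ed$cds_del_len > 0 && net %% 3 != 0) "frameshift"
                   else if (ed$cds_del_len > 0) "inframe_indel"
                   else "intronic"
    annotation <- "spans exon/intron junction"
  } else {                                          # exonic
    k <- nchar(ed$del)
    in_cds <- if (ed$type == "ins") {
      ed$tstart > t$cds_lo && ed$tstart <= t$cds_hi
    } else {
      ed$tstart <= t$cds_hi && (ed$tstart + k - 1L) >= t$cds_lo
    }
    if (!in_cds) {
      consequence <- "utr"
    } else {
      res <- apply_tx_edit(t, ed$tstart, ed$del, ed$ins)
      ctx$res <- res
      rp <- ref_peptide(t)
      N <- nchar(rp)
      ap <- res$peptide
      s_alt <- if (endsWith(ap, "*")) nchar(ap) else Inf
      expected <- N + res$net / 3
      if (res$start_lost) {
        consequence <- "start_loss"
      } else if (res$net %% 3 != 0) {
        consequence <- "frameshift"
      } else if (s_alt < expected) {
        consequence <- "stop_gain"
      } else if (s_alt > expected || res$no_stop) {
        consequence <- "stop_loss"
      } else if (res$net != 0) {
        consequence <- "inframe_indel"
      } else {
        consequence <- if (identical(ap, rp)) "synonymous" else "missense"
      }
    }
  }

  call <- structure(list(variant = v, transcript_id = t$id,
                         consequence = consequence,
                         is_ptv = consequence %in% PTV_CLASSES,
                         hgvs_c = NA_character_, hgvs_p = NA_character_,
                         annotation = annotation),
                    class = "consequence_call")
  if (name) {
    nm <- hgvs_name(t, v, call, ctx = ctx)
    call$hgvs_c <- nm[["hgvs_c"]]
    call$hgvs_p <- nm[["hgvs_p"]]
  }
  call
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s | %s | %s | %s%s\n", x$variant$id, x$consequence,
              x$hgvs_c, x$hgvs_p,
              if (x$is_ptv) " [PTV]" else ""))
  invisible(x)
}

#' Tabulate consequence calls
#'
#' @param calls List of `consequence_call`s.
#' @return Data frame with one row per call: `variant_id`, `consequence`,
#'   `is_ptv`, `hgvs_c`, `hgvs_p`, `annotation`.
#' @export
consequence_table <- function(calls) {
  data.frame(
    variant_id = vapply(calls, function(x) x$variant$id, character(1)),
    consequence = vapply(calls, function(x) x$consequence, character(1)),
    is_ptv = vapply(calls, function(x) x$is_ptv, logical(1)),
    hgvs_c = vapply(calls, function(x) x$hgvs_c, character(1)),
    hgvs_p = vapply(calls, function(x) x$hgvs_p, character(1)),
    annotation = vapply(calls, function(x) x$annotation, character(1)),
    stringsAsFactors = FALSE)
}
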