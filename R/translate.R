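# Translation of (edited) coding sequences with the standard nuclear code.

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter", X = "Xaa")

aa3 <- function(aa1) unname(AA_THREE[aa1])

# Translate a nucleotide string codon-by-codon (standard code). Trailing
# partial codons are dropped. If to_first_stop, stop at (and include) the
# first stop codon.
translate_nt <- function(seq, to_first_stop = TRUE) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (to_first_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1])]
  }
  paste(aa, collapse = "")
}

#' Apply a variant to a transcript and translate the edited coding sequence
#'
#' The edit is mapped into spliced-transcript space (reverse-complemented for
#' minus-strand transcripts), applied, and the coding sequence re-translated
#' with the standard nuclear code. Translation starts at the (possibly
#' shifted) start codon and continues to the first in-frame stop codon; for
#' frameshifts that abolish the natural stop, translation runs on into the
#' 3' UTR so the new termination codon is found where one exists.
#'
#' @param t A [transcript_model()].
#' @param v A [variant_record()] whose edit overlaps the CDS (or the 5' UTR,
#'   in which case the frame downstream is shifted accordingly).
#' @return List with elements
#'   \describe{
#'     \item{cds}{edited CDS-region nucleotide string (start codon through the
#'       natural CDS end, adjusted for length changes),}
#'     \item{peptide}{translation up to and including the first stop (`"*"`),
#'       possibly extending past the natural stop position,}
#'     \item{tx}{the full edited spliced transcript,}
#'     \item{start_lost}{`TRUE` when the edit destroys the start codon,}
#'     \item{no_stop}{`TRUE` when no stop codon is reached before the
#'       transcript end.}
#'   }
#' @examples
#' tx <- transcript_model("TX1", "chr1", "+",
#'                        exons = data.frame(start = 101, end = 109),
#'                        cds_start = 101, cds_end = 109,
#'                        sequence = "ATGAAATAG")
#' apply_and_translate(tx, variant_record("chr1", 104, "A", "T"))$peptide  # "M*"
#' @export
apply_and_translate <- function(t, v) {
  ed <- map_edit(t, v)
  if (ed$status != "exonic")
    stop("variant does not lie within the spliced transcript (status: ",
         ed$status, ")")
  apply_tx_edit(t, ed$tstart, ed$del, ed$ins)
}

# core worker shared with classify_consequence: edit already in transcript space
apply_tx_edit <- function(t, tstart, del, ins) {
  seq <- t$sequence
  k <- nchar(del)
  tx <- paste0(substr(seq, 1, tstart - 1L), ins,
               substr(seq, tstart + k, nchar(seq)))
  net <- nchar(ins) - k
  # CDS start shifts when the whole edit lies 5' of it
  cds_lo <- t$cds_lo
  if (tstart + k - 1L < cds_lo) cds_lo <- cds_lo + net
  start_lost <- substr(tx, cds_lo, cds_lo + 2L) != "ATG" || cds_lo < 1L
  coding_tail <- substr(tx, cds_lo, nchar(tx))
  peptide <- translate_nt(coding_tail, to_first_stop = TRUE)
  no_stop <- !endsWith(peptide, "*") && nzchar(peptide)
  cds_len_new <- (t$cds_hi - t$cds_lo + 1L) +
    if (tstart <= t$cds_hi) net else 0L
  list(cds = substr(tx, cds_lo, cds_lo + max(cds_len_new, 0L) - 1L),
       peptide = peptide, tx = tx,
       start_lost = isTRUE(start_lost), no_stop = no_stop,
       cds_lo = cds_lo, net = net)
}
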