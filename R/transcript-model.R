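#' Construct a transcript model
#'
#' A transcript model is the coordinate frame for all consequence calls: an
#' ordered set of exons on a genomic contig, a CDS span, the strand, and the
#' spliced transcript sequence (always in transcript orientation, 5' to 3').
#'
#' @param id Transcript accession string.
#' @param contig Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or matrix) with columns `start`, `end`: 1-based
#'   inclusive genomic intervals, non-overlapping, sorted by genomic position.
#' @param cds_start,cds_end Genomic positions bounding the CDS
#'   (`cds_start <= cds_end`, GFF-style: the genomic span, not the
#'   translation direction).
#' @param sequence Spliced transcript sequence (transcript orientation).
#'   Derived from `contig_seq` when omitted.
#' @param contig_seq Optional full contig sequence (forward genomic strand,
#'   position 1 = genomic coordinate 1). Needed to resolve intronic reference
#'   bases and to emit VCF records with anchor bases.
#' @param check_cds If `TRUE` (default), require the spliced CDS to be a
#'   multiple of 3, to begin with `ATG` and to end with a stop codon.
#' @return An object of class `"transcript_model"`.
#' @examples
#' tx <- transcript_model("TX1", "chr1", "+",
#'                        exons = data.frame(start = 101, end = 109),
#'                        cds_start = 101, cds_end = 109,
#'                        sequence = "ATGAAATAG")
#' tx
#' @export
transcript_model <- function(id, contig, strand, exons, cds_start, cds_end,
                             sequence = NULL, contig_seq = NULL,
                             check_cds = TRUE) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"),
            cds_start <= cds_end)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start))
    stop("exon with end < start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch; introns must have length >= 1")

  widths <- exons$end - exons$start + 1L
  tx_len <- sum(widths)

  if (is.null(sequence)) {
    if (is.null(contig_seq))
      stop("either 'sequence' or 'contig_seq' must be supplied")
    pieces <- substring(contig_seq, exons$start, exons$end)
    sequence <- paste(pieces, collapse = "")
    if (strand == "-") sequence <- revcomp(sequence)
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != tx_len)
    stop(sprintf("spliced sequence length (%d) does not match exon widths (%d)",
                 nchar(sequence), tx_len))

  t <- structure(list(id = id, contig = contig, strand = strand,
                      exons = exons, cds_start = cds_start, cds_end = cds_end,
                      sequence = sequence, contig_seq = contig_seq,
                      tx_len = tx_len),
                 class = "transcript_model")

  cds_lo <- g2t(t, if (strand == "+") cds_start else cds_end)
  cds_hi <- g2t(t, if (strand == "+") cds_end else cds_start)
  if (is.na(cds_lo) || is.na(cds_hi))
    stop("CDS boundaries must fall inside exons")
  t$cds_lo <- cds_lo
  t$cds_hi <- cds_hi

  if (check_cds) {
    cds_seq <- substr(sequence, cds_lo, cds_hi)
    if (nchar(cds_seq) %% 3 != 0)
      stop("spliced CDS length is not a multiple of 3")
    if (substr(cds_seq, 1, 3) != "ATG")
      stop("CDS does not begin with ATG")
    last <- substr(cds_seq, nchar(cds_seq) - 2, nchar(cds_seq))
    if (!last %in% c("TAA", "TAG", "TGA"))
      stop("CDS does not end with a stop codon")
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript model %s (%s%s), %d exon(s), %d nt spliced\n",
              x$id, x$contig, x$strand, nrow(x$exons), x$tx_len))
  cat(sprintf("  CDS: transcript %d..%d (%d nt, %d codons)\n",
              x$cds_lo, x$cds_hi, x$cds_hi - x$cds_lo + 1,
              (x$cds_hi - x$cds_lo + 1) %/% 3))
  invisible(x)
}

# genomic position -> transcript coordinate (1..tx_len), NA if intronic/outside
g2t <- function(t, gpos) {
  widths <- t$exons$end - t$exons$start + 1L
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_along(gpos)) {
    g <- gpos[k]
    i <- which(t$exons$start <= g & g <= t$exons$end)
    if (!length(i)) next
    if (t$strand == "+") {
      off <- if (i == 1) 0L else sum(widths[seq_len(i - 1)])
      out[k] <- off + (g - t$exons$start[i] + 1L)
    } else {
      n <- nrow(t$exons)
      off <- if (i == n) 0L else sum(widths[seq(i + 1, n)])
      out[k] <- off + (t$exons$end[i] - g + 1L)
    }
  }
  out
}

# transcript coordinate -> genomic position
t2g <- function(t, tpos) {
  widths <- t$exons$end - t$exons$start + 1L
  n <- nrow(t$exons)
  ord <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  ends <- cumsum(widths[ord])
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- rep(NA_integer_, length(tpos))
  for (k in seq_along(tpos)) {
    p <- tpos[k]
    if (is.na(p) || p < 1 || p > t$tx_len) next
    j <- which(starts <= p & p <= ends)[1]
    i <- ord[j]
    within <- p - starts[j]
    out[k] <- if (t$strand == "+") t$exons$start[i] + within
              else t$exons$end[i] - within
  }
  out
}

# reference CDS sequence and peptide (includes terminal "*")
cds_sequence <- function(t) substr(t$sequence, t$cds_lo, t$cds_hi)

ref_peptide <- function(t) translate_nt(cds_sequence(t), to_first_stop = TRUE)

#' Read a transcript model from a compact exon TSV
#'
#' One row per exon with columns `start` and `end`; transcript-level fields
#' are given as arguments. This is the test/fixture format; see
#' [read_transcript_gff()] for GFF3 input.
#'
#' @inheritParams transcript_model
#' @param path TSV file with columns `start`, `end`.
#' @return A `transcript_model`.
#' @export
read_transcript_tsv <- function(path, id, contig, strand, cds_start, cds_end,
                                sequence = NULL, contig_seq = NULL) {
  exons <- utils::read.delim(path, stringsAsFactors = FALSE)
  transcript_model(id, contig, strand, exons, cds_start, cds_end,
                   sequence = sequence, contig_seq = contig_seq)
}

#' Read a transcript model from GFF3 exon/CDS features plus a FASTA contig
#'
#' Reads a GFF3 subset containing `exon` and `CDS` features for a single
#' transcript and a FASTA file holding the contig sequence.
#'
#' @param gff Path to a GFF3 file with `exon` and `CDS` rows for one
#'   transcript.
#' @param fasta Path to a FASTA file whose first record is the contig.
#' @param id Transcript id; defaults to the first `ID`/`Parent` attribute.
#' @return A `transcript_model`.
#' @export
read_transcript_gff <- function(gff, fasta, id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_transcript_gff requires the 'rtracklayer' package")
  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  exons <- df[tolower(df$type) == "exon", ]
  cds <- df[toupper(df$type) == "CDS", ]
  if (!nrow(exons) || !nrow(cds))
    stop("GFF must contain exon and CDS features")
  fa <- Biostrings::readDNAStringSet(fasta)
  contig_seq <- as.character(fa[[1]])
  if (is.null(id)) {
    id <- if (!is.null(exons$ID) && !all(is.na(exons$ID))) exons$ID[1]
          else if (!is.null(exons$Parent)) as.character(unlist(exons$Parent))[1]
          else "transcript"
  }
  transcript_model(id = id,
                   contig = as.character(exons$seqnames[1]),
                   strand = as.character(exons$strand[1]),
                   exons = exons[, c("start", "end")],
                   cds_start = min(cds$start), cds_end = max(cds$end),
                   contig_seq = contig_seq)
}

# reverse complement of a plain character string (ACGTN alphabet)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
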