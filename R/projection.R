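# Coordinate projection: genomic positions and edits -> HGVS-style c. frame.
#
# All naming follows the HGVS convention of left-aligning an indel and then
# shifting it to the 3'-most equivalent position on the transcript strand;
# shifting is done in spliced-transcript space so it crosses exon junctions
# correctly.

# transcript-order exon table with transcript coordinates and intron spans
exon_frame <- function(t) {
  n <- nrow(t$exons)
  ord <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  widths <- (t$exons$end - t$exons$start + 1L)[ord]
  t_end <- cumsum(widths)
  t_start <- c(1L, utils::head(t_end, -1L) + 1L)
  data.frame(genomic_idx = ord,
             gstart = t$exons$start[ord], gend = t$exons$end[ord],
             t_start = t_start, t_end = t_end)
}

# introns in transcript order; donor = transcript-5' end of the intron
intron_frame <- function(t) {
  ef <- exon_frame(t)
  n <- nrow(ef)
  if (n < 2) return(NULL)
  up <- ef[-n, ]; down <- ef[-1, ]
  if (t$strand == "+") {
    data.frame(gstart = up$gend + 1L, gend = down$gstart - 1L,
               donor_edge_g = up$gend, acceptor_edge_g = down$gstart,
               donor_anchor_t = up$t_end, acceptor_anchor_t = down$t_start,
               step = 1L)
  } else {
    data.frame(gstart = down$gend + 1L, gend = up$gstart - 1L,
               donor_edge_g = up$gstart, acceptor_edge_g = down$gend,
               donor_anchor_t = up$t_end, acceptor_anchor_t = down$t_start,
               step = -1L)
  }
}

# c.-frame label of a transcript coordinate
cds_label <- function(t, tpos) {
  ifelse(tpos < t$cds_lo, paste0("-", t$cds_lo - tpos),
         ifelse(tpos > t$cds_hi, paste0("*", tpos - t$cds_hi),
                as.character(tpos - t$cds_lo + 1L)))
}

coordinate_kind <- function(t, tpos) {
  if (tpos < t$cds_lo) "utr5" else if (tpos > t$cds_hi) "utr3" else "cds"
}

# descriptor for a single genomic position
cds_coordinate <- function(t, gpos) {
  tpos <- g2t(t, gpos)
  if (!is.na(tpos)) {
    kind <- coordinate_kind(t, tpos)
    return(structure(list(kind = kind, label = cds_label(t, tpos),
                          tpos = tpos, gpos = gpos,
                          cds_pos = if (kind == "cds") tpos - t$cds_lo + 1L else NA_integer_,
                          offset = 0L),
                     class = "cds_coordinate"))
  }
  intr <- intron_frame(t)
  if (!is.null(intr)) {
    hit <- which(intr$gstart <= gpos & gpos <= intr$gend)
    if (length(hit)) {
      i <- intr[hit[1], ]
      d_donor <- abs(gpos - i$donor_edge_g)
      d_acceptor <- abs(i$acceptor_edge_g - gpos)
      if (d_donor <= d_acceptor) {
        lab <- paste0(cds_label(t, i$donor_anchor_t), "+", d_donor)
        anchor <- i$donor_anchor_t; off <- d_donor
      } else {
        lab <- paste0(cds_label(t, i$acceptor_anchor_t), "-", d_acceptor)
        anchor <- i$acceptor_anchor_t; off <- -d_acceptor
      }
      return(structure(list(kind = "intron", label = lab, tpos = anchor,
                            gpos = gpos, cds_pos = NA_integer_, offset = off),
                       class = "cds_coordinate"))
    }
  }
  structure(list(kind = "outside", label = "outside", tpos = NA_integer_,
                 gpos = gpos, cds_pos = NA_integer_, offset = NA_integer_),
            class = "cds_coordinate")
}

#' @export
print.cds_coordinate <- function(x, ...) {
  cat(sprintf("c.%s [%s]\n", x$label, x$kind))
  invisible(x)
}

# 3'-shift a pure deletion (tstart, length k) on sequence seq; returns new tstart
shift3_deletion <- function(seq, tstart, k) {
  L <- nchar(seq)
  while (tstart + k <= L &&
         substr(seq, tstart + k, tstart + k) == substr(seq, tstart, tstart)) {
    tstart <- tstart + 1L
  }
  tstart
}

# 3'-shift an insertion of `ins` before position p; returns list(p, ins)
shift3_insertion <- function(seq, p, ins) {
  L <- nchar(seq)
  while (p <= L && substr(seq, p, p) == substr(ins, 1, 1)) {
    ins <- paste0(substr(ins, 2, nchar(ins)), substr(seq, p, p))
    p <- p + 1L
  }
  list(p = p, ins = ins)
}

# Map a variant's minimal edit into transcript space.
# Returns a list with:
#   status: "exonic", "intronic", "junction", "outside"
#   type:   "sub", "del", "ins", "delins" (exonic only)
#   tstart: first affected transcript coordinate (for "ins": insertion is
#           immediately BEFORE tstart), 3'-normalised
#   del, ins: transcript-strand deleted/inserted sequences (post-normalisation)
#   span_g: affected genomic positions (deletion/substitution span; for an
#           insertion the two flanking positions)
#   cds_del_len: number of deleted bases falling in the CDS (junction calls)
map_edit <- function(t, v) {
  me <- min_edit(v)
  tx_span <- range(t$exons$start, t$exons$end)
  minus <- t$strand == "-"

  if (nchar(me$ref) > 0) {                      # substitution or deletion
    span_g <- me$pos:(me$pos + nchar(me$ref) - 1L)
    tmap <- g2t(t, span_g)
    if (all(is.na(tmap))) {
      if (all(span_g < tx_span[1] | span_g > tx_span[2]))
        return(list(status = "outside", span_g = span_g))
      return(list(status = "intronic", span_g = span_g))
    }
    if (any(is.na(tmap))) {
      in_cds <- !is.na(tmap) & tmap >= t$cds_lo & tmap <= t$cds_hi
      return(list(status = "junction", span_g = span_g,
                  cds_del_len = sum(in_cds), ins = if (minus) revcomp(me$alt) else me$alt))
    }
    tstart <- min(tmap)
    k <- nchar(me$ref)
    del <- substr(t$sequence, tstart, tstart + k - 1L)
    ins <- if (nchar(me$alt)) { if (minus) revcomp(me$alt) else me$alt } else ""
    if (nchar(ins) == 0) {                      # pure deletion: 3'-shift
      tstart <- shift3_deletion(t$sequence, tstart, k)
      del <- substr(t$sequence, tstart, tstart + k - 1L)
      type <- "del"
    } else if (k == 1 && nchar(ins) == 1) {
      type <- "sub"
    } else type <- "delins"
    return(list(status = "exonic", type = type, tstart = tstart,
                del = del, ins = ins, span_g = span_g))
  }

  # insertion before genomic position me$pos
  gleft <- me$pos - 1L; gright <- me$pos
  tl <- g2t(t, gleft); tr <- g2t(t, gright)
  span_g <- c(gleft, gright)
  ins <- if (minus) revcomp(me$alt) else me$alt
  if (!is.na(tl) && !is.na(tr) && abs(tl - tr) == 1L) {
    p <- max(tl, tr)
    sh <- shift3_insertion(t$sequence, p, ins)
    return(list(status = "exonic", type = "ins", tstart = sh$p,
                del = "", ins = sh$ins, span_g = span_g))
  }
  if (all(span_g < tx_span[1]) || all(span_g > tx_span[2]))
    return(list(status = "outside", span_g = span_g))
  list(status = "intronic", type = "ins", span_g = span_g, ins = ins)
}

#' Project a variant (or position) into the coding coordinate frame
#'
#' Maps a genomic position, or the left-aligned then 3'-shifted start of a
#' variant's edit, onto HGVS-style c. coordinates: CDS offsets for coding
#' positions, `-n` / `*n` for UTRs, `anchor+off` / `anchor-off` for intronic
#' positions relative to the nearest exon boundary, and an `"outside"`
#' descriptor beyond the transcript span. Reverse-strand transcripts are
#' handled by reverse complementation of the edit.
#'
#' @param t A [transcript_model()].
#' @param v A [variant_record()] or a single genomic position.
#' @return A `"cds_coordinate"`: list with `kind`
#'   (`cds`/`utr5`/`utr3`/`intron`/`outside`), `label` (e.g. `"4"`,
#'   `"9+2"`), `tpos`, `cds_pos`, `offset`.
#' @examples
#' tx <- transcript_model("TX1", "chr1", "+",
#'                        exons = data.frame(start = 101, end = 109),
#'                        cds_start = 101, cds_end = 109,
#'                        sequence = "ATGAAATAG")
#' project_to_cds(tx, 104)$label    # "4"
#' @export
project_to_cds <- function(t, v) {
  if (is.numeric(v)) {
    stopifnot(length(v) == 1)
    return(cds_coordinate(t, as.integer(v)))
  }
  stopifnot(inherits(v, "variant_record"))
  if (!identical(v$contig, t$contig))
    stop("variant contig does not match transcript contig")
  ed <- map_edit(t, v)
  if (ed$status == "exonic") {
    return(cds_coordinate(t, t2g(t, ed$tstart)))
  }
  if (ed$status %in% c("intronic", "junction")) {
    # describe the transcript-5'-most affected genomic position
    gps <- ed$span_g
    cands <- lapply(gps, cds_coordinate, t = t)
    # prefer an intronic descriptor when any position is intronic
    introny <- vapply(cands, function(x) x$kind == "intron", logical(1))
    if (any(introny)) return(cands[[which(introny)[1]]])
    return(cands[[1]])
  }
  cds_coordinate(t, ed$span_g[1])
}
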