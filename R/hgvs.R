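# HGVS coding (c.) and protein (p.) nomenclature.
#
# c. names use the 3'-most representation on the transcript strand; an
# insertion identical to the immediately preceding base(s) is written as a
# duplication (dup takes precedence over ins). Frameshift protein names use
# p.<First><pos><New>fsTer<k>, where k counts codons from the first changed
# residue (inclusive, so a stop arising k-1 codons downstream gives fsTer<k>;
# a stop at the changed residue itself is written as a plain substitution to
# Ter, the k = 1 case of the same count).

strand_base <- function(t, base) if (t$strand == "-") revcomp(base) else base

#' Generate HGVS c. and p. names for a classified variant
#'
#' Usually called through [classify_consequence()], which passes its own
#' edit/translation context; can be called directly with a bare call.
#'
#' @param t A [transcript_model()].
#' @param v A [variant_record()].
#' @param call A `"consequence_call"` (from [classify_consequence()]).
#' @param ctx Internal context (edit mapping and translation) computed by
#'   the classifier; recomputed when absent.
#' @return Named character vector with elements `hgvs_c` and `hgvs_p`.
#' @export
hgvs_name <- function(t, v, call, ctx = NULL) {
  if (is.null(ctx)) {
    ed <- map_edit(t, v)
    ctx <- list(edit = ed)
    if (ed$status == "exonic")
      ctx$res <- apply_tx_edit(t, ed$tstart, ed$del, ed$ins)
  }
  c(hgvs_c = hgvs_c_name(t, v, ctx),
    hgvs_p = hgvs_p_name(t, v, call, ctx))
}

hgvs_c_name <- function(t, v, ctx) {
  ed <- ctx$edit
  seq <- t$sequence
  if (ed$status == "exonic") {
    p <- ed$tstart
    if (ed$type == "sub")
      return(paste0("c.", cds_label(t, p), ed$del, ">", ed$ins))
    if (ed$type == "del") {
      k <- nchar(ed$del)
      if (k == 1) return(paste0("c.", cds_label(t, p), "del"))
      return(paste0("c.", cds_label(t, p), "_",
                    cds_label(t, p + k - 1L), "del"))
    }
    if (ed$type == "ins") {
      m <- nchar(ed$ins)
      if (p - m >= 1 && substr(seq, p - m, p - 1L) == ed$ins) {
        if (m == 1) return(paste0("c.", cds_label(t, p - 1L), "dup"))
        return(paste0("c.", cds_label(t, p - m), "_",
                      cds_label(t, p - 1L), "dup"))
      }
      return(paste0("c.", cds_label(t, p - 1L), "_", cds_label(t, p),
                    "ins", ed$ins))
    }
    # delins
    k <- nchar(ed$del)
    lab <- if (k == 1) cds_label(t, p)
           else paste0(cds_label(t, p), "_", cds_label(t, p + k - 1L))
    return(paste0("c.", lab, "delins", ed$ins))
  }

  # intronic / junction / outside: describe by per-position descriptors
  me <- min_edit(v)
  if (ed$status == "outside") return("c.?")
  if (nchar(me$ref) == 1 && nchar(me$alt) == 1) {
    d <- cds_coordinate(t, me$pos)
    return(paste0("c.", d$label, strand_base(t, me$ref), ">",
                  strand_base(t, me$alt)))
  }
  # range in transcript orientation
  gps <- if (nchar(me$ref)) c(me$pos, me$pos + nchar(me$ref) - 1L)
         else c(me$pos - 1L, me$pos)
  if (t$strand == "-") gps <- rev(gps)
  labs <- vapply(gps, function(g) cds_coordinate(t, g)$label, character(1))
  ins_t <- strand_base(t, me$alt)
  if (nchar(me$alt) == 0)
    return(paste0("c.", labs[1], "_", labs[2], "del"))
  if (nchar(me$ref) == 0)
    return(paste0("c.", labs[1], "_", labs[2], "ins", ins_t))
  paste0("c.", labs[1], "_", labs[2], "delins", ins_t)
}

hgvs_p_name <- function(t, v, call, ctx) {
  cons <- call$consequence
  if (cons %in% c("canonical_splice", "intronic", "utr"))
    return("p.?")
  if (cons == "start_loss") return("p.Met1?")
  res <- ctx$res
  if (is.null(res)) return("p.?")
  rp <- ref_peptide(t)
  N <- nchar(rp)
  ap <- res$peptide
  s_alt <- if (endsWith(ap, "*")) nchar(ap) else NA_integer_

  aa_at <- function(pep, i) substr(pep, i, i)

  if (cons == "stop_gain") {
    i <- s_alt
    return(paste0("p.", aa3(aa_at(rp, i)), i, "Ter"))
  }
  if (cons == "frameshift") {
    i <- first_diff(rp, ap)
    if (is.na(i)) i <- min(N, nchar(ap)) + 1L
    ref_aa <- if (i <= N) aa3(aa_at(rp, i)) else "Ter"
    new_aa1 <- if (i <= nchar(ap)) aa_at(ap, i) else ""
    if (identical(new_aa1, "*"))
      return(paste0("p.", ref_aa, i, "Ter"))
    new_aa <- if (nzchar(new_aa1)) aa3(new_aa1) else ""
    if (is.na(s_alt)) {
      warning("frameshift without downstream stop codon before transcript end")
      return(paste0("p.", ref_aa, i, new_aa, "fsTer?"))
    }
    k <- s_alt - i + 1L
    return(paste0("p.", ref_aa, i, new_aa, "fsTer", k))
  }
  if (cons == "missense") {
    i <- first_diff(rp, ap)
    return(paste0("p.", aa3(aa_at(rp, i)), i, aa3(aa_at(ap, i))))
  }
  if (cons == "synonymous") {
    ci <- (ctx$edit$tstart - t$cds_lo) %/% 3L + 1L
    ci <- min(max(ci, 1L), N)
    return(paste0("p.", aa3(aa_at(rp, ci)), ci, "="))
  }
  if (cons == "stop_loss") {
    new_aa1 <- aa_at(ap, N)
    ext <- if (!is.na(s_alt)) s_alt - N else NA_integer_
    return(paste0("p.Ter", N, aa3(new_aa1), "extTer",
                  if (is.na(ext)) "?" else ext))
  }
  if (cons == "inframe_indel") {
    # trim matching prefix/suffix of the peptides, then describe the middle
    tr <- trim_peptides(rp, ap)
    if (is.null(tr)) return("p.?")
    i <- tr$i; j <- tr$j
    if (!nzchar(tr$alt_mid)) {                     # pure residue deletion
      if (j == i) return(paste0("p.", aa3(aa_at(rp, i)), i, "del"))
      return(paste0("p.", aa3(aa_at(rp, i)), i, "_",
                    aa3(aa_at(rp, j)), j, "del"))
    }
    if (!nzchar(tr$ref_mid)) {                     # pure residue insertion
      return(paste0("p.", aa3(aa_at(rp, i - 1L)), i - 1L, "_",
                    aa3(aa_at(rp, i)), i, "ins",
                    paste(vapply(strsplit(tr$alt_mid, "")[[1]], aa3, ""),
                          collapse = "")))
    }
    lab <- if (j == i) paste0(aa3(aa_at(rp, i)), i)
           else paste0(aa3(aa_at(rp, i)), i, "_", aa3(aa_at(rp, j)), j)
    return(paste0("p.", lab, "delins",
                  paste(vapply(strsplit(tr$alt_mid, "")[[1]], aa3, ""),
                        collapse = "")))
  }
  "p.?"
}

first_diff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    av <- strsplit(substr(a, 1, n), "")[[1]]
    bv <- strsplit(substr(b, 1, n), "")[[1]]
    d <- which(av != bv)
    if (length(d)) return(d[1])
  }
  if (nchar(a) != nchar(b)) return(n + 1L)
  NA_integer_
}

# matching prefix/suffix trim of ref/alt peptides; returns ref/alt middles
# and the 1-based ref interval [i, j] they replace
trim_peptides <- function(rp, ap) {
  i <- first_diff(rp, ap)
  if (is.na(i)) return(NULL)
  # common suffix length (not overlapping the prefix)
  rn <- nchar(rp); an <- nchar(ap)
  s <- 0L
  while (s < rn - i + 1L && s < an - i + 1L &&
         substr(rp, rn - s, rn - s) == substr(ap, an - s, an - s)) s <- s + 1L
  list(i = i, j = rn - s,
       ref_mid = substr(rp, i, rn - s),
       alt_mid = substr(ap, i, an - s))
}

#' Parse an HGVS c. name back into a transcript-space edit
#'
#' Supports substitutions, `del`, `dup`, `ins` and `delins` forms with CDS,
#' UTR (`-n`, `*n`) and intronic (`+n` / `-n` offset) positions. The
#' returned edit is in spliced-transcript coordinates for exonic forms and
#' genomic coordinates for intronic substitutions.
#'
#' @param t A [transcript_model()].
#' @param name An HGVS c. string, e.g. `"c.3580dup"` or `"c.3965+2T>G"`.
#' @return For exonic forms, list with `tstart`, `del`, `ins`
#'   (transcript-space, 3'-normalised by construction of the name); for
#'   intronic substitutions, list with `gpos`, `ref`, `alt` (genomic forward
#'   strand).
#' @export
parse_hgvs_c <- function(t, name) {
  x <- sub("^c\\.", "", name)
  pos_re <- "(\\*?-?[0-9]+(?:[+-][0-9]+)?)"

  lab2t <- function(lab) {
    # returns list(tpos, offset): offset != 0 means intronic
    m <- regmatches(lab, regexec("^(\\*?-?[0-9]+)([+-][0-9]+)?$", lab, perl = TRUE))[[1]]
    base <- m[2]; off <- m[3]
    tpos <- if (startsWith(base, "*")) t$cds_hi + as.integer(substr(base, 2, nchar(base)))
            else if (startsWith(base, "-")) t$cds_lo - as.integer(substr(base, 2, nchar(base)))
            else t$cds_lo + as.integer(base) - 1L
    list(tpos = tpos, offset = if (nzchar(off) && !is.na(off)) as.integer(off) else 0L)
  }

  m <- regmatches(x, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"), x, perl = TRUE))[[1]]
  if (length(m)) {                               # substitution
    loc <- lab2t(m[2])
    if (loc$offset == 0L)
      return(list(tstart = loc$tpos, del = m[3], ins = m[4]))
    # intronic: genomic position = anchor exon edge +/- offset along strand
    ganchor <- t2g(t, loc$tpos)
    step <- if (t$strand == "+") 1L else -1L
    gpos <- ganchor + step * loc$offset
    return(list(gpos = gpos, ref = strand_base(t, m[3]),
                alt = strand_base(t, m[4])))
  }

  m <- regmatches(x, regexec(paste0("^", pos_re, "(?:_", pos_re, ")?",
                                    "(del|dup)(?:ins([ACGT]+))?$"), x))[[1]]
  if (length(m)) {
    a <- lab2t(m[2])$tpos
    b <- if (nzchar(m[3])) lab2t(m[3])$tpos else a
    kind <- m[4]; insseq <- m[5]
    if (kind == "del" && !nzchar(insseq))
      return(list(tstart = a, del = substr(t$sequence, a, b), ins = ""))
    if (kind == "del")                            # delins
      return(list(tstart = a, del = substr(t$sequence, a, b), ins = insseq))
    # dup: insertion of seq [a..b] before b+1
    dup <- substr(t$sequence, a, b)
    return(list(tstart = b + 1L, del = "", ins = dup))
  }

  m <- regmatches(x, regexec(paste0("^", pos_re, "_", pos_re,
                                    "ins([ACGT]+)$"), x))[[1]]
  if (length(m)) {
    b <- lab2t(m[3])$tpos
    return(list(tstart = b, del = "", ins = m[4]))
  }
  stop("unsupported HGVS c. form: ", name)
}
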