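# Independent oracles for the consequence engine, implemented from scratch
# (exhaustive position scans, direct string surgery, Biostrings translation)
# so they share no code path with the package internals they check.

# genomic position of transcript index i, by brute-force enumeration
oracle_tx_positions <- function(t) {
  gp <- unlist(mapply(seq, t$exons$start, t$exons$end, SIMPLIFY = FALSE))
  if (t$strand == "-") rev(gp) else gp
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_strand_seq <- function(t, s) if (t$strand == "-") oracle_revcomp(s) else s

# spliced sequence rebuilt from the contig, independent of t$sequence
oracle_spliced <- function(t) {
  s <- paste(substring(t$contig_seq, t$exons$start, t$exons$end),
             collapse = "")
  oracle_strand_seq(t, s)
}

# translation to (and including) the first stop, via Biostrings
oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, 3L * n)), no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at) else aa
}

# trim a VCF-style variant to its minimal edit (suffix then prefix)
oracle_trim <- function(pos, ref, alt) {
  while (nchar(ref) && nchar(alt) &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1); alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) && nchar(alt) && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# canonical splice dinucleotide positions, recomputed by direct arithmetic
oracle_canonical <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - 1)) {
    gstart <- t$exons$end[i] + 1L; gend <- t$exons$start[i + 1] - 1L
    out <- c(out, gstart, gstart + 1L, gend - 1L, gend)
  }
  out
}

# independent PTV predicate and class facts for a single-exon-contained edit
# or intronic SNV. Returns list(canonical, cds_overlap, net, premature_stop).
oracle_facts <- function(t, v) {
  me <- oracle_trim(v$pos, v$ref, v$alt)
  gp <- oracle_tx_positions(t)
  spliced <- oracle_spliced(t)
  cds_lo <- match(if (t$strand == "+") t$cds_start else t$cds_end, gp)
  cds_hi <- match(if (t$strand == "+") t$cds_end else t$cds_start, gp)
  ref_prot <- oracle_translate(substr(spliced, cds_lo, cds_hi))
  ref_n <- nchar(ref_prot)

  span <- if (nchar(me$ref)) me$pos:(me$pos + nchar(me$ref) - 1L)
          else c(me$pos - 1L, me$pos)
  canonical <- any(span %in% oracle_canonical(t))

  idx <- match(span, gp)
  if (any(is.na(idx))) {                 # intronic (single-exon domain assumed)
    return(list(canonical = canonical, cds_overlap = FALSE, net = 0L,
                premature_stop = FALSE))
  }
  ins_t <- if (nchar(me$alt)) oracle_strand_seq(t, me$alt) else ""
  if (nchar(me$ref)) {                   # substitution / deletion
    lo <- min(idx); hi <- max(idx)
    edited <- paste0(substr(spliced, 1, lo - 1L), ins_t,
                     substr(spliced, hi + 1L, nchar(spliced)))
    net <- nchar(ins_t) - (hi - lo + 1L)
    cds_overlap <- lo <= cds_hi && hi >= cds_lo
    edit_lo <- lo
  } else {                               # insertion between the two indices
    p <- max(idx)
    edited <- paste0(substr(spliced, 1, p - 1L), ins_t,
                     substr(spliced, p, nchar(spliced)))
    net <- nchar(ins_t)
    cds_overlap <- p > cds_lo && p <= cds_hi
    edit_lo <- p
  }
  cds_lo2 <- if (edit_lo < cds_lo && (edit_lo + max(0L, nchar(me$ref)) - 1L) < cds_lo)
    cds_lo + net else cds_lo
  alt_prot <- oracle_translate(substr(edited, cds_lo2, nchar(edited)))
  s_alt <- if (endsWith(alt_prot, "*")) nchar(alt_prot) else Inf
  expected <- ref_n + net / 3
  list(canonical = canonical, cds_overlap = cds_overlap, net = net,
       premature_stop = cds_overlap && net %% 3 == 0 && s_alt < expected,
       alt_prot = alt_prot, ref_prot = ref_prot)
}

oracle_is_ptv <- function(t, v) {
  f <- oracle_facts(t, v)
  f$canonical || (f$cds_overlap && f$net %% 3 != 0) || f$premature_stop
}

# random edits confined to one exon (or intronic SNVs), avoiding the start
# and stop codons whose start-loss/stop-loss semantics are out of the
# truncation predicate's domain
random_edit <- function(t, max_len = 4L) {
  gp <- oracle_tx_positions(t)
  avoid <- gp[c((t$cds_lo):(t$cds_lo + 2L), (t$cds_hi - 2L):(t$cds_hi))]
  repeat {
    g <- sample(min(t$exons$start):max(t$exons$end), 1)
    type <- sample(c("snv", "del", "ins"), 1, prob = c(0.5, 0.25, 0.25))
    exonic <- function(x) !is.na(match(x, gp))
    if (type == "snv") {
      if (g %in% avoid) next
      ref <- substr(t$contig_seq, g, g)
      return(variant_record(t$contig, g, ref,
                            sample(setdiff(c("A", "C", "G", "T"), ref), 1)))
    }
    if (!exonic(g) || !exonic(g - 1L)) next          # keep indels exonic
    if (type == "del") {
      len <- sample.int(max_len, 1)
      if (!exonic(g + len - 1L)) next
      if (any((g - 1L):(g + len - 1L) %in% avoid)) next
      ex <- which(t$exons$start <= g & g <= t$exons$end)
      if (g + len - 1L > t$exons$end[ex]) next       # single-exon domain
      return(variant_record(t$contig, g - 1L,
                            substr(t$contig_seq, g - 1L, g + len - 1L),
                            substr(t$contig_seq, g - 1L, g - 1L)))
    }
    if (g %in% avoid || (g - 1L) %in% avoid) next
    ins <- paste(sample(c("A", "C", "G", "T"), sample.int(max_len, 1),
                        replace = TRUE), collapse = "")
    anchor <- substr(t$contig_seq, g - 1L, g - 1L)
    return(variant_record(t$contig, g - 1L, anchor, paste0(anchor, ins)))
  }
}

first_mismatch <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d)) d[1] else n + 1L
}
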