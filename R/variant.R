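#' Construct a variant record
#'
#' A single genomic variant in VCF convention: 1-based position, REF and ALT
#' allele strings which may share a leading anchor base for indels.
#'
#' @param contig Contig name.
#' @param pos 1-based genomic position of the first REF base.
#' @param ref,alt Non-empty allele strings; must differ.
#' @param id Optional label. Defaults to the `chrom-pos-ref-alt` token.
#' @return An object of class `"variant_record"`.
#' @examples
#' variant_record("15", 85401543, "T", "TC")
#' parse_variant_token("15-85401543-T-TC")
#' @export
variant_record <- function(contig, pos, ref, alt, id = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt))
    stop("ref and alt must be non-empty")
  if (identical(ref, alt))
    stop("ref and alt must differ")
  if (pos < 1) stop("pos must be >= 1")
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
    stop("alleles must be ACGTN strings")
  if (is.null(id)) id <- paste(contig, pos, ref, alt, sep = "-")
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref = ref, alt = alt, id = id),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("Variant %s:%d %s>%s (%s)\n", x$contig, x$pos, x$ref, x$alt, x$id))
  invisible(x)
}

#' Parse a `chrom-pos-ref-alt` variant token
#'
#' @param token Character vector of tokens such as `"15-85401543-T-TC"`.
#' @return A `variant_record` (or list of them for a vector input).
#' @export
parse_variant_token <- function(token) {
  parse1 <- function(s) {
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) != 4)
      stop("malformed variant token: ", s)
    variant_record(parts[1], as.integer(parts[2]), parts[3], parts[4])
  }
  if (length(token) == 1) parse1(token) else lapply(token, parse1)
}

# minimal edit representation: trim shared suffix then shared prefix.
# After trimming, ref == "" means an insertion immediately before `pos`;
# alt == "" means deletion of ref at pos..pos+nchar(ref)-1.
min_edit <- function(v) {
  pos <- v$pos; ref <- v$ref; alt <- v$alt
  while (nchar(ref) && nchar(alt) &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) && nchar(alt) && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Decompose multi-allelic VCF records into biallelic variant records
#'
#' Sites with comma-separated ALT alleles are split into one record per
#' alternate allele, all sharing CHROM/POS/REF.
#'
#' @param contig,pos,ref Site fields.
#' @param alt ALT field, possibly `"A,AT"`.
#' @return List of `variant_record`s.
#' @export
decompose_multiallelic <- function(contig, pos, ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  lapply(alts, function(a) variant_record(contig, pos, ref, a))
}

#' Read the sites columns of a VCF into variant records
#'
#' Uses \pkg{vcfR} for parsing; multi-allelic sites are decomposed into
#' biallelic records.
#'
#' @param path Path to a (plain-text or bgzipped) VCF file.
#' @return List of `variant_record`s, in file order (alternates of one site
#'   adjacent).
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    out <- c(out, decompose_multiallelic(fix[i, "CHROM"],
                                         as.integer(fix[i, "POS"]),
                                         fix[i, "REF"], fix[i, "ALT"]))
  }
  out
}
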