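#' Construct a table of structural variant records
#'
#' SVs are represented as a plain data.frame with 0-based half-open reference
#' coordinates (`start` inclusive, `end` exclusive): the footprint of the
#' event on the reference. For insertions `start == end` (the insertion
#' point) and `inserted_seq` carries the inserted sequence.
#'
#' @param id character identifiers (unique).
#' @param chrom contig names.
#' @param start,end 0-based half-open footprint on the reference.
#' @param svtype one of `"DEL"`, `"INS"`, `"INV"`.
#' @param inserted_seq inserted sequence for INS (empty string otherwise).
#' @return data.frame of class `sv_records`.
#' @export
sv_records <- function(id, chrom, start, end, svtype, inserted_seq = "") {
  svtype <- toupper(as.character(svtype))
  bad <- !svtype %in% c("DEL", "INS", "INV")
  if (any(bad)) stop("unsupported svtype: ", paste(unique(svtype[bad]), collapse = ", "))
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   svtype = svtype,
                   inserted_seq = toupper(as.character(inserted_seq)),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("start > end")
  if (any(df$svtype == "INS" & df$start != df$end))
    stop("INS records must have start == end (insertion point)")
  if (anyDuplicated(df$id)) stop("duplicate SV ids")
  class(df) <- c("sv_records", "data.frame")
  df
}

GENOTYPES <- c("0/0", "0/1", "1/1")

#' Alternate-haplotype sequence around an SV
#'
#' Splices the alternate allele out of the reference: for a deletion the two
#' flanks are joined; for an insertion the inserted sequence is placed between
#' them; for an inversion the footprint is reverse-complemented in place.
#' Flanks are truncated at contig edges.
#'
#' @param ref_seq the contig sequence (single string) carrying the SV.
#' @param sv one row of an [sv_records()] table.
#' @param flank number of reference bases kept on each side of the event;
#'   must be at least k-1 for junction k-mers to exist.
#' @param k k-mer length used to validate `flank` (optional).
#' @return a single DNA string.
#' @export
alt_haplotype_window <- function(ref_seq, sv, flank, k = NULL) {
  stopifnot(nrow(sv) == 1L)
  if (!is.null(k) && flank < k - 1)
    stop("flank must be >= k-1 (junction k-mers would be impossible)")
  n <- nchar(ref_seq)
  s <- sv$start; e <- sv$end
  if (s < 0 || e > n) stop("SV coordinates outside the contig")
  left <- substr(ref_seq, max(1L, s - flank + 1L), s)            # ref[s-flank, s)
  right <- substr(ref_seq, e + 1L, min(n, e + flank))            # ref[e, e+flank)
  mid <- switch(sv$svtype,
    DEL = "",
    INS = sv$inserted_seq,
    INV = revcomp(substr(ref_seq, s + 1L, e)),
    stop("unsupported svtype: ", sv$svtype))
  paste0(left, mid, right)
}

#' Expected diploid copy number of a k-mer per genotype
#'
#' Each SV raises the copy number of k-mers that exist only on the alternate
#' haplotype (junction k-mers, insertion-internal k-mers) and lowers the copy
#' number of k-mers destroyed by the event (deleted sequence, reference
#' breakpoint windows). Alt-derived k-mers have 0/1/2 copies under genotypes
#' 0/0, 0/1, 1/1; reference-derived k-mers mirror this with 2/1/0.
#'
#' @param role one of `"inner_alt"`, `"inner_ref"`, `"junction_alt"`,
#'   `"junction_ref"`.
#' @param svtype SV type, used to reject impossible combinations
#'   (`inner_ref` only makes sense for DEL, `inner_alt` only for INS).
#' @return named numeric vector `c("0/0"=, "0/1"=, "1/1"=)` of diploid copies.
#' @export
expected_copy_table <- function(role, svtype) {
  role <- match.arg(role, c("inner_alt", "inner_ref", "junction_alt", "junction_ref"))
  svtype <- toupper(svtype)
  if (role == "inner_ref" && svtype != "DEL")
    stop("inner_ref k-mers exist only for deletions")
  if (role == "inner_alt" && svtype != "INS")
    stop("inner_alt k-mers exist only for insertions")
  if (endsWith(role, "_alt")) {
    c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  } else {
    c("0/0" = 2, "0/1" = 1, "1/1" = 0)
  }
}
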