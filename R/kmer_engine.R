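#' @useDynLib svkmer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rbinom rnorm runif var
#' @importFrom utils read.table write.table
NULL

#' Encode a k-mer as a packed integer
#'
#' Packs a DNA string into an integer with 2 bits per base (A=0, C=1, G=2,
#' T=3), most-significant bits first. Numeric (double) return values are exact
#' for k up to 26; the counting engine itself works on 64-bit codes internally
#' and supports k up to 32 through the sequence-level interface
#' ([canonical_kmer()], [kmer_index()]).
#'
#' @param seq character vector of DNA strings (case-insensitive), each of
#'   length 1--26.
#' @return numeric vector of packed codes; `NA` where the k-mer contains an
#'   ambiguous base (anything outside A/C/G/T), so callers can skip the window.
#' @examples
#' encode_kmer(c("AAAA", "ACGT", "GAT")) # 0, 27, 35
#' @export
encode_kmer <- function(seq) {
  .encode_kmer(as.character(seq))
}

#' Decode a packed k-mer code back to its DNA string
#'
#' @param code numeric vector of packed codes (see [encode_kmer()]).
#' @param k k-mer length, 1--26.
#' @return character vector of DNA strings.
#' @examples
#' decode_kmer(27, 4) # "ACGT"
#' @export
decode_kmer <- function(code, k) {
  .decode_kmer(as.numeric(code), as.integer(k))
}

#' Canonical form of a packed k-mer code
#'
#' The canonical code is the smaller, by integer value, of a code and the code
#' of its reverse complement. Canonicalization merges the two strands:
#' reads come from an unknown strand, so all counting is done on canonical
#' k-mers. Idempotent.
#'
#' @param code numeric vector of packed codes.
#' @param k k-mer length, 1--26 (numeric-code interface).
#' @return numeric vector of canonical codes.
#' @examples
#' canonical_code(encode_kmer("TTTT"), 4) # 0 == encode_kmer("AAAA")
#' @export
canonical_code <- function(code, k) {
  code <- as.numeric(code)
  pmin(code, .revcomp_code(code, as.integer(k)))
}

#' Canonical sequence form of k-mers
#'
#' Sequence-level canonicalization (supports k up to 32): returns whichever of
#' the k-mer and its reverse complement has the smaller packed-integer value.
#'
#' @param seq character vector of DNA strings (length 1--32 each).
#' @return character vector of canonical k-mers; `NA` for windows containing
#'   ambiguous bases.
#' @export
canonical_kmer <- function(seq) {
  .canonical_kmer(as.character(seq))
}

#' Reverse complement of DNA sequences
#'
#' @param seq character vector of DNA strings of any length.
#' @return character vector of reverse complements (case preserved; ambiguous
#'   characters pass through unchanged).
#' @export
revcomp <- function(seq) {
  .revcomp_seq(as.character(seq))
}

#' Build a k-mer index for counting
#'
#' Creates the lookup structure used by [scan_read()] and [count_reads()]:
#' a hash from canonical packed code to the panel entry carrying it, together
#' with the entry's stored left/right neighbor k-mers (the windows immediately
#' adjacent to it in the haplotype it was selected from). Neighbors drive the
#' verification rule that guards counts against spurious matches.
#'
#' @param kmers character vector of canonical k-mers, all the same length `k`
#'   (up to 32; production panels default to k = 32), unique.
#' @param neighbors optional list (same length) of character vectors of
#'   neighbor k-mers for each entry; entries with no neighbors are counted
#'   unconditionally. `NULL` means no neighbors anywhere.
#' @param k k-mer length; defaults to the length of the first k-mer.
#' @return an object of class `kmer_index`.
#' @export
kmer_index <- function(kmers, neighbors = NULL, k = nchar(kmers[[1]])) {
  kmers <- as.character(kmers)
  if (length(kmers) == 0L) stop("empty k-mer set")
  k <- as.integer(k)
  canon <- .canonical_kmer(kmers)
  if (anyNA(canon)) stop("ambiguous base in k-mer(s): ",
                         paste(utils::head(kmers[is.na(canon)], 3), collapse = ", "))
  if (anyDuplicated(canon)) stop("duplicate canonical k-mers in index")
  if (is.null(neighbors)) {
    neighbors <- rep(list(character(0)), length(kmers))
  } else {
    if (length(neighbors) != length(kmers)) stop("neighbors/kmers length mismatch")
    neighbors <- lapply(neighbors, function(x) {
      x <- as.character(x)
      x[!is.na(x) & nzchar(x)]
    })
  }
  ptr <- .kmer_index_build(canon, neighbors, k)
  structure(list(ptr = ptr, k = k, kmers = canon), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d canonical %d-mers\n", length(x$kmers), x$k))
  invisible(x)
}

#' Scan one read for indexed k-mers
#'
#' Slides a window of width `k` across the read, updating the packed code
#' incrementally, and reports every window whose canonical code is in the
#' index. With `verify_neighbors = TRUE` an occurrence is accepted only if an
#' adjacent window (one base left or one base right, in read orientation)
#' matches one of the entry's stored neighbors; adjacent windows that do not
#' exist within the read, or contain ambiguous bases, are not checkable, and
#' an occurrence with no checkable adjacent window is accepted (rejecting it
#' would bias counts at read ends). Windows containing ambiguous bases are
#' skipped silently.
#'
#' @param read_seq a single DNA string.
#' @param index a [kmer_index()].
#' @param verify_neighbors logical; apply the neighbor rule.
#' @return data.frame with columns `kmer` (canonical sequence) and `pos`
#'   (1-based window start) for each accepted occurrence.
#' @export
scan_read <- function(read_seq, index, verify_neighbors = TRUE) {
  stopifnot(inherits(index, "kmer_index"), length(read_seq) == 1L)
  .scan_read(index$ptr, as.character(read_seq), isTRUE(verify_neighbors))
}

#' Count panel k-mers in a set of reads
#'
#' Applies [scan_read()]'s acceptance rule across a character vector of reads
#' and accumulates per-k-mer occurrence counts. FASTQ mates and any other read
#' stream count identically; strand is irrelevant (canonical matching).
#'
#' @param reads character vector of read sequences.
#' @param index a [kmer_index()].
#' @param verify_neighbors logical; apply the neighbor verification rule.
#' @return named numeric vector of counts (names = canonical k-mers, in index
#'   order) with attribute `reads_processed`.
#' @export
count_reads <- function(reads, index, verify_neighbors = TRUE) {
  stopifnot(inherits(index, "kmer_index"))
  st <- .count_state_new(index$ptr)
  .count_sequences(index$ptr, st, as.character(reads), isTRUE(verify_neighbors))
  counts <- .count_state_counts(index$ptr, st)
  attr(counts, "reads_processed") <- .count_state_reads(st)
  counts
}

#' Count panel k-mers in FASTQ files
#'
#' Streams one or more FASTQ files (plain or gzip; e.g. the two mate files of
#' a paired-end run) in chunks and accumulates counts with the same acceptance
#' rule as [count_reads()]. No quality filtering is applied.
#'
#' @param files character vector of FASTQ paths.
#' @param index a [kmer_index()].
#' @param verify_neighbors logical; apply the neighbor verification rule.
#' @param chunk_size number of reads per chunk held in memory.
#' @return as [count_reads()].
#' @export
count_fastq <- function(files, index, verify_neighbors = TRUE,
                        chunk_size = 500000L) {
  stopifnot(inherits(index, "kmer_index"))
  st <- .count_state_new(index$ptr)
  nparsed <- 0
  for (f in files) {
    con <- gzfile(f, open = "rt")
    tryCatch({
      repeat {
        lines <- readLines(con, n = chunk_size * 4L)
        if (length(lines) == 0L) break
        nrec <- length(lines) %/% 4L
        if (nrec == 0L) break
        seqs <- lines[seq(2L, by = 4L, length.out = nrec)]
        .count_sequences(index$ptr, st, seqs, isTRUE(verify_neighbors))
        nparsed <- nparsed + nrec
        if (length(lines) < chunk_size * 4L) break
      }
    }, finally = close(con))
  }
  if (nparsed == 0) stop("no reads parsed from: ", paste(files, collapse = ", "))
  counts <- .count_state_counts(index$ptr, st)
  attr(counts, "reads_processed") <- .count_state_reads(st)
  counts
}

#' Count panel k-mers in a BAM file
#'
#' The BAM is treated purely as a read stream: only the sequence field is
#' used and alignment information is ignored, so counts are identical to
#' counting the FASTQ the BAM was made from (canonical matching absorbs the
#' reverse-complementing of minus-strand records).
#'
#' @param file BAM path.
#' @param index a [kmer_index()].
#' @param verify_neighbors logical; apply the neighbor verification rule.
#' @param chunk_size reads per chunk.
#' @return as [count_reads()].
#' @export
count_bam <- function(file, index, verify_neighbors = TRUE,
                      chunk_size = 500000L) {
  stopifnot(inherits(index, "kmer_index"))
  st <- .count_state_new(index$ptr)
  bf <- Rsamtools::BamFile(file, yieldSize = chunk_size)
  open(bf)
  on.exit(close(bf), add = TRUE)
  param <- Rsamtools::ScanBamParam(what = "seq")
  nparsed <- 0
  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1]]$seq
    if (length(res) == 0L) break
    .count_sequences(index$ptr, st, as.character(res), isTRUE(verify_neighbors))
    nparsed <- nparsed + length(res)
  }
  if (nparsed == 0) stop("no reads parsed from BAM: ", file)
  counts <- .count_state_counts(index$ptr, st)
  attr(counts, "reads_processed") <- .count_state_reads(st)
  counts
}

#' Count occurrences of k-mers in reference sequences
#'
#' Canonical, unverified occurrence counting of an arbitrary k-mer set over a
#' set of sequences (e.g. the reference genome or extracted footprint
#' windows). Used by the reference-occurrence filter and for picking unique
#' control k-mers.
#'
#' @param seqs character vector of sequences to scan.
#' @param kmers character vector of k-mers (need not be unique or canonical).
#' @param k k-mer length.
#' @return numeric vector, parallel to `kmers`, of total canonical occurrence
#'   counts over `seqs`.
#' @export
count_occurrences <- function(seqs, kmers, k = nchar(kmers[[1]])) {
  if (length(kmers) == 0L) return(numeric(0))
  canon <- .canonical_kmer(as.character(kmers))
  if (anyNA(canon)) stop("ambiguous base in query k-mers")
  uniq <- unique(canon)
  idx <- kmer_index(uniq, k = k)
  counts <- count_reads(as.character(seqs), idx, verify_neighbors = FALSE)
  unname(counts[canon])
}
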