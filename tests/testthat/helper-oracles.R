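# Independent oracles, deliberately naive: character-by-character encoding and
# substring-matching counts, used to cross-check the rolling 2-bit engine.

BASES <- c("A", "C", "G", "T")

# character-by-character packed encoding (A=0,C=1,G=2,T=3, MSB first)
naive_encode <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  codes <- match(ch, BASES) - 1
  if (anyNA(codes)) return(NA_real_)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

naive_revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "")[[1]])
  paste(c(T = "A", G = "C", C = "G", A = "T", N = "N")[ch], collapse = "")
}

naive_canonical <- function(seq) {
  rc <- naive_revcomp(seq)
  if (is.na(naive_encode(seq))) return(NA_character_)
  if (naive_encode(rc) < naive_encode(seq)) rc else seq
}

# overlapping occurrences of `kmer` (either strand) in one read
naive_count_read <- function(read, kmer) {
  pats <- unique(c(kmer, naive_revcomp(kmer)))
  sum(vapply(pats, function(p) {
    m <- gregexpr(paste0("(?=", p, ")"), read, perl = TRUE)[[1]]
    sum(m > 0)
  }, numeric(1)))
}

naive_count <- function(reads, kmer) {
  sum(vapply(reads, naive_count_read, numeric(1), kmer = kmer))
}

# all k-windows of a string
naive_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
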