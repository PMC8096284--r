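// Integer-packed k-mer machinery: 2 bits per base (A=0, C=1, G=2, T=3),
// most-significant bits first, canonical over strands.  All counting against
// a k-mer panel happens here; R only sees canonical k-mer strings.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t kmask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static inline uint64_t revcomp_bits(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

// returns false on ambiguous base
static bool encode_bits(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static std::string decode_bits(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[v & 3ULL];
    v >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".encode_kmer")]]
NumericVector encode_kmer_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(seqs[i]);
    int k = (int)strlen(s);
    if (k < 1 || k > 26)
      stop("numeric k-mer codes are exact only for 1 <= k <= 26 (doubles); use canonical_kmer() for longer k-mers");
    uint64_t v;
    out[i] = encode_bits(s, k, v) ? (double)v : NA_REAL;
  }
  return out;
}

// [[Rcpp::export(name = ".decode_kmer")]]
CharacterVector decode_kmer_cpp(NumericVector values, int k) {
  if (k < 1 || k > 26) stop("k must be in 1..26 for numeric codes");
  R_xlen_t n = values.size();
  CharacterVector out(n);
  double maxv = std::pow(4.0, k);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = values[i];
    if (NumericVector::is_na(v)) { out[i] = NA_STRING; continue; }
    if (v < 0 || v >= maxv || v != std::floor(v))
      stop("code out of range for k=%d", k);
    out[i] = decode_bits((uint64_t)v, k);
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_code")]]
NumericVector revcomp_code_cpp(NumericVector values, int k) {
  if (k < 1 || k > 26) stop("k must be in 1..26 for numeric codes");
  R_xlen_t n = values.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(values[i])) { out[i] = NA_REAL; continue; }
    out[i] = (double)revcomp_bits((uint64_t)values[i], k);
  }
  return out;
}

// canonical sequence form of each k-mer (min of itself and its reverse
// complement by packed integer value); NA for ambiguous bases; k <= 32
// [[Rcpp::export(name = ".canonical_kmer")]]
CharacterVector canonical_kmer_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    int k = (int)strlen(s);
    if (k < 1 || k > 32) stop("k must be in 1..32");
    uint64_t v;
    if (!encode_bits(s, k, v)) { out[i] = NA_STRING; continue; }
    uint64_t rc = revcomp_bits(v, k);
    out[i] = decode_bits(std::min(v, rc), k);
  }
  return out;
}

// reverse complement of arbitrary-length sequences (IUPAC ACGTN upper/lower)
// [[Rcpp::export(name = ".revcomp_seq")]]
CharacterVector revcomp_seq_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    size_t m = strlen(s);
    std::string r(m, 'N');
    for (size_t j = 0; j < m; ++j) {
      char c = s[m - 1 - j];
      switch (c) {
      case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
      case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
      case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
      case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
      default:  r[j] = c;
      }
    }
    out[i] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// panel index + counting

struct KmerIndexC {
  int k;
  std::unordered_map<uint64_t, uint32_t> ids;     // canonical code -> entry
  std::vector<std::vector<uint64_t>> neighbors;   // canonical neighbor codes
  std::vector<std::string> names;                 // canonical k-mer strings
};

struct CountStateC {
  std::vector<long long> counts;
  long long reads_processed = 0;
};

// kmers must be canonical, unique, all of length k; neighbors is a list of
// character vectors of canonical neighbor k-mers (may be empty)
// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build_cpp(CharacterVector kmers, List neighbors, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  if (neighbors.size() != kmers.size()) stop("kmers/neighbors length mismatch");
  XPtr<KmerIndexC> xp(new KmerIndexC(), true);
  xp->k = k;
  R_xlen_t n = kmers.size();
  xp->neighbors.resize(n);
  xp->names.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(kmers[i]);
    if ((int)strlen(s) != k) stop("k-mer %d has length != k", (int)i + 1);
    uint64_t v;
    if (!encode_bits(s, k, v)) stop("ambiguous base in k-mer %d", (int)i + 1);
    uint64_t rc = revcomp_bits(v, k);
    uint64_t canon = std::min(v, rc);
    if (canon != v) stop("k-mer %d is not in canonical form", (int)i + 1);
    if (xp->ids.count(canon)) stop("duplicate canonical k-mer at entry %d", (int)i + 1);
    xp->ids[canon] = (uint32_t)i;
    xp->names[i] = s;
    CharacterVector nb = neighbors[i];
    for (R_xlen_t j = 0; j < nb.size(); ++j) {
      if (nb[j] == NA_STRING) continue;
      const char* t = CHAR(nb[j]);
      if ((int)strlen(t) != k) stop("neighbor of entry %d has length != k", (int)i + 1);
      uint64_t w;
      if (!encode_bits(t, k, w)) continue;
      uint64_t wrc = revcomp_bits(w, k);
      xp->neighbors[i].push_back(std::min(w, wrc));
    }
  }
  return xp;
}

// [[Rcpp::export(name = ".kmer_index_size")]]
int kmer_index_size_cpp(SEXP xp_) { return (int)XPtr<KmerIndexC>(xp_)->ids.size(); }

// [[Rcpp::export(name = ".kmer_index_k")]]
int kmer_index_k_cpp(SEXP xp_) { return XPtr<KmerIndexC>(xp_)->k; }

// [[Rcpp::export(name = ".kmer_index_names")]]
CharacterVector kmer_index_names_cpp(SEXP xp_) {
  XPtr<KmerIndexC> xp(xp_);
  return wrap(xp->names);
}

// [[Rcpp::export(name = ".count_state_new")]]
SEXP count_state_new_cpp(SEXP xp_) {
  XPtr<KmerIndexC> idx(xp_);
  XPtr<CountStateC> st(new CountStateC(), true);
  st->counts.assign(idx->names.size(), 0);
  return st;
}

// window scan of one sequence; codes[i] = canonical code of window starting at
// 0-based i, valid[i] = no ambiguous base in the window
static void window_codes(const char* s, int len, int k,
                         std::vector<uint64_t>& codes, std::vector<char>& valid) {
  int nwin = len - k + 1;
  codes.assign(std::max(nwin, 0), 0);
  valid.assign(std::max(nwin, 0), 0);
  if (nwin <= 0) return;
  uint64_t mask = kmask(k);
  uint64_t fwd = 0, rc = 0;
  int run = 0;  // unambiguous run length ending at current base
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (k - 1)));
    ++run;
    int w = i - k + 1;
    if (w >= 0 && run >= k) {
      codes[w] = std::min(fwd, rc);
      valid[w] = 1;
    }
  }
}

// accept rule for a hit at window w: if !verify accept; else check the
// adjacent windows that exist and are unambiguous -- accept iff any of them is
// a stored neighbor of the entry, or none is checkable
static inline bool accept_hit(const KmerIndexC& idx, uint32_t id,
                              const std::vector<uint64_t>& codes,
                              const std::vector<char>& valid, int w) {
  const std::vector<uint64_t>& nb = idx.neighbors[id];
  int nwin = (int)codes.size();
  bool checkable = false;
  for (int d = -1; d <= 1; d += 2) {
    int a = w + d;
    if (a < 0 || a >= nwin || !valid[a]) continue;
    checkable = true;
    uint64_t c = codes[a];
    for (size_t j = 0; j < nb.size(); ++j)
      if (nb[j] == c) return true;
  }
  return !checkable;
}

// [[Rcpp::export(name = ".count_sequences")]]
void count_sequences_cpp(SEXP xp_, SEXP st_, CharacterVector seqs, bool verify) {
  XPtr<KmerIndexC> idx(xp_);
  XPtr<CountStateC> st(st_);
  int k = idx->k;
  std::vector<uint64_t> codes;
  std::vector<char> valid;
  R_xlen_t n = seqs.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    st->reads_processed++;
    if (seqs[r] == NA_STRING) continue;
    const char* s = CHAR(seqs[r]);
    int len = (int)strlen(s);
    if (len < k) continue;
    window_codes(s, len, k, codes, valid);
    int nwin = (int)codes.size();
    for (int w = 0; w < nwin; ++w) {
      if (!valid[w]) continue;
      auto it = idx->ids.find(codes[w]);
      if (it == idx->ids.end()) continue;
      if (!verify || accept_hit(*idx, it->second, codes, valid, w))
        st->counts[it->second]++;
    }
  }
}

// [[Rcpp::export(name = ".count_state_counts")]]
NumericVector count_state_counts_cpp(SEXP xp_, SEXP st_) {
  XPtr<KmerIndexC> idx(xp_);
  XPtr<CountStateC> st(st_);
  NumericVector out(st->counts.size());
  for (size_t i = 0; i < st->counts.size(); ++i) out[i] = (double)st->counts[i];
  out.names() = wrap(idx->names);
  return out;
}

// [[Rcpp::export(name = ".count_state_reads")]]
double count_state_reads_cpp(SEXP st_) {
  return (double)XPtr<CountStateC>(st_)->reads_processed;
}

// accepted occurrences of indexed k-mers in one read; 1-based positions
// [[Rcpp::export(name = ".scan_read")]]
DataFrame scan_read_cpp(SEXP xp_, std::string seq, bool verify) {
  XPtr<KmerIndexC> idx(xp_);
  int k = idx->k;
  std::vector<uint64_t> codes;
  std::vector<char> valid;
  std::vector<std::string> kout;
  std::vector<int> pout;
  int len = (int)seq.size();
  if (len >= k) {
    window_codes(seq.c_str(), len, k, codes, valid);
    for (int w = 0; w < (int)codes.size(); ++w) {
      if (!valid[w]) continue;
      auto it = idx->ids.find(codes[w]);
      if (it == idx->ids.end()) continue;
      if (!verify || accept_hit(*idx, it->second, codes, valid, w)) {
        kout.push_back(idx->names[it->second]);
        pout.push_back(w + 1);
      }
    }
  }
  return DataFrame::create(_["kmer"] = kout, _["pos"] = pout,
                           _["stringsAsFactors"] = false);
}

// substitution errors: reads[idx[i]] gets base at pos[i] replaced by a base
// rotated shift[i] (1..3) steps in the 2-bit alphabet -- always a different
// base; ambiguous bases are left untouched
// [[Rcpp::export(name = ".inject_errors")]]
CharacterVector inject_errors_cpp(CharacterVector reads, IntegerVector idx,
                                  IntegerVector pos, IntegerVector shift) {
  CharacterVector out = clone(reads);
  R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t r = idx[i] - 1;
    if (r < 0 || r >= out.size()) stop("read index out of range");
    std::string s = as<std::string>(out[r]);
    int p = pos[i] - 1;
    if (p < 0 || p >= (int)s.size()) continue;
    int b = base_code(s[p]);
    if (b < 0) continue;
    s[p] = CODE2BASE[(b + shift[i]) % 4];
    out[r] = s;
  }
  return out;
}
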