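// 64-bit k-mer core: 2-bit packing, canonical strand, FNV-1 hashing,
// window minimizer scan, and binary dbs/dbss record I/O.
//
// k-mers cross the R boundary as fixed-width 16-digit lowercase hex
// strings: lexicographic order on them equals numeric order on the
// underlying uint64, so R-side sort/unique/match behave correctly.

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <fstream>
#include <vector>
#include <string>

using namespace Rcpp;

static const uint64_t FNV_OFFSET = 14695981039346656037ULL;
static const uint64_t FNV_PRIME  = 1099511628211ULL;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string u64_to_hex(uint64_t v) {
  static const char digits[] = "0123456789abcdef";
  char buf[16];
  for (int i = 15; i >= 0; --i) { buf[i] = digits[v & 0xF]; v >>= 4; }
  return std::string(buf, 16);
}

static bool hex_to_u64(const char *s, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < 16; ++i) {
    char c = s[i];
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else return false;
    v = (v << 4) | (uint64_t)d;
  }
  if (s[16] != '\0') return false;
  out = v;
  return true;
}

static uint64_t hex_arg(const String &s) {
  uint64_t v;
  if (s == NA_STRING || !hex_to_u64(s.get_cstring(), v))
    stop("k-mer must be a 16-digit hex string");
  return v;
}

// FNV-1 (multiply then XOR), 64-bit
static inline uint64_t fnv1_bytes(const uint8_t *p, size_t n) {
  uint64_t h = FNV_OFFSET;
  for (size_t i = 0; i < n; ++i) {
    h *= FNV_PRIME;
    h ^= (uint64_t)p[i];
  }
  return h;
}

// hash the 8 bytes of the packed k-mer, little-endian byte order
static inline uint64_t fnv1_u64le(uint64_t v) {
  uint8_t b[8];
  for (int i = 0; i < 8; ++i) b[i] = (uint8_t)((v >> (8 * i)) & 0xFF);
  return fnv1_bytes(b, 8);
}

static inline uint64_t kmask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static inline uint64_t revcomp_u64(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL ^ (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static void check_k(int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
}

// [[Rcpp::export]]
CharacterVector kt_encode(CharacterVector seqs, int k) {
  check_k(k);
  int n = seqs.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j) {
    if (seqs[j] == NA_STRING) { out[j] = NA_STRING; continue; }
    const char *s = seqs[j];
    uint64_t v = 0;
    bool ok = true;
    int i = 0;
    for (; s[i] != '\0'; ++i) {
      if (i >= k) { ok = false; break; }
      int c = base2code(s[i]);
      if (c < 0) { ok = false; break; }
      v = (v << 2) | (uint64_t)c;
    }
    if (!ok || i != k) out[j] = NA_STRING;
    else out[j] = u64_to_hex(v);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kt_decode(CharacterVector kmers, int k) {
  check_k(k);
  int n = kmers.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j) {
    uint64_t v = hex_arg(kmers[j]);
    if (k < 32 && v > kmask(k)) stop("encoded value out of range for k = %d", k);
    char buf[33];
    for (int i = k - 1; i >= 0; --i) { buf[i] = CODE2BASE[v & 3ULL]; v >>= 2; }
    buf[k] = '\0';
    out[j] = std::string(buf, k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kt_revcomp(CharacterVector kmers, int k) {
  check_k(k);
  int n = kmers.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = u64_to_hex(revcomp_u64(hex_arg(kmers[j]), k));
  return out;
}

// [[Rcpp::export]]
CharacterVector kt_canonical(CharacterVector kmers, int k) {
  check_k(k);
  int n = kmers.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j) {
    uint64_t v = hex_arg(kmers[j]);
    uint64_t r = revcomp_u64(v, k);
    out[j] = u64_to_hex(r < v ? r : v);
  }
  return out;
}

// [[Rcpp::export]]
String kt_fnv1_raw(RawVector bytes) {
  return u64_to_hex(fnv1_bytes(RAW(bytes), bytes.size()));
}

// [[Rcpp::export]]
CharacterVector kt_fnv1_kmer(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = u64_to_hex(fnv1_u64le(hex_arg(kmers[j])));
  return out;
}

// Minimizer over candidate k-mer start positions [start, start + W),
// truncated at the last position where a whole k-mer fits.  Candidates
// containing a non-ACGT base are skipped.  Best = smallest FNV-1 hash of
// the canonical encoding; ties broken by smaller canonical value, then
// leftmost start.  Returns NA when no candidate is valid.
struct WinBest {
  uint64_t hash, canon;
  bool set;
  WinBest() : hash(0), canon(0), set(false) {}
  void offer(uint64_t h, uint64_t c) {
    if (!set || h < hash || (h == hash && c < canon)) {
      hash = h; canon = c; set = true;
    }
  }
};

// Single pass over seq maintaining rolling forward/reverse encodings and
// the length of the current ACGT-only run; visits each k-mer start once.
template <typename F>
static void scan_kmers(const char *s, size_t len, int k, F visit) {
  uint64_t mask = kmask(k);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  int shift = 2 * (k - 1);
  for (size_t pos = 0; pos < len; ++pos) {
    int c = base2code(s[pos]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 ^ c) << shift);
    if (++run >= k) {
      size_t kstart = pos + 1 - (size_t)k;
      visit(kstart, fwd < rc ? fwd : rc);
    }
  }
}

// [[Rcpp::export]]
CharacterVector kt_window_min(std::string seq, double start, int W, int k) {
  check_k(k);
  if (W < 1) stop("window must be >= 1");
  size_t s0 = (size_t)start;
  size_t s1 = s0 + (size_t)W;
  WinBest best;
  scan_kmers(seq.c_str(), seq.size(), k, [&](size_t kstart, uint64_t canon) {
    if (kstart < s0 || kstart >= s1) return;
    best.offer(fnv1_u64le(canon), canon);
  });
  CharacterVector out(1);
  out[0] = best.set ? String(u64_to_hex(best.canon)) : NA_STRING;
  return out;
}

// [[Rcpp::export]]
CharacterVector kt_minimize(std::string seq, int W, int k) {
  check_k(k);
  if (W < 1) stop("window must be >= 1");
  size_t len = seq.size();
  if (len < (size_t)k) return CharacterVector(0);
  size_t nwin = (len - (size_t)k) / (size_t)W + 1;
  std::vector<WinBest> best(nwin);
  scan_kmers(seq.c_str(), len, k, [&](size_t kstart, uint64_t canon) {
    best[kstart / (size_t)W].offer(fnv1_u64le(canon), canon);
  });
  std::vector<std::string> out;
  out.reserve(nwin);
  for (size_t w = 0; w < nwin; ++w)
    if (best[w].set) out.push_back(u64_to_hex(best[w].canon));
  return wrap(out);
}

// every canonical k-mer at every start position (non-ACGT skipped),
// duplicates retained in positional order
// [[Rcpp::export]]
CharacterVector kt_seq_kmers(std::string seq, int k) {
  check_k(k);
  std::vector<std::string> out;
  if (seq.size() >= (size_t)k) out.reserve(seq.size() - k + 1);
  scan_kmers(seq.c_str(), seq.size(), k, [&](size_t, uint64_t canon) {
    out.push_back(u64_to_hex(canon));
  });
  return wrap(out);
}

// TRUE when a single homopolymer run or a single perfect two-base tandem
// repeat spans strictly more than half the k-mer (the "> 50%" rule)
// [[Rcpp::export]]
LogicalVector kt_low_complexity(CharacterVector kmers, int k) {
  check_k(k);
  int n = kmers.size();
  LogicalVector out(n);
  std::vector<int> code(k);
  for (int j = 0; j < n; ++j) {
    uint64_t v = hex_arg(kmers[j]);
    for (int i = k - 1; i >= 0; --i) { code[i] = (int)(v & 3ULL); v >>= 2; }
    int hp = 1, hp_best = 1;
    for (int i = 1; i < k; ++i) {
      hp = (code[i] == code[i - 1]) ? hp + 1 : 1;
      if (hp > hp_best) hp_best = hp;
    }
    // maximal period-2 segment whose two alternating bases differ
    int di_best = 0, segstart = 0;
    for (int i = 1; i < k; ++i) {
      if (i >= 2 && code[i] != code[i - 2]) segstart = i - 1;
      int len = i - segstart + 1;
      if (len >= 2 && code[segstart] != code[segstart + 1] && len > di_best)
        di_best = len;
    }
    out[j] = (2 * hp_best > k) || (2 * di_best > k);
  }
  return out;
}

// ---- binary database I/O -------------------------------------------------
// dbs record: 8-byte little-endian k-mer, 4-byte little-endian TaxId;
// records sorted ascending by k-mer, each k-mer at most once.

static void put_u64le(std::ofstream &f, uint64_t v) {
  uint8_t b[8];
  for (int i = 0; i < 8; ++i) b[i] = (uint8_t)((v >> (8 * i)) & 0xFF);
  f.write((const char *)b, 8);
}

static void put_u32le(std::ofstream &f, uint32_t v) {
  uint8_t b[4];
  for (int i = 0; i < 4; ++i) b[i] = (uint8_t)((v >> (8 * i)) & 0xFF);
  f.write((const char *)b, 4);
}

static uint64_t get_u64le(const uint8_t *b) {
  uint64_t v = 0;
  for (int i = 7; i >= 0; --i) v = (v << 8) | (uint64_t)b[i];
  return v;
}

static uint32_t get_u32le(const uint8_t *b) {
  uint32_t v = 0;
  for (int i = 3; i >= 0; --i) v = (v << 8) | (uint32_t)b[i];
  return v;
}

// [[Rcpp::export]]
void kt_write_dbs(std::string path, CharacterVector kmers, IntegerVector taxids) {
  if (kmers.size() != taxids.size()) stop("kmers and taxids differ in length");
  std::ofstream f(path.c_str(), std::ios::binary | std::ios::trunc);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  uint64_t prev = 0;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t v = hex_arg(kmers[i]);
    if (i > 0 && v <= prev)
      stop("dbs records must be strictly ascending by k-mer");
    int t = taxids[i];
    if (t == NA_INTEGER || t <= 0) stop("TaxId must be a positive integer");
    put_u64le(f, v);
    put_u32le(f, (uint32_t)t);
    prev = v;
  }
  if (!f) stop("write to '%s' failed", path.c_str());
}

// [[Rcpp::export]]
List kt_read_dbs(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary | std::ios::ate);
  if (!f) stop("cannot open '%s'", path.c_str());
  std::streamoff sz = f.tellg();
  if (sz % 12 != 0)
    stop("corrupt dbs file '%s': size %lld is not a multiple of 12",
         path.c_str(), (long long)sz);
  size_t n = (size_t)(sz / 12);
  f.seekg(0);
  CharacterVector kmers(n);
  IntegerVector taxids(n);
  uint8_t rec[12];
  uint64_t prev = 0;
  for (size_t i = 0; i < n; ++i) {
    f.read((char *)rec, 12);
    if (!f) stop("read of '%s' failed", path.c_str());
    uint64_t v = get_u64le(rec);
    if (i > 0 && v <= prev)
      stop("corrupt dbs file '%s': records not strictly sorted by k-mer",
           path.c_str());
    kmers[i] = u64_to_hex(v);
    taxids[i] = (int)get_u32le(rec + 8);
    prev = v;
  }
  return List::create(_["kmer"] = kmers, _["taxid"] = taxids);
}

// [[Rcpp::export]]
void kt_write_u64(std::string path, CharacterVector kmers) {
  std::ofstream f(path.c_str(), std::ios::binary | std::ios::trunc);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) put_u64le(f, hex_arg(kmers[i]));
  if (!f) stop("write to '%s' failed", path.c_str());
}

// read n_rec 8-byte k-mers starting at record offset off_rec
// [[Rcpp::export]]
CharacterVector kt_read_u64(std::string path, double off_rec, double n_rec) {
  std::ifstream f(path.c_str(), std::ios::binary | std::ios::ate);
  if (!f) stop("cannot open '%s'", path.c_str());
  std::streamoff sz = f.tellg();
  if (sz % 8 != 0)
    stop("corrupt k-mer file '%s': size not a multiple of 8", path.c_str());
  long long off = (long long)off_rec, n = (long long)n_rec;
  if (off < 0 || n < 0 || (off + n) * 8 > (long long)sz)
    stop("requested slice extends past end of '%s'", path.c_str());
  f.seekg(off * 8);
  CharacterVector out(n);
  uint8_t b[8];
  for (long long i = 0; i < n; ++i) {
    f.read((char *)b, 8);
    if (!f) stop("read of '%s' failed", path.c_str());
    out[i] = u64_to_hex(get_u64le(b));
  }
  return out;
}
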