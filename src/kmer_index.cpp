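// Exact k-mer counting index over a read collection, with strand-aware
// occurrence counts, de Bruijn neighbor queries, branch scanning, greedy
// graph walks and seed-match postings for overlap computation.
//
// K-mers are packed 2 bits per base (A=0, C=1, G=2, T=3) into a 192-bit
// code with the first base in the most significant position, so numeric
// order equals lexicographic order and any k up to 96 shares one code path.
// Counts are stored per canonical k-mer (min of the k-mer and its reverse
// complement) as a pair (occurrences as the canonical string, occurrences
// as its reverse complement), making the strand-specific count and the
// combined count a single lookup. Codes are maintained by rolling updates
// while scanning reads, so no per-position allocation occurs.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---- 192-bit packed k-mer code ----

struct K192 {
  uint64_t w0 = 0, w1 = 0, w2 = 0;  // w2 most significant
  bool operator==(const K192& o) const {
    return w0 == o.w0 && w1 == o.w1 && w2 == o.w2;
  }
  bool operator<(const K192& o) const {
    if (w2 != o.w2) return w2 < o.w2;
    if (w1 != o.w1) return w1 < o.w1;
    return w0 < o.w0;
  }
};

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct K192Hash {
  size_t operator()(const K192& x) const {
    return splitmix64(x.w0 ^ splitmix64(x.w1 ^ splitmix64(x.w2)));
  }
};

static inline K192 k192_mask(int k) {
  // low 2k bits set
  K192 m;
  int bits = 2 * k;
  m.w0 = (bits >= 64) ? ~0ULL : ((bits == 0) ? 0 : (~0ULL >> (64 - bits)));
  int b1 = bits - 64;
  m.w1 = (b1 <= 0) ? 0 : ((b1 >= 64) ? ~0ULL : (~0ULL >> (64 - b1)));
  int b2 = bits - 128;
  m.w2 = (b2 <= 0) ? 0 : ((b2 >= 64) ? ~0ULL : (~0ULL >> (64 - b2)));
  return m;
}

// (x << 2 | b) & mask  -- append base b at the least significant end
static inline K192 k192_shl2_or(const K192& x, int b, const K192& mask) {
  K192 r;
  r.w2 = ((x.w2 << 2) | (x.w1 >> 62)) & mask.w2;
  r.w1 = ((x.w1 << 2) | (x.w0 >> 62)) & mask.w1;
  r.w0 = ((x.w0 << 2) | (uint64_t)b) & mask.w0;
  return r;
}

// (x >> 2) | (b << 2(k-1)) -- prepend base b at the most significant end
static inline K192 k192_shr2_or_top(const K192& x, int b, int k) {
  K192 r;
  r.w0 = (x.w0 >> 2) | (x.w1 << 62);
  r.w1 = (x.w1 >> 2) | (x.w2 << 62);
  r.w2 = x.w2 >> 2;
  int pos = 2 * (k - 1);
  uint64_t bb = (uint64_t)b;
  if (pos < 64) r.w0 |= bb << pos;
  else if (pos < 128) r.w1 |= bb << (pos - 64);
  else r.w2 |= bb << (pos - 128);
  return r;
}

static inline int k192_base_at(const K192& x, int pos_from_low) {
  int bit = 2 * pos_from_low;
  if (bit < 64) return (int)((x.w0 >> bit) & 3ULL);
  if (bit < 128) return (int)((x.w1 >> (bit - 64)) & 3ULL);
  return (int)((x.w2 >> (bit - 128)) & 3ULL);
}

// full reverse complement of a k-base code
static inline K192 k192_revcomp(const K192& x, int k) {
  K192 r;
  K192 mask = k192_mask(k);
  // the complement of the last base (position 0 from the low end) becomes
  // the most significant base of the reverse complement
  for (int i = 0; i < k; ++i) {
    int b = k192_base_at(x, i);
    r = k192_shl2_or(r, 3 - b, mask);
  }
  return r;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string k192_decode(const K192& x, int k) {
  std::string out(k, 'N');
  for (int i = 0; i < k; ++i)
    out[k - 1 - i] = BASES[k192_base_at(x, i)];
  return out;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 0;
  }
}

static std::string rc_string(const std::string& s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(s[n - 1 - i]);
    if (c == 0) stop("non-IUPAC character '%c' in sequence", s[n - 1 - i]);
    out[i] = c;
  }
  return out;
}

// oriented k-mer: forward code plus the code of its reverse complement
struct Kmer {
  K192 fwd, rc;
  bool palindrome() const { return fwd == rc; }
  const K192& canon() const { return rc < fwd ? rc : fwd; }
  bool is_canon() const { return !(rc < fwd); }
};

// encode a pattern string; returns false on non-ACGT
static bool encode_kmer(const std::string& p, Kmer& out) {
  const int k = (int)p.size();
  if (k > 96) stop("k values above 96 are not supported");
  K192 mask = k192_mask(k);
  K192 f, r;
  for (int i = 0; i < k; ++i) {
    int b = base_code(p[i]);
    if (b < 0) return false;
    f = k192_shl2_or(f, b, mask);
    r = k192_shr2_or_top(r, 3 - b, k);
  }
  out.fwd = f; out.rc = r;
  return true;
}

// rolling scanner over a sequence: yields valid k-mers with their position
class KmerRoller {
public:
  const std::string& seq;
  int k;
  K192 mask;
  K192 f, r;
  int run = 0;   // length of current run of ACGT bases
  int pos = -1;  // position of the last consumed base
  KmerRoller(const std::string& s, int k_) : seq(s), k(k_),
                                             mask(k192_mask(k_)) {}
  // advance to the next valid k-mer; false when the sequence is exhausted
  bool next(Kmer& out, int& start_pos) {
    const int L = (int)seq.size();
    while (pos + 1 < L) {
      ++pos;
      int b = base_code(seq[pos]);
      if (b < 0) { run = 0; continue; }
      f = k192_shl2_or(f, b, mask);
      r = k192_shr2_or_top(r, 3 - b, k);
      if (++run >= k) {
        out.fwd = f; out.rc = r;
        start_pos = pos - k + 1;
        return true;
      }
    }
    return false;
  }
};

struct StrandCount {
  int32_t fwd = 0;  // occurrences of the canonical k-mer as observed
  int32_t rev = 0;  // occurrences of its reverse complement as observed
};

typedef std::unordered_map<K192, StrandCount, K192Hash> KTable;

struct SeedHit {
  int32_t read;
  int32_t pos;
  bool rc;  // occurrence was the reverse complement of the canonical seed
};

class KmerIndexCpp {
public:
  std::vector<std::string> seqs;
  std::vector<int> kvals;
  std::unordered_map<int, KTable> tables;
  int seed_len = 0;
  std::unordered_map<K192, std::vector<SeedHit>, K192Hash> postings;

  const KTable& table(int k) const {
    auto it = tables.find(k);
    if (it == tables.end()) stop("no index for k = %d", k);
    return it->second;
  }

  static void insert(KTable& tab, const Kmer& km) {
    if (km.is_canon()) tab[km.fwd].fwd++;
    else               tab[km.rc].rev++;
  }

  // count of the k-mer exactly as oriented (one strand)
  static int count_obs(const KTable& tab, const Kmer& km) {
    auto e = tab.find(km.canon());
    if (e == tab.end()) return 0;
    return km.is_canon() ? e->second.fwd : e->second.rev;
  }

  // count(P) + count(rc(P)); for palindromes both terms are the same string
  static int count_rc(const KTable& tab, const Kmer& km) {
    auto e = tab.find(km.canon());
    if (e == tab.end()) return 0;
    return km.palindrome() ? 2 * e->second.fwd
                           : e->second.fwd + e->second.rev;
  }

  // seen at least once on each sequencing strand separately
  static bool strand_validated(const KTable& tab, const Kmer& km) {
    auto e = tab.find(km.canon());
    if (e == tab.end()) return false;
    if (km.palindrome()) return e->second.fwd > 0;
    return e->second.fwd > 0 && e->second.rev > 0;
  }
};

// suffix neighbor: drop the leading base of X, append b. The reverse
// complement follows by the mirror update: drop the least significant base
// of rc(X) and prepend comp(b) at the most significant position.
static inline Kmer suffix_neighbor(const Kmer& x, int b, int k,
                                   const K192& mask) {
  Kmer nb;
  nb.fwd = k192_shl2_or(x.fwd, b, mask);
  nb.rc = k192_shr2_or_top(x.rc, 3 - b, k);
  return nb;
}

// set base b at position pos_from_low without shifting (extension to k+1)
static inline K192 k192_or_at(const K192& x, int b, int pos_from_low) {
  K192 r = x;
  int bit = 2 * pos_from_low;
  uint64_t bb = (uint64_t)b;
  if (bit < 64) r.w0 |= bb << bit;
  else if (bit < 128) r.w1 |= bb << (bit - 64);
  else r.w2 |= bb << (bit - 128);
  return r;
}

// ---- exported API ----

// [[Rcpp::export(name = ".idx_build")]]
SEXP idx_build(CharacterVector seqs, IntegerVector k_values, int seed_len) {
  KmerIndexCpp* idx = new KmerIndexCpp();
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    idx->seqs.push_back(as<std::string>(seqs[i]));
  for (int j = 0; j < k_values.size(); ++j) {
    int k = k_values[j];
    if (k < 1) stop("k must be positive");
    if (k > 96) stop("k values above 96 are not supported");
    idx->kvals.push_back(k);
    KTable& tab = idx->tables[k];
    Kmer km; int sp;
    for (const std::string& s : idx->seqs) {
      KmerRoller roll(s, k);
      while (roll.next(km, sp)) KmerIndexCpp::insert(tab, km);
    }
  }
  idx->seed_len = seed_len;
  if (seed_len > 0) {
    Kmer km; int sp;
    for (int32_t i = 0; i < (int32_t)idx->seqs.size(); ++i) {
      KmerRoller roll(idx->seqs[i], seed_len);
      while (roll.next(km, sp))
        idx->postings[km.canon()].push_back({i, sp, !km.is_canon()});
    }
  }
  XPtr<KmerIndexCpp> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".idx_k_values")]]
IntegerVector idx_k_values(SEXP xp) {
  XPtr<KmerIndexCpp> idx(xp);
  return wrap(idx->kvals);
}

// [[Rcpp::export(name = ".idx_count")]]
IntegerVector idx_count(SEXP xp, CharacterVector p) {
  XPtr<KmerIndexCpp> idx(xp);
  IntegerVector out(p.size());
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    std::string s = as<std::string>(p[i]);
    Kmer km;
    if (!encode_kmer(s, km)) { out[i] = 0; continue; }
    out[i] = KmerIndexCpp::count_obs(idx->table((int)s.size()), km);
  }
  return out;
}

// [[Rcpp::export(name = ".idx_count_rc")]]
IntegerVector idx_count_rc(SEXP xp, CharacterVector p) {
  XPtr<KmerIndexCpp> idx(xp);
  IntegerVector out(p.size());
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    std::string s = as<std::string>(p[i]);
    Kmer km;
    if (!encode_kmer(s, km)) { out[i] = 0; continue; }
    out[i] = KmerIndexCpp::count_rc(idx->table((int)s.size()), km);
  }
  return out;
}

// [[Rcpp::export(name = ".rc_cpp")]]
CharacterVector rc_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = rc_string(as<std::string>(x[i]));
  return out;
}

// Neighbor enumeration; suffix = true for suffix side. Neighbors of the
// prefix side of X are the reverse complements of the suffix neighbors of
// rc(X), which is how they are computed here.
// [[Rcpp::export(name = ".idx_neighbors")]]
List idx_neighbors(SEXP xp, std::string x, bool suffix) {
  XPtr<KmerIndexCpp> idx(xp);
  const int k = (int)x.size();
  const KTable& tab = idx->table(k);
  Kmer km;
  if (!encode_kmer(x, km)) stop("non-ACGT k-mer");
  if (!suffix) std::swap(km.fwd, km.rc);
  K192 mask = k192_mask(k);
  std::vector<std::string> nbs;
  std::vector<int> counts;
  std::vector<bool> valid;
  for (int b = 0; b < 4; ++b) {
    Kmer nb = suffix_neighbor(km, b, k, mask);
    int c = KmerIndexCpp::count_rc(tab, nb);
    if (c > 0) {
      std::string s = suffix ? k192_decode(nb.fwd, k)
                             : k192_decode(nb.rc, k);
      nbs.push_back(s);
      counts.push_back(c);
      valid.push_back(KmerIndexCpp::strand_validated(tab, nb));
    }
  }
  if (!suffix) {
    // decoded prefix neighbors end in base order of their *last* base;
    // restore base order of the leading base for determinism
    std::vector<size_t> ord(nbs.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b2) {
      return nbs[a] < nbs[b2];
    });
    std::vector<std::string> n2; std::vector<int> c2; std::vector<bool> v2;
    for (size_t i : ord) {
      n2.push_back(nbs[i]); c2.push_back(counts[i]); v2.push_back(valid[i]);
    }
    nbs = n2; counts = c2; valid = v2;
  }
  return List::create(_["kmer"] = wrap(nbs), _["count_rc"] = wrap(counts),
                      _["strand_validated"] = wrap(valid));
}

// branch observation at an oriented k-mer; fills out = {ca, cb, cia, cib, d}
static bool branch_obs(const KTable& tab, const KTable& tab1, const Kmer& x,
                       int k, const K192& mask, const K192& mask1,
                       int out[5]) {
  int cnt[4]; bool ok[4];
  Kmer nb[4];
  int nvalid = 0;
  for (int b = 0; b < 4; ++b) {
    nb[b] = suffix_neighbor(x, b, k, mask);
    cnt[b] = KmerIndexCpp::count_rc(tab, nb[b]);
    ok[b] = cnt[b] > 0 && KmerIndexCpp::strand_validated(tab, nb[b]);
    if (ok[b]) nvalid++;
  }
  if (nvalid < 2) return false;
  int a = -1, b2 = -1;
  for (int b = 0; b < 4; ++b) {
    if (!ok[b]) continue;
    if (a < 0 || cnt[b] > cnt[a]) { b2 = a; a = b; }
    else if (b2 < 0 || cnt[b] > cnt[b2]) { b2 = b; }
  }
  // joining (k+1)-mers: X with the neighbor base appended; their reverse
  // complements keep all k bases of rc(X) and gain comp(b) at the top
  Kmer ja, jb;
  ja.fwd = k192_shl2_or(x.fwd, a, mask1);
  ja.rc = k192_or_at(x.rc, 3 - a, k);
  jb.fwd = k192_shl2_or(x.fwd, b2, mask1);
  jb.rc = k192_or_at(x.rc, 3 - b2, k);
  int ca = cnt[a], cb = cnt[b2];
  int cia = KmerIndexCpp::count_rc(tab1, ja);
  int cib = KmerIndexCpp::count_rc(tab1, jb);
  int d = (ca - cia) + (cb - cib);
  if (d < 0) d = 0;
  out[0] = ca; out[1] = cb; out[2] = cia; out[3] = cib; out[4] = d;
  return true;
}

// [[Rcpp::export(name = ".idx_branch_obs")]]
IntegerVector idx_branch_obs(SEXP xp, std::string x) {
  XPtr<KmerIndexCpp> idx(xp);
  const int k = (int)x.size();
  const KTable& tab = idx->table(k);
  const KTable& tab1 = idx->table(k + 1);
  Kmer km;
  if (!encode_kmer(x, km)) stop("non-ACGT k-mer");
  int o[5];
  if (!branch_obs(tab, tab1, km, k, k192_mask(k), k192_mask(k + 1), o))
    return IntegerVector(0);
  return IntegerVector::create(o[0], o[1], o[2], o[3], o[4]);
}

// [[Rcpp::export(name = ".idx_read_kmer_counts")]]
IntegerVector idx_read_kmer_counts(SEXP xp, IntegerVector read_ids, int k) {
  XPtr<KmerIndexCpp> idx(xp);
  const KTable& tab = idx->table(k);
  std::vector<int> out;
  Kmer km; int sp;
  for (R_xlen_t j = 0; j < read_ids.size(); ++j) {
    KmerRoller roll(idx->seqs[read_ids[j]], k);
    while (roll.next(km, sp))
      out.push_back(KmerIndexCpp::count_rc(tab, km));
  }
  return wrap(out);
}

// Scan sampled reads for suffix branches at k-mers passing the homozygous
// posterior threshold; post_hom[c-1] is the posterior for count c (capped).
// [[Rcpp::export(name = ".idx_scan_branches")]]
List idx_scan_branches(SEXP xp, IntegerVector read_ids, int k,
                       NumericVector post_hom, double threshold) {
  XPtr<KmerIndexCpp> idx(xp);
  const KTable& tab = idx->table(k);
  const KTable& tab1 = idx->table(k + 1);
  const K192 mask = k192_mask(k), mask1 = k192_mask(k + 1);
  const int cap = (int)post_hom.size();
  long long n_h = 0;
  std::vector<int> ca, cb, cia, cib, dd;
  Kmer km; int sp;
  for (R_xlen_t j = 0; j < read_ids.size(); ++j) {
    KmerRoller roll(idx->seqs[read_ids[j]], k);
    while (roll.next(km, sp)) {
      int ci = KmerIndexCpp::count_rc(tab, km);
      if (ci < 1) continue;
      if (post_hom[std::min(ci, cap) - 1] < threshold) continue;
      n_h++;
      int o[5];
      if (branch_obs(tab, tab1, km, k, mask, mask1, o)) {
        ca.push_back(o[0]); cb.push_back(o[1]);
        cia.push_back(o[2]); cib.push_back(o[3]); dd.push_back(o[4]);
      }
    }
  }
  return List::create(_["n_h"] = (double)n_h,
                      _["ca"] = wrap(ca), _["cb"] = wrap(cb),
                      _["cia"] = wrap(cia), _["cib"] = wrap(cib),
                      _["d"] = wrap(dd));
}

// ---- branch classification (shared by the R API and the assembly walk) ----

struct ClsParams {
  double lambda, rho, mu_ev, p_err, alpha, beta;
  std::vector<double> qm;  // weights over extra-copy multipliers 1..7
};

static ClsParams cls_from_list(List params) {
  ClsParams p;
  p.lambda = as<double>(params["lambda"]);
  p.rho    = as<double>(params["rho"]);
  p.mu_ev  = as<double>(params["mu_ev"]);
  p.p_err  = as<double>(params["p_error_balance"]);
  p.alpha  = as<double>(params["alpha"]);
  p.beta   = as<double>(params["beta"]);
  p.qm     = as<std::vector<double>>(params["repeat_weights"]);
  return p;
}

static double betabinom_pmf(int x, int n, double a, double b) {
  return std::exp(R::lchoose(n, x) + R::lbeta(x + a, n - x + b) -
                  R::lbeta(a, b));
}

static void classify_one(int ca, int cb, int d, const ClsParams& p,
                         double out[3]) {
  const int n = ca + cb;
  double de = R::dpois(d, p.mu_ev, 0);
  double lrep_d = 0.0;
  for (size_t m = 0; m < p.qm.size(); ++m)
    lrep_d += p.qm[m] * R::dpois(d, (double)(m + 1) * p.lambda + p.rho, 0);
  double le = de * R::dbinom(cb, n, p.p_err, 0);
  double lv = de * R::dbinom(cb, n, 0.5, 0);
  double lr = lrep_d * betabinom_pmf(cb, n, p.alpha, p.beta);
  double s = le + lv + lr;
  if (s <= 0) { out[0] = out[1] = out[2] = 1.0 / 3.0; return; }
  out[0] = le / s; out[1] = lv / s; out[2] = lr / s;
}

// [[Rcpp::export(name = ".classify_branches_cpp")]]
NumericMatrix classify_branches_cpp(IntegerVector ca, IntegerVector cb,
                                    IntegerVector d, List params) {
  ClsParams p = cls_from_list(params);
  NumericMatrix out(ca.size(), 3);
  double o[3];
  for (R_xlen_t i = 0; i < ca.size(); ++i) {
    classify_one(ca[i], cb[i], d[i], p, o);
    out(i, 0) = o[0]; out(i, 1) = o[1]; out(i, 2) = o[2];
  }
  colnames(out) = CharacterVector::create("p_error", "p_variant", "p_repeat");
  return out;
}

// ---- greedy walks ----

// best strand-validated suffix neighbor by count_rc, ties in base order
static bool best_suffix_neighbor(const KTable& tab, const Kmer& x, int k,
                                 const K192& mask, Kmer& next) {
  int bestc = 0;
  Kmer best;
  for (int b = 0; b < 4; ++b) {
    Kmer nb = suffix_neighbor(x, b, k, mask);
    int c = KmerIndexCpp::count_rc(tab, nb);
    if (c > bestc && KmerIndexCpp::strand_validated(tab, nb)) {
      bestc = c; best = nb;
    }
  }
  if (bestc == 0) return false;
  next = best;
  return true;
}

// Greedy walk from each start toward each target (both oriented k-mers);
// returns extension steps to reach the target, or -1 on dead end/cap.
// [[Rcpp::export(name = ".idx_walk_fragments")]]
IntegerVector idx_walk_fragments(SEXP xp, CharacterVector starts,
                                 CharacterVector targets, int max_steps) {
  XPtr<KmerIndexCpp> idx(xp);
  IntegerVector out(starts.size());
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    std::string s0 = as<std::string>(starts[i]);
    std::string t0 = as<std::string>(targets[i]);
    const int k = (int)s0.size();
    const KTable& tab = idx->table(k);
    const K192 mask = k192_mask(k);
    Kmer cur, target;
    int res = -1;
    if (encode_kmer(s0, cur) && encode_kmer(t0, target) &&
        KmerIndexCpp::count_rc(tab, cur) > 0) {
      for (int step = 0; step <= max_steps; ++step) {
        if (cur.fwd == target.fwd) { res = step; break; }
        Kmer next;
        if (!best_suffix_neighbor(tab, cur, k, mask, next)) break;
        cur = next;
      }
    }
    out[i] = res;
  }
  return out;
}

// ---- bloom filter over canonical k-mer codes ----

class BloomFilter {
public:
  std::vector<uint64_t> bits;
  uint64_t nbits;
  int nhash;
  BloomFilter(uint64_t nbits_, int nhash_) : nbits(nbits_), nhash(nhash_) {
    if (nbits < 64) nbits = 64;
    bits.assign((nbits + 63) / 64, 0);
  }
  void add(const K192& x) {
    uint64_t h = K192Hash{}(x);
    for (int i = 0; i < nhash; ++i) {
      uint64_t b = splitmix64(h + 0x9e3779b97f4a7c15ULL * i) % nbits;
      bits[b >> 6] |= (1ULL << (b & 63));
    }
  }
  bool has(const K192& x) const {
    uint64_t h = K192Hash{}(x);
    for (int i = 0; i < nhash; ++i) {
      uint64_t b = splitmix64(h + 0x9e3779b97f4a7c15ULL * i) % nbits;
      if (!(bits[b >> 6] & (1ULL << (b & 63)))) return false;
    }
    return true;
  }
};

// string-keyed bindings used by tests of the filter itself
// [[Rcpp::export(name = ".bloom_new")]]
SEXP bloom_new(double nbits, int nhash) {
  return XPtr<BloomFilter>(new BloomFilter((uint64_t)nbits, nhash), true);
}

// [[Rcpp::export(name = ".bloom_add")]]
void bloom_add(SEXP xp, CharacterVector keys) {
  XPtr<BloomFilter> bf(xp);
  Kmer km;
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    if (!encode_kmer(as<std::string>(keys[i]), km))
      stop("non-ACGT key");
    bf->add(km.canon());
  }
}

// [[Rcpp::export(name = ".bloom_has")]]
LogicalVector bloom_has(SEXP xp, CharacterVector keys) {
  XPtr<BloomFilter> bf(xp);
  LogicalVector out(keys.size());
  Kmer km;
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    if (!encode_kmer(as<std::string>(keys[i]), km))
      stop("non-ACGT key");
    out[i] = bf->has(km.canon());
  }
  return out;
}

// Simulated de Bruijn assembly walks; see simulate_assembly() for the
// contract. Starts are oriented k-mers in sampled order.
// [[Rcpp::export(name = ".idx_walk_assembly")]]
IntegerVector idx_walk_assembly(SEXP xp, int k, CharacterVector starts,
                                NumericVector post_hom, double start_threshold,
                                List params, int n_walks, int max_len,
                                double bloom_bits) {
  XPtr<KmerIndexCpp> idx(xp);
  const KTable& tab = idx->table(k);
  const KTable& tab1 = idx->table(k + 1);
  const K192 mask = k192_mask(k), mask1 = k192_mask(k + 1);
  ClsParams cp = cls_from_list(params);
  const int cap = (int)post_hom.size();
  BloomFilter bloom((uint64_t)bloom_bits, 4);
  std::vector<int> lengths;

  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    if ((int)lengths.size() >= n_walks) break;
    std::string s0 = as<std::string>(starts[i]);
    Kmer start;
    if ((int)s0.size() != k || !encode_kmer(s0, start)) continue;
    int c0 = KmerIndexCpp::count_rc(tab, start);
    if (c0 < 1) continue;
    if (post_hom[std::min(c0, cap) - 1] < start_threshold) continue;
    if (bloom.has(start.canon())) continue;

    std::unordered_set<K192, K192Hash> visited;
    visited.insert(start.canon());
    // suffix-wards from the start, then from its reverse complement
    for (int dir = 0; dir < 2; ++dir) {
      Kmer cur = start;
      if (dir == 1) std::swap(cur.fwd, cur.rc);
      while ((int)visited.size() < max_len) {
        int o[5];
        if (branch_obs(tab, tab1, cur, k, mask, mask1, o)) {
          double post[3];
          classify_one(o[0], o[1], o[4], cp, post);
          if (post[2] >= post[0] && post[2] >= post[1]) break;  // repeat
        }
        Kmer next;
        if (!best_suffix_neighbor(tab, cur, k, mask, next)) break;
        if (!visited.insert(next.canon()).second) break;  // revisit
        cur = next;
      }
    }
    for (const K192& x : visited) bloom.add(x);
    lengths.push_back((int)visited.size());
  }
  return wrap(lengths);
}

// ---- seed postings for overlap candidates ----

// Candidates overlapping read `rid` (0-based); see overlap_candidates().
// [[Rcpp::export(name = ".idx_seed_candidates")]]
List idx_seed_candidates(SEXP xp, int rid, int max_seed_count) {
  XPtr<KmerIndexCpp> idx(xp);
  if (idx->seed_len <= 0)
    stop("index was built without seed postings (seed_len = 0)");
  const int sl = idx->seed_len;
  const std::string& seq = idx->seqs[rid];
  std::unordered_map<int32_t, std::pair<int, bool>> cands;
  Kmer km; int p;
  KmerRoller roll(seq, sl);
  while (roll.next(km, p)) {
    auto it = idx->postings.find(km.canon());
    if (it == idx->postings.end()) continue;
    const std::vector<SeedHit>& hits = it->second;
    if ((int)hits.size() > max_seed_count) continue;
    bool pal = km.palindrome();
    bool s_is_canon = km.is_canon();
    for (const SeedHit& h : hits) {
      if (h.read == rid) continue;
      if (cands.count(h.read)) continue;  // first seed diagonal wins
      bool same_strand = pal || (h.rc == !s_is_canon);
      int lenS = (int)idx->seqs[h.read].size();
      int offset;
      if (same_strand) offset = p - h.pos;
      else             offset = p - (lenS - sl - h.pos);
      cands[h.read] = std::make_pair(offset, !same_strand);
    }
  }
  std::vector<int> rid_out, off_out;
  std::vector<bool> rc_out;
  for (auto& kv : cands) {
    rid_out.push_back(kv.first + 1);  // 1-based for R
    off_out.push_back(kv.second.first);
    rc_out.push_back(kv.second.second);
  }
  return List::create(_["read"] = wrap(rid_out), _["offset"] = wrap(off_out),
                      _["rc"] = wrap(rc_out));
}

// ---- exact branch rates from a diploid reference genome ----

// See reference_branch_rates() for the definition.
// [[Rcpp::export(name = ".ref_branch_rates_cpp")]]
List ref_branch_rates_cpp(std::string hap_a, std::string hap_b, int k) {
  if (k > (int)hap_a.size() || k > (int)hap_b.size())
    stop("k exceeds the genome length");
  typedef std::unordered_map<K192, std::pair<int32_t, int32_t>, K192Hash>
    RefTab;
  RefTab tab;
  const std::string* haps[2] = {&hap_a, &hap_b};
  Kmer km; int sp;
  for (int h = 0; h < 2; ++h) {
    KmerRoller roll(*haps[h], k);
    while (roll.next(km, sp)) {
      auto& e = tab[km.canon()];
      if (h == 0) e.first++;
      else        e.second++;
    }
  }
  const K192 mask = k192_mask(k);
  long long n_hom = 0, n_var = 0, n_rep = 0;
  for (auto& kv : tab) {
    if (kv.second.first != 1 || kv.second.second != 1) continue;
    n_hom++;
    Kmer v;
    v.fwd = kv.first;
    v.rc = k192_revcomp(kv.first, k);
    for (int o = 0; o < 2; ++o) {
      Kmer x = v;
      if (o == 1) std::swap(x.fwd, x.rc);
      std::vector<std::pair<int, int>> nb_mult;
      for (int b = 0; b < 4; ++b) {
        Kmer nb = suffix_neighbor(x, b, k, mask);
        auto it = tab.find(nb.canon());
        if (it != tab.end())
          nb_mult.push_back(std::make_pair(it->second.first,
                                           it->second.second));
      }
      if (nb_mult.size() < 2) continue;
      bool variant = false;
      if (nb_mult.size() == 2) {
        int a0 = nb_mult[0].first, b0 = nb_mult[0].second;
        int a1 = nb_mult[1].first, b1 = nb_mult[1].second;
        variant = ((a0 == 1 && b0 == 0 && a1 == 0 && b1 == 1) ||
                   (a0 == 0 && b0 == 1 && a1 == 1 && b1 == 0));
      }
      if (variant) n_var++;
      else         n_rep++;
    }
  }
  return List::create(_["n_h"] = (double)(2 * n_hom),
                      _["n_variant"] = (double)n_var,
                      _["n_repeat"] = (double)n_rep);
}
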