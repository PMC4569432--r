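// Alignment and simulation kernels.
//
// Identity convention used throughout the package: semi-global (overlap)
// alignment with free end gaps on both sequences, affine gap costs
// (gap of length L costs open + ext * L), match +1 / mismatch -2 /
// open 5 / ext 2; identity = matched columns / alignment columns inside
// the aligned span; coverage = aligned query bases / query length.
// IUPAC ambiguity codes count as a match iff their base sets intersect.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <random>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// ---- IUPAC -----------------------------------------------------------------

static int iupac_mask_tab[256];
static bool iupac_init_done = false;

static void iupac_init() {
  if (iupac_init_done) return;
  for (int i = 0; i < 256; ++i) iupac_mask_tab[i] = 0;
  auto set = [](char c, int m) {
    iupac_mask_tab[(unsigned char)c] = m;
    iupac_mask_tab[(unsigned char)std::tolower(c)] = m;
  };
  set('A', 1); set('C', 2); set('G', 4); set('T', 8); set('U', 8);
  set('R', 1 | 4); set('Y', 2 | 8); set('S', 2 | 4); set('W', 1 | 8);
  set('K', 4 | 8); set('M', 1 | 2);
  set('B', 2 | 4 | 8); set('D', 1 | 4 | 8); set('H', 1 | 2 | 8);
  set('V', 1 | 2 | 4); set('N', 15);
  iupac_init_done = true;
}

static inline bool iupac_match(char a, char b) {
  return (iupac_mask_tab[(unsigned char)a] & iupac_mask_tab[(unsigned char)b]) != 0;
}

// 2-bit code for unambiguous bases, -1 otherwise
static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

// distinct k-mer codes of a sequence (ACGT-only k-mers)
static void kmer_codes(const std::string& s, int k, std::vector<int>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  int code = 0, valid = 0, mask = (1 << (2 * k)) - 1;
  out.reserve(n);
  for (int i = 0; i < n; ++i) {
    int b = base2(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= k) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// ---- overlap alignment -----------------------------------------------------

struct AlnResult {
  int score;
  int matches;
  int columns;
  int a_start, a_end;   // 0-based half-open on query
  int b_start, b_end;   // 0-based half-open on reference
  double identity;      // matches / path columns (read-span identity)
  double gid;           // matches / (path columns + unaligned query bases)
  double coverage;
  std::string a_aln, b_aln;  // filled only on request
};

// Banded overlap alignment of a (query, length m) vs b (reference, length n).
// Band: cells (i, j) with |j - i - d0| <= w.  Pass w >= max(m, n) for full DP.
// States: M (pair), X (gap in reference, consumes a), Y (gap in query).
// Storage uses the diagonal-preserving layout col = j - i - d0 + w, so the
// diagonal predecessor sits at the same column of the previous row.
static AlnResult overlap_align(const std::string& a, const std::string& b,
                               int d0, int w,
                               int match, int mismatch, int gopen, int gext,
                               bool want_strings) {
  iupac_init();
  const int m = (int)a.size(), n = (int)b.size();
  AlnResult res;
  res.score = NEG; res.matches = 0; res.columns = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  res.identity = 0.0; res.gid = 0.0; res.coverage = 0.0;
  if (m == 0 || n == 0) return res;

  const int W = 2 * w + 1;
  std::vector<int> M((size_t)(m + 1) * W, NEG), X((size_t)(m + 1) * W, NEG),
      Y((size_t)(m + 1) * W, NEG);
  const int gopen_ext = gopen + gext;
  auto col_of = [&](int i, int j) { return j - i - d0 + w; };

  // free-start boundary: row 0 and column 0 cells carry value 0 in M
  {
    int lo = std::max(0, d0 - w), hi = std::min(n, d0 + w);
    for (int j = lo; j <= hi; ++j) M[col_of(0, j)] = 0;
  }
  for (int i = 0; i <= m; ++i) {
    int c = col_of(i, 0);
    if (c >= 0 && c <= 2 * w) M[(size_t)i * W + c] = 0;
  }

  for (int i = 1; i <= m; ++i) {
    int lo = std::max(1, i + d0 - w), hi = std::min(n, i + d0 + w);
    if (lo > hi) continue;
    int* Mi = &M[(size_t)i * W]; int* Mp = &M[(size_t)(i - 1) * W];
    int* Xi = &X[(size_t)i * W]; int* Xp = &X[(size_t)(i - 1) * W];
    int* Yi = &Y[(size_t)i * W]; int* Yp = &Y[(size_t)(i - 1) * W];
    const char ai = a[i - 1];
    const int amask = iupac_mask_tab[(unsigned char)ai];
    int c = lo - i - d0 + w;  // column of j = lo in this row
    for (int j = lo; j <= hi; ++j, ++c) {
      // diagonal predecessor (i-1, j-1): same column c
      int diag = Mp[c];
      if (Xp[c] > diag) diag = Xp[c];
      if (Yp[c] > diag) diag = Yp[c];
      int s = (amask & iupac_mask_tab[(unsigned char)b[j - 1]]) ? match : mismatch;
      Mi[c] = (diag <= NEG / 2) ? NEG : diag + s;
      // up predecessor (i-1, j): column c + 1
      int xv = NEG;
      if (c + 1 <= 2 * w) {
        int xm = Mp[c + 1], xx = Xp[c + 1];
        if (xm > NEG / 2) xv = xm - gopen_ext;
        if (xx > NEG / 2 && xx - gext > xv) xv = xx - gext;
      }
      Xi[c] = xv;
      // left predecessor (i, j-1): column c - 1
      int yv = NEG;
      if (c - 1 >= 0) {
        int ym = Mi[c - 1], yy = Yi[c - 1];
        if (ym > NEG / 2) yv = ym - gopen_ext;
        if (yy > NEG / 2 && yy - gext > yv) yv = yy - gext;
      }
      Yi[c] = yv;
    }
  }

  auto getv = [&](const std::vector<int>& V, int i, int j) -> int {
    if (i < 0 || i > m || j < 0 || j > n) return NEG;
    int c = col_of(i, j);
    if (c < 0 || c > 2 * w) return NEG;
    return V[(size_t)i * W + c];
  };

  // best end: query exhausted (i = m) or reference exhausted (j = n)
  int bi = -1, bj = -1, bstate = 0, best = NEG;
  {
    int lo = std::max(1, m + d0 - w), hi = std::min(n, m + d0 + w);
    for (int j = lo; j <= hi; ++j) {
      int v[3] = { getv(M, m, j), getv(X, m, j), getv(Y, m, j) };
      for (int st = 0; st < 3; ++st)
        if (v[st] > best) { best = v[st]; bi = m; bj = j; bstate = st; }
    }
  }
  for (int i = 1; i <= m; ++i) {
    int v[3] = { getv(M, i, n), getv(X, i, n), getv(Y, i, n) };
    for (int st = 0; st < 3; ++st)
      if (v[st] > best) { best = v[st]; bi = i; bj = n; bstate = st; }
  }
  if (bi < 0 || best <= NEG / 2) return res;

  // traceback
  std::string aa, bb;
  int i = bi, j = bj, state = bstate;
  int matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {  // M
      char ca = a[i - 1], cb = b[j - 1];
      if (want_strings) { aa.push_back(ca); bb.push_back(cb); }
      ++columns;
      bool hit = iupac_match(ca, cb);
      if (hit) ++matches;
      int s = hit ? match : mismatch;
      int need = getv(M, i, j) - s;
      --i; --j;
      if (i == 0 || j == 0) break;  // reached the free-start boundary
      if (getv(M, i, j) == need) state = 0;
      else if (getv(X, i, j) == need) state = 1;
      else if (getv(Y, i, j) == need) state = 2;
      else break;
    } else if (state == 1) {  // X: a[i-1] vs gap
      if (want_strings) { aa.push_back(a[i - 1]); bb.push_back('-'); }
      ++columns;
      int need = getv(X, i, j);
      state = (getv(X, i - 1, j) - gext == need) ? 1 : 0;
      --i;
    } else {  // Y: gap vs b[j-1]
      if (want_strings) { aa.push_back('-'); bb.push_back(b[j - 1]); }
      ++columns;
      int need = getv(Y, i, j);
      state = (getv(Y, i, j - 1) - gext == need) ? 2 : 0;
      --j;
    }
  }
  res.score = best;
  res.matches = matches;
  res.columns = columns;
  res.a_start = i; res.a_end = bi;
  res.b_start = j; res.b_end = bj;
  res.identity = columns > 0 ? (double)matches / columns : 0.0;
  int q_unaligned = i + (m - bi);
  res.gid = (columns + q_unaligned) > 0
      ? (double)matches / (columns + q_unaligned) : 0.0;
  res.coverage = (double)(bi - i) / m;
  if (want_strings) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    res.a_aln = aa; res.b_aln = bb;
  }
  return res;
}

static AlnResult full_align(const std::string& a, const std::string& b,
                            int match, int mismatch, int gopen, int gext,
                            bool want_strings) {
  int w = (int)std::max(a.size(), b.size()) + 1;
  return overlap_align(a, b, 0, w, match, mismatch, gopen, gext, want_strings);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b,
               int match = 1, int mismatch = -2, int gap_open = 5,
               int gap_ext = 2, int band = -1, int diag = 0) {
  AlnResult r;
  if (band < 0) r = full_align(a, b, match, mismatch, gap_open, gap_ext, true);
  else r = overlap_align(a, b, diag, band, match, mismatch, gap_open, gap_ext, true);
  return List::create(
      _["score"] = r.score <= NEG / 2 ? NA_INTEGER : r.score,
      _["identity"] = r.identity, _["global_identity"] = r.gid,
      _["coverage"] = r.coverage,
      _["matches"] = r.matches, _["columns"] = r.columns,
      _["a_start"] = r.a_start + 1, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start + 1, _["b_end"] = r.b_end,
      _["a_aln"] = r.a_aln, _["b_aln"] = r.b_aln);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs, int band = -1) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      AlnResult r = band < 0
          ? full_align(ss[i], ss[j], 1, -2, 5, 2, false)
          : overlap_align(ss[i], ss[j], 0, band, 1, -2, 5, 2, false);
      out(i, j) = r.gid;
      out(j, i) = r.gid;
    }
  }
  return out;
}

// ---- greedy centroid clustering -------------------------------------------
//
// Sequences are processed in the caller-supplied order.  A sequence joins the
// FIRST centroid (in founding order) whose identity is >= threshold, else it
// founds a new centroid.  A shared-k-mer lower bound prunes centroids that
// provably cannot reach the threshold (slack factor 0.5 keeps the bound
// conservative; exactness versus the brute-force oracle is asserted in tests).

// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 int k = 8, int band = -1) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  IntegerVector assign(n);
  if (n == 0) return assign;

  int nbuck = 1 << (2 * k);
  std::vector<std::vector<int>> post(nbuck);  // kmer -> centroid ids
  std::vector<int> cent_seq;                  // centroid id -> seq index
  std::vector<int> cent_nkmer;                // centroid id -> #distinct kmers
  std::vector<int> count;                     // per-centroid shared count
  std::vector<int> touched;
  std::vector<int> km;

  for (int i = 0; i < n; ++i) {
    kmer_codes(ss[i], k, km);
    int C = (int)cent_seq.size();
    if ((int)count.size() < C) count.resize(C, 0);
    touched.clear();
    for (int code : km)
      for (int c : post[code]) {
        if (count[c] == 0) touched.push_back(c);
        ++count[c];
      }
    int Lq = (int)ss[i].size();
    int nk = (int)km.size();   // distinct k-mers (repeats collapse)
    int joined = -1;
    for (int c = 0; c < C; ++c) {
      int Lc = (int)ss[cent_seq[c]].size();
      int Lmax = std::max(Lq, Lc);
      double bound = 0.75 * (nk - (double)k * (1.0 - threshold) * Lmax * 1.5);
      if (bound > 0.5 && count[c] < (int)bound) continue;
      const std::string& cs = ss[cent_seq[c]];
      AlnResult r = band < 0
          ? full_align(ss[i], cs, 1, -2, 5, 2, false)
          : overlap_align(ss[i], cs, 0, band, 1, -2, 5, 2, false);
      if (r.gid >= threshold) { joined = c; break; }
    }
    for (int c : touched) count[c] = 0;
    if (joined < 0) {
      joined = C;
      cent_seq.push_back(i);
      cent_nkmer.push_back((int)km.size());
      count.push_back(0);
      for (int code : km) post[code].push_back(joined);
    }
    assign[i] = joined + 1;  // 1-based centroid id
  }
  return assign;
}

// ---- read mapping ----------------------------------------------------------
//
// Best-hit search of each read against a reference set.  Candidate references
// are ranked by shared distinct k-mers; the best diagonal is estimated from
// k-mer position offsets and a banded alignment run around it.  Ties broken by
// identity, then coverage, then smaller reference index (callers pass
// references sorted by id).  top_n caps candidates; stop_after non-improving
// candidates end the scan early (set both large for exhaustive behaviour).

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        double min_identity = 0.96, double min_coverage = 0.90,
                        int k = 8, int top_n = 50, int band = 24,
                        int stop_after = 6, bool prune = true) {
  int nr = reads.size(), nf = refs.size();
  if (nf == 0) stop("empty reference set");
  std::vector<std::string> rr(nr), ff(nf);
  for (int i = 0; i < nr; ++i) rr[i] = as<std::string>(reads[i]);
  for (int i = 0; i < nf; ++i) ff[i] = as<std::string>(refs[i]);

  // positional k-mer index over references
  int nbuck = 1 << (2 * k);
  std::vector<std::vector<std::pair<int, int>>> post(nbuck);
  int max_ref_len = 0;
  for (int f = 0; f < nf; ++f) {
    const std::string& s = ff[f];
    int n = (int)s.size();
    max_ref_len = std::max(max_ref_len, n);
    int code = 0, valid = 0, mask = (1 << (2 * k)) - 1;
    for (int i = 0; i < n; ++i) {
      int b = base2(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= k) post[code].push_back({f, i - k + 1});
    }
  }

  const int B = 16;  // diagonal bucket width
  std::vector<int> count(nf, 0);
  std::vector<int> last_kmer(nf, -1);
  int max_read_len = 0;
  for (int i = 0; i < nr; ++i) max_read_len = std::max(max_read_len, (int)rr[i].size());
  int nb_diag = (max_ref_len + max_read_len) / B + 3;
  std::vector<int> dcount((size_t)nf * nb_diag, 0);
  std::vector<std::pair<int, int>> dtouched;
  std::vector<int> touched, km;

  IntegerVector best_ref(nr, NA_INTEGER);
  NumericVector best_id(nr, NA_REAL), best_cov(nr, NA_REAL);

  for (int i = 0; i < nr; ++i) {
    const std::string& q = rr[i];
    int m = (int)q.size();
    // distinct-kmer counting with per-ref dedup via last_kmer marker
    kmer_codes(q, k, km);
    touched.clear(); dtouched.clear();
    for (size_t t = 0; t < km.size(); ++t) {
      int code = km[t];
      for (auto& pr : post[code]) {
        int f = pr.first;
        if (last_kmer[f] != (int)t) {
          last_kmer[f] = (int)t;
          if (count[f] == 0) touched.push_back(f);
          ++count[f];
        }
        // diagonal votes use all positions
        // query position of this kmer unknown after dedup/sort; use first match
      }
    }
    // second pass for diagonals (positional, not distinct)
    {
      int code = 0, valid = 0, mask = (1 << (2 * k)) - 1;
      for (int p = 0; p < m; ++p) {
        int b = base2(q[p]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | b) & mask;
        if (valid + 1 >= k) {
          int qpos = p - k + 1;
          for (auto& pr : post[code]) {
            int f = pr.first, d = pr.second - qpos + max_read_len;
            if (d < 0) d = 0;
            int bk = d / B; if (bk >= nb_diag) bk = nb_diag - 1;
            size_t ix = (size_t)f * nb_diag + bk;
            if (dcount[ix] == 0) dtouched.push_back({f, bk});
            ++dcount[ix];
          }
        }
        ++valid;
      }
    }
    // rank candidates
    std::vector<std::pair<int, int>> cand;  // (-count, ref)
    cand.reserve(touched.size());
    for (int f : touched) cand.push_back({-count[f], f});
    std::sort(cand.begin(), cand.end());
    int ncand = std::min((int)cand.size(), top_n);

    // best accepted hit (passes both thresholds; ranked by span identity,
    // then coverage, then reference index) and best overall hit (ranked by
    // query-penalised identity; reported for unmapped reads)
    double pid = -1.0, pcov = -1.0; int pref = -1;
    double agid = -1.0, acov = -1.0; int aref = -1;
    int nk = (int)km.size();
    int nonimp = 0;
    for (int ci = 0; ci < ncand; ++ci) {
      int f = cand[ci].second;
      if (prune) {
        double bound = 0.75 * ((nk) - (double)k * (1.0 - min_identity) * m * 1.5);
        if (bound > 0.5 && count[f] < (int)bound) break;  // sorted: rest smaller
      }
      // best diagonal bucket for this ref
      int bbk = -1, bbc = -1;
      for (auto& pr : dtouched)
        if (pr.first == f) {
          size_t ix = (size_t)f * nb_diag + pr.second;
          if (dcount[ix] > bbc) { bbc = dcount[ix]; bbk = pr.second; }
        }
      AlnResult r;
      if (bbk < 0 || band < 0) {
        r = full_align(q, ff[f], 1, -2, 5, 2, false);
      } else {
        int d0 = bbk * B + B / 2 - max_read_len;
        r = overlap_align(q, ff[f], d0, band + B, 1, -2, 5, 2, false);
      }
      bool improved = false;
      if (r.identity >= min_identity && r.coverage >= min_coverage) {
        if (r.identity > pid || (r.identity == pid && r.coverage > pcov) ||
            (r.identity == pid && r.coverage == pcov &&
             (pref < 0 || f < pref))) {
          pid = r.identity; pcov = r.coverage; pref = f; improved = true;
        }
      }
      if (r.gid > agid || (r.gid == agid && (aref < 0 || f < aref))) {
        agid = r.gid; acov = r.coverage; aref = f;
        improved = true;
      }
      if (improved) nonimp = 0;
      else if (++nonimp >= stop_after) break;
    }
    for (int f : touched) count[f] = 0;
    for (auto& pr : dtouched) dcount[(size_t)pr.first * nb_diag + pr.second] = 0;

    if (pref >= 0) {
      best_ref[i] = pref + 1;
      best_id[i] = pid;
      best_cov[i] = pcov;
    } else if (aref >= 0) {
      // no accepted hit: report the best sub-threshold hit, identity on the
      // query-penalised scale
      best_ref[i] = -(aref + 1);
      best_id[i] = agid;
      best_cov[i] = acov;
    }
  }
  return DataFrame::create(_["ref"] = best_ref, _["identity"] = best_id,
                           _["coverage"] = best_cov);
}

// ---- sequence simulation helpers ------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double error_rate,
                                int seed) {
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, 2);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2(s[p]);
      if (b < 0) continue;
      if (unif(rng) < error_rate) {
        int r = pick(rng);
        if (r >= b) ++r;  // a different base
        s[p] = bases[r];
      }
    }
    out[i] = s;
  }
  return out;
}

// Phred quality strings: per-read mean ~ N(mean_q, sd_between), per-base
// ~ N(read mean, sd_within), rounded and clamped to [2, 40], Phred+33.
// [[Rcpp::export]]
CharacterVector cpp_quality_strings(IntegerVector lens, double mean_q,
                                    double sd_between, double sd_within,
                                    int seed) {
  std::mt19937 rng((uint32_t)seed);
  std::normal_distribution<double> nb(0.0, 1.0);
  int n = lens.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    double mu = mean_q + sd_between * nb(rng);
    int L = lens[i];
    std::string s((size_t)L, '!');
    for (int p = 0; p < L; ++p) {
      int q = (int)std::lround(mu + sd_within * nb(rng));
      if (q < 2) q = 2;
      if (q > 40) q = 40;
      s[p] = (char)(33 + q);
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mean_quality(CharacterVector quals, int offset = 33) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(quals, i));
    long sum = 0; int L = 0;
    for (; s[L]; ++L) sum += s[L] - offset;
    out[i] = L > 0 ? (double)sum / L : NA_REAL;
  }
  return out;
}

// ---- primer trimming -------------------------------------------------------
//
// Forward primer matched at the 5' end (IUPAC-aware Hamming, <= max_mm_f);
// reverse-complemented reverse primer searched in a 3' window, rightmost
// acceptable position wins.  status: 0 = ok, 1 = no forward match,
// 2 = empty after trimming.

// [[Rcpp::export]]
List cpp_trim_primers(CharacterVector seqs, CharacterVector quals,
                      std::string fwd, std::string rev_rc,
                      int max_mm_f = 2, int max_mm_r = 2,
                      int rev_window = 30) {
  iupac_init();
  int n = seqs.size();
  int lf = (int)fwd.size(), lr = (int)rev_rc.size();
  bool have_qual = quals.size() == n;
  CharacterVector oseq(n), oqual(n);
  IntegerVector status(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    if (L < lf + 1) { status[i] = 1; oseq[i] = ""; oqual[i] = ""; continue; }
    int mm = 0;
    for (int p = 0; p < lf; ++p)
      if (!iupac_match(fwd[p], s[p])) ++mm;
    if (mm > max_mm_f) { status[i] = 1; oseq[i] = ""; oqual[i] = ""; continue; }
    int end = L;  // half-open end of insert
    if (lr > 0 && L - lf >= lr) {
      int lo = std::max(lf, L - lr - rev_window);
      for (int pos = L - lr; pos >= lo; --pos) {
        int rmm = 0;
        for (int p = 0; p < lr && rmm <= max_mm_r; ++p)
          if (!iupac_match(rev_rc[p], s[pos + p])) ++rmm;
        if (rmm <= max_mm_r) { end = pos; break; }
      }
    }
    if (end <= lf) { status[i] = 2; oseq[i] = ""; oqual[i] = ""; continue; }
    status[i] = 0;
    oseq[i] = s.substr(lf, end - lf);
    if (have_qual) {
      std::string q = as<std::string>(quals[i]);
      oqual[i] = (int)q.size() == L ? q.substr(lf, end - lf) : q;
    }
  }
  return List::create(_["sequence"] = oseq, _["quality"] = oqual,
                      _["status"] = status);
}
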