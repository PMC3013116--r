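// Seed-and-extend short-read alignment against a mediator genome.
//
// Model: an alignment is a contiguous run of columns, each column one of
//   M  (ref base, read base)          -- match or mismatch
//   I  (gap,      read base)          -- insertion relative to the reference
//   D  (ref base, gap)                -- deletion relative to the reference
// errors = mismatches + gap columns; feasible iff errors <= max_errors and
// the number of matched (M) columns >= min_align_len.  Gap columns are
// forbidden at either end of an alignment.  The best alignment minimises
// errors, then maximises matched columns, then minimises gap columns (gaps
// are penalised above mismatches, as in blastn scoring), then minimises the
// reference start, then prefers the plus strand.  Reads whose two best
// placements tie on all of (errors, matched columns, gap columns) at
// distinct (strand, start) loci are discarded as ambiguous.
//
// The per-cell DP value is the scalar score = 64 * matched - gaps, whose
// ordering is exactly lexicographic (max matched, min gaps) since gaps <= 6.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int SCALE = 64;  // > max gap columns per alignment

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N and friends: never match anything
  }
}

static const char DEC[5] = {'A', 'C', 'G', 'T', 'N'};

static inline int matched_of(int score) { return (score + SCALE - 1) / SCALE; }

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)enc(s[i]);
  return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (int8_t)(3 - b) : (int8_t)4;
  }
  return r;
}

// ---------------------------------------------------------------------------
// Seed index: exact-match lookup from every word_size-mer of the forward
// reference strand to its (0-based) start positions; words containing N are
// excluded.

struct SeedIndex {
  int w;
  int ref_len;
  std::unordered_map<uint32_t, std::vector<int32_t>> idx;
};

// [[Rcpp::export]]
SEXP cpp_seed_index(std::string ref, int word_size) {
  if (word_size < 4 || word_size > 15)
    stop("word_size must be between 4 and 15");
  if ((int)ref.size() < word_size)
    stop("reference shorter than word_size");
  SeedIndex* si = new SeedIndex();
  si->w = word_size;
  si->ref_len = (int)ref.size();
  uint32_t mask = (1u << (2 * word_size)) - 1u;
  uint32_t val = 0;
  int run = 0;  // length of current run of ACGT bases
  for (int i = 0; i < (int)ref.size(); ++i) {
    int b = enc(ref[i]);
    if (b > 3) {
      run = 0;
      val = 0;
      continue;
    }
    val = ((val << 2) | (uint32_t)b) & mask;
    if (++run >= word_size) si->idx[val].push_back(i - word_size + 1);
  }
  XPtr<SeedIndex> xp(si, true);
  return xp;
}

// [[Rcpp::export]]
IntegerVector cpp_seed_lookup(SEXP xp_, std::string word) {
  XPtr<SeedIndex> xp(xp_);
  if ((int)word.size() != xp->w) stop("word length != word_size of index");
  uint32_t val = 0;
  for (char c : word) {
    int b = enc(c);
    if (b > 3) return IntegerVector(0);
    val = (val << 2) | (uint32_t)b;
  }
  auto it = xp->idx.find(val);
  if (it == xp->idx.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1;
  return out;
}

// [[Rcpp::export]]
int cpp_seed_index_nwords(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return (int)xp->idx.size();
}

// [[Rcpp::export]]
int cpp_seed_index_word_size(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return xp->w;
}

// ---------------------------------------------------------------------------
// Banded DP around one candidate diagonal d (ref_pos = read_pos + d at the
// seed).  State: i read bases consumed, band offset k (diagonal d-E .. d+E),
// error budget e (at most), last column type t.  Stores the best score and,
// among ties, min ref start; parent type for traceback.  Score 0 marks an
// impossible cell (real scores are >= SCALE - max_errors > 0).

struct Band {
  int m, n, E, W, d;
  std::vector<int32_t> sc;
  std::vector<int32_t> start;
  std::vector<int8_t> pt;  // parent type 0..2; 3 = carry (e-1); -1 = fresh
  inline size_t at(int i, int k, int e, int t) const {
    return (((size_t)i * W + k) * (E + 1) + e) * 3 + t;
  }
};

static void run_band(Band& B, const std::vector<int8_t>& r,
                     const std::vector<int8_t>& R) {
  const int m = B.m, n = B.n, E = B.E, W = B.W, d = B.d;
  size_t ncell = (size_t)(m + 1) * W * (E + 1) * 3;
  B.sc.assign(ncell, 0);
  B.start.assign(ncell, 0);
  B.pt.assign(ncell, -1);
  for (int i = 0; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + (d - E) + k;
      if (j < 0 || j > n) continue;
      for (int e = 0; e <= E; ++e) {
        for (int t = 0; t < 3; ++t) {
          int32_t bl = 0;
          int32_t bs = 0;
          int8_t bp = -1;
          // carry: same cell, smaller budget
          if (e > 0) {
            size_t c = B.at(i, k, e - 1, t);
            if (B.sc[c] > bl || (B.sc[c] == bl && bl > 0 && B.start[c] < bs)) {
              bl = B.sc[c]; bs = B.start[c]; bp = 3;
            }
          }
          if (t == 0) {  // M consumes r[i-1], R[j-1]
            if (i >= 1 && j >= 1) {
              int mm = (r[i - 1] < 4 && r[i - 1] == R[j - 1]) ? 0 : 1;
              if (e >= mm) {
                if (SCALE > bl || (SCALE == bl && (int32_t)(j - 1) < bs)) {
                  bl = SCALE; bs = j - 1; bp = -1;
                }
                for (int tp = 0; tp < 3; ++tp) {
                  size_t c = B.at(i - 1, k, e - mm, tp);
                  if (B.sc[c] <= 0) continue;
                  int32_t nl = B.sc[c] + SCALE;
                  if (nl > bl || (nl == bl && B.start[c] < bs)) {
                    bl = nl; bs = B.start[c]; bp = (int8_t)tp;
                  }
                }
              }
            }
          } else if (t == 1) {  // I consumes r[i-1] only
            if (i >= 1 && k + 1 < W && e >= 1) {
              for (int tp = 0; tp < 3; ++tp) {
                size_t c = B.at(i - 1, k + 1, e - 1, tp);
                if (B.sc[c] <= 0) continue;
                int32_t nl = B.sc[c] - 1;
                if (nl > bl || (nl == bl && B.start[c] < bs)) {
                  bl = nl; bs = B.start[c]; bp = (int8_t)tp;
                }
              }
            }
          } else {  // D consumes R[j-1] only
            if (j >= 1 && k >= 1 && e >= 1) {
              for (int tp = 0; tp < 3; ++tp) {
                size_t c = B.at(i, k - 1, e - 1, tp);
                if (B.sc[c] <= 0) continue;
                int32_t nl = B.sc[c] - 1;
                if (nl > bl || (nl == bl && B.start[c] < bs)) {
                  bl = nl; bs = B.start[c]; bp = (int8_t)tp;
                }
              }
            }
          }
          size_t c = B.at(i, k, e, t);
          B.sc[c] = bl; B.start[c] = bs; B.pt[c] = bp;
        }
      }
    }
  }
}

// Summary of the best M-terminated cells of one band, per error layer.
struct BandBest {
  std::vector<int32_t> sc;                // best score per e
  std::vector<int32_t> start;             // min ref start among best
  std::vector<int> bi, bk;                // end cell of the winner
  std::vector<std::vector<int32_t>> alts; // distinct starts tying best (<=3)
};

static void extract_band(const Band& B, BandBest& out) {
  const int E = B.E;
  out.sc.assign(E + 1, 0);
  out.start.assign(E + 1, 0);
  out.bi.assign(E + 1, -1);
  out.bk.assign(E + 1, -1);
  out.alts.assign(E + 1, {});
  for (int e = 0; e <= E; ++e) {
    for (int i = 0; i <= B.m; ++i) {
      for (int k = 0; k < B.W; ++k) {
        size_t c = B.at(i, k, e, 0);
        int32_t l = B.sc[c];
        if (l <= 0) continue;
        if (l > out.sc[e]) {
          out.sc[e] = l; out.start[e] = B.start[c];
          out.bi[e] = i; out.bk[e] = k;
          out.alts[e].clear();
          out.alts[e].push_back(B.start[c]);
        } else if (l == out.sc[e]) {
          int32_t s = B.start[c];
          bool seen = false;
          for (int32_t x : out.alts[e]) if (x == s) { seen = true; break; }
          if (!seen && out.alts[e].size() < 3) out.alts[e].push_back(s);
          if (s < out.start[e]) {
            out.start[e] = s; out.bi[e] = i; out.bk[e] = k;
          }
        }
      }
    }
  }
}

// One aligned read, traced back to explicit columns.
struct AlnResult {
  int status;  // 0 aligned, 1 unaligned, 2 ambiguous, 3 too_short
  int ref_start, ref_end;  // 1-based inclusive
  char strand;
  int n_mm, n_gap, alen;
  std::string ref_aln, read_aln;
};

static void traceback(const Band& B, const std::vector<int8_t>& r,
                      const std::vector<int8_t>& R, int i, int k, int e,
                      AlnResult& res) {
  std::string ra, qa;
  int t = 0;  // winners end with M
  int n_mm = 0, n_gap = 0;
  while (true) {
    int j = i + (B.d - B.E) + k;
    size_t c = B.at(i, k, e, t);
    int8_t p = B.pt[c];
    if (p == 3) { e -= 1; continue; }  // carry, same column set
    if (t == 0) {
      ra.push_back(DEC[(int)R[j - 1]]);
      qa.push_back(DEC[(int)r[i - 1]]);
      if (!(r[i - 1] < 4 && r[i - 1] == R[j - 1])) n_mm++;
      if (p < 0) { res.ref_start = j; break; }  // fresh start at this column
      int mm = (r[i - 1] < 4 && r[i - 1] == R[j - 1]) ? 0 : 1;
      i -= 1; e -= mm; t = p;
    } else if (t == 1) {
      ra.push_back('-');
      qa.push_back(DEC[(int)r[i - 1]]);
      n_gap++;
      i -= 1; k += 1; e -= 1; t = p;
    } else {
      ra.push_back(DEC[(int)R[j - 1]]);
      qa.push_back('-');
      n_gap++;
      k -= 1; e -= 1; t = p;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  res.ref_aln = ra;
  res.read_aln = qa;
  res.n_mm = n_mm;
  res.n_gap = n_gap;
  res.alen = (int)ra.size();
  int refbases = 0;
  for (char ch : ra) if (ch != '-') refbases++;
  res.ref_end = res.ref_start + refbases - 1;
}

// Align one (encoded) read; needs the index, the encoded forward reference.
static AlnResult align_one(const std::vector<int8_t>& fwd, SeedIndex* si,
                           const std::vector<int8_t>& R, int E, int L,
                           bool both_strands) {
  AlnResult res;
  res.status = 1;
  const int m = (int)fwd.size();
  const int n = (int)R.size();
  const int w = si->w;
  if (m < w) { res.status = 3; return res; }
  if (m > 10000) { res.status = 3; return res; }

  std::vector<int8_t> rc;
  int nstrand = both_strands ? 2 : 1;
  if (both_strands) rc = revcomp(fwd);

  // candidate diagonals per strand
  std::vector<std::vector<int>> diags(nstrand);
  uint32_t mask = (1u << (2 * w)) - 1u;
  for (int s = 0; s < nstrand; ++s) {
    const std::vector<int8_t>& r = (s == 0) ? fwd : rc;
    uint32_t val = 0;
    int run = 0;
    std::vector<int> ds;
    for (int i = 0; i < m; ++i) {
      if (r[i] > 3) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint32_t)r[i]) & mask;
      if (++run >= w) {
        auto it = si->idx.find(val);
        if (it != si->idx.end())
          for (int32_t p : it->second) ds.push_back(p - (i - w + 1));
      }
    }
    std::sort(ds.begin(), ds.end());
    ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
    diags[s] = ds;
  }

  // fast path: a full-length ungapped 0-error placement is globally optimal
  {
    std::vector<std::pair<int, int>> perfect;  // (strand, start0)
    for (int s = 0; s < nstrand; ++s) {
      const std::vector<int8_t>& r = (s == 0) ? fwd : rc;
      for (int d : diags[s]) {
        if (d < 0 || d + m > n) continue;
        bool ok = true;
        for (int i = 0; i < m; ++i)
          if (!(r[i] < 4 && r[i] == R[d + i])) { ok = false; break; }
        if (ok) perfect.push_back({s, d});
      }
    }
    if (!perfect.empty() && m >= L) {
      if (perfect.size() > 1) { res.status = 2; return res; }
      int s = perfect[0].first, d = perfect[0].second;
      const std::vector<int8_t>& r = (s == 0) ? fwd : rc;
      res.status = 0;
      res.strand = (s == 0) ? '+' : '-';
      res.ref_start = d + 1;
      res.ref_end = d + m;
      res.n_mm = 0; res.n_gap = 0; res.alen = m;
      std::string ra(m, 'N');
      for (int i = 0; i < m; ++i) ra[i] = DEC[(int)r[i]];
      res.ref_aln = ra;
      res.read_aln = ra;
      return res;
    }
  }

  // banded DP on every candidate diagonal, merged lexicographically
  std::vector<int32_t> gsc(E + 1, 0);
  std::vector<int32_t> gstart(E + 1, 0);
  std::vector<int> gs(E + 1, -1), gd(E + 1, 0), gi(E + 1, -1), gk(E + 1, -1);
  std::vector<std::vector<std::pair<int, int32_t>>> galts(E + 1);
  Band B;
  BandBest bb;
  for (int s = 0; s < nstrand; ++s) {
    const std::vector<int8_t>& r = (s == 0) ? fwd : rc;
    for (int d : diags[s]) {
      B.m = m; B.n = n; B.E = E; B.W = 2 * E + 1; B.d = d;
      run_band(B, r, R);
      extract_band(B, bb);
      for (int e = 0; e <= E; ++e) {
        if (bb.sc[e] <= 0) continue;
        bool better = bb.sc[e] > gsc[e] ||
                      (bb.sc[e] == gsc[e] &&
                       (bb.start[e] < gstart[e] ||
                        (bb.start[e] == gstart[e] && s == 0 && gs[e] == 1)));
        if (bb.sc[e] > gsc[e]) galts[e].clear();
        if (bb.sc[e] >= gsc[e]) {
          for (int32_t st : bb.alts[e]) {
            bool seen = false;
            for (auto& pr : galts[e])
              if (pr.first == s && pr.second == st) { seen = true; break; }
            if (!seen && galts[e].size() < 3) galts[e].push_back({s, st});
          }
        }
        if (better) {
          gsc[e] = bb.sc[e]; gstart[e] = bb.start[e];
          gs[e] = s; gd[e] = d; gi[e] = bb.bi[e]; gk[e] = bb.bk[e];
        }
      }
    }
  }

  int estar = -1;
  for (int e = 0; e <= E; ++e)
    if (gsc[e] > 0 && matched_of(gsc[e]) >= L) { estar = e; break; }
  if (estar < 0) { res.status = 1; return res; }
  if (galts[estar].size() > 1) { res.status = 2; return res; }

  // re-run the winning band and trace back explicit columns
  int s = gs[estar];
  const std::vector<int8_t>& r = (s == 0) ? fwd : rc;
  B.m = m; B.n = n; B.E = E; B.W = 2 * E + 1; B.d = gd[estar];
  run_band(B, r, R);
  res.status = 0;
  res.strand = (s == 0) ? '+' : '-';
  traceback(B, r, R, gi[estar], gk[estar], estar, res);
  return res;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, SEXP xp_, std::string ref,
                     int max_errors, int min_align_len, bool both_strands) {
  XPtr<SeedIndex> si(xp_);
  std::vector<int8_t> R = encode(ref);
  int nr = reads.size();
  CharacterVector status(nr), strand(nr), ref_aln(nr), read_aln(nr);
  IntegerVector ref_start(nr), ref_end(nr), n_mm(nr), n_gap(nr), alen(nr);
  for (int q = 0; q < nr; ++q) {
    std::string rd = as<std::string>(reads[q]);
    AlnResult a = align_one(encode(rd), si, R, max_errors, min_align_len,
                            both_strands);
    switch (a.status) {
      case 0: status[q] = "aligned"; break;
      case 1: status[q] = "unaligned"; break;
      case 2: status[q] = "ambiguous"; break;
      default: status[q] = "too_short";
    }
    if (a.status == 0) {
      strand[q] = std::string(1, a.strand);
      ref_start[q] = a.ref_start;
      ref_end[q] = a.ref_end;
      n_mm[q] = a.n_mm;
      n_gap[q] = a.n_gap;
      alen[q] = a.alen;
      ref_aln[q] = a.ref_aln;
      read_aln[q] = a.read_aln;
    } else {
      strand[q] = NA_STRING;
      ref_start[q] = NA_INTEGER;
      ref_end[q] = NA_INTEGER;
      n_mm[q] = NA_INTEGER;
      n_gap[q] = NA_INTEGER;
      alen[q] = NA_INTEGER;
      ref_aln[q] = NA_STRING;
      read_aln[q] = NA_STRING;
    }
    if (q % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["strand"] = strand,
                      _["n_mismatches"] = n_mm, _["n_gap_columns"] = n_gap,
                      _["aligned_len"] = alen, _["ref_aln"] = ref_aln,
                      _["read_aln"] = read_aln);
}

// ---------------------------------------------------------------------------
// Exhaustive DP oracle: full (unbanded, unseeded) scan over all placements
// and strands under the identical objective.  Rolling rows; reports the
// optimum (errors, matched columns, gap columns, ref_start, strand) only.

struct OracleCand {
  bool found = false;
  int e = 0, sc = 0, start = 0, strand = 0;
};

static void oracle_strand(const std::vector<int8_t>& r,
                          const std::vector<int8_t>& R, int E, int L,
                          int strand, OracleCand& best) {
  const int m = (int)r.size(), n = (int)R.size();
  const int S = (E + 1) * 3;
  std::vector<int32_t> lprev((size_t)(n + 1) * S, 0), lcur((size_t)(n + 1) * S, 0);
  std::vector<int32_t> sprev((size_t)(n + 1) * S, 0), scur((size_t)(n + 1) * S, 0);
  std::vector<int32_t> esc(E + 1, 0);
  std::vector<int32_t> estart(E + 1, 0);
  auto at = [S](int j, int e, int t) { return (size_t)j * S + e * 3 + t; };
  for (int i = 0; i <= m; ++i) {
    std::fill(lcur.begin(), lcur.end(), 0);
    for (int j = 0; j <= n; ++j) {
      for (int e = 0; e <= E; ++e) {
        for (int t = 0; t < 3; ++t) {
          int32_t bl = 0; int32_t bs = 0;
          if (e > 0) {
            size_t c = at(j, e - 1, t);
            if (lcur[c] > bl || (lcur[c] == bl && bl > 0 && scur[c] < bs)) {
              bl = lcur[c]; bs = scur[c];
            }
          }
          if (t == 0) {
            if (i >= 1 && j >= 1) {
              int mm = (r[i - 1] < 4 && r[i - 1] == R[j - 1]) ? 0 : 1;
              if (e >= mm) {
                if (SCALE > bl || (SCALE == bl && (int32_t)(j - 1) < bs)) {
                  bl = SCALE; bs = j - 1;
                }
                for (int tp = 0; tp < 3; ++tp) {
                  size_t c = at(j - 1, e - mm, tp);
                  if (lprev[c] <= 0) continue;
                  int32_t nl = lprev[c] + SCALE;
                  if (nl > bl || (nl == bl && sprev[c] < bs)) {
                    bl = nl; bs = sprev[c];
                  }
                }
              }
            }
          } else if (t == 1) {
            if (i >= 1 && e >= 1) {
              for (int tp = 0; tp < 3; ++tp) {
                size_t c = at(j, e - 1, tp);
                if (lprev[c] <= 0) continue;
                int32_t nl = lprev[c] - 1;
                if (nl > bl || (nl == bl && sprev[c] < bs)) {
                  bl = nl; bs = sprev[c];
                }
              }
            }
          } else {
            if (j >= 1 && e >= 1) {
              for (int tp = 0; tp < 3; ++tp) {
                size_t c = at(j - 1, e - 1, tp);
                if (lcur[c] <= 0) continue;
                int32_t nl = lcur[c] - 1;
                if (nl > bl || (nl == bl && scur[c] < bs)) {
                  bl = nl; bs = scur[c];
                }
              }
            }
          }
          size_t c = at(j, e, t);
          lcur[c] = bl; scur[c] = bs;
          if (t == 0 && bl > 0) {
            if (bl > esc[e]) { esc[e] = bl; estart[e] = bs; }
            else if (bl == esc[e] && bs < estart[e]) estart[e] = bs;
          }
        }
      }
    }
    std::swap(lprev, lcur);
    std::swap(sprev, scur);
  }
  for (int e = 0; e <= E; ++e) {
    if (esc[e] <= 0 || matched_of(esc[e]) < L) continue;
    OracleCand c;
    c.found = true; c.e = e; c.sc = esc[e]; c.start = estart[e];
    c.strand = strand;
    bool better = !best.found || c.e < best.e ||
                  (c.e == best.e && (c.sc > best.sc ||
                   (c.sc == best.sc && (c.start < best.start ||
                    (c.start == best.start && c.strand < best.strand)))));
    if (better) best = c;
    break;  // layers above e* cannot beat it lexicographically
  }
}

// [[Rcpp::export]]
List cpp_oracle_align(std::string read, std::string ref, int max_errors,
                      int min_align_len, bool both_strands) {
  std::vector<int8_t> r = encode(read), R = encode(ref);
  OracleCand best;
  oracle_strand(r, R, max_errors, min_align_len, 0, best);
  if (both_strands) oracle_strand(revcomp(r), R, max_errors, min_align_len, 1, best);
  if (!best.found)
    return List::create(_["aligned"] = false);
  int matched = matched_of(best.sc);
  int gaps = SCALE * matched - best.sc;
  return List::create(_["aligned"] = true, _["errors"] = best.e,
                      _["matched_columns"] = matched,
                      _["gap_columns"] = gaps,
                      _["aligned_len"] = matched + gaps,
                      _["ref_start"] = best.start + 1,
                      _["strand"] = best.strand == 0 ? "+" : "-");
}

// ---------------------------------------------------------------------------
// Pileup: project alignment columns onto the reference.

// [[Rcpp::export]]
List cpp_build_pileup(int genome_len, IntegerVector ref_start,
                      CharacterVector ref_aln, CharacterVector read_aln) {
  IntegerVector cov(genome_len), del(genome_len);
  IntegerMatrix counts(4, genome_len);  // rows A,C,G,T
  std::unordered_map<int64_t, std::unordered_map<std::string, int>> ins;
  int na = ref_start.size();
  for (int a = 0; a < na; ++a) {
    std::string ra = as<std::string>(ref_aln[a]);
    std::string qa = as<std::string>(read_aln[a]);
    int p = ref_start[a] - 1;  // 0-based next ref position
    int first = p;
    std::string pending;
    for (size_t c = 0; c < ra.size(); ++c) {
      if (ra[c] != '-') {
        if (!pending.empty()) {
          ins[p - 1][pending]++;
          pending.clear();
        }
        if (p < 0 || p >= genome_len) stop("alignment outside genome bounds");
        if (qa[c] != '-') {
          int b = enc(qa[c]);
          if (b < 4) counts(b, p)++;
        } else {
          del[p]++;
        }
        p++;
      } else {
        pending.push_back(qa[c]);
      }
    }
    if (!pending.empty()) ins[p - 1][pending]++;
    for (int q = first; q < p; ++q) cov[q]++;
    if (a % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<int> ipos;
  std::vector<std::string> iseq;
  std::vector<int> icnt;
  for (auto& kv : ins)
    for (auto& sv : kv.second) {
      ipos.push_back((int)kv.first + 1);  // 1-based anchor
      iseq.push_back(sv.first);
      icnt.push_back(sv.second);
    }
  return List::create(_["coverage"] = cov, _["del_count"] = del,
                      _["base_counts"] = counts, _["ins_pos"] = wrap(ipos),
                      _["ins_seq"] = wrap(iseq), _["ins_count"] = wrap(icnt));
}
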