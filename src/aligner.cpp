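// k-mer seeded local alignment engine (nucleotide and translated modes).
//
// The search heuristic is: hash all subject words, collect seed matches per
// query, cluster seeds by diagonal, and run a full affine-gap Smith-Waterman
// over the seeded subject window.  Because the DP over the window is exact,
// hits agree with full Smith-Waterman whenever the optimal local alignment
// contains at least one seed word (always the case at the identities this
// pipeline filters on).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// alphabets

static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4; // ambiguous
  }
}

static const char NT_CHR[5] = {'A', 'C', 'G', 'T', 'N'};

static std::vector<uint8_t> encode_nt(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) nt_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_nt(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

// amino acids: index into BLOSUM62 order ARNDCQEGHILKMFPSTWYVBZX*
static inline int aa_code(char c) {
  static const std::string order = "ARNDCQEGHILKMFPSTWYVBZX*";
  char u = (char) toupper(c);
  size_t p = order.find(u);
  return (p == std::string::npos) ? 22 : (int) p; // unknown -> X
}

static const int BLOSUM62[24][24] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

// standard genetic code, codon index = 16*b1 + 4*b2 + b3 (ACGT order)
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSSWCWCLFLF";

static std::vector<uint8_t> translate_frame(const std::vector<uint8_t> &nt,
                                            int offset) {
  std::vector<uint8_t> aa;
  size_t n = nt.size();
  for (size_t i = offset; i + 2 < n; i += 3) {
    if (nt[i] > 3 || nt[i + 1] > 3 || nt[i + 2] > 3) {
      aa.push_back((uint8_t) aa_code('X'));
    } else {
      int idx = 16 * nt[i] + 4 * nt[i + 1] + nt[i + 2];
      aa.push_back((uint8_t) aa_code(CODON_TABLE[idx]));
    }
  }
  return aa;
}

// ---------------------------------------------------------------------------
// Smith-Waterman, affine gaps, full DP over (query x subject window)

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0; // 0-based half-open
  int matches = 0, mismatches = 0, positives = 0, gap_opens = 0, aln_len = 0;
  bool ok = false;
};

struct Scorer {
  bool protein;
  int match, mismatch;
  int operator()(uint8_t a, uint8_t b) const {
    if (protein) return BLOSUM62[a][b];
    if (a > 3 || b > 3) return mismatch; // N never counts as a match
    return (a == b) ? match : mismatch;
  }
};

// Traceback byte per cell:
//   bits 0-1: provenance of H  (0 = local zero, 1 = diagonal, 2 = Is, 3 = Iq)
//   bit 2:    Is opened at this cell (came from H[i][j-1])
//   bit 3:    Iq opened at this cell (came from H[i-1][j])
// Is = gap run consuming subject chars; Iq = gap run consuming query chars.
static const uint8_t TB_SRC_MASK = 3;
static const uint8_t TB_SRC_DIAG = 1, TB_SRC_IS = 2, TB_SRC_IQ = 3;
static const uint8_t TB_IS_OPEN = 4, TB_IQ_OPEN = 8;

static AlnResult sw_align(const std::vector<uint8_t> &q,
                          const std::vector<uint8_t> &s,
                          const Scorer &sc, int gap_open, int gap_ext,
                          bool use_band = false, int band_lo = 0,
                          int band_hi = 0) {
  AlnResult res;
  int m = (int) q.size(), n = (int) s.size();
  if (m == 0 || n == 0) return res;
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Iq(n + 1, NEG);      // column-wise gap state
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (use_band) {
      jlo = std::max(1, i + band_lo);
      jhi = std::min(n, i + band_hi);
      if (jlo > jhi) { std::swap(Hprev, Hcur); continue; }
      Hcur[jlo - 1] = 0;
    } else {
      Hcur[0] = 0;
    }
    int Is = NEG;
    uint8_t *tbrow = &tb[(size_t) i * (n + 1)];
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t flags = 0;
      int is_open = Hcur[j - 1] - gap_open - gap_ext;
      int is_ext = Is - gap_ext;
      if (is_open >= is_ext) { Is = is_open; flags |= TB_IS_OPEN; }
      else Is = is_ext;
      int iq_open = Hprev[j] - gap_open - gap_ext;
      int iq_ext = Iq[j] - gap_ext;
      if (iq_open >= iq_ext) { Iq[j] = iq_open; flags |= TB_IQ_OPEN; }
      else Iq[j] = iq_ext;
      int h = Hprev[j - 1] + sc(q[i - 1], s[j - 1]);
      uint8_t src = TB_SRC_DIAG;
      if (Is > h) { h = Is; src = TB_SRC_IS; }
      if (Iq[j] > h) { h = Iq[j]; src = TB_SRC_IQ; }
      if (h <= 0) { h = 0; src = 0; }
      Hcur[j] = h;
      tbrow[j] = (uint8_t)(src | flags);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (use_band && jhi + 1 <= n) { Hcur[jhi + 1] = 0; Iq[jhi + 1] = NEG; }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;
  res.qend = bi; res.send = bj;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = Is, 2 = Iq
  int matches = 0, mism = 0, pos = 0, gapo = 0, alen = 0;
  while (i > 0 && j > 0) {
    uint8_t f = tb[(size_t) i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = f & TB_SRC_MASK;
      if (src == 0) break;
      if (src == TB_SRC_DIAG) {
        ++alen;
        bool eq = (q[i - 1] == s[j - 1]) && (sc.protein || q[i - 1] < 4);
        if (eq) ++matches; else ++mism;
        if (sc(q[i - 1], s[j - 1]) > 0) ++pos;
        --i; --j;
      } else if (src == TB_SRC_IS) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++alen;
      bool opened = (f & TB_IS_OPEN) != 0;
      --j;
      if (opened) { ++gapo; state = 0; }
    } else {
      ++alen;
      bool opened = (f & TB_IQ_OPEN) != 0;
      --i;
      if (opened) { ++gapo; state = 0; }
    }
  }
  res.qstart = i; res.sstart = j;
  res.score = best;
  res.matches = matches; res.mismatches = mism; res.positives = pos;
  res.gap_opens = gapo; res.aln_len = alen;
  res.ok = true;
  return res;
}

// ---------------------------------------------------------------------------
// seeding

struct SeedHit { int subject; int qpos; int spos; };

// nucleotide word hash over all subjects
struct NtIndex {
  int w;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > map;
  void build(const std::vector<std::vector<uint8_t> > &subs, int word) {
    w = word;
    uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    for (int si = 0; si < (int) subs.size(); ++si) {
      const std::vector<uint8_t> &s = subs[si];
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < (int) s.size(); ++p) {
        if (s[p] > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | s[p]) & mask;
        if (++run >= w) map[key].push_back(std::make_pair(si, p - w + 1));
      }
    }
  }
  void query(const std::vector<uint8_t> &q, std::vector<SeedHit> &out) const {
    uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int) q.size(); ++p) {
      if (q[p] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | q[p]) & mask;
      if (++run >= w) {
        std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator it = map.find(key);
        if (it != map.end())
          for (size_t k = 0; k < it->second.size(); ++k) {
            SeedHit h; h.subject = it->second[k].first;
            h.qpos = p - w + 1; h.spos = it->second[k].second;
            out.push_back(h);
          }
      }
    }
  }
};

// protein 3-mer index
struct AaIndex {
  int w;
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t> > > map;
  static bool valid(uint8_t a) { return a < 20; }
  void build(const std::vector<std::vector<uint8_t> > &subs, int word) {
    w = word;
    for (int si = 0; si < (int) subs.size(); ++si) {
      const std::vector<uint8_t> &s = subs[si];
      for (int p = 0; p + w <= (int) s.size(); ++p) {
        uint32_t key = 0; bool ok = true;
        for (int k = 0; k < w; ++k) {
          if (!valid(s[p + k])) { ok = false; break; }
          key = key * 25 + s[p + k];
        }
        if (ok) map[key].push_back(std::make_pair(si, p));
      }
    }
  }
  void query(const std::vector<uint8_t> &q, std::vector<SeedHit> &out) const {
    for (int p = 0; p + w <= (int) q.size(); ++p) {
      uint32_t key = 0; bool ok = true;
      for (int k = 0; k < w; ++k) {
        if (!valid(q[p + k])) { ok = false; break; }
        key = key * 25 + q[p + k];
      }
      if (!ok) continue;
      std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator it = map.find(key);
      if (it != map.end())
        for (size_t k2 = 0; k2 < it->second.size(); ++k2) {
          SeedHit h; h.subject = it->second[k2].first;
          h.qpos = p; h.spos = it->second[k2].second;
          out.push_back(h);
        }
    }
  }
};

struct Cluster {
  int subject;
  int n_seeds;
  int min_spos, max_spos;
  int min_qpos, max_qpos;
  int min_diag, max_diag;
};

// cluster seeds of one subject by diagonal proximity and subject-position gaps
static void cluster_seeds(std::vector<SeedHit> &seeds, int diag_tol, int pos_gap,
                          int max_span, std::vector<Cluster> &out) {
  std::sort(seeds.begin(), seeds.end(), [](const SeedHit &a, const SeedHit &b) {
    if (a.subject != b.subject) return a.subject < b.subject;
    int da = a.spos - a.qpos, db = b.spos - b.qpos;
    if (da != db) return da < db;
    return a.spos < b.spos;
  });
  size_t i = 0;
  while (i < seeds.size()) {
    Cluster c; c.subject = seeds[i].subject; c.n_seeds = 1;
    c.min_spos = c.max_spos = seeds[i].spos;
    c.min_qpos = c.max_qpos = seeds[i].qpos;
    c.min_diag = c.max_diag = seeds[i].spos - seeds[i].qpos;
    int dlast = c.min_diag;
    size_t j = i + 1;
    while (j < seeds.size() && seeds[j].subject == c.subject) {
      int d = seeds[j].spos - seeds[j].qpos;
      if (d - dlast > diag_tol) break;
      if (seeds[j].spos - c.max_spos > pos_gap) break;
      if (seeds[j].spos - c.min_spos > max_span) break;
      c.n_seeds++;
      c.min_spos = std::min(c.min_spos, seeds[j].spos);
      c.max_spos = std::max(c.max_spos, seeds[j].spos);
      c.min_qpos = std::min(c.min_qpos, seeds[j].qpos);
      c.max_qpos = std::max(c.max_qpos, seeds[j].qpos);
      c.min_diag = std::min(c.min_diag, d);
      c.max_diag = std::max(c.max_diag, d);
      dlast = d;
      ++j;
    }
    out.push_back(c);
    i = j;
  }
}

// ---------------------------------------------------------------------------
// E-value: Karlin-Altschul form E = m * n * 2^(-bits),
// bits = (lambda * S - ln K) / ln 2 with documentary (published, not
// fitted) constants for the scoring schemes the pipeline uses.

static void ka_params(bool protein, int match, int mismatch,
                      double *lambda, double *K) {
  if (protein) { *lambda = 0.267; *K = 0.041; return; }   // BLOSUM62
  if (match == 1 && mismatch == -2) { *lambda = 1.28; *K = 0.46; }
  else if (match == 2 && mismatch == -3) { *lambda = 0.625; *K = 0.41; }
  else if (match == 1 && mismatch == -3) { *lambda = 1.374; *K = 0.711; }
  else { // generic ungapped approximation for other reward/penalty pairs
    *lambda = std::log(4.0) / match;
    *K = 0.5;
  }
}

static double bits_of(int score, bool protein, double lambda, double K) {
  (void) protein;
  return (lambda * (double) score - std::log(K)) / std::log(2.0);
}

struct RawHit {
  int query, subject;
  double identity, similarity, evalue, bits;
  int score, aln_len, mismatches, gap_opens;
  int qs, qe, ss, se;   // 0-based half-open, plus-strand of query
  int strand;           // +1 / -1
  int frame;            // 0 for nucleotide; +-1..3 translated
};

// map an alignment interval on a (possibly revcomp/translated) query frame
// back to plus-strand nucleotide coordinates of the original query
static void map_q_interval(int qs_f, int qe_f, int frame, int strand,
                           int qlen_nt, bool protein, int *qs, int *qe) {
  if (!protein) {
    if (strand > 0) { *qs = qs_f; *qe = qe_f; }
    else { *qs = qlen_nt - qe_f; *qe = qlen_nt - qs_f; }
  } else {
    int off = std::abs(frame) - 1;
    int nts = off + 3 * qs_f, nte = off + 3 * qe_f;
    if (strand > 0) { *qs = nts; *qe = nte; }
    else { *qs = qlen_nt - nte; *qe = qlen_nt - nts; }
  }
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector query_ids, CharacterVector query_seqs,
                     CharacterVector subject_ids, CharacterVector subject_seqs,
                     std::string mode, int word_size,
                     int match, int mismatch, int gap_open, int gap_ext,
                     double max_evalue, int min_seeds, int max_extensions,
                     int max_hits_per_query, bool both_strands,
                     bool early_exit) {
  bool translated = (mode == "translated");
  int nq = query_seqs.size(), ns = subject_seqs.size();

  // encode subjects
  std::vector<std::vector<uint8_t> > subs(ns);
  std::vector<int> slen(ns);
  double db_len = 0;
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(subject_seqs[i]);
    if (translated) {
      subs[i].resize(s.size());
      for (size_t k = 0; k < s.size(); ++k) subs[i][k] = (uint8_t) aa_code(s[k]);
    } else subs[i] = encode_nt(s);
    slen[i] = (int) subs[i].size();
    db_len += slen[i];
  }
  NtIndex ntidx; AaIndex aaidx;
  if (translated) aaidx.build(subs, word_size);
  else ntidx.build(subs, word_size);

  Scorer sc; sc.protein = translated; sc.match = match; sc.mismatch = mismatch;
  int go = gap_open, ge = gap_ext;
  if (translated) { go = 11; ge = 1; } // BLOSUM62 standard gap costs
  double ka_lambda, ka_K;
  ka_params(translated, match, mismatch, &ka_lambda, &ka_K);

  std::vector<RawHit> hits;

  for (int qi = 0; qi < nq; ++qi) {
    std::vector<uint8_t> qnt = encode_nt(as<std::string>(query_seqs[qi]));
    int qlen_nt = (int) qnt.size();
    std::vector<RawHit> qhits;

    struct Frame { std::vector<uint8_t> seq; int strand; int frame; };
    std::vector<Frame> frames;
    if (!translated) {
      Frame f; f.seq = qnt; f.strand = 1; f.frame = 0; frames.push_back(f);
      if (both_strands) {
        Frame r; r.seq = revcomp_nt(qnt); r.strand = -1; r.frame = 0;
        frames.push_back(r);
      }
    } else {
      std::vector<uint8_t> rc = revcomp_nt(qnt);
      for (int off = 0; off < 3; ++off) {
        Frame f; f.seq = translate_frame(qnt, off); f.strand = 1; f.frame = off + 1;
        frames.push_back(f);
        Frame r; r.seq = translate_frame(rc, off); r.strand = -1; r.frame = -(off + 1);
        frames.push_back(r);
      }
    }

    bool satisfied = false;
    for (size_t fi = 0; fi < frames.size() && !satisfied; ++fi) {
      const std::vector<uint8_t> &q = frames[fi].seq;
      int qlen = (int) q.size();
      if (qlen < word_size) continue;
      std::vector<SeedHit> seeds;
      if (translated) aaidx.query(q, seeds); else ntidx.query(q, seeds);
      if (seeds.empty()) continue;
      std::vector<Cluster> clusters;
      int diag_tol = translated ? 8 : 16;
      cluster_seeds(seeds, diag_tol, qlen + 200, qlen + 200, clusters);
      std::stable_sort(clusters.begin(), clusters.end(),
                       [](const Cluster &a, const Cluster &b) {
                         return a.n_seeds > b.n_seeds;
                       });
      int done = 0;
      for (size_t ci = 0; ci < clusters.size(); ++ci) {
        const Cluster &c = clusters[ci];
        if (c.n_seeds < min_seeds) continue;
        if (done >= max_extensions) break;
        ++done;
        // window bounded by how much query is left of/right of the seeds
        // (+64 slack for gaps; larger gaps cannot pay for themselves)
        int ws = std::max(0, c.min_spos - c.min_qpos - 64);
        int we = std::min(slen[c.subject],
                          c.max_spos + word_size +
                            (qlen - c.max_qpos - word_size) + 64);
        std::vector<uint8_t> win(subs[c.subject].begin() + ws,
                                 subs[c.subject].begin() + we);
        // band around the seed diagonals for big problems; exact full DP
        // for small ones
        AlnResult a;
        if ((size_t) qlen * (size_t)(we - ws) > 60000) {
          int dmin = c.min_diag - ws - 64;
          int dmax = c.max_diag - ws + 64;
          a = sw_align(q, win, sc, go, ge, true, dmin, dmax);
        } else {
          a = sw_align(q, win, sc, go, ge);
        }
        if (!a.ok) continue;
        double bits = bits_of(a.score, translated, ka_lambda, ka_K);
        double ev = (double) qlen_nt * db_len * std::pow(2.0, -bits);
        if (ev > max_evalue) continue;
        RawHit h;
        h.query = qi; h.subject = c.subject;
        h.identity = 100.0 * a.matches / std::max(1, a.aln_len);
        h.similarity = translated ? 100.0 * a.positives / std::max(1, a.aln_len)
                                  : 100.0 * a.matches / std::max(1, a.aln_len);
        h.evalue = ev; h.bits = bits; h.score = a.score;
        h.aln_len = a.aln_len; h.mismatches = a.mismatches;
        h.gap_opens = a.gap_opens;
        map_q_interval(a.qstart, a.qend, frames[fi].frame, frames[fi].strand,
                       qlen_nt, translated, &h.qs, &h.qe);
        h.ss = ws + a.sstart; h.se = ws + a.send;
        h.strand = frames[fi].strand; h.frame = frames[fi].frame;
        qhits.push_back(h);
        if (early_exit) { satisfied = true; break; }
      }
    }

    // deduplicate identical loci (same subject/strand/coords): keep best score
    std::sort(qhits.begin(), qhits.end(), [](const RawHit &a, const RawHit &b) {
      if (a.subject != b.subject) return a.subject < b.subject;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.ss != b.ss) return a.ss < b.ss;
      if (a.se != b.se) return a.se < b.se;
      return a.score > b.score;
    });
    std::vector<RawHit> dedup;
    for (size_t k = 0; k < qhits.size(); ++k) {
      if (!dedup.empty()) {
        const RawHit &p = dedup.back();
        if (p.subject == qhits[k].subject && p.strand == qhits[k].strand &&
            std::max(p.ss, qhits[k].ss) < std::min(p.se, qhits[k].se) &&
            p.score >= qhits[k].score)
          continue; // overlapping weaker duplicate of same locus
      }
      dedup.push_back(qhits[k]);
    }
    // per-query cap by E-value then bitscore
    std::stable_sort(dedup.begin(), dedup.end(), [](const RawHit &a, const RawHit &b) {
      if (a.evalue != b.evalue) return a.evalue < b.evalue;
      return a.bits > b.bits;
    });
    if (max_hits_per_query > 0 && (int) dedup.size() > max_hits_per_query)
      dedup.resize(max_hits_per_query);
    for (size_t k = 0; k < dedup.size(); ++k) hits.push_back(dedup[k]);
  }

  int n = (int) hits.size();
  CharacterVector oq(n), os(n), ostrand(n);
  NumericVector oid(n), osim(n), oev(n), obits(n), oqcov(n), oscov(n);
  IntegerVector oal(n), omm(n), ogo(n), oqs(n), oqe(n), oss(n), ose(n),
    oframe(n), oqlen(n), oslen(n), oscore(n);
  for (int k = 0; k < n; ++k) {
    const RawHit &h = hits[k];
    oq[k] = query_ids[h.query]; os[k] = subject_ids[h.subject];
    oid[k] = h.identity; osim[k] = h.similarity;
    oev[k] = h.evalue; obits[k] = h.bits; oscore[k] = h.score;
    oal[k] = h.aln_len; omm[k] = h.mismatches; ogo[k] = h.gap_opens;
    oqs[k] = h.qs; oqe[k] = h.qe; oss[k] = h.ss; ose[k] = h.se;
    ostrand[k] = (h.strand > 0) ? "+" : "-";
    oframe[k] = h.frame;
    int qlnt = (int) std::string(query_seqs[h.query]).size();
    oqlen[k] = qlnt; oslen[k] = slen[h.subject];
    oqcov[k] = 100.0 * (h.qe - h.qs) / std::max(1, qlnt);
    oscov[k] = 100.0 * (h.se - h.ss) / std::max(1, slen[h.subject]);
  }
  return DataFrame::create(
    _["query_id"] = oq, _["subject_id"] = os,
    _["identity_pct"] = oid, _["similarity_pct"] = osim,
    _["align_len"] = oal, _["mismatches"] = omm, _["gap_opens"] = ogo,
    _["q_start"] = oqs, _["q_end"] = oqe,
    _["s_start"] = oss, _["s_end"] = ose,
    _["strand"] = ostrand, _["frame"] = oframe,
    _["evalue"] = oev, _["bitscore"] = obits, _["score"] = oscore,
    _["query_cov_pct"] = oqcov, _["subject_cov_pct"] = oscov,
    _["q_len"] = oqlen, _["s_len"] = oslen,
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double cpp_bits_of(int score, bool protein, int match, int mismatch) {
  double lambda, K;
  ka_params(protein, match, mismatch, &lambda, &K);
  return bits_of(score, protein, lambda, K);
}
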