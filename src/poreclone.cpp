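// Core sequence primitives: minimizer indexing, co-linear chaining, banded
// affine-gap alignment with explicit CIGAR, pileup/consensus accumulation,
// and the error process used by the read simulator.  Everything here is
// deterministic; randomness comes only through R's RNG (cpp_mutate).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[i] = comp_base(s[s.size() - 1 - i]);
  return out;
}

// 64-bit invertible finalizer (splitmix-style); spreads packed k-mer values
// so that window minima behave like random draws.
static inline uint64_t hash64(uint64_t x, uint64_t mask) {
  x = (~x + (x << 21)) & mask;
  x = x ^ (x >> 24);
  x = (x + (x << 3) + (x << 8)) & mask;
  x = x ^ (x >> 14);
  x = (x + (x << 2) + (x << 4)) & mask;
  x = x ^ (x >> 28);
  x = (x + (x << 31)) & mask;
  return x;
}

struct Minimizer { uint64_t hash; int pos; int strand; }; // strand +1 fwd, -1 rc

// Canonical (strand-min) minimizers; every window of w consecutive k-mers
// contributes all occurrences of its minimum hash (deduplicated).
static void minimizers_raw(const std::string& s, int k, int w,
                           std::vector<Minimizer>& out) {
  int n = (int) s.size();
  if (n < k) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int shift = 2 * (k - 1);
  std::vector<Minimizer> kmers; kmers.reserve(n);
  uint64_t fwd = 0, rev = 0;
  int len = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { len = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | (((uint64_t) (3 - c)) << shift);
    if (++len < k) continue;
    uint64_t hf = hash64(fwd, mask), hr = hash64(rev, mask);
    if (hf == hr) continue; // palindromic k-mer: strand undefined, skip
    Minimizer m;
    m.hash = std::min(hf, hr);
    m.pos = i - k + 1;
    m.strand = (hf < hr) ? 1 : -1;
    kmers.push_back(m);
  }
  int nk = (int) kmers.size();
  if (nk == 0) return;
  if (w <= 1) { out = kmers; return; }
  // O(n*w) rescan: w is small (<= ~16) in practice
  int last_emitted = -1;
  for (int i = 0; i + w <= nk; ++i) {
    uint64_t mn = kmers[i].hash;
    for (int j = i + 1; j < i + w; ++j) mn = std::min(mn, kmers[j].hash);
    for (int j = i; j < i + w; ++j) {
      if (kmers[j].hash == mn && kmers[j].pos > last_emitted) {
        out.push_back(kmers[j]);
        last_emitted = kmers[j].pos;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_minimizers(std::string seq, int k, int w) {
  std::vector<Minimizer> mz;
  minimizers_raw(seq, k, w, mz);
  int n = (int) mz.size();
  NumericVector hash(n); IntegerVector pos(n); IntegerVector strand(n);
  for (int i = 0; i < n; ++i) {
    // doubles hold 53 bits exactly; only very large k needs truncation
    hash[i] = (k <= 26) ? (double) mz[i].hash : (double) (mz[i].hash >> 11);
    pos[i] = mz[i].pos;
    strand[i] = mz[i].strand;
  }
  return DataFrame::create(_["hash"] = hash, _["pos"] = pos, _["strand"] = strand);
}

// ------------------------------------------------------------------ index --

struct MzIndex {
  int k, w;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // hash -> packed (ref << 33) | (pos << 1) | (strand==+1)
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector names, int k, int w) {
  MzIndex* idx = new MzIndex();
  idx->k = k; idx->w = w;
  for (int r = 0; r < seqs.size(); ++r) {
    idx->names.push_back(as<std::string>(names[r]));
    idx->seqs.push_back(as<std::string>(seqs[r]));
    std::vector<Minimizer> mz;
    minimizers_raw(idx->seqs[r], k, w, mz);
    for (const Minimizer& m : mz) {
      uint64_t packed = (((uint64_t) r) << 33) | (((uint64_t) m.pos) << 1) |
        (m.strand > 0 ? 1ULL : 0ULL);
      idx->table[m.hash].push_back(packed);
    }
  }
  XPtr<MzIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<MzIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["w"] = idx->w,
                      _["names"] = wrap(idx->names),
                      _["n_entries"] = (double) idx->table.size());
}

// --------------------------------------------------------------- chaining --

struct Anchor { int qpos, tpos; };
struct Chain { std::vector<int> idx; double score; };

// Co-linear chaining DP with bounded lookback; anchors must be sorted by
// (tpos, qpos).  Returns up to max_chains non-overlapping chains, best first.
static void chain_dp(const std::vector<Anchor>& a, int k, int max_gap,
                     double min_score, int max_chains,
                     std::vector<Chain>& out) {
  int n = (int) a.size();
  if (n == 0) return;
  const int LOOKBACK = 64;
  std::vector<char> used(n, 0);
  for (int pass = 0; pass < max_chains; ++pass) {
    std::vector<double> f(n); std::vector<int> bp(n, -1);
    double best = -1; int besti = -1;
    for (int i = 0; i < n; ++i) {
      if (used[i]) { f[i] = NEG_INF; continue; }
      f[i] = k;
      int lo = std::max(0, i - LOOKBACK);
      for (int j = i - 1; j >= lo; --j) {
        if (used[j]) continue;
        int dt = a[i].tpos - a[j].tpos;
        int dq = a[i].qpos - a[j].qpos;
        if (dt <= 0 || dq <= 0) continue;
        if (dt > max_gap || dq > max_gap) continue;
        double gain = std::min(k, std::min(dq, dt));
        double gap = std::abs(dq - dt);
        double cost = 0.5 * gap + (gap > 0 ? 0.5 * std::log2((double) gap + 1.0) : 0.0);
        double sc = f[j] + gain - cost;
        if (sc > f[i]) { f[i] = sc; bp[i] = j; }
      }
      if (f[i] > best) { best = f[i]; besti = i; }
    }
    if (besti < 0 || best < min_score) break;
    Chain c; c.score = best;
    for (int i = besti; i >= 0; i = bp[i]) c.idx.push_back(i);
    std::reverse(c.idx.begin(), c.idx.end());
    // mask anchors inside the chain's footprint (query AND target span):
    // a second copy of the query elsewhere on the target keeps its anchors
    // and can form a secondary chain
    int q0 = a[c.idx.front()].qpos, q1 = a[c.idx.back()].qpos;
    int t0 = a[c.idx.front()].tpos, t1 = a[c.idx.back()].tpos;
    for (int i = 0; i < n; ++i) {
      if (a[i].qpos >= q0 && a[i].qpos <= q1 &&
          a[i].tpos >= t0 && a[i].tpos <= t1) used[i] = 1;
    }
    out.push_back(c);
  }
}

// [[Rcpp::export]]
List cpp_chain(IntegerVector qpos, IntegerVector tpos, int k, int max_gap,
               double min_score, int max_chains) {
  int n = qpos.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (tpos[i] != tpos[j]) return tpos[i] < tpos[j];
    return qpos[i] < qpos[j];
  });
  std::vector<Anchor> a(n);
  for (int i = 0; i < n; ++i) { a[i].qpos = qpos[ord[i]]; a[i].tpos = tpos[ord[i]]; }
  std::vector<Chain> chains;
  chain_dp(a, k, max_gap, min_score, max_chains, chains);
  List out(chains.size());
  for (size_t c = 0; c < chains.size(); ++c) {
    IntegerVector qi(chains[c].idx.size()), ti(chains[c].idx.size()),
      orig(chains[c].idx.size());
    for (size_t i = 0; i < chains[c].idx.size(); ++i) {
      qi[i] = a[chains[c].idx[i]].qpos;
      ti[i] = a[chains[c].idx[i]].tpos;
      orig[i] = ord[chains[c].idx[i]] + 1;
    }
    out[c] = List::create(_["qpos"] = qi, _["tpos"] = ti, _["anchor"] = orig,
                          _["score"] = chains[c].score);
  }
  return out;
}

// ---------------------------------------------------- banded affine align --

struct CigOp { char op; int len; };

static void push_op(std::vector<CigOp>& v, char op, int len) {
  if (len <= 0) return;
  if (!v.empty() && v.back().op == op) v.back().len += len;
  else v.push_back({op, len});
}

struct AlnSeg {
  int score;
  std::vector<CigOp> cigar;
  bool band_hit;
  int q_used, t_used; // consumed lengths (== n,m for global)
  int matches;
};

// Banded Gotoh.  mode 0: global/global.  mode 1: extension (anchored at
// (0,0), free to end anywhere; traceback from the best-scoring cell).
// Gap of length L costs open + L * ext.  Band is centred on the (0,0)-(n,m)
// diagonal.
static AlnSeg gotoh_band(const std::string& q, const std::string& t, int band,
                         int match, int mismatch, int gap_open, int gap_ext,
                         int mode) {
  int n = (int) q.size(), m = (int) t.size();
  AlnSeg res; res.score = 0; res.band_hit = false; res.q_used = 0; res.t_used = 0;
  res.matches = 0;
  if (n == 0 && m == 0) return res;
  if (n == 0) {
    if (mode == 0) { res.score = -(gap_open + m * gap_ext); push_op(res.cigar, 'D', m); res.t_used = m; }
    return res;
  }
  if (m == 0) {
    if (mode == 0) { res.score = -(gap_open + n * gap_ext); push_op(res.cigar, 'I', n); res.q_used = n; }
    return res;
  }
  if (band < 1) band = 1;
  long W = 2L * band + 1;
  // column window for row i: [lo(i), hi(i)] around centre i*m/n
  auto centre = [&](int i) { return (int) std::llround((double) i * m / n); };
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF), X((size_t)(n + 1) * W, NEG_INF),
    Y((size_t)(n + 1) * W, NEG_INF);
  // traceback: 2 bits per state
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  auto off = [&](int i, int j) { return (size_t) i * W + (j - centre(i) + band); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j >= centre(i) - band && j <= centre(i) + band;
  };
  M[off(0, 0)] = 0;
  for (int j = 1; j <= m && inband(0, j); ++j) {
    Y[off(0, j)] = -(gap_open + j * gap_ext);
    tb[off(0, j)] |= (2 << 4); // Y from Y
  }
  int best_sc = (mode == 1) ? 0 : NEG_INF;
  int best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, centre(i) - band), hi = std::min(m, centre(i) + band);
    for (int j = lo; j <= hi; ++j) {
      size_t o = off(i, j);
      int mM = NEG_INF, mX = NEG_INF, mY = NEG_INF;
      uint8_t trace = 0;
      if (j >= 1 && inband(i - 1, j - 1)) {
        size_t p = off(i - 1, j - 1);
        int s = (base_code(q[i - 1]) >= 0 && base_code(q[i - 1]) == base_code(t[j - 1]))
          ? match : -mismatch;
        int b = M[p]; uint8_t which = 0;
        if (X[p] > b) { b = X[p]; which = 1; }
        if (Y[p] > b) { b = Y[p]; which = 2; }
        if (b > NEG_INF / 2) { mM = b + s; trace |= which; }
      }
      if (inband(i - 1, j)) {
        size_t p = off(i - 1, j);
        int from_open = std::max(M[p], Y[p]);
        uint8_t which = (Y[p] > M[p]) ? 2 : 0;
        int a1 = (from_open > NEG_INF / 2) ? from_open - gap_open - gap_ext : NEG_INF;
        int a2 = (X[p] > NEG_INF / 2) ? X[p] - gap_ext : NEG_INF;
        if (a2 >= a1) { mX = a2; trace |= (1 << 2); }
        else { mX = a1; trace |= (which << 2); }
      }
      if (j >= 1 && inband(i, j - 1)) {
        size_t p = off(i, j - 1);
        int from_open = std::max(M[p], X[p]);
        uint8_t which = (X[p] > M[p]) ? 1 : 0;
        int a1 = (from_open > NEG_INF / 2) ? from_open - gap_open - gap_ext : NEG_INF;
        int a2 = (Y[p] > NEG_INF / 2) ? Y[p] - gap_ext : NEG_INF;
        if (a2 >= a1) { mY = a2; trace |= (2 << 4); }
        else { mY = a1; trace |= (which << 4); }
      }
      M[o] = mM; X[o] = mX; Y[o] = mY; tb[o] = trace;
      if (mode == 1) {
        int cell = std::max(mM, std::max(mX, mY));
        if (cell > best_sc) { best_sc = cell; best_i = i; best_j = j; }
      }
    }
  }
  int ei, ej; int state;
  if (mode == 0) {
    ei = n; ej = m;
    if (!inband(n, m)) { res.band_hit = true; res.score = NEG_INF; return res; }
    size_t o = off(n, m);
    int b = M[o]; state = 0;
    if (X[o] > b) { b = X[o]; state = 1; }
    if (Y[o] > b) { b = Y[o]; state = 2; }
    res.score = b;
    if (b <= NEG_INF / 2) { res.band_hit = true; return res; }
  } else {
    ei = best_i; ej = best_j;
    res.score = best_sc;
    if (ei == 0 && ej == 0) return res;
    size_t o = off(ei, ej);
    int b = M[o]; state = 0;
    if (X[o] > b) { b = X[o]; state = 1; }
    if (Y[o] > b) { b = Y[o]; state = 2; }
  }
  res.q_used = ei; res.t_used = ej;
  // traceback
  std::vector<CigOp> rev;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (mode == 1 && i == 0 && j == 0) break;
    int lo = std::max(0, centre(i) - band), hi = std::min(m, centre(i) + band);
    if ((j == lo && lo > 0) || (j == hi && hi < m)) res.band_hit = true;
    size_t o = off(i, j);
    uint8_t trace = tb[o];
    if (state == 0) {
      if (i == 0 || j == 0) break;
      char c1 = q[i - 1], c2 = t[j - 1];
      if (base_code(c1) >= 0 && base_code(c1) == base_code(c2)) res.matches++;
      push_op(rev, 'M', 1);
      state = trace & 3; --i; --j;
    } else if (state == 1) {
      push_op(rev, 'I', 1);
      state = (trace >> 2) & 3; --i;
    } else {
      push_op(rev, 'D', 1);
      state = (trace >> 4) & 3; --j;
    }
  }
  std::reverse(rev.begin(), rev.end());
  res.cigar = rev;
  return res;
}

static std::string cigar_to_string(const std::vector<CigOp>& v) {
  std::string s;
  for (const CigOp& c : v) { s += std::to_string(c.len); s += c.op; }
  return s;
}

// Global banded alignment of two whole sequences (widen-once-then-flag).
// [[Rcpp::export]]
List cpp_align_global(std::string q, std::string t, int band, int match,
                      int mismatch, int gap_open, int gap_ext) {
  int need = std::abs((int) q.size() - (int) t.size()) + 2;
  int b = std::max(band, need);
  AlnSeg r = gotoh_band(q, t, b, match, mismatch, gap_open, gap_ext, 0);
  bool widened = false;
  if (r.band_hit) {
    widened = true;
    r = gotoh_band(q, t, 2 * b, match, mismatch, gap_open, gap_ext, 0);
  }
  int cols = 0;
  for (const CigOp& c : r.cigar) cols += c.len;
  return List::create(_["score"] = r.score,
                      _["cigar"] = cigar_to_string(r.cigar),
                      _["matches"] = r.matches,
                      _["columns"] = cols,
                      _["identity"] = cols > 0 ? (double) r.matches / cols : NA_REAL,
                      _["low_conf"] = (widened && r.band_hit));
}

// Full alignment along a chain of anchors: piecewise global between anchors,
// extension alignments at both ends, soft clips for unaligned query flanks.
struct FullAln {
  int q_start, q_end, t_start, t_end;
  std::vector<CigOp> cigar; // includes S at ends
  int score, matches, columns;
  bool low_conf;
};

static FullAln extend_chain_aln(const std::string& q, const std::string& t,
                                const std::vector<int>& qa, const std::vector<int>& ta,
                                int band, int match, int mismatch,
                                int gap_open, int gap_ext) {
  FullAln out; out.low_conf = false;
  int na = (int) qa.size();
  // keep strictly increasing anchor subset
  std::vector<int> keep; keep.push_back(0);
  for (int i = 1; i < na; ++i) {
    if (qa[i] > qa[keep.back()] && ta[i] > ta[keep.back()]) keep.push_back(i);
  }
  std::vector<CigOp> ops;
  int score = 0, matches = 0;
  // leading extension (reverse both flanks, extend from the first anchor)
  int q0 = qa[keep.front()], t0 = ta[keep.front()];
  int tlead = std::min(t0, q0 + band);
  std::string qf(q.rbegin() + (q.size() - q0), q.rend());
  std::string tf(t.rbegin() + (t.size() - t0), t.rbegin() + (t.size() - t0) + tlead);
  AlnSeg lead = gotoh_band(qf, tf, band, match, mismatch, gap_open, gap_ext, 1);
  out.q_start = q0 - lead.q_used;
  out.t_start = t0 - lead.t_used;
  push_op(ops, 'S', out.q_start);
  std::vector<CigOp> lc = lead.cigar;
  std::reverse(lc.begin(), lc.end());
  for (const CigOp& c : lc) push_op(ops, c.op, c.len);
  score += lead.score; matches += lead.matches;
  if (lead.band_hit) out.low_conf = true;
  // mid segments between consecutive anchor starts
  for (size_t s = 0; s + 1 < keep.size(); ++s) {
    int qi = qa[keep[s]], qj = qa[keep[s + 1]];
    int ti = ta[keep[s]], tj = ta[keep[s + 1]];
    int dq = qj - qi, dt = tj - ti;
    // widen with segment length: sparse anchors mean divergent sequence,
    // where the optimal path wanders further off the diagonal
    int b = std::min(band,
                     std::max(32, std::abs(dq - dt) + 16 + std::max(dq, dt) / 4));
    AlnSeg seg = gotoh_band(q.substr(qi, dq), t.substr(ti, dt), b, match,
                            mismatch, gap_open, gap_ext, 0);
    if (seg.band_hit || seg.score <= NEG_INF / 2) {
      seg = gotoh_band(q.substr(qi, dq), t.substr(ti, dt),
                       std::max(band, std::abs(dq - dt) + 2), match, mismatch,
                       gap_open, gap_ext, 0);
      if (seg.band_hit) out.low_conf = true;
    }
    for (const CigOp& c : seg.cigar) push_op(ops, c.op, c.len);
    score += seg.score; matches += seg.matches;
  }
  // trailing extension from the last anchor start
  int ql = qa[keep.back()], tl = ta[keep.back()];
  int qrem = (int) q.size() - ql;
  int trem = std::min((int) t.size() - tl, qrem + band);
  AlnSeg trail = gotoh_band(q.substr(ql, qrem), t.substr(tl, trem), band, match,
                            mismatch, gap_open, gap_ext, 1);
  for (const CigOp& c : trail.cigar) push_op(ops, c.op, c.len);
  score += trail.score; matches += trail.matches;
  if (trail.band_hit) out.low_conf = true;
  out.q_end = ql + trail.q_used;
  out.t_end = tl + trail.t_used;
  push_op(ops, 'S', (int) q.size() - out.q_end);
  out.cigar = ops;
  out.score = score; out.matches = matches;
  int cols = 0;
  for (const CigOp& c : ops) if (c.op != 'S') cols += c.len;
  out.columns = cols;
  return out;
}

// [[Rcpp::export]]
List cpp_extend_chain(std::string q, std::string t, IntegerVector qpos,
                      IntegerVector tpos, int band, int match, int mismatch,
                      int gap_open, int gap_ext) {
  std::vector<int> qa(qpos.begin(), qpos.end()), ta(tpos.begin(), tpos.end());
  FullAln a = extend_chain_aln(q, t, qa, ta, band, match, mismatch, gap_open, gap_ext);
  return List::create(_["q_start"] = a.q_start, _["q_end"] = a.q_end,
                      _["t_start"] = a.t_start, _["t_end"] = a.t_end,
                      _["cigar"] = cigar_to_string(a.cigar),
                      _["score"] = a.score, _["matches"] = a.matches,
                      _["columns"] = a.columns,
                      _["identity"] = a.columns > 0 ? (double) a.matches / a.columns : NA_REAL,
                      _["low_conf"] = a.low_conf);
}

// -------------------------------------------------------------- map reads --

// Map queries against an index: collect anchors per (target, strand), chain,
// optionally extend the top chains into full alignments.
// [[Rcpp::export]]
List cpp_map(SEXP xp, CharacterVector queries, int max_gap, double min_chain_score,
             int max_secondary, bool extend, int band, int match, int mismatch,
             int gap_open, int gap_ext, int max_extended) {
  XPtr<MzIndex> idx(xp);
  int k = idx->k, w = idx->w;
  int nref = (int) idx->seqs.size();
  std::vector<int> out_query, out_target, out_qs, out_qe, out_ts, out_te, out_nanchor;
  std::vector<std::string> out_strand, out_cigar;
  std::vector<double> out_chain_score, out_score, out_identity;
  std::vector<int> out_lowconf;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string query = as<std::string>(queries[qi]);
    int qlen = (int) query.size();
    std::vector<Minimizer> mz;
    minimizers_raw(query, k, w, mz);
    // bucket anchors by (target, strand)
    std::unordered_map<int64_t, std::vector<Anchor> > buckets;
    for (const Minimizer& m : mz) {
      auto it = idx->table.find(m.hash);
      if (it == idx->table.end()) continue;
      if ((int) it->second.size() > 200) continue; // repeat-masked seed
      for (uint64_t packed : it->second) {
        int rid = (int) (packed >> 33);
        int tpos = (int) ((packed >> 1) & 0xFFFFFFFFULL);
        int tstrand = (packed & 1ULL) ? 1 : -1;
        int rel = (m.strand == tstrand) ? 1 : -1;
        Anchor a;
        a.tpos = tpos;
        a.qpos = (rel == 1) ? m.pos : (qlen - k - m.pos);
        int64_t key = ((int64_t) rid << 1) | (rel == 1 ? 1 : 0);
        buckets[key].push_back(a);
      }
    }
    struct Cand {
      int rid, strand; double chain_score;
      std::vector<int> qa, ta;
    };
    std::vector<Cand> cands;
    for (auto& kv : buckets) {
      int rid = (int) (kv.first >> 1);
      int strand = (kv.first & 1) ? 1 : -1;
      std::vector<Anchor>& av = kv.second;
      std::sort(av.begin(), av.end(), [](const Anchor& a, const Anchor& b) {
        if (a.tpos != b.tpos) return a.tpos < b.tpos;
        return a.qpos < b.qpos;
      });
      std::vector<Chain> chains;
      chain_dp(av, k, max_gap, min_chain_score, 3, chains);
      for (const Chain& c : chains) {
        Cand cd; cd.rid = rid; cd.strand = strand; cd.chain_score = c.score;
        for (int i : c.idx) { cd.qa.push_back(av[i].qpos); cd.ta.push_back(av[i].tpos); }
        cands.push_back(cd);
      }
    }
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      return a.chain_score > b.chain_score;
    });
    int keep = std::min((int) cands.size(), max_secondary + 1);
    for (int c = 0; c < keep; ++c) {
      const Cand& cd = cands[c];
      out_query.push_back(qi + 1);
      out_target.push_back(cd.rid + 1);
      out_strand.push_back(cd.strand == 1 ? "+" : "-");
      out_nanchor.push_back((int) cd.qa.size());
      out_chain_score.push_back(cd.chain_score);
      if (extend && c < max_extended) {
        const std::string& tgt = idx->seqs[cd.rid];
        std::string qq = (cd.strand == 1) ? query : cpp_revcomp(query);
        FullAln a = extend_chain_aln(qq, tgt, cd.qa, cd.ta, band, match,
                                     mismatch, gap_open, gap_ext);
        out_qs.push_back(a.q_start); out_qe.push_back(a.q_end);
        out_ts.push_back(a.t_start); out_te.push_back(a.t_end);
        out_cigar.push_back(cigar_to_string(a.cigar));
        out_score.push_back((double) a.score);
        out_identity.push_back(a.columns > 0 ? (double) a.matches / a.columns : NA_REAL);
        out_lowconf.push_back(a.low_conf ? 1 : 0);
      } else {
        out_qs.push_back(cd.qa.front()); out_qe.push_back(cd.qa.back() + k);
        out_ts.push_back(cd.ta.front()); out_te.push_back(cd.ta.back() + k);
        out_cigar.push_back("");
        out_score.push_back(NA_REAL);
        out_identity.push_back(NA_REAL);
        out_lowconf.push_back(0);
      }
    }
    if (qi % 256 == 0) Rcpp::checkUserInterrupt();
  }
  (void) nref;
  return List::create(_["query"] = wrap(out_query), _["target"] = wrap(out_target),
                      _["strand"] = wrap(out_strand),
                      _["q_start"] = wrap(out_qs), _["q_end"] = wrap(out_qe),
                      _["t_start"] = wrap(out_ts), _["t_end"] = wrap(out_te),
                      _["n_anchors"] = wrap(out_nanchor),
                      _["chain_score"] = wrap(out_chain_score),
                      _["score"] = wrap(out_score),
                      _["identity"] = wrap(out_identity),
                      _["cigar"] = wrap(out_cigar),
                      _["low_conf"] = wrap(out_lowconf));
}

// ----------------------------------------------------------------- pileup --

static bool parse_cigar(const std::string& cig, std::vector<CigOp>& ops) {
  long len = 0;
  for (char ch : cig) {
    if (ch >= '0' && ch <= '9') { len = len * 10 + (ch - '0'); }
    else { ops.push_back({ch, (int) len}); len = 0; }
  }
  return true;
}

// Weighted pileup of alignments on a target.  Returns base counts (A,C,G,T,
// del) per column, weighted depth, and candidate insertions keyed by the
// target position they precede.
// [[Rcpp::export]]
List cpp_pileup(int target_len, IntegerVector t_start, CharacterVector cigar,
                CharacterVector qseq, NumericVector weight) {
  NumericMatrix counts(5, target_len); // rows A C G T del
  NumericVector depth(target_len);
  NumericVector span(target_len); // reads spanning the junction by >= 4 bp
  std::unordered_map<int64_t, std::unordered_map<std::string, double> > ins;
  int nr = t_start.size();
  for (int r = 0; r < nr; ++r) {
    std::vector<CigOp> ops;
    parse_cigar(as<std::string>(cigar[r]), ops);
    std::string qs = as<std::string>(qseq[r]);
    double wgt = weight[r];
    int tspan = 0;
    for (const CigOp& c : ops) if (c.op == 'M' || c.op == 'D') tspan += c.len;
    for (int p = std::max(0, t_start[r] + 4);
         p <= std::min(target_len - 1, t_start[r] + tspan - 4); ++p)
      span[p] += wgt;
    int tp = t_start[r], qp = 0;
    for (const CigOp& c : ops) {
      if (c.op == 'S') { qp += c.len; }
      else if (c.op == 'M') {
        for (int i = 0; i < c.len; ++i) {
          if (tp >= 0 && tp < target_len) {
            int b = base_code(qs[qp]);
            if (b >= 0) counts(b, tp) += wgt;
            depth[tp] += wgt;
          }
          ++tp; ++qp;
        }
      } else if (c.op == 'D') {
        for (int i = 0; i < c.len; ++i) {
          if (tp >= 0 && tp < target_len) { counts(4, tp) += wgt; depth[tp] += wgt; }
          ++tp;
        }
      } else if (c.op == 'I') {
        if (tp > 0 && tp < target_len) ins[tp][qs.substr(qp, c.len)] += wgt;
        qp += c.len;
      }
    }
  }
  std::vector<int> ipos; std::vector<std::string> iseq; std::vector<double> iw;
  for (auto& kv : ins) {
    for (auto& sv : kv.second) {
      ipos.push_back((int) kv.first);
      iseq.push_back(sv.first);
      iw.push_back(sv.second);
    }
  }
  return List::create(_["counts"] = counts, _["depth"] = depth,
                      _["span"] = span,
                      _["ins_pos"] = wrap(ipos), _["ins_seq"] = wrap(iseq),
                      _["ins_weight"] = wrap(iw));
}

// Observed homopolymer run lengths per spanning read.  For each run
// [start, end) of `run_base`, a read spanning [start-1, end] contributes the
// number of run-base query bases it aligns within the run plus same-base
// insertions at the run boundary/body.
// [[Rcpp::export]]
List cpp_run_obs(IntegerVector run_start, IntegerVector run_end,
                 CharacterVector run_base, IntegerVector t_start,
                 CharacterVector cigar, CharacterVector qseq) {
  int nruns = run_start.size();
  int nr = t_start.size();
  std::vector< std::vector<int> > obs(nruns);
  // precompute per-read span
  for (int r = 0; r < nr; ++r) {
    std::vector<CigOp> ops;
    parse_cigar(as<std::string>(cigar[r]), ops);
    std::string qs = as<std::string>(qseq[r]);
    int tp0 = t_start[r];
    int tspan = 0;
    for (const CigOp& c : ops) if (c.op == 'M' || c.op == 'D') tspan += c.len;
    int tp_end = tp0 + tspan;
    for (int u = 0; u < nruns; ++u) {
      int rs = run_start[u], re = run_end[u];
      if (tp0 > rs - 1 || tp_end < re + 1) continue; // must span run + 1 flank
      char rb = as<std::string>(run_base[u])[0];
      int cnt = 0;
      int tp = tp0, qp = 0;
      for (const CigOp& c : ops) {
        if (c.op == 'S') qp += c.len;
        else if (c.op == 'M') {
          for (int i = 0; i < c.len; ++i) {
            if (tp >= rs && tp < re && (qs[qp] == rb)) cnt++;
            ++tp; ++qp;
          }
        } else if (c.op == 'D') tp += c.len;
        else if (c.op == 'I') {
          if (tp >= rs && tp <= re) {
            for (int i = 0; i < c.len; ++i) if (qs[qp + i] == rb) cnt++;
          }
          qp += c.len;
        }
        if (tp > re + 1) break;
      }
      obs[u].push_back(cnt);
    }
  }
  List out(nruns);
  for (int u = 0; u < nruns; ++u) out[u] = wrap(obs[u]);
  return out;
}

// Observed query substring over target regions [a, b) per spanning read:
// M bases with tp in [a, b) plus I bases strictly inside (a, b). A read must
// align across [a-1, b+1] to contribute. Used to vote on homopolymer
// regions (run plus one flank base each side) as a unit.
// [[Rcpp::export]]
List cpp_region_obs(IntegerVector a, IntegerVector b, IntegerVector t_start,
                    CharacterVector cigar, CharacterVector qseq) {
  int nreg = a.size();
  int nr = t_start.size();
  std::vector< std::vector<std::string> > obs(nreg);
  for (int r = 0; r < nr; ++r) {
    std::vector<CigOp> ops;
    parse_cigar(as<std::string>(cigar[r]), ops);
    std::string qs = as<std::string>(qseq[r]);
    int tp0 = t_start[r];
    int tspan = 0;
    for (const CigOp& c : ops) if (c.op == 'M' || c.op == 'D') tspan += c.len;
    int tp_end = tp0 + tspan;
    for (int u = 0; u < nreg; ++u) {
      int ra = a[u], rb = b[u];
      if (tp0 > ra - 1 || tp_end < rb + 1) continue;
      std::string s;
      int tp = tp0, qp = 0;
      for (const CigOp& c : ops) {
        if (c.op == 'S') { qp += c.len; continue; }
        if (c.op == 'M') {
          for (int i = 0; i < c.len; ++i) {
            if (tp >= ra && tp < rb) s.push_back(qs[qp]);
            ++tp; ++qp;
          }
        } else if (c.op == 'D') {
          tp += c.len;
        } else if (c.op == 'I') {
          if (tp > ra && tp < rb)
            s.append(qs.substr(qp, c.len));
          qp += c.len;
        }
        if (tp > rb) break;
      }
      obs[u].push_back(s);
    }
  }
  List out(nreg);
  for (int u = 0; u < nreg; ++u) out[u] = wrap(obs[u]);
  return out;
}

// Per-read query base at selected target positions ('-' for a deletion).
// Used to genotype reads at SFV columns. Positions need not be sorted.
// [[Rcpp::export]]
List cpp_bases_at(IntegerVector t_start, CharacterVector cigar,
                  CharacterVector qseq, IntegerVector positions) {
  int npos = positions.size();
  int pmin = INT32_MAX, pmax = -1;
  for (int i = 0; i < npos; ++i) {
    pmin = std::min(pmin, positions[i]); pmax = std::max(pmax, positions[i]);
  }
  std::unordered_map<int, int> which_pos;
  for (int i = 0; i < npos; ++i) which_pos[positions[i]] = i;
  std::vector<int> out_read, out_pos;
  std::vector<std::string> out_base;
  int nr = t_start.size();
  for (int r = 0; r < nr; ++r) {
    std::vector<CigOp> ops;
    parse_cigar(as<std::string>(cigar[r]), ops);
    std::string qs = as<std::string>(qseq[r]);
    int tp = t_start[r], qp = 0;
    for (const CigOp& c : ops) {
      if (c.op == 'S' || c.op == 'I') { qp += c.len; continue; }
      if (c.op == 'M') {
        for (int i = 0; i < c.len; ++i) {
          if (tp >= pmin && tp <= pmax) {
            auto it = which_pos.find(tp);
            if (it != which_pos.end()) {
              out_read.push_back(r + 1);
              out_pos.push_back(tp);
              out_base.push_back(std::string(1, qs[qp]));
            }
          }
          ++tp; ++qp;
        }
      } else if (c.op == 'D') {
        for (int i = 0; i < c.len; ++i) {
          if (tp >= pmin && tp <= pmax && which_pos.count(tp)) {
            out_read.push_back(r + 1);
            out_pos.push_back(tp);
            out_base.push_back("-");
          }
          ++tp;
        }
      }
      if (tp > pmax) { /* may still need qp for later ops; keep walking */ }
    }
  }
  return List::create(_["read"] = wrap(out_read), _["pos"] = wrap(out_pos),
                      _["base"] = wrap(out_base));
}

// ---------------------------------------------------------- read mutation --

// Apply the nanopore/Illumina error process to a sequence using R's RNG.
// Indel probabilities are multiplied by hp_mult inside homopolymer runs of
// length >= 3 (insertions there duplicate the run base).
// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, double sub, double ins, double del,
                       double hp_mult) {
  int n = (int) seq.size();
  std::vector<char> in_hp(n, 0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && seq[j] == seq[i]) ++j;
    if (j - i >= 3) for (int p = i; p < j; ++p) in_hp[p] = 1;
    i = j;
  }
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out; out.reserve((size_t)(n * 1.1) + 16);
  for (int p = 0; p < n; ++p) {
    double mult = in_hp[p] ? hp_mult : 1.0;
    double pd = std::min(0.95, del * mult);
    if (R::unif_rand() < pd) continue; // deletion
    char b = seq[p];
    if (R::unif_rand() < sub) {
      int cur = base_code(b);
      int nb = (int) (R::unif_rand() * 3);
      if (nb >= 3) nb = 2;
      b = bases[(cur + 1 + nb) % 4];
    }
    out.push_back(b);
    double pi = std::min(0.95, ins * mult);
    if (R::unif_rand() < pi) {
      if (in_hp[p]) out.push_back(seq[p]);
      else {
        int nb = (int) (R::unif_rand() * 4);
        if (nb >= 4) nb = 3;
        out.push_back(bases[nb]);
      }
    }
  }
  return out;
}
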