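// Antisense duplex scan core: exact per-diagonal max-segment search for
// short pairs, word-seeded x-drop extension for long pairs. All coordinates
// are 0-based half-open. The alignment is antiparallel and ungapped: query
// position i pairs with target position j with i + j constant along a
// duplex ("diagonal" d = i + j).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Pair class for query base q vs target base t (both read 5'->3' on their
// own strand): 2 = Watson-Crick, 1 = G:T wobble (G:U in RNA), 0 = mismatch.
static inline int pair_class(char q, char t) {
  if ((q == 'A' && t == 'T') || (q == 'T' && t == 'A') ||
      (q == 'C' && t == 'G') || (q == 'G' && t == 'C')) return 2;
  if ((q == 'G' && t == 'T') || (q == 'T' && t == 'G')) return 1;
  return 0;
}

static inline double pair_score(char q, char t, double match, double wobble,
                                double mismatch) {
  int pc = pair_class(q, t);
  return pc == 2 ? match : (pc == 1 ? wobble : mismatch);
}

struct Cand { int qs, qe, ts, te; double score; };

static DataFrame cands_to_df(const std::vector<Cand>& cs) {
  int n = cs.size();
  IntegerVector qs(n), qe(n), ts(n), te(n);
  NumericVector sc(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = cs[i].qs; qe[i] = cs[i].qe;
    ts[i] = cs[i].ts; te[i] = cs[i].te; sc[i] = cs[i].score;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["t_start"] = ts, _["t_end"] = te,
                           _["ext_score"] = sc);
}

// Best-scoring segment on every antiparallel diagonal (Kadane); keeps one
// candidate per diagonal with score > 0.
// [[Rcpp::export(name = ".scan_exhaustive")]]
DataFrame scan_exhaustive(std::string q, std::string t, double match,
                          double wobble, double mismatch) {
  int m = q.size(), n = t.size();
  std::vector<Cand> out;
  for (int d = 0; d <= m + n - 2; ++d) {
    int ilo = std::max(0, d - (n - 1)), ihi = std::min(m - 1, d);
    double run = 0.0, best = 0.0;
    int run_start = ilo, best_i1 = -1, best_i2 = -1;
    for (int i = ilo; i <= ihi; ++i) {
      double s = pair_score(q[i], t[d - i], match, wobble, mismatch);
      if (run <= 0) { run = s; run_start = i; } else run += s;
      if (run > best) { best = run; best_i1 = run_start; best_i2 = i; }
    }
    if (best > 0) {
      Cand c;
      c.qs = best_i1; c.qe = best_i2 + 1;
      c.ts = d - best_i2; c.te = d - best_i1 + 1;
      c.score = best;
      out.push_back(c);
    }
  }
  return cands_to_df(out);
}

// All (q_pos, t_pos) where query[q_pos, q_pos+w) equals the reverse
// complement of target[t_pos, t_pos+w). Ordered by q_pos then t_pos.
// [[Rcpp::export(name = ".seed_matches")]]
IntegerMatrix seed_matches(std::string q, std::string t, int w) {
  int m = q.size(), n = t.size();
  std::vector<std::pair<int,int> > hits;
  if (w >= 4 && m >= w && n >= w && w <= 15) {
    // hash w-mers of the reverse complement of each target window; a seed is
    // q-word == revcomp(t-word).
    std::unordered_map<long long, std::vector<int> > tmap;
    long long mask = (1LL << (2 * w)) - 1;
    long long codei = 0; int valid = 0;
    for (int j = 0; j < n; ++j) {
      int c = code(t[j]);
      if (c < 0) { valid = 0; codei = 0; continue; }
      // build the revcomp word incrementally: revcomp of window ending at j
      // equals complement bases in reverse order; recompute per window start.
      valid++; codei = ((codei << 2) | c) & mask;
      if (valid >= w) {
        // codei encodes t[j-w+1..j]; derive revcomp code
        long long rc = 0, x = codei;
        for (int k = 0; k < w; ++k) { rc = (rc << 2) | (3 - (x & 3)); x >>= 2; }
        tmap[rc].push_back(j - w + 1);
      }
    }
    long long qc = 0; int qvalid = 0;
    for (int i = 0; i < m; ++i) {
      int c = code(q[i]);
      if (c < 0) { qvalid = 0; qc = 0; continue; }
      qvalid++; qc = ((qc << 2) | c) & mask;
      if (qvalid >= w) {
        std::unordered_map<long long, std::vector<int> >::iterator it =
          tmap.find(qc);
        if (it != tmap.end())
          for (size_t k = 0; k < it->second.size(); ++k)
            hits.push_back(std::make_pair(i - w + 1, it->second[k]));
      }
    }
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first; out(i, 1) = hits[i].second;
  }
  colnames(out) = CharacterVector::create("q_pos", "t_pos");
  return out;
}

// X-drop extension of one seed along its diagonal; returns the maximal
// scoring segment containing the seed.
static Cand extend_one(const std::string& q, const std::string& t, int qp,
                       int tp, int w, double match, double wobble,
                       double mismatch, double xdrop) {
  int m = q.size(), n = t.size();
  int d = qp + tp + w - 1;           // diagonal
  int i1 = qp, i2 = qp + w - 1;      // query index range of the seed
  double seed_score = w * match;     // seeds are exact WC words
  // right extension (query i increasing, target j decreasing)
  double run = 0, best = 0; int best_i = i2;
  for (int i = i2 + 1; i <= std::min(m - 1, d); ++i) {
    run += pair_score(q[i], t[d - i], match, wobble, mismatch);
    if (run > best) { best = run; best_i = i; }
    if (run < best - xdrop) break;
  }
  double right_gain = best; int r_i = best_i;
  // left extension
  run = 0; best = 0; best_i = i1;
  for (int i = i1 - 1; i >= std::max(0, d - (n - 1)); --i) {
    run += pair_score(q[i], t[d - i], match, wobble, mismatch);
    if (run > best) { best = run; best_i = i; }
    if (run < best - xdrop) break;
  }
  double left_gain = best; int l_i = best_i;
  Cand c;
  c.qs = l_i; c.qe = r_i + 1; c.ts = d - r_i; c.te = d - l_i + 1;
  c.score = seed_score + right_gain + left_gain;
  return c;
}

// [[Rcpp::export(name = ".extend_seed_cpp")]]
DataFrame extend_seed_cpp(std::string q, std::string t, int qp, int tp, int w,
                          double match, double wobble, double mismatch,
                          double xdrop) {
  std::vector<Cand> out(1, extend_one(q, t, qp, tp, w, match, wobble,
                                      mismatch, xdrop));
  return cands_to_df(out);
}

// Seeded scan: extend every seed, skipping seeds already covered by a
// previous extension on the same diagonal; keep the best candidate per
// diagonal.
// [[Rcpp::export(name = ".scan_seeded")]]
DataFrame scan_seeded(std::string q, std::string t, int w, double match,
                      double wobble, double mismatch, double xdrop) {
  IntegerMatrix seeds = seed_matches(q, t, w);
  std::unordered_map<int, Cand> best_by_diag;
  std::unordered_map<int, int> covered_to; // diagonal -> query end covered
  // process seeds grouped by diagonal, ordered by q_pos
  std::vector<std::pair<long long, std::pair<int,int> > > ordered;
  for (int k = 0; k < seeds.nrow(); ++k) {
    int qp = seeds(k, 0), tp = seeds(k, 1);
    int d = qp + tp + w - 1;
    ordered.push_back(std::make_pair(((long long)d << 32) | (unsigned)qp,
                                     std::make_pair(qp, tp)));
  }
  std::sort(ordered.begin(), ordered.end());
  for (size_t k = 0; k < ordered.size(); ++k) {
    int qp = ordered[k].second.first, tp = ordered[k].second.second;
    int d = qp + tp + w - 1;
    std::unordered_map<int,int>::iterator cov = covered_to.find(d);
    if (cov != covered_to.end() && qp + w <= cov->second) continue;
    Cand c = extend_one(q, t, qp, tp, w, match, wobble, mismatch, xdrop);
    covered_to[d] = c.qe;
    std::unordered_map<int, Cand>::iterator it = best_by_diag.find(d);
    if (it == best_by_diag.end() || c.score > it->second.score)
      best_by_diag[d] = c;
  }
  std::vector<Cand> out;
  std::vector<int> diags;
  for (std::unordered_map<int, Cand>::iterator it = best_by_diag.begin();
       it != best_by_diag.end(); ++it) diags.push_back(it->first);
  std::sort(diags.begin(), diags.end());
  for (size_t i = 0; i < diags.size(); ++i) out.push_back(best_by_diag[diags[i]]);
  return cands_to_df(out);
}

// Altschul-Erickson dinucleotide-preserving shuffle. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export(name = ".dinuc_shuffle_cpp")]]
std::string dinuc_shuffle_cpp(std::string s) {
  int n = s.size();
  if (n <= 2) return s;
  int first = code(s[0]), last = code(s[n - 1]);
  if (first < 0 || last < 0) Rcpp::stop("shuffle requires A/C/G/T sequence");
  std::vector<int> edges[4];
  for (int i = 0; i + 1 < n; ++i) {
    int u = code(s[i]), v = code(s[i + 1]);
    if (u < 0 || v < 0) Rcpp::stop("shuffle requires A/C/G/T sequence");
    edges[u].push_back(v);
  }
  int last_edge[4];
  for (;;) {
    bool ok = true;
    for (int u = 0; u < 4; ++u) {
      last_edge[u] = -1;
      if (u == last || edges[u].empty()) continue;
      last_edge[u] = edges[u][(int)(unif_rand() * edges[u].size())];
    }
    for (int u = 0; u < 4 && ok; ++u) {
      if (u == last || edges[u].empty()) continue;
      int cur = u;
      for (int steps = 0; steps <= 4; ++steps) {
        if (cur == last) break;
        cur = (cur == last || last_edge[cur] < 0) ? -1 : last_edge[cur];
        if (cur < 0) break;
      }
      if (cur != last) ok = false;
    }
    if (ok) break;
  }
  std::vector<int> elist[4];
  for (int u = 0; u < 4; ++u) {
    std::vector<int> outs = edges[u];
    if (u != last && last_edge[u] >= 0) {
      // remove one instance of the chosen last edge, permute, re-append
      for (size_t i = 0; i < outs.size(); ++i)
        if (outs[i] == last_edge[u]) { outs.erase(outs.begin() + i); break; }
    }
    for (int i = (int)outs.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(outs[i], outs[j]);
    }
    if (u != last && last_edge[u] >= 0) outs.push_back(last_edge[u]);
    elist[u] = outs;
  }
  static const char LET[4] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');
  out[0] = LET[first];
  int ptr[4] = {0, 0, 0, 0};
  int cur = first;
  for (int i = 1; i < n; ++i) {
    int nxt = elist[cur][ptr[cur]++];
    out[i] = LET[nxt];
    cur = nxt;
  }
  return out;
}
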