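// Alignment kernels: banded global alignment with affine gaps (Gotoh) and a
// word-seeded local search with gapped extension, used for the inverted
// homology search inside candidate regions.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Scoring {
  int match, mismatch, gap_open, gap_extend;
};

// 'N' never matches anything, including itself; gaps are handled by the DP.
inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

inline int pair_score(char a, char b, const Scoring& sc) {
  return base_match(a, b) ? sc.match : sc.mismatch;
}

const int NEG = INT_MIN / 4;

// ---------------------------------------------------------------------------
// Gapped extension: global at the (0,0) corner, free end anywhere.
// Used to extend seed hits outward; the caller reverses inputs for the
// left-hand extension. Work is capped at `cap` characters per sequence.
// ---------------------------------------------------------------------------
struct ExtResult {
  int score = 0;     // best extension score (>= 0; 0 means no extension)
  int qlen = 0, tlen = 0;
  std::string aq, at;
};

ExtResult extend_affine(const std::string& q, const std::string& t,
                        const Scoring& sc, int cap) {
  const int n = std::min<int>((int)q.size(), cap);
  const int m = std::min<int>((int)t.size(), cap);
  ExtResult best;
  if (n == 0 && m == 0) return best;

  const int W = m + 1;
  std::vector<int> H((n + 1) * W, NEG), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // traces: for H 0=diag,1=fromE,2=fromF; for E/F 0=open(H),1=extend
  std::vector<signed char> trH((n + 1) * W, 0), trE((n + 1) * W, 0),
      trF((n + 1) * W, 0);
  auto at2 = [W](int i, int j) { return i * W + j; };

  H[at2(0, 0)] = 0;
  for (int j = 1; j <= m; ++j) {
    E[at2(0, j)] = -sc.gap_open - j * sc.gap_extend;
    trE[at2(0, j)] = (j == 1) ? 0 : 1;
    H[at2(0, j)] = E[at2(0, j)];
    trH[at2(0, j)] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    F[at2(i, 0)] = -sc.gap_open - i * sc.gap_extend;
    trF[at2(i, 0)] = (i == 1) ? 0 : 1;
    H[at2(i, 0)] = F[at2(i, 0)];
    trH[at2(i, 0)] = 2;
  }

  int best_score = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = at2(i, j);
      // E: gap in query, consume target
      int e_open = H[at2(i, j - 1)] - sc.gap_open - sc.gap_extend;
      int e_ext = E[at2(i, j - 1)] - sc.gap_extend;
      if (e_open >= e_ext) { E[k] = e_open; trE[k] = 0; }
      else { E[k] = e_ext; trE[k] = 1; }
      // F: gap in target, consume query
      int f_open = H[at2(i - 1, j)] - sc.gap_open - sc.gap_extend;
      int f_ext = F[at2(i - 1, j)] - sc.gap_extend;
      if (f_open >= f_ext) { F[k] = f_open; trF[k] = 0; }
      else { F[k] = f_ext; trF[k] = 1; }
      // H
      int d = H[at2(i - 1, j - 1)] + pair_score(q[i - 1], t[j - 1], sc);
      int h = d; signed char tr = 0;
      if (F[k] > h) { h = F[k]; tr = 2; }
      if (E[k] > h) { h = E[k]; tr = 1; }
      H[k] = h; trH[k] = tr;
      if (h > best_score) { best_score = h; bi = i; bj = j; }
    }
  }
  if (best_score <= 0) return best;

  // traceback from (bi, bj) in state H
  std::string aq, at;
  int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
  while (i > 0 || j > 0) {
    const int k = at2(i, j);
    if (state == 0) {
      signed char tr = trH[k];
      if (tr == 0) {
        aq.push_back(q[i - 1]); at.push_back(t[j - 1]); --i; --j;
      } else {
        state = tr;  // move into E or F without consuming
      }
    } else if (state == 1) {  // E: gap in query
      aq.push_back('-'); at.push_back(t[j - 1]);
      state = (trE[k] == 0) ? 0 : 1;
      --j;
    } else {  // F: gap in target
      aq.push_back(q[i - 1]); at.push_back('-');
      state = (trF[k] == 0) ? 0 : 2;
      --i;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());
  best.score = best_score;
  best.qlen = bi;
  best.tlen = bj;
  best.aq = aq;
  best.at = at;
  return best;
}

struct Hsp {
  int q0, q1, t0, t1;  // half-open, ungapped coordinates
  int score;
};

}  // namespace

// ---------------------------------------------------------------------------
// Word-seeded local search (blastn-like): exact word seeds, ungapped X-drop
// extension, then gapped extension of the top HSPs.
// Coordinates returned are 0-based half-open in query/target.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".seed_extend_cpp")]]
List seed_extend_cpp(std::string query, std::string target, int word,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int max_hsp, int ext_cap, int xdrop) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  const int n = query.size(), m = target.size();
  List empty = List::create(
      Named("q_start") = IntegerVector(0), Named("q_end") = IntegerVector(0),
      Named("t_start") = IntegerVector(0), Named("t_end") = IntegerVector(0),
      Named("score") = IntegerVector(0), Named("aligned_q") = CharacterVector(0),
      Named("aligned_t") = CharacterVector(0));
  if (n < word || m < word) return empty;

  // index target words (2-bit encoding; words containing non-ACGT skipped)
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return -1;
    }
  };
  std::unordered_map<uint32_t, std::vector<int>> index;
  {
    uint32_t w = 0; int valid = 0;
    const uint32_t mask = (word >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word)) - 1);
    for (int j = 0; j < m; ++j) {
      int c = code(target[j]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++valid >= word) index[w].push_back(j - word + 1);
    }
  }

  // seeds -> maximal exact runs, deduped by (diagonal, run start)
  std::unordered_map<int64_t, Hsp> hsps;  // key: diag * big + q0
  {
    uint32_t w = 0; int valid = 0;
    const uint32_t mask = (word >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word)) - 1);
    for (int i = 0; i < n; ++i) {
      int c = code(query[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++valid < word) continue;
      auto it = index.find(w);
      if (it == index.end()) continue;
      int qpos = i - word + 1;
      for (int tpos : it->second) {
        // maximal exact run through this seed
        int qs = qpos, ts = tpos;
        while (qs > 0 && ts > 0 && base_match(query[qs - 1], target[ts - 1])) {
          --qs; --ts;
        }
        int qe = qpos + word, te = tpos + word;
        while (qe < n && te < m && base_match(query[qe], target[te])) {
          ++qe; ++te;
        }
        int64_t key = (int64_t)(qpos - tpos) * 1000003LL + qs;
        if (hsps.count(key)) continue;
        // ungapped X-drop extension beyond the exact run
        int scorev = (qe - qs) * sc.match;
        int bl = 0, cur = 0, li = qs, lj = ts, bi = qs, bj = ts;
        while (li > 0 && lj > 0) {
          cur += pair_score(query[li - 1], target[lj - 1], sc);
          --li; --lj;
          if (cur > bl) { bl = cur; bi = li; bj = lj; }
          if (bl - cur > xdrop) break;
        }
        int br = 0; cur = 0; int ri = qe, rj = te, ei = qe, ej = te;
        while (ri < n && rj < m) {
          cur += pair_score(query[ri], target[rj], sc);
          ++ri; ++rj;
          if (cur > br) { br = cur; ei = ri; ej = rj; }
          if (br - cur > xdrop) break;
        }
        hsps[key] = Hsp{bi, ei, bj, ej, scorev + bl + br};
      }
    }
  }
  if (hsps.empty()) return empty;

  std::vector<Hsp> hv;
  hv.reserve(hsps.size());
  for (auto& kv : hsps) hv.push_back(kv.second);
  std::sort(hv.begin(), hv.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.t0 != b.t0) return a.t0 < b.t0;
    return a.q0 < b.q0;
  });
  if ((int)hv.size() > max_hsp) hv.resize(max_hsp);

  // gapped extension of each HSP
  struct Hit {
    int q0, q1, t0, t1, score;
    std::string aq, at;
  };
  std::vector<Hit> hits;
  for (const Hsp& h : hv) {
    std::string lq(query.begin(), query.begin() + h.q0);
    std::string lt(target.begin(), target.begin() + h.t0);
    std::reverse(lq.begin(), lq.end());
    std::reverse(lt.begin(), lt.end());
    ExtResult left = extend_affine(lq, lt, sc, ext_cap);
    ExtResult right = extend_affine(query.substr(h.q1), target.substr(h.t1),
                                    sc, ext_cap);
    Hit hit;
    hit.q0 = h.q0 - left.qlen;
    hit.t0 = h.t0 - left.tlen;
    hit.q1 = h.q1 + right.qlen;
    hit.t1 = h.t1 + right.tlen;
    hit.score = h.score + left.score + right.score;
    std::string laq = left.aq, lat = left.at;
    std::reverse(laq.begin(), laq.end());
    std::reverse(lat.begin(), lat.end());
    hit.aq = laq + query.substr(h.q0, h.q1 - h.q0) + right.aq;
    hit.at = lat + target.substr(h.t0, h.t1 - h.t0) + right.at;
    hits.push_back(std::move(hit));
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.t0 != b.t0) return a.t0 < b.t0;
    return a.q0 < b.q0;
  });
  // drop duplicates and hits fully contained in a better hit
  std::vector<Hit> keep;
  for (const Hit& h : hits) {
    bool contained = false;
    for (const Hit& k : keep) {
      if (h.q0 >= k.q0 && h.q1 <= k.q1 && h.t0 >= k.t0 && h.t1 <= k.t1) {
        contained = true;
        break;
      }
    }
    if (!contained) keep.push_back(h);
  }

  const int nh = keep.size();
  IntegerVector qs(nh), qe(nh), ts(nh), te(nh), scv(nh);
  CharacterVector aq(nh), at(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = keep[i].q0; qe[i] = keep[i].q1;
    ts[i] = keep[i].t0; te[i] = keep[i].t1;
    scv[i] = keep[i].score;
    aq[i] = keep[i].aq; at[i] = keep[i].at;
  }
  return List::create(Named("q_start") = qs, Named("q_end") = qe,
                      Named("t_start") = ts, Named("t_end") = te,
                      Named("score") = scv, Named("aligned_q") = aq,
                      Named("aligned_t") = at);
}

// ---------------------------------------------------------------------------
// Global alignment with affine gaps (Gotoh), restricted to a diagonal band.
// Band is expressed as allowed values of (j - i); it always covers the
// corner-to-corner diagonal, so the optimum is band-limited only when the
// band is narrower than the true optimal path's excursion.
// Tie-breaking: diagonal move preferred, then gap in s2, then gap in s1.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".global_affine_cpp")]]
List global_affine_cpp(std::string s1, std::string s2, int match, int mismatch,
                       int gap_open, int gap_extend, int band) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  const int n = s1.size(), m = s2.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (band < 1) band = 1;
  const int lo = std::min(0, m - n) - band;  // j - i >= lo
  const int hi = std::max(0, m - n) + band;  // j - i <= hi
  const int W = hi - lo + 1;

  std::vector<int> H((size_t)(n + 1) * W, NEG), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  std::vector<signed char> trH((size_t)(n + 1) * W, 0),
      trE((size_t)(n + 1) * W, 0), trF((size_t)(n + 1) * W, 0);
  auto at2 = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  H[at2(0, 0)] = 0;
  for (int j = 1; j <= m && (j - 0) <= hi; ++j) {
    E[at2(0, j)] = -sc.gap_open - j * sc.gap_extend;
    trE[at2(0, j)] = (j == 1) ? 0 : 1;
    H[at2(0, j)] = E[at2(0, j)];
    trH[at2(0, j)] = 1;
  }
  for (int i = 1; i <= n && (0 - i) >= lo; ++i) {
    F[at2(i, 0)] = -sc.gap_open - i * sc.gap_extend;
    trF[at2(i, 0)] = (i == 1) ? 0 : 1;
    H[at2(i, 0)] = F[at2(i, 0)];
    trH[at2(i, 0)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const size_t k = at2(i, j);
      int e_open = NEG, e_ext = NEG;
      if (inband(i, j - 1)) {
        if (H[at2(i, j - 1)] > NEG)
          e_open = H[at2(i, j - 1)] - sc.gap_open - sc.gap_extend;
        if (E[at2(i, j - 1)] > NEG) e_ext = E[at2(i, j - 1)] - sc.gap_extend;
      }
      if (e_open >= e_ext) { E[k] = e_open; trE[k] = 0; }
      else { E[k] = e_ext; trE[k] = 1; }

      int f_open = NEG, f_ext = NEG;
      if (inband(i - 1, j)) {
        if (H[at2(i - 1, j)] > NEG)
          f_open = H[at2(i - 1, j)] - sc.gap_open - sc.gap_extend;
        if (F[at2(i - 1, j)] > NEG) f_ext = F[at2(i - 1, j)] - sc.gap_extend;
      }
      if (f_open >= f_ext) { F[k] = f_open; trF[k] = 0; }
      else { F[k] = f_ext; trF[k] = 1; }

      int d = NEG;
      if (inband(i - 1, j - 1) && H[at2(i - 1, j - 1)] > NEG)
        d = H[at2(i - 1, j - 1)] + pair_score(s1[i - 1], s2[j - 1], sc);
      int h = d; signed char tr = 0;
      if (F[k] > h) { h = F[k]; tr = 2; }  // gap in s2 preferred over gap in s1
      if (E[k] > h) { h = E[k]; tr = 1; }
      H[k] = h; trH[k] = tr;
    }
  }

  if (H[at2(n, m)] <= NEG) stop("band too narrow for a global alignment");
  std::string a1, a2;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    const size_t k = at2(i, j);
    if (state == 0) {
      signed char tr = trH[k];
      if (tr == 0) { a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]); --i; --j; }
      else state = tr;
    } else if (state == 1) {
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      state = (trE[k] == 0) ? 0 : 1;
      --j;
    } else {
      a1.push_back(s1[i - 1]); a2.push_back('-');
      state = (trF[k] == 0) ? 0 : 2;
      --i;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(Named("aligned1") = a1, Named("aligned2") = a2,
                      Named("score") = H[at2(n, m)]);
}
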