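// Core numerical routines for sequence-order-independent pocket alignment:
// Kabsch superposition, a Hungarian assignment solver, and the candidate
// search (seeded iterative matching plus an exhaustive branch for tiny
// pockets).  All search paths are deterministic for fixed inputs.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct KabschResult {
  arma::mat R;     // 3x3 proper rotation, maps centred P onto centred Q
  arma::vec t;     // translation so that q ~ R p + t
  double rmsd;
  bool ok;
};

KabschResult kabsch(const arma::mat& P, const arma::mat& Q) {
  KabschResult out;
  out.ok = false;
  const arma::uword k = P.n_rows;
  if (k < 3 || Q.n_rows != k) return out;
  arma::rowvec pbar = arma::mean(P, 0), qbar = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pbar;
  arma::mat Qc = Q.each_row() - qbar;
  arma::mat H = Pc.t() * Qc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return out;
  double d = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  out.R = V * D * U.t();
  out.t = qbar.t() - out.R * pbar.t();
  arma::mat Pt = (out.R * Pc.t()).t();
  out.rmsd = std::sqrt(arma::accu(arma::square(Pt - Qc)) / double(k));
  out.ok = true;
  return out;
}

// Minimum-cost perfect assignment on a square matrix (shortest augmenting
// path with potentials, O(n^3)).  Returns, for each row, the assigned column.
std::vector<int> hungarian(const arma::mat& a) {
  const int n = a.n_rows;
  const double INF = 1e18;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> ans(n, -1);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j - 1;
  return ans;
}

struct Candidate {
  std::vector<int> qi;   // query atom indices (0-based), sorted ascending
  std::vector<int> ri;   // matched reference indices, parallel to qi
  double rmsd = 0.0, structural = 0.0, seq = 0.0, combined = 0.0;
  double sim = 0.0, best = 0.0;
  arma::mat R;
  arma::vec t;
  bool valid = false;
};

struct SearchCtx {
  const arma::mat* A;
  const arma::mat* B;
  const arma::mat* simMat;
  const arma::vec* bestVec;
  double alpha, tau, tie_tol;
  int min_aligned, max_iter;
};

// Score a pair set: re-superpose with Kabsch, then apply the defining
// score identities.  Pair distances are not re-checked here; callers that
// need the <= tau guarantee check it themselves.
Candidate evaluate(const SearchCtx& cx, const std::vector<int>& qi,
                   const std::vector<int>& ri) {
  Candidate c;
  const int k = qi.size();
  if (k < cx.min_aligned) return c;
  arma::mat P(k, 3), Q(k, 3);
  for (int a = 0; a < k; ++a) {
    P.row(a) = cx.A->row(qi[a]);
    Q.row(a) = cx.B->row(ri[a]);
  }
  KabschResult kb = kabsch(P, Q);
  if (!kb.ok) return c;
  double sim = 0.0, best = 0.0;
  for (int a = 0; a < k; ++a) {
    sim += (*cx.simMat)(qi[a], ri[a]);
    best += (*cx.bestVec)(ri[a]);
  }
  if (best <= 0.0) return c;
  c.qi = qi; c.ri = ri;
  c.rmsd = kb.rmsd;
  c.R = kb.R; c.t = kb.t;
  c.structural = kb.rmsd * std::pow(double(k), -1.0 / 3.0);
  c.sim = sim; c.best = best;
  c.seq = 1.0 - sim / best;
  c.combined = c.structural + cx.alpha * c.seq;
  c.valid = true;
  return c;
}

bool pairs_within_tau(const SearchCtx& cx, const Candidate& c) {
  for (size_t a = 0; a < c.qi.size(); ++a) {
    arma::vec p = c.R * cx.A->row(c.qi[a]).t() + c.t;
    double d = arma::norm(p - cx.B->row(c.ri[a]).t());
    if (d > cx.tau + 1e-12) return false;
  }
  return true;
}

// Deterministic ordering: smaller combined wins; near-ties (tie_tol) go to
// larger N, then lexicographically smaller correspondence list.
bool better(const SearchCtx& cx, const Candidate& a, const Candidate& b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.combined < b.combined - cx.tie_tol) return true;
  if (a.combined > b.combined + cx.tie_tol) return false;
  if (a.qi.size() != b.qi.size()) return a.qi.size() > b.qi.size();
  if (a.qi != b.qi) return a.qi < b.qi;
  if (a.ri != b.ri) return a.ri < b.ri;
  return a.combined < b.combined;
}

void sort_pairs(std::vector<int>& qi, std::vector<int>& ri) {
  const int k = qi.size();
  std::vector<int> ord(k);
  for (int a = 0; a < k; ++a) ord[a] = a;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) { return qi[x] < qi[y]; });
  std::vector<int> q2(k), r2(k);
  for (int a = 0; a < k; ++a) { q2[a] = qi[ord[a]]; r2[a] = ri[ord[a]]; }
  qi.swap(q2); ri.swap(r2);
}

// Greedy threshold matching under a fixed transform: admissible pairs sorted
// by (distance, i, j), accepted when both endpoints are free.
void greedy_match(const SearchCtx& cx, const arma::mat& TA,
                  std::vector<int>& qi, std::vector<int>& ri) {
  const int n = TA.n_rows, m = cx.B->n_rows;
  struct PD { double d; int i, j; };
  std::vector<PD> cand;
  cand.reserve(64);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = arma::norm(TA.row(i) - cx.B->row(j));
      if (d <= cx.tau) cand.push_back({d, i, j});
    }
  }
  std::sort(cand.begin(), cand.end(), [](const PD& x, const PD& y) {
    if (x.d != y.d) return x.d < y.d;
    if (x.i != y.i) return x.i < y.i;
    return x.j < y.j;
  });
  std::vector<char> ui(n, 0), uj(m, 0);
  qi.clear(); ri.clear();
  for (const PD& p : cand) {
    if (ui[p.i] || uj[p.j]) continue;
    ui[p.i] = uj[p.j] = 1;
    qi.push_back(p.i); ri.push_back(p.j);
  }
  sort_pairs(qi, ri);
}

// Iterate greedy matching + re-superposition to a fixed point from a seed
// transform.  Returns an invalid candidate when it collapses below
// min_aligned.
Candidate refine(const SearchCtx& cx, arma::mat R, arma::vec t) {
  std::vector<int> qi, ri, prev_qi, prev_ri;
  Candidate cur;
  for (int it = 0; it < cx.max_iter; ++it) {
    arma::mat TA = (R * cx.A->t()).t();
    TA.each_row() += t.t();
    greedy_match(cx, TA, qi, ri);
    if ((int)qi.size() < cx.min_aligned) return Candidate();
    Candidate c = evaluate(cx, qi, ri);
    if (!c.valid) return Candidate();
    cur = c;
    R = c.R; t = c.t;
    if (qi == prev_qi && ri == prev_ri) break;
    prev_qi = qi; prev_ri = ri;
  }
  return cur;
}

// Optimal-assignment polish of one candidate: restrict to atoms/positions
// with at least one admissible pair under the candidate transform, solve the
// padded square assignment (unmatched costs tau), keep admissible pairs.
Candidate polish(const SearchCtx& cx, const Candidate& c0) {
  Candidate best = c0;
  arma::mat R = c0.R;
  arma::vec t = c0.t;
  std::vector<int> prev_qi, prev_ri;
  const double BIG = 1e6;
  for (int rep = 0; rep < 3; ++rep) {
    arma::mat TA = (R * cx.A->t()).t();
    TA.each_row() += t.t();
    const int n = TA.n_rows, m = cx.B->n_rows;
    arma::mat D(n, m);
    std::vector<char> rowok(n, 0), colok(m, 0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        double d = arma::norm(TA.row(i) - cx.B->row(j));
        D(i, j) = d;
        if (d <= cx.tau) { rowok[i] = 1; colok[j] = 1; }
      }
    }
    std::vector<int> rows, cols;
    for (int i = 0; i < n; ++i) if (rowok[i]) rows.push_back(i);
    for (int j = 0; j < m; ++j) if (colok[j]) cols.push_back(j);
    const int nr = rows.size(), nc = cols.size();
    if (nr < cx.min_aligned || nc < cx.min_aligned) break;
    const int N = nr + nc;
    arma::mat C(N, N);
    C.fill(BIG);
    for (int a = 0; a < nr; ++a)
      for (int b = 0; b < nc; ++b)
        C(a, b) = (D(rows[a], cols[b]) <= cx.tau) ? D(rows[a], cols[b]) : BIG;
    for (int a = 0; a < nr; ++a) C(a, nc + a) = cx.tau;      // row unmatched
    for (int b = 0; b < nc; ++b) C(nr + b, b) = cx.tau;      // col unmatched
    C.submat(nr, nc, N - 1, N - 1).zeros();                   // dummy-dummy
    std::vector<int> asg = hungarian(C);
    std::vector<int> qi, ri;
    for (int a = 0; a < nr; ++a) {
      int b = asg[a];
      if (b >= 0 && b < nc && D(rows[a], cols[b]) <= cx.tau) {
        qi.push_back(rows[a]); ri.push_back(cols[b]);
      }
    }
    if ((int)qi.size() < cx.min_aligned) break;
    sort_pairs(qi, ri);
    Candidate c = evaluate(cx, qi, ri);
    if (!c.valid) break;
    if (better(cx, c, best)) best = c;
    R = c.R; t = c.t;
    if (qi == prev_qi && ri == prev_ri) break;
    prev_qi = qi; prev_ri = ri;
  }
  return best;
}

// Exhaustive branch for tiny pockets: every >= min_aligned sized injective
// correspondence, each Kabsch-superposed, admissibility enforced.
void exhaustive_rec(const SearchCtx& cx, int next_i, std::vector<int>& qi,
                    std::vector<int>& ri, std::vector<char>& used_j,
                    Candidate& best) {
  const int n = cx.A->n_rows, m = cx.B->n_rows;
  if ((int)qi.size() >= cx.min_aligned) {
    Candidate c = evaluate(cx, qi, ri);
    if (c.valid && pairs_within_tau(cx, c) && better(cx, c, best)) best = c;
  }
  if (next_i >= n) return;
  // continue only while enough atoms remain to ever reach min_aligned
  for (int i = next_i; i < n; ++i) {
    if ((int)qi.size() + (n - i) < cx.min_aligned) break;
    for (int j = 0; j < m; ++j) {
      if (used_j[j]) continue;
      used_j[j] = 1;
      qi.push_back(i); ri.push_back(j);
      exhaustive_rec(cx, i + 1, qi, ri, used_j, best);
      qi.pop_back(); ri.pop_back();
      used_j[j] = 0;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& P, const arma::mat& Q) {
  KabschResult kb = kabsch(P, Q);
  if (!kb.ok) stop("Kabsch superposition failed (need >= 3 point pairs)");
  return List::create(_["rotation"] = kb.R, _["translation"] = kb.t,
                      _["rmsd"] = kb.rmsd);
}

// [[Rcpp::export(name = ".align_search_cpp")]]
List align_search_cpp(const arma::mat& A, const arma::mat& B,
                      const arma::mat& simMat, const arma::vec& bestVec,
                      double alpha, double tau, int min_aligned,
                      const IntegerMatrix& seedsA, const IntegerMatrix& seedsB,
                      bool exhaustive, int max_iter, double tie_tol,
                      int max_polish) {
  SearchCtx cx{&A, &B, &simMat, &bestVec, alpha, tau, tie_tol,
               min_aligned, max_iter};
  Candidate best;

  if (exhaustive) {
    std::vector<int> qi, ri;
    std::vector<char> used_j(B.n_rows, 0);
    exhaustive_rec(cx, 0, qi, ri, used_j, best);
  } else {
    // seeded candidates, deduplicated by correspondence set
    std::map<std::vector<int>, Candidate> uniq;
    const int S = seedsA.nrow();
    for (int s = 0; s < S; ++s) {
      arma::mat P(3, 3), Q(3, 3);
      for (int a = 0; a < 3; ++a) {
        P.row(a) = A.row(seedsA(s, a) - 1);
        Q.row(a) = B.row(seedsB(s, a) - 1);
      }
      KabschResult kb = kabsch(P, Q);
      if (!kb.ok || kb.rmsd > 1.2) continue;
      Candidate c = refine(cx, kb.R, kb.t);
      if (!c.valid) continue;
      std::vector<int> key;
      key.reserve(2 * c.qi.size());
      for (size_t a = 0; a < c.qi.size(); ++a) {
        key.push_back(c.qi[a]); key.push_back(c.ri[a]);
      }
      auto it = uniq.find(key);
      if (it == uniq.end()) uniq.emplace(key, c);
    }
    // rank unique candidates, polish the strongest
    std::vector<Candidate> cands;
    for (auto& kv : uniq) cands.push_back(kv.second);
    std::sort(cands.begin(), cands.end(), [&](const Candidate& a, const Candidate& b) {
      return better(cx, a, b);
    });
    if ((int)cands.size() > max_polish) cands.resize(max_polish);
    for (const Candidate& c : cands) {
      if (better(cx, c, best)) best = c;
      Candidate p = polish(cx, c);
      if (better(cx, p, best)) best = p;
    }
  }

  if (!best.valid) return List::create(_["aligned"] = false);
  IntegerMatrix pairs(best.qi.size(), 2);
  for (size_t a = 0; a < best.qi.size(); ++a) {
    pairs(a, 0) = best.qi[a] + 1;
    pairs(a, 1) = best.ri[a] + 1;
  }
  return List::create(
      _["aligned"] = true, _["pairs"] = pairs, _["n"] = (int)best.qi.size(),
      _["rmsd"] = best.rmsd, _["rotation"] = best.R,
      _["translation"] = best.t, _["similarity"] = best.sim,
      _["best_similarity"] = best.best, _["sequence_score"] = best.seq,
      _["structural_score"] = best.structural, _["combined_score"] = best.combined);
}
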