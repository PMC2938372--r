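#include <Rcpp.h>
using namespace Rcpp;

// Accumulate Kelvin-Voigt element forces over all nodes.
//
// Returns:
//   full : N x 2 matrix, exact antisymmetric Voigt forces
//          f_a = [k (|r| - L0) + eta * (v_b - v_a).u] u,  f_b = -f_a
//   semi : N x 2 matrix, same spring term but only the *neighbor* axial
//          dashpot contribution eta (v_other . u) u; the own-node axial
//          dashpot is returned separately as the scalar eta sum 'H' so the
//          integrator can treat it implicitly (effective drag D + H).
//   H    : length-N vector, sum of incident element viscosities.
// a, b are 1-based node row indices.
// [[Rcpp::export]]
List cpp_voigt_accumulate(const NumericMatrix& pos, const NumericMatrix& vel,
                          const IntegerVector& a, const IntegerVector& b,
                          const NumericVector& k, const NumericVector& eta,
                          const NumericVector& L0) {
  const int N = pos.nrow(), M = a.size();
  NumericMatrix full(N, 2), semi(N, 2);
  NumericVector H(N);
  for (int e = 0; e < M; ++e) {
    const int ia = a[e] - 1, ib = b[e] - 1;
    const double dx = pos(ib, 0) - pos(ia, 0);
    const double dy = pos(ib, 1) - pos(ia, 1);
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len <= 0.0) stop("coincident element endpoints (zero length axis)");
    const double ux = dx / len, uy = dy / len;
    const double rvx = vel(ib, 0) - vel(ia, 0);
    const double rvy = vel(ib, 1) - vel(ia, 1);
    const double vrel = rvx * ux + rvy * uy;       // >0 when separating
    const double fm = k[e] * (len - L0[e]) + eta[e] * vrel;
    full(ia, 0) += fm * ux;  full(ia, 1) += fm * uy;
    full(ib, 0) -= fm * ux;  full(ib, 1) -= fm * uy;
    const double spring = k[e] * (len - L0[e]);
    const double va_u = vel(ia, 0) * ux + vel(ia, 1) * uy;
    const double vb_u = vel(ib, 0) * ux + vel(ib, 1) * uy;
    const double fa = spring + eta[e] * vb_u;      // own -eta va.u goes to H
    const double fb = -spring + eta[e] * va_u;     // sign: along u from a->b
    semi(ia, 0) += fa * ux;  semi(ia, 1) += fa * uy;
    semi(ib, 0) += fb * ux;  semi(ib, 1) += fb * uy;
    H[ia] += eta[e];
    H[ib] += eta[e];
  }
  return List::create(_["full"] = full, _["semi"] = semi, _["H"] = H);
}

// All index pairs (i in setA, j in setB) with |pos_i - pos_j| < cutoff.
// Brute force over the two (pre-filtered, small) sets; 1-based in and out.
// skip_same_owner: owner vector, pairs with equal owner are skipped.
// [[Rcpp::export]]
IntegerMatrix cpp_close_pairs(const NumericMatrix& pos,
                              const IntegerVector& setA,
                              const IntegerVector& setB,
                              double cutoff,
                              const IntegerVector& owner) {
  const double c2 = cutoff * cutoff;
  std::vector<int> ri, rj;
  for (int p = 0; p < setA.size(); ++p) {
    const int i = setA[p] - 1;
    for (int q = 0; q < setB.size(); ++q) {
      const int j = setB[q] - 1;
      if (owner[i] == owner[j]) continue;
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      if (dx * dx + dy * dy < c2) { ri.push_back(i + 1); rj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t r = 0; r < ri.size(); ++r) { out(r, 0) = ri[r]; out(r, 1) = rj[r]; }
  return out;
}

// Uniform-hash-grid neighbor search: all unordered pairs (i, j) of nodes
// from 'cand' (1-based rows of pos) with different owners and
// |r_i - r_j| < cutoff.  Equidistant ties are irrelevant here (all pairs
// under the cutoff are returned); output ordered (smaller row first).
// [[Rcpp::export]]
IntegerMatrix cpp_grid_pairs(const NumericMatrix& pos,
                             const IntegerVector& cand,
                             const IntegerVector& owner,
                             double cutoff) {
  const int M = cand.size();
  const double c2 = cutoff * cutoff, h = cutoff;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(M * 2);
  std::vector<long long> key(M);
  for (int p = 0; p < M; ++p) {
    const int i = cand[p] - 1;
    const long long gx = (long long)std::floor(pos(i, 0) / h);
    const long long gy = (long long)std::floor(pos(i, 1) / h);
    key[p] = gx * 2000003LL + gy;
    grid[key[p]].push_back(i);
  }
  std::vector<int> ri, rj;
  for (int p = 0; p < M; ++p) {
    const int i = cand[p] - 1;
    const long long gx = (long long)std::floor(pos(i, 0) / h);
    const long long gy = (long long)std::floor(pos(i, 1) / h);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = grid.find((gx + dx) * 2000003LL + (gy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;               // each unordered pair once
          if (owner[i] == owner[j]) continue;
          const double ddx = pos(i, 0) - pos(j, 0);
          const double ddy = pos(i, 1) - pos(j, 1);
          if (ddx * ddx + ddy * ddy < c2) { ri.push_back(i + 1); rj.push_back(j + 1); }
        }
      }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t r = 0; r < ri.size(); ++r) { out(r, 0) = ri[r]; out(r, 1) = rj[r]; }
  return out;
}

// Batched short-range repulsion.  Queries are grouped: group g holds
// query nodes (1-based indices qidx with qgrp == g) tested against one
// foreign polyline (node indices polyflat[polyoff[g] .. +polylen[g]-1],
// closed if polyclosed[g]).  A query node at nearest distance d < d_rep
// receives magnitude k_rep * (d_rep - d) along 'inward' (given per node,
// the negated outward membrane normal); the reaction is split onto the
// nearest segment's endpoints by barycentric weights, conserving
// momentum exactly.
// [[Rcpp::export]]
NumericMatrix cpp_repulsion(const NumericMatrix& pos,
                            const IntegerVector& qidx,
                            const IntegerVector& qgrp,
                            const NumericMatrix& inward,
                            const IntegerVector& polyflat,
                            const IntegerVector& polyoff,
                            const IntegerVector& polylen,
                            const LogicalVector& polyclosed,
                            double d_rep, double k_rep) {
  const int N = pos.nrow();
  NumericMatrix F(N, 2);
  // a node repels against its single nearest foreign surface: first find
  // the best (distance, segment) over all candidate groups per node ...
  std::unordered_map<int, double> bestd;
  std::unordered_map<int, int> besta, bestb;
  std::unordered_map<int, double> bestt;
  for (int q = 0; q < qidx.size(); ++q) {
    const int i = qidx[q] - 1;
    const int g = qgrp[q] - 1;
    const int off = polyoff[g] - 1, len = polylen[g];
    const bool closed = polyclosed[g];
    const int S = closed ? len : len - 1;
    if (S < 1) continue;
    const double px = pos(i, 0), py = pos(i, 1);
    for (int s = 0; s < S; ++s) {
      const int ia = polyflat[off + s] - 1;
      const int ib = polyflat[off + ((s + 1) % len)] - 1;
      const double ax = pos(ia, 0), ay = pos(ia, 1);
      const double ex = pos(ib, 0) - ax, ey = pos(ib, 1) - ay;
      const double L2 = ex * ex + ey * ey;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((px - ax) * ex + (py - ay) * ey) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double cx = ax + t * ex - px, cy = ay + t * ey - py;
      const double d2 = cx * cx + cy * cy;
      auto it = bestd.find(i);
      if (it == bestd.end() || d2 < it->second) {
        bestd[i] = d2; besta[i] = ia; bestb[i] = ib; bestt[i] = t;
      }
    }
  }
  // ... then apply the linear ramp along the node's inward normal, with
  // the reaction split barycentrically onto the nearest segment
  for (auto& kv : bestd) {
    const int i = kv.first;
    const double d = std::sqrt(kv.second);
    if (d >= d_rep) continue;
    const double mag = k_rep * (d_rep - d);
    const double fx = mag * inward(i, 0), fy = mag * inward(i, 1);
    F(i, 0) += fx; F(i, 1) += fy;
    const double bt = bestt[i];
    const int ia = besta[i], ib = bestb[i];
    F(ia, 0) -= (1.0 - bt) * fx; F(ia, 1) -= (1.0 - bt) * fy;
    F(ib, 0) -= bt * fx;         F(ib, 1) -= bt * fy;
  }
  return F;
}

// Minimum distance from each query point to a polyline (closed if 'closed').
// Returns distance, 1-based index of the nearest segment's first vertex,
// and barycentric coordinate t in [0,1] along that segment.
// [[Rcpp::export]]
List cpp_point_polyline(const NumericMatrix& pts, const NumericMatrix& poly,
                        bool closed) {
  const int P = pts.nrow(), Q = poly.nrow();
  const int S = closed ? Q : Q - 1;
  if (S < 1) stop("polyline needs at least one segment");
  NumericVector dist(P), tt(P);
  IntegerVector seg(P);
  for (int p = 0; p < P; ++p) {
    const double px = pts(p, 0), py = pts(p, 1);
    double best = R_PosInf, bt = 0.0; int bs = 0;
    for (int s = 0; s < S; ++s) {
      const int s2 = (s + 1) % Q;
      const double ax = poly(s, 0), ay = poly(s, 1);
      const double bx = poly(s2, 0), by = poly(s2, 1);
      const double ex = bx - ax, ey = by - ay;
      const double L2 = ex * ex + ey * ey;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((px - ax) * ex + (py - ay) * ey) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double cx = ax + t * ex - px, cy = ay + t * ey - py;
      const double d2 = cx * cx + cy * cy;
      if (d2 < best) { best = d2; bs = s; bt = t; }
    }
    dist[p] = std::sqrt(best); seg[p] = bs + 1; tt[p] = bt;
  }
  return List::create(_["dist"] = dist, _["seg"] = seg, _["t"] = tt);
}
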