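#include <Rcpp.h>
using namespace Rcpp;

// Joint spatial-range mean-shift filtering with the Epanechnikov profile.
// With this profile the shadow g() is the indicator of the unit ball, so a
// shift step is the plain mean of the samples inside the joint window:
// spatial candidates ||x^s - y^s|| <= h_s, then range ||x^r - y^r|| <= h_r.
// Both spatial and range components move each iteration; the stop rule is
// spatial quasi-stationarity (||dy^s|| <= s_thr) together with a range move
// ||dy^r|| <= thr, or max_iter.

// [[Rcpp::export]]
List meanshift_filter_cpp(NumericMatrix L, NumericMatrix U, NumericMatrix V,
                          double hs, double hr, double thr, double s_thr,
                          int max_iter) {
  const int H = L.nrow(), W = L.ncol(), n = H * W;
  NumericMatrix modes(n, 5);  // row, col (0-based), l, u, v
  IntegerVector iters(n);
  LogicalVector converged(n);
  const double hs2 = hs * hs, hr2 = hr * hr;

  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      const int i = c * H + r;  // column-major, matches R indexing
      double yr = r, yc = c, yl = L(r, c), yu = U(r, c), yv = V(r, c);
      int it = 0;
      bool done = false, conv = false;
      while (it < max_iter && !done) {
        it++;
        int r0 = std::max(0, (int)std::ceil(yr - hs));
        int r1 = std::min(H - 1, (int)std::floor(yr + hs));
        int c0 = std::max(0, (int)std::ceil(yc - hs));
        int c1 = std::min(W - 1, (int)std::floor(yc + hs));
        double sr = 0, sc = 0, sl = 0, su = 0, sv = 0;
        int cnt = 0;
        for (int cc = c0; cc <= c1; cc++) {
          for (int rr = r0; rr <= r1; rr++) {
            const double dr = rr - yr, dc = cc - yc;
            if (dr * dr + dc * dc > hs2) continue;
            const double dl = L(rr, cc) - yl, du = U(rr, cc) - yu,
                         dv = V(rr, cc) - yv;
            if (dl * dl + du * du + dv * dv > hr2) continue;
            sr += rr; sc += cc;
            sl += L(rr, cc); su += U(rr, cc); sv += V(rr, cc);
            cnt++;
          }
        }
        if (cnt == 0) { done = true; break; }  // empty window: stay put
        const double nr = sr / cnt, nc = sc / cnt, nl = sl / cnt,
                     nu = su / cnt, nv = sv / cnt;
        const double ds2 = (nr - yr) * (nr - yr) + (nc - yc) * (nc - yc);
        const double dr2 = (nl - yl) * (nl - yl) + (nu - yu) * (nu - yu) +
                           (nv - yv) * (nv - yv);
        yr = nr; yc = nc; yl = nl; yu = nu; yv = nv;
        if (ds2 <= s_thr * s_thr && dr2 <= thr * thr) { done = true; conv = true; }
      }
      modes(i, 0) = yr; modes(i, 1) = yc;
      modes(i, 2) = yl; modes(i, 3) = yu; modes(i, 4) = yv;
      iters[i] = it;
      converged[i] = conv;
    }
  }
  return List::create(_["modes"] = modes, _["iters"] = iters,
                      _["converged"] = converged);
}

// Transitive merge of per-pixel modes: two modes join when they are within
// ds spatially AND dr in range. Union-find accelerated by uniform spatial
// binning (bin edge = ds, so candidate pairs live in adjacent bins); the
// binning is exactness-preserving.

// [[Rcpp::export]]
IntegerVector cluster_modes_cpp(NumericMatrix modes, double ds, double dr) {
  const int n = modes.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  double rmin = R_PosInf, rmax = R_NegInf, cmin = R_PosInf, cmax = R_NegInf;
  for (int i = 0; i < n; i++) {
    rmin = std::min(rmin, modes(i, 0)); rmax = std::max(rmax, modes(i, 0));
    cmin = std::min(cmin, modes(i, 1)); cmax = std::max(cmax, modes(i, 1));
  }
  const double bin = std::max(ds, 1e-9);
  const int nbr = (int)((rmax - rmin) / bin) + 1;
  const int nbc = (int)((cmax - cmin) / bin) + 1;
  std::vector<std::vector<int> > bins((size_t)nbr * nbc);
  std::vector<int> br(n), bc(n);
  for (int i = 0; i < n; i++) {
    br[i] = (int)((modes(i, 0) - rmin) / bin);
    bc[i] = (int)((modes(i, 1) - cmin) / bin);
    bins[(size_t)bc[i] * nbr + br[i]].push_back(i);
  }
  const double ds2 = ds * ds, dr2 = dr * dr;
  for (int i = 0; i < n; i++) {
    for (int dbc = -1; dbc <= 1; dbc++) {
      for (int dbr = -1; dbr <= 1; dbr++) {
        const int rr = br[i] + dbr, cc = bc[i] + dbc;
        if (rr < 0 || rr >= nbr || cc < 0 || cc >= nbc) continue;
        const std::vector<int>& cell = bins[(size_t)cc * nbr + rr];
        for (size_t m = 0; m < cell.size(); m++) {
          const int j = cell[m];
          if (j <= i) continue;
          const double a = modes(i, 0) - modes(j, 0),
                       b = modes(i, 1) - modes(j, 1);
          if (a * a + b * b > ds2) continue;
          const double dl = modes(i, 2) - modes(j, 2),
                       du = modes(i, 3) - modes(j, 3),
                       dv = modes(i, 4) - modes(j, 4);
          if (dl * dl + du * du + dv * dv > dr2) continue;
          unite(i, j);
        }
      }
    }
  }
  IntegerVector out(n);
  std::map<int, int> relabel;
  for (int i = 0; i < n; i++) {
    const int root = find(i);
    std::map<int, int>::iterator it = relabel.find(root);
    if (it == relabel.end()) {
      const int id = (int)relabel.size() + 1;
      relabel[root] = id;
      out[i] = id;
    } else {
      out[i] = it->second;
    }
  }
  return out;
}
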