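#include <Rcpp.h>
using namespace Rcpp;

// Grid search for the smoothed IR objective
//   sum_k ( y_k^2 - (A + B exp(-TI_k/T1))^2 )^2
// over the cartesian grid t1_grid x a_grid x b_grid. Ties broken toward the
// smallest T1 (grids are scanned in increasing T1 order; strict improvement
// required to move).
// [[Rcpp::export(name = ".ir_grid_search_cpp")]]
List ir_grid_search_cpp(NumericVector y, NumericVector ti,
                        NumericVector t1_grid, NumericVector a_grid,
                        NumericVector b_grid) {
  const int K = y.size();
  std::vector<double> y2(K);
  for (int k = 0; k < K; ++k) y2[k] = y[k] * y[k];

  double best = R_PosInf;
  double bt1 = t1_grid[0], ba = a_grid[0], bb = b_grid[0];
  std::vector<double> E(K);
  for (int i = 0; i < t1_grid.size(); ++i) {
    for (int k = 0; k < K; ++k) E[k] = std::exp(-ti[k] / t1_grid[i]);
    for (int j = 0; j < a_grid.size(); ++j) {
      const double A = a_grid[j];
      for (int l = 0; l < b_grid.size(); ++l) {
        const double B = b_grid[l];
        double obj = 0.0;
        for (int k = 0; k < K; ++k) {
          const double f = A + B * E[k];
          const double r = y2[k] - f * f;
          obj += r * r;
        }
        if (obj < best) {
          best = obj; bt1 = t1_grid[i]; ba = A; bb = B;
        }
      }
    }
  }
  return List::create(_["t1"] = bt1, _["a"] = ba, _["b"] = bb,
                      _["objective"] = best);
}

// Grid search for the Ernst-equation least squares
//   sum_m ( z_m - M0 sin(a_m) (1-E)/(1-E cos(a_m)) )^2,  E = exp(-TR/T1)
// [[Rcpp::export(name = ".vfa_grid_search_cpp")]]
List vfa_grid_search_cpp(NumericVector z, NumericVector alpha_rad,
                         double tr, NumericVector t1_grid,
                         NumericVector m0_grid) {
  const int M = z.size();
  std::vector<double> sa(M), ca(M);
  for (int m = 0; m < M; ++m) {
    sa[m] = std::sin(alpha_rad[m]);
    ca[m] = std::cos(alpha_rad[m]);
  }
  double best = R_PosInf, bt1 = t1_grid[0], bm0 = m0_grid[0];
  std::vector<double> s(M);
  for (int i = 0; i < t1_grid.size(); ++i) {
    const double E = std::exp(-tr / t1_grid[i]);
    for (int m = 0; m < M; ++m) s[m] = sa[m] * (1.0 - E) / (1.0 - E * ca[m]);
    for (int j = 0; j < m0_grid.size(); ++j) {
      const double M0 = m0_grid[j];
      double obj = 0.0;
      for (int m = 0; m < M; ++m) {
        const double r = z[m] - M0 * s[m];
        obj += r * r;
      }
      if (obj < best) { best = obj; bt1 = t1_grid[i]; bm0 = M0; }
    }
  }
  return List::create(_["t1"] = bt1, _["m0"] = bm0, _["objective"] = best);
}

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& zbuf) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zbuf[0] = -R_PosInf;
  zbuf[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest
// nonzero pixel of a binary matrix.
// [[Rcpp::export(name = ".distance_transform_cpp")]]
NumericMatrix distance_transform_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  const double INF = 1e18;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = mask(i, j) ? 0.0 : INF;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> zbuf(std::max(nr, nc) + 1);

  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    f.resize(nr); d.resize(nr);
    edt1d(f, d, v, zbuf);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    f.resize(nc); d.resize(nc);
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    edt1d(f, d, v, zbuf);
    for (int j = 0; j < nc; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}

// Coarse-grid rigid registration scoring: for every (rotation, tx, ty) on the
// grid, the mean distance (pixels, from the precomputed distance map D of the
// edge image) of the transformed template boundary points. Returns an array
// [n_rot x n_tx x n_ty].
// [[Rcpp::export(name = ".rigid_score_grid_cpp")]]
NumericVector rigid_score_grid_cpp(NumericMatrix D, NumericMatrix centers_mm,
                                   double radius_mm, int n_boundary,
                                   double pixel_mm,
                                   NumericVector rot_deg, NumericVector tx_mm,
                                   NumericVector ty_mm) {
  const int nr = D.nrow(), nc = D.ncol();
  const int ns = centers_mm.nrow();
  const int nrot = rot_deg.size(), ntx = tx_mm.size(), nty = ty_mm.size();
  NumericVector out(nrot * ntx * nty);
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;

  std::vector<double> bx(ns * n_boundary), by(ns * n_boundary);
  for (int ir = 0; ir < nrot; ++ir) {
    const double th = rot_deg[ir] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    int idx = 0;
    for (int s = 0; s < ns; ++s) {
      const double x0 = ct * centers_mm(s, 0) - st * centers_mm(s, 1);
      const double y0 = st * centers_mm(s, 0) + ct * centers_mm(s, 1);
      for (int b = 0; b < n_boundary; ++b) {
        const double phi = 2.0 * M_PI * b / n_boundary;
        bx[idx] = x0 + radius_mm * std::cos(phi);
        by[idx] = y0 + radius_mm * std::sin(phi);
        ++idx;
      }
    }
    for (int it = 0; it < ntx; ++it) {
      for (int jt = 0; jt < nty; ++jt) {
        double acc = 0.0;
        for (int p = 0; p < idx; ++p) {
          int col = (int)std::lround((bx[p] + tx_mm[it]) / pixel_mm + cx);
          int row = (int)std::lround((by[p] + ty_mm[jt]) / pixel_mm + cy);
          if (col < 0) col = 0; else if (col >= nc) col = nc - 1;
          if (row < 0) row = 0; else if (row >= nr) row = nr - 1;
          acc += D(row, col);
        }
        out[ir + nrot * (it + (R_xlen_t)ntx * jt)] = acc / idx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nrot, ntx, nty);
  return out;
}
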