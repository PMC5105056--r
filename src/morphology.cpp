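#include <Rcpp.h>
using namespace Rcpp;

// Grayscale max-plus dilation: out(x) = max_u [ S(x+u) + T(u) ],
// u ranging over the tip grid relative to its apex (ai, aj), truncated to
// in-grid offsets near the border.
// [[Rcpp::export]]
NumericMatrix dilate_cpp(NumericMatrix S, NumericMatrix T, int ai, int aj) {
  const int nr = S.nrow(), nc = S.ncol();
  const int tr = T.nrow(), tc = T.ncol();
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nr; ++x) {
    for (int y = 0; y < nc; ++y) {
      double m = R_NegInf;
      for (int i = 0; i < tr; ++i) {
        const int xs = x + i - ai;
        if (xs < 0 || xs >= nr) continue;
        for (int j = 0; j < tc; ++j) {
          const int ys = y + j - aj;
          if (ys < 0 || ys >= nc) continue;
          const double v = S(xs, ys) + T(i, j);
          if (v > m) m = v;
        }
      }
      out(x, y) = m;
    }
  }
  return out;
}

// Adjoint min-plus erosion: out(x) = min_u [ I(x-u) - T(u) ].
// [[Rcpp::export]]
NumericMatrix erode_cpp(NumericMatrix I, NumericMatrix T, int ai, int aj) {
  const int nr = I.nrow(), nc = I.ncol();
  const int tr = T.nrow(), tc = T.ncol();
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nr; ++x) {
    for (int y = 0; y < nc; ++y) {
      double m = R_PosInf;
      for (int i = 0; i < tr; ++i) {
        const int xs = x - (i - ai);
        if (xs < 0 || xs >= nr) continue;
        for (int j = 0; j < tc; ++j) {
          const int ys = y - (j - aj);
          if (ys < 0 || ys >= nc) continue;
          const double v = I(xs, ys) - T(i, j);
          if (v < m) m = v;
        }
      }
      out(x, y) = m;
    }
  }
  return out;
}

// Blind tip reconstruction (iterative outer-bound refinement).
//
// Imaging model: I(x) = max_u [S(x+u) + T(u)]. For the (unknown) contact
// offset v at image pixel x, every tip pixel p obeys
//   T(p) <= T(v) + I(x+v-p) - I(x).
// A candidate v is admissible only if it satisfies the apex constraint
//   T(v) >= I(x) - I(x+v)  (within the noise threshold);
// without this filter the relaxation stalls at the flat tip.
// The estimate starts flat (0) and is carved down in sweeps until no pixel
// moves by more than tol.
// [[Rcpp::export]]
NumericMatrix btr_cpp(NumericMatrix I, int trow, int tcol, double thr,
                      double tol, int max_iter) {
  const int nr = I.nrow(), nc = I.ncol();
  const int wr = trow / 2, wc = tcol / 2;     // half widths, grids odd
  NumericMatrix T(trow, tcol);                // zero-initialized (flat tip)
  std::vector<unsigned char> feas(trow * tcol);

  for (int iter = 0; iter < max_iter; ++iter) {
    double max_change = 0.0;
    for (int x = wr; x < nr - wr; ++x) {
      for (int y = wc; y < nc - wc; ++y) {
        const double Ix = I(x, y);
        // cheap prune: the v = 0 (apex-contact) term lower-bounds every
        // bound; if it cannot tighten any tip pixel, nothing here can.
        bool useful = false;
        for (int pi = 0; pi < trow && !useful; ++pi)
          for (int pj = 0; pj < tcol; ++pj) {
            const int xs = x - (pi - wr), ys = y - (pj - wc);
            if (I(xs, ys) - Ix + thr < T(pi, pj)) { useful = true; break; }
          }
        if (!useful) continue;

        // admissible contact offsets; the 1e-7 nm grace keeps contacts that
        // sit exactly on the feasibility boundary (ubiquitous in noiseless
        // morphology) from being dropped through float rounding, which
        // would break the outer-bound guarantee
        for (int vi = 0; vi < trow; ++vi)
          for (int vj = 0; vj < tcol; ++vj) {
            const int xv = x + vi - wr, yv = y + vj - wc;
            feas[vi * tcol + vj] =
              (T(vi, vj) >= Ix - I(xv, yv) - thr - 1e-7) ? 1 : 0;
          }

        for (int pi = 0; pi < trow; ++pi) {
          for (int pj = 0; pj < tcol; ++pj) {
            double bound = R_NegInf;
            bool ok = true;
            for (int vi = 0; vi < trow && ok; ++vi) {
              const int xs0 = x + vi - wr - (pi - wr);
              if (xs0 < 0 || xs0 >= nr) {
                // an admissible contact may exist in this row; check
                for (int vj = 0; vj < tcol; ++vj)
                  if (feas[vi * tcol + vj]) { ok = false; break; }
                continue;
              }
              for (int vj = 0; vj < tcol; ++vj) {
                if (!feas[vi * tcol + vj]) continue;
                const int ys0 = y + vj - wc - (pj - wc);
                if (ys0 < 0 || ys0 >= nc) { ok = false; break; }
                const double b = T(vi, vj) + I(xs0, ys0) - Ix + thr;
                if (b > bound) bound = b;
              }
            }
            if (ok && bound < T(pi, pj)) {
              const double ch = T(pi, pj) - bound;
              if (ch > max_change) max_change = ch;
              T(pi, pj) = bound;
            }
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
    if (max_change <= tol) break;
  }
  return T;
}
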