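// Batched separable Gabor response engine.
//
// The complex separable kernel v[u] = g[u] exp(i w u) is factored into
// diagonal phase terms around a real Gaussian band matrix, so each pass is a
// real matrix product: row pass  D3 Cg (D4 .* P), column pass analogous.
// Orientations 45/135 share |wy| and hence a row pass; orientation 0 shares
// its real row pass with the DC-correction Gaussian blur.  Results are
// identical (to rounding) to direct 2-D convolution with the zero-mean
// complex kernel under symmetric padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static uvec mirror_index0(int n, int k) {
  // 0-based symmetric (edge-repeating) padding indices, length n + 2k
  uvec idx(n + 2 * k);
  for (int i = 0; i < k; ++i) idx[i] = (unsigned)(k - 1 - i);
  for (int i = 0; i < n; ++i) idx[k + i] = (unsigned)i;
  for (int i = 0; i < k; ++i) idx[k + n + i] = (unsigned)(n - 1 - i);
  return idx;
}

static mat band_matrix(int n, const vec& g) {
  int w = g.n_elem;            // 2k + 1
  mat C(n, n + w - 1, fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < w; ++j) C(i, i + j) = g[j];
  return C;
}

// transpose each (n x p2) slice of M (n x p2*nb) into T (p2 x n*nb)
static void slice_transpose(const mat& M, mat& T, int n, int p2, int nb) {
  for (int b = 0; b < nb; ++b)
    T.cols(b * n, b * n + n - 1) = M.cols(b * p2, b * p2 + p2 - 1).t();
}

// [[Rcpp::export]]
arma::mat gabor_scale_cpp(const arma::cube& imgs, const arma::mat& maskt,
                          const arma::vec& msums, const arma::vec& g,
                          const arma::vec& wxs, const arma::vec& wys,
                          const arma::vec& dc_re, const arma::vec& dc_im,
                          double norm0) {
  const int n = imgs.n_rows, m = imgs.n_cols, nb = imgs.n_slices;
  const int k = ((int)g.n_elem - 1) / 2;
  const int p1 = n + 2 * k, p2 = m + 2 * k;
  const int no = wxs.n_elem;

  uvec ridx = mirror_index0(n, k), cidx = mirror_index0(m, k);
  mat pp(p1, p2 * nb);
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < p2; ++c) {
      const double* src = imgs.slice_colptr(b, cidx[c]);
      double* dst = pp.colptr(b * p2 + c);
      for (int r = 0; r < p1; ++r) dst[r] = src[ridx[r]];
    }

  mat Cgr = band_matrix(n, g), Cgc = band_matrix(m, g);

  // row passes, one per distinct |input phase| (wy value)
  std::vector<double> uw;            // distinct wy values
  std::vector<int> which_w(no);
  for (int o = 0; o < no; ++o) {
    int hit = -1;
    for (size_t q = 0; q < uw.size(); ++q)
      if (std::abs(uw[q] - wys[o]) < 1e-12) { hit = (int)q; break; }
    if (hit < 0) { uw.push_back(wys[o]); hit = (int)uw.size() - 1; }
    which_w[o] = hit;
  }
  int zero_at = -1;
  for (size_t q = 0; q < uw.size(); ++q)
    if (std::abs(uw[q]) < 1e-12) zero_at = (int)q;
  if (zero_at < 0) { uw.push_back(0.0); zero_at = (int)uw.size() - 1; }

  std::vector<mat> Mre(uw.size()), Mim(uw.size());
  mat buf(p1, p2 * nb);
  for (size_t q = 0; q < uw.size(); ++q) {
    double wy = uw[q];
    if (std::abs(wy) < 1e-12) {
      Mre[q] = Cgr * pp;
      Mim[q].reset();
      continue;
    }
    vec cr(p1), sr(p1);
    for (int r = 0; r < p1; ++r) {
      cr[r] = std::cos(-wy * (r + 1));
      sr[r] = std::sin(-wy * (r + 1));
    }
    buf = pp;  buf.each_col() %= cr;
    mat A = Cgr * buf;
    buf = pp;  buf.each_col() %= sr;
    mat B = Cgr * buf;
    // output-row phase e^{i wy (i + k)}, rows are 1-based + pad offset k
    vec co(n), si(n);
    for (int i = 0; i < n; ++i) {
      co[i] = std::cos(wy * (i + 1 + k));
      si[i] = std::sin(wy * (i + 1 + k));
    }
    Mre[q] = A;  Mre[q].each_col() %= co;
    Mim[q] = B;  Mim[q].each_col() %= co;
    { mat t1 = B; t1.each_col() %= si; Mre[q] -= t1; }
    { mat t2 = A; t2.each_col() %= si; Mim[q] += t2; }
  }

  // DC-correction blur (transposed layout), from the wy = 0 row pass
  mat T0(p2, n * nb), gb;
  slice_transpose(Mre[zero_at], T0, n, p2, nb);
  gb = Cgc * T0;                       // m x n*nb

  mat feats(nb, no);
  mat Are(n, p2 * nb), Aim(n, p2 * nb), Tre(p2, n * nb), Tim(p2, n * nb);
  for (int o = 0; o < no; ++o) {
    const mat& R = Mre[which_w[o]];
    const bool has_im = Mim[which_w[o]].n_elem > 0;
    const double wx = wxs[o];
    // input-column phase e^{i wx r}, r = 1..p2 within each slice block
    vec cc(p2), sc(p2);
    for (int r = 0; r < p2; ++r) {
      cc[r] = std::cos(wx * (r + 1));
      sc[r] = std::sin(wx * (r + 1));
    }
    for (int b = 0; b < nb; ++b)
      for (int c = 0; c < p2; ++c) {
        int gc = b * p2 + c;
        const double* rr = R.colptr(gc);
        double* ar = Are.colptr(gc);
        double* ai = Aim.colptr(gc);
        if (has_im) {
          const double* ri = Mim[which_w[o]].colptr(gc);
          for (int i = 0; i < n; ++i) {
            ar[i] = rr[i] * cc[c] - ri[i] * sc[c];
            ai[i] = rr[i] * sc[c] + ri[i] * cc[c];
          }
        } else {
          for (int i = 0; i < n; ++i) {
            ar[i] = rr[i] * cc[c];
            ai[i] = rr[i] * sc[c];
          }
        }
      }
    slice_transpose(Are, Tre, n, p2, nb);
    slice_transpose(Aim, Tim, n, p2, nb);
    mat Ore = Cgc * Tre;              // m x n*nb
    mat Oim = Cgc * Tim;
    // output-column phase e^{-i wx (j + k)} and DC subtraction, fused with
    // the magnitude/mask reduction
    vec cj(m), sj(m);
    for (int j = 0; j < m; ++j) {
      cj[j] = std::cos(-wx * (j + 1 + k));
      sj[j] = std::sin(-wx * (j + 1 + k));
    }
    const double dre = dc_re[o], dim = dc_im[o];
    for (int b = 0; b < nb; ++b) {
      const double* mk = maskt.colptr(b);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* pr = Ore.colptr(b * n + i);
        const double* pi = Oim.colptr(b * n + i);
        const double* pg = gb.colptr(b * n + i);
        const double* pm = mk + (size_t)i * m;
        for (int j = 0; j < m; ++j) {
          double re = pr[j] * cj[j] - pi[j] * sj[j] - dre * pg[j];
          double im = pr[j] * sj[j] + pi[j] * cj[j] - dim * pg[j];
          acc += pm[j] * std::sqrt(re * re + im * im);
        }
      }
      feats(b, o) = norm0 * acc / msums[b];
    }
  }
  return feats;
}

// batched separable real correlation with symmetric padding:
// out[i,j,b] = sum_{a,c} vy[a] vx[c] x[i+a, j+c, b] (mirror-extended)
// [[Rcpp::export]]
arma::cube sepconv2_batch_cpp(const arma::cube& imgs, const arma::vec& vy,
                              const arma::vec& vx) {
  const int n = imgs.n_rows, m = imgs.n_cols, nb = imgs.n_slices;
  const int ky = ((int)vy.n_elem - 1) / 2, kx = ((int)vx.n_elem - 1) / 2;
  const int p1 = n + 2 * ky, p2 = m + 2 * kx;
  uvec ridx = mirror_index0(n, ky), cidx = mirror_index0(m, kx);
  mat pp(p1, p2 * nb);
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < p2; ++c) {
      const double* src = imgs.slice_colptr(b, cidx[c]);
      double* dst = pp.colptr(b * p2 + c);
      for (int r = 0; r < p1; ++r) dst[r] = src[ridx[r]];
    }
  mat Cr = band_matrix(n, vy), Cc = band_matrix(m, vx);
  mat mid = Cr * pp;                  // n x p2*nb
  mat T(p2, n * nb);
  slice_transpose(mid, T, n, p2, nb);
  mat out_t = Cc * T;                 // m x n*nb (transposed slices)
  cube out(n, m, nb);
  for (int b = 0; b < nb; ++b)
    out.slice(b) = out_t.cols(b * n, b * n + n - 1).t();
  return out;
}
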