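// Spectral-convolution kernels for the Fourier neural operator.
//
// The retained-mode transforms are dense complex matrix products
// (E v E^T with E the DFT matrix restricted to the kept frequencies),
// batched over all channel/batch slices so each direction is two large
// GEMMs plus a cheap per-slice transpose. Mode mixing is an elementwise
// complex contraction over channels. The R-level finite-difference tests
// verify the gradients of these kernels end to end.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Batched restricted 2-D transform: for each of K slices (M x M),
// out.slice(k) = E * in.slice(k) * strans(E), giving (r, r, K).
static cx_cube fwd_transform_batched(const cx_mat &E, const double *vmem,
                                     uword M, uword K) {
  const uword r = E.n_rows;
  const mat vm(const_cast<double *>(vmem), M, M * K, false, true);
  // real input: two real GEMMs beat one complex GEMM
  cx_mat y1(real(E) * vm, imag(E) * vm);  // (r, M*K), [a, (y, k)]
  cx_cube y1c(y1.memptr(), r, M, K, false, true);
  cx_cube a1(M, r, K);
  for (uword k = 0; k < K; ++k) a1.slice(k) = strans(y1c.slice(k));
  cx_mat a1m(a1.memptr(), M, r * K, false, true);
  cx_mat y2 = E * a1m;                // (r, r*K), [b, (a, k)]
  cx_cube y2c(y2.memptr(), r, r, K, false, true);
  cx_cube out(r, r, K);
  for (uword k = 0; k < K; ++k) out.slice(k) = strans(y2c.slice(k));
  return out;
}

// Batched inverse: out.slice(k) = real(D * S.slice(k) * strans(D)) with
// D = trans(E) (M x r), written into omem (M, M, K).
static void inv_transform_batched(const cx_mat &E, const cx_cube &S,
                                  double *omem, double scale) {
  const uword r = E.n_rows, M = E.n_cols, K = S.n_slices;
  cx_mat D = trans(E);                // M x r (conjugate transpose)
  cx_mat Sm(const_cast<cx_double *>(S.memptr()), r, r * K, false, true);
  cx_mat o1 = D * Sm;                 // (M, r*K), [x, (b, k)]
  cx_cube o1c(o1.memptr(), M, r, K, false, true);
  cx_cube a1(r, M, K);
  for (uword k = 0; k < K; ++k) a1.slice(k) = strans(o1c.slice(k));
  cx_mat a1m(a1.memptr(), r, M * K, false, true);
  cx_mat o2 = D * a1m;                // (M, M*K), [y, (x, k)]
  cx_cube o2c(o2.memptr(), M, M, K, false, true);
  cube out(omem, M, M, K, false, true);
  for (uword k = 0; k < K; ++k)
    out.slice(k) = trans(real(o2c.slice(k))) * scale;
}

// Forward spectral convolution on a (M, M, B, C) state.
// E: r x M restricted DFT matrix. Wre/Wim: (r, r, C, Cout) mode weights.
// Returns out (M, M, B, Cout) and the cached input modes Vb (r, r, B*C).
// [[Rcpp::export]]
Rcpp::List cpp_spectral_forward(Rcpp::NumericVector v_,
                                Rcpp::ComplexMatrix E_,
                                Rcpp::NumericVector Wre_,
                                Rcpp::NumericVector Wim_,
                                int M, int B, int C, int Cout) {
  cx_mat E(reinterpret_cast<cx_double *>(E_.begin()), E_.nrow(), E_.ncol(),
           false, true);
  const uword r = E.n_rows, r2 = r * r;
  cx_cube Vb = fwd_transform_batched(E, v_.begin(), (uword)M,
                                     (uword)B * C);
  cube Wre(Wre_.begin(), r, r, (uword)C * Cout, false, true);
  cube Wim(Wim_.begin(), r, r, (uword)C * Cout, false, true);

  // S[(m,b), o] = sum_i W[m, i, o] * Vb[(m,b), i]
  cx_cube S(r, r, (uword)B * Cout, fill::zeros);
  for (int o = 0; o < Cout; ++o) {
    cx_mat So(S.slice_memptr((uword)o * B), r2, (uword)B, false, true);
    for (int i = 0; i < C; ++i) {
      cx_vec w = cx_vec(vectorise(Wre.slice((uword)o * C + i)),
                        vectorise(Wim.slice((uword)o * C + i)));
      cx_mat Vi(Vb.slice_memptr((uword)i * B), r2, (uword)B, false, true);
      So += Vi.each_col() % w;
    }
  }

  Rcpp::NumericVector out_((R_xlen_t)M * M * B * Cout);
  inv_transform_batched(E, S, out_.begin(), 1.0 / ((double)M * M));
  out_.attr("dim") = Rcpp::IntegerVector::create(M, M, B, Cout);
  Rcpp::ComplexVector Vb_((R_xlen_t)r2 * B * C);
  std::memcpy(Vb_.begin(), Vb.memptr(), sizeof(cx_double) * Vb.n_elem);
  Vb_.attr("dim") = Rcpp::IntegerVector::create(r, r, B * C);
  return Rcpp::List::create(Rcpp::Named("out") = out_,
                            Rcpp::Named("Vb") = Vb_);
}

// Backward of the spectral convolution. G is the loss gradient w.r.t.
// the (M, M, B, Cout) output; returns dv, dWre, dWim.
// [[Rcpp::export]]
Rcpp::List cpp_spectral_backward(Rcpp::NumericVector G_,
                                 Rcpp::ComplexVector Vb_,
                                 Rcpp::ComplexMatrix E_,
                                 Rcpp::NumericVector Wre_,
                                 Rcpp::NumericVector Wim_,
                                 int M, int B, int C, int Cout) {
  cx_mat E(reinterpret_cast<cx_double *>(E_.begin()), E_.nrow(), E_.ncol(),
           false, true);
  const uword r = E.n_rows, r2 = r * r;
  cx_cube Vb(reinterpret_cast<cx_double *>(Vb_.begin()), r, r,
             (uword)B * C, false, true);
  cube Wre(Wre_.begin(), r, r, (uword)C * Cout, false, true);
  cube Wim(Wim_.begin(), r, r, (uword)C * Cout, false, true);

  // modes of the output gradient, conjugate-packed (dRe + i dIm)
  cx_cube gS = fwd_transform_batched(E, G_.begin(), (uword)M,
                                     (uword)B * Cout);
  gS /= (double)M * M;

  Rcpp::NumericVector dWre_((R_xlen_t)r2 * C * Cout);
  Rcpp::NumericVector dWim_((R_xlen_t)r2 * C * Cout);
  cube dWre(dWre_.begin(), r, r, (uword)C * Cout, false, true);
  cube dWim(dWim_.begin(), r, r, (uword)C * Cout, false, true);
  cx_cube gV(r, r, (uword)B * C, fill::zeros);
  for (int o = 0; o < Cout; ++o) {
    cx_mat gSo(gS.slice_memptr((uword)o * B), r2, (uword)B, false, true);
    for (int i = 0; i < C; ++i) {
      cx_mat Vi(Vb.slice_memptr((uword)i * B), r2, (uword)B, false, true);
      cx_vec gw = sum(conj(Vi) % gSo, 1);
      dWre.slice((uword)o * C + i) = reshape(real(gw), r, r);
      dWim.slice((uword)o * C + i) = reshape(imag(gw), r, r);
      cx_vec wc = conj(cx_vec(vectorise(Wre.slice((uword)o * C + i)),
                              vectorise(Wim.slice((uword)o * C + i))));
      cx_mat gVi(gV.slice_memptr((uword)i * B), r2, (uword)B, false, true);
      gVi += gSo.each_col() % wc;
    }
  }

  Rcpp::NumericVector dv_((R_xlen_t)M * M * B * C);
  inv_transform_batched(E, gV, dv_.begin(), 1.0);
  dv_.attr("dim") = Rcpp::IntegerVector::create(M, M, B, C);
  Rcpp::IntegerVector wd = Rcpp::IntegerVector::create(r, r, C, Cout);
  dWre_.attr("dim") = wd;
  dWim_.attr("dim") = wd;
  return Rcpp::List::create(Rcpp::Named("dv") = dv_,
                            Rcpp::Named("dWre") = dWre_,
                            Rcpp::Named("dWim") = dWim_);
}

// ---------------------------------------------------------------------
// Fused FNO training step: forward pass, MSE loss, and full backward
// pass in one call, so intermediate states never leave C++. All complex
// arithmetic is carried split into real/imaginary parts: real GEMMs (and
// a 3-multiplication complex product) replace complex GEMMs, and the
// mode mixing runs as plain fused loops.
// Layer n: v_{n+1} = sigmoid(SpectralConv_n(v_n) + v_n W_n + b_n).

namespace {

struct SplitDFT {
  mat Er, Ei, Es;          // E, and Er + Ei for the 3-mult product
  mat Dr, Di, Ds;          // D = trans(E) (conjugate transpose)
  uword r, M;
};

SplitDFT make_split(const cx_mat &E) {
  SplitDFT d;
  d.Er = real(E); d.Ei = imag(E); d.Es = d.Er + d.Ei;
  d.Dr = d.Er.t(); d.Di = -d.Ei.t(); d.Ds = d.Dr + d.Di;
  d.r = E.n_rows; d.M = E.n_cols;
  return d;
}

// transpose each (r x c) slice of src (r, c, K) into dst (c, r, K)
void tr_slices(const mat &src, uword rr, uword cc, uword K, mat &dst) {
  dst.set_size(cc, rr * K);
  for (uword k = 0; k < K; ++k)
    dst.cols(k * rr, k * rr + rr - 1) =
        src.cols(k * cc, k * cc + cc - 1).t();
}

// Forward restricted transform of K real (M x M) slices ->
// re/im (r, r*K) with slice layout [a, (b, k)].
void sp_fwd(const SplitDFT &d, const double *vmem, uword K, mat &outr,
            mat &outi) {
  const mat vm(const_cast<double *>(vmem), d.M, d.M * K, false, true);
  mat y1r = d.Er * vm, y1i = d.Ei * vm;      // [a, (y, k)]
  mat a1r, a1i;                              // [y, (a, k)]
  tr_slices(y1r, d.r, d.M, K, a1r);
  tr_slices(y1i, d.r, d.M, K, a1i);
  // (Er + iEi)(a1r + ia1i) via 3 real products
  mat P1 = d.Er * a1r, P2 = d.Ei * a1i, P3 = d.Es * (a1r + a1i);
  mat y2r = P1 - P2, y2i = P3 - P1 - P2;     // [b, (a, k)]
  tr_slices(y2r, d.r, d.r, K, outr);         // [a, (b, k)]
  tr_slices(y2i, d.r, d.r, K, outi);
  outr.reshape(d.r * d.r, K);                // mode-major (r^2, K) view
  outi.reshape(d.r * d.r, K);
}

// Inverse restricted transform: real part of D S strans(D) for K slices,
// written to omem (M, M, K). S given as re/im (r, r*K).
void sp_inv(const SplitDFT &d, const mat &Sr, const mat &Si, uword K,
            double *omem, double scale) {
  const mat Srv(const_cast<double *>(Sr.memptr()), d.r, d.r * K, false,
                true);
  const mat Siv(const_cast<double *>(Si.memptr()), d.r, d.r * K, false,
                true);
  mat P1 = d.Dr * Srv, P2 = d.Di * Siv, P3 = d.Ds * (Srv + Siv);
  mat o1r = P1 - P2, o1i = P3 - P1 - P2;     // [x, (b, k)]
  mat a1r, a1i;                              // [b, (x, k)]
  tr_slices(o1r, d.M, d.r, K, a1r);
  tr_slices(o1i, d.M, d.r, K, a1i);
  mat o2 = d.Dr * a1r - d.Di * a1i;          // real part, [y, (x, k)]
  mat out(omem, d.M, d.M * K, false, true);
  tr_slices(o2, d.M, d.M, K, out);
  if (scale != 1.0) out *= scale;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_fno_step(Rcpp::NumericVector x_, Rcpp::NumericVector y_,
                        Rcpp::ComplexMatrix E_, Rcpp::List params,
                        int M, int B, int Tin, int H, int L, int W) {
  cx_mat E(reinterpret_cast<cx_double *>(E_.begin()), E_.nrow(), E_.ncol(),
           false, true);
  SplitDFT D = make_split(E);
  const uword r = D.r, r2 = r * r;
  const uword n = (uword)M * M * B;
  const uword K = (uword)B * W;
  mat X(x_.begin(), n, (uword)Tin, false, true);
  mat Y(y_.begin(), n, (uword)H, false, true);

  auto getM = [&](std::string nm) {
    Rcpp::NumericMatrix m = params[nm];
    return mat(m.begin(), m.nrow(), m.ncol(), false, true);
  };
  auto getV = [&](std::string nm) {
    Rcpp::NumericVector v = params[nm];
    return vec(v.begin(), v.size(), false, true);
  };
  auto getW = [&](std::string nm) {
    Rcpp::NumericVector v = params[nm];
    return mat(v.begin(), r2, (uword)W * W, false, true);
  };
  auto nm = [](const char *base, int k) {
    return std::string(base) + std::to_string(k + 1);
  };

  // mixing: S[, (o,b)] = sum_i W[(i,o)] * V[, (i,b)], complex, where V
  // columns are (r2 x B) blocks per channel and W columns are r2 modes
  auto mix = [&](const mat &Wr, const mat &Wi, const mat &Vr,
                 const mat &Vi, mat &Sr, mat &Si, bool conj_w) {
    Sr.zeros(r2, K); Si.zeros(r2, K);
    const double sgn = conj_w ? -1.0 : 1.0;
    for (int o = 0; o < W; ++o)
      for (int i = 0; i < W; ++i) {
        const double *wr = Wr.colptr((uword)o * W + i);
        const double *wi = Wi.colptr((uword)o * W + i);
        for (int b = 0; b < B; ++b) {
          const double *vr = Vr.colptr((uword)i * B + b);
          const double *vi = Vi.colptr((uword)i * B + b);
          double *sr = Sr.colptr((uword)o * B + b);
          double *si = Si.colptr((uword)o * B + b);
          for (uword m = 0; m < r2; ++m) {
            sr[m] += wr[m] * vr[m] - sgn * wi[m] * vi[m];
            si[m] += sgn * wi[m] * vr[m] + wr[m] * vi[m];
          }
        }
      }
  };

  mat lift_W = getM("lift_W");
  mat proj_W = getM("proj_W");

  // forward
  std::vector<mat> v_in(L), act(L), VbrL(L), VbiL(L);
  mat v = X * lift_W;
  v.each_row() += getV("lift_b").t();
  mat Sr, Si, spec(n, (uword)W);
  for (int l = 0; l < L; ++l) {
    v_in[l] = v;
    sp_fwd(D, v.memptr(), K, VbrL[l], VbiL[l]);
    mix(getW(nm("spec_re_", l)), getW(nm("spec_im_", l)), VbrL[l], VbiL[l],
        Sr, Si, false);
    sp_inv(D, Sr, Si, K, spec.memptr(), 1.0 / ((double)M * M));
    mat z = spec + v * getM(nm("pw_W_", l));
    z.each_row() += getV(nm("pw_b_", l)).t();
    act[l] = 1.0 / (1.0 + exp(-z));
    v = act[l];
  }
  mat out = v * proj_W;
  out.each_row() += getV("proj_b").t();

  // loss and its gradient
  mat diff = out - Y;
  double loss = accu(square(diff)) / diff.n_elem;
  mat dout = diff * (2.0 / diff.n_elem);

  Rcpp::List grads;
  grads["proj_W"] = Rcpp::wrap(mat(v.t() * dout));
  grads["proj_b"] = Rcpp::wrap(vec(sum(dout, 0).t()));
  mat dv = dout * proj_W.t();
  mat gSr, gSi, gVr, gVi, dspec(n, (uword)W);
  for (int l = L - 1; l >= 0; --l) {
    mat dz = dv % act[l] % (1.0 - act[l]);
    // modes of dz, conjugate-packed: (dRe + i dIm) = conj-free transform
    sp_fwd(D, dz.memptr(), K, gSr, gSi);
    const double sc = 1.0 / ((double)M * M);
    gSr *= sc; gSi *= sc;
    // dW[(i,o)] = sum_b Conj(Vb[, (i,b)]) .* gS[, (o,b)]
    Rcpp::NumericVector dWre_((R_xlen_t)r2 * W * W);
    Rcpp::NumericVector dWim_((R_xlen_t)r2 * W * W);
    mat dWre(dWre_.begin(), r2, (uword)W * W, false, true);
    mat dWim(dWim_.begin(), r2, (uword)W * W, false, true);
    const mat &Vr = VbrL[l], &Vi = VbiL[l];
    for (int o = 0; o < W; ++o)
      for (int i = 0; i < W; ++i) {
        double *gr = dWre.colptr((uword)o * W + i);
        double *gi = dWim.colptr((uword)o * W + i);
        for (int b = 0; b < B; ++b) {
          const double *vr = Vr.colptr((uword)i * B + b);
          const double *vi = Vi.colptr((uword)i * B + b);
          const double *sr = gSr.colptr((uword)o * B + b);
          const double *si = gSi.colptr((uword)o * B + b);
          for (uword m = 0; m < r2; ++m) {
            gr[m] += vr[m] * sr[m] + vi[m] * si[m];
            gi[m] += vr[m] * si[m] - vi[m] * sr[m];
          }
        }
      }
    Rcpp::IntegerVector wd = Rcpp::IntegerVector::create(r, r, W, W);
    dWre_.attr("dim") = wd;
    dWim_.attr("dim") = wd;
    grads[nm("spec_re_", l)] = dWre_;
    grads[nm("spec_im_", l)] = dWim_;
    // gV[, (i,b)] = sum_o Conj(W[(i,o)]) .* gS[, (o,b)]  (note transposed
    // channel roles: accumulate over o into channel i)
    gVr.zeros(r2, K); gVi.zeros(r2, K);
    const mat Wr = getW(nm("spec_re_", l)), Wi = getW(nm("spec_im_", l));
    for (int o = 0; o < W; ++o)
      for (int i = 0; i < W; ++i) {
        const double *wr = Wr.colptr((uword)o * W + i);
        const double *wi = Wi.colptr((uword)o * W + i);
        for (int b = 0; b < B; ++b) {
          const double *sr = gSr.colptr((uword)o * B + b);
          const double *si = gSi.colptr((uword)o * B + b);
          double *vr = gVr.colptr((uword)i * B + b);
          double *vi = gVi.colptr((uword)i * B + b);
          for (uword m = 0; m < r2; ++m) {
            vr[m] += wr[m] * sr[m] + wi[m] * si[m];
            vi[m] += wr[m] * si[m] - wi[m] * sr[m];
          }
        }
      }
    sp_inv(D, gVr, gVi, K, dspec.memptr(), 1.0);
    grads[nm("pw_W_", l)] = Rcpp::wrap(mat(v_in[l].t() * dz));
    grads[nm("pw_b_", l)] = Rcpp::wrap(vec(sum(dz, 0).t()));
    dv = dspec + dz * getM(nm("pw_W_", l)).t();
  }
  grads["lift_W"] = Rcpp::wrap(mat(X.t() * dv));
  grads["lift_b"] = Rcpp::wrap(vec(sum(dv, 0).t()));
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
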