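// Hot path of the subspace solver: one application of the normal-equations
// operator  U -> sum_i S_i^H F_y^H (Omega^H Omega) F_y S_i (U V) V^H.
//
// Layout contract (established by the R caller):
//  * voxels are ordered y-fastest with the phase-encode axis already in
//    natural (corner-origin) FFT ordering, so no shifts are needed here;
//  * S is an (ny, nx, nc) cube in the same ordering;
//  * W is the (ny, T) sampling multiplicity in natural ky ordering
//    (Omega^H Omega is diagonal with these counts);
//  * the unnormalised FFTW forward/backward pair contributes a factor ny,
//    which is divided out in the accumulation pass, realising the
//    unitary-FFT normal operator.

#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cx_mat kt_normal_op(const arma::cx_mat& U, const arma::cx_mat& V,
                          const arma::cx_cube& S, const arma::mat& W) {
  const uword ny = S.n_rows, nx = S.n_cols, nc = S.n_slices;
  const uword T = V.n_cols;
  const uword ncols = nx * T;
  cx_mat C = U * V;                    // (ny*nx) x T
  cx_mat G(ny * nx, T, fill::zeros);
  cx_mat work(ny, ncols);

  int n = static_cast<int>(ny);
  fftw_complex* buf = reinterpret_cast<fftw_complex*>(work.memptr());
  fftw_plan fwd = fftw_plan_many_dft(1, &n, static_cast<int>(ncols),
                                     buf, nullptr, 1, n, buf, nullptr, 1, n,
                                     FFTW_FORWARD, FFTW_ESTIMATE);
  fftw_plan bwd = fftw_plan_many_dft(1, &n, static_cast<int>(ncols),
                                     buf, nullptr, 1, n, buf, nullptr, 1, n,
                                     FFTW_BACKWARD, FFTW_ESTIMATE);
  const double inv_ny = 1.0 / static_cast<double>(ny);
  const std::complex<double>* cptr = C.memptr();
  std::complex<double>* wptr = work.memptr();
  std::complex<double>* gptr = G.memptr();
  const double* wgt = W.memptr();

  for (uword i = 0; i < nc; ++i) {
    const std::complex<double>* sptr = S.slice_memptr(i);
    // work = C .* S_i (S_i broadcast along T)
    for (uword t = 0; t < T; ++t) {
      const std::complex<double>* cs = cptr + t * ny * nx;
      std::complex<double>* ws = wptr + t * ny * nx;
      for (uword j = 0; j < ny * nx; ++j) ws[j] = cs[j] * sptr[j];
    }
    fftw_execute(fwd);
    // mask by the per-(ky, frame) sampling multiplicity
    for (uword t = 0; t < T; ++t) {
      const double* wc = wgt + t * ny;
      std::complex<double>* ws = wptr + t * ny * nx;
      for (uword x = 0; x < nx; ++x) {
        std::complex<double>* col = ws + x * ny;
        for (uword y = 0; y < ny; ++y) col[y] *= wc[y];
      }
    }
    fftw_execute(bwd);
    // G += work .* conj(S_i) / ny
    for (uword t = 0; t < T; ++t) {
      std::complex<double>* ws = wptr + t * ny * nx;
      std::complex<double>* gs = gptr + t * ny * nx;
      for (uword j = 0; j < ny * nx; ++j) {
        gs[j] += ws[j] * std::conj(sptr[j]) * inv_ny;
      }
    }
  }
  fftw_destroy_plan(fwd);
  fftw_destroy_plan(bwd);
  return G * V.t();                    // .t() is the conjugate transpose
}
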