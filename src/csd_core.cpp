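#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Predicted cross-spectral densities of the linearized network.
//
// For each frequency f the transfer function is obtained by a direct
// resolvent solve, T(f) = C (2*pi*i*f I - J)^{-1} B, and the sensor-level
// spectrum assembled as G(f) = L T diag(gu(f)) T^H L^H + Gn(f).
//
// J   : n x n real state Jacobian
// B   : n x s innovation input map
// C   : s x n pyramidal read-out
// L   : m x s lead field (modes x sources)
// freqs : frequencies in Hz
// gu  : s x nf innovation spectral densities (>= 0)
// Gn  : m x m x nf real observation-noise spectra
//
// Returns an m x m x nf complex cube, Hermitian-symmetrized per bin.
// [[Rcpp::export]]
arma::cx_cube csd_predict_core(const arma::mat& J, const arma::mat& B,
                               const arma::mat& C, const arma::mat& L,
                               const arma::vec& freqs, const arma::mat& gu,
                               const arma::cube& Gn) {
  const uword n = J.n_rows;
  const uword m = L.n_rows;
  const uword nf = freqs.n_elem;

  cx_mat Jc = conv_to<cx_mat>::from(J);
  cx_mat Bc = conv_to<cx_mat>::from(B);
  cx_mat LC = conv_to<cx_mat>::from(L * C);  // m x n read-out incl. lead field

  cx_cube G(m, m, nf);
  cx_mat I = eye<cx_mat>(n, n);

  for (uword k = 0; k < nf; ++k) {
    std::complex<double> iw(0.0, 2.0 * datum::pi * freqs(k));
    cx_mat X;
    bool ok = solve(X, iw * I - Jc, Bc, solve_opts::no_approx);
    if (!ok) {
      Rcpp::stop("singular resolvent at frequency %f Hz", freqs(k));
    }
    cx_mat T = LC * X;  // m x s
    cx_vec guk = conv_to<cx_vec>::from(gu.col(k));
    cx_mat Gy = T * diagmat(guk) * T.t();  // .t() is conjugate transpose
    Gy += conv_to<cx_mat>::from(Gn.slice(k));
    G.slice(k) = 0.5 * (Gy + Gy.t());
  }
  return G;
}

// Predicted cross-spectra together with their exact gradient with respect
// to coupling parameters. Each parameter perturbs the Jacobian sparsely,
// dJ_p given as a triplet matrix (row, col, value; 1-based indices), and
//   d/dp [L C R B] = (L C R) dJ_p (R B),  R = (2*pi*i*f I - J)^{-1},
// so the spectral gradient is dT diag(gu) T^H + T diag(gu) dT^H (projected
// through the lead field, which is folded into T here).
//
// Returns list(G = m x m x nf complex cube,
//              grad = (m*m*nf) x npar complex matrix, columns are the
//              column-major vectorization of each parameter's dG cube).
// [[Rcpp::export]]
Rcpp::List csd_predict_grad(const arma::mat& J, const arma::mat& B,
                            const arma::mat& C, const arma::mat& L,
                            const arma::vec& freqs, const arma::mat& gu,
                            const arma::cube& Gn, const Rcpp::List& dJ) {
  const uword n = J.n_rows;
  const uword m = L.n_rows;
  const uword nf = freqs.n_elem;
  const uword np = dJ.size();

  cx_mat Jc = conv_to<cx_mat>::from(J);
  cx_mat Bc = conv_to<cx_mat>::from(B);
  cx_mat LC = conv_to<cx_mat>::from(L * C);  // m x n

  std::vector<arma::mat> trip(np);
  for (uword p = 0; p < np; ++p) trip[p] = Rcpp::as<arma::mat>(dJ[p]);

  cx_cube G(m, m, nf);
  cx_mat grad(m * m * nf, np);
  cx_mat I = eye<cx_mat>(n, n);

  for (uword k = 0; k < nf; ++k) {
    std::complex<double> iw(0.0, 2.0 * datum::pi * freqs(k));
    cx_mat R;
    bool ok = inv(R, iw * I - Jc);
    if (!ok) Rcpp::stop("singular resolvent at frequency %f Hz", freqs(k));
    cx_mat U = LC * R;        // m x n
    cx_mat W = R * Bc;        // n x s
    cx_mat T = U * Bc;        // m x s  (= L C R B)
    cx_vec guk = conv_to<cx_vec>::from(gu.col(k));
    cx_mat TG = T * diagmat(guk);   // m x s
    cx_mat Gy = TG * T.t();
    Gy += conv_to<cx_mat>::from(Gn.slice(k));
    G.slice(k) = 0.5 * (Gy + Gy.t());

    for (uword p = 0; p < np; ++p) {
      const arma::mat& tp = trip[p];
      cx_mat dT(m, B.n_cols, fill::zeros);
      for (uword t = 0; t < tp.n_rows; ++t) {
        uword i = (uword)tp(t, 0) - 1;
        uword j = (uword)tp(t, 1) - 1;
        dT += tp(t, 2) * (U.col(i) * W.row(j));
      }
      cx_mat dTG = dT * diagmat(guk);
      cx_mat dG = dTG * T.t() + TG * dT.t();
      grad.col(p).subvec(k * m * m, (k + 1) * m * m - 1) = vectorise(dG);
    }
  }
  return Rcpp::List::create(Rcpp::Named("G") = G,
                            Rcpp::Named("grad") = grad);
}
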