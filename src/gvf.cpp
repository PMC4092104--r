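#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Explicit gradient-vector-flow diffusion.
//
// Starting from (u, v) = (fx, fy), iterate
//   u <- u + dt * ( mu * lap(u) - b * (u - fx) )
// and likewise for v, where b = fx^2 + fy^2 and lap() is the 5-point
// Laplacian with reflected (zero-flux) boundaries. dt must respect the
// explicit stability bound dt <= 1/(4*mu).
// [[Rcpp::export]]
List gvf_iterate_cpp(NumericMatrix fx, NumericMatrix fy, double mu,
                     double dt, int n_iter) {
  const int H = fx.nrow(), W = fx.ncol();
  const size_t n = static_cast<size_t>(H) * W;
  std::vector<double> fxv(fx.begin(), fx.end()), fyv(fy.begin(), fy.end());
  std::vector<double> b(n), u(fxv), v(fyv), un(n), vn(n);
  for (size_t k = 0; k < n; ++k) b[k] = fxv[k] * fxv[k] + fyv[k] * fyv[k];

  std::vector<double>* pu = &u;
  std::vector<double>* pv = &v;
  std::vector<double>* pun = &un;
  std::vector<double>* pvn = &vn;
  for (int it = 0; it < n_iter; ++it) {
    const double* cu = pu->data();
    const double* cv = pv->data();
    double* nu = pun->data();
    double* nv = pvn->data();
    for (int j = 0; j < W; ++j) {
      const int jm = j > 0 ? j - 1 : 0, jp = j < W - 1 ? j + 1 : W - 1;
      const size_t o = static_cast<size_t>(j) * H;
      const size_t om = static_cast<size_t>(jm) * H;
      const size_t op = static_cast<size_t>(jp) * H;
      for (int i = 0; i < H; ++i) {
        const int im = i > 0 ? i - 1 : 0, ip = i < H - 1 ? i + 1 : H - 1;
        const size_t k = o + i;
        const double lap_u =
            cu[o + im] + cu[o + ip] + cu[om + i] + cu[op + i] - 4.0 * cu[k];
        const double lap_v =
            cv[o + im] + cv[o + ip] + cv[om + i] + cv[op + i] - 4.0 * cv[k];
        nu[k] = cu[k] + dt * (mu * lap_u - b[k] * (cu[k] - fxv[k]));
        nv[k] = cv[k] + dt * (mu * lap_v - b[k] * (cv[k] - fyv[k]));
      }
    }
    std::swap(pu, pun);
    std::swap(pv, pvn);
  }
  NumericMatrix uo(H, W), vo(H, W);
  std::copy(pu->begin(), pu->end(), uo.begin());
  std::copy(pv->begin(), pv->end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo);
}
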