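#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Jacobi iterations of the Horn-Schunck update for a flow increment
// (du, dv), given image gradients (gi, gj) and the temporal difference it.
// Neighbour average uses the standard 1/6 orthogonal + 1/12 diagonal
// stencil with edge replication. Iterations stop early once the largest
// per-voxel update falls below `tol` (0 disables the check).
// [[Rcpp::export(name = ".hs_iterate")]]
List hs_iterate(NumericMatrix gi, NumericMatrix gj, NumericMatrix it,
                double alpha, int n_iter, double tol = 0.0) {
  const int n1 = gi.nrow(), n2 = gi.ncol();
  const R_xlen_t n = (R_xlen_t)n1 * n2;
  const double *pgi = gi.begin(), *pgj = gj.begin(), *pit = it.begin();
  NumericMatrix du(n1, n2), dv(n1, n2);
  double *pdu = du.begin(), *pdv = dv.begin();
  std::vector<double> dub(n), dvb(n), den(n);
  for (R_xlen_t q = 0; q < n; q++)
    den[q] = alpha * alpha + pgi[q] * pgi[q] + pgj[q] * pgj[q];
  for (int k = 0; k < n_iter; k++) {
    for (int j = 0; j < n2; j++) {
      const R_xlen_t c = (R_xlen_t)j * n1;
      const R_xlen_t cm = (j > 0 ? c - n1 : c);
      const R_xlen_t cp = (j < n2 - 1 ? c + n1 : c);
      for (int i = 0; i < n1; i++) {
        const int im = i > 0 ? i - 1 : 0, ip = i < n1 - 1 ? i + 1 : n1 - 1;
        dub[c + i] =
          (pdu[cm + i] + pdu[cp + i] + pdu[c + im] + pdu[c + ip]) / 6.0 +
          (pdu[cm + im] + pdu[cm + ip] + pdu[cp + im] + pdu[cp + ip]) / 12.0;
        dvb[c + i] =
          (pdv[cm + i] + pdv[cp + i] + pdv[c + im] + pdv[c + ip]) / 6.0 +
          (pdv[cm + im] + pdv[cm + ip] + pdv[cp + im] + pdv[cp + ip]) / 12.0;
      }
    }
    double dmax = 0.0;
    for (R_xlen_t q = 0; q < n; q++) {
      const double t1 =
        (pgi[q] * dub[q] + pgj[q] * dvb[q] + pit[q]) / den[q];
      const double nu = dub[q] - pgi[q] * t1;
      const double nv = dvb[q] - pgj[q] * t1;
      const double d = std::fabs(nu - pdu[q]) + std::fabs(nv - pdv[q]);
      if (d > dmax) dmax = d;
      pdu[q] = nu;
      pdv[q] = nv;
    }
    if (tol > 0.0 && dmax < tol) break;
  }
  return List::create(_["du"] = du, _["dv"] = dv);
}
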