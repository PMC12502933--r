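#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbour in 3D. Reference sets in this package are a
// few tens of thousands of points, where the O(n*m) scan is fast enough and
// has no tree-build overhead or approximation error.
// [[Rcpp::export(name = ".closest_point_idx")]]
IntegerVector closest_point_idx(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0);
    ry[j] = ref(j, 1);
    rz[j] = ref(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        besti = j;
      }
    }
    out[i] = besti + 1;
  }
  return out;
}
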