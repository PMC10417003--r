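#include <Rcpp.h>
using namespace Rcpp;

// Brute-force 3D nearest neighbour: for each row of src find the closest row
// of dst within max_dist (Inf allowed). Returns 1-based indices (0 = none
// within range) and Euclidean distances. Clouds in this pipeline are a few
// thousand points, so O(N*M) beats building a tree.
// [[Rcpp::export(name = ".nn1_cpp")]]
List nn1_cpp(NumericMatrix src, NumericMatrix dst, double max_dist) {
  const int n = src.nrow(), m = dst.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  const double cap2 = R_FINITE(max_dist) ? max_dist * max_dist : R_PosInf;
  const double *s = REAL(src), *d = REAL(dst);   // column-major
  const double *dx0 = d, *dy0 = d + m, *dz0 = d + 2 * m;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    const double x = s[i], y = s[i + n], z = s[i + 2 * n];
    for (int j = 0; j < m; ++j) {
      const double dx = dx0[j] - x, dy = dy0[j] - y, dz = dz0[j] - z;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j + 1; }
    }
    if (best <= cap2) { idx[i] = bi; dist[i] = std::sqrt(best); }
    else              { idx[i] = 0;  dist[i] = R_PosInf; }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// CRC-32 (ISO 3309, as used by PNG chunks) over a raw vector.
// Returned as a double because R has no unsigned 32-bit integer.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xedb88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xffffffffu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xffu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xffffffffu);
}
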