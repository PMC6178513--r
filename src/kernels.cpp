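#include <Rcpp.h>
using namespace Rcpp;

// symmetric (edge-including) reflection of index i into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Local Shannon entropy (bits) of the 256-bin histogram of a w x w window
// centred at each pixel. Input is quantised to 256 levels; borders are
// reflected symmetrically.
// [[Rcpp::export(name = ".local_entropy_cpp")]]
NumericMatrix local_entropy_cpp(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol();
  int h = window / 2;
  NumericMatrix out(nr, nc);
  IntegerMatrix q(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (v < 0) v = 0; if (v > 1) v = 1;
      q(i, j) = (int)(v * 255.0 + 0.5);
    }
  std::vector<int> hist(256, 0);
  std::vector<int> touched; touched.reserve(window * window);
  double inv_n = 1.0 / (double)(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      touched.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int cj = reflect_idx(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          int ci = reflect_idx(i + di, nr);
          int lev = q(ci, cj);
          if (hist[lev] == 0) touched.push_back(lev);
          hist[lev]++;
        }
      }
      double ent = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        double p = hist[touched[t]] * inv_n;
        ent -= p * std::log2(p);
        hist[touched[t]] = 0;
      }
      out(i, j) = ent;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask.
// Labels are 1..K in scan order of each component's first pixel; 0 = background.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
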