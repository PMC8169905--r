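#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary mask to a 1-px skeleton,
// followed by a staircase-removal pass so that 8-connected path tracing
// sees no redundant corner pixels. Border pixels are treated as background.

static inline int at(const std::vector<unsigned char>& m, int i, int j,
                     int nr, int nc) {
  if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
  return m[(size_t)j * nr + i];
}

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> m((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[(size_t)j * nr + i] = mask(i, j) ? 1 : 0;

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!at(m, i, j, nr, nc)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(m, i - 1, j, nr, nc), p3 = at(m, i - 1, j + 1, nr, nc),
              p4 = at(m, i, j + 1, nr, nc), p5 = at(m, i + 1, j + 1, nr, nc),
              p6 = at(m, i + 1, j, nr, nc), p7 = at(m, i + 1, j - 1, nr, nc),
              p8 = at(m, i, j - 1, nr, nc), p9 = at(m, i - 1, j - 1, nr, nc);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((size_t)j * nr + i);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m[kill[k]] = 0;
    }
  }

  // Sequential cleanup to a strict 1-px skeleton: delete any pixel that is
  // 8-simple (Yokoi connectivity number 1) and not a curve endpoint.
  // Removes the redundant corner/staircase pixels Zhang-Suen leaves behind
  // without changing topology or shortening branches.
  bool again = true;
  while (again) {
    again = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!at(m, i, j, nr, nc)) continue;
        // neighbours counter-clockwise from east: x[0]=E, x[1]=NE, ...
        int x[8] = {at(m, i, j + 1, nr, nc),     at(m, i - 1, j + 1, nr, nc),
                    at(m, i - 1, j, nr, nc),     at(m, i - 1, j - 1, nr, nc),
                    at(m, i, j - 1, nr, nc),     at(m, i + 1, j - 1, nr, nc),
                    at(m, i + 1, j, nr, nc),     at(m, i + 1, j + 1, nr, nc)};
        int B = 0;
        for (int k = 0; k < 8; ++k) B += x[k];
        if (B < 2) continue;  // endpoint or isolated: keep
        int C = 0;  // Yokoi number for 8-connectivity (on the complement)
        for (int k = 0; k < 8; k += 2) {
          int a = 1 - x[k], b = 1 - x[(k + 1) % 8], c = 1 - x[(k + 2) % 8];
          C += a - a * b * c;
        }
        if (C == 1) {
          m[(size_t)j * nr + i] = 0;
          again = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[(size_t)j * nr + i] != 0;
  return out;
}
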