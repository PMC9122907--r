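// Binary-mask geometry: 8-connected component labelling in deterministic
// scan order, Moore-neighbour boundary tracing, and enclosed-hole detection.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// neighbour tables; (row, col) with row increasing downwards
static const int DR8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DC8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};  // W NW N NE E SE S SW

// [[Rcpp::export]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int d = 0; d < 8; ++d) {
          const int rr = r + DR8[d], cc = c + DC8[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// 4-connected labelling of the background (mask == 0); used for hole detection
// [[Rcpp::export]]
IntegerMatrix cc_label4_bg(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int DR4[4] = {-1, 1, 0, 0}, DC4[4] = {0, 0, -1, 1};
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) != 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int d = 0; d < 4; ++d) {
          const int rr = r + DR4[d], cc = c + DC4[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) == 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// Moore-neighbour tracing of the outer boundary of the component with the
// given label.  Returns an n x 2 matrix of 0-based (row, col) boundary pixel
// centres, ordered along the boundary, starting at the first pixel in
// row-major scan order.  Termination by Jacob's stopping criterion.
// [[Rcpp::export]]
IntegerMatrix trace_boundary(IntegerMatrix lab, int id) {
  const int H = lab.nrow(), W = lab.ncol();
  int sr = -1, sc = -1;
  for (int i = 0; i < H && sr < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (lab(i, j) == id) { sr = i; sc = j; break; }
  if (sr < 0) stop("label %d not present", id);
  auto fg = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && lab(r, c) == id;
  };
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  int cr = sr, cc = sc;
  int bdir = 0;        // direction (index) from current pixel to its backtrack;
                       // start backtrack is the west neighbour (background by scan order)
  int d0 = -1;         // initial move direction (Jacob's criterion)
  const long maxit = 8L * (long)H * W + 16;
  for (long it = 0; it < maxit; ++it) {
    int found = -1;
    for (int t = 1; t <= 8; ++t) {
      const int d = (bdir + t) % 8;
      if (fg(cr + DR8[d], cc + DC8[d])) { found = d; break; }
    }
    if (found < 0) break;                       // isolated single pixel
    if (cr == sr && cc == sc && d0 >= 0 && found == d0) break;  // closed
    if (d0 < 0) d0 = found;
    const int pd = (found + 7) % 8;             // background neighbour just before
    const int br = cr + DR8[pd], bc = cc + DC8[pd];
    cr += DR8[found]; cc += DC8[found];
    rows.push_back(cr); cols.push_back(cc);
    bdir = 0;
    for (int d = 0; d < 8; ++d)
      if (cr + DR8[d] == br && cc + DC8[d] == bc) { bdir = d; break; }
  }
  // drop the closing revisit of the start pixel, if present
  if (rows.size() > 1 && rows.back() == sr && cols.back() == sc) {
    rows.pop_back(); cols.pop_back();
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// pixel counts per label (index 1..n)
// [[Rcpp::export]]
IntegerVector cc_sizes(IntegerMatrix lab) {
  int n = lab.attr("n");
  IntegerVector sz(n);
  for (int i = 0; i < lab.nrow(); ++i)
    for (int j = 0; j < lab.ncol(); ++j)
      if (lab(i, j) > 0) sz[lab(i, j) - 1]++;
  return sz;
}
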