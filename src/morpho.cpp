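#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8- and 4-neighbourhood offsets (row, col)
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise), 8-connectivity. Hybrid algorithm:
// forward/backward raster sweeps followed by a FIFO queue phase.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) stop("marker must lie below mask pointwise");

  // column-major "previous" neighbours: (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
  static const int PR[4] = {-1, -1, 0, 1};
  static const int PC[4] = {0, -1, -1, -1};
  // "next" neighbours: mirror image
  static const int QR[4] = {1, 1, 0, -1};
  static const int QC[4] = {0, 1, 1, 1};

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + PR[k], cc = c + PC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + QR[k], cc = c + QC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      v = std::min(v, mask(r, c));
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int rr = r + QR[k], cc = c + QC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + nr * c);
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    double v = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < v && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(v, mask(rr, cc));
        fifo.push(rr + nr * cc);
      }
    }
  }
  return J;
}

// Regional maxima of a gray image: 8-connected plateaus with no
// strictly higher neighbour. Returns a 0/1 integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  IntegerMatrix out(nr, nc);
  std::vector<char> visited(n, 0);
  std::vector<int> plateau;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (visited[start]) continue;
    double v = img[start];
    bool is_max = true;
    plateau.clear();
    stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      plateau.push_back(p);
      int r = p % nr, c = p / nr;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr + nr * cc;
        if (img[q] > v) { is_max = false; continue; }
        if (img[q] == v && !visited[q]) {
          visited[q] = 1;
          stack.push_back(q);
        }
      }
    }
    if (is_max)
      for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = 1;
  }
  return out;
}

// Connected-component labelling of a binary image in raster
// (column-major) order; conn is 4 or 8. Labels are 1..L.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix binary, int conn) {
  int nr = binary.nrow(), nc = binary.ncol(), n = nr * nc;
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  const int *dr = (conn == 4) ? DR4 : DR8;
  const int *dc = (conn == 4) ? DC4 : DC8;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!binary[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int r = p % nr, c = p / nr;
      for (int k = 0; k < conn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr + nr * cc;
        if (binary[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

struct FloodEntry {
  double v;
  long long seq;
  int idx;
};
struct FloodOrder {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.v != b.v) return a.v > b.v;       // min-heap on flood level
    return a.seq > b.seq;                   // FIFO within a level
  }
};

// Meyer flooding of `relief` from labelled `markers` (0 = unlabelled),
// 4-connected growth, assigning every pixel to a marker region.
// Ties are deterministic: equal flood levels are processed FIFO and
// marker pixels are seeded in increasing label order.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix relief, IntegerMatrix markers) {
  int nr = relief.nrow(), nc = relief.ncol(), n = nr * nc;
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("relief and markers dimensions differ");
  IntegerMatrix lab = clone(markers);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodOrder> pq;
  long long seq = 0;

  std::vector<std::pair<int, int> > seeds;   // (label, idx)
  for (int i = 0; i < n; ++i)
    if (markers[i] > 0) seeds.push_back(std::make_pair(markers[i], i));
  if (seeds.empty()) stop("no markers");
  std::sort(seeds.begin(), seeds.end());
  for (size_t i = 0; i < seeds.size(); ++i) {
    FloodEntry e = {relief[seeds[i].second], seq++, seeds[i].second};
    pq.push(e);
  }
  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    int l = lab[e.idx];
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR4[k], cc = c + DC4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int q = rr + nr * cc;
      if (lab[q] == 0) {
        lab[q] = l;
        FloodEntry ne = {std::max(relief[q], e.v), seq++, q};
        pq.push(ne);
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning of a binary image to an 8-connected,
// 1-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix binary) {
  int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix img = clone(binary);
  for (int i = 0; i < nr * nc; ++i) img[i] = img[i] ? 1 : 0;
  std::vector<int> kill;
  bool changed = true;
  // neighbours P2..P9 clockwise from north
  static const int NR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int NC[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int rr = r + NR[k], cc = c + NC[k];
            p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? img(rr, cc) : 0;
          }
          int b = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            b += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          bool ok;
          if (step == 0)
            ok = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          else
            ok = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          if (ok) kill.push_back(r + nr * c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) img[kill[i]] = 0;
      }
    }
  }
  return img;
}

// Nearest-seed (Voronoi) labelling of an nr x nc pixel grid for seed
// coordinates (sr, sc) given in pixel units; ties go to the lowest
// seed index. Returns the seed index (1-based) per pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_seed(int nr, int nc, NumericVector sr, NumericVector sc) {
  int ns = sr.size();
  if (ns == 0) stop("no seeds");
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = R_PosInf;
      int arg = 0;
      for (int s = 0; s < ns; ++s) {
        double dr = (r + 1) - sr[s], dc = (c + 1) - sc[s];
        double d = dr * dr + dc * dc;
        if (d < best) { best = d; arg = s; }
      }
      lab(r, c) = arg + 1;
    }
  }
  return lab;
}
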