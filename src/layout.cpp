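// Chemistry-free layout core: greedy grid placement minimizing an overlap
// score, and iterative hill-climbing refinement with corner repulsion.
// Operates purely on axis-aligned rectangles (center x/y, width, height).

#include <Rcpp.h>
using namespace Rcpp;

static inline double overlap1(double ax, double aw, double bx, double bw) {
  double lo = std::max(ax - aw / 2.0, bx - bw / 2.0);
  double hi = std::min(ax + aw / 2.0, bx + bw / 2.0);
  return hi > lo ? hi - lo : 0.0;
}

static inline double pair_overlap(double ax, double ay, double aw, double ah,
                                  double bx, double by, double bw, double bh) {
  return overlap1(ax, aw, bx, bw) * overlap1(ay, ah, by, bh);
}

// [[Rcpp::export]]
double pair_overlap_cpp(double ax, double ay, double aw, double ah,
                        double bx, double by, double bw, double bh) {
  return pair_overlap(ax, ay, aw, ah, bx, by, bw, bh);
}

// score of a candidate frame at (cx, cy) against the first `n` placed frames
static double score_against(double cx, double cy, double cw, double ch,
                            const double* x, const double* y,
                            const double* w, const double* h, int n,
                            double w_overlap, double w_distance) {
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    s += w_overlap * pair_overlap(cx, cy, cw, ch, x[j], y[j], w[j], h[j]);
    s += w_distance * std::sqrt((cx - x[j]) * (cx - x[j]) +
                                (cy - y[j]) * (cy - y[j]));
  }
  return s;
}

// [[Rcpp::export]]
double placement_score_cpp(double cx, double cy, double cw, double ch,
                           NumericVector x, NumericVector y,
                           NumericVector w, NumericVector h,
                           double w_overlap, double w_distance) {
  return score_against(cx, cy, cw, ch, x.begin(), y.begin(), w.begin(),
                       h.begin(), x.size(), w_overlap, w_distance);
}

static inline double corner_pen(double cx, double cy, double cw_canvas,
                                double ch_canvas, double strength,
                                double eps) {
  if (strength <= 0.0) return 0.0;
  const double corners[4][2] = {{0.0, 0.0}, {cw_canvas, 0.0},
                                {0.0, ch_canvas}, {cw_canvas, ch_canvas}};
  double s = 0.0;
  for (int k = 0; k < 4; ++k) {
    double dx = cx - corners[k][0], dy = cy - corners[k][1];
    s += 1.0 / (eps + std::sqrt(dx * dx + dy * dy));
  }
  return strength * s;
}

// [[Rcpp::export]]
double corner_penalty_cpp(double cx, double cy, double canvas_w,
                          double canvas_h, double strength, double eps) {
  return corner_pen(cx, cy, canvas_w, canvas_h, strength, eps);
}

// [[Rcpp::export]]
double total_score_cpp(NumericVector x, NumericVector y, NumericVector w,
                       NumericVector h, double canvas_w, double canvas_h,
                       double w_overlap, double w_distance,
                       double corner_strength, double corner_eps) {
  int n = x.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      s += w_overlap * pair_overlap(x[i], y[i], w[i], h[i],
                                    x[j], y[j], w[j], h[j]);
      s += w_distance * std::sqrt((x[i] - x[j]) * (x[i] - x[j]) +
                                  (y[i] - y[j]) * (y[i] - y[j]));
    }
    s += corner_pen(x[i], y[i], canvas_w, canvas_h, corner_strength,
                    corner_eps);
  }
  return s;
}

// Greedy placement. Items arrive sorted (largest first); the first is put
// at the canvas center, every further one at the grid point (row-major
// scan, ties keep the first) minimizing the placement score, considering
// only points whose frame lies fully inside the canvas.
// [[Rcpp::export]]
List greedy_place_cpp(NumericVector w, NumericVector h, double canvas_w,
                      double canvas_h, NumericVector gx, NumericVector gy,
                      double w_overlap, double w_distance, bool debug) {
  int n = w.size(), nx = gx.size(), ny = gy.size();
  NumericVector x(n), y(n), step_score(n);
  List traces(debug ? n : 0);
  for (int i = 0; i < n; ++i) {
    if (w[i] > canvas_w || h[i] > canvas_h)
      stop("item %d (w=%g, h=%g) is larger than the canvas", i + 1, w[i], h[i]);
    if (i == 0) {
      x[0] = canvas_w / 2.0;
      y[0] = canvas_h / 2.0;
      step_score[0] = 0.0;
      if (debug) traces[0] = NumericVector::create(0.0);
      continue;
    }
    double best = R_PosInf, bx = NA_REAL, by = NA_REAL;
    std::vector<double> trace;
    for (int iy = 0; iy < ny; ++iy) {      // row-major: rows outer,
      for (int ix = 0; ix < nx; ++ix) {    // columns inner
        double cx = gx[ix], cy = gy[iy];
        if (cx - w[i] / 2.0 < 0.0 || cx + w[i] / 2.0 > canvas_w ||
            cy - h[i] / 2.0 < 0.0 || cy + h[i] / 2.0 > canvas_h)
          continue;  // frame would cross the canvas boundary
        double s = score_against(cx, cy, w[i], h[i], x.begin(), y.begin(),
                                 w.begin(), h.begin(), i, w_overlap,
                                 w_distance);
        if (s < best) {  // strict: ties keep the first candidate scanned
          best = s; bx = cx; by = cy;
          if (debug) trace.push_back(s);
        }
      }
    }
    if (!R_finite(best))
      stop("item %d (w=%g, h=%g) fits at no grid point", i + 1, w[i], h[i]);
    x[i] = bx; y[i] = by; step_score[i] = best;
    if (debug) traces[i] = wrap(trace);
  }
  List out = List::create(_["x"] = x, _["y"] = y,
                          _["step_score"] = step_score);
  if (debug) out["traces"] = traces;
  return out;
}

// One refinement pass structure: each item in turn tries 8 compass moves of
// length `step`; the best candidate is taken only if it strictly lowers the
// item's contribution to the total score (pairwise terms + its corner
// penalty), which makes the total monotonically non-increasing. When a full
// sweep improves the total by less than `tol` the step is halved, down to
// `step_floor`, then the loop stops.
// [[Rcpp::export]]
List refine_cpp(NumericVector x0, NumericVector y0, NumericVector w,
                NumericVector h, LogicalVector pinned, double canvas_w,
                double canvas_h, double w_overlap, double w_distance,
                double corner_strength, double corner_eps, double step,
                double step_floor, int max_iter, double tol) {
  int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0);
  const int dx8[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dy8[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  auto local = [&](int i, double cx, double cy) {
    double s = corner_pen(cx, cy, canvas_w, canvas_h, corner_strength,
                          corner_eps);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      s += w_overlap * pair_overlap(cx, cy, w[i], h[i], x[j], y[j], w[j], h[j]);
      s += w_distance * std::sqrt((cx - x[j]) * (cx - x[j]) +
                                  (cy - y[j]) * (cy - y[j]));
    }
    return s;
  };

  double total = total_score_cpp(x, y, w, h, canvas_w, canvas_h, w_overlap,
                                 w_distance, corner_strength, corner_eps);
  std::vector<double> totals;
  totals.push_back(total);
  for (int sweep = 0; sweep < max_iter; ++sweep) {
    double improvement = 0.0;
    for (int i = 0; i < n; ++i) {
      if (pinned[i]) continue;
      double cur = local(i, x[i], y[i]);
      double best = cur, bx = x[i], by = y[i];
      for (int d = 0; d < 8; ++d) {
        double cx = x[i] + dx8[d] * step, cy = y[i] + dy8[d] * step;
        if (cx - w[i] / 2.0 < 0.0 || cx + w[i] / 2.0 > canvas_w ||
            cy - h[i] / 2.0 < 0.0 || cy + h[i] / 2.0 > canvas_h)
          continue;
        double s = local(i, cx, cy);
        if (s < best) { best = s; bx = cx; by = cy; }
      }
      if (best < cur) {
        x[i] = bx; y[i] = by;
        improvement += cur - best;
      }
    }
    total -= improvement;
    totals.push_back(total);
    if (improvement < tol) {
      if (step / 2.0 >= step_floor) step /= 2.0; else break;
    }
  }
  return List::create(_["x"] = x, _["y"] = y,
                      _["sweep_totals"] = wrap(totals),
                      _["final_step"] = step);
}
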