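#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right dispersion-threshold (I-DT) fixation scan.
//
// A window of consecutive samples [s, e] is a fixation candidate iff every
// member confidence >= min_conf, its time span t[e] - t[s] >= min_dur, and
// its dispersion (max x - min x) + (max y - min y) <= disp_thr. Dispersion
// is non-decreasing as a window grows, so for each candidate start the
// minimal window reaching min_dur decides validity; valid windows are then
// extended maximally to the right (a sample that could either extend the
// current fixation or begin the next one extends the current one).
// Low-confidence samples terminate windows. Emitted fixations never overlap.
//
// Returns a matrix with one row per fixation:
// onset, offset, duration, centroid_x, centroid_y, dispersion, n_samples,
// first_idx, last_idx (indices 1-based).
// [[Rcpp::export]]
NumericMatrix idt_scan(NumericVector t, NumericVector x, NumericVector y,
                       NumericVector conf, double disp_thr, double min_dur,
                       double min_conf) {
  const int n = t.size();
  std::vector<double> out; // 9 per event
  int s = 0;
  while (s < n) {
    if (conf[s] < min_conf) { ++s; continue; }
    double xmin = x[s], xmax = x[s], ymin = y[s], ymax = y[s];
    int e = s;
    bool reached = false, blocked = false;
    // grow to minimal span
    while (t[e] - t[s] < min_dur) {
      if (e + 1 >= n || conf[e + 1] < min_conf) { blocked = true; break; }
      ++e;
      xmin = std::min(xmin, x[e]); xmax = std::max(xmax, x[e]);
      ymin = std::min(ymin, y[e]); ymax = std::max(ymax, y[e]);
    }
    if (blocked) {
      if (e + 1 >= n) break;  // stream exhausted: no later start can span min_dur
      s = e + 2;              // no start in [s, e] clears the low-confidence block
      continue;
    }
    reached = ((xmax - xmin) + (ymax - ymin)) <= disp_thr;
    if (!reached) { ++s; continue; }
    // extend maximally while dispersion and confidence allow
    while (e + 1 < n && conf[e + 1] >= min_conf) {
      double nxmin = std::min(xmin, x[e + 1]), nxmax = std::max(xmax, x[e + 1]);
      double nymin = std::min(ymin, y[e + 1]), nymax = std::max(ymax, y[e + 1]);
      if ((nxmax - nxmin) + (nymax - nymin) > disp_thr) break;
      ++e;
      xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax;
    }
    double cx = 0.0, cy = 0.0;
    for (int i = s; i <= e; ++i) { cx += x[i]; cy += y[i]; }
    int ns = e - s + 1;
    cx /= ns; cy /= ns;
    out.push_back(t[s]);                       // onset
    out.push_back(t[e]);                       // offset
    out.push_back(t[e] - t[s]);                // duration
    out.push_back(cx);
    out.push_back(cy);
    out.push_back((xmax - xmin) + (ymax - ymin));
    out.push_back(ns);
    out.push_back(s + 1);
    out.push_back(e + 1);
    s = e + 1;
  }
  const int m = out.size() / 9;
  NumericMatrix res(m, 9);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 9; ++j) res(i, j) = out[i * 9 + j];
  return res;
}

// Smallest-area visible ROI containing each (x, y) point, with boxes held at
// the most recent track observation (zero-order hold). Query times must be
// ascending. `tracks` holds one list per ROI, pre-sorted by roi_id, each with
// ascending frame times. Containment is half-open. Returns the 1-based index
// of the winning ROI (ties on area go to the earlier, i.e. lexicographically
// smaller, roi_id), or 0 when the point is inside no visible ROI.
// [[Rcpp::export]]
IntegerVector assign_min_area_scan(NumericVector t, NumericVector x,
                                   NumericVector y, List tracks) {
  const int n = t.size(), k = tracks.size();
  IntegerVector out(n, 0);
  std::vector<double> best(n, R_PosInf);
  for (int j = 0; j < k; ++j) {
    List tr = tracks[j];
    NumericVector ot = tr["t"], xmin = tr["x_min"], ymin = tr["y_min"],
                  xmax = tr["x_max"], ymax = tr["y_max"];
    LogicalVector vis = tr["visible"];
    const int m = ot.size();
    int p = -1;
    for (int i = 0; i < n; ++i) {
      while (p + 1 < m && ot[p + 1] <= t[i]) ++p;
      if (p < 0 || !vis[p]) continue;
      if (x[i] >= xmin[p] && x[i] < xmax[p] && y[i] >= ymin[p] && y[i] < ymax[p]) {
        double a = (xmax[p] - xmin[p]) * (ymax[p] - ymin[p]);
        if (a < best[i]) { best[i] = a; out[i] = j + 1; }
      }
    }
  }
  return out;
}
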