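#include <Rcpp.h>
using namespace Rcpp;

// I-DT fixation detection over one gap-free run of valid samples.
//
// From each window start the window grows while the maximum pairwise
// angular separation of its unit gaze directions stays at or below the
// threshold (tracked as the minimum pairwise cosine, updated as each
// sample joins); the maximal window is accepted when its duration reaches
// min_dur, otherwise the start advances one sample. Accepted windows
// longer than max_dur are split greedily into chunks of at most max_dur
// (trailing remnants shorter than min_dur are dropped); split_long = false
// keeps them whole. Per chunk the unit centroid direction and the maximum
// pairwise separation (degrees) are reported.
//
// [[Rcpp::export]]
DataFrame idt_fixations_cpp(NumericVector t, NumericMatrix x,
                            double cos_thr, double min_dur, double max_dur,
                            bool split_long) {
  int n = t.size();
  std::vector<int> cs, ce; // chunk start/end (0-based)

  int i = 0;
  while (i < n - 1) {
    int j = i + 1;
    double minc = 1.0;
    while (j < n) {
      double xj = x(j, 0), yj = x(j, 1), zj = x(j, 2);
      double m = 1.0;
      for (int k = i; k < j; ++k) {
        double d = x(k, 0) * xj + x(k, 1) * yj + x(k, 2) * zj;
        if (d < m) {
          m = d;
          if (m < cos_thr) break; // window cannot close, stop scanning
        }
      }
      if (m < cos_thr) break;
      if (m < minc) minc = m;
      ++j;
    }
    int e = j - 1;
    if (t[e] - t[i] >= min_dur) {
      if (!split_long || t[e] - t[i] <= max_dur) {
        cs.push_back(i);
        ce.push_back(e);
      } else {
        int s = i;
        while (s <= e) {
          int m2 = s;
          while (m2 + 1 <= e && t[m2 + 1] - t[s] <= max_dur) ++m2;
          if (t[m2] - t[s] >= min_dur) {
            cs.push_back(s);
            ce.push_back(m2);
          }
          s = m2 + 1;
        }
      }
      i = e + 1;
    } else {
      ++i;
    }
  }

  int nf = cs.size();
  NumericVector start_t(nf), end_t(nf), duration(nf);
  NumericVector cx(nf), cy(nf), cz(nf), disp(nf);
  IntegerVector nsamp(nf);
  for (int f = 0; f < nf; ++f) {
    int a = cs[f], b = ce[f];
    double sx = 0, sy = 0, sz = 0;
    for (int k = a; k <= b; ++k) {
      sx += x(k, 0);
      sy += x(k, 1);
      sz += x(k, 2);
    }
    double nrm = std::sqrt(sx * sx + sy * sy + sz * sz);
    double mind = 1.0;
    for (int k = a; k <= b; ++k) {
      for (int l = k + 1; l <= b; ++l) {
        double d = x(k, 0) * x(l, 0) + x(k, 1) * x(l, 1) +
          x(k, 2) * x(l, 2);
        if (d < mind) mind = d;
      }
    }
    if (mind > 1.0) mind = 1.0;
    if (mind < -1.0) mind = -1.0;
    start_t[f] = t[a];
    end_t[f] = t[b];
    duration[f] = t[b] - t[a];
    cx[f] = sx / nrm;
    cy[f] = sy / nrm;
    cz[f] = sz / nrm;
    disp[f] = std::acos(mind) * 180.0 / M_PI;
    nsamp[f] = b - a + 1;
  }
  return DataFrame::create(
    _["start_t"] = start_t, _["end_t"] = end_t, _["duration_s"] = duration,
    _["cx"] = cx, _["cy"] = cy, _["cz"] = cz,
    _["dispersion_deg"] = disp, _["n_samples"] = nsamp
  );
}
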