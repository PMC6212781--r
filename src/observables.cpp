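// Trajectory post-processing kernels: contact-map accumulation and the
// geometric transcription criterion (bead within a capture radius of a
// binding-competent factor of matching color).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate bead-bead contacts over frames.  Returns an n x n matrix
// of contact fractions (entry = fraction of frames with centre-centre
// distance below the capture radius); diagonal left at zero.
// [[Rcpp::export]]
NumericMatrix contacts_accumulate(List bead_frames, double radius) {
  int T = bead_frames.size();
  if (T == 0) stop("no frames");
  NumericMatrix f0 = bead_frames[0];
  int n = f0.nrow();
  NumericMatrix acc(n, n);
  double r2 = radius * radius;
  for (int t = 0; t < T; ++t) {
    NumericMatrix p = bead_frames[t];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = p(i, 0) - p(j, 0);
        double dy = p(i, 1) - p(j, 1);
        double dz = p(i, 2) - p(j, 2);
        if (dx * dx + dy * dy + dz * dz < r2) {
          acc(i, j) += 1.0; acc(j, i) += 1.0;
        }
      }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) acc(i, j) /= T;
  return acc;
}

// For every (bead, frame): 1-based index of the first binding-competent
// factor of a matching color within `radius`, or 0 if none.
// [[Rcpp::export]]
IntegerMatrix transcribing_factor(List bead_frames, List factor_frames,
                                  List competent, IntegerMatrix beadcol,
                                  IntegerVector fcol, double radius) {
  int T = bead_frames.size();
  NumericMatrix b0 = bead_frames[0];
  int n = b0.nrow();
  int K = beadcol.ncol();
  IntegerMatrix out(n, T);
  double r2 = radius * radius;
  for (int t = 0; t < T; ++t) {
    NumericMatrix bp = bead_frames[t];
    NumericMatrix fp = factor_frames[t];
    LogicalVector cp = competent[t];
    int m = fp.nrow();
    for (int i = 0; i < n; ++i) {
      bool colored = false;
      for (int k = 0; k < K; ++k) if (beadcol(i, k)) colored = true;
      if (!colored) continue;
      for (int f = 0; f < m; ++f) {
        if (!cp[f]) continue;
        int c = fcol[f];
        if (c < 0 || !beadcol(i, c)) continue;
        double dx = bp(i, 0) - fp(f, 0);
        double dy = bp(i, 1) - fp(f, 1);
        double dz = bp(i, 2) - fp(f, 2);
        if (dx * dx + dy * dy + dz * dz < r2) { out(i, t) = f + 1; break; }
      }
    }
  }
  return out;
}

// Factor-factor adjacency (distance < cutoff) for one frame.
// [[Rcpp::export]]
LogicalMatrix factor_adjacency(NumericMatrix pos, double cutoff) {
  int m = pos.nrow();
  LogicalMatrix adj(m, m);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) {
        adj(i, j) = true; adj(j, i) = true;
      }
    }
  return adj;
}

// Per (factor, frame): is the factor within `radius` of any bead it can
// bind (cognate color or nonspecific affinity), and is it competent?
// Used for bound-fraction and reversibility statistics.
// [[Rcpp::export]]
LogicalMatrix factor_bound(List bead_frames, List factor_frames,
                           List competent, IntegerMatrix beadcol,
                           IntegerVector fcol, LogicalVector nonspecific,
                           double radius) {
  int T = bead_frames.size();
  NumericMatrix f0 = factor_frames[0];
  int m = f0.nrow();
  int n = as<NumericMatrix>(bead_frames[0]).nrow();
  LogicalMatrix out(m, T);
  double r2 = radius * radius;
  for (int t = 0; t < T; ++t) {
    NumericMatrix bp = bead_frames[t];
    NumericMatrix fp = factor_frames[t];
    LogicalVector cp = competent[t];
    for (int f = 0; f < m; ++f) {
      if (!cp[f]) continue;
      int c = fcol[f];
      bool ns = nonspecific[f];
      for (int i = 0; i < n; ++i) {
        bool cognate = (c >= 0 && beadcol(i, c));
        if (!cognate && !ns) continue;
        double dx = bp(i, 0) - fp(f, 0);
        double dy = bp(i, 1) - fp(f, 1);
        double dz = bp(i, 2) - fp(f, 2);
        if (dx * dx + dy * dy + dz * dz < r2) { out(f, t) = true; break; }
      }
    }
  }
  return out;
}
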