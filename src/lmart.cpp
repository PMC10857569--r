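#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Best-first regression tree on pre-binned features, fit to (grad, hess)
// with Newton leaf values sum(g) / (sum(h) + eps). Split thresholds are
// bin boundaries (equal-frequency quantiles computed in R); both children
// of a split must hold at least min_support samples.

struct NodeWork {
  int id;
  std::vector<int> samples;
  double G, H;
  int best_feat = -1, best_bin = -1;
  double best_gain = 0.0;
};

static void find_best_split(const IntegerMatrix &bins,
                            const NumericVector &grad,
                            const NumericVector &hess,
                            const IntegerVector &nbins,
                            int min_support, double eps, NodeWork &nw) {
  const int nf = bins.ncol();
  nw.best_feat = -1;
  nw.best_gain = 1e-12;
  const double parent = nw.G * nw.G / (nw.H + eps);
  for (int f = 0; f < nf; ++f) {
    const int nb = nbins[f];
    if (nb < 2) continue;
    std::vector<double> Gb(nb, 0.0), Hb(nb, 0.0);
    std::vector<int> Cb(nb, 0);
    for (int s : nw.samples) {
      const int b = bins(s, f);
      Gb[b] += grad[s];
      Hb[b] += hess[s];
      Cb[b] += 1;
    }
    double GL = 0.0, HL = 0.0;
    int CL = 0;
    const int n = (int)nw.samples.size();
    for (int b = 0; b < nb - 1; ++b) {
      GL += Gb[b]; HL += Hb[b]; CL += Cb[b];
      const int CR = n - CL;
      if (CL < min_support || CR < min_support) continue;
      const double GR = nw.G - GL, HR = nw.H - HL;
      const double gain = GL * GL / (HL + eps) + GR * GR / (HR + eps)
                          - parent;
      if (gain > nw.best_gain) {
        nw.best_gain = gain;
        nw.best_feat = f;
        nw.best_bin = b;
      }
    }
  }
}

// [[Rcpp::export]]
List lmart_build_tree(const IntegerMatrix &bins, const NumericVector &grad,
                      const NumericVector &hess, const IntegerVector &nbins,
                      int n_leaves, int min_support, double eps) {
  const int n = bins.nrow();
  std::vector<int> feat, sbin, left, right;
  std::vector<double> value;
  std::vector<NodeWork> work;

  NodeWork root;
  root.id = 0;
  root.samples.resize(n);
  root.G = 0.0; root.H = 0.0;
  for (int i = 0; i < n; ++i) {
    root.samples[i] = i;
    root.G += grad[i];
    root.H += hess[i];
  }
  feat.push_back(-1); sbin.push_back(-1);
  left.push_back(-1); right.push_back(-1);
  value.push_back(root.G / (root.H + eps));
  find_best_split(bins, grad, hess, nbins, min_support, eps, root);
  work.push_back(std::move(root));

  int leaves = 1;
  while (leaves < n_leaves) {
    // pick the splittable leaf with the largest gain
    int pick = -1;
    double best = 1e-12;
    for (size_t i = 0; i < work.size(); ++i) {
      if (work[i].best_feat >= 0 && work[i].best_gain > best) {
        best = work[i].best_gain;
        pick = (int)i;
      }
    }
    if (pick < 0) break;
    NodeWork nw = std::move(work[pick]);
    work.erase(work.begin() + pick);

    NodeWork lc, rc;
    lc.G = lc.H = rc.G = rc.H = 0.0;
    for (int s : nw.samples) {
      if (bins(s, nw.best_feat) <= nw.best_bin) {
        lc.samples.push_back(s); lc.G += grad[s]; lc.H += hess[s];
      } else {
        rc.samples.push_back(s); rc.G += grad[s]; rc.H += hess[s];
      }
    }
    lc.id = (int)feat.size();
    feat.push_back(-1); sbin.push_back(-1);
    left.push_back(-1); right.push_back(-1);
    value.push_back(lc.G / (lc.H + eps));
    rc.id = (int)feat.size();
    feat.push_back(-1); sbin.push_back(-1);
    left.push_back(-1); right.push_back(-1);
    value.push_back(rc.G / (rc.H + eps));

    feat[nw.id] = nw.best_feat;
    sbin[nw.id] = nw.best_bin;
    left[nw.id] = lc.id;
    right[nw.id] = rc.id;
    value[nw.id] = 0.0;

    find_best_split(bins, grad, hess, nbins, min_support, eps, lc);
    find_best_split(bins, grad, hess, nbins, min_support, eps, rc);
    work.push_back(std::move(lc));
    work.push_back(std::move(rc));
    ++leaves;
  }

  // per-sample predictions from the remaining leaves
  NumericVector pred(n);
  for (const NodeWork &nw : work)
    for (int s : nw.samples) pred[s] = value[nw.id];

  return List::create(_["feature"] = IntegerVector(feat.begin(), feat.end()),
                      _["bin"] = IntegerVector(sbin.begin(), sbin.end()),
                      _["left"] = IntegerVector(left.begin(), left.end()),
                      _["right"] = IntegerVector(right.begin(), right.end()),
                      _["value"] = NumericVector(value.begin(), value.end()),
                      _["pred"] = pred);
}
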