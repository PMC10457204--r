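#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Enumeration of all compositions of n into k parts, accumulating the
// multinomial pmf mass of outcomes at most as likely as a reference outcome.
// The per-category terms x*log(p_j) - lgamma(x+1) are tabulated so the leaf
// cost is a handful of lookups; exp() is only paid on leaves that contribute.

namespace {

struct TailEnum {
  int k;
  std::vector<std::vector<double>> term;  // k x (n+1)
  double log_thresh;
  double tail;
  double total;
  bool want_total;
  double events;

  void dfs(int j, int rem, double acc) {
    if (j == k - 1) {
      double lp = acc + term[j][rem];
      events += 1.0;
      if (lp <= log_thresh) tail += std::exp(lp);
      if (want_total) total += std::exp(lp);
      return;
    }
    const std::vector<double>& tj = term[j];
    for (int x = 0; x <= rem; ++x) dfs(j + 1, rem - x, acc + tj[x]);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_multinom_tail(int n, NumericVector probs, double log_thresh,
                       bool want_total = false) {
  int k = probs.size();
  if (k < 1) stop("at least one category is required");
  TailEnum e;
  e.k = k;
  e.log_thresh = log_thresh;
  e.tail = 0.0;
  e.total = 0.0;
  e.want_total = want_total;
  e.events = 0.0;
  e.term.assign(k, std::vector<double>(n + 1));

  std::vector<double> lgf(n + 1);
  for (int x = 0; x <= n; ++x) lgf[x] = std::lgamma((double)x + 1.0);
  for (int j = 0; j < k; ++j) {
    double lpj = std::log(probs[j]);
    for (int x = 0; x <= n; ++x)
      e.term[j][x] = (x == 0 ? 0.0 : x * lpj) - lgf[x];
  }

  if (k == 1) {
    double lp = lgf[n] + e.term[0][n];
    e.events = 1.0;
    double p = std::exp(lp);
    return List::create(_["tail"] = (lp <= log_thresh ? p : 0.0),
                        _["total"] = p, _["events"] = e.events);
  }

  // split the top level so user interrupts are honoured on long enumerations
  const std::vector<double>& t0 = e.term[0];
  for (int x = 0; x <= n; ++x) {
    e.dfs(1, n - x, lgf[n] + t0[x]);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["tail"] = e.tail, _["total"] = e.total,
                      _["events"] = e.events);
}

// Literal Monte Carlo sampler: ntrial multinomial draws under the null via
// conditional binomials (R's RNG, so results follow set.seed()), counting
// draws whose pmf falls at or below the threshold.

// [[Rcpp::export]]
double cpp_multinom_mc_hits(int n, NumericVector probs, double log_thresh,
                            double ntrial) {
  int k = probs.size();
  std::vector<double> lgf(n + 1), lp(k);
  for (int x = 0; x <= n; ++x) lgf[x] = std::lgamma((double)x + 1.0);
  for (int j = 0; j < k; ++j) lp[j] = std::log(probs[j]);
  double lgn = lgf[n];
  double hits = 0.0;
  RNGScope scope;
  for (double t = 0.0; t < ntrial; t += 1.0) {
    int rem = n;
    double ptail = 1.0;
    double acc = lgn;
    for (int j = 0; j < k - 1 && rem > 0; ++j) {
      double pj = probs[j] / ptail;
      if (pj > 1.0) pj = 1.0;
      int x = (int)R::rbinom((double)rem, pj);
      acc += (x ? x * lp[j] : 0.0) - lgf[x];
      rem -= x;
      ptail -= probs[j];
    }
    acc += (rem ? rem * lp[k - 1] : 0.0) - lgf[rem];
    if (acc <= log_thresh) hits += 1.0;
    if (((long long)t & 0xFFFFFLL) == 0) Rcpp::checkUserInterrupt();
  }
  return hits;
}
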