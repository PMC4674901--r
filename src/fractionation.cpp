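#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal constant-state run lengths of a 0/1 state vector.
// On a circular genome the walk starts at a run boundary so the wrap-around
// run is counted once; a uniform state is a single run of length n.
static void run_lengths(const std::vector<unsigned char>& s, bool circular,
                        std::vector<int>& sruns, std::vector<int>& druns) {
  const int n = (int)s.size();
  sruns.clear();
  druns.clear();
  int start = 0;
  if (circular) {
    int b = -1;
    for (int i = 0; i < n; ++i) {
      int prev = (i == 0) ? n - 1 : i - 1;
      if (s[i] != s[prev]) { b = i; break; }
    }
    if (b < 0) {
      if (s[0]) sruns.push_back(n); else druns.push_back(n);
      return;
    }
    start = b;
  }
  unsigned char cur = s[start];
  int len = 1;
  for (int cnt = 1; cnt < n; ++cnt) {
    int idx = circular ? (start + cnt) % n : cnt;
    if (s[idx] == cur) {
      ++len;
    } else {
      if (cur) sruns.push_back(len); else druns.push_back(len);
      cur = s[idx];
      len = 1;
    }
  }
  if (cur) sruns.push_back(len); else druns.push_back(len);
}

// Core fractionation event loop. Draw order per event is fixed (u1 = start,
// u2 = length, u2 drawn even when mu = 1) so that the pure-R mirror used in
// the tests can reproduce trajectories bit-identically from the same seed.
// targets: strictly increasing deleted-gene counts at which checkpoints are
// recorded; when truncate is true the final event of each leg is capped so
// deleted lands exactly on the target.
// [[Rcpp::export]]
List sim_fractionation_cpp(int n_genes, double mu, IntegerVector targets,
                           bool circular, bool truncate, bool keep_events) {
  const int n = n_genes;
  const int nt = targets.size();
  std::vector<unsigned char> single(n, 0);
  std::vector<int> evid(n, 0);
  int deleted = 0, k = n;
  const double logq = (mu > 1.0) ? std::log(1.0 - 1.0 / mu) : 0.0;

  std::vector<int> ev_start, ev_conv, ev_over;
  std::vector<double> ev_req;
  List single_runs(nt), double_runs(nt), ev_ids(nt);
  IntegerVector chk_deleted(nt), chk_events(nt);
  std::vector<int> sruns, druns;
  int evcount = 0;

  for (int ti = 0; ti < nt; ++ti) {
    const int target = targets[ti];
    while (deleted < target) {
      ++evcount;
      if ((evcount & 0xFFF) == 0) Rcpp::checkUserInterrupt();

      double u1 = unif_rand();
      int idx = (int)std::floor(u1 * k);
      if (idx >= k) idx = k - 1;
      if (idx < 0) idx = 0;
      int pos = -1;
      for (int i = 0, c = -1; i < n; ++i) {
        if (!single[i] && ++c == idx) { pos = i; break; }
      }

      double u2 = unif_rand();
      double a_d = 1.0;
      if (mu > 1.0) {
        double v = std::log(1.0 - u2) / logq;
        a_d = 1.0 + std::floor(v);
        if (!(a_d >= 1.0) || a_d > 2147483647.0) a_d = 2147483647.0;
      }
      long quota = (long)a_d;
      if (truncate && quota > (long)(target - deleted)) quota = target - deleted;
      if (quota > (long)k) quota = k;

      int converted = 0, overlapped = 0;
      bool in_gap = false;
      int i = pos;
      while (converted < quota) {
        if (!single[i]) {
          single[i] = 1;
          evid[i] = evcount;
          ++converted;
          in_gap = false;
        } else if (!in_gap) {
          ++overlapped;
          in_gap = true;
        }
        ++i;
        if (i == n) {
          if (circular) i = 0; else break;
        }
      }
      deleted += converted;
      k -= converted;

      if (keep_events) {
        ev_start.push_back(pos + 1);
        ev_req.push_back(a_d);
        ev_conv.push_back(converted);
        ev_over.push_back(overlapped);
      }
      if (!truncate && deleted >= target) break;
    }
    run_lengths(single, circular, sruns, druns);
    single_runs[ti] = IntegerVector(sruns.begin(), sruns.end());
    double_runs[ti] = IntegerVector(druns.begin(), druns.end());
    chk_deleted[ti] = deleted;
    chk_events[ti] = evcount;
    if (keep_events) ev_ids[ti] = IntegerVector(evid.begin(), evid.end());
  }

  List out = List::create(
    _["single_runs"] = single_runs,
    _["double_runs"] = double_runs,
    _["deleted"] = chk_deleted,
    _["n_events"] = chk_events);
  if (keep_events) {
    out["event_ids"] = ev_ids;
    out["ev_start"] = IntegerVector(ev_start.begin(), ev_start.end());
    out["ev_requested"] = NumericVector(ev_req.begin(), ev_req.end());
    out["ev_converted"] = IntegerVector(ev_conv.begin(), ev_conv.end());
    out["ev_overlapped"] = IntegerVector(ev_over.begin(), ev_over.end());
  }
  return out;
}
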