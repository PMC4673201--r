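#include <Rcpp.h>
using namespace Rcpp;

// Tandem-repeat finder on a single sequence.
//
// For each period p in [min_period, max_period], positions j compare seq[j]
// vs seq[j+p] (j in [0, n-p)). Maximal windows of comparison positions with
// at most `resolution` mismatches are enumerated; windows of the same period
// sharing comparison positions are merged (union); a window of length w
// yields a repeat of span w + p, kept when span >= 2p (copies >= 2).
// Runs that are exactly periodic at a proper divisor of p (homopolymers,
// microsatellites) are not reported at p.

struct Rep {
  int start, period, span, mism;
};

static void repeats_one(const std::string& s, int min_period, int max_period,
                        int resolution, std::vector<Rep>& out) {
  int n = (int) s.size();
  int pmax = std::min(max_period, n / 2);
  for (int p = min_period; p <= pmax; ++p) {
    int m = n - p;
    std::vector<int> z;
    z.push_back(-1);
    for (int j = 0; j < m; ++j)
      if (s[j] != s[j + p]) z.push_back(j);
    z.push_back(m);
    int K = (int) z.size() - 2;  // number of mismatching positions

    // maximal windows with <= resolution mismatches, as (a, b) half-open
    std::vector<std::pair<int, int> > win;
    if (K <= resolution) {
      if (m > 0) win.push_back(std::make_pair(0, m));
    } else {
      for (int j0 = 0; j0 <= K - resolution; ++j0) {
        int a = z[j0] + 1;
        int b = z[j0 + resolution + 1];
        if (b > a) win.push_back(std::make_pair(a, b));
      }
    }

    // merge windows sharing comparison positions (a and b are nondecreasing)
    std::vector<std::pair<int, int> > mw;
    for (size_t k = 0; k < win.size(); ++k) {
      if (!mw.empty() && win[k].first < mw.back().second)
        mw.back().second = std::max(mw.back().second, win[k].second);
      else
        mw.push_back(win[k]);
    }

    for (size_t k = 0; k < mw.size(); ++k) {
      int a = mw[k].first, b = mw[k].second;
      if (b - a < p) continue;  // span < 2p
      int span = b - a + p;
      // longest exact-match run of comparisons within the window
      int rs = a, rl = 0, cs = a, cl = 0;
      for (int j = a; j < b; ++j) {
        if (s[j] == s[j + p]) {
          if (cl == 0) cs = j;
          ++cl;
          if (cl > rl) { rl = cl; rs = cs; }
        } else {
          cl = 0;
        }
      }
      // primitivity: drop if the exact core segment is exactly periodic at
      // a proper divisor of p (homopolymer / microsatellite)
      bool primitive = true;
      for (int d = 1; d <= p / 2 && primitive; ++d) {
        if (p % d != 0) continue;
        bool all = true;
        for (int j = rs; j < rs + rl + p - d; ++j)
          if (s[j] != s[j + d]) { all = false; break; }
        if (all) primitive = false;
      }
      if (!primitive) continue;
      int mm = 0;
      for (int j = a; j < b; ++j)
        if (s[j] != s[j + p]) ++mm;
      Rep r; r.start = a; r.period = p; r.span = span; r.mism = mm;
      out.push_back(r);
    }
  }
  std::sort(out.begin(), out.end(), [](const Rep& x, const Rep& y) {
    if (x.start != y.start) return x.start < y.start;
    return x.period < y.period;
  });
}

// [[Rcpp::export]]
DataFrame find_repeats_cpp(std::string seq, int min_period, int max_period,
                           int resolution) {
  std::vector<Rep> reps;
  if ((int) seq.size() >= 2 * min_period)
    repeats_one(seq, min_period, max_period, resolution, reps);
  int n = (int) reps.size();
  IntegerVector start(n), period(n), span(n), mism(n);
  for (int i = 0; i < n; ++i) {
    start[i] = reps[i].start; period[i] = reps[i].period;
    span[i] = reps[i].span;   mism[i] = reps[i].mism;
  }
  return DataFrame::create(_["start"] = start, _["period"] = period,
                           _["span"] = span, _["mismatches"] = mism);
}

// Per-read best repeat (largest span, ties by smaller start then smaller
// period) plus its longest exact-match core (used to left-anchor the
// duplication breakpoint). Rows are NA when a read has no qualifying repeat.
// [[Rcpp::export]]
DataFrame best_repeat_cpp(CharacterVector seqs, int min_period,
                          int max_period, int resolution) {
  R_xlen_t n = seqs.size();
  IntegerVector start(n, NA_INTEGER), period(n, NA_INTEGER),
      span(n, NA_INTEGER), mism(n, NA_INTEGER),
      core_start(n, NA_INTEGER), core_len(n, NA_INTEGER);
  std::vector<Rep> reps;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    if ((int) s.size() < 2 * min_period) continue;
    reps.clear();
    repeats_one(s, min_period, max_period, resolution, reps);
    if (reps.empty()) continue;
    const Rep* best = &reps[0];
    for (size_t k = 1; k < reps.size(); ++k) {
      const Rep& r = reps[k];
      if (r.span > best->span ||
          (r.span == best->span && r.start < best->start) ||
          (r.span == best->span && r.start == best->start &&
           r.period < best->period))
        best = &r;
    }
    // longest run of exact matches at lag `period` within the window
    int p = best->period;
    int a = best->start, b = best->start + best->span - p;
    int cs = a, cl = 0, rs = a, rl = 0;
    for (int j = a; j < b; ++j) {
      if (s[j] == s[j + p]) {
        if (rl == 0) rs = j;
        ++rl;
        if (rl > cl) { cl = rl; cs = rs; }
      } else {
        rl = 0;
      }
    }
    start[i] = best->start; period[i] = p; span[i] = best->span;
    mism[i] = best->mism; core_start[i] = cs; core_len[i] = cl;
  }
  return DataFrame::create(_["start"] = start, _["period"] = period,
                           _["span"] = span, _["mismatches"] = mism,
                           _["core_start"] = core_start,
                           _["core_len"] = core_len);
}
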