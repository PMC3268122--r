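#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; 4 marks N (or anything else), which matches nothing,
// not even another N.
static inline uint8_t base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static std::vector<uint8_t> encode(const char *s, size_t n) {
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  size_t n = v.size();
  std::vector<uint8_t> r(n);
  for (size_t i = 0; i < n; ++i) {
    uint8_t c = v[n - 1 - i];
    r[i] = c < 4 ? uint8_t(3 - c) : uint8_t(4);
  }
  return r;
}

// All maximal exact matches (length >= min_match, both strands) between each
// query and each target sequence. Coordinates are 0-based half-open; the
// target is always reported on its forward strand and `strand` describes the
// query. Seeds are k-mers (k = min(min_match, 31)) extended to maximality;
// a per-diagonal high-water mark suppresses redundant seeds inside an
// already-emitted match. Targets are concatenated with N separators so no
// seed or extension can cross a sequence boundary.
//
// In self mode, queries and targets must be the same vector and the identity
// diagonal of each sequence against itself is suppressed (the self-match
// convention of repeat scanning).
// [[Rcpp::export(name = ".mem_scan_cpp")]]
DataFrame mem_scan_cpp(CharacterVector queries, CharacterVector targets,
                       int min_match, bool self_mode) {
  if (min_match < 1) stop("min_match must be >= 1");
  if (self_mode && queries.size() != targets.size())
    stop("self mode requires queries and targets of equal length");
  const int k = std::min(min_match, 31);
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<uint8_t> tcat;
  std::vector<long long> toff(targets.size());
  {
    size_t tot = 0;
    for (R_xlen_t i = 0; i < targets.size(); ++i)
      tot += (size_t)LENGTH(STRING_ELT(targets, i)) + 1;
    tcat.reserve(tot);
    for (R_xlen_t i = 0; i < targets.size(); ++i) {
      toff[i] = (long long)tcat.size();
      const char *s = CHAR(STRING_ELT(targets, i));
      size_t n = (size_t)LENGTH(STRING_ELT(targets, i));
      for (size_t p = 0; p < n; ++p) tcat.push_back(base_code(s[p]));
      tcat.push_back(4);
    }
  }
  const long long tn = (long long)tcat.size();

  std::unordered_map<uint64_t, std::vector<long long> > index;
  {
    uint64_t key = 0;
    int run = 0;
    for (long long p = 0; p < tn; ++p) {
      uint8_t c = tcat[p];
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & mask;
      if (++run >= k) index[key].push_back(p - k + 1);
    }
  }

  std::vector<int> o_q, o_t, o_qs, o_qe, o_ts, o_te, o_len;
  std::vector<std::string> o_strand;

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    const char *qsC = CHAR(STRING_ELT(queries, qi));
    size_t qn0 = (size_t)LENGTH(STRING_ELT(queries, qi));
    std::vector<uint8_t> qfwd = encode(qsC, qn0);
    for (int si = 0; si < 2; ++si) {
      const bool minus = (si == 1);
      std::vector<uint8_t> q = minus ? revcomp(qfwd) : qfwd;
      const long long qn = (long long)q.size();
      std::unordered_map<long long, long long> covered;  // diag -> query end
      uint64_t key = 0;
      int run = 0;
      for (long long i = 0; i < qn; ++i) {
        uint8_t c = q[i];
        if (c > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | c) & mask;
        if (++run < k) continue;
        const long long i0 = i - k + 1;
        auto hit = index.find(key);
        if (hit == index.end()) continue;
        for (long long j0 : hit->second) {
          const long long diag = i0 - j0;
          auto cv = covered.find(diag);
          if (cv != covered.end() && i0 < cv->second) continue;
          long long qs = i0, js = j0;
          while (qs > 0 && js > 0 && q[qs - 1] < 4 && q[qs - 1] == tcat[js - 1]) {
            --qs; --js;
          }
          long long qe = i0 + k, je = j0 + k;
          while (qe < qn && je < tn && q[qe] < 4 && q[qe] == tcat[je]) {
            ++qe; ++je;
          }
          covered[diag] = qe;
          const long long len = qe - qs;
          if (len < min_match) continue;
          R_xlen_t ti = std::upper_bound(toff.begin(), toff.end(), js) -
                        toff.begin() - 1;
          const long long ts = js - toff[ti], te = je - toff[ti];
          if (self_mode && !minus && ti == qi && ts == qs) continue;
          int a_qs, a_qe;
          if (minus) {
            a_qs = (int)(qn - qe);
            a_qe = (int)(qn - qs);
          } else {
            a_qs = (int)qs;
            a_qe = (int)qe;
          }
          o_q.push_back((int)qi + 1);
          o_t.push_back((int)ti + 1);
          o_qs.push_back(a_qs);
          o_qe.push_back(a_qe);
          o_ts.push_back((int)ts);
          o_te.push_back((int)te);
          o_len.push_back((int)len);
          o_strand.push_back(minus ? "-" : "+");
        }
      }
    }
  }
  return DataFrame::create(
    _["q_idx"] = o_q, _["t_idx"] = o_t,
    _["q_start"] = o_qs, _["q_end"] = o_qe,
    _["t_start"] = o_ts, _["t_end"] = o_te,
    _["strand"] = o_strand, _["len"] = o_len,
    _["stringsAsFactors"] = false);
}
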