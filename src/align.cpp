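#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Alignment primitives shared by the monomer, flank and whole-genome stages.
// Scoring convention throughout: match +1, mismatch -1, gap -1 (linear), no
// end-gap forgiveness in the global aligner.  'N' (or any non-ACGT letter)
// never counts as a match.

static inline bool is_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// Global Needleman-Wunsch. Traceback tie-break: prefer diagonal, then up
// (consume a), then left (consume b); the preference is applied at fill time
// so exactly one optimal traceback is reported.
// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in global alignment");
  if ((double)(n + 1) * (m + 1) > 6e7) stop("sequences too long for global alignment");
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> ptr((size_t)(n + 1) * (m + 1)); // 0 diag, 1 up, 2 left
  for (int j = 0; j <= m; ++j) { prev[j] = -j; ptr[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    ptr[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (is_match(a[i - 1], b[j - 1]) ? 1 : -1);
      int su = prev[j] - 1;
      int sl = cur[j - 1] - 1;
      int best = sd; uint8_t p = 0;
      if (su > best) { best = su; p = 1; }
      if (sl > best) { best = sl; p = 2; }
      cur[j] = best;
      ptr[(size_t)i * (m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  int i = n, j = m, matches = 0, alen = 0;
  while (i > 0 || j > 0) {
    uint8_t p = ptr[(size_t)i * (m + 1) + j];
    ++alen;
    if (i > 0 && j > 0 && p == 0) {
      if (is_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["length"] = alen);
}

// Best local (Smith-Waterman) alignment between two sequences (match +1,
// mismatch -2, gap -2: safely inside the local regime for DNA).  Used for
// breakpoint-flank homology and small orientation checks; both inputs are
// expected to be modest in size.
// [[Rcpp::export]]
List cpp_sw_best(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["matches"] = 0, _["length"] = 0,
                        _["qstart"] = 0, _["qend"] = 0, _["tstart"] = 0, _["tend"] = 0);
  if ((double)(n + 1) * (m + 1) > 2.5e8) stop("sequences too long for local alignment");
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  std::vector<uint8_t> ptr((size_t)(n + 1) * (m + 1), 3); // 3 = stop
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (is_match(a[i - 1], b[j - 1]) ? 1 : -2);
      int su = prev[j] - 2;
      int sl = cur[j - 1] - 2;
      int v = sd; uint8_t p = 0;
      if (su > v) { v = su; p = 1; }
      if (sl > v) { v = sl; p = 2; }
      if (v <= 0) { v = 0; p = 3; }
      cur[j] = v;
      ptr[(size_t)i * (m + 1) + j] = p;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  int i = bi, j = bj, matches = 0, alen = 0;
  int qe = bi, te = bj;
  while (i > 0 && j > 0) {
    uint8_t p = ptr[(size_t)i * (m + 1) + j];
    if (p == 3) break;
    ++alen;
    if (p == 0) { if (is_match(a[i - 1], b[j - 1])) ++matches; --i; --j; }
    else if (p == 1) --i;
    else --j;
  }
  return List::create(_["score"] = best, _["matches"] = matches, _["length"] = alen,
                      _["qstart"] = i + 1, _["qend"] = qe,
                      _["tstart"] = j + 1, _["tend"] = te);
}

// Greedy non-overlapping local hits of a (short) query against a target:
// repeated Smith-Waterman where previously claimed target positions are
// masked out.  Returns hits in discovery (score-descending) order.
// [[Rcpp::export]]
DataFrame cpp_sw_hits(std::string query, std::string target, int min_score,
                      int max_hits = 10000) {
  const int n = (int)query.size();
  int m = (int)target.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)n * m > 2.5e8) stop("problem too large for exhaustive local hits");
  std::string tgt = target;
  std::vector<int> qs_v, qe_v, ts_v, te_v, sc_v, ma_v, ln_v;
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> ptr((size_t)(n + 1) * (m + 1));
  for (int iter = 0; iter < max_hits; ++iter) {
    std::fill(prev.begin(), prev.end(), 0);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      cur[0] = 0;
      for (int j = 1; j <= m; ++j) {
        int sd = prev[j - 1] + (is_match(query[i - 1], tgt[j - 1]) ? 1 : -2);
        int su = prev[j] - 2;
        int sl = cur[j - 1] - 2;
        int v = sd; uint8_t p = 0;
        if (su > v) { v = su; p = 1; }
        if (sl > v) { v = sl; p = 2; }
        if (v <= 0) { v = 0; p = 3; }
        cur[j] = v;
        ptr[(size_t)i * (m + 1) + j] = p;
        if (v > best) { best = v; bi = i; bj = j; }
      }
      std::swap(prev, cur);
    }
    if (best < min_score) break;
    int i = bi, j = bj, matches = 0, alen = 0;
    while (i > 0 && j > 0) {
      uint8_t p = ptr[(size_t)i * (m + 1) + j];
      if (p == 3) break;
      ++alen;
      if (p == 0) { if (is_match(query[i - 1], tgt[j - 1])) ++matches; --i; --j; }
      else if (p == 1) --i;
      else --j;
    }
    qs_v.push_back(i + 1); qe_v.push_back(bi);
    ts_v.push_back(j + 1); te_v.push_back(bj);
    sc_v.push_back(best); ma_v.push_back(matches); ln_v.push_back(alen);
    for (int t = j; t < bj; ++t) tgt[t] = '#'; // mask claimed target interval
  }
  return DataFrame::create(_["qstart"] = qs_v, _["qend"] = qe_v,
                           _["tstart"] = ts_v, _["tend"] = te_v,
                           _["score"] = sc_v, _["matches"] = ma_v,
                           _["length"] = ln_v);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// Ungapped same-diagonal seed blocks: exact k-mer seeds of the query located
// in a hash index of the target, merged along diagonals.  Suited to
// substitution-diverged genome pairs where indels occur only as discrete
// structural events between blocks.
// [[Rcpp::export]]
DataFrame cpp_seed_blocks(std::string query, std::string target, int k = 15,
                          int max_gap = 400, int max_occ = 20,
                          int min_len = 100, double min_ident = 0.75) {
  const int nq = (int)query.size(), nt = (int)target.size();
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(nt > k ? (size_t)(nt - k + 1) : 16);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // index target
  {
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < nt; ++i) {
      int b = base2bits(target[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        std::vector<int> &v = idx[key];
        if ((int)v.size() <= max_occ) v.push_back(i - k + 1);
      }
    }
  }
  // collect seed pairs as (diagonal, query position)
  std::vector<std::pair<int, int> > pairs;
  {
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < nq; ++i) {
      int b = base2bits(query[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<int> &v = it->second;
        if ((int)v.size() > max_occ) continue;
        int q = i - k + 1;
        for (int t : v) pairs.push_back(std::make_pair(t - q, q));
      }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<int> qs_v, qe_v, ts_v, te_v, ln_v, ma_v;
  std::vector<double> id_v;
  size_t i = 0;
  while (i < pairs.size()) {
    int diag = pairs[i].first;
    int qs = pairs[i].second, qe = pairs[i].second;
    size_t j = i + 1;
    while (j < pairs.size() && pairs[j].first == diag &&
           pairs[j].second - qe <= max_gap) {
      qe = pairs[j].second; ++j;
    }
    int qend = qe + k - 1;
    int len = qend - qs + 1;
    if (len >= min_len) {
      int matches = 0;
      for (int q = qs; q <= qend; ++q)
        if (is_match(query[q], target[q + diag])) ++matches;
      double ident = (double)matches / len;
      if (ident >= min_ident) {
        qs_v.push_back(qs + 1); qe_v.push_back(qend + 1);
        ts_v.push_back(qs + diag + 1); te_v.push_back(qend + diag + 1);
        ln_v.push_back(len); ma_v.push_back(matches); id_v.push_back(ident);
      }
    }
    i = j;
  }
  return DataFrame::create(_["qstart"] = qs_v, _["qend"] = qe_v,
                           _["tstart"] = ts_v, _["tend"] = te_v,
                           _["length"] = ln_v, _["matches"] = ma_v,
                           _["identity"] = id_v);
}

// Persistent k-mer index over a set of named sequences, so that many probes
// (e.g. SV breakpoint flanks) can be mapped without rebuilding the hash.
struct SeedIndex {
  int k;
  int max_occ;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > map; // (seq, pos)
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, int k = 15, int max_occ = 20) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k; idx->max_occ = max_occ;
  CharacterVector nm = seqs.names();
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    idx->names.push_back(nm.size() ? as<std::string>(nm[s]) : std::to_string(s + 1));
    idx->seqs.push_back(seq);
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < (int)seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        std::vector<std::pair<int,int> > &v = idx->map[key];
        if ((int)v.size() <= max_occ)
          v.push_back(std::make_pair(s, i - k + 1));
      }
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// Map a probe against a prebuilt index; same diagonal-merge logic as
// cpp_seed_blocks, applied per target sequence.
// [[Rcpp::export]]
DataFrame cpp_index_blocks(SEXP xp, std::string query, int max_gap = 400,
                           int min_len = 100, double min_ident = 0.75) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  // (target seq, diagonal, qpos)
  std::vector<std::tuple<int,int,int> > pairs;
  uint64_t key = 0; int run = 0;
  const int nq = (int)query.size();
  for (int i = 0; i < nq; ++i) {
    int b = base2bits(query[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      auto it = idx->map.find(key);
      if (it == idx->map.end()) continue;
      if ((int)it->second.size() > idx->max_occ) continue;
      int q = i - k + 1;
      for (auto &tp : it->second)
        pairs.push_back(std::make_tuple(tp.first, tp.second - q, q));
    }
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<int> qs_v, qe_v, ts_v, te_v, ln_v, ma_v, sq_v;
  std::vector<double> id_v;
  size_t i = 0;
  while (i < pairs.size()) {
    int sidx = std::get<0>(pairs[i]);
    int diag = std::get<1>(pairs[i]);
    int qs = std::get<2>(pairs[i]), qe = qs;
    size_t j = i + 1;
    while (j < pairs.size() && std::get<0>(pairs[j]) == sidx &&
           std::get<1>(pairs[j]) == diag &&
           std::get<2>(pairs[j]) - qe <= max_gap) {
      qe = std::get<2>(pairs[j]); ++j;
    }
    int qend = qe + k - 1;
    int len = qend - qs + 1;
    if (len >= min_len) {
      const std::string &tgt = idx->seqs[sidx];
      int matches = 0;
      for (int q = qs; q <= qend; ++q)
        if (is_match(query[q], tgt[q + diag])) ++matches;
      double ident = (double)matches / len;
      if (ident >= min_ident) {
        sq_v.push_back(sidx + 1);
        qs_v.push_back(qs + 1); qe_v.push_back(qend + 1);
        ts_v.push_back(qs + diag + 1); te_v.push_back(qend + diag + 1);
        ln_v.push_back(len); ma_v.push_back(matches); id_v.push_back(ident);
      }
    }
    i = j;
  }
  CharacterVector tname(sq_v.size());
  for (size_t z = 0; z < sq_v.size(); ++z) tname[z] = idx->names[sq_v[z] - 1];
  return DataFrame::create(_["target"] = tname,
                           _["qstart"] = qs_v, _["qend"] = qe_v,
                           _["tstart"] = ts_v, _["tend"] = te_v,
                           _["length"] = ln_v, _["matches"] = ma_v,
                           _["identity"] = id_v,
                           _["stringsAsFactors"] = false);
}

// Sparse k-mer counts for a set of sequences; windows containing non-ACGT
// letters are skipped.  Returns, per sequence, 1-based indices into the
// 4^k k-mer space plus counts.
// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 15) stop("k must be in [1, 15]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  List out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    std::unordered_map<uint64_t, int> cnt;
    uint64_t key = 0; int run = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) cnt[key]++;
    }
    IntegerVector idxv(cnt.size()), cv(cnt.size());
    int p = 0;
    for (auto &kv : cnt) { idxv[p] = (int)(kv.first + 1); cv[p] = (int)kv.second; ++p; }
    out[s] = List::create(_["index"] = idxv, _["count"] = cv);
  }
  return out;
}
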