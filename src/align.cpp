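#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 for anything that is not an unambiguous base.
// N (and any masked/ambiguous character) never matches, not even itself.
static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline bool base_match(char a, char b) {
  int x = base2bit(a);
  return x >= 0 && x == base2bit(b);
}

// Enumerate maximal exact matches (forward strand) between one reference
// string and a set of query strings.  A match is maximal when it cannot be
// extended by one base on either side without breaking identity.  Seeds are
// k-mers hashed over the reference; each maximal match is emitted exactly
// once, from the seed at its leftmost position.
// [[Rcpp::export(name = ".mem_find_cpp")]]
DataFrame mem_find_cpp(std::string ref, CharacterVector qry, int min_len,
                       bool unique_in_ref) {
  if (min_len < 1) stop("min_len must be >= 1");
  const int k = std::min(min_len, 24);
  const size_t rn = ref.size();

  // rolling-hash (exact 2-bit key, k <= 24 so it fits in 48 bits)
  std::unordered_map<uint64_t, std::vector<int>> index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  {
    uint64_t key = 0;
    int run = 0;
    for (size_t i = 0; i < rn; ++i) {
      int b = base2bit(ref[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back((int)(i - k + 1));
    }
  }

  std::vector<int> out_qidx, out_rs, out_qs, out_len;

  for (int qi = 0; qi < qry.size(); ++qi) {
    std::string q = as<std::string>(qry[qi]);
    const size_t qn = q.size();
    uint64_t key = 0;
    int run = 0;
    for (size_t j = 0; j < qn; ++j) {
      int b = base2bit(q[j]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (run + 1 < k) { ++run; continue; }
      ++run;
      size_t qpos = j - k + 1;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (int rpos : it->second) {
        // leftmost-seed check: skip if the match extends left of the seed
        if (qpos > 0 && rpos > 0 && base_match(q[qpos - 1], ref[rpos - 1]))
          continue;
        size_t ri = (size_t)rpos + k, qj = qpos + k;
        while (ri < rn && qj < qn && base_match(ref[ri], q[qj])) { ++ri; ++qj; }
        int len = (int)(ri - rpos);
        if (len < min_len) continue;
        if (unique_in_ref) {
          // count occurrences of ref[rpos, rpos+len) in the reference
          uint64_t k0 = 0;
          for (int t = 0; t < k; ++t)
            k0 = (k0 << 2) | (uint64_t)base2bit(ref[rpos + t]);
          int occ = 0;
          for (int p : index[k0 & mask]) {
            if (p + len > (int)rn) continue;
            if (ref.compare(p, len, ref, rpos, len) == 0 && ++occ > 1) break;
          }
          if (occ > 1) continue;
        }
        out_qidx.push_back(qi + 1);
        out_rs.push_back(rpos);
        out_qs.push_back((int)qpos);
        out_len.push_back(len);
      }
    }
  }

  return DataFrame::create(_["qry_idx"] = out_qidx, _["ref_start"] = out_rs,
                           _["qry_start"] = out_qs, _["length"] = out_len);
}

// Chain collinear matches (one ref/qry/strand group, pre-sorted by
// ref_start then qry_start) into clusters by dynamic programming that
// maximises total matched length subject to separation <= s and diagonal
// drift <= f * separation.  Returns a cluster id per match (0 = unclustered);
// chains whose total matched length is below min_total get id 0.
// [[Rcpp::export(name = ".chain_matches_cpp")]]
IntegerVector chain_matches_cpp(IntegerVector ref_start, IntegerVector qry_start,
                                IntegerVector len, double s, double f,
                                int max_overlap, double min_total) {
  const int n = ref_start.size();
  IntegerVector cluster(n, 0);
  if (n == 0) return cluster;

  std::vector<double> best(n);
  std::vector<int> pred(n, -1);
  int lmax = 0;
  for (int i = 0; i < n; ++i) lmax = std::max(lmax, len[i]);

  for (int i = 0; i < n; ++i) {
    best[i] = (double)len[i];
    for (int j = i - 1; j >= 0; --j) {
      if ((double)(ref_start[i] - ref_start[j]) > s + lmax) break;
      double rg = (double)ref_start[i] - (ref_start[j] + len[j]);
      double qg = (double)qry_start[i] - (qry_start[j] + len[j]);
      if (rg < -max_overlap || qg < -max_overlap) continue;
      if (rg > s || qg > s) continue;
      double sep = std::max(std::max(rg, qg), 0.0);
      if (std::abs(rg - qg) > f * sep + 1e-9) continue;
      double ov = std::max(0.0, std::max(-rg, -qg));
      double cand = best[j] + (double)len[i] - ov;
      bool better = cand > best[i] + 1e-9;
      if (!better && std::abs(cand - best[i]) <= 1e-9 && pred[i] >= 0) {
        // deterministic tie-break: leftmost ref then qry predecessor
        if (ref_start[j] < ref_start[pred[i]] ||
            (ref_start[j] == ref_start[pred[i]] &&
             qry_start[j] < qry_start[pred[i]]))
          better = true;
      }
      if (better) { best[i] = cand; pred[i] = j; }
    }
  }

  // extract chains greedily by descending end score
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (best[a] != best[b]) return best[a] > best[b];
    if (ref_start[a] != ref_start[b]) return ref_start[a] < ref_start[b];
    return qry_start[a] < qry_start[b];
  });

  std::vector<bool> used(n, false);
  int next_id = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (used[i]) continue;
    std::vector<int> chain;
    int cur = i;
    double total = 0;
    int prev = -1;
    while (cur >= 0 && !used[cur]) {
      chain.push_back(cur);
      double gain = (double)len[cur];
      if (prev >= 0) {
        double rg = (double)ref_start[prev] - (ref_start[cur] + len[cur]);
        double qg = (double)qry_start[prev] - (qry_start[cur] + len[cur]);
        gain -= std::max(0.0, std::max(-rg, -qg));
      }
      total += gain;
      used[cur] = true;
      prev = cur;
      cur = pred[cur];
    }
    if (total >= min_total) {
      ++next_id;
      for (int m : chain) cluster[m] = next_id;
    }
  }
  return cluster;
}

// Affine-gap global alignment (Gotoh).  A gap of length g costs
// gap_open + g * gap_ext.  Returns score and a CIGAR over {=, X, I, D}
// where D consumes only the reference (a) and I only the query (b).
// Traceback is explicit per matrix: tbM holds which matrix the diagonal
// step came from; tbE/tbF hold which matrix the gap was opened from
// (0 = M, 1 = E, 2 = F).
// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  const size_t area = (size_t)(m + 1) * (size_t)(n + 1);
  if ((double)area > 1.2e7) stop("alignment problem too large");

  // interiors are always written before being read, so only the
  // boundaries need initialisation
  std::vector<double> M(area), E(area), F(area);
  std::vector<uint8_t> tbM(area, 0), tbE(area, 0), tbF(area, 0);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  M[idx(0, 0)] = 0;
  E[idx(0, 0)] = F[idx(0, 0)] = NEG;
  for (int i = 1; i <= m; ++i) {
    M[idx(i, 0)] = F[idx(i, 0)] = NEG;
    E[idx(i, 0)] = -gap_open - gap_ext * i;
    tbE[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    M[idx(0, j)] = E[idx(0, j)] = NEG;
    F[idx(0, j)] = -gap_open - gap_ext * j;
    tbF[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t ij = idx(i, j), up = idx(i - 1, j), lf = idx(i, j - 1),
                   dg = idx(i - 1, j - 1);
      // E: gap consuming a (op D)
      {
        double fromM = M[up] - gap_open - gap_ext;
        double fromE = E[up] - gap_ext;
        double fromF = F[up] - gap_open - gap_ext;
        if (fromE >= fromM && fromE >= fromF) { E[ij] = fromE; tbE[ij] = 1; }
        else if (fromM >= fromF)              { E[ij] = fromM; tbE[ij] = 0; }
        else                                  { E[ij] = fromF; tbE[ij] = 2; }
      }
      // F: gap consuming b (op I)
      {
        double fromM = M[lf] - gap_open - gap_ext;
        double fromF = F[lf] - gap_ext;
        double fromE = E[lf] - gap_open - gap_ext;
        if (fromF >= fromM && fromF >= fromE) { F[ij] = fromF; tbF[ij] = 2; }
        else if (fromM >= fromE)              { F[ij] = fromM; tbF[ij] = 0; }
        else                                  { F[ij] = fromE; tbF[ij] = 1; }
      }
      // M: diagonal
      {
        double sc = base_match(a[i - 1], b[j - 1]) ? match : -std::abs(mismatch);
        if (M[dg] >= E[dg] && M[dg] >= F[dg]) { M[ij] = M[dg] + sc; tbM[ij] = 0; }
        else if (E[dg] >= F[dg])              { M[ij] = E[dg] + sc; tbM[ij] = 1; }
        else                                  { M[ij] = F[dg] + sc; tbM[ij] = 2; }
      }
    }
  }

  const size_t endij = idx(m, n);
  int state;
  double score;
  if (M[endij] >= E[endij] && M[endij] >= F[endij]) { score = M[endij]; state = 0; }
  else if (E[endij] >= F[endij])                    { score = E[endij]; state = 1; }
  else                                              { score = F[endij]; state = 2; }

  std::string ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const size_t ij = idx(i, j);
    if (state == 0) {
      ops.push_back(base_match(a[i - 1], b[j - 1]) ? '=' : 'X');
      state = tbM[ij];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('D');
      state = tbE[ij];
      --i;
    } else {
      ops.push_back('I');
      state = tbF[ij];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  return List::create(_["score"] = score, _["cigar"] = cig);
}
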