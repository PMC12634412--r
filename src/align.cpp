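// Seed-and-extend local aligner for scoring window recovery.
// Exact seed_k-mer seeds (both strands) are clustered by diagonal and each
// cluster is resolved by a banded affine-gap Smith-Waterman over the
// implied subject region. A gap of length L costs gap_open + L * gap_ext.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG = -1000000000;

inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct Aln {
  int score = NEG;
  int columns = 0, matches = 0, mismatches = 0, gap_opens = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;  // 1-based
};

// Banded local alignment of q vs s; allowed diagonals d = j - i within
// [dlo, dhi]. Returns the best local alignment with full traceback stats.
Aln banded_sw(const std::string& q, const std::string& s, int dlo, int dhi,
              int match, int mismatch, int gap_open, int gap_ext) {
  int m = (int)q.size(), ns = (int)s.size();
  dlo = std::max(dlo, -(m - 1));
  dhi = std::min(dhi, ns - 1);
  Aln out;
  if (dlo > dhi) return out;
  int W = dhi - dlo + 1;
  // cell (i, j) stored at row i, offset j - i - dlo, for i in 0..m, j in 0..ns
  std::vector<int> H((size_t)(m + 1) * W, 0), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  // traceback: 0 stop, 1 diag, 2 E (gap consuming subject), 3 F (gap
  // consuming query); for E/F, extra bit marks "extend" vs "open"
  std::vector<uint8_t> tbH((size_t)(m + 1) * W, 0), tbE((size_t)(m + 1) * W, 0),
      tbF((size_t)(m + 1) * W, 0);
  auto off = [&](int i, int j) -> long { return (long)i * W + (j - i - dlo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= ns && (j - i) >= dlo && (j - i) <= dhi;
  };

  int besti = 0, bestj = 0, best = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(ns, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      long o = off(i, j);
      // E: gap in query (move along subject)
      if (inband(i, j - 1)) {
        long ol = off(i, j - 1);
        int open = H[ol] + gap_open + gap_ext;
        int ext = E[ol] + gap_ext;
        if (ext > open) { E[o] = ext; tbE[o] = 1; }
        else { E[o] = open; tbE[o] = 0; }
      }
      // F: gap in subject (move along query)
      if (inband(i - 1, j)) {
        long ou = off(i - 1, j);
        int open = H[ou] + gap_open + gap_ext;
        int ext = F[ou] + gap_ext;
        if (ext > open) { F[o] = ext; tbF[o] = 1; }
        else { F[o] = open; tbF[o] = 0; }
      }
      int diag = NEG;
      if (inband(i - 1, j - 1)) {
        int sub = (base2bits(q[i - 1]) >= 0 &&
                   base2bits(q[i - 1]) == base2bits(s[j - 1]))
                      ? match
                      : mismatch;
        diag = H[off(i - 1, j - 1)] + sub;
      }
      // ties prefer continuing the alignment (diagonal over stopping,
      // later cells over earlier), so the longest optimal local
      // alignment is reported
      int h = 0;
      uint8_t tb = 0;
      if (diag >= h) { h = diag; tb = 1; }
      if (E[o] > h) { h = E[o]; tb = 2; }
      if (F[o] > h) { h = F[o]; tb = 3; }
      H[o] = h;
      tbH[o] = tb;
      if (h >= best && h > 0) { best = h; besti = i; bestj = j; }
    }
  }
  if (best <= 0) return out;

  out.score = best;
  out.q_end = besti;
  out.s_end = bestj;
  int i = besti, j = bestj;
  int state = 0;  // 0 = H
  while (true) {
    long o = off(i, j);
    if (state == 0) {
      uint8_t tb = tbH[o];
      if (tb == 0) break;
      if (tb == 1) {
        out.columns++;
        if (base2bits(q[i - 1]) >= 0 && base2bits(q[i - 1]) == base2bits(s[j - 1]))
          out.matches++;
        else
          out.mismatches++;
        --i; --j;
      } else if (tb == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {
      out.columns++;
      uint8_t ext = tbE[o];
      --j;
      if (!ext) { out.gap_opens++; state = 0; }
    } else {
      out.columns++;
      uint8_t ext = tbF[o];
      --i;
      if (!ext) { out.gap_opens++; state = 0; }
    }
  }
  out.q_start = i + 1;
  out.s_start = j + 1;
  return out;
}

struct Seed {
  int diag, qpos, spos;  // 0-based
};

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector qseqs, CharacterVector qids,
                          CharacterVector sseqs, CharacterVector sids,
                          int seed_k, double min_identity, int match,
                          int mismatch, int gap_open, int gap_ext) {
  if (seed_k < 4 || seed_k > 31) stop("seed_k must be between 4 and 31");
  uint64_t mask = (1ULL << (2 * seed_k)) - 1;

  // index all forward seed_k-mers of the subjects
  std::vector<std::string> subj(sseqs.size());
  std::map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (R_xlen_t si = 0; si < sseqs.size(); ++si) {
    subj[si] = as<std::string>(sseqs[si]);
    const std::string& s = subj[si];
    uint64_t v = 0;
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++run >= seed_k) index[v].push_back({(int)si, p - seed_k + 1});
    }
  }

  std::vector<std::string> r_qid, r_sid;
  std::vector<double> r_pident, r_score;
  std::vector<int> r_len, r_mm, r_go, r_qs, r_qe, r_ss, r_se;
  const int pad = 50, band_pad = 32;

  for (R_xlen_t qi = 0; qi < qseqs.size(); ++qi) {
    std::string qfwd = as<std::string>(qseqs[qi]);
    int m = (int)qfwd.size();
    if (m < seed_k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand ? revcomp(qfwd) : qfwd;
      // collect seeds per subject
      std::map<int, std::vector<Seed>> per_subj;
      uint64_t v = 0;
      int run = 0;
      for (int p = 0; p < m; ++p) {
        int b = base2bits(q[p]);
        if (b < 0) { run = 0; v = 0; continue; }
        v = ((v << 2) | (uint64_t)b) & mask;
        if (++run >= seed_k) {
          auto it = index.find(v);
          if (it == index.end()) continue;
          int qpos = p - seed_k + 1;
          for (auto& hit : it->second)
            per_subj[hit.first].push_back({hit.second - qpos, qpos, hit.second});
        }
      }
      for (auto& kv : per_subj) {
        int si = kv.first;
        std::vector<Seed>& seeds = kv.second;
        std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
          if (a.diag != b.diag) return a.diag < b.diag;
          return a.spos < b.spos;
        });
        // cluster seeds by diagonal proximity
        std::vector<std::pair<size_t, size_t>> clusters;
        size_t start = 0;
        for (size_t t = 1; t <= seeds.size(); ++t) {
          if (t == seeds.size() || seeds[t].diag - seeds[t - 1].diag > 40) {
            clusters.push_back({start, t});
            start = t;
          }
        }
        // subject regions implied by each cluster; merge overlaps
        struct Region { int slo, shi, dlo, dhi; };
        std::vector<Region> regs;
        for (auto& cl : clusters) {
          int dlo = seeds[cl.first].diag, dhi = seeds[cl.second - 1].diag;
          int smin = INT_MAX, smax = INT_MIN, qmin = INT_MAX, qmax = INT_MIN;
          for (size_t t = cl.first; t < cl.second; ++t) {
            smin = std::min(smin, seeds[t].spos);
            smax = std::max(smax, seeds[t].spos + seed_k);
            qmin = std::min(qmin, seeds[t].qpos);
            qmax = std::max(qmax, seeds[t].qpos + seed_k);
          }
          int slo = std::max(0, smin - qmin - pad);
          int shi = std::min((int)subj[si].size(), smax + (m - qmax) + pad);
          regs.push_back({slo, shi, dlo, dhi});
        }
        std::sort(regs.begin(), regs.end(),
                  [](const Region& a, const Region& b) { return a.slo < b.slo; });
        std::vector<Region> merged;
        for (auto& r : regs) {
          if (!merged.empty() && r.slo <= merged.back().shi) {
            merged.back().shi = std::max(merged.back().shi, r.shi);
            merged.back().dlo = std::min(merged.back().dlo, r.dlo);
            merged.back().dhi = std::max(merged.back().dhi, r.dhi);
          } else {
            merged.push_back(r);
          }
        }
        for (auto& r : merged) {
          std::string region = subj[si].substr(r.slo, r.shi - r.slo);
          Aln a = banded_sw(q, region, r.dlo - r.slo - band_pad,
                            r.dhi - r.slo + band_pad, match, mismatch,
                            gap_open, gap_ext);
          if (a.score <= 0 || a.columns < seed_k) continue;
          double pid = 100.0 * a.matches / a.columns;
          if (!(pid > min_identity)) continue;
          int qs, qe, ss, se;
          if (strand == 0) {
            qs = a.q_start; qe = a.q_end;
            ss = r.slo + a.s_start; se = r.slo + a.s_end;
          } else {
            qs = m - a.q_end + 1; qe = m - a.q_start + 1;
            ss = r.slo + a.s_end; se = r.slo + a.s_start;  // minus strand
          }
          r_qid.push_back(as<std::string>(qids[qi]));
          r_sid.push_back(as<std::string>(sids[si]));
          r_pident.push_back(pid);
          r_len.push_back(a.columns);
          r_mm.push_back(a.mismatches);
          r_go.push_back(a.gap_opens);
          r_qs.push_back(qs);
          r_qe.push_back(qe);
          r_ss.push_back(ss);
          r_se.push_back(se);
          r_score.push_back((double)a.score);
        }
      }
    }
  }
  return DataFrame::create(
      _["window_id"] = r_qid, _["subject_contig_id"] = r_sid,
      _["pct_identity"] = r_pident, _["aln_length"] = r_len,
      _["mismatches"] = r_mm, _["gap_opens"] = r_go, _["q_start"] = r_qs,
      _["q_end"] = r_qe, _["s_start"] = r_ss, _["s_end"] = r_se,
      _["score"] = r_score, _["stringsAsFactors"] = false);
}
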