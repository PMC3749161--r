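#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Mismatch count between equal-length strings, or -1 as soon as it exceeds maxmm.
static inline int hamming_bounded(const char *a, const char *b, int n, int maxmm) {
  if (maxmm < 0) return -1;
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      if (++mm > maxmm) return -1;
    }
  }
  return mm;
}

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// [[Rcpp::export]]
int hamming_bounded_cpp(std::string a, std::string b, int maxmm) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  return hamming_bounded(a.c_str(), b.c_str(), (int)a.size(), maxmm);
}

// Greedy representative clustering. `seqs` must already be in processing
// order (decreasing multiplicity, ties lexicographic); each sequence joins
// the first existing cluster whose representative (the cluster's founding
// sequence) is within max_mismatch substitutions, else founds a new cluster.
// Returns 1-based cluster ids in cluster-creation order.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, int max_mismatch) {
  if (max_mismatch < 0) stop("max_mismatch must be non-negative");
  int n = seqs.size();
  IntegerVector out(n);
  std::vector<std::string> reps;
  reps.reserve(1024);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int hit = -1;
    for (size_t j = 0; j < reps.size(); ++j) {
      if (reps[j].size() == s.size() &&
          hamming_bounded(reps[j].c_str(), s.c_str(), (int)s.size(), max_mismatch) >= 0) {
        hit = (int)j;
        break;
      }
    }
    if (hit < 0) {
      reps.push_back(s);
      hit = (int)reps.size() - 1;
    }
    out[i] = hit + 1;
  }
  return out;
}

// Per-column majority vote over weighted sequences; ties broken by the fixed
// base order A < C < G < T. Columns with no A/C/G/T evidence become 'N'.
// [[Rcpp::export]]
String consensus_vote_cpp(CharacterVector seqs, IntegerVector counts) {
  int n = seqs.size();
  if (n == 0) stop("cannot build a consensus from an empty cluster");
  if (counts.size() != n) stop("counts must parallel seqs");
  int L = (int)strlen(CHAR(STRING_ELT(seqs, 0)));
  std::vector<long> tab(4L * L, 0);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != L) stop("sequences must have equal length");
    long w = counts[i];
    for (int p = 0; p < L; ++p) {
      int b = base_index(s[p]);
      if (b >= 0) tab[4L * p + b] += w;
    }
  }
  const char *bases = "ACGT";
  std::string cons(L, 'N');
  for (int p = 0; p < L; ++p) {
    int best = -1;
    long bestc = 0;
    for (int b = 0; b < 4; ++b) {
      long c = tab[4L * p + b];
      if (c > bestc) { bestc = c; best = b; }
    }
    if (best >= 0) cons[p] = bases[best];
  }
  return cons;
}

// Paired end-to-end mapping at fixed offsets: forward mate against the
// reference forward segment, reverse mate against the reference reverse
// segment, total mismatches over both mates bounded by max_mismatch.
// Candidate references come from exact seed lookup on a fixed-length prefix
// of either mate; a full scan is the fallback when no seeded candidate is
// acceptable. Best hit = minimum mismatches, ties to the lowest reference
// index. Returns 1-based reference indices (NA when unmapped).
// [[Rcpp::export]]
List map_pairs_cpp(CharacterVector q_fwd, CharacterVector q_rev,
                   CharacterVector r_fwd, CharacterVector r_rev,
                   int max_mismatch, int seed_len) {
  int nq = q_fwd.size(), nr = r_fwd.size();
  if (q_rev.size() != nq) stop("query mates desynchronised");
  if (r_rev.size() != nr) stop("reference segments desynchronised");
  std::vector<std::string> rf(nr), rr(nr);
  std::unordered_multimap<std::string, int> idx_f, idx_r;
  idx_f.reserve(nr * 2);
  idx_r.reserve(nr * 2);
  for (int j = 0; j < nr; ++j) {
    rf[j] = as<std::string>(r_fwd[j]);
    rr[j] = as<std::string>(r_rev[j]);
    idx_f.emplace(rf[j].substr(0, seed_len), j);
    idx_r.emplace(rr[j].substr(0, seed_len), j);
  }
  IntegerVector locus(nq, NA_INTEGER), mism(nq, NA_INTEGER);
  std::vector<int> cand;
  cand.reserve(64);
  for (int i = 0; i < nq; ++i) {
    std::string qf = as<std::string>(q_fwd[i]);
    std::string qr = as<std::string>(q_rev[i]);
    int Lf = (int)qf.size(), Lr = (int)qr.size();
    int best = -1, bestmm = max_mismatch + 1;
    // evaluates reference j; strict improvement keeps the lowest index on ties
    // because candidates are visited in ascending index order
    const char *qfc = qf.c_str(), *qrc = qr.c_str();
    auto eval = [&](int j) {
      if ((int)rf[j].size() != Lf || (int)rr[j].size() != Lr) return;
      int m1 = hamming_bounded(rf[j].c_str(), qfc, Lf, bestmm - 1);
      if (m1 < 0) return;
      int m2 = hamming_bounded(rr[j].c_str(), qrc, Lr, bestmm - 1 - m1);
      if (m2 < 0) return;
      bestmm = m1 + m2;
      best = j;
    };
    cand.clear();
    auto range = idx_f.equal_range(qf.substr(0, seed_len));
    for (auto it = range.first; it != range.second; ++it) cand.push_back(it->second);
    range = idx_r.equal_range(qr.substr(0, seed_len));
    for (auto it = range.first; it != range.second; ++it) cand.push_back(it->second);
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int j : cand) eval(j);
    if (best < 0) {
      for (int j = 0; j < nr; ++j) eval(j);
    }
    if (best >= 0) {
      locus[i] = best + 1;
      mism[i] = bestmm;
    }
  }
  return List::create(_["locus"] = locus, _["mismatches"] = mism);
}

// Accumulates per (base, offset, founder, locus) read-pair counts. Offsets
// 0..read_length-1 are forward-mate positions, read_length..2*read_length-1
// reverse-mate positions (both in sequencing orientation). locus and founder
// are 1-based; locus may be NA (unmapped pair, skipped).
// [[Rcpp::export]]
IntegerVector tally_alleles_cpp(IntegerVector locus, IntegerVector founder,
                                CharacterVector fwd, CharacterVector rev,
                                int n_loci, int n_founders, int read_length) {
  int n = locus.size();
  int L = 2 * read_length;
  IntegerVector out((R_xlen_t)4 * L * n_founders * n_loci);
  for (int i = 0; i < n; ++i) {
    if (locus[i] == NA_INTEGER) continue;
    int lo = locus[i] - 1, fo = founder[i] - 1;
    if (lo < 0 || lo >= n_loci || fo < 0 || fo >= n_founders)
      stop("locus/founder index out of range");
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *r = CHAR(STRING_ELT(rev, i));
    R_xlen_t off0 = (((R_xlen_t)lo * n_founders) + fo) * L * 4;
    for (int p = 0; p < read_length; ++p) {
      int b = base_index(f[p]);
      if (b >= 0) out[off0 + 4L * p + b]++;
      int b2 = base_index(r[p]);
      if (b2 >= 0) out[off0 + 4L * (read_length + p) + b2]++;
    }
  }
  out.attr("dim") = IntegerVector::create(4, L, n_founders, n_loci);
  return out;
}

// Maximal pure tandem runs of 2-4 base motifs. For each motif length k the
// full-unit run count u(i) at position i satisfies u(i) = u(i+k)+1 when the
// unit at i equals the unit at i+k. A run is reported at its leftmost
// in-phase start (u(i-k) == 1 or i < k) when u(i) reaches the per-k
// threshold; motifs that are repeats of a shorter unit are excluded.
// Starts are 1-based. Phase-shifted duplicates of one physical run (rotated
// motifs) are deduplicated downstream.
// [[Rcpp::export]]
DataFrame find_strs_cpp(CharacterVector seqs, IntegerVector min_units) {
  if (min_units.size() != 3) stop("min_units must give thresholds for k = 2, 3, 4");
  std::vector<int> seq_idx, klen, start, units;
  std::vector<std::string> motifs;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    int L = (int)s.size();
    for (int k = 2; k <= 4; ++k) {
      int thr = min_units[k - 2];
      if (L < 2 * k || thr < 2) continue;
      std::vector<int> u(L, 0);
      for (int i = L - k; i >= 0; --i) {
        bool m = (i + 2 * k <= L);
        if (m) {
          for (int t = 0; t < k; ++t) {
            if (s[i + t] != s[i + k + t]) { m = false; break; }
          }
        }
        u[i] = m ? u[i + k] + 1 : 1;
      }
      for (int i = 0; i + k <= L; ++i) {
        if (u[i] < thr) continue;
        if (i >= k && u[i - k] != 1) continue; // not the leftmost in-phase start
        std::string motif = s.substr(i, k);
        bool bad = false;
        for (char c : motif) {
          if (base_index(c) < 0) { bad = true; break; }
        }
        if (bad) continue;
        bool subper = false;
        for (int d = 1; d < k && !subper; ++d) {
          if (k % d != 0) continue;
          bool all = true;
          for (int t = d; t < k; ++t) {
            if (motif[t] != motif[t % d]) { all = false; break; }
          }
          if (all) subper = true;
        }
        if (subper) continue;
        seq_idx.push_back(si + 1);
        klen.push_back(k);
        start.push_back(i + 1);
        units.push_back(u[i]);
        motifs.push_back(motif);
      }
    }
  }
  return DataFrame::create(_["seq_index"] = seq_idx, _["motif_len"] = klen,
                           _["start"] = start, _["n_units"] = units,
                           _["motif"] = motifs, _["stringsAsFactors"] = false);
}
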