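#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit DNA encoding; supports k up to 31 in a uint64_t.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Collect the encoded k-mers of one sequence via a rolling window;
// windows containing a non-ACGT base are skipped.
template <typename F>
static void roll_kmers(const char* s, size_t n, int k, F&& emit) {
  if ((int)n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;  // length of current valid base run
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) emit((size_t)(i + 1 - k), code);
  }
}

// [[Rcpp::export]]
List cpp_enumerate_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  size_t total_len = 0;
  for (int si = 0; si < seqs.size(); ++si) total_len += LENGTH(STRING_ELT(seqs, si));
  std::unordered_map<uint64_t, int> ids;
  ids.reserve(total_len / 4);
  std::vector<uint64_t> codes;
  std::vector<double> totals;
  std::vector<int> occ_seq, occ_kmer, occ_pos;
  occ_seq.reserve(total_len); occ_kmer.reserve(total_len); occ_pos.reserve(total_len);
  for (int si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    size_t n = LENGTH(STRING_ELT(seqs, si));
    roll_kmers(s, n, k, [&](size_t pos, uint64_t code) {
      auto it = ids.find(code);
      int id;
      if (it == ids.end()) {
        id = (int)codes.size();
        ids.emplace(code, id);
        codes.push_back(code);
        totals.push_back(0.0);
      } else id = it->second;
      totals[id] += 1.0;
      occ_seq.push_back(si + 1);
      occ_kmer.push_back(id + 1);
      occ_pos.push_back((int)pos);
    });
  }
  CharacterVector kmers(codes.size());
  for (size_t i = 0; i < codes.size(); ++i)
    kmers[i] = decode_kmer(codes[i], k);
  return List::create(_["kmer"] = kmers,
                      _["count"] = NumericVector(totals.begin(), totals.end()),
                      _["occ_seq"] = IntegerVector(occ_seq.begin(), occ_seq.end()),
                      _["occ_kmer"] = IntegerVector(occ_kmer.begin(), occ_kmer.end()),
                      _["occ_pos"] = IntegerVector(occ_pos.begin(), occ_pos.end()));
}

static uint64_t encode_or_die(const char* s, int k, bool* ok) {
  uint64_t code = 0;
  *ok = true;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { *ok = false; return 0; }
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

// Greedy one-mismatch clustering. K-mers are scanned in the given order; a
// k-mer joins the earliest-founded cluster whose *representative* is within
// Hamming distance 1, else it founds a new cluster. Representatives end up
// pairwise at Hamming distance >= 2, so membership is checked by probing the
// 3k+1 point-mutation neighbourhood of the incoming k-mer against the
// representative hash.
// [[Rcpp::export]]
List cpp_cluster_kmers(CharacterVector kmers, int k) {
  int n = kmers.size();
  std::unordered_map<uint64_t, int> reps;  // rep code -> cluster index (0-based)
  reps.reserve((size_t)n / 2);
  std::vector<int> assign(n);
  std::vector<int> rep_idx;  // index into kmers of each cluster's representative
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer %d has length != k", i + 1);
    bool ok;
    uint64_t code = encode_or_die(s, k, &ok);
    if (!ok) stop("k-mer %d contains a non-ACGT base", i + 1);
    int best = -1;
    auto probe = [&](uint64_t c) {
      auto it = reps.find(c);
      if (it != reps.end() && (best < 0 || it->second < best)) best = it->second;
    };
    probe(code);
    for (int pos = 0; pos < k; ++pos) {
      uint64_t shift = 2ULL * (uint64_t)(k - 1 - pos);
      uint64_t cur = (code >> shift) & 3ULL;
      for (uint64_t b = 0; b < 4; ++b) {
        if (b == cur) continue;
        probe((code & ~(3ULL << shift)) | (b << shift));
      }
    }
    if (best < 0) {
      best = (int)rep_idx.size();
      rep_idx.push_back(i + 1);
      reps.emplace(code, best);
    }
    assign[i] = best + 1;
  }
  return List::create(_["cluster"] = IntegerVector(assign.begin(), assign.end()),
                      _["rep_idx"] = IntegerVector(rep_idx.begin(), rep_idx.end()));
}

// Assign k-mers to existing clusters (by representative, Hamming <= 1,
// earliest cluster wins); 0 = unassigned. Used to project held-out promoters
// onto clusters learned from training promoters.
// [[Rcpp::export]]
IntegerVector cpp_assign_kmers(CharacterVector reps, CharacterVector kmers, int k) {
  std::unordered_map<uint64_t, int> rep_map;
  for (int i = 0; i < reps.size(); ++i) {
    bool ok;
    uint64_t code = encode_or_die(CHAR(STRING_ELT(reps, i)), k, &ok);
    if (!ok) stop("representative %d contains a non-ACGT base", i + 1);
    auto it = rep_map.find(code);
    if (it == rep_map.end()) rep_map.emplace(code, i);
  }
  int n = kmers.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    bool ok;
    uint64_t code = encode_or_die(CHAR(STRING_ELT(kmers, i)), k, &ok);
    if (!ok) { out[i] = 0; continue; }
    int best = -1;
    auto probe = [&](uint64_t c) {
      auto it = rep_map.find(c);
      if (it != rep_map.end() && (best < 0 || it->second < best)) best = it->second;
    };
    probe(code);
    for (int pos = 0; pos < k; ++pos) {
      uint64_t shift = 2ULL * (uint64_t)(k - 1 - pos);
      uint64_t cur = (code >> shift) & 3ULL;
      for (uint64_t b = 0; b < 4; ++b) {
        if (b == cur) continue;
        probe((code & ~(3ULL << shift)) | (b << shift));
      }
    }
    out[i] = best + 1;  // 0 when unassigned
  }
  return out;
}

static void unique_codes(const char* s, size_t n, int k, std::unordered_set<uint64_t>& out) {
  roll_kmers(s, n, k, [&](size_t, uint64_t code) { out.insert(code); });
}

// Number of distinct k-mers shared by two sequences (alignment-free
// similarity; N-containing windows excluded).
// [[Rcpp::export]]
double cpp_shared_kmers(CharacterVector a, CharacterVector b, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> sa, sb;
  unique_codes(CHAR(STRING_ELT(a, 0)), LENGTH(STRING_ELT(a, 0)), k, sa);
  unique_codes(CHAR(STRING_ELT(b, 0)), LENGTH(STRING_ELT(b, 0)), k, sb);
  if (sb.size() < sa.size()) sa.swap(sb);
  double shared = 0;
  for (uint64_t c : sa) if (sb.count(c)) shared += 1;
  return shared;
}

// Aggregate per-(row, cluster) occurrence counts in one pass.
// occ_seq/occ_kmer: per-occurrence promoter index (1-based) and k-mer index
// (1-based); cl_of_kmer: cluster per unique k-mer (0 = unclustered);
// row_of_seq: X row per promoter (0 = dropped). Returns triplets plus the
// per-cluster number of distinct rows (prevalence numerator).
// [[Rcpp::export]]
List cpp_count_pairs(const IntegerVector& occ_seq, const IntegerVector& occ_kmer,
                     const IntegerVector& cl_of_kmer, const IntegerVector& row_of_seq,
                     int n_clusters) {
  // occurrences arrive grouped by promoter (enumeration order), so counts
  // accumulate in a per-cluster scratch array flushed at each promoter
  // boundary; no hashing needed
  const R_xlen_t n = occ_seq.size();
  std::vector<int> scratch(n_clusters, 0), touched;
  std::vector<int> ri, ci, nn;
  ri.reserve(n / 4); ci.reserve(n / 4); nn.reserve(n / 4);
  std::vector<int> prevalence(n_clusters, 0);
  int cur_seq = -1, cur_row = 0;
  auto flush = [&]() {
    if (cur_row > 0) {
      for (int cl : touched) {
        ri.push_back(cur_row);
        ci.push_back(cl);
        nn.push_back(scratch[cl - 1]);
        prevalence[cl - 1] += 1;
        scratch[cl - 1] = 0;
      }
    } else {
      for (int cl : touched) scratch[cl - 1] = 0;
    }
    touched.clear();
  };
  for (R_xlen_t t = 0; t < n; ++t) {
    const int sq = occ_seq[t];
    if (sq != cur_seq) {
      if (sq < cur_seq) stop("occurrences must be grouped by promoter");
      flush();
      cur_seq = sq;
      cur_row = row_of_seq[sq - 1];
    }
    if (cur_row == 0) continue;
    const int cl = cl_of_kmer[occ_kmer[t] - 1];
    if (cl == 0) continue;
    if (scratch[cl - 1] == 0) touched.push_back(cl);
    scratch[cl - 1] += 1;
  }
  flush();
  return List::create(_["row"] = IntegerVector(ri.begin(), ri.end()),
                      _["cluster"] = IntegerVector(ci.begin(), ci.end()),
                      _["n"] = IntegerVector(nn.begin(), nn.end()),
                      _["prevalence"] = IntegerVector(prevalence.begin(), prevalence.end()));
}

// [[Rcpp::export]]
double cpp_n_unique_kmers(CharacterVector a, int k) {
  std::unordered_set<uint64_t> sa;
  unique_codes(CHAR(STRING_ELT(a, 0)), LENGTH(STRING_ELT(a, 0)), k, sa);
  return (double)sa.size();
}
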