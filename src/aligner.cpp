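#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Seed index + ungapped end-to-end aligner. Seeds are 2-bit encoded k-mers;
// windows containing non-ACGT letters are skipped (a read block that matches
// exactly can contain neither N in the read nor N in the reference, so
// skipping them does not break the pigeonhole completeness guarantee).

namespace {

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > table;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

bool encode_seed(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// N (or any non-ACGT letter) on either side counts as a mismatch.
inline int count_mm(const std::string& ref, int32_t start, const std::string& q,
                    int cap) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    char a = ref[start + i], b = q[i];
    if (a != b || base_code(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector names, CharacterVector seqs, int seed_len) {
  SeedIndex* idx = new SeedIndex();
  idx->k = seed_len;
  for (int ci = 0; ci < names.size(); ++ci) {
    idx->names.push_back(as<std::string>(names[ci]));
    idx->seqs.push_back(as<std::string>(seqs[ci]));
  }
  for (int ci = 0; ci < (int)idx->seqs.size(); ++ci) {
    const std::string& s = idx->seqs[ci];
    int n = (int)s.size();
    for (int p = 0; p + seed_len <= n; ++p) {
      uint64_t v;
      if (encode_seed(s.c_str() + p, seed_len, v))
        idx->table[v].push_back(std::make_pair((int32_t)ci, (int32_t)p));
    }
  }
  XPtr<SeedIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
DataFrame cpp_index_query(SEXP xp_, std::string seed) {
  XPtr<SeedIndex> xp(xp_);
  std::vector<int> contig, pos;
  uint64_t v;
  if ((int)seed.size() == xp->k && encode_seed(seed.c_str(), xp->k, v)) {
    std::unordered_map<uint64_t,
                       std::vector<std::pair<int32_t, int32_t> > >::iterator it =
        xp->table.find(v);
    if (it != xp->table.end()) {
      for (size_t i = 0; i < it->second.size(); ++i) {
        contig.push_back(it->second[i].first + 1);
        pos.push_back(it->second[i].second);
      }
    }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos);
}

// [[Rcpp::export]]
CharacterVector cpp_index_contigs(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return wrap(xp->names);
}

// All end-to-end placements of each read (both strands) with at most
// max_mismatch mismatches. Candidates come from m+1 block seeds per strand;
// with seed_len <= floor(L / (m+1)) the search is complete by pigeonhole.
// Reads too short for that guarantee fall back to an exhaustive scan, so
// the hit set is complete for every read length.
// [[Rcpp::export]]
DataFrame cpp_align(SEXP xp_, CharacterVector reads, int max_mismatch) {
  XPtr<SeedIndex> xp(xp_);
  const int k = xp->k;
  std::vector<int> o_read, o_contig, o_start, o_mm;
  std::vector<int> o_fwd;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    std::string rev = revcomp_str(fwd);
    int B = max_mismatch + 1;
    int block = L / B;
    if (k > block) {
      // exhaustive scan over every placement
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = (strand == 0) ? fwd : rev;
        for (int ci = 0; ci < (int)xp->seqs.size(); ++ci) {
          int64_t last = (int64_t)xp->seqs[ci].size() - L;
          for (int64_t st = 0; st <= last; ++st) {
            int mm = count_mm(xp->seqs[ci], (int32_t)st, q, max_mismatch);
            if (mm <= max_mismatch) {
              o_read.push_back(ri + 1);
              o_contig.push_back(ci + 1);
              o_start.push_back((int)st);
              o_fwd.push_back(strand == 0 ? 1 : 0);
              o_mm.push_back(mm);
            }
          }
        }
      }
      continue;
    }
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? fwd : rev;
      std::unordered_set<uint64_t> seen;
      for (int b = 0; b < B; ++b) {
        int off = b * block;
        if (off + k > L) off = L - k;
        uint64_t v;
        if (!encode_seed(q.c_str() + off, k, v)) continue;
        std::unordered_map<uint64_t,
                           std::vector<std::pair<int32_t, int32_t> > >::iterator
            it = xp->table.find(v);
        if (it == xp->table.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int ci = it->second[h].first;
          int64_t st = (int64_t)it->second[h].second - off;
          if (st < 0 || st + L > (int64_t)xp->seqs[ci].size()) continue;
          uint64_t key = ((uint64_t)ci << 40) | (uint64_t)st;
          if (!seen.insert(key).second) continue;
          int mm = count_mm(xp->seqs[ci], (int32_t)st, q, max_mismatch);
          if (mm <= max_mismatch) {
            o_read.push_back(ri + 1);
            o_contig.push_back(ci + 1);
            o_start.push_back((int)st);
            o_fwd.push_back(strand == 0 ? 1 : 0);
            o_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                           _["start"] = o_start, _["fwd"] = o_fwd,
                           _["mismatches"] = o_mm);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}
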