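#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// k-mer index over a set of chromosome sequences. Positions are 0-based.
// k-mers containing any non-ACGT character are not indexed.
struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<std::string, std::vector<std::pair<int, int> > > tab;
};

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector names, CharacterVector seqs, int k) {
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  xp->k = k;
  for (int i = 0; i < names.size(); ++i) {
    xp->names.push_back(as<std::string>(names[i]));
    xp->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (size_t ci = 0; ci < xp->seqs.size(); ++ci) {
    const std::string& s = xp->seqs[ci];
    if ((int)s.size() < k) continue;
    int n_ambig = 0;  // count of non-ACGT in current window
    for (int j = 0; j < k - 1; ++j) if (!is_acgt(s[j])) n_ambig++;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      if (!is_acgt(s[i + k - 1])) n_ambig++;
      if (n_ambig == 0) {
        xp->tab[s.substr(i, k)].push_back(std::make_pair((int)ci, (int)i));
      }
      if (!is_acgt(s[i])) n_ambig--;
    }
  }
  return xp;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xptr) {
  XPtr<KmerIndex> xp(xptr);
  if (!xp) return -1;
  return xp->k;
}

// [[Rcpp::export]]
DataFrame cpp_index_query(SEXP xptr, std::string kmer) {
  XPtr<KmerIndex> xp(xptr);
  std::vector<int> ci;
  std::vector<int> pos;
  std::unordered_map<std::string, std::vector<std::pair<int, int> > >::iterator it =
      xp->tab.find(kmer);
  if (it != xp->tab.end()) {
    for (size_t i = 0; i < it->second.size(); ++i) {
      ci.push_back(it->second[i].first + 1);
      pos.push_back(it->second[i].second);
    }
  }
  return DataFrame::create(Named("chrom_i") = wrap(ci), Named("pos") = wrap(pos));
}

struct Candidate {
  int chrom;
  int pos;
  int strand;  // 0 = '+', 1 = '-'
  bool operator<(const Candidate& o) const {
    if (chrom != o.chrom) return chrom < o.chrom;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
  bool operator==(const Candidate& o) const {
    return chrom == o.chrom && pos == o.pos && strand == o.strand;
  }
};

// Hamming distance capped at `cap` (returns cap + 1 when exceeded).
static int hamming_capped(const std::string& ref, int pos, const std::string& read, int cap) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    if (ref[pos + i] != read[i]) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

// Seed-and-extend mapping of reads against an indexed genome.
// Candidates come from every seed hit of every read k-mer on both strands;
// each candidate is scored by full-length Hamming distance (ungapped).
// Ties at the best score: lowest (chrom, pos, strand) wins, unless
// unique_best, in which case an ambiguous best leaves the read unmapped.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xptr, CharacterVector ids, CharacterVector seqs,
                        int max_mismatches, bool unique_best) {
  XPtr<KmerIndex> xp(xptr);
  const int k = xp->k;
  const int n = seqs.size();

  CharacterVector out_chrom(n);
  IntegerVector out_pos(n);
  CharacterVector out_strand(n);
  IntegerVector out_mm(n);
  LogicalVector out_mapped(n);

  std::vector<Candidate> cands;
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(seqs[r]);
    const int len = (int)fwd.size();
    out_mapped[r] = false;
    out_chrom[r] = NA_STRING;
    out_pos[r] = NA_INTEGER;
    out_strand[r] = NA_STRING;
    out_mm[r] = NA_INTEGER;
    if (len < k) continue;
    std::string rev = revcomp_str(fwd);
    const std::string* oriented[2] = { &fwd, &rev };

    cands.clear();
    for (int st = 0; st < 2; ++st) {
      const std::string& q = *oriented[st];
      int n_ambig = 0;
      for (int j = 0; j < k - 1; ++j) if (!is_acgt(q[j])) n_ambig++;
      for (int off = 0; off + k <= len; ++off) {
        if (!is_acgt(q[off + k - 1])) n_ambig++;
        if (n_ambig == 0) {
          std::unordered_map<std::string, std::vector<std::pair<int, int> > >::iterator it =
              xp->tab.find(q.substr(off, k));
          if (it != xp->tab.end()) {
            for (size_t h = 0; h < it->second.size(); ++h) {
              int ci = it->second[h].first;
              int pos = it->second[h].second - off;
              if (pos < 0 || pos + len > (int)xp->seqs[ci].size()) continue;
              Candidate c;
              c.chrom = ci; c.pos = pos; c.strand = st;
              cands.push_back(c);
            }
          }
        }
        if (!is_acgt(q[off])) n_ambig--;
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best = max_mismatches + 1;
    int best_i = -1;
    int n_best = 0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Candidate& c = cands[ci];
      int mm = hamming_capped(xp->seqs[c.chrom], c.pos, *oriented[c.strand], max_mismatches);
      if (mm < best) {
        best = mm;
        best_i = (int)ci;
        n_best = 1;
      } else if (mm == best && best <= max_mismatches) {
        n_best++;
      }
    }
    if (best > max_mismatches) continue;
    if (unique_best && n_best > 1) continue;
    const Candidate& b = cands[best_i];
    out_chrom[r] = xp->names[b.chrom];
    out_pos[r] = b.pos;
    out_strand[r] = b.strand == 0 ? "+" : "-";
    out_mm[r] = best;
    out_mapped[r] = true;
  }

  return DataFrame::create(
      Named("read_id") = ids,
      Named("chrom") = out_chrom,
      Named("pos") = out_pos,
      Named("strand") = out_strand,
      Named("n_mismatches") = out_mm,
      Named("mapped") = out_mapped,
      Named("stringsAsFactors") = false);
}

// Per-position base counts from ungapped alignments.
// Returns, per chromosome, a 5 x L integer matrix with rows A, C, G, T, other.
// `chrom_idx` is 1-based into `chrom_len`; `pos0` is the 0-based leftmost
// position; `seqs` are reference-forward oriented read sequences.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector chrom_len, IntegerVector chrom_idx,
                IntegerVector pos0, CharacterVector seqs) {
  const int n_chrom = chrom_len.size();
  List out(n_chrom);
  std::vector<IntegerMatrix> mats;
  for (int c = 0; c < n_chrom; ++c) {
    IntegerMatrix m(5, chrom_len[c]);
    out[c] = m;
    mats.push_back(m);
  }
  for (int i = 0; i < seqs.size(); ++i) {
    if (chrom_idx[i] == NA_INTEGER) continue;
    int c = chrom_idx[i] - 1;
    int p = pos0[i];
    std::string s = as<std::string>(seqs[i]);
    IntegerMatrix& m = mats[c];
    for (size_t j = 0; j < s.size(); ++j) {
      int row;
      switch (s[j]) {
        case 'A': row = 0; break;
        case 'C': row = 1; break;
        case 'G': row = 2; break;
        case 'T': row = 3; break;
        default:  row = 4; break;
      }
      m(row, p + (int)j)++;
    }
  }
  return out;
}
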