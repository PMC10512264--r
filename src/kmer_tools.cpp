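#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding A=0 C=1 G=2 T=3; canonical k-mer = min(forward, reverse
// complement). Codes are returned as doubles, exact for k <= 25 (2k <= 50
// bits < 2^53); callers enforce the k range.

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// canonical code at every start position; NA where the window hits a non-ACGT
static void canon_codes(const char *s, int n, int k, std::vector<double> &out) {
  out.clear();
  if (n < k) return;
  out.resize(n - k + 1, NA_REAL);
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < n; i++) {
    int b = base2code(s[i]);
    if (b < 0) {
      valid = 0; fwd = 0; rev = 0;
    } else {
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      valid++;
    }
    if (i >= k - 1 && valid >= k)
      out[i - k + 1] = (double)(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
NumericVector cpp_canonical_codes(std::string seq, int k) {
  std::vector<double> v;
  canon_codes(seq.c_str(), (int)seq.size(), k, v);
  return NumericVector(v.begin(), v.end());
}

// exact canonical k-mer counting with an occurrence threshold
// [[Rcpp::export]]
NumericVector cpp_count_kmers(CharacterVector seqs, int k, int min_count) {
  std::unordered_map<uint64_t, int> counts;
  std::vector<double> v;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    canon_codes(s, (int)LENGTH(STRING_ELT(seqs, i)), k, v);
    for (double d : v) if (!ISNA(d)) counts[(uint64_t)d]++;
  }
  std::vector<double> keep;
  keep.reserve(counts.size());
  for (auto &kv : counts)
    if (kv.second >= min_count) keep.push_back((double)kv.first);
  std::sort(keep.begin(), keep.end());
  return NumericVector(keep.begin(), keep.end());
}

struct IdxEntry { int sp; int chrom; int pos; };

// diagnostic index: k-mers occurring in exactly one species, with the first
// occurrence position; species/chrom are 1-based codes assigned by the caller
// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, IntegerVector species,
                     IntegerVector chrom, int k) {
  std::unordered_map<uint64_t, IdxEntry> map;
  std::vector<double> v;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int sp = species[i], ch = chrom[i];
    canon_codes(s, (int)LENGTH(STRING_ELT(seqs, i)), k, v);
    for (int p = 0; p < (int)v.size(); p++) {
      if (ISNA(v[p])) continue;
      uint64_t code = (uint64_t)v[p];
      auto it = map.find(code);
      if (it == map.end()) {
        map[code] = IdxEntry{sp, ch, p};
      } else if (it->second.sp != sp) {
        it->second.sp = -1;  // shared across species -> ambiguous
      }
    }
  }
  double n_amb = 0;
  std::vector<std::pair<uint64_t, IdxEntry> > diag;
  diag.reserve(map.size());
  for (auto &kv : map) {
    if (kv.second.sp < 0) n_amb += 1;
    else diag.push_back(kv);
  }
  std::sort(diag.begin(), diag.end(),
            [](const std::pair<uint64_t, IdxEntry> &a,
               const std::pair<uint64_t, IdxEntry> &b) {
              return a.first < b.first;
            });
  R_xlen_t n = (R_xlen_t)diag.size();
  NumericVector keys(n);
  IntegerVector sp(n), ch(n), pos(n);
  for (R_xlen_t i = 0; i < n; i++) {
    keys[i] = (double)diag[i].first;
    sp[i] = diag[i].second.sp;
    ch[i] = diag[i].second.chrom;
    pos[i] = diag[i].second.pos;
  }
  return List::create(_["keys"] = keys, _["species"] = sp, _["chrom"] = ch,
                      _["pos"] = pos, _["ambiguous_count"] = n_amb,
                      _["n_distinct"] = (double)map.size());
}

// count distinct k-mers of one sequence set and how many of them occur in a
// sorted key vector (used for diagnostic-fraction diagnostics)
// [[Rcpp::export]]
NumericVector cpp_distinct_in_keys(CharacterVector seqs, int k,
                                   NumericVector keys) {
  std::unordered_map<uint64_t, char> seen;
  std::vector<double> v;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    canon_codes(s, (int)LENGTH(STRING_ELT(seqs, i)), k, v);
    for (double d : v) if (!ISNA(d)) seen[(uint64_t)d] = 1;
  }
  double hit = 0;
  for (auto &kv : seen) {
    double d = (double)kv.first;
    if (std::binary_search(keys.begin(), keys.end(), d)) hit += 1;
  }
  return NumericVector::create((double)seen.size(), hit);
}

// assign each read by counting diagnostic hits per species
// species out: 0 = unassigned, -1 = ambiguous, else 1..n_species
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, NumericVector keys,
                      IntegerVector key_sp, IntegerVector key_chrom,
                      IntegerVector key_pos, int k, int n_species,
                      int min_hits, int min_margin) {
  R_xlen_t n = reads.size();
  IntegerVector out_sp(n), out_chrom(n), out_pos(n), out_hits(n), out_margin(n);
  std::vector<int> hits(n_species + 1);
  std::vector<int> f_pos(n_species + 1), f_chrom(n_species + 1),
      f_off(n_species + 1);
  std::vector<double> v;
  std::unordered_map<uint64_t, R_xlen_t> lut;
  lut.reserve((size_t)(keys.size() * 1.4));
  for (R_xlen_t i = 0; i < keys.size(); i++) lut[(uint64_t)keys[i]] = i;
  for (R_xlen_t i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    std::fill(hits.begin(), hits.end(), 0);
    std::fill(f_pos.begin(), f_pos.end(), -1);
    canon_codes(s, len, k, v);
    for (int o = 0; o < (int)v.size(); o++) {
      if (ISNA(v[o])) continue;
      auto it = lut.find((uint64_t)v[o]);
      if (it != lut.end()) {
        R_xlen_t idx = it->second;
        int sp = key_sp[idx];
        hits[sp]++;
        if (f_pos[sp] < 0) {
          f_pos[sp] = key_pos[idx];
          f_chrom[sp] = key_chrom[idx];
          f_off[sp] = o;
        }
      }
    }
    int top = 0, top_sp = 0, second = 0;
    for (int sp = 1; sp <= n_species; sp++) {
      if (hits[sp] > top) { second = top; top = hits[sp]; top_sp = sp; }
      else if (hits[sp] > second) second = hits[sp];
    }
    out_hits[i] = top;
    out_margin[i] = top - second;
    if (top == 0) {
      out_sp[i] = 0; out_chrom[i] = NA_INTEGER; out_pos[i] = NA_INTEGER;
    } else if (top < min_hits || (top - second) < min_margin) {
      out_sp[i] = -1; out_chrom[i] = NA_INTEGER; out_pos[i] = NA_INTEGER;
    } else {
      out_sp[i] = top_sp;
      out_chrom[i] = f_chrom[top_sp];
      out_pos[i] = f_pos[top_sp] - f_off[top_sp];
    }
  }
  return List::create(_["species"] = out_sp, _["chrom"] = out_chrom,
                      _["pos"] = out_pos, _["n_hits"] = out_hits,
                      _["margin"] = out_margin);
}

// size of the intersection of two sorted double vectors
// [[Rcpp::export]]
double cpp_intersect_size(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) i++;
    else if (a[i] > b[j]) j++;
    else { n += 1; i++; j++; }
  }
  return n;
}

// extract substrings as reads, applying uniform substitution errors with the
// R RNG (so set.seed() governs the output)
// [[Rcpp::export]]
CharacterVector cpp_extract_reads(std::string seq, IntegerVector starts,
                                  int read_len, double error_rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = starts.size();
  CharacterVector out(n);
  std::string buf(read_len, 'N');
  for (R_xlen_t i = 0; i < n; i++) {
    int s = starts[i];
    for (int j = 0; j < read_len; j++) {
      char c = seq[s + j];
      if (error_rate > 0 && unif_rand() < error_rate) {
        int b = base2code(c);
        int r = (int)(unif_rand() * 3.0);
        if (r > 2) r = 2;
        c = BASES[(b + 1 + r) & 3];
      }
      buf[j] = c;
    }
    out[i] = buf;
  }
  return out;
}

// per-marker allele counts from placed reads of one chromosome
// marker_pos sorted ascending, 0-based; read_pos 0-based placements
// [[Rcpp::export]]
List cpp_count_alleles(CharacterVector reads, IntegerVector read_pos,
                       IntegerVector marker_pos, CharacterVector a1,
                       CharacterVector a2) {
  R_xlen_t nm = marker_pos.size();
  IntegerVector n1(nm), n2(nm);
  std::vector<char> c1(nm), c2(nm);
  for (R_xlen_t m = 0; m < nm; m++) {
    c1[m] = CHAR(STRING_ELT(a1, m))[0];
    c2[m] = CHAR(STRING_ELT(a2, m))[0];
  }
  const int *mp = INTEGER(marker_pos);
  for (R_xlen_t i = 0; i < reads.size(); i++) {
    int p = read_pos[i];
    if (p == NA_INTEGER) continue;
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    const int *lo = std::lower_bound(mp, mp + nm, p);
    for (const int *m = lo; m < mp + nm && *m < p + len; m++) {
      R_xlen_t mi = m - mp;
      char c = s[*m - p];
      if (c == c1[mi]) n1[mi]++;
      else if (c == c2[mi]) n2[mi]++;
    }
  }
  return List::create(_["depth_p1"] = n1, _["depth_p2"] = n2);
}
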