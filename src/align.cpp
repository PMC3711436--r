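#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include <cstdint>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

struct Aln {
  bool found = false;
  int score = INT_MIN;
  int read_start = 0, read_end = 0;   // 0-based half-open span of aligned read bases
  int ref_start = 0, ref_end = 0;     // 0-based half-open contig coordinates
  int nsub = 0, nins = 0, ndel = 0, ncols = 0;
  std::string aread, aref;            // aligned region only, '-' for gaps
};

// Fit alignment of a full read against ref[ws, we): reference-side end gaps are
// always free (the read lands anywhere in the window); read-side end gaps are
// free only when the window edge is a true contig edge (free_left / free_right),
// producing unpenalised overhangs there. N matches nothing.
static Aln aln_window(const std::string& read, const std::string& ref,
                      int ws, int we, bool free_left, bool free_right,
                      int ma, int mi, int go) {
  int m = (int)read.size(), w = we - ws;
  Aln res;
  if (m == 0 || w <= 0) return res;
  std::vector<int> H((size_t)(m + 1) * (w + 1));
  std::vector<unsigned char> D((size_t)(m + 1) * (w + 1));
  auto at = [&](int i, int j) { return (size_t)i * (w + 1) + j; };
  for (int j = 0; j <= w; ++j) { H[at(0, j)] = 0; D[at(0, j)] = 0; }
  for (int i = 1; i <= m; ++i) {
    H[at(i, 0)] = free_left ? 0 : i * go;
    D[at(i, 0)] = free_left ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    char rc = read[i - 1];
    for (int j = 1; j <= w; ++j) {
      char cc = ref[ws + j - 1];
      int sub = (rc == cc && rc != 'N') ? ma : mi;
      int best = H[at(i - 1, j - 1)] + sub;
      unsigned char d = 1;
      int up = H[at(i - 1, j)] + go;    // read base against ref gap (insertion)
      if (up > best) { best = up; d = 2; }
      int lf = H[at(i, j - 1)] + go;    // ref base against read gap (deletion)
      if (lf > best) { best = lf; d = 3; }
      H[at(i, j)] = best;
      D[at(i, j)] = d;
    }
  }
  int bi = m, bj = 0, bs = INT_MIN;
  for (int j = 0; j <= w; ++j) {
    int v = H[at(m, j)];
    if (v > bs) { bs = v; bi = m; bj = j; }
  }
  if (free_right) {
    for (int i = 0; i <= m; ++i) {
      int v = H[at(i, w)];
      if (v > bs) { bs = v; bi = i; bj = w; }
    }
  }
  // traceback
  std::string ar, af;
  int i = bi, j = bj;
  while (i > 0 && D[at(i, j)] != 0) {
    unsigned char d = D[at(i, j)];
    if (d == 1) { ar += read[i - 1]; af += ref[ws + j - 1]; --i; --j; }
    else if (d == 2) { ar += read[i - 1]; af += '-'; --i; }
    else { ar += '-'; af += ref[ws + j - 1]; --j; }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(af.begin(), af.end());
  res.found = true;
  res.score = bs;
  res.read_start = i;
  res.read_end = bi;
  res.ref_start = ws + j;
  res.ref_end = ws + bj;
  res.aread = ar;
  res.aref = af;
  for (size_t c = 0; c < ar.size(); ++c) {
    if (ar[c] == '-') ++res.ndel;
    else if (af[c] == '-') ++res.nins;
    else if (ar[c] != af[c] || ar[c] == 'N') ++res.nsub;
  }
  res.ncols = (int)ar.size();
  return res;
}

static List aln_to_list(const Aln& a, const std::string& strand) {
  return List::create(
    _["found"] = a.found, _["score"] = a.score, _["strand"] = strand,
    _["read_start"] = a.read_start, _["read_end"] = a.read_end,
    _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
    _["nsub"] = a.nsub, _["nins"] = a.nins, _["ndel"] = a.ndel,
    _["overlap_len"] = a.ncols, _["aln_read"] = a.aread, _["aln_ref"] = a.aref);
}

// Full (unbanded) overlap alignment of one oriented read against a contig:
// free end gaps on the reference and at read ends that hang off contig edges.
// [[Rcpp::export]]
List cpp_overlap_align(std::string read, std::string ref,
                       int ma = 1, int mi = -1, int go = -2) {
  Aln a = aln_window(read, ref, 0, (int)ref.size(), true, true, ma, mi, go);
  return aln_to_list(a, "+");
}

// better-placement comparator: score desc, then ref_start asc, then '+' strand
static bool better(const Aln& a, bool a_plus, const Aln& b, bool b_plus) {
  if (!b.found) return a.found;
  if (!a.found) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
  return a_plus && !b_plus;
}

// Seed-and-extend placement of many reads on one contig. Exact k_anchor-mers of
// the oriented read hitting the contig define candidate diagonals; windows of
// +/- pad around each diagonal cluster are aligned exhaustively.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string contig,
                        int k_anchor, int pad,
                        int ma = 1, int mi = -1, int go = -2,
                        int max_clusters = 8) {
  int n = (int)contig.size();
  if (k_anchor < 1 || k_anchor > 31) stop("k_anchor must be in [1, 31]");
  if (n < k_anchor) stop("contig shorter than anchor k-mer");
  // forward (strand-specific) k-mer -> positions
  std::unordered_map<uint64_t, std::vector<int>> pos;
  pos.reserve(n * 2);
  {
    uint64_t mask = (1ULL << (2 * k_anchor)) - 1, code = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b;
      switch (contig[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: b = -1;
      }
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k_anchor) {
        auto& v = pos[code];
        if ((int)v.size() < 100) v.push_back(i - k_anchor + 1);
      }
    }
  }
  R_xlen_t nr = reads.size();
  LogicalVector found(nr);
  CharacterVector strand(nr), aln_read(nr), aln_ref(nr);
  IntegerVector score(nr), read_start(nr), read_end(nr),
    ref_start(nr), ref_end(nr), nsub(nr), nins(nr), ndel(nr), overlap_len(nr);

  std::vector<int> diags;
  for (R_xlen_t r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    Aln best;
    bool best_plus = true;
    for (int s = 0; s < 2; ++s) {
      const std::string oriented = (s == 0) ? fwd : revcomp(fwd);
      int m = (int)oriented.size();
      if (m < k_anchor) continue;
      diags.clear();
      uint64_t mask = (1ULL << (2 * k_anchor)) - 1, code = 0;
      int run = 0;
      for (int i = 0; i < m; ++i) {
        int b;
        switch (oriented[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
        }
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= k_anchor) {
          auto it = pos.find(code);
          if (it != pos.end())
            for (int p : it->second) diags.push_back(p - (i - k_anchor + 1));
        }
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      // cluster diagonals within pad of each other
      struct Clu { int dmin, dmax, count; };
      std::vector<Clu> clus;
      for (size_t i = 0; i < diags.size(); ++i) {
        if (clus.empty() || diags[i] - clus.back().dmax > pad)
          clus.push_back({diags[i], diags[i], 1});
        else { clus.back().dmax = diags[i]; ++clus.back().count; }
      }
      if ((int)clus.size() > max_clusters) {
        std::stable_sort(clus.begin(), clus.end(),
                         [](const Clu& a, const Clu& b) { return a.count > b.count; });
        clus.resize(max_clusters);
        std::sort(clus.begin(), clus.end(),
                  [](const Clu& a, const Clu& b) { return a.dmin < b.dmin; });
      }
      for (const Clu& c : clus) {
        int ws = std::max(0, c.dmin - pad);
        int we = std::min(n, c.dmax + m + pad);
        Aln a = aln_window(oriented, contig, ws, we, ws == 0, we == n, ma, mi, go);
        bool plus = (s == 0);
        if (better(a, plus, best, best_plus)) { best = a; best_plus = plus; }
      }
    }
    found[r] = best.found;
    if (best.found) {
      strand[r] = best_plus ? "+" : "-";
      score[r] = best.score;
      read_start[r] = best.read_start; read_end[r] = best.read_end;
      ref_start[r] = best.ref_start; ref_end[r] = best.ref_end;
      nsub[r] = best.nsub; nins[r] = best.nins; ndel[r] = best.ndel;
      overlap_len[r] = best.ncols;
      aln_read[r] = best.aread; aln_ref[r] = best.aref;
    } else {
      strand[r] = NA_STRING; aln_read[r] = NA_STRING; aln_ref[r] = NA_STRING;
      score[r] = NA_INTEGER;
      read_start[r] = NA_INTEGER; read_end[r] = NA_INTEGER;
      ref_start[r] = NA_INTEGER; ref_end[r] = NA_INTEGER;
      nsub[r] = NA_INTEGER; nins[r] = NA_INTEGER; ndel[r] = NA_INTEGER;
      overlap_len[r] = NA_INTEGER;
    }
  }
  return DataFrame::create(
    _["found"] = found, _["strand"] = strand, _["score"] = score,
    _["read_start"] = read_start, _["read_end"] = read_end,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end,
    _["nsub"] = nsub, _["nins"] = nins, _["ndel"] = ndel,
    _["overlap_len"] = overlap_len,
    _["aln_read"] = aln_read, _["aln_ref"] = aln_ref,
    _["stringsAsFactors"] = false);
}

// Banded pairwise alignment of two long, similar sequences. free_ends makes
// terminal gaps free (overlap-style), which is what circular-assembly
// comparison after rotation needs.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int band,
                      int ma = 1, int mi = -1, int go = -2,
                      bool free_ends = true) {
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  int W = band + std::abs(n - m);
  const int NEG = INT_MIN / 4;
  std::vector<int> lo(m + 1), hi(m + 1);
  for (int i = 0; i <= m; ++i) {
    int center = (int)((long long)i * n / m);
    lo[i] = std::max(0, center - W);
    hi[i] = std::min(n, center + W);
  }
  int width = 2 * W + 1;
  std::vector<unsigned char> D((size_t)(m + 1) * width, 0);
  auto dat = [&](int i, int j) -> unsigned char& { return D[(size_t)i * width + (j - lo[i])]; };
  std::vector<int> prev(width, NEG), cur(width, NEG);
  // row 0
  for (int j = lo[0]; j <= hi[0]; ++j) {
    prev[j - lo[0]] = free_ends ? 0 : j * go;
    dat(0, j) = (j == 0) ? 0 : 3;
  }
  if (free_ends) for (int j = lo[0]; j <= hi[0]; ++j) dat(0, j) = 0;
  int best_s = NEG, best_i = m, best_j = n;
  if (free_ends) {
    if (hi[0] == n) { best_s = prev[n - lo[0]]; best_i = 0; best_j = n; }
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int h_diag = NEG, h_up = NEG, h_left = NEG;
      if (j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) h_diag = prev[j - 1 - lo[i - 1]];
      if (j >= lo[i - 1] && j <= hi[i - 1]) h_up = prev[j - lo[i - 1]];
      if (j - 1 >= lo[i]) h_left = cur[j - 1 - lo[i]];
      int best; unsigned char d;
      if (j == 0) {
        best = free_ends ? 0 : i * go; d = 2;
        if (free_ends) d = 0;
      } else {
        int sub = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? ma : mi;
        best = (h_diag > NEG) ? h_diag + sub : NEG; d = 1;
        if (h_up > NEG && h_up + go > best) { best = h_up + go; d = 2; }
        if (h_left > NEG && h_left + go > best) { best = h_left + go; d = 3; }
        if (h_diag <= NEG && h_up <= NEG && h_left <= NEG) { best = NEG; d = 0; }
      }
      cur[j - lo[i]] = best;
      dat(i, j) = d;
    }
    if (free_ends && hi[i] == n && cur[n - lo[i]] > best_s) {
      best_s = cur[n - lo[i]]; best_i = i; best_j = n;
    }
    std::swap(prev, cur);
  }
  // prev now holds row m
  if (free_ends) {
    for (int j = lo[m]; j <= hi[m]; ++j)
      if (prev[j - lo[m]] > best_s) { best_s = prev[j - lo[m]]; best_i = m; best_j = j; }
  } else {
    best_s = prev[n - lo[m]]; best_i = m; best_j = n;
  }
  // traceback; terminal unaligned stretches are reported as clips
  std::string aa, ab;
  int i = best_i, j = best_j;
  while (i > 0 || j > 0) {
    if (i == 0) { if (!free_ends) { aa += '-'; ab += b[j - 1]; } --j; continue; }
    if (j == 0) { if (!free_ends) { aa += a[i - 1]; ab += '-'; } --i; continue; }
    unsigned char d = dat(i, j);
    if (d == 0) break;
    if (d == 1) { aa += a[i - 1]; ab += b[j - 1]; --i; --j; }
    else if (d == 2) { aa += a[i - 1]; ab += '-'; --i; }
    else { aa += '-'; ab += b[j - 1]; --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  return List::create(
    _["score"] = best_s, _["aln_a"] = aa, _["aln_b"] = ab,
    _["a_start"] = i, _["a_end"] = best_i,
    _["b_start"] = j, _["b_end"] = best_j);
}

// Best ungapped suffix-prefix overlap (or containment) between two sequences,
// over both orientations of b. Used by the greedy verification assembler.
// [[Rcpp::export]]
List cpp_best_merge(std::string a, std::string b, int min_overlap,
                    double max_mm_frac) {
  std::string brc = revcomp(b);
  // containment first: exact substring
  if (b.size() <= a.size()) {
    if (a.find(b) != std::string::npos || a.find(brc) != std::string::npos)
      return List::create(_["type"] = "contain", _["keep"] = "a",
                          _["score"] = (int)b.size(), _["merged"] = a);
  }
  if (a.size() < b.size()) {
    std::string arc = revcomp(a);
    if (b.find(a) != std::string::npos || b.find(arc) != std::string::npos)
      return List::create(_["type"] = "contain", _["keep"] = "b",
                          _["score"] = (int)a.size(), _["merged"] = b);
  }
  int la = (int)a.size();
  int best_score = INT_MIN, best_L = 0, best_mm = 0, best_combo = -1;
  // combos: 0: a..b, 1: a..rc(b), 2: b..a, 3: rc(b)..a
  const std::string* X[4] = {&a, &a, &b, &brc};
  const std::string* Y[4] = {&b, &brc, &a, &a};
  for (int c = 0; c < 4; ++c) {
    const std::string& x = *X[c];
    const std::string& y = *Y[c];
    int lx = (int)x.size(), ly = (int)y.size();
    int Lmax = std::min(lx, ly);
    for (int L = Lmax; L >= min_overlap; --L) {
      int mm = 0, allowed = (int)(max_mm_frac * L);
      for (int t = 0; t < L && mm <= allowed; ++t)
        if (x[lx - L + t] != y[t]) ++mm;
      if (mm > allowed) continue;
      int sc = L - 2 * mm;
      if (sc > best_score) { best_score = sc; best_L = L; best_mm = mm; best_combo = c; }
    }
  }
  if (best_combo < 0)
    return List::create(_["type"] = "none");
  const std::string& x = *X[best_combo];
  const std::string& y = *Y[best_combo];
  int lx = (int)x.size();
  std::string merged = x.substr(0, lx - best_L);
  for (int t = 0; t < best_L; ++t) {
    char cx = x[lx - best_L + t], cy = y[t];
    merged += (cx == cy) ? cx : std::min(cx, cy); // 2-way tie: alphabetic
  }
  merged += y.substr(best_L);
  return List::create(_["type"] = "merge", _["combo"] = best_combo,
                      _["overlap"] = best_L, _["mismatches"] = best_mm,
                      _["score"] = best_score, _["merged"] = merged);
}

// Terminal self-overlap (circularity) detection: occurrences of the leading
// probe in the downstream half mark candidate duplication starts; the longest
// one with ungapped identity >= min_identity wins.
// [[Rcpp::export]]
List cpp_self_overlap(std::string seq, int min_overlap, double min_identity,
                      int probe_len = 20) {
  int n = (int)seq.size();
  int best_L = 0;
  double best_id = 0.0;
  if (n >= 2 * min_overlap && n > probe_len) {
    std::string probe = seq.substr(0, probe_len);
    size_t from = (size_t)(n / 2);
    size_t p = seq.find(probe, from);
    while (p != std::string::npos) {
      int L = n - (int)p;
      if (L >= min_overlap) {
        int match = 0;
        for (int t = 0; t < L; ++t) if (seq[t] == seq[p + t]) ++match;
        double id = (double)match / L;
        if (id >= min_identity && L > best_L) { best_L = L; best_id = id; }
      }
      p = seq.find(probe, p + 1);
    }
  }
  return List::create(_["overlap"] = best_L, _["identity"] = best_id);
}
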