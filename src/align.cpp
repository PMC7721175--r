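// Banded affine-gap local alignment of short reads against breakpoint-fusion
// templates, seeded by exact 13-mer matches.  Scores: match +1, mismatch -1,
// gap open -3, gap extend -1; alignments scoring below min_frac * read_length
// are discarded.  Both strands are tried; coordinates are reported on the
// template, 0-based half-open.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = 3, GAP_EXT = 1;
static const int KMER = 13;
static const int BAND = 10;            // half-width around the seed diagonal
static const int MIN_VOTES = 3;        // seed k-mer hits needed to trigger DP
static const int NEG_INF = -1000000000;

static inline int bcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

struct Hit { int tmpl; int diag; };
struct Aln { int tstart, tend, score, aligned; bool ok; };

// Banded local (Smith-Waterman, Gotoh affine) alignment of `read` vs `tmpl`
// restricted to template positions t with |t - r - d| <= w.
static Aln banded_local(const std::string& read, const std::string& tmpl,
                        int d, int w) {
  const int n = (int)read.size(), m = (int)tmpl.size();
  const int W = 2 * w + 1;
  // H/E/F rows; pointers for traceback: 0 stop, 1 diag, 2 up (gap in tmpl),
  // 3 left (gap in read); separate pointer planes for E and F chains.
  std::vector<int> Hp(W, 0), Hc(W, 0), Ep(W, NEG_INF), Ec(W, NEG_INF),
      Fc(W, NEG_INF);
  std::vector<uint8_t> ptrH((size_t)(n + 1) * W, 0), ptrE((size_t)(n + 1) * W, 0),
      ptrF((size_t)(n + 1) * W, 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    std::fill(Hc.begin(), Hc.end(), 0);
    std::fill(Ec.begin(), Ec.end(), NEG_INF);
    std::fill(Fc.begin(), Fc.end(), NEG_INF);
    for (int j = 0; j < W; ++j) {
      int t = i + d + (j - w);               // template position (1-based)
      if (t < 1 || t > m) { Hc[j] = 0; continue; }
      // E: read base i consumed, gap in template; from row i-1, same t => j+1
      int e = NEG_INF; uint8_t pe = 0;
      if (j + 1 < W) {
        int open = Hp[j + 1] - GAP_OPEN;
        int ext  = Ep[j + 1] - GAP_EXT;
        if (ext > open) { e = ext; pe = 1; } else { e = open; pe = 0; }
      }
      // F: template base consumed, gap in read; same row, t-1 => j-1
      int f = NEG_INF; uint8_t pf = 0;
      if (j - 1 >= 0) {
        int open = Hc[j - 1] - GAP_OPEN;
        int ext  = Fc[j - 1] - GAP_EXT;
        if (ext > open) { f = ext; pf = 1; } else { f = open; pf = 0; }
      }
      // diagonal: from row i-1, t-1 => same j
      int rc = bcode(read[i - 1]), tc = bcode(tmpl[t - 1]);
      int sub = (rc >= 0 && rc == tc) ? MATCH : MISMATCH;
      int diag = Hp[j] + sub;
      int h = 0; uint8_t ph = 0;
      if (diag > h) { h = diag; ph = 1; }
      if (e > h)    { h = e;    ph = 2; }
      if (f > h)    { h = f;    ph = 3; }
      Hc[j] = h; Ec[j] = e; Fc[j] = f;
      size_t ix = (size_t)i * W + j;
      ptrH[ix] = ph; ptrE[ix] = pe; ptrF[ix] = pf;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec);
  }
  Aln a; a.ok = false; a.score = best; a.tstart = 0; a.tend = 0; a.aligned = 0;
  if (best <= 0) return a;
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int tend = bi + d + (bj - w), tstart = tend, aligned = 0;
  while (i > 0) {
    size_t ix = (size_t)i * W + j;
    if (state == 0) {
      uint8_t p = ptrH[ix];
      if (p == 0) break;
      if (p == 1) { aligned++; tstart = i + d + (j - w); i--; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t p = ptrE[ix];
      i--; j++;
      state = p ? 1 : 0;
    } else {
      uint8_t p = ptrF[ix];
      tstart = i + d + (j - w);   // template base consumed
      j--;
      state = p ? 2 : 0;
    }
  }
  a.ok = true; a.tstart = tstart - 1; a.tend = tend; a.aligned = aligned;
  return a;
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector templates,
                          double min_frac) {
  // k-mer index over all templates
  std::unordered_map<uint32_t, std::vector<std::pair<int,int> > > index;
  std::vector<std::string> tms(templates.size());
  for (int ti = 0; ti < templates.size(); ++ti) {
    tms[ti] = as<std::string>(templates[ti]);
    const std::string& t = tms[ti];
    if ((int)t.size() < KMER) continue;
    uint32_t key = 0, mask = (1u << (2 * KMER)) - 1u;
    int run = 0;
    for (int p = 0; p < (int)t.size(); ++p) {
      int c = bcode(t[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++run >= KMER) index[key].push_back(std::make_pair(ti, p - KMER + 1));
    }
  }
  std::vector<int> out_read, out_tmpl, out_start, out_end, out_score, out_aln;
  std::vector<std::string> out_strand;
  std::unordered_map<int64_t, int> votes;  // (tmpl, diag-bucket) -> count
  std::unordered_map<int64_t, int> diag_of;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    if ((int)fwd.size() < KMER) continue;
    int floor_score = (int)std::ceil(min_frac * (double)fwd.size());
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = strand ? revcomp(fwd) : fwd;
      votes.clear(); diag_of.clear();
      uint32_t key = 0, mask = (1u << (2 * KMER)) - 1u;
      int run = 0;
      for (int p = 0; p < (int)rd.size(); ++p) {
        int c = bcode(rd[p]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t)c) & mask;
        if (++run < KMER) continue;
        std::unordered_map<uint32_t, std::vector<std::pair<int,int> > >::iterator
            it = index.find(key);
        if (it == index.end()) continue;
        int rpos = p - KMER + 1;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int ti = it->second[h].first;
          int diag = it->second[h].second - rpos;
          int bucket = diag >= 0 ? diag / (BAND / 2) : -1 - ((-1 - diag) / (BAND / 2));
          int64_t kk = (int64_t)ti * 1000000LL + (bucket + 500000);
          votes[kk]++;
          diag_of[kk] = diag;
        }
      }
      // best diagonal bucket per template
      std::unordered_map<int, std::pair<int,int> > best_per_tmpl; // ti -> (votes, diag)
      for (std::unordered_map<int64_t,int>::iterator v = votes.begin();
           v != votes.end(); ++v) {
        int ti = (int)(v->first / 1000000LL);
        int dg = diag_of[v->first];
        std::unordered_map<int, std::pair<int,int> >::iterator b =
            best_per_tmpl.find(ti);
        if (b == best_per_tmpl.end() || v->second > b->second.first)
          best_per_tmpl[ti] = std::make_pair(v->second, dg);
      }
      for (std::unordered_map<int, std::pair<int,int> >::iterator b =
               best_per_tmpl.begin(); b != best_per_tmpl.end(); ++b) {
        int ti = b->first;
        if (b->second.first < MIN_VOTES) continue;
        Aln a = banded_local(rd, tms[ti], b->second.second, BAND);
        if (a.ok && a.score >= floor_score) {
          out_read.push_back(ri + 1);
          out_tmpl.push_back(ti + 1);
          out_start.push_back(a.tstart);
          out_end.push_back(a.tend);
          out_score.push_back(a.score);
          out_aln.push_back(a.aligned);
          out_strand.push_back(strand ? "-" : "+");
        }
      }
    }
  }
  return DataFrame::create(
      _["read"] = out_read, _["template"] = out_tmpl,
      _["start"] = out_start, _["end"] = out_end,
      _["score"] = out_score, _["aligned_bases"] = out_aln,
      _["strand"] = out_strand, _["stringsAsFactors"] = false);
}
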