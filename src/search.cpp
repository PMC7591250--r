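// Translated six-frame protein search: exact k-mer seeding over a reference
// protein set followed by banded affine Smith-Waterman extension around the
// seed diagonal. Best-hit (-k 1) semantics with ties broken by database order.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// BLOSUM62 over the alphabet ARNDCQEGHILKMFPSTWYVBZX* (NCBI scores)
static const char AA_ALPHA[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int NAA = 24;
static const int BL62[24][24] = {
{4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-2,-1,-1,-4},
{-1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-1,0,-1,-4},
{-2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,4,0,-1,-4},
{-2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,4,1,-1,-4},
{0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
{-1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,0,3,-1,-4},
{-1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,1,4,-1,-4},
{0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-1,-2,-1,-4},
{-2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,0,0,-1,-4},
{-1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-3,-3,-1,-4},
{-1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-4,-3,-1,-4},
{-1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,0,1,-1,-4},
{-1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-3,-1,-1,-4},
{-2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-3,-3,-1,-4},
{-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
{1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,0,0,0,-4},
{0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-1,-1,0,-4},
{-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-4,-3,-2,-4},
{-2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-3,-2,-1,-4},
{0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-3,-2,-1,-4},
{-2,-1,4,4,-3,0,1,-1,0,-3,-4,0,-3,-3,-2,0,-1,-4,-3,-3,4,1,-1,-4},
{-1,0,0,1,-3,3,4,-2,0,-3,-3,1,-1,-3,-1,0,-1,-3,-2,-2,1,4,-1,-4},
{-1,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2,0,0,-2,-1,-1,-1,-1,-1,-4},
{-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,1}};

// standard genetic code indexed by 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3
static const char CODON_AA[] = "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static int aa_idx_tab[256];
static int nt_idx_tab[256];   // A=0 C=1 G=2 T=3 N=4 other=-1
static char nt_comp_tab[256];
static bool tables_ready = false;

static void init_tables() {
  if (tables_ready) return;
  for (int i = 0; i < 256; ++i) { aa_idx_tab[i] = -1; nt_idx_tab[i] = -1; nt_comp_tab[i] = 0; }
  for (int i = 0; i < NAA; ++i) {
    aa_idx_tab[(unsigned char)AA_ALPHA[i]] = i;
    aa_idx_tab[(unsigned char)tolower(AA_ALPHA[i])] = i;
  }
  aa_idx_tab[(unsigned char)'U'] = aa_idx_tab[(unsigned char)'C']; // selenocysteine
  const char *nt = "ACGTN", *cm = "TGCAN";
  for (int i = 0; i < 5; ++i) {
    nt_idx_tab[(unsigned char)nt[i]] = i;
    nt_idx_tab[(unsigned char)tolower(nt[i])] = i;
    nt_comp_tab[(unsigned char)nt[i]] = cm[i];
    nt_comp_tab[(unsigned char)tolower(nt[i])] = cm[i];
  }
  tables_ready = true;
}

// translate codon given base codes (0..4); any N -> 'X'
static inline char codon_aa(int b1, int b2, int b3) {
  if (b1 > 3 || b2 > 3 || b3 > 3) return 'X';
  return CODON_AA[(b1 << 4) | (b2 << 2) | b3];
}

// six-frame translation of a nucleotide string; frames 0..2 forward, 3..5 reverse
// complement; trailing partial codons dropped; returns false on invalid character
static bool six_frames(const char* s, int len, std::string out[6]) {
  std::vector<int> code(len);
  for (int i = 0; i < len; ++i) {
    int c = nt_idx_tab[(unsigned char)s[i]];
    if (c < 0) return false;
    code[i] = c;
  }
  for (int f = 0; f < 3; ++f) {
    int n = (len - f) / 3;
    if (n < 0) n = 0;
    std::string& p = out[f];
    p.clear(); p.reserve(n);
    for (int i = 0; i < n; ++i) {
      int o = f + 3 * i;
      p.push_back(codon_aa(code[o], code[o + 1], code[o + 2]));
    }
  }
  // reverse complement codes: rc[i] = 3 - code[len-1-i] (N stays 4)
  for (int f = 0; f < 3; ++f) {
    int n = (len - f) / 3;
    if (n < 0) n = 0;
    std::string& p = out[3 + f];
    p.clear(); p.reserve(n);
    for (int i = 0; i < n; ++i) {
      int o = len - 1 - f - 3 * i;
      int b1 = code[o]     < 4 ? 3 - code[o]     : 4;
      int b2 = code[o - 1] < 4 ? 3 - code[o - 1] : 4;
      int b3 = code[o - 2] < 4 ? 3 - code[o - 2] : 4;
      p.push_back(codon_aa(b1, b2, b3));
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// k-mer index over reference proteins (codes base 20 over the standard aa)

struct RefIndex {
  int k;
  uint64_t pow_k1;                       // 20^(k-1)
  std::vector<std::vector<int8_t> > prot; // encoded proteins (aa indices)
  std::vector<uint32_t> keys;            // sorted distinct k-mer codes
  std::vector<int> off;                  // postings offsets, size keys+1
  std::vector<int> post_prot;
  std::vector<int> post_pos;
  std::vector<uint64_t> present;         // bitset over 20^k codes
};

static void build_index(const CharacterVector& prots, int k, RefIndex& ix) {
  init_tables();
  int np = prots.size();
  ix.k = k;
  ix.pow_k1 = 1;
  for (int i = 0; i < k - 1; ++i) ix.pow_k1 *= 20;
  uint64_t space = ix.pow_k1 * 20;
  ix.present.assign((space >> 6) + 1, 0ull);
  ix.prot.resize(np);
  std::vector<std::pair<uint32_t, std::pair<int,int> > > items;
  for (int p = 0; p < np; ++p) {
    const char* s = CHAR(STRING_ELT(prots, p));
    int n = (int)std::strlen(s);
    std::vector<int8_t>& enc = ix.prot[p];
    enc.resize(n);
    for (int j = 0; j < n; ++j) {
      int a = aa_idx_tab[(unsigned char)s[j]];
      if (a < 0) stop("invalid amino-acid character '%c' in reference protein %d", s[j], p + 1);
      enc[j] = (int8_t)a;
    }
    uint64_t code = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int a = enc[j];
      if (a >= 20) { run = 0; code = 0; continue; } // B,Z,X,* break seeds
      code = (code % ix.pow_k1) * 20 + a;
      if (++run >= k) {
        items.push_back(std::make_pair((uint32_t)code, std::make_pair(p, j - k + 1)));
        ix.present[code >> 6] |= (1ull << (code & 63));
      }
    }
  }
  std::sort(items.begin(), items.end());
  ix.keys.clear(); ix.off.clear();
  ix.post_prot.resize(items.size());
  ix.post_pos.resize(items.size());
  for (size_t i = 0; i < items.size(); ++i) {
    if (i == 0 || items[i].first != items[i - 1].first) {
      ix.keys.push_back(items[i].first);
      ix.off.push_back((int)i);
    }
    ix.post_prot[i] = items[i].second.first;
    ix.post_pos[i] = items[i].second.second;
  }
  ix.off.push_back((int)items.size());
}

// ---------------------------------------------------------------------------
// banded affine local alignment (gap of length g costs open + g*ext)

struct AlnResult { int score, matches, columns; };

struct SWScratch {
  std::vector<int> H, E, F;
  std::vector<uint8_t> TB;
};

// encoded query qe vs ref protein around diagonal d0 = ref_pos - q_pos,
// half band width B. Traceback recovers matches (exact equality, X never a
// match) and aligned columns.
static AlnResult banded_sw(const std::vector<int8_t>& qe, const std::vector<int8_t>& s,
                           int d0, int B, int gap_open, int gap_ext, SWScratch& w) {
  const int m = (int)qe.size(), n = (int)s.size();
  const int W = 2 * B + 1;
  const int NEG = -1000000;
  const int GO = gap_open + gap_ext;
  // H,E,F over rows 0..m, band cells 0..W-1; j = i + d0 - B + c
  const size_t need = (size_t)(m + 1) * W;
  if (w.H.size() < need) { w.H.resize(need); w.E.resize(need); w.F.resize(need); w.TB.resize(need); }
  std::vector<int>& H = w.H; std::vector<int>& E = w.E; std::vector<int>& F = w.F;
  std::vector<uint8_t>& TB = w.TB;
  for (int c = 0; c < W; ++c) { H[c] = 0; E[c] = NEG; F[c] = NEG; TB[c] = 0; }
  // TB bits: 0-1 H-source (0 stop, 1 from H, 2 from E, 3 from F),
  //          2 E-extend flag, 3 F-extend flag
  int best = 0, bi = -1, bc = -1;
  for (int i = 1; i <= m; ++i) {
    int jlo = i + d0 - B, row = i * W, prow = row - W;
    for (int c = 0; c < W; ++c) {
      int j = jlo + c;
      int h = NEG, e = NEG, f = NEG; uint8_t tb = 0;
      if (j >= 1 && j <= n) {
        // E: gap consuming s (move along j): from cell (i, c-1)
        if (c - 1 >= 0) {
          int ho = H[row + c - 1] - GO;
          int ee = E[row + c - 1] - gap_ext;
          if (ee > ho) { e = ee; tb |= 4; } else e = ho;
        }
        // F: gap consuming q (move along i): from (i-1, c+1) same j
        if (c + 1 < W) {
          int ho = H[prow + c + 1] - GO;
          int fe = F[prow + c + 1] - gap_ext;
          if (fe > ho) { f = fe; tb |= 8; } else f = ho;
        }
        // H: diagonal from (i-1, c) same band column
        int sub = BL62[(int)qe[i - 1]][(int)s[j - 1]];
        int dh = H[prow + c], de = E[prow + c], df = F[prow + c];
        int dbest = dh; uint8_t src = 1;
        if (de > dbest) { dbest = de; src = 2; }
        if (df > dbest) { dbest = df; src = 3; }
        h = dbest + sub;
        if (h < sub) { h = sub; src = 1; }  // fresh start treated as from-H at 0
        if (h < 0) { h = 0; src = 0; }
        tb |= src;
        int cell = std::max(h, std::max(e, f));
        if (h >= e && h >= f && h > best) { best = h; bi = i; bc = c; }
        (void)cell;
      }
      H[row + c] = h < 0 ? (j >= 1 && j <= n ? h : NEG) : h;
      if (j < 1 || j > n) H[row + c] = NEG;
      E[row + c] = e;
      F[row + c] = f;
      TB[row + c] = tb;
    }
  }
  AlnResult r; r.score = best; r.matches = 0; r.columns = 0;
  if (best <= 0 || bi < 0) { r.score = 0; return r; }
  // traceback from H state at (bi, bc)
  int i = bi, c = bc, state = 0; // 0=H 1=E 2=F
  while (i > 0) {
    int cell = i * W + c;
    if (state == 0) {
      int j = i + d0 - B + c;
      uint8_t src = TB[cell] & 3;
      if (src == 0) break;
      ++r.columns;
      if (H[cell] <= 0) break;
      int qa = qe[i - 1], sa = s[j - 1];
      if (qa == sa && qa != 22) ++r.matches;
      int ph = H[cell] - BL62[(int)qe[i - 1]][(int)s[j - 1]];
      if (ph <= 0) { break; } // local start
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
      --i; // move diagonally: same band column c
    } else if (state == 1) { // E at (i,c): came from (i, c-1)
      ++r.columns;
      uint8_t ext = TB[cell] & 4;
      state = ext ? 1 : 0;
      --c;
    } else { // F at (i,c): came from (i-1, c+1)
      ++r.columns;
      uint8_t ext = TB[cell] & 8;
      state = ext ? 2 : 0;
      --i; ++c;
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// per-read best-hit search

struct Hit { int prot, score, matches, columns, frame, diag; bool found; };

struct Cand { int prot, diag, frame; };

struct SearchScratch {
  std::vector<Cand> cands;
  std::string frames[6];
  std::vector<int8_t> enc[6];
  SWScratch sw;
};

static void search_one(const char* seq, int len, const RefIndex& ix, int band,
                       int min_cols, Hit& out, SearchScratch& ws) {
  out.found = false;
  if (len < 3) return;
  std::string* frames = ws.frames;
  if (!six_frames(seq, len, frames))
    stop("read contains characters outside {A,C,G,T,N}");
  std::vector<Cand>& cands = ws.cands;
  cands.clear();
  const int k = ix.k;
  for (int f = 0; f < 6; ++f) {
    const std::string& p = frames[f];
    const int m = (int)p.size();
    std::vector<int8_t>& enc = ws.enc[f];
    enc.resize(m);
    for (int i = 0; i < m; ++i) {
      int a = aa_idx_tab[(unsigned char)p[i]];
      enc[i] = (int8_t)(a < 0 ? 22 : a);
    }
    uint64_t code = 0; int run = 0;
    int last_prot = -1, last_diag = 0;
    for (int i = 0; i < m; ++i) {
      int a = enc[i];
      if (a < 0 || a >= 20) { run = 0; code = 0; continue; }
      code = (code % ix.pow_k1) * 20 + a;
      if (++run < k) continue;
      if (!(ix.present[code >> 6] & (1ull << (code & 63)))) continue;
      // postings lookup
      std::vector<uint32_t>::const_iterator it =
        std::lower_bound(ix.keys.begin(), ix.keys.end(), (uint32_t)code);
      if (it == ix.keys.end() || *it != (uint32_t)code) continue;
      int ki = (int)(it - ix.keys.begin());
      int qpos = i - k + 1;
      for (int t = ix.off[ki]; t < ix.off[ki + 1]; ++t) {
        int prot = ix.post_prot[t];
        int diag = ix.post_pos[t] - qpos;
        if (prot == last_prot && std::abs(diag - last_diag) <= band) continue;
        bool dup = false;
        for (size_t u = 0; u < cands.size(); ++u)
          if (cands[u].frame == f && cands[u].prot == prot &&
              std::abs(cands[u].diag - diag) <= band) { dup = true; break; }
        if (!dup) { Cand cd; cd.prot = prot; cd.diag = diag; cd.frame = f; cands.push_back(cd); }
        last_prot = prot; last_diag = diag;
      }
    }
  }
  Hit best; best.found = false; best.score = 0;
  for (size_t u = 0; u < cands.size(); ++u) {
    const Cand& cd = cands[u];
    AlnResult a = banded_sw(ws.enc[cd.frame], ix.prot[cd.prot], cd.diag, band, 11, 1, ws.sw);
    if (a.score <= 0 || a.columns < min_cols) continue;
    bool better = false;
    if (!best.found) better = true;
    else if (a.score > best.score) better = true;
    else if (a.score == best.score) {
      if (cd.prot < best.prot) better = true;
      else if (cd.prot == best.prot &&
               (cd.frame < best.frame || (cd.frame == best.frame && cd.diag < best.diag)))
        better = true;
    }
    if (better) {
      best.found = true; best.prot = cd.prot; best.score = a.score;
      best.matches = a.matches; best.columns = a.columns;
      best.frame = cd.frame; best.diag = cd.diag;
    }
  }
  out = best;
}

struct HitSink {
  std::vector<int> read, prot, score, cols;
  std::vector<double> pident;
  void add(int r, const Hit& h) {
    read.push_back(r + 1);
    prot.push_back(h.prot + 1);
    score.push_back(h.score);
    cols.push_back(h.columns);
    pident.push_back(100.0 * h.matches / h.columns);
  }
  List wrap() {
    return List::create(_["read"] = wrap_iv(read), _["target"] = wrap_iv(prot),
                        _["score"] = wrap_iv(score), _["aln_len"] = wrap_iv(cols),
                        _["pident"] = NumericVector(pident.begin(), pident.end()));
  }
  static IntegerVector wrap_iv(const std::vector<int>& v) {
    return IntegerVector(v.begin(), v.end());
  }
};

// [[Rcpp::export]]
List cpp_search_reads(CharacterVector reads, CharacterVector prots,
                      int kmer, int band, int min_aln_len) {
  init_tables();
  RefIndex ix;
  build_index(prots, kmer, ix);
  HitSink sink;
  SearchScratch ws;
  Hit h;
  for (int r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    search_one(s, (int)std::strlen(s), ix, band, min_aln_len, h, ws);
    if (h.found) sink.add(r, h);
  }
  return sink.wrap();
}

// fragments taken directly from genome strings: avoids materialising millions
// of read strings in R when benchmarking
// [[Rcpp::export]]
List cpp_search_fragments(CharacterVector genomes, IntegerVector species,
                          IntegerVector start, IntegerVector strand,
                          int read_len, CharacterVector prots,
                          int kmer, int band, int min_aln_len) {
  init_tables();
  RefIndex ix;
  build_index(prots, kmer, ix);
  int ng = genomes.size();
  std::vector<const char*> gs(ng);
  std::vector<int> gl(ng);
  for (int g = 0; g < ng; ++g) {
    gs[g] = CHAR(STRING_ELT(genomes, g));
    gl[g] = (int)std::strlen(gs[g]);
  }
  HitSink sink;
  SearchScratch ws;
  std::vector<char> buf(read_len + 1);
  Hit h;
  int n = species.size();
  for (int r = 0; r < n; ++r) {
    int g = species[r] - 1, st = start[r] - 1;
    if (g < 0 || g >= ng) stop("species index out of range");
    if (st < 0 || st + read_len > gl[g]) stop("fragment outside genome");
    const char* src = gs[g] + st;
    if (strand[r] >= 0) {
      std::memcpy(&buf[0], src, read_len);
    } else {
      for (int i = 0; i < read_len; ++i) buf[i] = nt_comp_tab[(unsigned char)src[read_len - 1 - i]];
    }
    buf[read_len] = 0;
    search_one(&buf[0], read_len, ix, band, min_aln_len, h, ws);
    if (h.found) sink.add(r, h);
  }
  return sink.wrap();
}

// [[Rcpp::export]]
CharacterVector cpp_extract_fragments(CharacterVector genomes, IntegerVector species,
                                      IntegerVector start, IntegerVector strand,
                                      int read_len) {
  init_tables();
  int n = species.size();
  CharacterVector out(n);
  std::vector<char> buf(read_len + 1);
  for (int r = 0; r < n; ++r) {
    int g = species[r] - 1, st = start[r] - 1;
    const char* src = CHAR(STRING_ELT(genomes, g));
    int glen = (int)std::strlen(src);
    if (st < 0 || st + read_len > glen) stop("fragment outside genome");
    if (strand[r] >= 0) std::memcpy(&buf[0], src + st, read_len);
    else for (int i = 0; i < read_len; ++i)
      buf[i] = nt_comp_tab[(unsigned char)src[st + read_len - 1 - i]];
    buf[read_len] = 0;
    out[r] = std::string(&buf[0], read_len);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_translate6(std::string seq) {
  init_tables();
  std::string frames[6];
  if (!six_frames(seq.c_str(), (int)seq.size(), frames))
    stop("sequence contains characters outside {A,C,G,T,N}");
  CharacterVector out(6);
  for (int f = 0; f < 6; ++f) out[f] = frames[f];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  init_tables();
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(s);
    buf.assign(len, ' ');
    for (int j = 0; j < len; ++j) {
      char c = nt_comp_tab[(unsigned char)s[len - 1 - j]];
      if (!c) stop("sequence contains characters outside {A,C,G,T,N}");
      buf[j] = c;
    }
    out[i] = buf;
  }
  return out;
}
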