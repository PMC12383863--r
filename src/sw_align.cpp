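#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) of a read against an amplicon
// reference. A gap of length L costs gap_open + L * gap_extend (both
// penalties are <= 0). With bisulfite = true, a read T opposite a
// reference C scores as a match (C->T conversion on the sequenced
// strand); the asymmetric rule applies to the read/reference pair only in
// that orientation.

static inline int subscore(char rd, char rf, int match, int mismatch,
                           bool bisulfite) {
  if (rd == rf) return match;
  if (bisulfite && rf == 'C' && rd == 'T') return match;
  return mismatch;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref, int match,
                  int mismatch, int gap_open, int gap_extend,
                  bool bisulfite) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const int NEG = -1000000000;
  // H: best score ending at (i,j); E: gap in read (consumes ref, CIGAR D);
  // F: gap in ref (consumes read, CIGAR I)
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG);
  std::vector<int> F((n + 1) * (m + 1), NEG);
  #define IX(i, j) ((i) * (m + 1) + (j))

  int best = 0, bi = 0, bj = 0;
  const int go = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    int *Hr = &H[IX(i, 0)], *Er = &E[IX(i, 0)], *Fr = &F[IX(i, 0)];
    const int *Hp = &H[IX(i - 1, 0)], *Fp = &F[IX(i - 1, 0)];
    const char rd = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      int e = std::max(Hr[j - 1] + go, Er[j - 1] + gap_extend);
      int f = std::max(Hp[j] + go, Fp[j] + gap_extend);
      int s = subscore(rd, ref[j - 1], match, mismatch, bisulfite);
      int h = Hp[j - 1] + s;
      h = std::max(h, std::max(e, f));
      h = std::max(h, 0);
      Er[j] = e;
      Fr[j] = f;
      Hr[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string cigar_rev;
  std::vector<int> ref_pos;       // 0-based ref positions of M columns
  std::string read_bases;         // read base aligned at each M column
  int i = bi, j = bj;
  if (best > 0) {
    char state = 'H';
    while (i > 0 && j > 0) {
      if (state == 'H') {
        int h = H[IX(i, j)];
        if (h == 0) break;
        int s = subscore(read[i - 1], ref[j - 1], match, mismatch,
                         bisulfite);
        if (h == H[IX(i - 1, j - 1)] + s) {
          cigar_rev.push_back('M');
          ref_pos.push_back(j - 1);
          read_bases.push_back(read[i - 1]);
          --i; --j;
        } else if (h == E[IX(i, j)]) {
          state = 'E';
        } else {
          state = 'F';
        }
      } else if (state == 'E') {
        cigar_rev.push_back('D');
        if (E[IX(i, j)] == E[IX(i, j - 1)] + gap_extend) { --j; }
        else { --j; state = 'H'; }
      } else {  // F
        cigar_rev.push_back('I');
        if (F[IX(i, j)] == F[IX(i - 1, j)] + gap_extend) { --i; }
        else { --i; state = 'H'; }
      }
    }
  }
  std::reverse(ref_pos.begin(), ref_pos.end());
  std::reverse(read_bases.begin(), read_bases.end());

  // run-length encode the (reversed) CIGAR
  std::string cigar;
  if (!cigar_rev.empty()) {
    std::reverse(cigar_rev.begin(), cigar_rev.end());
    int run = 1;
    for (size_t k = 1; k <= cigar_rev.size(); ++k) {
      if (k < cigar_rev.size() && cigar_rev[k] == cigar_rev[k - 1]) ++run;
      else {
        cigar += std::to_string(run);
        cigar += cigar_rev[k - 1];
        run = 1;
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["read_start"] = (best > 0) ? i : 0,   // 0-based, half-open interval
    _["read_end"] = (best > 0) ? bi : 0,
    _["ref_start"] = (best > 0) ? j : 0,
    _["ref_end"] = (best > 0) ? bj : 0,
    _["cigar"] = cigar,
    _["ref_pos"] = wrap(ref_pos),
    _["read_bases"] = read_bases);
}
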