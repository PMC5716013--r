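#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Spliced alignment of a cDNA against its own genomic sequence.
//
// Model: exons align base-for-base (no indels inside exons; inputs are
// same-gene pairs at near identity), introns are genomic-only jumps.
// Scoring: match +1, mismatch -2, intron open -4, intron extension 0.
// An intron must be at least min_intron long and, when require_gt_ag is
// set, must start with GT and end with AG.
//
// E[i][j]: best score with genomic prefix i and cdna prefix j, genomic
// base i aligned to cdna base j (both 1-based prefixes). An intron ending
// at genomic position i-1 enters through a running maximum over eligible
// donor cut points d (intron occupies genomic d+1 .. i-1).
//
// Tie-breaking: during traceback the exon diagonal is preferred over an
// intron end, and the donor running maximum keeps the earliest (leftmost)
// cut point on ties; together this yields the leftmost placement of any
// slidable intron.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_spliced_align(std::string genomic, std::string cdna,
                       int min_intron, bool require_gt_ag) {
  const int n = genomic.size(), m = cdna.size();
  if (m < 1 || n < m) stop("cdna must be non-empty and no longer than genomic");

  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  // donor index used when an intron ends just before (i, j); -1 = none
  std::vector<int> Dd((size_t)(n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // running max over donors d of E[d][j] (intron starts at genomic d+1)
  std::vector<int> best(m + 1, NEG), bestd(m + 1, -1);

  auto donor_ok = [&](int d) {
    // intron starts at genomic position d+1 (1-based)
    if (!require_gt_ag) return d + 2 <= n;
    return d + 2 <= n && genomic[d] == 'G' && genomic[d + 1] == 'T';
  };
  auto acceptor_ok = [&](int e) {
    // intron ends at genomic position e (1-based)
    if (!require_gt_ag) return e >= 2;
    return e >= 2 && genomic[e - 2] == 'A' && genomic[e - 1] == 'G';
  };

  E[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    // admit donor cut point d = (i-1) - min_intron for introns ending at i-1
    int d = i - 1 - min_intron;
    if (d >= 0 && donor_ok(d)) {
      for (int j = 0; j <= m; ++j) {
        int v = E[at(d, j)];
        if (v > best[j]) { best[j] = v; bestd[j] = d; }  // strict > keeps leftmost
      }
    }
    bool acc = acceptor_ok(i - 1);
    int jlo = std::max(1, m - (n - i));  // genomic suffix must fit remaining cdna
    int jhi = std::min(m, i);
    for (int j = jlo; j <= jhi; ++j) {
      int s = (genomic[i - 1] == cdna[j - 1]) ? 1 : -2;
      int fromExon = E[at(i - 1, j - 1)];
      int fromIntron = (acc && best[j - 1] > NEG) ? best[j - 1] - 4 : NEG;
      if (fromExon >= fromIntron) {            // prefer exon diagonal on ties
        if (fromExon <= NEG) continue;
        E[at(i, j)] = fromExon + s;
      } else {
        E[at(i, j)] = fromIntron + s;
        Dd[at(i, j)] = bestd[j - 1];
      }
    }
  }

  int score = E[at(n, m)];
  if (score <= NEG)
    return List::create(_["ok"] = false);

  // traceback
  std::vector<int> exon_starts, exon_ends;  // 1-based inclusive on genomic
  int i = n, j = m, ee = n;
  int matches = 0;
  while (j > 0) {
    matches += (genomic[i - 1] == cdna[j - 1]) ? 1 : 0;
    int d = Dd[at(i, j)];
    if (d >= 0) {
      // intron occupied genomic d+1 .. i-1; exon ran from i to ee
      exon_starts.push_back(i);
      exon_ends.push_back(ee);
      ee = d;
      i = d;
      --j;
    } else {
      --i; --j;
    }
  }
  if (i != 0) return List::create(_["ok"] = false);  // genomic prefix unconsumed
  if (ee >= 1) {  // empty only if the genomic sequence opens with an intron
    exon_starts.push_back(1);
    exon_ends.push_back(ee);
  }
  std::reverse(exon_starts.begin(), exon_starts.end());
  std::reverse(exon_ends.begin(), exon_ends.end());

  return List::create(_["ok"] = true,
                      _["score"] = score,
                      _["matches"] = matches,
                      _["exon_starts"] = exon_starts,
                      _["exon_ends"] = exon_ends);
}
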