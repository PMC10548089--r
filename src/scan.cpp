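// Dynamic-programming kernel for high-complementarity miRNA target-site
// scanning. For every start position on the reversed transcript the miRNA
// (5'->3') is globally aligned against the local window under the
// expectation-penalty scheme: Watson-Crick 0, G:U wobble gu, other mismatch
// mm, gap open/extend, every penalty at a seed position multiplied by
// seed_w. At most max_gaps gap columns per duplex; the first and last
// miRNA positions must be paired. Seed mismatches (mismatch, G:U or gap at
// a seed position) are a capped DP dimension so the returned optimum is
// the best *feasible* alignment, not merely the cheapest one.
//
// Base codes: A=0, C=1, G=2, U=3, N=4 (N never pairs).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double INF = 1e18;
static const char BASE[] = "ACGUN";

static inline double pair_pen(int m, int t, double gu, double mm) {
  if ((m == 0 && t == 3) || (m == 1 && t == 2) ||
      (m == 2 && t == 1) || (m == 3 && t == 0)) return 0.0;  // Watson-Crick
  if ((m == 2 && t == 3) || (m == 3 && t == 2)) return gu;   // G:U wobble
  return mm;
}

// [[Rcpp::export]]
List scan_transcript_cpp(IntegerVector mir, IntegerVector rt,
                         double gu, double mm, double seed_w,
                         double gap_open, double gap_ext,
                         int seed_start, int seed_end,
                         double e_max, int max_seed_mm,
                         int hsp_size, int max_gaps) {
  const int m = mir.size();
  const int Lt = rt.size();
  const int G = max_gaps;
  const int S = max_seed_mm + 1;  // saturation value = "cap exceeded"
  // miRNA-bulge gaps shrink the paired span; cap them so span >= hsp_size.
  const int gTmax = std::min(G, std::max(0, m - hsp_size));

  const int D_s = S + 1, D_last = 3, D_gM = G + 1, D_gT = G + 1;
  auto IDX = [&](int p, int gT, int gM, int last, int s) {
    return (((p * D_gT + gT) * D_gM + gM) * D_last + last) * D_s + s;
  };
  const int NSTATE = (m + 1) * D_gT * D_gM * D_last * D_s;
  std::vector<double> cost(NSTATE);
  std::vector<unsigned char> choice(NSTATE);
  auto in_seed = [&](int pos) { return pos >= seed_start && pos <= seed_end; };

  std::vector<int> out_start, out_L, out_gaps, out_seedmm, out_span;
  std::vector<double> out_cost;
  std::vector<std::string> out_mrow, out_trow;

  for (int i = 0; i + (m - G) <= Lt; ++i) {
    std::fill(cost.begin(), cost.end(), INF);
    // First column must be a pairing of miRNA position 1.
    {
      double pen0 = pair_pen(mir[0], rt[i], gu, mm);
      bool sd = in_seed(1);
      int s0 = (pen0 > 0 && sd) ? 1 : 0;
      int j = IDX(1, 0, 0, 0, s0);
      cost[j] = pen0 * (sd ? seed_w : 1.0);
      choice[j] = 255;
    }
    for (int p = 1; p <= m; ++p)
      for (int gT = 0; gT <= G; ++gT)
        for (int gM = 0; gM <= G; ++gM)
          for (int last = 0; last < 3; ++last)
            for (int s = 0; s <= S; ++s) {
              double c = cost[IDX(p, gT, gM, last, s)];
              if (c >= INF) continue;
              int q = p + gM - gT;  // target bases consumed so far
              // pair miRNA position p+1 with the next target base
              if (p < m && i + q < Lt) {
                int pos = p + 1;
                double pen0 = pair_pen(mir[p], rt[i + q], gu, mm);
                bool sd = in_seed(pos);
                double nc = c + pen0 * (sd ? seed_w : 1.0);
                int ns = std::min(S, s + ((pen0 > 0 && sd) ? 1 : 0));
                int j = IDX(p + 1, gT, gM, 0, ns);
                if (nc < cost[j] - 1e-12) {
                  cost[j] = nc;
                  choice[j] = (unsigned char)(0 * 4 + last);
                }
              }
              // miRNA bulge: position p+1 unpaired (forbidden at position m)
              if (p < m - 1 && gT < gTmax && gT + gM < G) {
                int pos = p + 1;
                bool sd = in_seed(pos);
                double pen0 = (last == 1) ? gap_ext : gap_open;
                double nc = c + pen0 * (sd ? seed_w : 1.0);
                int ns = std::min(S, s + (sd ? 1 : 0));
                int j = IDX(p + 1, gT + 1, gM, 1, ns);
                if (nc < cost[j] - 1e-12) {
                  cost[j] = nc;
                  choice[j] = (unsigned char)(1 * 4 + last);
                }
              }
              // target bulge: extra target base, weighted at position p+1
              if (p < m && gT + gM < G && i + q < Lt) {
                int pos = p + 1;
                bool sd = in_seed(pos);
                double pen0 = (last == 2) ? gap_ext : gap_open;
                double nc = c + pen0 * (sd ? seed_w : 1.0);
                int ns = std::min(S, s + (sd ? 1 : 0));
                int j = IDX(p, gT, gM + 1, 2, ns);
                if (nc < cost[j] - 1e-12) {
                  cost[j] = nc;
                  choice[j] = (unsigned char)(2 * 4 + last);
                }
              }
            }

    // Best feasible end state: min cost, then fewer gaps, then shorter site.
    double best = INF;
    int bgT = 0, bgM = 0, bs = 0;
    bool found = false;
    for (int gT = 0; gT <= G; ++gT)
      for (int gM = 0; gM <= G; ++gM)
        for (int s = 0; s <= max_seed_mm; ++s) {
          double c = cost[IDX(m, gT, gM, 0, s)];
          if (c >= INF) continue;
          bool better;
          if (!found || c < best - 1e-12) {
            better = true;
          } else if (c < best + 1e-12) {
            int tg = gT + gM, btg = bgT + bgM;
            better = (tg < btg) || (tg == btg && gM < bgM);
          } else {
            better = false;
          }
          if (better) { best = c; bgT = gT; bgM = gM; bs = s; found = true; }
        }
    if (!found || best > e_max + 1e-9) continue;

    // Traceback, building aligned rows in miRNA 5'->3' register.
    std::string mrow, trow;
    int p = m, gT = bgT, gM = bgM, last = 0, s = bs;
    while (true) {
      int j = IDX(p, gT, gM, last, s);
      unsigned char ch = choice[j];
      int q = p + gM - gT;
      if (ch == 255) {  // initial column
        mrow += BASE[mir[0]];
        trow += BASE[rt[i]];
        break;
      }
      int move = ch / 4, prev_last = ch % 4;
      if (move == 0) {
        double pen0 = pair_pen(mir[p - 1], rt[i + q - 1], gu, mm);
        int d = (pen0 > 0 && in_seed(p)) ? 1 : 0;
        mrow += BASE[mir[p - 1]];
        trow += BASE[rt[i + q - 1]];
        p -= 1; s -= d;
      } else if (move == 1) {
        int d = in_seed(p) ? 1 : 0;
        mrow += BASE[mir[p - 1]];
        trow += '-';
        p -= 1; gT -= 1; s -= d;
      } else {
        int d = in_seed(p + 1) ? 1 : 0;
        mrow += '-';
        trow += BASE[rt[i + q - 1]];
        gM -= 1; s -= d;
      }
      last = prev_last;
    }
    std::reverse(mrow.begin(), mrow.end());
    std::reverse(trow.begin(), trow.end());

    int L = m + bgM - bgT;
    out_start.push_back(i);
    out_L.push_back(L);
    out_cost.push_back(best);
    out_gaps.push_back(bgT + bgM);
    out_seedmm.push_back(bs);
    out_span.push_back(m - bgT);
    out_mrow.push_back(mrow);
    out_trow.push_back(trow);
  }

  return List::create(
    _["start_rt"] = out_start, _["site_length"] = out_L,
    _["expectation"] = out_cost, _["gaps"] = out_gaps,
    _["seed_mismatches"] = out_seedmm, _["span"] = out_span,
    _["mir_row"] = out_mrow, _["target_row"] = out_trow);
}
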