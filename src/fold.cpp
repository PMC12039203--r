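// Reduced RNA secondary-structure backend.
//
// Model (shared by the MFE and partition-function routines, and by the
// enumeration oracle in the test suite):
//   - Watson-Crick pairs only (AU, UA, CG, GC); minimum hairpin loop 3 nt.
//   - Structure free energy = sum of nearest-neighbor stacking terms over
//     directly stacked pairs ((i,j) and (i+1,j-1) both present); unstacked
//     pairs and loops contribute 0.
// This keeps the model additive in the published stack table while staying
// exactly enumerable for oracle verification on short sequences.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int MIN_HAIRPIN = 3;

static inline bool wc_pair(int a, int b) {
  // A=0 C=1 G=2 U=3: the complementary pairs are exactly those summing to 3
  return a + b == 3;
}

// stacks: length-16 vector indexed by 4*x1 + x2 of the 5'->3' top-strand
// dinucleotide (partner strand is the Watson-Crick complement).
static inline double stack_e(const NumericVector& stacks, int x1, int x2) {
  return stacks[4 * x1 + x2];
}

// [[Rcpp::export(name = "c_fold_mfe")]]
double c_fold_mfe(IntegerVector seq, NumericVector stacks) {
  int n = seq.size();
  if (n < 2) return 0.0;
  std::vector<double> W(n * n, 0.0), V(n * n, 0.0);
  std::vector<bool> Vdef(n * n, false);
  const double INF = 1e9;
  // order by increasing span
  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j): (i,j) paired
      double v = INF;
      if (wc_pair(seq[i], seq[j])) {
        v = W[(i + 1) * n + (j - 1)];
        if (j - 1 - (i + 1) > MIN_HAIRPIN && Vdef[(i + 1) * n + (j - 1)]) {
          double stacked = stack_e(stacks, seq[i], seq[i + 1]) +
                           V[(i + 1) * n + (j - 1)];
          if (stacked < v) v = stacked;
        }
        V[i * n + j] = v;
        Vdef[i * n + j] = true;
      }
      // W(i,j)
      double w = W[(i + 1) * n + j];
      if (W[i * n + (j - 1)] < w) w = W[i * n + (j - 1)];
      if (Vdef[i * n + j] && v < w) w = v;
      for (int k = i; k < j; ++k) {
        double split = W[i * n + k] + W[(k + 1) * n + j];
        if (split < w) w = split;
      }
      W[i * n + j] = w;
    }
  }
  double mfe = W[0 * n + (n - 1)];
  return mfe < 0.0 ? mfe : 0.0;
}

// Partition function over the same model at inverse temperature 1/RT.
// ban: 0-based position forbidden from pairing (-1 for none).
static double pf_total(const IntegerVector& seq, const NumericVector& stacks,
                       double RT, int ban) {
  int n = seq.size();
  std::vector<double> Q(n * n, 1.0), Qb(n * n, 0.0);
  // Q over empty/short segments is 1 (only the open structure)
  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // Qb(i,j): (i,j) paired
      double qb = 0.0;
      if (wc_pair(seq[i], seq[j]) && i != ban && j != ban) {
        double q_in = (j - 1 >= i + 1) ? Q[(i + 1) * n + (j - 1)] : 1.0;
        double qb_in = (j - 1 >= i + 1) ? Qb[(i + 1) * n + (j - 1)] : 0.0;
        // interior without (i+1,j-1) paired, plus stacked interior
        qb = (q_in - qb_in) +
             std::exp(-stack_e(stacks, seq[i], seq[i + 1]) / RT) * qb_in;
      }
      Qb[i * n + j] = qb;
      // Q(i,j) anchored on j: j unpaired, or j paired with some k
      double q = Q[i * n + (j - 1)];
      for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
        if (Qb[k * n + j] > 0.0) {
          double left = (k - 1 >= i) ? Q[i * n + (k - 1)] : 1.0;
          q += left * Qb[k * n + j];
        }
      }
      Q[i * n + j] = q;
    }
  }
  return n >= 2 ? Q[0 * n + (n - 1)] : 1.0;
}

// [[Rcpp::export(name = "c_unpaired_probs")]]
NumericVector c_unpaired_probs(IntegerVector seq, NumericVector stacks,
                               IntegerVector positions, double RT) {
  double qtot = pf_total(seq, stacks, RT, -1);
  NumericVector out(positions.size());
  for (int p = 0; p < positions.size(); ++p) {
    double qfree = pf_total(seq, stacks, RT, positions[p]);
    double pr = qfree / qtot;
    if (pr > 1.0) pr = 1.0;
    if (pr < 0.0) pr = 0.0;
    out[p] = pr;
  }
  return out;
}
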