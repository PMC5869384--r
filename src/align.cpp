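#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap alignment kernels. Gap cost convention: a gap of length g costs
// gap_open + (g - 1) * gap_extend, i.e. the opening residue itself costs
// gap_open. Sequences arrive as 1-based integer indices into the scoring
// matrix (X row for unknowns); index conversion happens in R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnResult {
  double score;
  int qstart, qend, sstart, send;  // 0-based half-open
  int matches, aln_len;
};

// Smith-Waterman local alignment with affine gaps, full traceback.
static AlnResult sw_core(const IntegerVector& q, const IntegerVector& s,
                         const IntegerMatrix& mat, double go, double ge) {
  const int m = q.size(), n = s.size();
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG_INF);
  std::vector<double> F((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double sub = mat(q[i - 1] - 1, s[j - 1] - 1);
      E[at(i, j)] = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - ge);
      F[at(i, j)] = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - ge);
      double h = H[at(i - 1, j - 1)] + sub;
      h = std::max(h, E[at(i, j)]);
      h = std::max(h, F[at(i, j)]);
      h = std::max(h, 0.0);
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult r;
  r.score = best;
  r.matches = 0;
  r.aln_len = 0;
  if (best <= 0.0) {
    r.qstart = r.qend = r.sstart = r.send = 0;
    return r;
  }
  // Traceback from the best cell, state machine over H/E/F.
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      const double h = H[at(i, j)];
      if (h == 0.0) break;
      const double sub = mat(q[i - 1] - 1, s[j - 1] - 1);
      if (h == H[at(i - 1, j - 1)] + sub) {
        if (q[i - 1] == s[j - 1]) ++r.matches;
        ++r.aln_len;
        --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {  // gap in query (consumes subject)
      ++r.aln_len;
      if (E[at(i, j)] == H[at(i, j - 1)] - go) {
        --j; state = 'H';
      } else {
        --j;
      }
    } else {  // F: gap in subject (consumes query)
      ++r.aln_len;
      if (F[at(i, j)] == H[at(i - 1, j)] - go) {
        --i; state = 'H';
      } else {
        --i;
      }
    }
  }
  r.qstart = i; r.qend = bi;
  r.sstart = j; r.send = bj;
  return r;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  double gap_open, double gap_extend) {
  AlnResult r = sw_core(q, s, mat, gap_open, gap_extend);
  return List::create(
    _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["sstart"] = r.sstart, _["send"] = r.send, _["matches"] = r.matches,
    _["aln_len"] = r.aln_len);
}

// Score-only Smith-Waterman (linear memory, no traceback) for the search
// phase; full alignments are recomputed only for accepted hits.
static double sw_score_only(const int* q, int m, const int* s, int n,
                            const int* mat, int nrow, double go, double ge) {
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const int* mrow = mat + (q[i - 1] - 1);  // column-major: row offset
    double diag = 0.0;       // H[i-1][j-1]
    double f = NEG_INF;      // F[i][j] running along the row
    for (int j = 1; j <= n; ++j) {
      const double e = std::max(H[j - 1] - go, E[j - 1] - ge);
      f = std::max(H[j] - go, f - ge);
      double h = diag + mrow[(size_t)(s[j - 1] - 1) * nrow];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      E[j] = e;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_many_cpp(IntegerVector q, List subjects,
                                IntegerMatrix mat, double gap_open,
                                double gap_extend) {
  const int k = subjects.size();
  NumericVector score(k);
  const int nrow = mat.nrow();
  for (int u = 0; u < k; ++u) {
    IntegerVector s = subjects[u];
    score[u] = sw_score_only(q.begin(), q.size(), s.begin(), s.size(),
                             mat.begin(), nrow, gap_open, gap_extend);
  }
  return score;
}

// One query against many subjects; avoids per-pair call overhead in search().
// [[Rcpp::export]]
DataFrame sw_align_many_cpp(IntegerVector q, List subjects, IntegerMatrix mat,
                            double gap_open, double gap_extend) {
  const int k = subjects.size();
  NumericVector score(k);
  IntegerVector qstart(k), qend(k), sstart(k), send(k), matches(k), aln_len(k);
  for (int u = 0; u < k; ++u) {
    IntegerVector s = subjects[u];
    AlnResult r = sw_core(q, s, mat, gap_open, gap_extend);
    score[u] = r.score;
    qstart[u] = r.qstart; qend[u] = r.qend;
    sstart[u] = r.sstart; send[u] = r.send;
    matches[u] = r.matches; aln_len[u] = r.aln_len;
  }
  return DataFrame::create(
    _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["matches"] = matches,
    _["aln_len"] = aln_len);
}

// Global (Needleman-Wunsch) affine alignment. Among all score-optimal
// alignments it reports the maximal number of identical aligned positions,
// which makes the identity fraction well-defined and symmetric in its
// arguments (co-optimal tracebacks can otherwise differ in match count).
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> H(sz, NEG_INF), E(sz, NEG_INF), F(sz, NEG_INF);
  std::vector<int> MH(sz, 0), ME(sz, 0), MF(sz, 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) {
    E[at(0, j)] = -(gap_open + (j - 1) * gap_extend);
    H[at(0, j)] = E[at(0, j)];
  }
  for (int i = 1; i <= m; ++i) {
    F[at(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    H[at(i, 0)] = F[at(i, 0)];
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // E: gap in query; no match gained
      {
        const double open = H[at(i, j - 1)] - gap_open;
        const double ext = E[at(i, j - 1)] - gap_extend;
        if (open > ext) { E[at(i, j)] = open; ME[at(i, j)] = MH[at(i, j - 1)]; }
        else if (ext > open) { E[at(i, j)] = ext; ME[at(i, j)] = ME[at(i, j - 1)]; }
        else { E[at(i, j)] = open;
               ME[at(i, j)] = std::max(MH[at(i, j - 1)], ME[at(i, j - 1)]); }
      }
      // F: gap in subject
      {
        const double open = H[at(i - 1, j)] - gap_open;
        const double ext = F[at(i - 1, j)] - gap_extend;
        if (open > ext) { F[at(i, j)] = open; MF[at(i, j)] = MH[at(i - 1, j)]; }
        else if (ext > open) { F[at(i, j)] = ext; MF[at(i, j)] = MF[at(i - 1, j)]; }
        else { F[at(i, j)] = open;
               MF[at(i, j)] = std::max(MH[at(i - 1, j)], MF[at(i - 1, j)]); }
      }
      const double sub = mat(q[i - 1] - 1, s[j - 1] - 1);
      const double diag = H[at(i - 1, j - 1)] + sub;
      const int mdiag = MH[at(i - 1, j - 1)] + (q[i - 1] == s[j - 1] ? 1 : 0);
      double h = diag; int mh = mdiag;
      if (E[at(i, j)] > h) { h = E[at(i, j)]; mh = ME[at(i, j)]; }
      else if (E[at(i, j)] == h) mh = std::max(mh, ME[at(i, j)]);
      if (F[at(i, j)] > h) { h = F[at(i, j)]; mh = MF[at(i, j)]; }
      else if (F[at(i, j)] == h) mh = std::max(mh, MF[at(i, j)]);
      H[at(i, j)] = h; MH[at(i, j)] = mh;
    }
  }
  return List::create(_["score"] = H[at(m, n)],
                      _["matches"] = MH[at(m, n)]);
}

// Pairwise identity matrix over a sequence set (global alignment identity,
// denominator = shorter sequence). Used for distance matrices and clustering.
// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(List seqs, IntegerMatrix mat,
                                  double gap_open, double gap_extend) {
  const int k = seqs.size();
  NumericMatrix out(k, k);
  for (int a = 0; a < k; ++a) {
    out(a, a) = 1.0;
    IntegerVector qa = seqs[a];
    for (int b = a + 1; b < k; ++b) {
      IntegerVector sb = seqs[b];
      List r = nw_align_cpp(qa, sb, mat, gap_open, gap_extend);
      const int matches = r["matches"];
      const double id =
          (double)matches / std::min((double)qa.size(), (double)sb.size());
      out(a, b) = id;
      out(b, a) = id;
    }
  }
  return out;
}
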