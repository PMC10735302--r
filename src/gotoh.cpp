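#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over integer-encoded
// residues. A gap of length L costs gap_open + L * gap_extend (so a
// length-1 gap costs gap_open + gap_extend). Three states per cell:
//   M - q[i] aligned to r[j] (diagonal)
//   E - gap in the reference row, consuming a query residue ("up")
//   F - gap in the query row, consuming a reference residue ("left")
// Ties are broken with fixed priority M > E > F (diagonal > up > left),
// both when filling and during traceback, so results are deterministic.
//
// mode: 0 = global, 1 = local (Smith-Waterman), 2 = semiglobal (terminal
// gaps in the query row -- i.e. unaligned reference overhangs -- are free;
// the query itself is aligned end to end).

static const int NEG = INT_MIN / 4;

static inline int max3(int a, int b, int c) {
  int m = a;
  if (b > m) m = b;
  if (c > m) m = c;
  return m;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector q, IntegerVector r, IntegerMatrix mat,
                 int gap_open, int gap_extend, int mode) {
  const int m = q.size(), n = r.size();
  const int open_cost = gap_open + gap_extend;

  std::vector<int> qcol, rcol; // 0-based residue index per column, -1 = gap
  int score = 0;
  int qstart = 1, qend = m, rstart = 1, rend = n;

  // degenerate sizes (validated upstream for local mode)
  if (m == 0 || n == 0) {
    if (m == 0 && n == 0) {
      score = 0;
    } else if (m == 0) {
      score = (mode == 0) ? -(gap_open + n * gap_extend) : 0;
      for (int j = 0; j < n; ++j) { qcol.push_back(-1); rcol.push_back(j); }
    } else {
      score = (mode == 1) ? 0 : -(gap_open + m * gap_extend);
      if (mode != 1)
        for (int i = 0; i < m; ++i) { qcol.push_back(i); rcol.push_back(-1); }
    }
    if (mode == 1) { qstart = qend = rstart = rend = 0; }
    return List::create(_["score"] = score,
                        _["q_col"] = IntegerVector(qcol.begin(), qcol.end()),
                        _["r_col"] = IntegerVector(rcol.begin(), rcol.end()),
                        _["q_start"] = qstart, _["q_end"] = qend,
                        _["r_start"] = rstart, _["r_end"] = rend);
  }

  const size_t W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) {
    if (mode == 1) M[IDX(i, 0)] = 0;
    else E[IDX(i, 0)] = -(gap_open + i * gap_extend);
  }
  for (int j = 1; j <= n; ++j) {
    if (mode == 0) F[IDX(0, j)] = -(gap_open + j * gap_extend);
    else if (mode == 1) M[IDX(0, j)] = 0;
    else F[IDX(0, j)] = 0; // semiglobal: free leading reference overhang
  }

  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int s = mat(qi, r[j - 1]);
      int diag = max3(M[IDX(i - 1, j - 1)], E[IDX(i - 1, j - 1)],
                      F[IDX(i - 1, j - 1)]);
      int mv = (diag <= NEG / 2) ? NEG : diag + s;
      if (mode == 1 && mv < 0) mv = 0;
      M[IDX(i, j)] = mv;

      int eu = max3(M[IDX(i - 1, j)] == NEG ? NEG : M[IDX(i - 1, j)] - open_cost,
                    E[IDX(i - 1, j)] == NEG ? NEG : E[IDX(i - 1, j)] - gap_extend,
                    F[IDX(i - 1, j)] == NEG ? NEG : F[IDX(i - 1, j)] - open_cost);
      E[IDX(i, j)] = (eu <= NEG / 2) ? NEG : eu;

      int fl = max3(M[IDX(i, j - 1)] == NEG ? NEG : M[IDX(i, j - 1)] - open_cost,
                    E[IDX(i, j - 1)] == NEG ? NEG : E[IDX(i, j - 1)] - open_cost,
                    F[IDX(i, j - 1)] == NEG ? NEG : F[IDX(i, j - 1)] - gap_extend);
      F[IDX(i, j)] = (fl <= NEG / 2) ? NEG : fl;
    }
  }

  // locate the traceback start
  int bi = m, bj = n;
  int state; // 0 = M, 1 = E, 2 = F
  if (mode == 1) {
    int best = 0; bi = 0; bj = 0;
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j)
        if (M[IDX(i, j)] > best) { best = M[IDX(i, j)]; bi = i; bj = j; }
    score = best;
    state = 0;
    if (best == 0) { // no positive-scoring alignment
      return List::create(_["score"] = 0,
                          _["q_col"] = IntegerVector(0),
                          _["r_col"] = IntegerVector(0),
                          _["q_start"] = 0, _["q_end"] = 0,
                          _["r_start"] = 0, _["r_end"] = 0);
    }
    qend = bi; rend = bj;
  } else if (mode == 2) {
    // free trailing reference overhang: best over the last query row
    int best = NEG; int bestj = n; int beststate = 0;
    for (int j = 0; j <= n; ++j) {
      const int vm = M[IDX(m, j)], ve = E[IDX(m, j)];
      // F at (m, j) would be an internal query gap ending before a free
      // tail; allowed too (counts as penalized internal gap) -- but a
      // trailing F run is better represented by stopping earlier, and the
      // free tail makes any trailing F suboptimal or equal; include it for
      // completeness with lowest priority.
      const int vf = F[IDX(m, j)];
      int v = max3(vm, ve, vf);
      if (v > best) {
        best = v; bestj = j;
        beststate = (v == vm) ? 0 : (v == ve ? 1 : 2);
      }
    }
    score = best; bj = bestj; state = beststate;
  } else {
    const int vm = M[IDX(m, n)], ve = E[IDX(m, n)], vf = F[IDX(m, n)];
    score = max3(vm, ve, vf);
    state = (score == vm) ? 0 : (score == ve ? 1 : 2);
  }

  // traceback (columns collected in reverse)
  std::vector<int> rq, rr;
  if (mode == 2) // free trailing overhang columns
    for (int j = n - 1; j >= bj; --j) { rq.push_back(-1); rr.push_back(j); }

  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    if (mode == 1 && state == 0 && M[IDX(i, j)] == 0 && (i < bi || j < bj)) break;
    if (mode == 2 && i == 0) break; // free leading overhang handled below
    if (state == 0) {
      rq.push_back(i - 1); rr.push_back(j - 1);
      const int target = M[IDX(i, j)] - mat(q[i - 1], r[j - 1]);
      --i; --j;
      if (mode == 1 && M[IDX(i, j)] == 0 && target == 0) { state = 0; continue; }
      if (M[IDX(i, j)] == target) state = 0;
      else if (E[IDX(i, j)] == target) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in reference row, consume query
      rq.push_back(i - 1); rr.push_back(-1);
      const int v = E[IDX(i, j)];
      --i;
      if (M[IDX(i, j)] != NEG && M[IDX(i, j)] - open_cost == v) state = 0;
      else if (E[IDX(i, j)] != NEG && E[IDX(i, j)] - gap_extend == v) state = 1;
      else state = 2;
    } else { // gap in query row, consume reference
      rq.push_back(-1); rr.push_back(j - 1);
      const int v = F[IDX(i, j)];
      --j;
      if (M[IDX(i, j)] != NEG && M[IDX(i, j)] - open_cost == v) state = 0;
      else if (E[IDX(i, j)] != NEG && E[IDX(i, j)] - open_cost == v) state = 1;
      else state = 2;
    }
  }
  if (mode == 1) { qstart = i + 1; rstart = j + 1; }
  if (mode == 2) // free leading overhang columns
    for (int jj = j - 1; jj >= 0; --jj) { rq.push_back(-1); rr.push_back(jj); }

  std::reverse(rq.begin(), rq.end());
  std::reverse(rr.begin(), rr.end());
  return List::create(_["score"] = score,
                      _["q_col"] = IntegerVector(rq.begin(), rq.end()),
                      _["r_col"] = IntegerVector(rr.begin(), rr.end()),
                      _["q_start"] = qstart, _["q_end"] = qend,
                      _["r_start"] = rstart, _["r_end"] = rend);
#undef IDX
}
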