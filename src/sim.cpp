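// Fast trial simulation for Markov-brain animats.
// Mirrors the R reference loop in R/trial.R exactly (tested bitwise).
#include <Rcpp.h>
using namespace Rcpp;

static const int WIDTH = 16, N_NODES = 8, N_STEPS = 35, N_ANALYZED = 33;

inline int wrap(int c) { return ((c % WIDTH) + WIDTH) % WIDTH; }

// [[Rcpp::export]]
List sim_trials_cpp(List gate_inputs, List gate_tables,
                    IntegerVector lengths, IntegerVector dirs,
                    IntegerVector init_cols, int animat_anchor0,
                    bool record) {
  int n_gates = gate_inputs.size(); // 6 (nodes 3..8, 0-based 2..7)
  std::vector<std::vector<int>> gin(n_gates);
  std::vector<std::vector<int>> gtab(n_gates);
  for (int g = 0; g < n_gates; ++g) {
    gin[g] = as<std::vector<int>>(gate_inputs[g]);   // 0-based node ids
    gtab[g] = as<std::vector<int>>(gate_tables[g]);
  }
  int nt = lengths.size();
  LogicalVector caught(nt);
  IntegerMatrix states(record ? nt * N_ANALYZED : 0, 11);

  for (int tr = 0; tr < nt; ++tr) {
    int L = lengths[tr], shift = dirs[tr];
    int banchor = wrap(init_cols[tr]);
    int brow = 0;
    int aanchor = wrap(animat_anchor0);
    int state[N_NODES] = {0};
    int nxt[N_NODES];
    // t = 1: initialization step, all-off, block advances
    brow += 1; banchor = wrap(banchor + shift);
    for (int t = 2; t <= N_STEPS; ++t) {
      // sensors: block column above leftmost / rightmost animat cell
      int sL = 0, sR = 0;
      for (int k = 0; k < L; ++k) {
        int bc = wrap(banchor + k);
        if (bc == aanchor) sL = 1;
        if (bc == wrap(aanchor + 2)) sR = 1;
      }
      state[0] = sL; state[1] = sR;
      // synchronous gate update for nodes 2..7
      for (int g = 0; g < n_gates; ++g) {
        int idx = 0;
        for (size_t j = 0; j < gin[g].size(); ++j)
          idx |= state[gin[g][j]] << j;
        nxt[g + 2] = gtab[g][idx];
      }
      for (int g = 0; g < n_gates; ++g) state[g + 2] = nxt[g + 2];
      // motors
      int mL = state[6], mR = state[7];
      if (mL == 1 && mR == 0) aanchor = wrap(aanchor - 1);
      else if (mL == 0 && mR == 1) aanchor = wrap(aanchor + 1);
      if (record && t <= N_STEPS - 1) {
        int r = tr * N_ANALYZED + (t - 2);
        for (int j = 0; j < N_NODES; ++j) states(r, j) = state[j];
        states(r, 8) = aanchor;
        states(r, 9) = brow;
        states(r, 10) = banchor;
      }
      brow += 1; banchor = wrap(banchor + shift);
    }
    // block at bottom row: overlap check
    bool hit = false;
    for (int k = 0; k < L && !hit; ++k) {
      int bc = wrap(banchor + k);
      for (int a = 0; a < 3; ++a)
        if (bc == wrap(aanchor + a)) { hit = true; break; }
    }
    caught[tr] = hit;
  }
  if (record) return List::create(_["caught"] = caught, _["states"] = states);
  return List::create(_["caught"] = caught);
}
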