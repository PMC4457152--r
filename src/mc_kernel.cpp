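#include <Rcpp.h>
using namespace Rcpp;

// Random sequential Fermi-imitation dynamics on an L x L torus.
//
// One elementary step: pick a site x uniformly at random, compute its payoff
// against its four von Neumann neighbors, pick one neighbor y uniformly,
// compute y's payoff the same way on the current grid, then let x adopt y's
// strategy with probability 1/(1 + exp((Pi_x - Pi_y)/K)). A Monte Carlo step
// (MCS) is N = L^2 elementary steps. Draws come from R's global RNG in a
// fixed order (site, neighbor, acceptance), three draws per elementary step,
// so a pure-R transcription of the same protocol reproduces trajectories
// draw for draw.

static inline double site_payoff_at(const IntegerVector &grid,
                                    const NumericVector &pay, int S,
                                    int L, int row, int col) {
  int s = grid[row + L * col];
  int up    = (row == 0 ? L - 1 : row - 1);
  int down  = (row == L - 1 ? 0 : row + 1);
  int left  = (col == 0 ? L - 1 : col - 1);
  int right = (col == L - 1 ? 0 : col + 1);
  double pi = 0.0;
  pi += pay[s + S * grid[up + L * col]];
  pi += pay[s + S * grid[down + L * col]];
  pi += pay[s + S * grid[row + L * left]];
  pi += pay[s + S * grid[row + L * right]];
  return pi;
}

static inline double fermi_w(double pix, double piy, double K) {
  double d = (pix - piy) / K;
  if (d > 700.0) d = 700.0;
  if (d < -700.0) d = -700.0;
  return 1.0 / (1.0 + std::exp(d));
}

// grid0: L x L integer matrix of 0-based strategy codes.
// pay:   S x S payoff matrix, [focal, opponent].
// Samples per-strategy counts at MCS 0 and then every sample_every sweeps;
// records the sweep at which each strategy's count first reaches zero and,
// optionally, stops once the lattice is homogeneous.
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerMatrix grid0, NumericMatrix paym, double K,
                int mcs, int sample_every, bool stop_on_absorb) {
  int L = grid0.nrow();
  if (grid0.ncol() != L) stop("grid must be square");
  int S = paym.nrow();
  int N = L * L;
  IntegerVector grid(N);
  for (int i = 0; i < N; ++i) grid[i] = grid0[i];
  NumericVector pay = as<NumericVector>(paym);

  std::vector<int> counts(S, 0);
  for (int i = 0; i < N; ++i) {
    int s = grid[i];
    if (s < 0 || s >= S) stop("strategy code out of range");
    counts[s]++;
  }

  int n_samples = 1 + (sample_every > 0 ? mcs / sample_every : 0);
  IntegerMatrix samp(n_samples, S);
  IntegerVector samp_mcs(n_samples);
  int isamp = 0;
  for (int s = 0; s < S; ++s) samp(0, s) = counts[s];
  samp_mcs[0] = 0;
  isamp = 1;

  IntegerVector extinct_mcs(S, NA_INTEGER);
  for (int s = 0; s < S; ++s) if (counts[s] == 0) extinct_mcs[s] = 0;

  RNGScope scope;
  int absorbed_at = NA_INTEGER;
  int sweep = 0;
  for (sweep = 1; sweep <= mcs; ++sweep) {
    for (int step = 0; step < N; ++step) {
      int x = (int)(unif_rand() * N);
      if (x == N) x = N - 1;            // guard: unif_rand() in (0,1)
      int row = x % L, col = x / L;
      int sx = grid[x];
      double pix = site_payoff_at(grid, pay, S, L, row, col);
      int k = (int)(unif_rand() * 4.0);
      if (k == 4) k = 3;
      int nr = row, nc = col;
      switch (k) {
        case 0: nr = (row == 0 ? L - 1 : row - 1); break;       // up
        case 1: nr = (row == L - 1 ? 0 : row + 1); break;       // down
        case 2: nc = (col == 0 ? L - 1 : col - 1); break;       // left
        default: nc = (col == L - 1 ? 0 : col + 1); break;      // right
      }
      int y = nr + L * nc;
      int sy = grid[y];
      double piy = site_payoff_at(grid, pay, S, L, nr, nc);
      double u = unif_rand();
      if (u < fermi_w(pix, piy, K) && sy != sx) {
        grid[x] = sy;
        counts[sx]--;
        counts[sy]++;
        if (counts[sx] == 0 && extinct_mcs[sx] == NA_INTEGER)
          extinct_mcs[sx] = sweep;
      }
    }
    bool homogeneous = false;
    for (int s = 0; s < S; ++s) if (counts[s] == N) homogeneous = true;
    if (sample_every > 0 && sweep % sample_every == 0 && isamp < n_samples) {
      for (int s = 0; s < S; ++s) samp(isamp, s) = counts[s];
      samp_mcs[isamp] = sweep;
      isamp++;
    }
    if (stop_on_absorb && homogeneous) break;
  }

  if (sweep > mcs) sweep = mcs;
  for (int s = 0; s < S; ++s) if (counts[s] == N) absorbed_at = sweep;

  IntegerVector final_grid(grid);
  final_grid.attr("dim") = Dimension(L, L);
  return List::create(
    _["grid"] = final_grid,
    _["sample_mcs"] = head(samp_mcs, isamp),
    _["sample_counts"] = samp(Range(0, isamp - 1), _),
    _["extinct_mcs"] = extinct_mcs,
    _["absorbed_at"] = absorbed_at,
    _["mcs_run"] = sweep
  );
}
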