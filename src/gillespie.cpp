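// Exact (direct-method) Gillespie simulation of the individual-level
// reaction rules:
//   I -> I + I   birth without mutation, rate lambda_b (1 - mu) x_i
//   I -> I + I'  birth with mutation,    rate lambda_b mu x_i
//   I -> 0       background death,       rate lambda_d x_i
//   I + J -> J   competition death,      rate d_ij per ordered victim-killer
//                pair among distinct individuals
// with d_ij = alpha + exp(-A_ij). The payoff matrix grows by one row and
// column at every mutation (offspring inherits the parent's payoffs plus
// independent Gaussian noise) and shrinks when types die out.
//
// The mutation split is resolved at birth: each birth is a mutant with
// probability mu. Same-type competition counts ordered pairs of distinct
// individuals, giving victim rate x_i * (S_i - d_ii) with
// S_i = sum_j d_ij x_j. Uses R's RNG so runs are reproducible via set.seed.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Community {
  std::vector<int> ids;
  std::vector<double> x;                 // abundances (integer-valued)
  std::vector<std::vector<double>> A;    // payoffs
  std::vector<std::vector<double>> d;    // competition death rates
  std::vector<double> S;                 // S_i = sum_j d_ij x_j
  double N = 0.0;

  int n() const { return static_cast<int>(ids.size()); }

  void recompute_S() {
    int m = n();
    S.assign(m, 0.0);
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += d[i][j] * x[j];
      S[i] = s;
    }
  }

  void abundance_change(int i, double delta) {
    x[i] += delta;
    N += delta;
    int m = n();
    for (int k = 0; k < m; ++k) S[k] += delta * d[k][i];
  }

  void remove_type(int i) {
    int m = n();
    ids.erase(ids.begin() + i);
    x.erase(x.begin() + i);
    A.erase(A.begin() + i);
    d.erase(d.begin() + i);
    for (int k = 0; k < m - 1; ++k) {
      A[k].erase(A[k].begin() + i);
      d[k].erase(d[k].begin() + i);
    }
    recompute_S();
  }

  // returns index of new type
  int add_mutant(int parent, int new_id, double sigma, double alpha, double clamp) {
    int m = n();
    std::vector<double> new_row(m + 1), new_col(m);
    for (int j = 0; j < m; ++j) new_row[j] = A[parent][j] + norm_rand() * sigma;
    for (int j = 0; j < m; ++j) new_col[j] = A[j][parent] + norm_rand() * sigma;
    new_row[m] = A[parent][parent] + norm_rand() * sigma;
    for (int j = 0; j < m; ++j) {
      A[j].push_back(new_col[j]);
      double aj = new_col[j];
      d[j].push_back(alpha + (aj > clamp ? 0.0 : std::exp(-aj)));
    }
    A.push_back(new_row);
    std::vector<double> drow(m + 1);
    for (int j = 0; j <= m; ++j) {
      double a = new_row[j];
      drow[j] = alpha + (a > clamp ? 0.0 : std::exp(-a));
    }
    d.push_back(drow);
    ids.push_back(new_id);
    x.push_back(0.0);
    S.push_back(0.0);
    recompute_S();
    return m;
  }

  NumericMatrix A_matrix() const {
    int m = n();
    NumericMatrix out(m, m);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) out(i, j) = A[i][j];
    return out;
  }
};

int sample_linear(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int m = static_cast<int>(w.size());
  for (int i = 0; i < m; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return m - 1;
}

} // namespace

// [[Rcpp::export]]
List run_gillespie_cpp(NumericMatrix A0, IntegerVector ids0, NumericVector x0,
                       double lambda_b, double lambda_d, double alpha,
                       double mu, double sigma, int t_mut_max,
                       double max_events, int next_id,
                       int trace_thin, double exp_clamp) {
  Community cm;
  int n0 = A0.nrow();
  cm.ids.assign(ids0.begin(), ids0.end());
  cm.x.assign(x0.begin(), x0.end());
  cm.A.assign(n0, std::vector<double>(n0));
  cm.d.assign(n0, std::vector<double>(n0));
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j) {
      cm.A[i][j] = A0(i, j);
      cm.d[i][j] = alpha + (A0(i, j) > exp_clamp ? 0.0 : std::exp(-A0(i, j)));
    }
  cm.N = 0.0;
  for (double xi : cm.x) cm.N += xi;
  cm.recompute_S();

  RNGScope scope;

  int t_mut = 0;
  double T = 0.0;
  long long events = 0;
  bool extinct = false;

  // per-mutation-event snapshots
  std::vector<int> snap_t, snap_n;
  std::vector<double> snap_N, snap_T;
  List snap_ids, snap_A;
  // genealogy log: (t_mut, parent id, child id)
  std::vector<int> gen_t, gen_parent, gen_child;
  // thinned event trace of N
  std::vector<double> trace_event, trace_T, trace_N;

  std::vector<double> comp(16);

  while (true) {
    if (cm.N <= 0.0) { extinct = true; break; }
    if (t_mut >= t_mut_max) break;
    if ((double)events >= max_events) break;

    int m = cm.n();
    comp.resize(m);
    double C = 0.0;
    for (int i = 0; i < m; ++i) {
      double ci = cm.x[i] * (cm.S[i] - cm.d[i][i]);
      if (ci < 0.0) ci = 0.0;  // guard against tiny negative round-off
      comp[i] = ci;
      C += ci;
    }
    double B = lambda_b * cm.N;
    double D = lambda_d * cm.N;
    double total = B + D + C;

    T += exp_rand() / total;
    events += 1;
    double u = unif_rand() * total;

    if (u < B) {
      int i = sample_linear(cm.x, cm.N);
      if (mu > 0.0 && unif_rand() < mu) {
        // mutant birth
        int child_id = next_id++;
        int parent_id = cm.ids[i];
        int k = cm.add_mutant(i, child_id, sigma, alpha, exp_clamp);
        cm.abundance_change(k, 1.0);
        ++t_mut;
        gen_t.push_back(t_mut);
        gen_parent.push_back(parent_id);
        gen_child.push_back(child_id);
        snap_t.push_back(t_mut);
        snap_N.push_back(cm.N);
        snap_n.push_back(cm.n());
        snap_T.push_back(T);
        snap_ids.push_back(IntegerVector(cm.ids.begin(), cm.ids.end()));
        snap_A.push_back(cm.A_matrix());
      } else {
        cm.abundance_change(i, 1.0);
      }
    } else {
      int i;
      if (u < B + D) {
        i = sample_linear(cm.x, cm.N);
      } else {
        i = sample_linear(comp, C);
      }
      cm.abundance_change(i, -1.0);
      if (cm.x[i] <= 0.0) cm.remove_type(i);
    }

    // periodic refresh of the incrementally maintained S against drift
    if ((events & 0x3FFFF) == 0) cm.recompute_S();

    if (trace_thin > 0 && events % trace_thin == 0) {
      trace_event.push_back((double)events);
      trace_T.push_back(T);
      trace_N.push_back(cm.N);
    }
  }

  List final_state = List::create(
      _["ids"] = IntegerVector(cm.ids.begin(), cm.ids.end()),
      _["x"] = NumericVector(cm.x.begin(), cm.x.end()),
      _["A"] = cm.A_matrix(),
      _["next_id"] = next_id);

  return List::create(
      _["snap_t_mut"] = IntegerVector(snap_t.begin(), snap_t.end()),
      _["snap_N"] = NumericVector(snap_N.begin(), snap_N.end()),
      _["snap_n"] = IntegerVector(snap_n.begin(), snap_n.end()),
      _["snap_T"] = NumericVector(snap_T.begin(), snap_T.end()),
      _["snap_ids"] = snap_ids,
      _["snap_A"] = snap_A,
      _["genealogy"] = DataFrame::create(
          _["t_mut"] = IntegerVector(gen_t.begin(), gen_t.end()),
          _["parent"] = IntegerVector(gen_parent.begin(), gen_parent.end()),
          _["child"] = IntegerVector(gen_child.begin(), gen_child.end())),
      _["trace"] = DataFrame::create(
          _["event"] = NumericVector(trace_event.begin(), trace_event.end()),
          _["T"] = NumericVector(trace_T.begin(), trace_T.end()),
          _["N"] = NumericVector(trace_N.begin(), trace_N.end())),
      _["final"] = final_state,
      _["extinct"] = extinct,
      _["t_mut"] = t_mut,
      _["wall_time"] = T,
      _["events"] = (double)events);
}
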