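#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// J is an L x L x q x q array in R's column-major layout
static inline double Jat(const NumericVector& J, int L, int q,
                         int i, int j, int a, int b) {
  return J[i + (size_t)L * j + (size_t)L * L * a + (size_t)L * L * q * b];
}

static inline double evh_of(const NumericMatrix& h, const NumericVector& J,
                            int L, int q, const int* s) {
  double e = 0.0;
  for (int i = 0; i < L; ++i) e += h(i, s[i]);
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j)
      e += Jat(J, L, q, i, j, s[i], s[j]);
  return e;
}

// [[Rcpp::export]]
double cpp_evh(NumericMatrix h, NumericVector J, IntegerVector s0) {
  int L = h.nrow(), q = h.ncol();
  std::vector<int> s(s0.begin(), s0.end());
  return evh_of(h, J, L, q, s.data());
}

// [[Rcpp::export]]
NumericVector cpp_evh_many(NumericMatrix h, NumericVector J, IntegerMatrix X0) {
  int L = h.nrow(), q = h.ncol(), n = X0.nrow();
  NumericVector out(n);
  std::vector<int> s(L);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < L; ++i) s[i] = X0(r, i);
    out[r] = evh_of(h, J, L, q, s.data());
  }
  return out;
}

// incremental ddEVH of replacing bg at positions pos0 with states st0
// [[Rcpp::export]]
double cpp_delta_evh(NumericMatrix h, NumericVector J, IntegerVector bg0,
                     IntegerVector pos0, IntegerVector st0) {
  int L = h.nrow(), q = h.ncol(), K = pos0.size();
  std::vector<int> mut(bg0.begin(), bg0.end());
  for (int k = 0; k < K; ++k) mut[pos0[k]] = st0[k];
  double d = 0.0;
  // field terms + pair terms touching mutated positions; pairs of two
  // mutated positions counted once
  for (int k = 0; k < K; ++k) {
    int i = pos0[k];
    d += h(i, mut[i]) - h(i, bg0[i]);
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      bool j_mut = false;
      for (int k2 = 0; k2 < K; ++k2) if (pos0[k2] == j) { j_mut = true; break; }
      if (j_mut && j < i) continue;  // count mutated pair once
      d += Jat(J, L, q, i, j, mut[i], mut[j]) - Jat(J, L, q, i, j, bg0[i], bg0[j]);
    }
  }
  return d;
}

// scan all single substitutions over allowed states
// [[Rcpp::export]]
List cpp_mutation_scan(NumericMatrix h, NumericVector J, IntegerVector bg0,
                       IntegerVector states0) {
  int L = h.nrow(), q = h.ncol(), ns = states0.size();
  std::vector<int> pos; std::vector<int> st; std::vector<double> del;
  pos.reserve((size_t)L * ns); st.reserve((size_t)L * ns); del.reserve((size_t)L * ns);
  for (int i = 0; i < L; ++i) {
    int cur = bg0[i];
    // coupling sums to the rest of the sequence for each candidate state
    for (int k = 0; k < ns; ++k) {
      int a = states0[k];
      if (a == cur) continue;
      double d = h(i, a) - h(i, cur);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        d += Jat(J, L, q, i, j, a, bg0[j]) - Jat(J, L, q, i, j, cur, bg0[j]);
      }
      pos.push_back(i); st.push_back(a); del.push_back(d);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["state"] = wrap(st),
                      _["delta"] = wrap(del));
}

// [[Rcpp::export]]
NumericVector cpp_sequence_weights(IntegerMatrix X, double theta) {
  int n = X.nrow(), L = X.ncol();
  std::vector<int> nb(n, 1);  // each record neighbours itself
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int mism = 0;
      for (int i = 0; i < L; ++i) if (X(a, i) != X(b, i)) ++mism;
      if ((double)mism / L < theta) { ++nb[a]; ++nb[b]; }
    }
  }
  NumericVector w(n);
  for (int a = 0; a < n; ++a) w[a] = 1.0 / nb[a];
  return w;
}

// ---- regularized pseudolikelihood: one site's conditional problem --------
// par = [h_i(0..q-1), J-block for each other site jj (q x q, column-major:
// entry (a, b) = par[q + jj*q*q + a + q*b], a = state of site i, b = state
// of site j)]. Returns weighted negative conditional log-likelihood plus
// lambda_h*||h||^2 + lambda_Jc*||J||^2, and its gradient.
// [[Rcpp::export]]
List cpp_plm_site(NumericVector par, IntegerMatrix X0, NumericVector w,
                  int site0, double lambda_h, double lambda_Jc, int q) {
  int n = X0.nrow(), L = X0.ncol(), i = site0;
  int npar = q + (L - 1) * q * q;
  if (par.size() != npar) stop("parameter vector has wrong length");
  NumericVector grad(npar);
  double nll = 0.0;
  std::vector<double> logit(q), p(q);
  // map other-site index j -> slot jj
  std::vector<int> slot(L, -1);
  { int jj = 0; for (int j = 0; j < L; ++j) if (j != i) slot[j] = jj++; }
  for (int r = 0; r < n; ++r) {
    double wr = w[r];
    for (int a = 0; a < q; ++a) logit[a] = par[a];
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      int b = X0(r, j);
      const double* blk = &par[q + (size_t)slot[j] * q * q + (size_t)q * b];
      for (int a = 0; a < q; ++a) logit[a] += blk[a];
    }
    double mx = logit[0];
    for (int a = 1; a < q; ++a) if (logit[a] > mx) mx = logit[a];
    double Z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(logit[a] - mx); Z += p[a]; }
    int xi = X0(r, i);
    nll += wr * (std::log(Z) + mx - logit[xi]);
    for (int a = 0; a < q; ++a) {
      double g = wr * (p[a] / Z - (a == xi ? 1.0 : 0.0));
      grad[a] += g;
      // chain through every J block at the observed partner state
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        grad[q + (size_t)slot[j] * q * q + (size_t)q * X0(r, j) + a] += g;
      }
    }
  }
  // L2 penalties
  for (int k = 0; k < q; ++k) {
    nll += lambda_h * par[k] * par[k];
    grad[k] += 2.0 * lambda_h * par[k];
  }
  for (int k = q; k < npar; ++k) {
    nll += lambda_Jc * par[k] * par[k];
    grad[k] += 2.0 * lambda_Jc * par[k];
  }
  return List::create(_["value"] = nll, _["gradient"] = grad);
}

// ---- penalized batch Gibbs sampler ---------------------------------------

// band membership with a small tolerance so D values that are exact
// multiples of 1/L compare reliably against the bounds
static inline bool in_band(double D, double dmin, double dmax) {
  return D >= dmin - 1e-9 && D <= dmax + 1e-9;
}
static inline double target_pen(int mism, int L, double lt,
                                double dmin, double dmax) {
  double D = (double)mism / L;
  return in_band(D, dmin, dmax) ? 0.0 : lt * std::fabs(D - dmin);
}
static inline bool too_close(int mism, int L, double dfloor) {
  return (double)mism / L < dfloor - 1e-9;
}

// Annealed batch Gibbs sampling of M sequences under
// U(sigma_a) = -EVH + target-band + batch-diversity + alignment penalties.
// All inputs 0-based. target0 may be length 0 (no target penalty); msa0 may
// have 0 rows. beta_sched has one value per sweep; one sweep = M*L random
// single-site updates. If count_states = true (requires pow(q, L) <= guard
// checked in R), visits of every member after each sweep are tallied.
// [[Rcpp::export]]
List cpp_gibbs_design(NumericMatrix h, NumericVector J, IntegerVector target0,
                      IntegerMatrix msa0, IntegerMatrix init0,
                      IntegerVector propose0, NumericVector beta_sched,
                      double dmin, double dmax, double ddiv, double daln,
                      double lt, double ld, double la,
                      bool count_states) {
  int L = h.nrow(), q = h.ncol();
  int M = init0.nrow(), N = msa0.nrow();
  int n_prop = propose0.size(), n_sweeps = beta_sched.size();
  bool has_target = target0.size() == L;

  IntegerMatrix S(clone(init0));
  std::vector<double> evh_cur(M);
  std::vector<int> mt(M, 0);                    // mismatches to target
  std::vector<std::vector<int>> mb(M, std::vector<int>(M, 0));  // batch pairs
  std::vector<std::vector<int>> ma(M, std::vector<int>(N, 0));  // vs MSA rows
  for (int a = 0; a < M; ++a) {
    std::vector<int> s(L);
    for (int i = 0; i < L; ++i) s[i] = S(a, i);
    evh_cur[a] = evh_of(h, J, L, q, s.data());
    if (has_target)
      for (int i = 0; i < L; ++i) if (S(a, i) != target0[i]) ++mt[a];
    for (int b = a + 1; b < M; ++b) {
      int m = 0;
      for (int i = 0; i < L; ++i) if (S(a, i) != S(b, i)) ++m;
      mb[a][b] = mb[b][a] = m;
    }
    for (int r = 0; r < N; ++r) {
      int m = 0;
      for (int i = 0; i < L; ++i) if (S(a, i) != msa0(r, i)) ++m;
      ma[a][r] = m;
    }
  }

  NumericVector trace_U(n_sweeps);
  std::vector<double> state_counts;
  size_t n_states = 0;
  if (count_states) {
    n_states = 1;
    for (int i = 0; i < L; ++i) n_states *= (size_t)q;
    state_counts.assign(n_states, 0.0);
  }

  std::vector<double> dE(n_prop), dU(n_prop), pr(n_prop);
  for (int sw = 0; sw < n_sweeps; ++sw) {
    double beta = beta_sched[sw];
    for (int step = 0; step < M * L; ++step) {
      int a = (int)(unif_rand() * M); if (a == M) a = M - 1;
      int i = (int)(unif_rand() * L); if (i == L) i = L - 1;
      int cur = S(a, i);
      // EVH deltas for every candidate state
      for (int k = 0; k < n_prop; ++k) {
        int x = propose0[k];
        dE[k] = h(i, x) - h(i, cur);
      }
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        int sj = S(a, j);
        double base = Jat(J, L, q, i, j, cur, sj);
        for (int k = 0; k < n_prop; ++k)
          dE[k] += Jat(J, L, q, i, j, propose0[k], sj) - base;
      }
      // penalty deltas on the total batch energy (diversity pairs appear in
      // both members' U, hence the factor 2)
      for (int k = 0; k < n_prop; ++k) {
        int x = propose0[k];
        double d = -dE[k];
        if (has_target && lt > 0) {
          int m_new = mt[a] - (cur != target0[i]) + (x != target0[i]);
          d += target_pen(m_new, L, lt, dmin, dmax) -
               target_pen(mt[a], L, lt, dmin, dmax);
        }
        if (ld > 0) {
          for (int b = 0; b < M; ++b) {
            if (b == a) continue;
            int m_new = mb[a][b] - (cur != S(b, i)) + (x != S(b, i));
            d += 2.0 * ld * ((too_close(m_new, L, ddiv) ? 1 : 0) -
                             (too_close(mb[a][b], L, ddiv) ? 1 : 0));
          }
        }
        if (la > 0 && N > 0) {
          for (int r = 0; r < N; ++r) {
            int m_new = ma[a][r] - (cur != msa0(r, i)) + (x != msa0(r, i));
            d += la * ((too_close(m_new, L, daln) ? 1 : 0) -
                       (too_close(ma[a][r], L, daln) ? 1 : 0));
          }
        }
        dU[k] = d;
      }
      double mn = dU[0];
      for (int k = 1; k < n_prop; ++k) if (dU[k] < mn) mn = dU[k];
      double Z = 0.0;
      for (int k = 0; k < n_prop; ++k) { pr[k] = std::exp(-beta * (dU[k] - mn)); Z += pr[k]; }
      double u = unif_rand() * Z, acc = 0.0;
      int sel = n_prop - 1;
      for (int k = 0; k < n_prop; ++k) { acc += pr[k]; if (u <= acc) { sel = k; break; } }
      int x = propose0[sel];
      if (x != cur) {
        evh_cur[a] += dE[sel];
        if (has_target) mt[a] += (x != target0[i]) - (cur != target0[i]);
        for (int b = 0; b < M; ++b) {
          if (b == a) continue;
          int dm = (x != S(b, i)) - (cur != S(b, i));
          mb[a][b] += dm; mb[b][a] += dm;
        }
        for (int r = 0; r < N; ++r)
          ma[a][r] += (x != msa0(r, i)) - (cur != msa0(r, i));
        S(a, i) = x;
      }
    }
    // total batch energy from the maintained statistics
    double U = 0.0;
    for (int a = 0; a < M; ++a) {
      U -= evh_cur[a];
      if (has_target) U += target_pen(mt[a], L, lt, dmin, dmax);
      for (int b = 0; b < M; ++b)
        if (b != a && too_close(mb[a][b], L, ddiv)) U += ld;
      for (int r = 0; r < N; ++r)
        if (too_close(ma[a][r], L, daln)) U += la;
    }
    trace_U[sw] = U;
    if (count_states) {
      for (int a = 0; a < M; ++a) {
        size_t idx = 0, mult = 1;
        for (int i = 0; i < L; ++i) { idx += (size_t)S(a, i) * mult; mult *= q; }
        state_counts[idx] += 1.0;
      }
    }
  }
  List out = List::create(_["batch"] = S, _["evh"] = wrap(evh_cur),
                          _["trace_U"] = trace_U);
  if (count_states) out["state_counts"] = wrap(state_counts);
  return out;
}

// ---- parallel tempering on EVH -------------------------------------------
// R replicas, replica r targets exp(beta_r * EVH); after sweep i,
// beta_r = beta0_r * growth^i. Adjacent Metropolis swaps each sweep with
// acceptance min(1, exp((beta_r - beta_{r+1}) (U_r - U_{r+1}))), U = -EVH.
// Returns the best-EVH sequence ever visited.
// [[Rcpp::export]]
List cpp_tempering(NumericMatrix h, NumericVector J, IntegerMatrix init0,
                   NumericVector beta0, double growth, int n_sweeps,
                   IntegerVector propose0) {
  int L = h.nrow(), q = h.ncol();
  int R = init0.nrow(), n_prop = propose0.size();
  IntegerMatrix S(clone(init0));
  std::vector<double> evh_cur(R), beta(R);
  for (int r = 0; r < R; ++r) {
    std::vector<int> s(L);
    for (int i = 0; i < L; ++i) s[i] = S(r, i);
    evh_cur[r] = evh_of(h, J, L, q, s.data());
    beta[r] = beta0[r];
  }
  double best = R_NegInf;
  std::vector<int> best_seq(L);
  NumericVector trace_best(n_sweeps);
  std::vector<double> dE(n_prop), pr(n_prop);
  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int r = 0; r < R; ++r) {
      for (int step = 0; step < L; ++step) {
        int i = (int)(unif_rand() * L); if (i == L) i = L - 1;
        int cur = S(r, i);
        for (int k = 0; k < n_prop; ++k) dE[k] = h(i, propose0[k]) - h(i, cur);
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          int sj = S(r, j);
          double base = Jat(J, L, q, i, j, cur, sj);
          for (int k = 0; k < n_prop; ++k)
            dE[k] += Jat(J, L, q, i, j, propose0[k], sj) - base;
        }
        double mx = dE[0];
        for (int k = 1; k < n_prop; ++k) if (dE[k] > mx) mx = dE[k];
        double Z = 0.0;
        for (int k = 0; k < n_prop; ++k) { pr[k] = std::exp(beta[r] * (dE[k] - mx)); Z += pr[k]; }
        double u = unif_rand() * Z, acc = 0.0;
        int sel = n_prop - 1;
        for (int k = 0; k < n_prop; ++k) { acc += pr[k]; if (u <= acc) { sel = k; break; } }
        if (propose0[sel] != cur) {
          S(r, i) = propose0[sel];
          evh_cur[r] += dE[sel];
        }
      }
      if (evh_cur[r] > best) {
        best = evh_cur[r];
        for (int i = 0; i < L; ++i) best_seq[i] = S(r, i);
      }
    }
    // adjacent replica swaps (U = -EVH)
    for (int r = 0; r + 1 < R; ++r) {
      double lacc = (beta[r] - beta[r + 1]) * (-evh_cur[r] - (-evh_cur[r + 1]));
      if (lacc >= 0 || unif_rand() < std::exp(lacc)) {
        for (int i = 0; i < L; ++i) std::swap(S(r, i), S(r + 1, i));
        std::swap(evh_cur[r], evh_cur[r + 1]);
      }
    }
    for (int r = 0; r < R; ++r) beta[r] = beta0[r] * std::pow(growth, sw + 1);
    trace_best[sw] = best;
  }
  return List::create(_["best_seq"] = wrap(best_seq), _["best_evh"] = best,
                      _["trace_best_evh"] = trace_best,
                      _["final"] = S, _["final_evh"] = wrap(evh_cur));
}

// ---- single-chain Gibbs sampler over the full alphabet -------------------
// Draws n samples from p(sigma) proportional to exp(beta * EVH(sigma)),
// recording the chain every `thin` sweeps after `burn_in` sweeps.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_chain(NumericMatrix h, NumericVector J, double beta,
                              int n, int burn_in, int thin,
                              IntegerVector init0) {
  int L = h.nrow(), q = h.ncol();
  std::vector<int> s(init0.begin(), init0.end());
  IntegerMatrix out(n, L);
  std::vector<double> logit(q), pr(q);
  int total_sweeps = burn_in + n * thin, taken = 0;
  for (int sw = 0; sw < total_sweeps; ++sw) {
    for (int step = 0; step < L; ++step) {
      int i = (int)(unif_rand() * L); if (i == L) i = L - 1;
      for (int a = 0; a < q; ++a) logit[a] = h(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        for (int a = 0; a < q; ++a) logit[a] += Jat(J, L, q, i, j, a, s[j]);
      }
      double mx = logit[0];
      for (int a = 1; a < q; ++a) if (logit[a] > mx) mx = logit[a];
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { pr[a] = std::exp(beta * (logit[a] - mx)); Z += pr[a]; }
      double u = unif_rand() * Z, acc = 0.0;
      int sel = q - 1;
      for (int a = 0; a < q; ++a) { acc += pr[a]; if (u <= acc) { sel = a; break; } }
      s[i] = sel;
    }
    if (sw >= burn_in && (sw - burn_in + 1) % thin == 0 && taken < n) {
      for (int i = 0; i < L; ++i) out(taken, i) = s[i];
      ++taken;
    }
  }
  return out;
}
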