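// Collapsed allocation sampler for the multivariate Bernoulli mixture with a
// truncated Poisson prior on the number of components, run as a ladder of
// Metropolis-coupled (tempered) chains with state-swap moves.
//
// The state of each chain is (K, z): K labelled components (empty ones
// allowed) and a label per row. Mixture weights and Bernoulli probabilities
// are integrated out; every move evaluates the collapsed joint through the
// sufficient statistics n_k and s_jk only. Per-component log tables
// log(alpha + s_jk), log(beta + n_k - s_jk), log(alpha + beta + n_k) are
// cached and refreshed only for components whose statistics change, which
// keeps a full Gibbs pass at O(n * K * p) additions.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Prior {
  double lambda, gamma, alpha, beta;
  int Kmax;
  double log_k_norm;  // log of the truncated Poisson normalizer
};

struct Chain {
  int K;                      // labelled components
  std::vector<int> z;         // 0-based labels, length n
  std::vector<int> nk;        // length Kmax
  std::vector<int> s;         // p x Kmax, column-major: s[j + p*k]
  std::vector<double> lt1;    // log(alpha + s_jk), same layout as s
  std::vector<double> lt0;    // log(beta + n_k - s_jk)
  std::vector<double> ld;     // log(alpha + beta + n_k), length Kmax
};

struct Data {
  int n, p;
  std::vector<unsigned char> x;  // row-major: x[i*p + j]
};

double log_k_prior(int K, const Prior& pr) {
  if (K < 1 || K > pr.Kmax) return R_NegInf;
  return K * std::log(pr.lambda) - std::lgamma((double)K + 1.0) - pr.log_k_norm;
}

void refresh_comp(Chain& ch, const Prior& pr, int p, int k) {
  const int base = p * k;
  const double nk = ch.nk[k];
  for (int j = 0; j < p; ++j) {
    ch.lt1[base + j] = std::log(pr.alpha + ch.s[base + j]);
    ch.lt0[base + j] = std::log(pr.beta + nk - ch.s[base + j]);
  }
  ch.ld[k] = std::log(pr.alpha + pr.beta + nk);
}

// Contribution of component k to the collapsed joint (0 for empty k).
double comp_term(const Chain& ch, const Prior& pr, int p, int k) {
  const int nk = ch.nk[k];
  if (nk == 0) return 0.0;
  const int base = p * k;
  double out = std::lgamma(nk + pr.gamma) - std::lgamma(pr.gamma);
  const double lb0 = R::lbeta(pr.alpha, pr.beta);
  for (int j = 0; j < p; ++j) {
    const int s = ch.s[base + j];
    out += R::lbeta(pr.alpha + s, pr.beta + nk - s) - lb0;
  }
  return out;
}

double log_joint(const Chain& ch, const Prior& pr, const Data& d) {
  double out = std::lgamma(ch.K * pr.gamma) -
               std::lgamma(ch.K * pr.gamma + d.n);
  for (int k = 0; k < ch.K; ++k) out += comp_term(ch, pr, d.p, k);
  return out;
}

void remove_row(Chain& ch, const Prior& pr, const Data& d, int i) {
  const int k = ch.z[i];
  const int base = d.p * k;
  const unsigned char* xi = &d.x[(size_t)i * d.p];
  ch.nk[k] -= 1;
  for (int j = 0; j < d.p; ++j) ch.s[base + j] -= xi[j];
  refresh_comp(ch, pr, d.p, k);
}

void add_row(Chain& ch, const Prior& pr, const Data& d, int i, int k) {
  const int base = d.p * k;
  const unsigned char* xi = &d.x[(size_t)i * d.p];
  ch.nk[k] += 1;
  for (int j = 0; j < d.p; ++j) ch.s[base + j] += xi[j];
  ch.z[i] = k;
  refresh_comp(ch, pr, d.p, k);
}

// One full Gibbs reallocation pass at inverse temperature t.
void gibbs_pass(Chain& ch, const Prior& pr, const Data& d, double t,
                std::vector<double>& lw) {
  const int K = ch.K, p = d.p;
  for (int i = 0; i < d.n; ++i) {
    remove_row(ch, pr, d, i);
    const unsigned char* xi = &d.x[(size_t)i * p];
    double lmax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const int base = p * k;
      double acc = std::log(ch.nk[k] + pr.gamma) - p * ch.ld[k];
      for (int j = 0; j < p; ++j)
        acc += xi[j] ? ch.lt1[base + j] : ch.lt0[base + j];
      acc *= t;
      lw[k] = acc;
      if (acc > lmax) lmax = acc;
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { lw[k] = std::exp(lw[k] - lmax); tot += lw[k]; }
    double u = R::unif_rand() * tot;
    int knew = K - 1;
    for (int k = 0; k < K; ++k) { u -= lw[k]; if (u <= 0) { knew = k; break; } }
    add_row(ch, pr, d, i, knew);
  }
}

// Metropolis block reallocation: propose fresh uniform labels for a small
// random set of rows; symmetric proposal, accepted on the tempered
// collapsed-joint ratio.
bool block_move(Chain& ch, const Prior& pr, const Data& d, double t) {
  const int K = ch.K;
  const int bmax = std::min(d.n, 10);
  const int b = 1 + (int)(R::unif_rand() * bmax);
  std::vector<int> rows(b), old_lab(b), new_lab(b);
  // sample rows without replacement (small b, rejection is fine)
  for (int m = 0; m < b; ++m) {
    int r;
    bool dup;
    do {
      r = (int)(R::unif_rand() * d.n);
      if (r == d.n) r = d.n - 1;
      dup = false;
      for (int q = 0; q < m; ++q) if (rows[q] == r) { dup = true; break; }
    } while (dup);
    rows[m] = r;
    old_lab[m] = ch.z[r];
    int lab = (int)(R::unif_rand() * K);
    if (lab == K) lab = K - 1;
    new_lab[m] = lab;
  }
  std::vector<int> touched;
  for (int m = 0; m < b; ++m) {
    touched.push_back(old_lab[m]);
    touched.push_back(new_lab[m]);
  }
  std::sort(touched.begin(), touched.end());
  touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
  double before = 0.0;
  for (int k : touched) before += comp_term(ch, pr, d.p, k);
  for (int m = 0; m < b; ++m) {
    remove_row(ch, pr, d, rows[m]);
    add_row(ch, pr, d, rows[m], new_lab[m]);
  }
  double after = 0.0;
  for (int k : touched) after += comp_term(ch, pr, d.p, k);
  const double la = t * (after - before);
  if (std::log(R::unif_rand()) <= la) return true;
  for (int m = b - 1; m >= 0; --m) {
    remove_row(ch, pr, d, rows[m]);
    add_row(ch, pr, d, rows[m], old_lab[m]);
  }
  return false;
}

// Swap the full contents of labels k1 and k2 (a measure-preserving label
// permutation; the prior is symmetric over labels).
void swap_labels(Chain& ch, const Data& d, int k1, int k2) {
  if (k1 == k2) return;
  std::swap(ch.nk[k1], ch.nk[k2]);
  const int b1 = d.p * k1, b2 = d.p * k2;
  for (int j = 0; j < d.p; ++j) {
    std::swap(ch.s[b1 + j], ch.s[b2 + j]);
    std::swap(ch.lt1[b1 + j], ch.lt1[b2 + j]);
    std::swap(ch.lt0[b1 + j], ch.lt0[b2 + j]);
  }
  std::swap(ch.ld[k1], ch.ld[k2]);
  for (int i = 0; i < d.n; ++i) {
    if (ch.z[i] == k1) ch.z[i] = k2;
    else if (ch.z[i] == k2) ch.z[i] = k1;
  }
}

// Eject: split a uniformly chosen source component, moving each member to a
// new component with probability u ~ Beta(a_e, a_e); the new component is
// then placed at a uniformly chosen label slot. Acceptance uses the
// subset-marginal proposal probability B(a_e+m, a_e+r)/B(a_e, a_e); the
// uniform source / slot choices cancel against the absorb pair choice.
bool eject_move(Chain& ch, const Prior& pr, const Data& d, double t,
                double a_e) {
  const int K = ch.K;
  if (K >= pr.Kmax) return false;
  int k0 = (int)(R::unif_rand() * K);
  if (k0 == K) k0 = K - 1;
  const double u = R::rbeta(a_e, a_e);
  const int knew = K;  // provisional top slot
  const double before = comp_term(ch, pr, d.p, k0);
  std::vector<int> moved;
  for (int i = 0; i < d.n; ++i) {
    if (ch.z[i] == k0 && R::unif_rand() < u) moved.push_back(i);
  }
  for (int i : moved) {
    remove_row(ch, pr, d, i);
    add_row(ch, pr, d, i, knew);
  }
  const int m = (int)moved.size();
  const int r = ch.nk[k0];
  const double after = comp_term(ch, pr, d.p, k0) +
                       comp_term(ch, pr, d.p, knew);
  const double dglobal =
      (std::lgamma((K + 1) * pr.gamma) - std::lgamma((K + 1) * pr.gamma + d.n)) -
      (std::lgamma(K * pr.gamma) - std::lgamma(K * pr.gamma + d.n));
  const double dprior = log_k_prior(K + 1, pr) - log_k_prior(K, pr);
  const double lq_split = R::lbeta(a_e + m, a_e + r) - R::lbeta(a_e, a_e);
  const double la = t * (after - before + dglobal + dprior) - lq_split;
  if (std::log(R::unif_rand()) <= la) {
    ch.K = K + 1;
    int slot = (int)(R::unif_rand() * (K + 1));
    if (slot == K + 1) slot = K;
    swap_labels(ch, d, knew, slot);
    return true;
  }
  for (int i : moved) {
    remove_row(ch, pr, d, i);
    add_row(ch, pr, d, i, k0);
  }
  return false;
}

// Absorb: merge a uniformly chosen component into another, then move the top
// label into the vacated slot and decrement K. Exact reverse of eject.
bool absorb_move(Chain& ch, const Prior& pr, const Data& d, double t,
                 double a_e) {
  const int K = ch.K;
  if (K <= 1) return false;
  int ka = (int)(R::unif_rand() * K);
  if (ka == K) ka = K - 1;
  int kb = (int)(R::unif_rand() * (K - 1));
  if (kb == K - 1) kb = K - 2;
  if (kb >= ka) kb += 1;
  const int m = ch.nk[ka];
  const int r = ch.nk[kb];
  const double before = comp_term(ch, pr, d.p, ka) + comp_term(ch, pr, d.p, kb);
  // merged statistics evaluated without mutating state
  double after = 0.0;
  {
    const int nm = m + r;
    if (nm > 0) {
      after = std::lgamma(nm + pr.gamma) - std::lgamma(pr.gamma);
      const double lb0 = R::lbeta(pr.alpha, pr.beta);
      const int ba = d.p * ka, bb = d.p * kb;
      for (int j = 0; j < d.p; ++j) {
        const int s = ch.s[ba + j] + ch.s[bb + j];
        after += R::lbeta(pr.alpha + s, pr.beta + nm - s) - lb0;
      }
    }
  }
  const double dglobal =
      (std::lgamma((K - 1) * pr.gamma) - std::lgamma((K - 1) * pr.gamma + d.n)) -
      (std::lgamma(K * pr.gamma) - std::lgamma(K * pr.gamma + d.n));
  const double dprior = log_k_prior(K - 1, pr) - log_k_prior(K, pr);
  const double lq_split = R::lbeta(a_e + m, a_e + r) - R::lbeta(a_e, a_e);
  const double la = t * (after - before + dglobal + dprior) + lq_split;
  if (std::log(R::unif_rand()) > la) return false;
  // apply: members of ka -> kb, then top label -> slot ka, K--
  const int ba = d.p * ka, bb = d.p * kb;
  for (int i = 0; i < d.n; ++i) if (ch.z[i] == ka) ch.z[i] = kb;
  ch.nk[kb] += ch.nk[ka];
  ch.nk[ka] = 0;
  for (int j = 0; j < d.p; ++j) {
    ch.s[bb + j] += ch.s[ba + j];
    ch.s[ba + j] = 0;
  }
  refresh_comp(ch, pr, d.p, ka);
  refresh_comp(ch, pr, d.p, kb);
  swap_labels(ch, d, ka, K - 1);
  ch.K = K - 1;
  return true;
}

// Relabel so nonempty components occupy the lowest labels (stable); a label
// permutation only, K unchanged.
void compact_labels(Chain& ch, const Data& d) {
  int target = 0;
  for (int k = 0; k < ch.K; ++k) {
    if (ch.nk[k] > 0) {
      if (k != target) swap_labels(ch, d, k, target);
      ++target;
    }
  }
}

int nonempty_count(const Chain& ch) {
  int c = 0;
  for (int k = 0; k < ch.K; ++k) if (ch.nk[k] > 0) ++c;
  return c;
}

}  // namespace

// [[Rcpp::export]]
List run_mc3_cpp(IntegerMatrix X, double lambda, int Kmax, double gamma_,
                 double alpha, double beta, NumericVector temperatures,
                 int n_iter, int burn_in, int thin, int swap_attempts,
                 NumericVector move_mix, double eject_alpha, int k_init,
                 bool verbose) {
  Data d;
  d.n = X.nrow();
  d.p = X.ncol();
  d.x.resize((size_t)d.n * d.p);
  for (int i = 0; i < d.n; ++i)
    for (int j = 0; j < d.p; ++j)
      d.x[(size_t)i * d.p + j] = (unsigned char)X(i, j);

  Prior pr;
  pr.lambda = lambda; pr.gamma = gamma_; pr.alpha = alpha; pr.beta = beta;
  pr.Kmax = Kmax;
  {
    double lmax = R_NegInf;
    std::vector<double> terms(Kmax);
    for (int k = 1; k <= Kmax; ++k) {
      terms[k - 1] = k * std::log(lambda) - std::lgamma((double)k + 1.0);
      if (terms[k - 1] > lmax) lmax = terms[k - 1];
    }
    double tot = 0.0;
    for (int k = 0; k < Kmax; ++k) tot += std::exp(terms[k] - lmax);
    pr.log_k_norm = lmax + std::log(tot);
  }

  const int n_chains = temperatures.size();
  std::vector<Chain> chains(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    Chain& ch = chains[c];
    ch.K = std::min(k_init, Kmax);
    ch.z.resize(d.n);
    ch.nk.assign(Kmax, 0);
    ch.s.assign((size_t)d.p * Kmax, 0);
    ch.lt1.assign((size_t)d.p * Kmax, 0.0);
    ch.lt0.assign((size_t)d.p * Kmax, 0.0);
    ch.ld.assign(Kmax, 0.0);
    for (int i = 0; i < d.n; ++i) {
      int lab = (int)(R::unif_rand() * ch.K);
      if (lab == ch.K) lab = ch.K - 1;
      ch.z[i] = lab;
      ch.nk[lab] += 1;
      const unsigned char* xi = &d.x[(size_t)i * d.p];
      for (int j = 0; j < d.p; ++j) ch.s[(size_t)d.p * lab + j] += xi[j];
    }
    for (int k = 0; k < Kmax; ++k) refresh_comp(ch, pr, d.p, k);
    compact_labels(ch, d);
  }

  const int total = burn_in + n_iter;
  const int n_keep = (thin > 0) ? (n_iter / thin) : 0;
  IntegerMatrix z_draws(n_keep, d.n);
  IntegerVector k_trace(n_keep);
  NumericVector logpost_trace(n_keep);
  int kept = 0;

  // acceptance bookkeeping (cold chain for moves; global for swaps)
  double att_block = 0, acc_block = 0, att_eject = 0, acc_eject = 0,
         att_absorb = 0, acc_absorb = 0, att_swap = 0, acc_swap = 0,
         n_gibbs = 0;

  std::vector<double> lw(Kmax);
  const double m0 = move_mix[0], m1 = move_mix[1], m2 = move_mix[2];

  for (int it = 0; it < total; ++it) {
    for (int c = 0; c < n_chains; ++c) {
      Chain& ch = chains[c];
      const double t = temperatures[c];
      const double u = R::unif_rand();
      if (u < m0) {
        gibbs_pass(ch, pr, d, t, lw);
        if (c == 0) n_gibbs += 1;
      } else if (u < m0 + m1) {
        bool ok = block_move(ch, pr, d, t);
        if (c == 0) { att_block += 1; acc_block += ok; }
      } else if (u < m0 + m1 + m2) {
        if (ch.K < pr.Kmax) {
          bool ok = eject_move(ch, pr, d, t, eject_alpha);
          if (c == 0) { att_eject += 1; acc_eject += ok; }
        }
      } else {
        if (ch.K > 1) {
          bool ok = absorb_move(ch, pr, d, t, eject_alpha);
          if (c == 0) { att_absorb += 1; acc_absorb += ok; }
        }
      }
      compact_labels(ch, d);
    }
    if (n_chains >= 2) {
      for (int s = 0; s < swap_attempts; ++s) {
        int c = (int)(R::unif_rand() * (n_chains - 1));
        if (c == n_chains - 1) c = n_chains - 2;
        const double Lc = log_joint(chains[c], pr, d) +
                          log_k_prior(chains[c].K, pr);
        const double Ln = log_joint(chains[c + 1], pr, d) +
                          log_k_prior(chains[c + 1].K, pr);
        const double la = (temperatures[c] - temperatures[c + 1]) * (Ln - Lc);
        att_swap += 1;
        if (std::log(R::unif_rand()) <= la) {
          std::swap(chains[c], chains[c + 1]);
          acc_swap += 1;
        }
      }
    }
    if (it >= burn_in && thin > 0 && (it - burn_in) % thin == thin - 1 &&
        kept < n_keep) {
      const Chain& ch = chains[0];
      for (int i = 0; i < d.n; ++i) z_draws(kept, i) = ch.z[i] + 1;
      k_trace[kept] = nonempty_count(ch);
      logpost_trace[kept] = log_joint(ch, pr, d) + log_k_prior(ch.K, pr);
      ++kept;
    }
    if (verbose && (it + 1) % 1000 == 0) {
      Rcpp::Rcout << "sweep " << (it + 1) << "/" << total
                  << "  nonempty K (cold) = " << nonempty_count(chains[0])
                  << std::endl;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // final sufficient-statistic audit for the cold chain
  const Chain& cold = chains[0];
  IntegerVector nk_final(cold.K);
  for (int k = 0; k < cold.K; ++k) nk_final[k] = cold.nk[k];
  IntegerMatrix s_final(d.p, cold.K);
  for (int k = 0; k < cold.K; ++k)
    for (int j = 0; j < d.p; ++j) s_final(j, k) = cold.s[(size_t)d.p * k + j];
  IntegerVector z_final(d.n);
  for (int i = 0; i < d.n; ++i) z_final[i] = cold.z[i] + 1;

  List acc = List::create(
      _["gibbs_passes"] = n_gibbs,
      _["block"] = NumericVector::create(_["attempted"] = att_block,
                                         _["accepted"] = acc_block),
      _["eject"] = NumericVector::create(_["attempted"] = att_eject,
                                         _["accepted"] = acc_eject),
      _["absorb"] = NumericVector::create(_["attempted"] = att_absorb,
                                          _["accepted"] = acc_absorb),
      _["swap"] = NumericVector::create(_["attempted"] = att_swap,
                                        _["accepted"] = acc_swap));

  return List::create(
      _["z_draws"] = z_draws,
      _["k_trace"] = k_trace,
      _["logpost_trace"] = logpost_trace,
      _["acceptance"] = acc,
      _["final_state"] = List::create(_["z"] = z_final, _["K"] = cold.K,
                                      _["n_k"] = nk_final,
                                      _["s_jk"] = s_final));
}
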