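#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Binomial deviance; probabilities clamped away from {0,1}.
static double binom_deviance(const arma::vec &y, const arma::vec &p) {
  double d = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double pi = std::min(std::max(p[i], 1e-12), 1.0 - 1e-12);
    d += (y[i] > 0.5) ? -2.0 * std::log(pi) : -2.0 * std::log1p(-pi);
  }
  return d;
}

static arma::vec sigmoid(const arma::vec &eta) {
  return 1.0 / (1.0 + arma::exp(-eta));
}

// IRLS with step halving so the deviance never increases.
// X must already carry the intercept column. Convergence when the score
// vanishes (max |X'(y-p)| < score_tol) or the relative deviance change
// drops below dev_tol. Separation is flagged from runaway coefficients /
// a deviance collapsing to zero.
static bool irls_core(const arma::mat &X, const arma::vec &y, int maxit,
                      double score_tol, double dev_tol, arma::vec &beta,
                      double &deviance, bool &separated, bool &singular,
                      int &iters) {
  const arma::uword pdim = X.n_cols;
  beta.zeros(pdim);
  arma::vec p = sigmoid(X * beta);
  deviance = binom_deviance(y, p);
  separated = false;
  singular = false;
  bool converged = false;
  int it = 0;
  while (it < maxit) {
    ++it;
    arma::vec score = X.t() * (y - p);
    if (arma::abs(score).max() < score_tol) { converged = true; break; }
    arma::vec w = arma::clamp(p % (1.0 - p), 1e-10, 0.25);
    arma::mat XtWX = X.t() * (X.each_col() % w);
    arma::vec delta;
    if (!arma::solve(delta, XtWX, score, arma::solve_opts::no_approx)) {
      singular = true;
      break;
    }
    double step = 1.0;
    arma::vec beta_new;
    arma::vec p_new;
    double dev_new = deviance;
    for (int h = 0; h < 30; ++h) {
      beta_new = beta + step * delta;
      p_new = sigmoid(X * beta_new);
      dev_new = binom_deviance(y, p_new);
      if (dev_new <= deviance + 1e-8) break;
      step *= 0.5;
    }
    double rel = std::fabs(deviance - dev_new) / (std::fabs(deviance) + 0.1);
    beta = beta_new;
    p = p_new;
    deviance = dev_new;
    if (rel < dev_tol) { converged = true; break; }
  }
  iters = it;
  if (arma::abs(beta).max() > 20.0 || deviance < 1e-6) {
    separated = true;
    converged = false;
  }
  return converged;
}

//' @noRd
// [[Rcpp::export(name = ".irls_fit")]]
List irls_fit_cpp(const arma::mat &X, const arma::vec &y, int maxit = 100,
                  double score_tol = 1e-8, double dev_tol = 1e-10) {
  arma::vec beta;
  double deviance = NA_REAL;
  bool separated = false, singular = false;
  int iters = 0;
  bool converged = irls_core(X, y, maxit, score_tol, dev_tol, beta, deviance,
                             separated, singular, iters);
  arma::vec p = sigmoid(X * beta);
  arma::vec w = arma::clamp(p % (1.0 - p), 1e-10, 0.25);
  arma::mat XtWX = X.t() * (X.each_col() % w);
  arma::mat cov;
  arma::vec se(X.n_cols);
  if (arma::inv_sympd(cov, XtWX)) {
    se = arma::sqrt(cov.diag());
  } else {
    se.fill(NA_REAL);
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["fitted"] = p, _["deviance"] = deviance,
                      _["converged"] = converged, _["separated"] = separated,
                      _["singular"] = singular, _["iterations"] = iters);
}

// Lightweight IRLS for fitness evaluation: plain Newton steps, no
// step-halving bookkeeping, few iterations. Classification accuracy only
// needs the decision boundary, which stabilises within a handful of
// iterations; runaway coefficients under separation are bounded by the
// iteration cap and do not change the predicted class.
static void irls_fast(const arma::mat &X, const arma::vec &y, int maxit,
                      arma::vec &beta) {
  beta.zeros(X.n_cols);
  arma::vec p(y.n_elem, arma::fill::value(0.5));
  for (int it = 0; it < maxit; ++it) {
    arma::vec score = X.t() * (y - p);
    if (arma::abs(score).max() < 1e-6) break;
    arma::vec w = arma::clamp(p % (1.0 - p), 1e-10, 0.25);
    arma::mat XtWX = X.t() * (X.each_col() % w);
    arma::vec delta;
    if (!arma::solve(delta, XtWX, score, arma::solve_opts::no_approx)) break;
    beta += delta;
    p = sigmoid(X * beta);
  }
}

// Fit on the training rows of one fold and count correct test-set calls.
// Returns false when the training rows hold a single class only.
static bool fold_accuracy(const arma::mat &Xcc, const arma::vec &ycc,
                          const arma::ivec &foldcc, int f, double threshold,
                          int &correct, int &scored) {
  arma::uvec train = arma::find(foldcc != f);
  arma::uvec test = arma::find(foldcc == f);
  if (test.n_elem == 0) return true; // nothing to score in this fold
  arma::vec ytr = ycc.elem(train);
  double my = arma::mean(ytr);
  if (my <= 0.0 || my >= 1.0) return false;
  arma::mat Xtr = Xcc.rows(train);
  arma::vec beta;
  irls_fast(Xtr, ytr, 5, beta);
  arma::vec eta = Xcc.rows(test) * beta;
  double cut = std::log(threshold / (1.0 - threshold));
  for (arma::uword i = 0; i < test.n_elem; ++i) {
    int pred = eta[i] > cut ? 1 : 0;
    if (pred == (int)std::lround(ycc[test[i]])) ++correct;
    ++scored;
  }
  return true;
}

// CV accuracy of one chromosome (0-based column indices) on its
// complete-case subjects.
static double eval_chrom(const arma::mat &X, const arma::vec &y,
                         const arma::ivec &fold, const std::vector<int> &genes,
                         int k, double threshold) {
  const arma::uword n = X.n_rows;
  const int csize = (int)genes.size();
  std::vector<arma::uword> keep;
  keep.reserve(n);
  for (arma::uword i = 0; i < n; ++i) {
    bool ok = true;
    for (int j = 0; j < csize; ++j) {
      if (!arma::is_finite(X(i, genes[j]))) { ok = false; break; }
    }
    if (ok) keep.push_back(i);
  }
  if (keep.size() < 4) return 0.0;
  arma::uvec rows(keep);
  arma::mat Xcc(rows.n_elem, csize + 1);
  Xcc.col(0).ones();
  for (int j = 0; j < csize; ++j) {
    arma::vec col = X.col(genes[j]);
    Xcc.col(j + 1) = col.elem(rows);
  }
  arma::vec ycc = y.elem(rows);
  arma::ivec foldcc(rows.n_elem);
  for (arma::uword i = 0; i < rows.n_elem; ++i) foldcc[i] = fold[rows[i]];
  int correct = 0, scored = 0;
  for (int f = 1; f <= k; ++f) {
    fold_accuracy(Xcc, ycc, foldcc, f, threshold, correct, scored);
  }
  return scored > 0 ? (double)correct / scored : 0.0;
}

//' Cross-validated accuracy for a batch of fixed-size feature subsets.
//'
//' X is subjects x features with NaN for missing cells; chromosomes are
//' 1-based column indices (one row per chromosome). Subjects missing any
//' chromosome feature are dropped before fitting (complete-case rule).
//' Folds with a single training class are skipped; a chromosome with no
//' scorable fold gets fitness 0.
//' @noRd
// [[Rcpp::export(name = ".cv_fitness_batch")]]
NumericVector cv_fitness_batch(const arma::mat &X, const arma::vec &y,
                               const arma::ivec &fold,
                               const IntegerMatrix &chroms, int k,
                               double threshold = 0.5) {
  const int npop = chroms.nrow();
  const int csize = chroms.ncol();
  NumericVector out(npop);
  for (int c = 0; c < npop; ++c) {
    std::vector<int> genes(csize);
    for (int j = 0; j < csize; ++j) genes[j] = chroms(c, j) - 1;
    out[c] = eval_chrom(X, y, fold, genes, k, threshold);
  }
  return out;
}

//' One full GA run: tournament selection, uniform crossover with repair to
//' distinct genes, per-gene mutation, single-best elitism. Uses R's RNG,
//' so results are reproducible under set.seed(); fitness values are cached
//' by gene set within the run. Returns the best chromosome (1-based
//' indices) and its fitness.
//' @noRd
// [[Rcpp::export(name = ".ga_run")]]
List ga_run(const arma::mat &X, const arma::vec &y, const arma::ivec &fold,
            int k, double threshold, int pop_n, int csize, int ngen,
            double mutation, int tsize) {
  const int nf = (int)X.n_cols;
  std::unordered_map<std::string, double> cache;
  auto rand_int = [&](int n) {
    int v;
    do { v = (int)(unif_rand() * n); } while (v >= n);
    return v;
  };
  auto eval = [&](const std::vector<int> &genes) {
    std::vector<int> s(genes);
    std::sort(s.begin(), s.end());
    std::string key((const char *)s.data(), s.size() * sizeof(int));
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    double f = eval_chrom(X, y, fold, s, k, threshold);
    cache.emplace(std::move(key), f);
    return f;
  };
  auto tournament = [&](const std::vector<double> &fit) {
    int best = rand_int((int)fit.size());
    for (int t = 1; t < tsize; ++t) {
      int c = rand_int((int)fit.size());
      if (fit[c] > fit[best]) best = c;
    }
    return best;
  };

  std::vector<std::vector<int>> pop(pop_n, std::vector<int>(csize));
  for (auto &c : pop) {
    for (int j = 0; j < csize; ++j) {
      int g;
      bool dup;
      do {
        g = rand_int(nf);
        dup = false;
        for (int t = 0; t < j; ++t) if (c[t] == g) dup = true;
      } while (dup);
      c[j] = g;
    }
  }
  std::vector<double> fit(pop_n);
  for (int i = 0; i < pop_n; ++i) fit[i] = eval(pop[i]);

  for (int gen = 0; gen < ngen; ++gen) {
    int elite = (int)(std::max_element(fit.begin(), fit.end()) - fit.begin());
    std::vector<std::vector<int>> next(pop_n);
    std::vector<double> next_fit(pop_n);
    next[0] = pop[elite];
    next_fit[0] = fit[elite];
    for (int i = 1; i < pop_n; ++i) {
      int p1 = tournament(fit);
      int p2 = tournament(fit);
      std::vector<int> child(csize);
      for (int j = 0; j < csize; ++j) {
        child[j] = (unif_rand() < 0.5) ? pop[p1][j] : pop[p2][j];
      }
      for (int j = 0; j < csize; ++j) {
        if (unif_rand() < mutation) child[j] = -1;
      }
      for (int j = 0; j < csize; ++j) {  // repair: distinct genes
        bool bad = child[j] < 0;
        for (int t = 0; t < j && !bad; ++t) if (child[t] == child[j]) bad = true;
        while (bad) {
          int g = rand_int(nf);
          bad = false;
          for (int t = 0; t < csize; ++t) if (t != j && child[t] == g) bad = true;
          if (!bad) child[j] = g;
        }
      }
      next_fit[i] = eval(child);
      next[i] = std::move(child);
    }
    pop = std::move(next);
    fit = std::move(next_fit);
  }
  int best = (int)(std::max_element(fit.begin(), fit.end()) - fit.begin());
  IntegerVector genes(csize);
  for (int j = 0; j < csize; ++j) genes[j] = pop[best][j] + 1;
  return List::create(_["genes"] = genes, _["fitness"] = fit[best],
                      _["evaluations"] = (double)cache.size());
}
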