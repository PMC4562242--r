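// Searchlight engine: per-center Gaussian naive Bayes decoding under
// leave-one-run-out cross-validation, evaluated for several label sets
// (true labels plus within-run permutations) in one pass so the per-center
// z-normalized data are shared across label sets.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// splitmix64: small deterministic counter-based generator so balancing draws
// depend only on (seed, center, fold, label set), never on evaluation order.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix_key(uint64_t seed, uint64_t a, uint64_t b,
                               uint64_t c) {
  uint64_t s = seed ^ (a * 0x9E3779B97F4A7C15ULL) ^
               (b * 0xC2B2AE3D27D4EB4FULL) ^ (c * 0x165667B19E3779F9ULL);
  uint64_t st = s;
  return splitmix64(st);
}

// draw m of n indices (partial Fisher-Yates over a scratch copy)
static void sample_m_of_n(std::vector<int> &pool, int m, uint64_t &state) {
  int n = (int)pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(splitmix64(state) % (uint64_t)(n - i));
    std::swap(pool[i], pool[j]);
  }
  pool.resize(m);
  std::sort(pool.begin(), pool.end());
}

// [[Rcpp::export(name = ".searchlight_engine")]]
List searchlight_engine(const arma::mat &data,       // samples x voxels
                        const IntegerVector &voxcol, // prod(dim), 0 or 1-based
                        const IntegerMatrix &centers,// m x 3, 1-based
                        const IntegerMatrix &offsets,// k x 3
                        const IntegerVector &dims,   // 3
                        const IntegerVector &run,    // samples
                        const IntegerMatrix &labels, // samples x n_maps, 0=skip
                        const int n_classes,
                        const double floor_factor,
                        const double seed,
                        const bool store_confusion) {
  const int m = centers.nrow();
  const int n_maps = labels.ncol();
  const int n_samples = data.n_rows;
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const uint64_t useed = (uint64_t)seed;

  // eligible rows (label > 0 in the first label set; wrapper guarantees the
  // eligible set is identical across label sets)
  std::vector<int> elig;
  for (int i = 0; i < n_samples; ++i)
    if (labels(i, 0) > 0) elig.push_back(i);
  const int ne = (int)elig.size();

  // fold structure from run ids of eligible samples
  std::vector<int> uruns;
  for (int i = 0; i < ne; ++i) {
    int r = run[elig[i]];
    if (std::find(uruns.begin(), uruns.end(), r) == uruns.end())
      uruns.push_back(r);
  }
  std::sort(uruns.begin(), uruns.end());
  const int n_folds = (int)uruns.size();
  if (n_folds < 2) stop("Leave-one-run-out needs >= 2 runs.");

  NumericMatrix acc(m, n_maps);
  IntegerVector counts(m);
  NumericMatrix confusion(store_confusion ? m : 1,
                          n_classes * n_classes);

  std::vector<int> cols;
  cols.reserve(offsets.nrow());

  for (int c = 0; c < m; ++c) {
    cols.clear();
    for (int o = 0; o < offsets.nrow(); ++o) {
      int x = centers(c, 0) + offsets(o, 0);
      int y = centers(c, 1) + offsets(o, 1);
      int z = centers(c, 2) + offsets(o, 2);
      if (x < 1 || x > dx || y < 1 || y > dy || z < 1 || z > dz) continue;
      int v = voxcol[(x - 1) + (y - 1) * dx + (z - 1) * dx * dy];
      if (v > 0) cols.push_back(v - 1);
    }
    const int V = (int)cols.size();
    counts[c] = V;
    if (V < 2) {
      for (int mm = 0; mm < n_maps; ++mm) acc(c, mm) = NA_REAL;
      continue;
    }

    // gather + per-sample z-normalization (population SD across the
    // center's voxels), shared across folds and label sets
    arma::mat Z(ne, V);
    for (int j = 0; j < V; ++j)
      for (int i = 0; i < ne; ++i) Z(i, j) = data(elig[i], cols[j]);
    for (int i = 0; i < ne; ++i) {
      double mu = arma::mean(Z.row(i));
      Z.row(i) -= mu;
      double s = std::sqrt(arma::dot(Z.row(i), Z.row(i)) / V);
      if (s == 0.0) stop("Zero-variance sample inside a searchlight.");
      Z.row(i) /= s;
    }

    std::vector<long> correct(n_maps, 0), total(n_maps, 0);

    for (int f = 0; f < n_folds; ++f) {
      const int hold = uruns[f];
      std::vector<int> tr, te; // indices into Z / elig
      for (int i = 0; i < ne; ++i) {
        if (run[elig[i]] == hold) te.push_back(i); else tr.push_back(i);
      }
      if (te.empty() || tr.empty()) continue;

      for (int mm = 0; mm < n_maps; ++mm) {
        // class-wise training pools
        std::vector<std::vector<int>> pools(n_classes);
        for (int idx : tr) {
          int cl = labels(elig[idx], mm);
          pools[cl - 1].push_back(idx);
        }
        int mincnt = INT_MAX;
        bool balanced = true;
        for (int k = 0; k < n_classes; ++k) {
          int n_k = (int)pools[k].size();
          if (n_k < 2) stop("A training fold lacks a class (or has < 2 samples).");
          mincnt = std::min(mincnt, n_k);
        }
        for (int k = 0; k < n_classes; ++k)
          if ((int)pools[k].size() != mincnt) balanced = false;
        if (!balanced) {
          uint64_t st = mix_key(useed, (uint64_t)(c + 1),
                                (uint64_t)(f + 1), (uint64_t)(mm + 1));
          for (int k = 0; k < n_classes; ++k)
            if ((int)pools[k].size() > mincnt)
              sample_m_of_n(pools[k], mincnt, st);
        }

        // per-class mean / population variance over the balanced pool
        arma::mat mu(n_classes, V), var(n_classes, V);
        for (int k = 0; k < n_classes; ++k) {
          arma::rowvec s1(V, arma::fill::zeros), s2(V, arma::fill::zeros);
          for (int idx : pools[k]) {
            s1 += Z.row(idx);
            s2 += arma::square(Z.row(idx));
          }
          double n_k = (double)pools[k].size();
          mu.row(k) = s1 / n_k;
          var.row(k) = s2 / n_k - arma::square(mu.row(k));
        }
        double fl = floor_factor * arma::mean(arma::mean(var));
        if (!(fl > 0)) fl = 1e-12;
        var.transform([fl](double v) { return v < fl ? fl : v; });

        arma::vec cterm(n_classes);
        for (int k = 0; k < n_classes; ++k)
          cterm[k] = -0.5 * arma::accu(arma::log(2.0 * M_PI * var.row(k)));

        // predict the held-out run
        for (int idx : te) {
          int best = 0;
          double best_ll = -std::numeric_limits<double>::infinity();
          for (int k = 0; k < n_classes; ++k) {
            arma::rowvec d = Z.row(idx) - mu.row(k);
            double ll = cterm[k] -
              0.5 * arma::accu(arma::square(d) / var.row(k));
            if (ll > best_ll) { best_ll = ll; best = k; }
          }
          int actual = labels(elig[idx], mm) - 1;
          total[mm] += 1;
          if (best == actual) correct[mm] += 1;
          if (store_confusion && mm == 0)
            confusion(c, actual + best * n_classes) += 1.0;
        }
      }
    }
    for (int mm = 0; mm < n_maps; ++mm)
      acc(c, mm) = total[mm] > 0 ? (double)correct[mm] / total[mm] : NA_REAL;
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["accuracy"] = acc, _["counts"] = counts,
                      _["confusion"] = confusion);
}
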