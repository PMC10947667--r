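#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event-by-event constant-rate birth-death simulation started from a single
// stem lineage at the origin, in the budding representation: every lineage
// records its parent, its birth time and (if it died) its death time.
//
// Exactly one of the two stopping rules is active:
//   * n_target > 0 : halt at the first instant the number of alive lineages
//     equals n_target (the instant of the birth event that reaches it);
//   * t_max > 0    : halt at absolute time t_max (lineages alive then are
//     censored alive).
//
// Returns a list(parent, btime, dtime, t_end, n_alive); dtime is NA for
// lineages alive at t_end.  A run in which all lineages die before the
// stopping rule fires returns with n_alive == 0; the caller discards and
// redraws.  Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".bd_gillespie")]]
List bd_gillespie(double lambda, double mu, int n_target, double t_max,
                  int max_lineages) {
  if (lambda <= 0.0) stop("lambda must be > 0");
  if (mu < 0.0) stop("mu must be >= 0");
  const bool by_n = n_target > 0;
  if (!by_n && t_max <= 0.0) stop("either n_target or t_max must be set");

  std::vector<int> parent;
  std::vector<double> btime, dtime;
  std::vector<int> alive; // indices (0-based) of alive lineages
  parent.reserve(1024); btime.reserve(1024); dtime.reserve(1024);
  alive.reserve(1024);

  parent.push_back(0); btime.push_back(0.0); dtime.push_back(NA_REAL);
  alive.push_back(0);

  double t = 0.0;
  const double tot = lambda + mu;
  const double pb = lambda / tot;

  while (true) {
    int na = (int) alive.size();
    if (na == 0) break;                       // total extinction
    if (by_n && na == n_target) break;        // hit the extant target
    double dt = R::exp_rand() / (tot * na);
    if (!by_n && t + dt > t_max) { t = t_max; break; }
    t += dt;
    int k = (int) (unif_rand() * na);
    if (k == na) k = na - 1; // guard against unif_rand() == 1.0
    int lin = alive[k];
    if (unif_rand() < pb) {
      // birth: lineage `lin` buds off a new lineage
      if ((int) parent.size() >= max_lineages)
        stop("lineage cap exceeded (%d); epsilon too close to 1 for this target?",
             max_lineages);
      parent.push_back(lin + 1); // 1-based for R
      btime.push_back(t);
      dtime.push_back(NA_REAL);
      alive.push_back((int) parent.size() - 1);
    } else {
      // death
      dtime[lin] = t;
      alive[k] = alive.back();
      alive.pop_back();
    }
  }

  int n = (int) parent.size();
  IntegerVector p(parent.begin(), parent.end());
  NumericVector b(btime.begin(), btime.end());
  NumericVector d(dtime.begin(), dtime.end());
  return List::create(_["parent"] = p, _["btime"] = b, _["dtime"] = d,
                      _["t_end"] = t, _["n_alive"] = (int) alive.size(),
                      _["n_lineages"] = n);
}
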