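// FIML machinery for the three-level normative model.
//
// Per study k with n_k participants who all completed the same test set S
// (|S| = b), the stacked residual vector has covariance
//   I_{n_k} (x) W_S  +  J_{n_k} (x) B_S ,
// with W the p x p within-study covariance and B = diag(sigma2_b) the
// between-study covariance.  Projecting onto the participant mean and the
// (n_k - 1) orthogonal contrasts gives the standard one-way decomposition:
// contrasts are N(0, W_S) and the scaled mean is N(0, W_S + n_k B_S), so
// the study log-likelihood needs only b x b factorizations and the
// centered sufficient statistics of the residuals.
//
// Fixed effects are profiled out exactly: given the covariance parameters,
// the GLS estimate of G (p x c1 matrix of per-test intercept + covariate
// effects) solves a (p*c1) square linear system assembled from the same
// sufficient statistics.  At the GLS optimum the gradient of the profiled
// likelihood with respect to the covariance parameters equals the partial
// gradient (envelope theorem), so analytic derivatives stay cheap.
//
// Parameter vector: log-Cholesky of W (columnwise lower triangle, diagonal
// on the log scale), then log sigma2_b per test when between-study variance
// is estimated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

struct StudyStats {
  uvec S;       // 0-based test indices observed in this study
  double n;     // number of participants
  vec ybar;     // mean score vector (b)
  vec cbar;     // mean covariate-design vector (c1)
  mat YtYc;     // centered crossprod of scores (b x b)
  mat YtCc;     // centered crossprod scores x design (b x c1)
  mat CtCc;     // centered crossprod of design (c1 x c1)
};

static std::vector<StudyStats> parse_studies(const List& studies) {
  std::vector<StudyStats> out;
  out.reserve(studies.size());
  for (int k = 0; k < studies.size(); ++k) {
    List st = studies[k];
    StudyStats s;
    s.S = as<uvec>(st["S"]);
    s.n = as<double>(st["n"]);
    s.ybar = as<vec>(st["ybar"]);
    s.cbar = as<vec>(st["cbar"]);
    s.YtYc = as<mat>(st["YtYc"]);
    s.YtCc = as<mat>(st["YtCc"]);
    s.CtCc = as<mat>(st["CtCc"]);
    out.push_back(s);
  }
  return out;
}

static mat theta_to_L(const vec& theta, int p) {
  mat L(p, p, fill::zeros);
  int k = 0;
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i) {
      double v = theta[k++];
      L(i, j) = (i == j) ? std::exp(v) : v;
    }
  return L;
}

// Profiled negative log-likelihood (and gradient) at covariance parameters
// theta; returns the GLS fixed effects as a by-product.
// [[Rcpp::export]]
List mnc_profiled_nll(const arma::vec& theta, List studies, int p, int c1,
                      bool est_between, bool want_grad) {
  const int nL = p * (p + 1) / 2;
  mat L = theta_to_L(theta, p);
  mat W = L * L.t();
  vec B(p, fill::zeros);
  if (est_between) B = exp(theta.subvec(nL, nL + p - 1));

  std::vector<StudyStats> st = parse_studies(studies);
  const int q = p * c1;

  // Pass 1: per-study covariance factorizations + GLS normal equations.
  std::vector<mat> Winv_k(st.size()), Minv_k(st.size());
  std::vector<double> ldW_k(st.size()), ldM_k(st.size());
  mat Abig(q, q, fill::zeros);
  vec rhs(q, fill::zeros);

  for (size_t k = 0; k < st.size(); ++k) {
    const StudyStats& s = st[k];
    const uword b = s.S.n_elem;
    mat Ws = W.submat(s.S, s.S);
    mat Ms = Ws + s.n * diagmat(B.elem(s.S));
    mat cW, cM;
    if (!chol(cW, Ws, "lower") || !chol(cM, Ms, "lower")) {
      return List::create(_["nll"] = R_PosInf);
    }
    ldW_k[k] = 2.0 * accu(log(cW.diag()));
    ldM_k[k] = 2.0 * accu(log(cM.diag()));
    Winv_k[k] = inv_sympd(Ws);
    Minv_k[k] = inv_sympd(Ms);

    mat WinvYtCc = Winv_k[k] * s.YtCc;               // b x c1
    vec Minv_ybar = Minv_k[k] * s.ybar;              // b
    // scatter into the big system; vec(G) column-major, index j*p + m
    for (uword j = 0; j < (uword)c1; ++j) {
      for (uword jp = 0; jp < (uword)c1; ++jp) {
        double a1 = s.CtCc(jp, j);
        double a2 = s.n * s.cbar(jp) * s.cbar(j);
        for (uword a = 0; a < b; ++a)
          for (uword bb = 0; bb < b; ++bb)
            Abig(jp * p + s.S(a), j * p + s.S(bb)) +=
              a1 * Winv_k[k](a, bb) + a2 * Minv_k[k](a, bb);
      }
      for (uword a = 0; a < b; ++a)
        rhs(j * p + s.S(a)) += WinvYtCc(a, j) + s.n * Minv_ybar(a) * s.cbar(j);
    }
  }

  vec gvec;
  bool ok = solve(gvec, Abig, rhs,
                  solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) {
    return List::create(_["nll"] = R_PosInf);
  }
  mat G(gvec.memptr(), p, c1);  // copy into p x c1

  // Pass 2: log-likelihood and gradient at the GLS fixed effects.
  double ll = 0.0;
  mat Dfull(p, p, fill::zeros);   // d ll / d W (treating entries free)
  vec gB(p, fill::zeros);         // d ll / d B_mm

  for (size_t k = 0; k < st.size(); ++k) {
    const StudyStats& s = st[k];
    const uword b = s.S.n_elem;
    mat Gs = G.rows(s.S);                              // b x c1
    mat A = s.YtYc - s.YtCc * Gs.t() - Gs * s.YtCc.t() + Gs * s.CtCc * Gs.t();
    vec rbar = s.ybar - Gs * s.cbar;
    const mat& Winv = Winv_k[k];
    const mat& Minv = Minv_k[k];
    vec Mr = Minv * rbar;
    double quad_mean = s.n * dot(rbar, Mr);
    ll += -0.5 * ((s.n - 1.0) * ldW_k[k] + ldM_k[k] + trace(Winv * A) +
                  quad_mean + s.n * b * LOG2PI);
    if (want_grad) {
      mat WAW = Winv * A * Winv;
      mat MrrM = s.n * (Mr * Mr.t());
      mat Ds = -0.5 * ((s.n - 1.0) * Winv - WAW + Minv - MrrM);
      Dfull.submat(s.S, s.S) += Ds;
      if (est_between) {
        mat Dm = -0.5 * s.n * (Minv - MrrM);
        for (uword a = 0; a < b; ++a) gB(s.S(a)) += Dm(a, a);
      }
    }
  }

  List out = List::create(_["nll"] = -ll, _["gamma"] = G);
  if (want_grad) {
    mat gradL = 2.0 * Dfull * L;
    vec g(theta.n_elem, fill::zeros);
    int k = 0;
    for (int j = 0; j < p; ++j)
      for (int i = j; i < p; ++i) {
        double gv = gradL(i, j);
        if (i == j) gv *= L(i, i);  // log-scale diagonal
        g[k++] = -gv;               // gradient of the NEGATIVE log-lik
      }
    if (est_between)
      for (int m = 0; m < p; ++m) g[nL + m] = -gB(m) * B(m);
    out["grad"] = g;
  }
  return out;
}

// Total log-likelihood at explicit parameter values (no profiling); used
// for reporting and cross-checks against the R-level per-study evaluator.
// [[Rcpp::export]]
double mnc_loglik_at(List studies, const arma::mat& G, const arma::mat& W,
                     const arma::vec& B) {
  std::vector<StudyStats> st = parse_studies(studies);
  double ll = 0.0;
  for (size_t k = 0; k < st.size(); ++k) {
    const StudyStats& s = st[k];
    const uword b = s.S.n_elem;
    mat Ws = W.submat(s.S, s.S);
    mat Ms = Ws + s.n * diagmat(B.elem(s.S));
    mat Gs = G.rows(s.S);
    mat A = s.YtYc - s.YtCc * Gs.t() - Gs * s.YtCc.t() + Gs * s.CtCc * Gs.t();
    vec rbar = s.ybar - Gs * s.cbar;
    double ldW = log_det_sympd(Ws);
    double ldM = log_det_sympd(Ms);
    ll += -0.5 * ((s.n - 1.0) * ldW + ldM + trace(inv_sympd(Ws) * A) +
                  s.n * dot(rbar, inv_sympd(Ms) * rbar) + s.n * b * LOG2PI);
  }
  return ll;
}
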