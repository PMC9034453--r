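// Marginalized state-space Cormack-Jolly-Seber likelihood and an adaptive
// random-walk Metropolis-within-Gibbs sampler over the nine detection
// structures.  The latent alive states are summed out with the backward
// ("chi") recursion, so the sampler only ever walks over continuous
// parameters; per-individual log-likelihood terms are cached and only the
// individuals a proposal can touch are recomputed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static inline double invlogit(double x) {
  if (x > 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// Marginal log-probability of one capture history conditional on release at
// occasion f (1-based).  phi[t] is survival over interval t -> t+1
// (1-based t, length T-1); p[t] is detection at occasion t (length T,
// entries at t <= f ignored).  Detection probabilities of exactly 0
// (e.g. no trapping effort) are legal provided y is 0 there.
// [[Rcpp::export]]
double cpp_history_loglik(IntegerVector y, int f, NumericVector phi, NumericVector p) {
  int T = y.size();
  if (f < 1 || f > T) stop("first-capture occasion out of range");
  int f0 = f - 1;
  if (y[f0] != 1) stop("history has y[f] != 1 (must condition on first capture)");
  if (phi.size() < T - 1) stop("phi must have length T-1");
  if (p.size() < T) stop("p must have length T");
  int last = f0;
  for (int t = f0 + 1; t < T; t++) if (y[t] == 1) last = t;
  double ll = 0.0;
  for (int t = f0; t < last; t++) {
    ll += std::log(phi[t]);
    ll += y[t + 1] ? std::log(p[t + 1]) : std::log(1.0 - p[t + 1]);
  }
  double chi = 1.0;
  for (int t = T - 2; t >= last; t--)
    chi = (1.0 - phi[t]) + phi[t] * (1.0 - p[t + 1]) * chi;
  return ll + std::log(chi);
}

// ---------------------------------------------------------------------------
// Sampler
// ---------------------------------------------------------------------------

// 20-point Gauss-Hermite quadrature for a standard normal weight, used to
// integrate the individual detection random effect out of the stored
// pointwise log-likelihoods (the WAIC pointwise unit is the individual's
// capture history, i.e. its marginal likelihood given the structural
// parameters; conditioning on the fitted individual effects would let them
// memorize the histories and overstate the support for heterogeneity).
static const double GH_NODE[20] = {
  -7.6190485416797662e+00, -6.5105901570136497e+00, -5.5787388058931962e+00,
  -4.7345813340460534e+00, -3.9439673506573145e+00, -3.1890148165533887e+00,
  -2.4586636111723661e+00, -1.7452473208141270e+00, -1.0429453488027514e+00,
  -3.4696415708135586e-01, 3.4696415708135614e-01, 1.0429453488027514e+00,
  1.7452473208141266e+00, 2.4586636111723701e+00, 3.1890148165533878e+00,
  3.9439673506573132e+00, 4.7345813340460534e+00, 5.5787388058931979e+00,
  6.5105901570136488e+00, 7.6190485416797635e+00};
static const double GH_WT[20] = {
  1.2578006724378765e-13, 2.4820623623151512e-10, 6.1274902599829147e-08,
  4.4021210902308722e-06, 1.2882627996192914e-04, 1.8301031310804939e-03,
  1.3997837447101015e-02, 6.1506372063976932e-02, 1.6173933398399995e-01,
  2.6079306344955455e-01, 2.6079306344955477e-01, 1.6173933398400003e-01,
  6.1506372063976834e-02, 1.3997837447101005e-02, 1.8301031310804946e-03,
  1.2882627996193085e-04, 4.4021210902308544e-06, 6.1274902599829425e-08,
  2.4820623623151745e-10, 1.2578006724379027e-13};

struct CjsModel {
  int n, T, A, S, nsx;
  bool sexByAge;
  bool useSite, useB, useOccF, useTrend, useOccRE, useIndRE;
  const int *y;         // n x T column-major
  std::vector<int> f, sex, site, lastDet;
  std::vector<int> ageOcc;   // n x T column-major, 0-based class, valid t >= f
  std::vector<int> effort;   // S x T column-major 0/1
  double coefSd, sdScale;
  int sdPriorType;           // 0 = uniform(0, sdScale) on sigma, 1 = half-normal(sdScale)

  // parameter vector offsets
  int offBAge, offBSex, offEps, offSAst, offA0, offU, offB, offOccF, offTr,
      offGam, offST, offEta, offSMH, P;
  int nEps, nU, nOccF, nGam;

  std::vector<double> par;
  std::vector<double> phiCell;   // A*2*(T-1)
  std::vector<double> detBase;   // S*T linear predictor (excl. individual effect)
  std::vector<double> pProb;     // S*T invlogit(detBase), used when !useIndRE
  std::vector<double> xTrend;    // length T
  std::vector<double> curLL;

  inline int epsIdx(int a, int s, int t) const { return a + A * (s + 2 * t); }
  inline int Y(int i, int t) const { return y[i + n * t]; }
  inline int age(int i, int t) const { return ageOcc[i + n * t]; }
  inline int eff(int s, int t) const { return effort[s + S * t]; }

  void layout() {
    nsx = sexByAge ? A : 1;
    nEps = A * 2 * (T - 1);
    nU = useSite ? S - 1 : 0;
    nOccF = useOccF ? T - 2 : 0;
    nGam = useOccRE ? T - 1 : 0;
    offBAge = 0;
    offBSex = offBAge + A;
    offEps = offBSex + nsx;
    offSAst = offEps + nEps;
    offA0 = offSAst + 1;
    offU = offA0 + 1;
    offB = offU + nU;
    offOccF = offB + (useB ? 1 : 0);
    offTr = offOccF + nOccF;
    offGam = offTr + (useTrend ? 1 : 0);
    offST = offGam + nGam;
    offEta = offST + (useOccRE ? 1 : 0);
    offSMH = offEta + (useIndRE ? n : 0);
    P = offSMH + (useIndRE ? 1 : 0);
    par.assign(P, 0.0);
    phiCell.assign(nEps, 0.5);
    detBase.assign(S * T, 0.0);
    pProb.assign(S * T, 0.5);
    xTrend.assign(T, 0.0);
    for (int t = 0; t < T; t++)
      xTrend[t] = ((t + 1) - (T + 1) / 2.0) / (T - 1);
  }

  void rebuildPhi() {
    for (int t = 0; t < T - 1; t++)
      for (int s = 0; s < 2; s++)
        for (int a = 0; a < A; a++) {
          double lp = par[offBAge + a] + par[offEps + epsIdx(a, s, t)];
          if (s == 1) lp += par[offBSex + (sexByAge ? a : 0)];
          phiCell[epsIdx(a, s, t)] = invlogit(lp);
        }
  }

  void rebuildDet() {
    double uLast = 0.0;
    if (useSite) {
      for (int j = 0; j < S - 1; j++) uLast -= par[offU + j];
    }
    for (int t = 1; t < T; t++) {
      double base = par[offA0];
      if (useB) base += par[offB];       // recapture indicator is 1 at every
                                         // occasion after first capture
      if (useOccF && t >= 2) base += par[offOccF + t - 2];
      if (useTrend) base += par[offTr] * xTrend[t];
      if (useOccRE) base += par[offGam + t - 1];
      for (int s = 0; s < S; s++) {
        double lp = base;
        if (useSite) lp += (s < S - 1) ? par[offU + s] : uLast;
        detBase[s + S * t] = lp;
        pProb[s + S * t] = invlogit(lp);
      }
    }
  }

  inline double pDet(int i, int t) const {
    int s = site[i];
    if (!eff(s, t)) return 0.0;
    if (useIndRE) return invlogit(detBase[s + S * t] + par[offEta + i]);
    return pProb[s + S * t];
  }

  double indLL(int i) const {
    int fi = f[i], sx = sex[i], last = lastDet[i];
    double ll = 0.0;
    for (int t = fi; t < last; t++) {
      double ph = phiCell[epsIdx(age(i, t), sx, t)];
      double pp = pDet(i, t + 1);
      ll += std::log(ph);
      ll += Y(i, t + 1) ? std::log(pp) : std::log(1.0 - pp);
    }
    double chi = 1.0;
    for (int t = T - 2; t >= last; t--) {
      double ph = phiCell[epsIdx(age(i, t), sx, t)];
      double pp = pDet(i, t + 1);
      chi = (1.0 - ph) + ph * (1.0 - pp) * chi;
    }
    return ll + std::log(chi);
  }

  // like indLL but with the individual detection effect set explicitly
  double indLLeta(int i, double eta) const {
    int fi = f[i], sx = sex[i], last = lastDet[i], si = site[i];
    double ll = 0.0;
    for (int t = fi; t < last; t++) {
      double ph = phiCell[epsIdx(age(i, t), sx, t)];
      double pp = eff(si, t + 1) ? invlogit(detBase[si + S * (t + 1)] + eta) : 0.0;
      ll += std::log(ph);
      ll += Y(i, t + 1) ? std::log(pp) : std::log(1.0 - pp);
    }
    double chi = 1.0;
    for (int t = T - 2; t >= last; t--) {
      double ph = phiCell[epsIdx(age(i, t), sx, t)];
      double pp = eff(si, t + 1) ? invlogit(detBase[si + S * (t + 1)] + eta) : 0.0;
      chi = (1.0 - ph) + ph * (1.0 - pp) * chi;
    }
    return ll + std::log(chi);
  }

  double coefLP(double v) const { return -0.5 * v * v / (coefSd * coefSd); }
  // s = log sigma; includes the log-scale Jacobian term
  double sdLP(double s) const {
    double sig = std::exp(s);
    if (sdPriorType == 0) return (sig < sdScale) ? s : R_NegInf;
    return -0.5 * sig * sig / (sdScale * sdScale) + s;
  }
};

// [[Rcpp::export]]
List cpp_cjs_mcmc(IntegerMatrix y, IntegerVector f0, IntegerVector sex,
                  IntegerVector site0, IntegerMatrix ageOcc0,
                  IntegerMatrix effort, int A, bool sexByAge,
                  LogicalVector use, double coefSd, int sdPriorType,
                  double sdScale, int nIter, int nBurn, int thin,
                  double jitterSd) {
  CjsModel m;
  m.n = y.nrow(); m.T = y.ncol(); m.A = A; m.S = effort.nrow();
  m.sexByAge = sexByAge;
  m.useSite = use[0]; m.useB = use[1]; m.useOccF = use[2];
  m.useTrend = use[3]; m.useOccRE = use[4]; m.useIndRE = use[5];
  m.coefSd = coefSd; m.sdPriorType = sdPriorType; m.sdScale = sdScale;
  m.y = y.begin();
  int n = m.n, T = m.T;
  m.f.assign(f0.begin(), f0.end());
  m.sex.assign(sex.begin(), sex.end());
  m.site.assign(site0.begin(), site0.end());
  m.ageOcc.assign(ageOcc0.begin(), ageOcc0.end());
  m.effort.assign(effort.begin(), effort.end());
  m.lastDet.assign(n, 0);
  for (int i = 0; i < n; i++) {
    int last = m.f[i];
    for (int t = m.f[i] + 1; t < T; t++) if (m.Y(i, t)) last = t;
    m.lastDet[i] = last;
  }
  m.layout();

  // initialization: coefficients near 0, sds at 1, jittered
  for (int k = 0; k < m.P; k++) m.par[k] = jitterSd * R::norm_rand();
  m.par[m.offSAst] = 0.1 * R::norm_rand();
  if (m.useOccRE) m.par[m.offST] = 0.1 * R::norm_rand();
  if (m.useIndRE) m.par[m.offSMH] = 0.1 * R::norm_rand();
  m.rebuildPhi(); m.rebuildDet();
  m.curLL.assign(n, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n; i++) { m.curLL[i] = m.indLL(i); tot += m.curLL[i]; }
  if (!std::isfinite(tot))
    stop("non-finite log-likelihood at initialization");

  // affected-individual index sets
  std::vector<int> all(n); for (int i = 0; i < n; i++) all[i] = i;
  std::vector<std::vector<int>> affEps(m.nEps), affBAge(A), affBSex(m.nsx),
      affOcc(T), affSite(m.S);
  {
    std::vector<std::vector<char>> hitA(A, std::vector<char>(n, 0));
    for (int i = 0; i < n; i++) {
      for (int t = m.f[i]; t <= T - 2; t++) {
        int a = m.age(i, t);
        affEps[m.epsIdx(a, m.sex[i], t)].push_back(i);
        hitA[a][i] = 1;
      }
      for (int t = m.f[i] + 1; t < T; t++) affOcc[t].push_back(i);
      affSite[m.site[i]].push_back(i);
    }
    for (int a = 0; a < A; a++)
      for (int i = 0; i < n; i++) {
        if (hitA[a][i]) affBAge[a].push_back(i);
        if (hitA[a][i] && m.sex[i] == 1 && sexByAge) affBSex[a].push_back(i);
      }
    if (!sexByAge)
      for (int i = 0; i < n; i++) if (m.sex[i] == 1) affBSex[0].push_back(i);
  }
  std::vector<std::vector<int>> affSitePair(m.nU);
  for (int j = 0; j < m.nU; j++) {
    affSitePair[j] = affSite[j];
    affSitePair[j].insert(affSitePair[j].end(), affSite[m.S - 1].begin(),
                          affSite[m.S - 1].end());
  }

  std::vector<double> lstep(m.P, std::log(0.3));
  double lstepRAst = std::log(0.2), lstepRT = std::log(0.2),
         lstepRMH = std::log(0.2);
  std::vector<double> tmp(n);

  // one Metropolis step on par[idx]; priorFn returns the log-prior of the
  // parameter (hierarchical terms included by the caller via sig)
  auto mhStep = [&](int idx, const std::function<double(double)> &priorFn,
                    const std::vector<int> &aff, bool touchPhi, bool touchDet,
                    double &ls, int burnK) {
    double old = m.par[idx];
    double prop = old + std::exp(ls) * R::norm_rand();
    double dpr = priorFn(prop) - priorFn(old);
    double alpha = 0.0;
    if (std::isfinite(dpr)) {
      m.par[idx] = prop;
      if (touchPhi) m.rebuildPhi();
      if (touchDet) m.rebuildDet();
      double dll = 0.0;
      size_t na = aff.size();
      for (size_t k = 0; k < na; k++) {
        tmp[k] = m.indLL(aff[k]);
        dll += tmp[k] - m.curLL[aff[k]];
      }
      double lr = dll + dpr;
      alpha = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < alpha) {
        for (size_t k = 0; k < na; k++) m.curLL[aff[k]] = tmp[k];
      } else {
        m.par[idx] = old;
        if (touchPhi) m.rebuildPhi();
        if (touchDet) m.rebuildDet();
      }
    }
    if (burnK >= 0) {
      double g = 1.0 / std::sqrt(1.0 + burnK);
      ls += g * (alpha - 0.44);
      if (ls < -8) ls = -8;
      if (ls > 3) ls = 3;
    }
  };

  // prior-only update of a log-sd parameter governing K effects with sum sq
  auto sdStep = [&](int idx, int K, double sumsq, double &ls, int burnK) {
    double old = m.par[idx];
    double prop = old + std::exp(ls) * R::norm_rand();
    double sOld = std::exp(old), sProp = std::exp(prop);
    double d = m.sdLP(prop) - m.sdLP(old);
    double alpha = 0.0;
    if (std::isfinite(d)) {
      d += -0.5 * sumsq * (1.0 / (sProp * sProp) - 1.0 / (sOld * sOld))
           - K * (prop - old);
      alpha = d >= 0 ? 1.0 : std::exp(d);
      if (R::unif_rand() < alpha) m.par[idx] = prop;
    }
    if (burnK >= 0) {
      double g = 1.0 / std::sqrt(1.0 + burnK);
      ls += g * (alpha - 0.44);
      if (ls < -8) ls = -8;
      if (ls > 3) ls = 3;
    }
  };

  // joint rescaling move (s, v) -> (s + d, e^d v): beats the funnel between a
  // hierarchical sd and its effects.  Hierarchical prior and Jacobian cancel;
  // acceptance is data delta plus hyperprior delta.
  auto rescale = [&](int sIdx, int vOff, int K, bool touchPhi, bool touchDet,
                     double &ls, int burnK) {
    double old = m.par[sIdx];
    double d = std::exp(ls) * R::norm_rand();
    double c = std::exp(d);
    double dpr = m.sdLP(old + d) - m.sdLP(old);
    double alpha = 0.0;
    if (std::isfinite(dpr)) {
      m.par[sIdx] = old + d;
      for (int k = 0; k < K; k++) m.par[vOff + k] *= c;
      if (touchPhi) m.rebuildPhi();
      if (touchDet) m.rebuildDet();
      double dll = 0.0;
      for (int i = 0; i < n; i++) { tmp[i] = m.indLL(i); dll += tmp[i] - m.curLL[i]; }
      double lr = dll + dpr;
      alpha = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < alpha) {
        for (int i = 0; i < n; i++) m.curLL[i] = tmp[i];
      } else {
        m.par[sIdx] = old;
        for (int k = 0; k < K; k++) m.par[vOff + k] /= c;
        if (touchPhi) m.rebuildPhi();
        if (touchDet) m.rebuildDet();
      }
    }
    if (burnK >= 0) {
      double g = 1.0 / std::sqrt(1.0 + burnK);
      ls += g * (alpha - 0.30);
      if (ls < -8) ls = -8;
      if (ls > 3) ls = 3;
    }
  };

  // Recentering move: main += d, each listed effect -= d.  The linear
  // predictors (hence the data likelihood) are unchanged; only the priors
  // move.  This walks along the intercept/random-effect ridge that a
  // single-site sampler traverses slowly.  vSd entries give each effect's
  // prior sd (the hierarchical sd, or coefSd for a coefficient partner).
  auto recenter = [&](int mainIdx, const std::vector<int> &vIdx, double vSd,
                      bool touchPhi, bool touchDet, double &ls, int burnK) {
    double d = std::exp(ls) * R::norm_rand();
    double mOld = m.par[mainIdx];
    double dpr = m.coefLP(mOld + d) - m.coefLP(mOld);
    for (size_t k = 0; k < vIdx.size(); k++) {
      double v = m.par[vIdx[k]];
      dpr += -0.5 * ((v - d) * (v - d) - v * v) / (vSd * vSd);
    }
    double alpha = dpr >= 0 ? 1.0 : std::exp(dpr);
    if (R::unif_rand() < alpha) {
      m.par[mainIdx] = mOld + d;
      for (size_t k = 0; k < vIdx.size(); k++) m.par[vIdx[k]] -= d;
      if (touchPhi) m.rebuildPhi();
      if (touchDet) m.rebuildDet();
    }
    if (burnK >= 0) {
      double g = 1.0 / std::sqrt(1.0 + burnK);
      ls += g * (alpha - 0.44);
      if (ls < -8) ls = -8;
      if (ls > 3) ls = 3;
    }
  };
  // index lists for the recentering moves
  std::vector<std::vector<int>> epsOfAge(A), epsOfSexAge(m.nsx);
  for (int t = 0; t < T - 1; t++)
    for (int s = 0; s < 2; s++)
      for (int a = 0; a < A; a++) {
        epsOfAge[a].push_back(m.offEps + m.epsIdx(a, s, t));
        if (s == 1) epsOfSexAge[sexByAge ? a : 0].push_back(
            m.offEps + m.epsIdx(a, s, t));
      }
  std::vector<int> etaIdx, gamIdx, behavIdx;
  if (m.useIndRE) for (int i = 0; i < n; i++) etaIdx.push_back(m.offEta + i);
  if (m.useOccRE) for (int k = 0; k < m.nGam; k++) gamIdx.push_back(m.offGam + k);
  if (m.useB) behavIdx.push_back(m.offB);
  std::vector<double> lsRecA(A, std::log(0.3)), lsRecS(m.nsx, std::log(0.3));
  double lsRecEta = std::log(0.3), lsRecGam = std::log(0.3),
         lsRecB = std::log(0.3);

  int nKept = nIter / thin;
  NumericMatrix draws(nKept, m.P), pw(nKept, n), phiDraws(nKept, m.nEps);
  int kept = 0;

  std::function<double(double)> coefPrior =
      [&](double v) { return m.coefLP(v); };

  for (int it = 0; it < nBurn + nIter; it++) {
    int burnK = it < nBurn ? it : -1;
    double sigAst = std::exp(m.par[m.offSAst]);
    for (int a = 0; a < A; a++)
      mhStep(m.offBAge + a, coefPrior, affBAge[a], true, false,
             lstep[m.offBAge + a], burnK);
    for (int a = 0; a < m.nsx; a++)
      mhStep(m.offBSex + a, coefPrior, affBSex[a], true, false,
             lstep[m.offBSex + a], burnK);
    for (int k = 0; k < m.nEps; k++) {
      std::function<double(double)> pf = [&](double v) {
        return -0.5 * v * v / (sigAst * sigAst);
      };
      mhStep(m.offEps + k, pf, affEps[k], true, false, lstep[m.offEps + k],
             burnK);
    }
    {
      double ss = 0.0;
      for (int k = 0; k < m.nEps; k++)
        ss += m.par[m.offEps + k] * m.par[m.offEps + k];
      sdStep(m.offSAst, m.nEps, ss, lstep[m.offSAst], burnK);
      rescale(m.offSAst, m.offEps, m.nEps, true, false, lstepRAst, burnK);
    }
    mhStep(m.offA0, coefPrior, all, false, true, lstep[m.offA0], burnK);
    if (m.useSite)
      for (int j = 0; j < m.nU; j++)
        mhStep(m.offU + j, coefPrior, affSitePair[j], false, true,
               lstep[m.offU + j], burnK);
    if (m.useB)
      mhStep(m.offB, coefPrior, all, false, true, lstep[m.offB], burnK);
    if (m.useOccF)
      for (int t = 2; t < T; t++)
        mhStep(m.offOccF + t - 2, coefPrior, affOcc[t], false, true,
               lstep[m.offOccF + t - 2], burnK);
    if (m.useTrend)
      mhStep(m.offTr, coefPrior, all, false, true, lstep[m.offTr], burnK);
    if (m.useOccRE) {
      double sigT = std::exp(m.par[m.offST]);
      for (int t = 1; t < T; t++) {
        std::function<double(double)> pf = [&](double v) {
          return -0.5 * v * v / (sigT * sigT);
        };
        mhStep(m.offGam + t - 1, pf, affOcc[t], false, true,
               lstep[m.offGam + t - 1], burnK);
      }
      double ss = 0.0;
      for (int k = 0; k < m.nGam; k++)
        ss += m.par[m.offGam + k] * m.par[m.offGam + k];
      sdStep(m.offST, m.nGam, ss, lstep[m.offST], burnK);
      rescale(m.offST, m.offGam, m.nGam, false, true, lstepRT, burnK);
    }
    if (m.useIndRE) {
      double sigMH = std::exp(m.par[m.offSMH]);
      std::function<double(double)> pf;
      for (int i = 0; i < n; i++) {
        pf = [&](double v) { return -0.5 * v * v / (sigMH * sigMH); };
        // single-individual affected set
        double oldv = m.par[m.offEta + i];
        double prop = oldv + std::exp(lstep[m.offEta + i]) * R::norm_rand();
        double dpr = pf(prop) - pf(oldv);
        m.par[m.offEta + i] = prop;
        double newll = m.indLL(i);
        double lr = newll - m.curLL[i] + dpr;
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < alpha) m.curLL[i] = newll;
        else m.par[m.offEta + i] = oldv;
        if (burnK >= 0) {
          double g = 1.0 / std::sqrt(1.0 + burnK);
          lstep[m.offEta + i] += g * (alpha - 0.44);
          if (lstep[m.offEta + i] < -8) lstep[m.offEta + i] = -8;
          if (lstep[m.offEta + i] > 3) lstep[m.offEta + i] = 3;
        }
      }
      double ss = 0.0;
      for (int i = 0; i < n; i++)
        ss += m.par[m.offEta + i] * m.par[m.offEta + i];
      sdStep(m.offSMH, n, ss, lstep[m.offSMH], burnK);
      rescale(m.offSMH, m.offEta, n, false, false, lstepRMH, burnK);
    }

    { // recentering sweeps (prior-only; likelihood invariant)
      double sigAstNow = std::exp(m.par[m.offSAst]);
      for (int a = 0; a < A; a++)
        recenter(m.offBAge + a, epsOfAge[a], sigAstNow, true, false,
                 lsRecA[a], burnK);
      for (int a = 0; a < m.nsx; a++)
        recenter(m.offBSex + a, epsOfSexAge[a], sigAstNow, true, false,
                 lsRecS[a], burnK);
      if (m.useIndRE)
        recenter(m.offA0, etaIdx, std::exp(m.par[m.offSMH]), false, false,
                 lsRecEta, burnK);
      if (m.useOccRE)
        recenter(m.offA0, gamIdx, std::exp(m.par[m.offST]), false, true,
                 lsRecGam, burnK);
      if (m.useB)
        recenter(m.offA0, behavIdx, m.coefSd, false, true, lsRecB, burnK);
    }

    if (it >= nBurn && ((it - nBurn + 1) % thin == 0)) {
      for (int k = 0; k < m.P; k++) draws(kept, k) = m.par[k];
      // report sds on their natural scale
      draws(kept, m.offSAst) = std::exp(m.par[m.offSAst]);
      if (m.useOccRE) draws(kept, m.offST) = std::exp(m.par[m.offST]);
      if (m.useIndRE) draws(kept, m.offSMH) = std::exp(m.par[m.offSMH]);
      if (m.useIndRE) {
        double sigNow = std::exp(m.par[m.offSMH]);
        for (int i = 0; i < n; i++) {
          double vals[20], vmax = R_NegInf;
          for (int q = 0; q < 20; q++) {
            vals[q] = m.indLLeta(i, sigNow * GH_NODE[q]);
            if (vals[q] > vmax) vmax = vals[q];
          }
          double s = 0.0;
          for (int q = 0; q < 20; q++) s += GH_WT[q] * std::exp(vals[q] - vmax);
          pw(kept, i) = vmax + std::log(s);
        }
      } else {
        for (int i = 0; i < n; i++) pw(kept, i) = m.curLL[i];
      }
      for (int k = 0; k < m.nEps; k++) phiDraws(kept, k) = m.phiCell[k];
      kept++;
    }
  }

  // parameter names
  CharacterVector nm(m.P);
  for (int a = 0; a < A; a++)
    nm[m.offBAge + a] = "beta_age[" + std::to_string(a + 1) + "]";
  for (int a = 0; a < m.nsx; a++)
    nm[m.offBSex + a] = sexByAge ? ("beta_sex[" + std::to_string(a + 1) + "]")
                                 : "beta_sex";
  for (int t = 0; t < T - 1; t++)
    for (int s = 0; s < 2; s++)
      for (int a = 0; a < A; a++)
        nm[m.offEps + m.epsIdx(a, s, t)] =
            "eps[" + std::to_string(a + 1) + "," + std::to_string(s) + "," +
            std::to_string(t + 1) + "]";
  nm[m.offSAst] = "sigma_ast";
  nm[m.offA0] = "p_intercept";
  if (m.useSite)
    for (int j = 0; j < m.nU; j++)
      nm[m.offU + j] = "p_site[" + std::to_string(j + 1) + "]";
  if (m.useB) nm[m.offB] = "p_behav";
  if (m.useOccF)
    for (int t = 2; t < T; t++)
      nm[m.offOccF + t - 2] = "p_occ[" + std::to_string(t + 1) + "]";
  if (m.useTrend) nm[m.offTr] = "p_trend";
  if (m.useOccRE) {
    for (int t = 1; t < T; t++)
      nm[m.offGam + t - 1] = "p_gamma[" + std::to_string(t + 1) + "]";
    nm[m.offST] = "sigma_t";
  }
  if (m.useIndRE) {
    for (int i = 0; i < n; i++)
      nm[m.offEta + i] = "p_eta[" + std::to_string(i + 1) + "]";
    nm[m.offSMH] = "sigma_mH";
  }
  CharacterVector phiNm(m.nEps);
  for (int t = 0; t < T - 1; t++)
    for (int s = 0; s < 2; s++)
      for (int a = 0; a < A; a++)
        phiNm[m.epsIdx(a, s, t)] = "phi[" + std::to_string(a + 1) + "," +
                                   std::to_string(s) + "," +
                                   std::to_string(t + 1) + "]";
  colnames(draws) = nm;
  colnames(phiDraws) = phiNm;
  return List::create(_["draws"] = draws, _["pointwise"] = pw,
                      _["phi"] = phiDraws);
}
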