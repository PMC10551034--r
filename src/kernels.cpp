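// Compiled sampling kernels for the host-guest toy: anchor-CV geometry,
// metric-corrected pathCV evaluation with gradients, and the BAOAB
// integrator with umbrella or node-restraint biases. The R implementations
// of the same quantities are the reference; the kernels draw from R's RNG
// in the same order as the R integrator, so runs agree statistically and
// per-seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double TWO_PI = 6.283185307179586476925286766559;

static inline double wrapAngle(double x) {
  double y = x - TWO_PI * std::round(x / TWO_PI);
  if (y <= -datum::pi) y += TWO_PI;
  return y;
}

struct CVResult {
  vec cv;    // 6
  mat jac;   // 6 x 3n
};

// anchor groups: list of uvec (0-based atom indices), order P1 P2 P3 L1 L2 L3
static void anchorCenters(const mat& coords, const std::vector<uvec>& groups,
                          mat& centers) {
  for (size_t g = 0; g < 6; ++g) {
    rowvec c(3, fill::zeros);
    for (uword k = 0; k < groups[g].n_elem; ++k)
      c += coords.row(groups[g][k]);
    centers.row(g) = c / double(groups[g].n_elem);
  }
}

static inline vec crossv(const vec& a, const vec& b) { return cross(a, b); }

// distance gradient wrt endpoints
static void gradDistance(const vec& A, const vec& B, vec& gA, vec& gB,
                         double& d) {
  vec u = A - B;
  d = norm(u);
  gA = u / d;
  gB = -gA;
}

static void gradAngle(const vec& A, const vec& B, const vec& C,
                      vec& gA, vec& gB, vec& gC, double& th) {
  vec u = A - B, v = C - B;
  double nu = norm(u), nv = norm(v);
  vec uh = u / nu, vh = v / nv;
  double cs = dot(uh, vh);
  cs = std::max(-1.0, std::min(1.0, cs));
  th = std::acos(cs);
  double sn = std::sqrt(std::max(1.0 - cs * cs, 1e-24));
  gA = (cs * uh - vh) / (nu * sn);
  gC = (cs * vh - uh) / (nv * sn);
  gB = -gA - gC;
}

static void gradDihedral(const vec& A, const vec& B, const vec& C, const vec& D,
                         vec& gA, vec& gB, vec& gC, vec& gD, double& phi) {
  vec b1 = B - A, b2 = C - B, b3 = D - C;
  vec n1 = crossv(b1, b2), n2 = crossv(b2, b3);
  double nb2 = norm(b2);
  double x = dot(n1, n2);
  double y = dot(crossv(n1, n2), b2) / nb2;
  phi = std::atan2(y, x);
  if (phi <= -datum::pi) phi += TWO_PI;
  gA = -nb2 / dot(n1, n1) * n1;
  gD = nb2 / dot(n2, n2) * n2;
  double f1 = dot(b1, b2) / (nb2 * nb2);
  double f3 = dot(b3, b2) / (nb2 * nb2);
  gB = -(1.0 + f1) * gA + f3 * gD;
  gC = f1 * gA - (1.0 + f3) * gD;
}

static void addToJac(mat& J, int row, const uvec& grp, const vec& g3) {
  double w = 1.0 / double(grp.n_elem);
  for (uword k = 0; k < grp.n_elem; ++k) {
    uword a = grp[k];
    J(row, 3 * a) += w * g3[0];
    J(row, 3 * a + 1) += w * g3[1];
    J(row, 3 * a + 2) += w * g3[2];
  }
}

static void computeCVJac(const mat& coords, const std::vector<uvec>& groups,
                         CVResult& out) {
  mat P(6, 3);
  anchorCenters(coords, groups, P);
  vec P1 = P.row(0).t(), P2 = P.row(1).t(), P3 = P.row(2).t();
  vec L1 = P.row(3).t(), L2 = P.row(4).t(), L3 = P.row(5).t();
  out.cv.set_size(6);
  out.jac.zeros(6, 3 * coords.n_rows);
  vec gA, gB, gC, gD;
  double val;
  gradDistance(P1, L1, gA, gB, val);
  out.cv[0] = val;
  addToJac(out.jac, 0, groups[0], gA); addToJac(out.jac, 0, groups[3], gB);
  gradAngle(P2, P1, L1, gA, gB, gC, val);
  out.cv[1] = val;
  addToJac(out.jac, 1, groups[1], gA); addToJac(out.jac, 1, groups[0], gB);
  addToJac(out.jac, 1, groups[3], gC);
  gradAngle(P1, L1, L2, gA, gB, gC, val);
  out.cv[2] = val;
  addToJac(out.jac, 2, groups[0], gA); addToJac(out.jac, 2, groups[3], gB);
  addToJac(out.jac, 2, groups[4], gC);
  gradDihedral(P3, P2, P1, L1, gA, gB, gC, gD, val);
  out.cv[3] = val;
  addToJac(out.jac, 3, groups[2], gA); addToJac(out.jac, 3, groups[1], gB);
  addToJac(out.jac, 3, groups[0], gC); addToJac(out.jac, 3, groups[3], gD);
  gradDihedral(P2, P1, L1, L2, gA, gB, gC, gD, val);
  out.cv[4] = val;
  addToJac(out.jac, 4, groups[1], gA); addToJac(out.jac, 4, groups[0], gB);
  addToJac(out.jac, 4, groups[3], gC); addToJac(out.jac, 4, groups[4], gD);
  gradDihedral(P1, L1, L2, L3, gA, gB, gC, gD, val);
  out.cv[5] = val;
  addToJac(out.jac, 5, groups[0], gA); addToJac(out.jac, 5, groups[3], gB);
  addToJac(out.jac, 5, groups[4], gC); addToJac(out.jac, 5, groups[5], gD);
}

struct HostGuestParams {
  double De, d0, aMorse, kTheta, kPhi, bumpHeight, bumpCenter, bumpWidth,
    kBond, thetaA0, phiB0;
  umat pairs;   // nBond x 2 (0-based atom indices)
  vec r0;
};

// CV-space interaction energy and gradient (6 components)
static double cvPotential(const vec& cv, const HostGuestParams& p, vec& g) {
  double e = std::exp(-p.aMorse * (cv[0] - p.d0));
  double morse = p.De * (1.0 - e) * (1.0 - e) - p.De;
  double bz = (cv[0] - p.bumpCenter) / p.bumpWidth;
  double bump = p.bumpHeight * std::exp(-0.5 * bz * bz);
  double dth = cv[1] - p.thetaA0;
  double dph = wrapAngle(cv[4] - p.phiB0);
  g.zeros(6);
  g[0] = 2.0 * p.De * (1.0 - e) * p.aMorse * e -
    p.bumpHeight * (cv[0] - p.bumpCenter) / (p.bumpWidth * p.bumpWidth) *
      std::exp(-0.5 * bz * bz);
  g[1] = p.kTheta * dth;
  g[4] = p.kPhi * dph;
  return morse + bump + 0.5 * p.kTheta * dth * dth + 0.5 * p.kPhi * dph * dph;
}

static double bondTerms(const mat& coords, const HostGuestParams& p,
                        mat& force) {
  double E = 0.0;
  for (uword b = 0; b < p.pairs.n_rows; ++b) {
    uword i = p.pairs(b, 0), j = p.pairs(b, 1);
    rowvec dv = coords.row(i) - coords.row(j);
    double r = norm(dv);
    double dr = r - p.r0[b];
    E += 0.5 * p.kBond * dr * dr;
    rowvec f = p.kBond * dr / r * dv;
    force.row(i) -= f;
    force.row(j) += f;
  }
  return E;
}

struct PathDef {
  mat nodes;        // N x 6
  cube Ginv;        // 6 x 6 x (N-1)
  double lambda;
  uvec periodic;    // length 6, 0/1
};

struct PathCVOut {
  double s, z;
  vec ds, dz; // 6
};

static void evalPathCV(const vec& x, const PathDef& P, PathCVOut& out) {
  uword nSeg = P.nodes.n_rows - 1;
  vec t(nSeg), tRaw(nSeg), D2(nSeg), cc(nSeg);
  mat Gr(nSeg, 6), GV(nSeg, 6), R(nSeg, 6);
  for (uword i = 0; i < nSeg; ++i) {
    const mat& G = P.Ginv.slice(i);
    vec v = (P.nodes.row(i + 1) - P.nodes.row(i)).t();
    vec delta = x - P.nodes.row(i).t();
    for (int j = 0; j < 6; ++j)
      if (P.periodic[j]) delta[j] = wrapAngle(delta[j]);
    vec Gv = G * v;
    double c = dot(v, Gv);
    double tr = c > 0 ? dot(delta, Gv) / c : 0.0;
    double tc = std::min(1.0, std::max(0.0, tr));
    vec r = delta - tc * v;
    vec gr = G * r;
    t[i] = tc; tRaw[i] = tr; cc[i] = c;
    D2[i] = std::max(dot(r, gr), 0.0);
    Gr.row(i) = gr.t(); GV.row(i) = Gv.t(); R.row(i) = r.t();
  }
  uword m = D2.index_min();
  // exact endpoint saturation
  int sat = 0;
  if (m == 0 && tRaw[0] <= 0) sat = -1;
  if (m == nSeg - 1 && tRaw[nSeg - 1] >= 1) sat = 1;
  if (sat != 0) {
    const mat& G = P.Ginv.slice(sat < 0 ? 0 : nSeg - 1);
    vec node = (sat < 0 ? P.nodes.row(0) : P.nodes.row(nSeg)).t();
    vec delta = x - node;
    for (int j = 0; j < 6; ++j)
      if (P.periodic[j]) delta[j] = wrapAngle(delta[j]);
    vec Gd = G * delta;
    double z2 = std::max(dot(delta, Gd), 0.0);
    out.s = sat < 0 ? 0.0 : 1.0;
    out.z = std::sqrt(z2);
    out.ds.zeros(6);
    out.dz = out.z > 1e-12 ? vec(Gd / out.z) : vec(6, fill::zeros);
    return;
  }
  double Dmin2 = std::max(D2[m], 1e-300);
  vec u = D2 / Dmin2;
  vec a = exp(-P.lambda * (u - 1.0));
  vec w = a / accu(a);
  vec sigma = (regspace<vec>(0, nSeg - 1) + t) / double(nSeg);
  out.s = dot(w, sigma);
  double z2 = dot(w, D2);
  out.z = std::sqrt(std::max(z2, 0.0));
  // gradients
  mat dD2 = 2.0 * Gr;                         // nSeg x 6
  mat dt(nSeg, 6, fill::zeros);
  for (uword i = 0; i < nSeg; ++i)
    if (tRaw[i] > 0 && tRaw[i] < 1 && cc[i] > 0)
      dt.row(i) = GV.row(i) / cc[i];
  rowvec gq = dD2.row(m);
  mat du = (dD2 - u * gq) / Dmin2;
  for (uword i = 0; i < nSeg; ++i)
    if (w[i] < 1e-14) du.row(i).zeros();
  rowvec wdu = w.t() * du;
  mat dw = du;
  dw.each_row() -= wdu;
  dw.each_col() %= (-P.lambda * w);
  out.ds = (dw.t() * sigma + dt.t() * w / double(nSeg));
  vec dz2 = dw.t() * D2 + dD2.t() * w;
  out.dz = out.z > 1e-12 ? vec(dz2 / (2.0 * out.z)) : vec(6, fill::zeros);
}

static std::vector<uvec> asGroups(const Rcpp::List& groups) {
  std::vector<uvec> out;
  for (int g = 0; g < 6; ++g) {
    Rcpp::IntegerVector idx = groups[g];
    uvec u(idx.size());
    for (int k = 0; k < idx.size(); ++k) u[k] = idx[k]; // already 0-based
    out.push_back(u);
  }
  return out;
}

static HostGuestParams asParams(const Rcpp::List& par) {
  HostGuestParams p;
  p.De = par["De"]; p.d0 = par["d0"]; p.aMorse = par["aMorse"];
  p.kTheta = par["kTheta"]; p.kPhi = par["kPhi"];
  p.bumpHeight = par["bumpHeight"]; p.bumpCenter = par["bumpCenter"];
  p.bumpWidth = par["bumpWidth"]; p.kBond = par["kBond"];
  p.thetaA0 = par["thetaA0"]; p.phiB0 = par["phiB0"];
  Rcpp::IntegerMatrix pr = par["pairs"]; // 0-based
  p.pairs.set_size(pr.nrow(), 2);
  for (int i = 0; i < pr.nrow(); ++i) {
    p.pairs(i, 0) = pr(i, 0);
    p.pairs(i, 1) = pr(i, 1);
  }
  p.r0 = Rcpp::as<vec>(par["r0"]);
  return p;
}

static PathDef asPath(const Rcpp::List& path) {
  PathDef P;
  P.nodes = Rcpp::as<mat>(path["nodes"]);
  Rcpp::List gl = path["Ginv"];
  uword nSeg = P.nodes.n_rows - 1;
  P.Ginv.set_size(6, 6, nSeg);
  for (uword i = 0; i < nSeg; ++i)
    P.Ginv.slice(i) = Rcpp::as<mat>(gl[i]);
  P.lambda = path["lambda"];
  Rcpp::LogicalVector per = path["periodic"];
  P.periodic.set_size(6);
  for (int j = 0; j < 6; ++j) P.periodic[j] = per[j] ? 1 : 0;
  return P;
}

// Shared BAOAB driver. mode 0: umbrella bias on (s, z); mode 1: harmonic
// CV restraint at `node` (records wrapped CV deviations).
// [[Rcpp::export(name = ".cppHostGuestRun")]]
Rcpp::List cppHostGuestRun(
    const arma::vec& x0, const Rcpp::List& groupsR, const Rcpp::List& paramsR,
    const Rcpp::List& pathR, int mode,
    double sCenter, double kS, double kZ, int rampSteps,
    const arma::vec& node, double kNode,
    int nSteps, double dt, double gamma, double kT, int stride, int burnin,
    const arma::uvec& mobileAtoms) {
  // mobileAtoms are 0-based atom indices
  std::vector<uvec> groups = asGroups(groupsR);
  HostGuestParams par = asParams(paramsR);
  PathDef P;
  bool havePath = mode == 0;
  if (havePath) P = asPath(pathR);

  uword nAtoms = x0.n_elem / 3;
  mat coords(reinterpret_cast<const double*>(x0.memptr()), 3, nAtoms);
  mat X = coords.t(); // nAtoms x 3
  mat V(nAtoms, 3, fill::zeros);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  double sdv = std::sqrt(kT); // unit masses

  CVResult cvj;
  PathCVOut pc;
  vec gpot;
  uvec mob = mobileAtoms;

  // force evaluation into F; returns bias energy (mode 0) and records
  mat F(nAtoms, 3);
  double biasE = 0, curS = 0, curZ = 0;
  auto forceEval = [&](int step) {
    F.zeros();
    double Eb = bondTerms(X, par, F);
    (void)Eb;
    computeCVJac(X, groups, cvj);
    vec g;
    cvPotential(cvj.cv, par, g);
    biasE = 0; curS = 0; curZ = 0;
    if (mode == 0) {
      evalPathCV(cvj.cv, P, pc);
      double f = rampSteps > 0 ? std::min(double(step) / rampSteps, 1.0) : 1.0;
      double ks = f * kS, kz = f * kZ;
      double dsv = pc.s - sCenter;
      biasE = 0.5 * ks * dsv * dsv + 0.5 * kz * pc.z * pc.z;
      curS = pc.s; curZ = pc.z;
      g += ks * dsv * pc.ds + kz * pc.z * pc.dz;
    } else {
      vec delta = cvj.cv - node;
      for (int j = 0; j < 6; ++j) delta[j] = wrapAngle(delta[j]);
      g += kNode * delta;
    }
    vec fFlat = -cvj.jac.t() * g; // 3n
    for (uword a = 0; a < nAtoms; ++a)
      for (int k = 0; k < 3; ++k)
        F(a, k) += fFlat[3 * a + k];
    if (!F.is_finite())
      Rcpp::stop("integration blow-up: non-finite force at step %d", step);
  };

  forceEval(0);
  int nRecMax = nSteps / std::max(stride, 1) + 1;
  mat recS(nRecMax, 4);   // mode 0: step, s, z, bias
  mat recDev(nRecMax, 6); // mode 1: wrapped deviations
  int nRec = 0;
  Rcpp::RNGScope scope;
  for (int step = 1; step <= nSteps; ++step) {
    for (uword a = 0; a < mob.n_elem; ++a)
      V.row(mob[a]) += 0.5 * dt * F.row(mob[a]);
    for (uword a = 0; a < mob.n_elem; ++a)
      X.row(mob[a]) += 0.5 * dt * V.row(mob[a]);
    if (c2 > 0) {
      // draw in the same order as the R engine: one vector per step
      for (uword a = 0; a < mob.n_elem; ++a)
        for (int k = 0; k < 3; ++k)
          V(mob[a], k) = c1 * V(mob[a], k) + c2 * sdv * R::norm_rand();
    } else if (c1 < 1) {
      for (uword a = 0; a < mob.n_elem; ++a)
        V.row(mob[a]) *= c1;
    }
    for (uword a = 0; a < mob.n_elem; ++a)
      X.row(mob[a]) += 0.5 * dt * V.row(mob[a]);
    forceEval(step);
    for (uword a = 0; a < mob.n_elem; ++a)
      V.row(mob[a]) += 0.5 * dt * F.row(mob[a]);
    if (step % stride == 0) {
      if (mode == 0 && step > rampSteps) {
        // record the full-strength bias energy, matching the R engine
        double dsv = curS - sCenter;
        recS.row(nRec) = rowvec({double(step), curS, curZ,
                                 0.5 * kS * dsv * dsv + 0.5 * kZ * curZ * curZ});
        ++nRec;
      } else if (mode == 1 && step > burnin) {
        vec delta = cvj.cv - node;
        for (int j = 0; j < 6; ++j) delta[j] = wrapAngle(delta[j]);
        recDev.row(nRec) = delta.t();
        ++nRec;
      }
    }
  }
  if (mode == 0)
    return Rcpp::List::create(Rcpp::Named("records") = recS.rows(0, nRec - 1),
                              Rcpp::Named("x") = vectorise(X.t()));
  return Rcpp::List::create(Rcpp::Named("dev") = recDev.rows(0, nRec - 1),
                            Rcpp::Named("x") = vectorise(X.t()));
}

// Batch pathCV evaluation (s, z only) used by oracles on large samples.
// [[Rcpp::export(name = ".cppPathCVBatch")]]
arma::mat cppPathCVBatch(const arma::mat& Xin, const Rcpp::List& pathR) {
  PathDef P = asPath(pathR);
  mat out(Xin.n_rows, 2);
  PathCVOut pc;
  for (uword i = 0; i < Xin.n_rows; ++i) {
    evalPathCV(Xin.row(i).t(), P, pc);
    out(i, 0) = pc.s;
    out(i, 1) = pc.z;
  }
  return out;
}
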