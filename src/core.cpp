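#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Potential-energy model of a bead-cylinder filament network.
// Units: nm, pN, pN*nm. Coordinates are an nbeads x 3 matrix.
//
// Terms:
//  stretch   0.5*ks*(l-l0)^2 per cylinder
//  bend      kb*(1-cos phi) per consecutive cylinder pair
//  excluded  kev*(1/d^4 - 1/dcut^4) per non-adjacent cylinder pair, d = min
//            inter-segment distance, zero beyond dcut (one cylinder length)
//  boundary  eps*exp(-d/lam) per bead over the six box faces and the probe
//            spherical surface
//  motor/linker/anchor harmonic springs 0.5*k*(l-l0)^2

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// capped exponential: exp(t) for t <= 40, linear continuation above
// (avoids overflow when a bead is pushed far through a wall; the gradient
// stays finite and points back inside); hard zero below -40 where the
// repulsion is physically negligible (skips costly underflowing exp calls)
static inline double safe_exp(double t, double &dvdt) {
  if (t < -40.0) {
    dvdt = 0.0;
    return 0.0;
  }
  if (t <= 40.0) {
    double e = std::exp(t);
    dvdt = e;
    return e;
  }
  double e40 = std::exp(40.0);
  dvdt = e40;
  return e40 * (1.0 + (t - 40.0));
}

// minimum distance between segments [P1,P2] and [Q1,Q2]
static double seg_seg_dist(const double *P1, const double *P2,
                           const double *Q1, const double *Q2,
                           double &s, double &t, double *w) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = P2[k] - P1[k];
    d2[k] = Q2[k] - Q1[k];
    r[k] = P1[k] - Q1[k];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
  double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
  double denom = a*e - b*b;
  s = (denom > 1e-12) ? clamp01((b*f - c*e) / denom) : 0.0;
  t = (e > 1e-12) ? (b*s + f) / e : 0.0;
  if (t < 0.0) { t = 0.0; s = (a > 1e-12) ? clamp01(-c / a) : 0.0; }
  else if (t > 1.0) { t = 1.0; s = (a > 1e-12) ? clamp01((b - c) / a) : 0.0; }
  double d2sum = 0.0;
  for (int k = 0; k < 3; ++k) {
    w[k] = (P1[k] + s*d1[k]) - (Q1[k] + t*d2[k]);
    d2sum += w[k]*w[k];
  }
  return std::sqrt(d2sum);
}

struct Topology {
  int n;                       // beads
  const int *cb1, *cb2;        // cylinders
  const double *cl0;
  const int *cfil, *cidx;
  int ncyl;
  double ks, kb;
  const int *ba, *bb, *bc;     // bend triples
  int nbend;
  const int *e1a, *e1b, *e2a, *e2b;   // bond endpoints
  const double *f1, *f2, *bond_k, *bond_l0;
  const int *bond_type;
  int nbond;
  const int *anch_bead;        // anchors
  const double *anch_x, *anch_y, *anch_z;
  int nanch;
  double ka;
  double box[3];
  double beps, blam;
  bool has_probe;
  double pc[3], pr;
  double kev, evcut;
};

// X is column-major n x 3 (R layout); G same shape, zeroed by caller
static double compute_energy(const Topology &T, const double *X,
                             double *G, double *terms, bool want_grad,
                             bool *err) {
  const int n = T.n;
  if (err) *err = false;
  double E_stretch = 0, E_bend = 0, E_ev = 0, E_bnd = 0;
  double E_motor = 0, E_linker = 0, E_anchor = 0;
  const double *Xx = X, *Xy = X + n, *Xz = X + 2 * n;
  double *Gx = G, *Gy = G ? G + n : 0, *Gz = G ? G + 2 * n : 0;

  // ---- stretching
  for (int i = 0; i < T.ncyl; ++i) {
    int b1 = T.cb1[i], b2 = T.cb2[i];
    double u0 = Xx[b2]-Xx[b1], u1 = Xy[b2]-Xy[b1], u2 = Xz[b2]-Xz[b1];
    double l = std::sqrt(u0*u0 + u1*u1 + u2*u2);
    if (l < 1e-9) { if (err) *err = true; return R_PosInf; }
    double dl = l - T.cl0[i];
    E_stretch += 0.5 * T.ks * dl * dl;
    if (want_grad) {
      double coef = T.ks * dl / l;
      Gx[b2] += coef*u0; Gy[b2] += coef*u1; Gz[b2] += coef*u2;
      Gx[b1] -= coef*u0; Gy[b1] -= coef*u1; Gz[b1] -= coef*u2;
    }
  }

  // ---- bending
  for (int i = 0; i < T.nbend; ++i) {
    int A = T.ba[i], B = T.bb[i], C = T.bc[i];
    double u[3] = { Xx[B]-Xx[A], Xy[B]-Xy[A], Xz[B]-Xz[A] };
    double v[3] = { Xx[C]-Xx[B], Xy[C]-Xy[B], Xz[C]-Xz[B] };
    double lu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    double lv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    if (lu < 1e-9 || lv < 1e-9) continue;
    double dot = u[0]*v[0]+u[1]*v[1]+u[2]*v[2];
    double cphi = dot / (lu * lv);
    if (cphi > 1.0) cphi = 1.0;
    if (cphi < -1.0) cphi = -1.0;
    E_bend += T.kb * (1.0 - cphi);
    if (want_grad) {
      for (int k = 0; k < 3; ++k) {
        double dcdu = v[k]/(lu*lv) - cphi*u[k]/(lu*lu);
        double dcdv = u[k]/(lu*lv) - cphi*v[k]/(lv*lv);
        double dEdu = -T.kb * dcdu;
        double dEdv = -T.kb * dcdv;
        double *Gk = (k == 0) ? Gx : (k == 1 ? Gy : Gz);
        Gk[A] -= dEdu;
        Gk[B] += dEdu - dEdv;
        Gk[C] += dEdv;
      }
    }
  }

  // ---- excluded volume between non-adjacent cylinder pairs
  // (uniform cell list over cylinder midpoints prunes distant pairs)
  if (T.kev > 0 && T.ncyl > 1) {
    const double cut = T.evcut;
    const double cut4 = cut*cut*cut*cut;
    std::vector<double> lo(3*T.ncyl), hi(3*T.ncyl), mid(3*T.ncyl);
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    double lmax = 0;
    for (int i = 0; i < T.ncyl; ++i) {
      int b1 = T.cb1[i], b2 = T.cb2[i];
      lo[3*i+0] = std::min(Xx[b1], Xx[b2]); hi[3*i+0] = std::max(Xx[b1], Xx[b2]);
      lo[3*i+1] = std::min(Xy[b1], Xy[b2]); hi[3*i+1] = std::max(Xy[b1], Xy[b2]);
      lo[3*i+2] = std::min(Xz[b1], Xz[b2]); hi[3*i+2] = std::max(Xz[b1], Xz[b2]);
      double ll = 0;
      for (int k = 0; k < 3; ++k) {
        mid[3*i+k] = 0.5*(lo[3*i+k] + hi[3*i+k]);
        double ext = hi[3*i+k] - lo[3*i+k];
        ll += ext*ext;
        mn[k] = std::min(mn[k], mid[3*i+k]);
        mx[k] = std::max(mx[k], mid[3*i+k]);
      }
      lmax = std::max(lmax, std::sqrt(ll));
    }
    const double cell = lmax + cut;     // one-cell reach suffices
    int nc[3];
    for (int k = 0; k < 3; ++k)
      nc[k] = std::max(1, (int)((mx[k]-mn[k])/cell) + 1);
    const int reach = 1;
    const int ncells = nc[0]*nc[1]*nc[2];
    std::vector<int> headc(ncells, -1), nextc(T.ncyl);
    std::vector<int> ci(T.ncyl), cj(T.ncyl), ck(T.ncyl);
    for (int i = 0; i < T.ncyl; ++i) {
      ci[i] = std::min(nc[0]-1, std::max(0, (int)((mid[3*i+0]-mn[0])/cell)));
      cj[i] = std::min(nc[1]-1, std::max(0, (int)((mid[3*i+1]-mn[1])/cell)));
      ck[i] = std::min(nc[2]-1, std::max(0, (int)((mid[3*i+2]-mn[2])/cell)));
      int c = ci[i] + nc[0]*(cj[i] + nc[1]*ck[i]);
      nextc[i] = headc[c];
      headc[c] = i;
    }
    for (int i = 0; i < T.ncyl; ++i) {
      for (int dz = -reach; dz <= reach; ++dz) {
        int z = ck[i] + dz;
        if (z < 0 || z >= nc[2]) continue;
        for (int dy = -reach; dy <= reach; ++dy) {
          int y = cj[i] + dy;
          if (y < 0 || y >= nc[1]) continue;
          for (int dx = -reach; dx <= reach; ++dx) {
            int xc = ci[i] + dx;
            if (xc < 0 || xc >= nc[0]) continue;
            for (int j = headc[xc + nc[0]*(y + nc[1]*z)]; j >= 0;
                 j = nextc[j]) {
        if (j <= i) continue;
        if (T.cfil[i] == T.cfil[j] && std::abs(T.cidx[i]-T.cidx[j]) <= 1)
          continue;
        if (lo[3*j+0] - hi[3*i+0] > cut || lo[3*i+0] - hi[3*j+0] > cut ||
            lo[3*j+1] - hi[3*i+1] > cut || lo[3*i+1] - hi[3*j+1] > cut ||
            lo[3*j+2] - hi[3*i+2] > cut || lo[3*i+2] - hi[3*j+2] > cut)
          continue;
        int a1 = T.cb1[i], a2 = T.cb2[i], b1 = T.cb1[j], b2 = T.cb2[j];
        double P1[3] = {Xx[a1], Xy[a1], Xz[a1]};
        double P2[3] = {Xx[a2], Xy[a2], Xz[a2]};
        double Q1[3] = {Xx[b1], Xy[b1], Xz[b1]};
        double Q2[3] = {Xx[b2], Xy[b2], Xz[b2]};
        double s, t, w[3];
        double d = seg_seg_dist(P1, P2, Q1, Q2, s, t, w);
        if (d >= cut) continue;
        // linear continuation below d_soft: keeps the barrier steep but the
        // force bounded, with energy and gradient exactly consistent (a
        // hard divergence makes deep contacts numerically unminimizable)
        const double dsoft = 2.0;
        double e_pair, dEdd;
        if (d >= dsoft) {
          double inv4 = 1.0 / (d*d*d*d);
          e_pair = T.kev * (inv4 - 1.0/cut4);
          dEdd = -4.0 * T.kev * inv4 / d;
        } else {
          double inv4s = 1.0 / (dsoft*dsoft*dsoft*dsoft);
          dEdd = -4.0 * T.kev * inv4s / dsoft;
          e_pair = T.kev * (inv4s - 1.0/cut4) + dEdd * (d - dsoft);
        }
        E_ev += e_pair;
        if (want_grad) {
          double wn[3];
          if (d > 1e-9) { wn[0]=w[0]/d; wn[1]=w[1]/d; wn[2]=w[2]/d; }
          else { wn[0]=0; wn[1]=0; wn[2]=1; }
          for (int k = 0; k < 3; ++k) {
            double g = dEdd * wn[k];
            double *Gk = (k == 0) ? Gx : (k == 1 ? Gy : Gz);
            Gk[a1] += (1.0-s) * g;
            Gk[a2] += s * g;
            Gk[b1] -= (1.0-t) * g;
            Gk[b2] -= t * g;
          }
        }
            }
          }
        }
      }
    }
  }

  // ---- boundary repulsion (six faces + probe surface)
  if (T.beps > 0) {
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        const double *Xk = (k == 0) ? Xx : (k == 1 ? Xy : Xz);
        double *Gk = want_grad ? ((k == 0) ? Gx : (k == 1 ? Gy : Gz)) : 0;
        double dvdt;
        E_bnd += T.beps * safe_exp(-Xk[i]/T.blam, dvdt);
        if (want_grad) Gk[i] -= T.beps/T.blam * dvdt;
        E_bnd += T.beps * safe_exp(-(T.box[k]-Xk[i])/T.blam, dvdt);
        if (want_grad) Gk[i] += T.beps/T.blam * dvdt;
      }
      if (T.has_probe) {
        double v[3] = { Xx[i]-T.pc[0], Xy[i]-T.pc[1], Xz[i]-T.pc[2] };
        double r = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
        double d = r - T.pr;
        double dvdt;
        E_bnd += T.beps * safe_exp(-d/T.blam, dvdt);
        if (want_grad) {
          double coef = -T.beps/T.blam * dvdt;
          if (r > 1e-9) {
            Gx[i] += coef * v[0]/r;
            Gy[i] += coef * v[1]/r;
            Gz[i] += coef * v[2]/r;
          } else {
            Gz[i] -= coef;
          }
        }
      }
    }
  }

  // ---- motor / linker springs (endpoints interpolated on cylinders)
  for (int i = 0; i < T.nbond; ++i) {
    double g1 = T.f1[i], g2 = T.f2[i];
    int p1a = T.e1a[i], p1b = T.e1b[i], p2a = T.e2a[i], p2b = T.e2b[i];
    double p1[3] = { (1-g1)*Xx[p1a] + g1*Xx[p1b],
                     (1-g1)*Xy[p1a] + g1*Xy[p1b],
                     (1-g1)*Xz[p1a] + g1*Xz[p1b] };
    double p2[3] = { (1-g2)*Xx[p2a] + g2*Xx[p2b],
                     (1-g2)*Xy[p2a] + g2*Xy[p2b],
                     (1-g2)*Xz[p2a] + g2*Xz[p2b] };
    double u[3] = { p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2] };
    double l = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    double dl = l - T.bond_l0[i];
    double e = 0.5 * T.bond_k[i] * dl * dl;
    if (T.bond_type[i] == 0) E_motor += e; else E_linker += e;
    if (want_grad && l > 1e-9) {
      double coef = T.bond_k[i] * dl / l;
      for (int k = 0; k < 3; ++k) {
        double g = coef * u[k];
        double *Gk = (k == 0) ? Gx : (k == 1 ? Gy : Gz);
        Gk[p2a] += (1.0-g2) * g;
        Gk[p2b] += g2 * g;
        Gk[p1a] -= (1.0-g1) * g;
        Gk[p1b] -= g1 * g;
      }
    }
  }

  // ---- anchors (stiff springs, zero rest length)
  for (int i = 0; i < T.nanch; ++i) {
    int b = T.anch_bead[i];
    double v[3] = { Xx[b]-T.anch_x[i], Xy[b]-T.anch_y[i], Xz[b]-T.anch_z[i] };
    E_anchor += 0.5 * T.ka * (v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    if (want_grad) {
      Gx[b] += T.ka * v[0];
      Gy[b] += T.ka * v[1];
      Gz[b] += T.ka * v[2];
    }
  }

  terms[0] = E_stretch; terms[1] = E_bend; terms[2] = E_ev;
  terms[3] = E_bnd; terms[4] = E_motor; terms[5] = E_linker;
  terms[6] = E_anchor;
  return E_stretch + E_bend + E_ev + E_bnd + E_motor + E_linker + E_anchor;
}

static Topology make_topology(NumericMatrix &X,
    IntegerVector &cb1, IntegerVector &cb2, NumericVector &cl0,
    IntegerVector &cfil, IntegerVector &cidx, double ks, double kb,
    IntegerVector &ba, IntegerVector &bb, IntegerVector &bc,
    IntegerVector &e1a, IntegerVector &e1b, NumericVector &f1,
    IntegerVector &e2a, IntegerVector &e2b, NumericVector &f2,
    NumericVector &bond_k, NumericVector &bond_l0, IntegerVector &bond_type,
    IntegerVector &anch_bead, NumericMatrix &anch_pt, double ka,
    NumericVector &box, double beps, double blam,
    bool has_probe, NumericVector &pc, double pr,
    double kev, double evcut) {
  Topology T;
  T.n = X.nrow();
  T.cb1 = cb1.begin(); T.cb2 = cb2.begin(); T.cl0 = cl0.begin();
  T.cfil = cfil.begin(); T.cidx = cidx.begin();
  T.ncyl = cb1.size();
  T.ks = ks; T.kb = kb;
  T.ba = ba.begin(); T.bb = bb.begin(); T.bc = bc.begin();
  T.nbend = ba.size();
  T.e1a = e1a.begin(); T.e1b = e1b.begin();
  T.e2a = e2a.begin(); T.e2b = e2b.begin();
  T.f1 = f1.begin(); T.f2 = f2.begin();
  T.bond_k = bond_k.begin(); T.bond_l0 = bond_l0.begin();
  T.bond_type = bond_type.begin();
  T.nbond = e1a.size();
  T.anch_bead = anch_bead.begin();
  T.nanch = anch_bead.size();
  T.anch_x = anch_pt.begin();
  T.anch_y = anch_pt.begin() + anch_pt.nrow();
  T.anch_z = anch_pt.begin() + 2 * anch_pt.nrow();
  T.ka = ka;
  T.box[0] = box[0]; T.box[1] = box[1]; T.box[2] = box[2];
  T.beps = beps; T.blam = blam;
  T.has_probe = has_probe;
  T.pc[0] = pc[0]; T.pc[1] = pc[1]; T.pc[2] = pc[2];
  T.pr = pr;
  T.kev = kev; T.evcut = evcut;
  return T;
}

static const char *term_names[7] = {
  "stretch", "bend", "excluded_volume", "boundary", "motor", "linker",
  "anchor" };

// [[Rcpp::export]]
List energy_grad_cpp(NumericMatrix X,
                     IntegerVector cb1, IntegerVector cb2, NumericVector cl0,
                     IntegerVector cfil, IntegerVector cidx,
                     double ks, double kb,
                     IntegerVector ba, IntegerVector bb, IntegerVector bc,
                     IntegerVector e1a, IntegerVector e1b, NumericVector f1,
                     IntegerVector e2a, IntegerVector e2b, NumericVector f2,
                     NumericVector bond_k, NumericVector bond_l0,
                     IntegerVector bond_type,
                     IntegerVector anch_bead, NumericMatrix anch_pt, double ka,
                     NumericVector box, double beps, double blam,
                     bool has_probe, NumericVector pc, double pr,
                     double kev, double evcut,
                     bool want_grad) {
  Topology T = make_topology(X, cb1, cb2, cl0, cfil, cidx, ks, kb,
                             ba, bb, bc, e1a, e1b, f1, e2a, e2b, f2,
                             bond_k, bond_l0, bond_type, anch_bead, anch_pt,
                             ka, box, beps, blam, has_probe, pc, pr,
                             kev, evcut);
  NumericVector terms(7);
  terms.attr("names") = CharacterVector(term_names, term_names + 7);
  bool errflag = false;
  if (want_grad) {
    NumericMatrix G(T.n, 3);
    double total = compute_energy(T, X.begin(), G.begin(), terms.begin(),
                                  true, &errflag);
    if (errflag) stop("coincident beads in a cylinder (zero length)");
    return List::create(_["total"] = total, _["terms"] = terms,
                        _["grad"] = G);
  }
  double total = compute_energy(T, X.begin(), 0, terms.begin(), false,
                                &errflag);
  if (errflag) stop("coincident beads in a cylinder (zero length)");
  return List::create(_["total"] = total, _["terms"] = terms);
}

// L-BFGS energy minimization with Armijo backtracking, stopping when the
// largest per-bead force magnitude is <= force_tol. Descent is enforced:
// the returned configuration never has higher energy than the input.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix X,
                  IntegerVector cb1, IntegerVector cb2, NumericVector cl0,
                  IntegerVector cfil, IntegerVector cidx,
                  double ks, double kb,
                  IntegerVector ba, IntegerVector bb, IntegerVector bc,
                  IntegerVector e1a, IntegerVector e1b, NumericVector f1,
                  IntegerVector e2a, IntegerVector e2b, NumericVector f2,
                  NumericVector bond_k, NumericVector bond_l0,
                  IntegerVector bond_type,
                  IntegerVector anch_bead, NumericMatrix anch_pt, double ka,
                  NumericVector box, double beps, double blam,
                  bool has_probe, NumericVector pc, double pr,
                  double kev, double evcut,
                  double force_tol, int maxit) {
  Topology T = make_topology(X, cb1, cb2, cl0, cfil, cidx, ks, kb,
                             ba, bb, bc, e1a, e1b, f1, e2a, e2b, f2,
                             bond_k, bond_l0, bond_type, anch_bead, anch_pt,
                             ka, box, beps, blam, has_probe, pc, pr,
                             kev, evcut);
  const int n = T.n, dim = 3 * n;
  NumericMatrix Xout(clone(X));
  double *x = Xout.begin();
  std::vector<double> g(dim, 0.0), gnew(dim, 0.0), xnew(dim), d(dim);
  NumericVector terms(7);
  terms.attr("names") = CharacterVector(term_names, term_names + 7);
  bool errflag = false;
  double E = compute_energy(T, x, g.data(), terms.begin(), true, &errflag);
  if (errflag) stop("coincident beads in a cylinder (zero length)");

  auto max_force = [&](const double *gr) {
    double m2 = 0;
    for (int i = 0; i < n; ++i) {
      double f2 = gr[i]*gr[i] + gr[n+i]*gr[n+i] + gr[2*n+i]*gr[2*n+i];
      if (f2 > m2) m2 = f2;
    }
    return std::sqrt(m2);
  };

  const int m = 8;                     // L-BFGS memory
  std::vector<std::vector<double> > S(m, std::vector<double>(dim));
  std::vector<std::vector<double> > Y(m, std::vector<double>(dim));
  std::vector<double> rho(m), alpha_v(m);
  int mem = 0, head = 0;
  bool converged = max_force(g.data()) <= force_tol;
  int iter = 0;
  int nfun = 1;

  while (!converged && iter < maxit) {
    ++iter;
    // two-loop recursion: d = -H g
    std::memcpy(d.data(), g.data(), dim * sizeof(double));
    for (int i = 0; i < mem; ++i) {
      int idx = (head - 1 - i + m * 4) % m;
      double a = 0;
      for (int k = 0; k < dim; ++k) a += S[idx][k] * d[k];
      a *= rho[idx];
      alpha_v[idx] = a;
      for (int k = 0; k < dim; ++k) d[k] -= a * Y[idx][k];
    }
    if (mem > 0) {
      int idx = (head - 1 + m) % m;
      double yy = 0, sy = 0;
      for (int k = 0; k < dim; ++k) { yy += Y[idx][k]*Y[idx][k]; sy += S[idx][k]*Y[idx][k]; }
      double gamma = (yy > 0) ? sy / yy : 1.0;
      for (int k = 0; k < dim; ++k) d[k] *= gamma;
      for (int i = mem - 1; i >= 0; --i) {
        int idx2 = (head - 1 - i + m * 4) % m;
        double beta = 0;
        for (int k = 0; k < dim; ++k) beta += Y[idx2][k] * d[k];
        beta *= rho[idx2];
        double coef = alpha_v[idx2] - beta;
        for (int k = 0; k < dim; ++k) d[k] += coef * S[idx2][k];
      }
    } else {
      // first step: scale so max displacement ~ 0.1 nm
      double gmax = 0;
      for (int k = 0; k < dim; ++k) gmax = std::max(gmax, std::abs(d[k]));
      double sc = (gmax > 0) ? 0.1 / gmax : 1.0;
      for (int k = 0; k < dim; ++k) d[k] *= sc;
    }
    for (int k = 0; k < dim; ++k) d[k] = -d[k];
    double gd = 0;
    for (int k = 0; k < dim; ++k) gd += g[k] * d[k];
    if (gd >= 0) {                     // reset to steepest descent
      mem = 0;
      double gmax = 0;
      for (int k = 0; k < dim; ++k) gmax = std::max(gmax, std::abs(g[k]));
      double sc = (gmax > 0) ? 0.1 / gmax : 1.0;
      gd = 0;
      for (int k = 0; k < dim; ++k) { d[k] = -sc * g[k]; gd += g[k]*d[k]; }
      if (gd >= 0) break;
    }
    // backtracking Armijo line search
    double step = 1.0, Enew = R_PosInf;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int k = 0; k < dim; ++k) xnew[k] = x[k] + step * d[k];
      std::fill(gnew.begin(), gnew.end(), 0.0);
      Enew = compute_energy(T, xnew.data(), gnew.data(), terms.begin(),
                            true, &errflag);
      ++nfun;
      if (!errflag && R_finite(Enew) && Enew <= E + 1e-4 * step * gd) {
        ok = true;
        break;
      }
      step *= 0.5;
    }
    if (!ok) {
      if (mem > 0) { mem = 0; continue; }   // retry as steepest descent
      break;
    }
    // store curvature pair
    double sy = 0;
    for (int k = 0; k < dim; ++k) {
      double sk = step * d[k];
      double yk = gnew[k] - g[k];
      S[head][k] = sk;
      Y[head][k] = yk;
      sy += sk * yk;
    }
    if (sy > 1e-12) {
      rho[head] = 1.0 / sy;
      head = (head + 1) % m;
      if (mem < m) ++mem;
    }
    std::memcpy(x, xnew.data(), dim * sizeof(double));
    std::swap(g, gnew);
    E = Enew;
    converged = max_force(g.data()) <= force_tol;
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // final term breakdown at the returned configuration
  std::fill(g.begin(), g.end(), 0.0);
  E = compute_energy(T, x, g.data(), terms.begin(), true, &errflag);
  return List::create(_["X"] = Xout, _["total"] = E, _["terms"] = terms,
                      _["converged"] = converged, _["iter"] = iter,
                      _["nfun"] = nfun,
                      _["max_force"] = max_force(g.data()));
}

// Unoccupied site pairs whose separation lies in [lo, hi], excluding pairs
// on the same or adjacent cylinders of one filament. 1-based indices out.
// [[Rcpp::export]]
IntegerMatrix candidate_pairs_cpp(NumericMatrix S, IntegerVector sfil,
                                  IntegerVector scyl, LogicalVector occ,
                                  double lo, double hi) {
  const int n = S.nrow();
  const double lo2 = lo*lo, hi2 = hi*hi;
  const double *sx = S.begin(), *sy = S.begin() + n, *sz = S.begin() + 2*n;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    if (occ[i]) continue;
    for (int j = i+1; j < n; ++j) {
      if (occ[j]) continue;
      if (sfil[i] == sfil[j] && std::abs(scyl[i]-scyl[j]) <= 1) continue;
      double dx = sx[i]-sx[j];
      double d2 = dx*dx;
      if (d2 > hi2) continue;
      double dy = sy[i]-sy[j];
      d2 += dy*dy;
      if (d2 > hi2) continue;
      double dz = sz[i]-sz[j];
      d2 += dz*dz;
      if (d2 < lo2 || d2 > hi2) continue;
      ii.push_back(i+1);
      jj.push_back(j+1);
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t r = 0; r < ii.size(); ++r) { out(r,0) = ii[r]; out(r,1) = jj[r]; }
  return out;
}
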