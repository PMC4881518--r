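// Compiled core: molecular-mechanics force field, collective variables with
// analytic gradients, harmonic bias potentials, and a BAOAB Langevin integrator.
//
// Units throughout: length Angstrom, energy kcal/mol, time ps, mass amu,
// temperature K.  Angles cross the R boundary in degrees; internally radians.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;

static const double KB = 0.0019872041;      // kcal/(mol K)
static const double KCAL_TO_AKMA = 418.4;   // 1 kcal/mol = 418.4 amu A^2 / ps^2
static const double COULOMB = 332.0637;     // (kcal/mol) A / e^2
static const double DEG = 3.14159265358979323846 / 180.0;
static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Force field container (parsed once per run from an R list)
// ---------------------------------------------------------------------------

struct ForceField {
  arma::vec mass, charge, eps, sigma;
  arma::umat bonds;   arma::mat bondp;    // cols i j | kb r0        E = kb (r-r0)^2
  arma::umat angles;  arma::mat anglep;   // cols i j k | ka th0(rad) E = ka (th-th0)^2
  arma::umat torsions; arma::mat torsp;   // cols i j k l | v2 n gamma(rad)
  arma::umat nb;      arma::mat nbp;      // cols i j | eps_ij sig_ij qq_scaled
  arma::umat extat;   arma::mat extp;     // atom axis kind | p1 p2 p3 p4
  int natoms;
};

static arma::umat as_umat_idx(SEXP m) {
  arma::mat mm = as<arma::mat>(m);
  arma::umat out(mm.n_rows, mm.n_cols);
  for (arma::uword i = 0; i < mm.n_elem; ++i) out(i) = (arma::uword)(mm(i) - 1); // 1- to 0-based
  return out;
}

static ForceField parse_ff(const List& sys) {
  ForceField ff;
  ff.mass = as<arma::vec>(sys["mass"]);
  ff.charge = as<arma::vec>(sys["charge"]);
  ff.natoms = ff.mass.n_elem;
  List b = sys["bonds"];
  ff.bonds = as_umat_idx(b["idx"]);  ff.bondp = as<arma::mat>(b["par"]);
  List a = sys["angles"];
  ff.angles = as_umat_idx(a["idx"]); ff.anglep = as<arma::mat>(a["par"]);
  List t = sys["torsions"];
  ff.torsions = as_umat_idx(t["idx"]); ff.torsp = as<arma::mat>(t["par"]);
  List nb = sys["nb"];
  ff.nb = as_umat_idx(nb["idx"]);    ff.nbp = as<arma::mat>(nb["par"]);
  List ex = sys["external"];
  ff.extat = as_umat_idx(ex["idx"]); ff.extp = as<arma::mat>(ex["par"]);
  return ff;
}

// ---------------------------------------------------------------------------
// Energy and forces.  coords is natoms x 3; forces accumulated as -dE/dx.
// ---------------------------------------------------------------------------

struct EnergyTerms { double bond = 0, angle = 0, torsion = 0, nonbonded = 0, external = 0;
  double total() const { return bond + angle + torsion + nonbonded + external; } };

static double dihedral_rad(const arma::mat& x, arma::uword i, arma::uword j,
                           arma::uword k, arma::uword l,
                           arma::mat* grad = nullptr) {
  arma::rowvec b1 = x.row(j) - x.row(i);
  arma::rowvec b2 = x.row(k) - x.row(j);
  arma::rowvec b3 = x.row(l) - x.row(k);
  arma::rowvec n1 = arma::cross(b1, b2);
  arma::rowvec n2 = arma::cross(b2, b3);
  double nb2 = arma::norm(b2);
  if (nb2 < 1e-12 || arma::norm(n1) < 1e-10 || arma::norm(n2) < 1e-10)
    stop("dihedral undefined: collinear atoms");
  double xphi = arma::dot(n1, n2);
  double yphi = arma::dot(arma::cross(n1, n2), b2 / nb2);
  double phi = std::atan2(yphi, xphi);
  if (grad) {
    double in1 = 1.0 / arma::dot(n1, n1), in2 = 1.0 / arma::dot(n2, n2);
    arma::rowvec gi = -(nb2 * in1) * n1;
    arma::rowvec gl =  (nb2 * in2) * n2;
    double c12 = arma::dot(b1, b2) / (nb2 * nb2);
    double c32 = arma::dot(b3, b2) / (nb2 * nb2);
    arma::rowvec gj = (-1.0 - c12) * gi + c32 * gl;
    arma::rowvec gk = (-1.0 - c32) * gl + c12 * gi;
    grad->zeros(x.n_rows, 3);
    grad->row(i) = gi; grad->row(j) = gj; grad->row(k) = gk; grad->row(l) = gl;
  }
  return phi;
}

static EnergyTerms energy_forces(const ForceField& ff, const arma::mat& x, arma::mat& f) {
  EnergyTerms e;
  f.zeros(ff.natoms, 3);

  for (arma::uword r = 0; r < ff.bonds.n_rows; ++r) {
    arma::uword i = ff.bonds(r, 0), j = ff.bonds(r, 1);
    arma::rowvec d = x.row(i) - x.row(j);
    double rij = arma::norm(d);
    if (rij < 1e-10) stop("zero-length bond vector between atoms %d and %d", (int)i + 1, (int)j + 1);
    double kb = ff.bondp(r, 0), r0 = ff.bondp(r, 1);
    e.bond += kb * (rij - r0) * (rij - r0);
    arma::rowvec fi = (-2.0 * kb * (rij - r0) / rij) * d;
    f.row(i) += fi; f.row(j) -= fi;
  }

  for (arma::uword r = 0; r < ff.angles.n_rows; ++r) {
    arma::uword i = ff.angles(r, 0), j = ff.angles(r, 1), k = ff.angles(r, 2);
    arma::rowvec u = x.row(i) - x.row(j), v = x.row(k) - x.row(j);
    double nu = arma::norm(u), nv = arma::norm(v);
    double c = arma::dot(u, v) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c), s = std::sqrt(std::max(1e-12, 1.0 - c * c));
    double ka = ff.anglep(r, 0), th0 = ff.anglep(r, 1);
    e.angle += ka * (th - th0) * (th - th0);
    double dEdth = 2.0 * ka * (th - th0);
    arma::rowvec uh = u / nu, vh = v / nv;
    arma::rowvec dthdi = (uh * c - vh) / (nu * s);
    arma::rowvec dthdk = (vh * c - uh) / (nv * s);
    f.row(i) -= dEdth * dthdi;
    f.row(k) -= dEdth * dthdk;
    f.row(j) += dEdth * (dthdi + dthdk);
  }

  arma::mat dphi;
  for (arma::uword r = 0; r < ff.torsions.n_rows; ++r) {
    double phi = dihedral_rad(x, ff.torsions(r, 0), ff.torsions(r, 1),
                              ff.torsions(r, 2), ff.torsions(r, 3), &dphi);
    double v2 = ff.torsp(r, 0), n = ff.torsp(r, 1), g = ff.torsp(r, 2);
    e.torsion += v2 * (1.0 + std::cos(n * phi - g));
    double dEdphi = -v2 * n * std::sin(n * phi - g);
    f -= dEdphi * dphi;
  }

  for (arma::uword r = 0; r < ff.nb.n_rows; ++r) {
    arma::uword i = ff.nb(r, 0), j = ff.nb(r, 1);
    arma::rowvec d = x.row(i) - x.row(j);
    double r2 = arma::dot(d, d);
    double rij = std::sqrt(r2);
    if (rij < 1e-10) stop("overlapping nonbonded pair %d-%d", (int)i + 1, (int)j + 1);
    double epsij = ff.nbp(r, 0), sigij = ff.nbp(r, 1), qq = ff.nbp(r, 2);
    double elj = 0, dEdr = 0;
    if (epsij > 0) {
      double sr6 = std::pow(sigij * sigij / r2, 3.0), sr12 = sr6 * sr6;
      elj = 4.0 * epsij * (sr12 - sr6);
      dEdr += 4.0 * epsij * (-12.0 * sr12 + 6.0 * sr6) / rij;
    }
    double ec = COULOMB * qq / rij;
    dEdr += -ec / rij;
    e.nonbonded += elj + ec;
    arma::rowvec fi = (-dEdr / rij) * d;
    f.row(i) += fi; f.row(j) -= fi;
  }

  // external one-body terms (toy systems): kind 1 = A(1 + cos(n w q - phase)),
  // w = 2 pi / period; kind 2 = k (q - q0)^2
  for (arma::uword r = 0; r < ff.extat.n_rows; ++r) {
    arma::uword a = ff.extat(r, 0), ax = ff.extat(r, 1), kind = ff.extat(r, 2);
    double q = x(a, ax);
    if (kind == 0) {  // cosine (stored kind 1 in R, 0-based here)
      double A = ff.extp(r, 0), n = ff.extp(r, 1), ph = ff.extp(r, 2), per = ff.extp(r, 3);
      double w = 2.0 * PI / per;
      e.external += A * (1.0 + std::cos(n * w * q - ph));
      f(a, ax) += A * std::sin(n * w * q - ph) * n * w;
    } else {          // harmonic
      double k = ff.extp(r, 0), q0 = ff.extp(r, 1);
      e.external += k * (q - q0) * (q - q0);
      f(a, ax) += -2.0 * k * (q - q0);
    }
  }
  return e;
}

// [[Rcpp::export(name = ".ff_energy_forces")]]
List ff_energy_forces_cpp(List sys, arma::mat coords) {
  ForceField ff = parse_ff(sys);
  if ((int)coords.n_rows != ff.natoms)
    stop("frame has %d atoms but system has %d", (int)coords.n_rows, ff.natoms);
  arma::mat f;
  EnergyTerms e = energy_forces(ff, coords, f);
  return List::create(_["energy"] = e.total(), _["forces"] = f,
                      _["terms"] = NumericVector::create(
                        _["bond"] = e.bond, _["angle"] = e.angle,
                        _["torsion"] = e.torsion, _["nonbonded"] = e.nonbonded,
                        _["external"] = e.external));
}

// ---------------------------------------------------------------------------
// Collective variables
// kind: 1 dihedral (deg, periodic 360); 2 mass-weighted RMSD (A);
//       3 radius of gyration (A); 4 raw coordinate of one atom (periodic deg);
//       5 center-of-mass distance (A)
// ---------------------------------------------------------------------------

struct Colvar {
  int kind;
  arma::uvec sel, sel2;
  arma::mat ref;       // rmsd reference (nsel x 3), pre-centered copy kept as-is
  arma::vec w;         // weights over sel (masses)
  int axis = 0;
};

static Colvar parse_cv(const List& cv) {
  Colvar c;
  c.kind = as<int>(cv["kind"]);
  arma::vec s = as<arma::vec>(cv["sel"]);
  c.sel.set_size(s.n_elem);
  for (arma::uword i = 0; i < s.n_elem; ++i) c.sel(i) = (arma::uword)(s(i) - 1);
  if (cv.containsElementNamed("sel2") && !Rf_isNull(cv["sel2"])) {
    arma::vec s2 = as<arma::vec>(cv["sel2"]);
    c.sel2.set_size(s2.n_elem);
    for (arma::uword i = 0; i < s2.n_elem; ++i) c.sel2(i) = (arma::uword)(s2(i) - 1);
  }
  if (cv.containsElementNamed("ref") && !Rf_isNull(cv["ref"])) c.ref = as<arma::mat>(cv["ref"]);
  if (cv.containsElementNamed("weights") && !Rf_isNull(cv["weights"])) c.w = as<arma::vec>(cv["weights"]);
  if (cv.containsElementNamed("axis")) c.axis = as<int>(cv["axis"]) - 1;
  return c;
}

// Weighted Kabsch rotation taking centered ref (Y) onto centered mobile (X).
static arma::mat kabsch(const arma::mat& Xc, const arma::mat& Yc, const arma::vec& w) {
  arma::mat C = (Yc.each_col() % w).t() * Xc;   // 3x3
  arma::mat U, V; arma::vec s;
  if (!arma::svd(U, s, V, C)) stop("superposition SVD failed");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;
  return V * D * U.t();  // R maps ref-frame vectors into mobile frame
}

// value + optional gradient (w.r.t. full coords) of a CV
static double cv_eval(const Colvar& c, const arma::mat& x, arma::mat* grad) {
  switch (c.kind) {
  case 1: { // dihedral, degrees in [-180, 180)
    double phi = dihedral_rad(x, c.sel(0), c.sel(1), c.sel(2), c.sel(3), grad);
    if (grad) *grad /= DEG;   // rad/A -> deg/A
    double deg = phi / DEG;
    if (deg >= 180.0) deg -= 360.0;
    return deg;
  }
  case 2: { // mass-weighted RMSD after optimal superposition
    arma::uword n = c.sel.n_elem;
    arma::mat X(n, 3);
    for (arma::uword i = 0; i < n; ++i) X.row(i) = x.row(c.sel(i));
    double W = arma::accu(c.w);
    arma::rowvec xc = (c.w.t() * X) / W;
    arma::rowvec yc = (c.w.t() * c.ref) / W;
    arma::mat Xc = X.each_row() - xc;
    arma::mat Yc = c.ref;
    Yc.each_row() -= yc;
    arma::mat R = kabsch(Xc, Yc, c.w);
    arma::mat Yr = Yc * R.t();
    arma::mat D = Xc - Yr;
    double msd = arma::accu((c.w % arma::sum(D % D, 1))) / W;
    double rmsd = std::sqrt(std::max(0.0, msd));
    if (grad) {
      grad->zeros(x.n_rows, 3);
      if (rmsd > 1e-10) {
        // at the optimal rotation/translation the only explicit dependence remains
        arma::mat g = D.each_col() % (c.w / (W * rmsd));
        for (arma::uword i = 0; i < n; ++i) grad->row(c.sel(i)) = g.row(i);
      } // else: gradient undefined at 0; return zeros (bias force vanishes there)
    }
    return rmsd;
  }
  case 3: { // radius of gyration
    arma::uword n = c.sel.n_elem;
    arma::mat X(n, 3);
    for (arma::uword i = 0; i < n; ++i) X.row(i) = x.row(c.sel(i));
    double W = arma::accu(c.w);
    arma::rowvec xc = (c.w.t() * X) / W;
    arma::mat Xc = X.each_row() - xc;
    double rg2 = arma::accu(c.w % arma::sum(Xc % Xc, 1)) / W;
    double rg = std::sqrt(std::max(0.0, rg2));
    if (grad) {
      grad->zeros(x.n_rows, 3);
      if (rg > 1e-10) {
        arma::mat g = Xc.each_col() % (c.w / (W * rg));
        for (arma::uword i = 0; i < n; ++i) grad->row(c.sel(i)) = g.row(i);
      }
    }
    return rg;
  }
  case 4: { // raw coordinate of one atom along an axis (toy 1-D systems)
    if (grad) { grad->zeros(x.n_rows, 3); (*grad)(c.sel(0), c.axis) = 1.0; }
    return x(c.sel(0), c.axis);
  }
  case 5: { // center-of-mass distance between two groups
    double W1 = 0, W2 = 0;
    arma::rowvec c1(3, arma::fill::zeros), c2(3, arma::fill::zeros);
    for (arma::uword i = 0; i < c.sel.n_elem; ++i) { c1 += c.w(i) * x.row(c.sel(i)); W1 += c.w(i); }
    arma::vec w2 = c.w.subvec(c.sel.n_elem, c.w.n_elem - 1);
    for (arma::uword i = 0; i < c.sel2.n_elem; ++i) { c2 += w2(i) * x.row(c.sel2(i)); W2 += w2(i); }
    c1 /= W1; c2 /= W2;
    arma::rowvec d = c1 - c2;
    double dist = arma::norm(d);
    if (grad) {
      grad->zeros(x.n_rows, 3);
      if (dist > 1e-10) {
        arma::rowvec u = d / dist;
        for (arma::uword i = 0; i < c.sel.n_elem; ++i) grad->row(c.sel(i)) += (c.w(i) / W1) * u;
        for (arma::uword i = 0; i < c.sel2.n_elem; ++i) grad->row(c.sel2(i)) -= (w2(i) / W2) * u;
      }
    }
    return dist;
  }
  }
  stop("unknown collective-variable kind");
}

// [[Rcpp::export(name = ".cv_value")]]
double cv_value_cpp(List cv, arma::mat coords) {
  Colvar c = parse_cv(cv);
  return cv_eval(c, coords, nullptr);
}

// [[Rcpp::export(name = ".cv_gradient")]]
arma::mat cv_gradient_cpp(List cv, arma::mat coords) {
  Colvar c = parse_cv(cv);
  arma::mat g;
  cv_eval(c, coords, &g);
  return g;
}

// ---------------------------------------------------------------------------
// Bias potentials
//   kind 0: none
//   kind 1: umbrella, E = 1/2 k2 D^2; D = minimum-image CV deviation from the
//           center (converted to radians when `angular`, so k2 is kcal/mol/rad^2)
//   kind 2: TMD, E = 1/2 (k1/N) [RMSD(t) - RMSD0(t)]^2 with a linear ramp
//           RMSD0(t) = rmsd0_start (1 - t/duration), floored at 0
// ---------------------------------------------------------------------------

struct Bias {
  int kind = 0;
  Colvar cv;
  double k = 0, center = 0;
  bool angular = false, periodic = false;
  double period = 360.0;
  double k_per_atom = 0, rmsd0_start = 0, duration = 1;
};

static Bias parse_bias(SEXP biasS) {
  Bias b;
  if (Rf_isNull(biasS)) return b;
  List bias(biasS);
  std::string kind = as<std::string>(bias["kind"]);
  if (kind == "none") return b;
  b.cv = parse_cv(bias["cv"]);
  if (kind == "umbrella") {
    b.kind = 1;
    b.k = as<double>(bias["k2"]);
    b.center = as<double>(bias["center"]);
    b.angular = as<bool>(bias["angular"]);
    b.periodic = as<bool>(bias["periodic"]);
    if (bias.containsElementNamed("period")) b.period = as<double>(bias["period"]);
  } else if (kind == "tmd") {
    b.kind = 2;
    b.k_per_atom = as<double>(bias["k1"]);
    b.rmsd0_start = as<double>(bias["rmsd0_start"]);
    b.duration = as<double>(bias["duration"]);
  } else stop("unknown bias kind '%s'", kind.c_str());
  return b;
}

static double bias_energy_forces(const Bias& b, const arma::mat& x, double t, arma::mat& f) {
  if (b.kind == 0) return 0.0;
  arma::mat g;
  double v = cv_eval(b.cv, x, &g);
  if (b.kind == 1) {
    double d = v - b.center;
    if (b.periodic) d -= b.period * std::round(d / b.period);
    double scale = b.angular ? DEG : 1.0;  // deviation and gradient to radians
    double dr = d * scale;
    f -= (b.k * dr * scale) * g;
    return 0.5 * b.k * dr * dr;
  }
  // TMD: per-atom constant k1, total restraint scales with the atom count N
  double frac = 1.0 - t / b.duration;
  if (frac < 0) frac = 0;
  double rmsd0 = b.rmsd0_start * frac;
  double N = (double)b.cv.sel.n_elem;
  double d = v - rmsd0;
  f -= (b.k_per_atom * N * d) * g;
  return 0.5 * b.k_per_atom * N * d * d;
}

// [[Rcpp::export(name = ".bias_energy_forces")]]
List bias_energy_forces_cpp(List bias, arma::mat coords, double t) {
  Bias b = parse_bias(bias);
  arma::mat f(coords.n_rows, 3, arma::fill::zeros);
  double e = bias_energy_forces(b, coords, t, f);
  return List::create(_["energy"] = e, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Deterministic portable PRNG (mt19937_64 + Box-Muller); the C++ standard
// normal_distribution is implementation-defined, so normals are hand-rolled.
// ---------------------------------------------------------------------------

struct Rng {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * PI * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".run_langevin")]]
List run_langevin_cpp(List sys, arma::mat coords, SEXP velS, List params,
                      SEXP biasS, List report_cvs) {
  ForceField ff = parse_ff(sys);
  if ((int)coords.n_rows != ff.natoms)
    stop("frame has %d atoms but system has %d", (int)coords.n_rows, ff.natoms);
  Bias bias = parse_bias(biasS);

  double dt = as<double>(params["timestep"]);
  double T = as<double>(params["temperature"]);
  double gamma = as<double>(params["friction"]);
  long nsteps = as<double>(params["n_steps"]);
  long frame_stride = as<double>(params["record_interval"]);
  long cv_stride = as<double>(params["cv_stride"]);
  uint64_t seed = (uint64_t)as<double>(params["seed"]);
  double ceiling = as<double>(params["energy_ceiling"]);
  double t0 = params.containsElementNamed("t0") ? as<double>(params["t0"]) : 0.0;

  Rng rng(seed);

  int n = ff.natoms;
  arma::vec invm = 1.0 / ff.mass;
  arma::mat v(n, 3);
  if (Rf_isNull(velS)) {
    // Maxwell-Boltzmann initial velocities (A/ps)
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KB * T * KCAL_TO_AKMA / ff.mass(i));
      for (int d = 0; d < 3; ++d) v(i, d) = (T > 0) ? s * rng.norm() : 0.0;
    }
  } else v = as<arma::mat>(velS);

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int ncv = report_cvs.size();
  std::vector<Colvar> rcv(ncv);
  for (int i = 0; i < ncv; ++i) rcv[i] = parse_cv(report_cvs[i]);

  long nframes = nsteps / frame_stride + 1;
  long ncvrec = (cv_stride > 0) ? nsteps / cv_stride + 1 : 0;
  arma::cube frames(n, 3, nframes);
  arma::vec ftimes(nframes);
  arma::mat cvvals(ncvrec > 0 ? ncv : 0, std::max(ncvrec, 0L));
  arma::vec cvtimes(std::max(ncvrec, 0L));
  arma::vec energies(nframes);

  arma::mat f;
  EnergyTerms e = energy_forces(ff, coords, f);
  double eb = bias_energy_forces(bias, coords, t0, f);

  long fi = 0, ci = 0;
  auto record = [&](long step) {
    double t = t0 + step * dt;
    if (step % frame_stride == 0 && fi < nframes) {
      frames.slice(fi) = coords; ftimes(fi) = t;
      double ke = 0.5 * arma::accu((arma::sum(v % v, 1) % ff.mass)) / KCAL_TO_AKMA;
      energies(fi) = e.total() + eb + ke;
      ++fi;
    }
    if (cv_stride > 0 && step % cv_stride == 0 && ci < ncvrec) {
      for (int q = 0; q < ncv; ++q) cvvals(q, ci) = cv_eval(rcv[q], coords, nullptr);
      cvtimes(ci) = t;
      ++ci;
    }
  };
  record(0);

  double sqrtkT = std::sqrt(KB * T * KCAL_TO_AKMA);
  for (long step = 1; step <= nsteps; ++step) {
    // B
    v += (0.5 * dt * KCAL_TO_AKMA) * (f.each_col() % invm);
    // A
    coords += (0.5 * dt) * v;
    // O
    if (gamma > 0 && T > 0) {
      for (int i = 0; i < n; ++i) {
        double s = c2 * sqrtkT / std::sqrt(ff.mass(i));
        for (int d = 0; d < 3; ++d) v(i, d) = c1 * v(i, d) + s * rng.norm();
      }
    } else if (gamma > 0) {
      v *= c1;
    }
    // A
    coords += (0.5 * dt) * v;
    // B
    e = energy_forces(ff, coords, f);
    eb = bias_energy_forces(bias, coords, t0 + step * dt, f);
    v += (0.5 * dt * KCAL_TO_AKMA) * (f.each_col() % invm);

    double etot = e.total() + eb;
    if (!std::isfinite(etot) || std::fabs(etot) > ceiling)
      stop("integration blew up at step %ld (t = %.4f ps): potential energy %g kcal/mol",
           step, t0 + step * dt, etot);
    record(step);
  }

  return List::create(
    _["frame_times"] = arma::vec(ftimes.head(fi)),
    _["frames"] = arma::cube(frames.slices(0, fi - 1)),
    _["energies"] = arma::vec(energies.head(fi)),
    _["cv_times"] = (ncvrec > 0) ? wrap(arma::vec(cvtimes.head(ci))) : R_NilValue,
    _["cv_values"] = (ncvrec > 0) ? wrap(arma::mat(cvvals.cols(0, std::max(ci - 1, 0L)))) : R_NilValue,
    _["final_coords"] = coords, _["final_velocities"] = v);
}
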