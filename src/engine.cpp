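// Voxelized Monte Carlo photon transport: hop/drop/spin with a dimensionless
// pathlength budget consumed across voxels of differing mu_t, stochastic
// Fresnel reflection/refraction at faces where the refractive index changes,
// Russian roulette termination, and escape scoring on the anterior surface.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// 53-bit uniforms from a seeded Mersenne twister; we draw bits ourselves so
// the stream does not depend on the standard library's distribution objects.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // (0, 1] — safe for log()
  double unif_open() { return 1.0 - unif(); }
};

// Unpolarized Fresnel reflectance for incidence cosine ci in (0, 1].
// Writes the transmitted cosine through ct (0 under total internal reflection).
double fresnel_R(double ni, double nt, double ci, double *ct) {
  if (ni == nt) { *ct = ci; return 0.0; }
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) { *ct = 0.0; return 1.0; }  // total internal reflection
  double c2 = std::sqrt(1.0 - st * st);
  double rs = (ni * ci - nt * c2) / (ni * ci + nt * c2);
  double rp = (ni * c2 - nt * ci) / (ni * c2 + nt * ci);
  *ct = c2;
  return 0.5 * (rs * rs + rp * rp);
}

double hg_costheta(double g, double x1) {
  if (g == 0.0) return 2.0 * x1 - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * x1);
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate a unit direction by polar angle theta (cos sampled from HG) and
// uniform azimuth, in the local frame of the current direction (MCML update).
void spin_dir(double *u, double g, double x1, double x2) {
  double ct = hg_costheta(g, x1);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double psi = 2.0 * M_PI * x2;
  double cp = std::cos(psi), sp = std::sin(psi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = st * cp;
    u[1] = st * sp;
    u[2] = (uz >= 0.0 ? ct : -ct);
  } else {
    double d = std::sqrt(1.0 - uz * uz);
    u[0] = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    u[1] = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    u[2] = -st * cp * d + uz * ct;
  }
  double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

}  // namespace

//' Unpolarized Fresnel reflectance at a planar refractive-index interface
//'
//' @param n_i refractive index on the incidence side
//' @param n_t refractive index on the transmission side
//' @param cos_i cosine of the incidence angle, in (0, 1]
//' @return list with `R` (reflectance in \[0, 1\]) and `cos_t` (refracted
//'   cosine; 0 under total internal reflection)
//' @examples
//' fresnel_reflectance(1.0, 1.37, 1.0)$R  # air/skin normal incidence
//' @export
// [[Rcpp::export]]
List fresnel_reflectance(double n_i, double n_t, double cos_i) {
  if (!(cos_i > 0.0) || cos_i > 1.0 + 1e-12)
    stop("cos_i must be in (0, 1]");
  if (n_i < 1.0 || n_t < 1.0)
    stop("refractive indices must be >= 1");
  double ct;
  double R = fresnel_R(n_i, n_t, cos_i, &ct);
  return List::create(_["R"] = R, _["cos_t"] = ct);
}

//' Henyey–Greenstein direction update (single scattering event)
//'
//' Deflects a unit direction vector by a polar angle whose cosine is drawn
//' from the Henyey–Greenstein phase function with anisotropy `g`, and a
//' uniform azimuth, using the two supplied uniform deviates.
//'
//' @param direction unit 3-vector
//' @param g scattering anisotropy, |g| < 1 (g = 0 gives isotropic scattering)
//' @param xi1,xi2 uniform deviates in \[0, 1)
//' @return the new unit direction (numeric 3-vector)
//' @export
// [[Rcpp::export]]
NumericVector spin_direction(NumericVector direction, double g,
                             double xi1, double xi2) {
  if (direction.size() != 3) stop("direction must have length 3");
  if (std::fabs(g) >= 1.0) stop("|g| must be < 1");
  double u[3] = {direction[0], direction[1], direction[2]};
  double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (std::fabs(nrm - 1.0) > 1e-6) stop("direction must be a unit vector");
  spin_dir(u, g, xi1, xi2);
  return NumericVector::create(u[0], u[1], u[2]);
}

//' Sample Henyey–Greenstein deflection cosines
//'
//' Draws `n` values of cos(theta) from the Henyey–Greenstein phase function;
//' their expectation is `g`. Used for statistical validation of the sampler.
//'
//' @param n number of draws
//' @param g anisotropy, |g| < 1
//' @param seed integer seed for the generator
//' @return numeric vector of length `n`
//' @export
// [[Rcpp::export]]
NumericVector sample_hg_costheta(int n, double g, int seed) {
  if (std::fabs(g) >= 1.0) stop("|g| must be < 1");
  if (n < 1) stop("n must be positive");
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_costheta(g, rng.unif());
  return out;
}

// 2D binary erosion with the 3x3 (8-neighbour) structuring element, applied
// `iters` times. Used to carve the fixed-width skin border off a tissue mask.
// [[Rcpp::export]]
LogicalMatrix erode_mask(LogicalMatrix mask, int iters) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iters; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        bool keep = cur(i, j);
        if (keep) {
          for (int dj = -1; dj <= 1 && keep; ++dj) {
            for (int di = -1; di <= 1 && keep; ++di) {
              int ii = i + di, jj = j + dj;
              if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) keep = false;
              else if (!cur(ii, jj)) keep = false;
            }
          }
        }
        nxt(i, j) = keep;
      }
    }
    cur = nxt;
  }
  return cur;
}

// The transport engine. Photons are given explicit launch positions,
// directions and initial weights; excitation runs launch from above the
// medium (ambient label 0) and emission runs launch inside the cancer.
//
// labels: integer vector with dim (nx, ny, nz); 0 = ambient, 1..4 = tissue.
// props:  (n_label x 4) matrix, columns mu_a, mu_s, g, n; row r = label r.
// Escape events from tissue into ambient with direction z < 0 are binned by
// (x, y) voxel column into `surface`. The ledger closes exactly:
// launched = absorbed + escaped + roulette_killed, where roulette_killed is
// the NET weight retired by the roulette game (deaths minus the survival
// top-ups that multiply a surviving photon's weight by m); the gross
// components are reported separately.
// [[Rcpp::export]]
List mc_transport(IntegerVector labels, NumericMatrix props, double voxel_cm,
                  NumericMatrix pos0, NumericMatrix dir0, NumericVector w0,
                  bool specular_launch, double weight_threshold,
                  int roulette_m, double max_events, int seed) {
  IntegerVector dims = labels.attr("dim");
  if (dims.size() != 3) stop("labels must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h = voxel_cm;
  if (!(h > 0)) stop("voxel_cm must be positive");
  const int n_labels = props.nrow();
  if (props.ncol() != 4) stop("props must have columns mu_a, mu_s, g, n");
  const int N = pos0.nrow();
  if (dir0.nrow() != N || w0.size() != N) stop("photon arrays disagree");
  if (!(weight_threshold > 0 && weight_threshold < 1))
    stop("weight_threshold must be in (0, 1)");
  if (roulette_m < 2) stop("roulette_m must be >= 2");

  std::vector<double> mu_a(n_labels), mu_s(n_labels), gg(n_labels), nn(n_labels);
  for (int r = 0; r < n_labels; ++r) {
    mu_a[r] = props(r, 0); mu_s[r] = props(r, 1);
    gg[r] = props(r, 2);   nn[r] = props(r, 3);
  }

  NumericVector absorbed(nx * ny * nz);
  absorbed.attr("dim") = dims;
  NumericMatrix surface(nx, ny);

  double launched = 0.0, specular = 0.0, absorbed_tot = 0.0,
         escaped = 0.0, killed = 0.0, deaths = 0.0, gained = 0.0;
  long n_capped = 0;

  Rng rng(static_cast<uint64_t>(seed));

  for (int ph = 0; ph < N; ++ph) {
    double w = w0[ph];
    launched += w;
    if (w <= 0.0) continue;
    const double wth = weight_threshold * w;

    double p[3] = {pos0(ph, 0), pos0(ph, 1), pos0(ph, 2)};
    double u[3] = {dir0(ph, 0), dir0(ph, 1), dir0(ph, 2)};
    int ix = (int)std::floor(p[0] / h);
    int iy = (int)std::floor(p[1] / h);
    int iz = (int)std::floor(p[2] / h);
    // photons launched exactly on the upper grid face belong to slice 0
    if (iz == nz) iz = nz - 1;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      stop("photon launched outside the grid");

    bool entered = false;          // has crossed into tissue yet
    bool alive = true;
    double sbar = -std::log(rng.unif_open());
    double ev = 0.0;

    // A photon launched directly inside tissue with specular accounting on
    // (flat-surface launch where the first voxel is already tissue).
    {
      int lab = labels[ix + nx * (iy + (size_t)ny * iz)];
      if (lab > 0) {
        if (specular_launch) {
          double ct;
          double R = fresnel_R(1.0, nn[lab], std::fabs(u[2]), &ct);
          specular += w * R;
          escaped += w * R;
          w *= (1.0 - R);
        }
        entered = true;
      }
    }

    while (alive) {
      if (++ev > max_events) { killed += w; ++n_capped; break; }
      const size_t vidx = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
      const int lab = labels[vidx];
      const double mut = mu_a[lab] + mu_s[lab];

      // distance to the nearest voxel face along the direction of travel
      int axis = -1;
      double dmin = R_PosInf;
      for (int k = 0; k < 3; ++k) {
        if (u[k] == 0.0) continue;
        int idx = (k == 0 ? ix : (k == 1 ? iy : iz));
        double face = (u[k] > 0.0 ? (idx + 1) * h : idx * h);
        double pk = p[k];
        double d = (face - pk) / u[k];
        if (d < 0.0) d = 0.0;
        if (d < dmin) { dmin = d; axis = k; }
      }
      if (axis < 0) stop("degenerate direction vector");

      if (mut > 0.0 && mut * dmin > sbar) {
        // interaction inside this voxel: hop, drop, spin
        double s = sbar / mut;
        p[0] += u[0] * s; p[1] += u[1] * s; p[2] += u[2] * s;
        double dw = w * mu_a[lab] / mut;
        absorbed[vidx] += dw;
        absorbed_tot += dw;
        w -= dw;
        spin_dir(u, gg[lab], rng.unif(), rng.unif());
        if (w < wth) {
          if (rng.unif() < 1.0 / roulette_m) {
            gained += (roulette_m - 1) * w;
            killed -= (roulette_m - 1) * w;
            w *= roulette_m;
          } else {
            deaths += w;
            killed += w;
            alive = false;
            continue;
          }
        }
        sbar = -std::log(rng.unif_open());
      } else {
        // advance to the face; consume optical pathlength on the way
        if (mut > 0.0) sbar -= mut * dmin;
        p[0] += u[0] * dmin; p[1] += u[1] * dmin; p[2] += u[2] * dmin;
        // snap the crossed coordinate onto the face to stop roundoff drift
        int jx = ix, jy = iy, jz = iz;
        const int sgn = (u[axis] > 0.0 ? 1 : -1);
        if (axis == 0)      { p[0] = (sgn > 0 ? ix + 1 : ix) * h; jx += sgn; }
        else if (axis == 1) { p[1] = (sgn > 0 ? iy + 1 : iy) * h; jy += sgn; }
        else                { p[2] = (sgn > 0 ? iz + 1 : iz) * h; jz += sgn; }

        const bool in_grid = (jx >= 0 && jx < nx && jy >= 0 && jy < ny &&
                              jz >= 0 && jz < nz);
        const int nlab = in_grid
          ? labels[(size_t)jx + (size_t)nx * ((size_t)jy + (size_t)ny * jz)]
          : 0;

        const double ni = nn[lab], nt = (in_grid ? nn[nlab] : 1.0);
        bool crossed = true;
        if (ni != nt) {
          double ci = std::fabs(u[axis]);
          double ct;
          double R = fresnel_R(ni, nt, ci, &ct);
          if (lab == 0 && nlab > 0 && !entered && specular_launch) {
            // first air->tissue entry: deterministic specular deduction
            specular += w * R;
            escaped += w * R;
            w *= (1.0 - R);
            // refract into the tissue
            double ratio = ni / nt;
            for (int k = 0; k < 3; ++k) if (k != axis) u[k] *= ratio;
            u[axis] = (sgn > 0 ? ct : -ct);
          } else if (rng.unif() < R) {
            u[axis] = -u[axis];      // internal reflection; stay in voxel
            crossed = false;
          } else {
            double ratio = ni / nt;  // Snell refraction across the face
            for (int k = 0; k < 3; ++k) if (k != axis) u[k] *= ratio;
            u[axis] = (sgn > 0 ? ct : -ct);
          }
          if (crossed) {
            double nrm = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
            u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
          }
        }

        if (crossed) {
          if (lab > 0 && (!in_grid || nlab == 0)) {
            // tissue -> ambient: the photon escapes the medium
            escaped += w;
            if (u[2] < 0.0) {
              int bx = ix < 0 ? 0 : (ix >= nx ? nx - 1 : ix);
              int by = iy < 0 ? 0 : (iy >= ny ? ny - 1 : iy);
              surface(bx, by) += w;
            }
            alive = false;
            continue;
          }
          if (!in_grid) {            // ambient photon leaves the grid
            escaped += w;
            alive = false;
            continue;
          }
          ix = jx; iy = jy; iz = jz;
          if (nlab > 0) entered = true;
        }
      }
    }
  }

  List ledger = List::create(
    _["launched"] = launched,
    _["specular"] = specular,
    _["absorbed"] = absorbed_tot,
    _["escaped"] = escaped,
    _["roulette_killed"] = killed,
    _["roulette_deaths"] = deaths,
    _["roulette_gained"] = gained,
    _["n_capped"] = (double)n_capped,
    _["n_photons"] = (double)N);
  return List::create(_["absorbed"] = absorbed,
                      _["surface"] = surface,
                      _["ledger"] = ledger);
}
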