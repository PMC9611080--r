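// Weighted-packet Monte Carlo photon transport on a labelled voxel grid.
//
// MCML-style hop-drop-spin extended to fully 3D voxelated geometry:
// the dimensionless step is consumed voxel by voxel (mu_t * segment length),
// Fresnel reflection/refraction is evaluated at every axis-aligned voxel
// face where the refractive index changes, lateral (x, y) grid limits are
// mirrors, and packets leaving through the z faces are binned into
// reflectance (backward) or transmittance (forward) images at the (x, y)
// pixel of exit.  Each packet owns an independent, reproducibly seeded
// PCG32 stream, so results are bit-identical for a fixed seed.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state = 0, inc = 1;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31u));
  }
  // strictly inside (0, 1)
  double uniform() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Henyey-Greenstein polar cosine from an inverse-CDF draw.
inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate the direction (ux,uy,uz) by polar angle (ct) and azimuth phi.
inline void spin(double ct, double phi, double& ux, double& uy, double& uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = (uz >= 0 ? 1.0 : -1.0) * ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

// Unpolarized Fresnel reflectance; cost receives the refracted cosine.
inline double fresnelR(double ni, double nt, double cosi, double& cost) {
  if (ni == nt) { cost = cosi; return 0.0; }
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (ni / nt) * (ni / nt) * sini2;
  if (sint2 >= 1.0) { cost = 0.0; return 1.0; }  // total internal reflection
  cost = std::sqrt(1.0 - sint2);
  double rs = (ni * cosi - nt * cost) / (ni * cosi + nt * cost);
  double rp = (ni * cost - nt * cosi) / (ni * cost + nt * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export]]
double cpp_sample_step(double mu_t, double u) {
  if (mu_t <= 0.0) return R_PosInf;  // ballistic to boundary
  return -std::log(u) / mu_t;
}

// [[Rcpp::export]]
NumericVector cpp_scatter_hg(NumericVector dir, double g, double u1, double u2) {
  double ux = dir[0], uy = dir[1], uz = dir[2];
  spin(hg_cos(g, u1), 2.0 * M_PI * u2, ux, uy, uz);
  return NumericVector::create(ux, uy, uz);
}

// [[Rcpp::export]]
List cpp_fresnel(double n_i, double n_t, double cos_theta_i) {
  double cost;
  double R = fresnelR(n_i, n_t, cos_theta_i, cost);
  return List::create(_["R"] = R, _["cos_theta_t"] = cost,
                      _["tir"] = (R >= 1.0 && n_i != n_t));
}

// [[Rcpp::export]]
double cpp_roulette(double w, double w_th, double m, double u) {
  if (w >= w_th) return w;
  return (u < 1.0 / m) ? w * m : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_launch(int n, double width, double height, double seed) {
  NumericMatrix out(n, 3);
  uint64_t base = splitmix64((uint64_t)seed);
  for (int i = 0; i < n; ++i) {
    Pcg32 rng;
    rng.seed(splitmix64(base ^ (uint64_t)i * 0xA24BAED4963EE407ULL), (uint64_t)i);
    out(i, 0) = rng.uniform() * width;
    out(i, 1) = rng.uniform() * height;
    out(i, 2) = 1.0;  // packet weight is one
  }
  return out;
}

// Geometry-only traversal: walk voxel faces along `dir`, consuming
// mu_t * segment length until the dimensionless step is spent (interaction)
// or the packet exits through a z face; lateral limits mirror the direction.
// Refractive indices are not consulted here (the full engine layers Fresnel
// events on the same walk).
// [[Rcpp::export]]
List cpp_traverse(IntegerVector labels, IntegerVector dims, NumericVector pitch,
                  NumericVector mu_t_by_label, NumericVector pos,
                  NumericVector dir, double step) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = pitch[0], hy = pitch[1], hz = pitch[2];
  double x = pos[0], y = pos[1], z = pos[2];
  double ux = dir[0], uy = dir[1], uz = dir[2];
  double s = step, travelled = 0.0;
  int ix = std::min(nx - 1, std::max(0, (int)std::floor(x / hx)));
  int iy = std::min(ny - 1, std::max(0, (int)std::floor(y / hy)));
  int iz = std::min(nz - 1, std::max(0, (int)std::floor(z / hz)));
  std::string event = "interaction";
  for (int guard = 0; guard < 100000000; ++guard) {
    double mu_t = mu_t_by_label[labels[ix + nx * (iy + (R_xlen_t)ny * iz)]];
    double tx = ux > 0 ? ((ix + 1) * hx - x) / ux : (ux < 0 ? (ix * hx - x) / ux : R_PosInf);
    double ty = uy > 0 ? ((iy + 1) * hy - y) / uy : (uy < 0 ? (iy * hy - y) / uy : R_PosInf);
    double tz = uz > 0 ? ((iz + 1) * hz - z) / uz : (uz < 0 ? (iz * hz - z) / uz : R_PosInf);
    int axis = 0; double t = tx;
    if (ty < t) { t = ty; axis = 1; }
    if (tz < t) { t = tz; axis = 2; }
    if (t < 0) t = 0;
    if (mu_t > 0 && s <= mu_t * t) {
      double d = s / mu_t;
      x += ux * d; y += uy * d; z += uz * d;
      travelled += d; s = 0;
      event = "interaction";
      break;
    }
    x += ux * t; y += uy * t; z += uz * t;
    travelled += t;
    if (mu_t > 0) s -= mu_t * t;
    if (axis == 0) {
      int ni = ix + (ux > 0 ? 1 : -1);
      x = (ux > 0 ? (ix + 1) : ix) * hx;
      if (ni < 0 || ni >= nx) { ux = -ux; continue; }  // mirror
      ix = ni;
    } else if (axis == 1) {
      int ni = iy + (uy > 0 ? 1 : -1);
      y = (uy > 0 ? (iy + 1) : iy) * hy;
      if (ni < 0 || ni >= ny) { uy = -uy; continue; }  // mirror
      iy = ni;
    } else {
      int ni = iz + (uz > 0 ? 1 : -1);
      z = (uz > 0 ? (iz + 1) : iz) * hz;
      if (ni < 0) { event = "exit_backward"; break; }
      if (ni >= nz) { event = "exit_forward"; break; }
      iz = ni;
    }
  }
  return List::create(
    _["event"] = event,
    _["pos"] = NumericVector::create(x, y, z),
    _["dir"] = NumericVector::create(ux, uy, uz),
    _["voxel"] = IntegerVector::create(ix, iy, iz),
    _["distance"] = travelled,
    _["step_left"] = s);
}

// Full simulation at one wavelength.  props has one row per label id
// (row index = id, starting at 0 = ambient) and columns mu_a, mu_s, g, n
// in mm^-1 / dimensionless.  `stream` decorrelates wavelength substreams.
// [[Rcpp::export]]
List cpp_run_mc(IntegerVector labels, IntegerVector dims, NumericVector pitch,
                NumericMatrix props, double n_photons, double seed,
                double stream, double w_th, double m_roulette,
                bool record_absorption) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = pitch[0], hy = pitch[1], hz = pitch[2];
  double Lx = nx * hx, Ly = ny * hy;
  int nlab = props.nrow();
  std::vector<double> mu_a(nlab), mu_s(nlab), mu_t(nlab), gg(nlab), nn(nlab);
  for (int i = 0; i < nlab; ++i) {
    mu_a[i] = props(i, 0); mu_s[i] = props(i, 1);
    mu_t[i] = mu_a[i] + mu_s[i];
    gg[i] = props(i, 2); nn[i] = props(i, 3);
  }
  NumericMatrix Rimg(nx, ny), Timg(nx, ny);
  NumericVector Avox;
  double* Aptr = nullptr;
  if (record_absorption) {
    Avox = NumericVector((R_xlen_t)nx * ny * nz);
    Aptr = REAL(Avox);
  }
  double Rtot = 0, Ttot = 0, Atot = 0, lost = 0;
  uint64_t base = splitmix64((uint64_t)seed) ^
                  splitmix64(0x94D049BB133111EBULL * (uint64_t)(stream + 1));
  long long N = (long long)n_photons;
  for (long long ph = 0; ph < N; ++ph) {
    Pcg32 rng;
    rng.seed(splitmix64(base ^ (uint64_t)ph * 0xA24BAED4963EE407ULL), (uint64_t)ph);
    double x = rng.uniform() * Lx, y = rng.uniform() * Ly, z = 0.0;
    double ux = 0, uy = 0, uz = 1, w = 1.0;
    int ix = std::min(nx - 1, (int)(x / hx));
    int iy = std::min(ny - 1, (int)(y / hy));
    int iz = 0;
    // entry face: ambient (n = 1) -> first voxel
    {
      double n2 = nn[labels[ix + (R_xlen_t)nx * iy]];
      double cost;
      double R = fresnelR(1.0, n2, 1.0, cost);
      if (rng.uniform() < R) { Rimg(ix, iy) += w; Rtot += w; continue; }
    }
    double s = -std::log(rng.uniform());
    bool alive = true;
    long long guard = 0;
    while (alive) {
      if (++guard > 50000000LL) { lost += w; break; }  // pathological orbit
      R_xlen_t vi = ix + nx * (iy + (R_xlen_t)ny * iz);
      int lab = labels[vi];
      double mt = mu_t[lab];
      double tx = ux > 0 ? ((ix + 1) * hx - x) / ux : (ux < 0 ? (ix * hx - x) / ux : R_PosInf);
      double ty = uy > 0 ? ((iy + 1) * hy - y) / uy : (uy < 0 ? (iy * hy - y) / uy : R_PosInf);
      double tz = uz > 0 ? ((iz + 1) * hz - z) / uz : (uz < 0 ? (iz * hz - z) / uz : R_PosInf);
      int axis = 0; double t = tx;
      if (ty < t) { t = ty; axis = 1; }
      if (tz < t) { t = tz; axis = 2; }
      if (t < 0) t = 0;
      if (mt > 0 && s <= mt * t) {
        // hop to the interaction site, drop, roulette, spin
        double d = s / mt;
        x += ux * d; y += uy * d; z += uz * d;
        double dw = w * mu_a[lab] / mt;
        if (dw > 0) {
          Atot += dw;
          if (Aptr) Aptr[vi] += dw;
          w -= dw;
        }
        if (w < w_th) {
          if (rng.uniform() < 1.0 / m_roulette) w *= m_roulette;
          else { alive = false; break; }
        }
        spin(hg_cos(gg[lab], rng.uniform()), 2.0 * M_PI * rng.uniform(),
             ux, uy, uz);
        s = -std::log(rng.uniform());
        continue;
      }
      // advance to the face
      x += ux * t; y += uy * t; z += uz * t;
      if (mt > 0) s -= mt * t;
      int stepdir, ni;
      if (axis == 0) {
        stepdir = ux > 0 ? 1 : -1;
        x = (stepdir > 0 ? (ix + 1) : ix) * hx;
        ni = ix + stepdir;
        if (ni < 0 || ni >= nx) { ux = -ux; continue; }  // lateral mirror
      } else if (axis == 1) {
        stepdir = uy > 0 ? 1 : -1;
        y = (stepdir > 0 ? (iy + 1) : iy) * hy;
        ni = iy + stepdir;
        if (ni < 0 || ni >= ny) { uy = -uy; continue; }  // lateral mirror
      } else {
        stepdir = uz > 0 ? 1 : -1;
        z = (stepdir > 0 ? (iz + 1) : iz) * hz;
        ni = iz + stepdir;
      }
      bool exiting = (axis == 2) && (ni < 0 || ni >= nz);
      double n1 = nn[lab];
      double n2;
      if (exiting) n2 = 1.0;  // ambient beyond the z faces
      else {
        R_xlen_t vj;
        if (axis == 0)      vj = ni + nx * (iy + (R_xlen_t)ny * iz);
        else if (axis == 1) vj = ix + nx * (ni + (R_xlen_t)ny * iz);
        else                vj = ix + nx * (iy + (R_xlen_t)ny * ni);
        n2 = nn[labels[vj]];
      }
      if (n1 != n2) {
        double cosi = (axis == 0 ? std::fabs(ux) : axis == 1 ? std::fabs(uy)
                                                             : std::fabs(uz));
        if (cosi < 1e-12) {  // grazing: treat as pure reflection
          if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
          continue;
        }
        double cost;
        double R = fresnelR(n1, n2, cosi, cost);
        if (rng.uniform() < R) {
          if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
          continue;
        }
        // Snell refraction across the axis-aligned face
        double ratio = n1 / n2;
        if (axis == 0) {
          uy *= ratio; uz *= ratio; ux = (ux > 0 ? cost : -cost);
        } else if (axis == 1) {
          ux *= ratio; uz *= ratio; uy = (uy > 0 ? cost : -cost);
        } else {
          ux *= ratio; uy *= ratio; uz = (uz > 0 ? cost : -cost);
        }
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
      }
      if (exiting) {
        if (stepdir > 0) { Timg(ix, iy) += w; Ttot += w; }
        else             { Rimg(ix, iy) += w; Rtot += w; }
        alive = false;
      } else {
        if (axis == 0) ix = ni; else if (axis == 1) iy = ni; else iz = ni;
      }
    }
  }
  double inv = 1.0 / (double)N;
  std::transform(Rimg.begin(), Rimg.end(), Rimg.begin(),
                 [inv](double v) { return v * inv; });
  std::transform(Timg.begin(), Timg.end(), Timg.begin(),
                 [inv](double v) { return v * inv; });
  List out = List::create(
    _["reflectance"] = Rimg, _["transmittance"] = Timg,
    _["R_total"] = Rtot * inv, _["T_total"] = Ttot * inv,
    _["A_total"] = Atot * inv, _["lost"] = lost * inv);
  if (record_absorption) {
    std::transform(Avox.begin(), Avox.end(), Avox.begin(),
                   [inv](double v) { return v * inv; });
    Avox.attr("dim") = dims;
    out["absorbed"] = Avox;
  }
  return out;
}
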