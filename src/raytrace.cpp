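#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Unpolarised Fresnel reflectance and transmitted cosine for an interface
// hit with incidence cosine cos_i (>0), refractive indices n1 -> n2.
// Returns reflectance; cos_t is set unless total internal reflection.
static inline double fresnel_unpol(double cos_i, double n1, double n2,
                                   double &cos_t, bool &tir) {
  double sin_i2 = 1.0 - cos_i * cos_i;
  double eta = n1 / n2;
  double sin_t2 = eta * eta * sin_i2;
  if (sin_t2 >= 1.0) { tir = true; cos_t = 0.0; return 1.0; }
  tir = false;
  cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Monte-Carlo voxel ray tracer.  Labelled volume dims = (nx, ny, nz),
// column-major; x and y periodic, light enters through z = 0 (adaxial).
// n_by_label / k_by_label map label -> refractive index / absorption
// coefficient (per micrometre).  Weights absorbed in each voxel are
// accumulated as fractions of the incident flux.
// [[Rcpp::export]]
List trace_rays_cpp(IntegerVector label, IntegerVector dims, double h,
                    NumericVector n_by_label, NumericVector k_by_label,
                    int n_rays, int seed, NumericVector dir0,
                    double diffuse_fraction, int n_batches,
                    double roulette_threshold, int max_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double lx = nx * h, ly = ny * h;
  NumericVector absorbed((R_xlen_t)nx * ny * nz);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  if (n_batches < 1) n_batches = 1;
  std::vector<double> bR(n_batches, 0.0), bT(n_batches, 0.0),
      bA(n_batches, 0.0), bL(n_batches, 0.0);
  std::vector<int> bn(n_batches, 0);

  for (int r = 0; r < n_rays; ++r) {
    int batch = (int)(((long long)r * n_batches) / n_rays);
    bn[batch]++;
    double px = unif(rng) * lx;
    double py = unif(rng) * ly;
    double pz = 0.0;
    double dx, dy, dz;
    if (unif(rng) < diffuse_fraction) {
      double u1 = unif(rng), u2 = unif(rng);
      double st = std::sqrt(1.0 - u1);
      dz = std::sqrt(u1);
      dx = st * std::cos(2.0 * M_PI * u2);
      dy = st * std::sin(2.0 * M_PI * u2);
    } else {
      dx = dir0[0]; dy = dir0[1]; dz = dir0[2];
    }
    double w = 1.0;
    // entry interface: outside air (n = 1) -> top voxel medium
    {
      int ix0 = (int)(px / h); if (ix0 >= nx) ix0 = nx - 1;
      int iy0 = (int)(py / h); if (iy0 >= ny) iy0 = ny - 1;
      double n2 = n_by_label[label[ix0 + (R_xlen_t)nx * iy0]];
      double cos_t; bool tir;
      double R = fresnel_unpol(dz, 1.0, n2, cos_t, tir);
      if (unif(rng) < R) { bR[batch] += w; continue; }
      double eta = 1.0 / n2;
      dx *= eta; dy *= eta; dz = cos_t;
      double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= nrm; dy /= nrm; dz /= nrm;
    }
    int ix = (int)(px / h); if (ix >= nx) ix = nx - 1;
    int iy = (int)(py / h); if (iy >= ny) iy = ny - 1;
    int iz = 0;
    bool alive = true;
    int events = 0;
    while (alive) {
      R_xlen_t vi = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      int lab = label[vi];
      double nv = n_by_label[lab];
      double kv = k_by_label[lab];
      // distance to each voxel face along the ray
      double tx = (dx > 1e-15) ? ((ix + 1) * h - px) / dx
                : (dx < -1e-15 ? (ix * h - px) / dx : 1e30);
      double ty = (dy > 1e-15) ? ((iy + 1) * h - py) / dy
                : (dy < -1e-15 ? (iy * h - py) / dy : 1e30);
      double tz = (dz > 1e-15) ? ((iz + 1) * h - pz) / dz
                : (dz < -1e-15 ? (iz * h - pz) / dz : 1e30);
      int axis = 0; double t = tx;
      if (ty < t) { t = ty; axis = 1; }
      if (tz < t) { t = tz; axis = 2; }
      if (t < 0) t = 0;
      if (kv > 0 && t > 0) {
        double f = std::exp(-kv * t);
        absorbed[vi] += w * (1.0 - f);
        bA[batch] += w * (1.0 - f);
        w *= f;
      }
      px += dx * t; py += dy * t; pz += dz * t;
      // Russian roulette on low weight
      if (w < roulette_threshold) {
        if (unif(rng) < 0.1) { w /= 0.1; }
        else { alive = false; break; }
      }
      // determine neighbour voxel across the crossed face
      int jx = ix, jy = iy, jz = iz;
      double sgn = 1.0;
      if (axis == 0) { sgn = (dx > 0) ? 1.0 : -1.0; jx += (dx > 0) ? 1 : -1; }
      else if (axis == 1) { sgn = (dy > 0) ? 1.0 : -1.0; jy += (dy > 0) ? 1 : -1; }
      else { sgn = (dz > 0) ? 1.0 : -1.0; jz += (dz > 0) ? 1 : -1; }
      // leaf surfaces
      if (axis == 2 && (jz < 0 || jz >= nz)) {
        // interface leaf medium -> outside air before escaping
        double cos_i = std::fabs(dz);
        double cos_t; bool tir;
        double R = fresnel_unpol(cos_i, nv, 1.0, cos_t, tir);
        if (unif(rng) < R) {
          dz = -dz;
          pz += dz * 1e-9;
          if (++events > max_events) { bL[batch] += w; alive = false; }
          continue;
        }
        if (jz < 0) bR[batch] += w; else bT[batch] += w;
        alive = false;
        break;
      }
      // periodic wrap in x and y
      if (jx < 0) { jx = nx - 1; px += lx; }
      else if (jx >= nx) { jx = 0; px -= lx; }
      if (jy < 0) { jy = ny - 1; py += ly; }
      else if (jy >= ny) { jy = 0; py -= ly; }
      R_xlen_t vj = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
      double n2 = n_by_label[label[vj]];
      if (n2 != nv) {
        double cos_i = (axis == 0) ? std::fabs(dx)
                     : (axis == 1) ? std::fabs(dy) : std::fabs(dz);
        double cos_t; bool tir;
        double R = fresnel_unpol(cos_i, nv, n2, cos_t, tir);
        if (unif(rng) < R) {
          // reflect: flip the crossing component, stay in current voxel
          if (axis == 0) dx = -dx; else if (axis == 1) dy = -dy; else dz = -dz;
        } else {
          // refract: scale tangential components, set normal component
          double eta = nv / n2;
          if (axis == 0) { dy *= eta; dz *= eta; dx = sgn * cos_t; }
          else if (axis == 1) { dx *= eta; dz *= eta; dy = sgn * cos_t; }
          else { dx *= eta; dy *= eta; dz = sgn * cos_t; }
          double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
          dx /= nrm; dy /= nrm; dz /= nrm;
          ix = jx; iy = jy; iz = jz;
        }
        if (++events > max_events) { bL[batch] += w; alive = false; }
      } else {
        ix = jx; iy = jy; iz = jz;
      }
      // nudge off the face to avoid degenerate zero-length steps
      px += dx * 1e-9; py += dy * 1e-9; pz += dz * 1e-9;
      if (px < 0) px += lx; else if (px >= lx) px -= lx;
      if (py < 0) py += ly; else if (py >= ly) py -= ly;
    }
  }

  // totals and batch standard errors
  double R = 0, T = 0, A = 0, L = 0;
  for (int b = 0; b < n_batches; ++b) { R += bR[b]; T += bT[b]; A += bA[b]; L += bL[b]; }
  R /= n_rays; T /= n_rays; A /= n_rays; L /= n_rays;
  auto se_of = [&](std::vector<double> &v) {
    double m = 0; int nb = 0;
    std::vector<double> fr(n_batches);
    for (int b = 0; b < n_batches; ++b) {
      if (bn[b] > 0) { fr[b] = v[b] / bn[b]; m += fr[b]; nb++; }
    }
    if (nb < 2) return 0.0;
    m /= nb;
    double s2 = 0;
    for (int b = 0; b < n_batches; ++b) if (bn[b] > 0) s2 += (fr[b] - m) * (fr[b] - m);
    s2 /= (nb - 1);
    return std::sqrt(s2 / nb);
  };
  for (R_xlen_t i = 0; i < absorbed.size(); ++i) absorbed[i] /= n_rays;
  return List::create(_["absorbed"] = absorbed,
                      _["reflected"] = R, _["transmitted"] = T,
                      _["absorbed_total"] = A, _["lost"] = L,
                      _["se_reflected"] = se_of(bR),
                      _["se_transmitted"] = se_of(bT),
                      _["se_absorbed"] = se_of(bA));
}
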