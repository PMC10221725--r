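// Ray-based Monte Carlo photon transport through a parallel-cylinder scene
// with a confocal launch and ABCD thin-lens / pinhole detection model.
//
// Units: positions in micrometres.  The lens plane sits at z = zf + 2f above
// the focus (xf, yf, zf); illumination travels towards -z.  Free flight is
// straight-line (volume scattering and absorption are zero by design);
// interfaces are specular dielectric boundaries with unpolarised Fresnel
// reflectance and stochastic branching (reflect with probability R, refract
// otherwise, weight 1).
//
// Randomness comes from a counter-based splitmix64 stream so that every
// pixel is reproducible in isolation and independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return z;
}

struct Rng {
  uint64_t base;
  uint64_t ctr;
  explicit Rng(uint64_t seed, uint64_t start = 0) : base(seed), ctr(start) {}
  double u() {
    uint64_t z = splitmix64(base + 0x9E3779B97F4A7C15ULL * (++ctr));
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
};

// [[Rcpp::export]]
NumericVector cpp_uniforms(double seed, double offset, int n) {
  Rng rng((uint64_t)(int64_t)seed, (uint64_t)offset);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.u();
  return out;
}

// [[Rcpp::export]]
double cpp_pixel_seed(double base_seed, int iy, int iz) {
  uint64_t h = splitmix64((uint64_t)(int64_t)base_seed);
  h = splitmix64(h ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(iy + 1)));
  h = splitmix64(h ^ (0xC2B2AE3D27D4EB4FULL * (uint64_t)(iz + 1)));
  // keep representable exactly as a double
  return (double)(h >> 12);
}

struct Scene {
  std::vector<double> cy, cz, r, n;
  double ns;
};

struct Optics {
  double r_lens;   // um
  double f;        // um
  double r_pin;    // um
};

// Nearest positive intersection of a ray with an infinite cylinder along x.
// Returns distance (> eps) or -1; outward normal via pointer.
static const double HIT_EPS = 1e-6;
static const double TANGENT_EPS = 1e-12;

static double ray_cylinder(double py, double pz, double dy, double dz,
                           double cy, double cz, double radius,
                           double* ny, double* nz) {
  double oy = py - cy, oz = pz - cz;
  double a = dy * dy + dz * dz;
  if (a <= 0) return -1.0;
  double b = oy * dy + oz * dz;
  double c = oy * oy + oz * oz - radius * radius;
  double disc = b * b - a * c;
  if (disc < TANGENT_EPS) return -1.0;   // miss or tangent tie-break
  double sq = std::sqrt(disc);
  double t = (-b - sq) / a;
  if (t <= HIT_EPS) t = (-b + sq) / a;
  if (t <= HIT_EPS) return -1.0;
  double hy = oy + t * dy, hz = oz + t * dz;
  double inv = 1.0 / std::sqrt(hy * hy + hz * hz);
  *ny = hy * inv; *nz = hz * inv;
  return t;
}

// [[Rcpp::export]]
List cpp_intersect_ray_cylinder(NumericVector origin, NumericVector dir,
                                double cy, double cz, double radius) {
  double ny, nz;
  double t = ray_cylinder(origin[1], origin[2], dir[1], dir[2],
                          cy, cz, radius, &ny, &nz);
  if (t < 0) return List::create(_["hit"] = false);
  NumericVector p = NumericVector::create(origin[0] + t * dir[0],
                                          origin[1] + t * dir[1],
                                          origin[2] + t * dir[2]);
  return List::create(_["hit"] = true, _["distance"] = t,
                      _["point"] = p,
                      _["normal"] = NumericVector::create(0.0, ny, nz));
}

// Unpolarised Fresnel reflectance; cos_i >= 0 against the interface normal.
static double fresnel_R(double cos_i, double n1, double n2) {
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - cos_i * cos_i);
  if (s2 >= 1.0) return 1.0;             // total internal reflection
  double cos_t = std::sqrt(1.0 - s2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
double cpp_fresnel_reflectance(double cos_i, double n1, double n2) {
  if (cos_i < 0 || cos_i > 1) stop("cos_i must lie in [0, 1]");
  return fresnel_R(cos_i, n1, n2);
}

struct Photon {
  double x, y, z;
  double dx, dy, dz;
  int inside;      // cylinder index or -1
  int n_events;
};

// Apply one Fresnel event in place.  n points against the incident ray.
static void fresnel_event(Photon& ph, double nx, double ny, double nz,
                          double n1, double n2, double u, bool* transmitted) {
  double cos_i = -(ph.dx * nx + ph.dy * ny + ph.dz * nz);
  double R = fresnel_R(cos_i, n1, n2);
  if (u < R) {
    ph.dx += 2.0 * cos_i * nx;
    ph.dy += 2.0 * cos_i * ny;
    ph.dz += 2.0 * cos_i * nz;
    *transmitted = false;
  } else {
    double eta = n1 / n2;
    double s2 = eta * eta * (1.0 - cos_i * cos_i);
    double cos_t = std::sqrt(1.0 - s2);
    ph.dx = eta * ph.dx + (eta * cos_i - cos_t) * nx;
    ph.dy = eta * ph.dy + (eta * cos_i - cos_t) * ny;
    ph.dz = eta * ph.dz + (eta * cos_i - cos_t) * nz;
    *transmitted = true;
  }
  double inv = 1.0 / std::sqrt(ph.dx * ph.dx + ph.dy * ph.dy + ph.dz * ph.dz);
  ph.dx *= inv; ph.dy *= inv; ph.dz *= inv;
  ph.n_events++;
}

// [[Rcpp::export]]
List cpp_fresnel_interact(NumericVector dir, NumericVector normal,
                          double n1, double n2, double u) {
  Photon ph{0, 0, 0, dir[0], dir[1], dir[2], -1, 0};
  bool trans;
  fresnel_event(ph, normal[0], normal[1], normal[2], n1, n2, u, &trans);
  return List::create(
    _["direction"] = NumericVector::create(ph.dx, ph.dy, ph.dz),
    _["transmitted"] = trans,
    _["reflectance"] = fresnel_R(-(dir[0] * normal[0] + dir[1] * normal[1] +
                                   dir[2] * normal[2]), n1, n2));
}

// Trace one photon.  Returns:
//  0 undetected, 1 detected.  Fills lens hit and pinhole position if the
//  photon reached the lens plane inside the aperture.
struct TraceResult {
  int status;          // 0 lost, 1 detected, 2 hit lens plane but missed pinhole
  double x1, y1;       // lens-plane hit (absolute um)
  double x2, y2;       // detection-plane position relative to axis
};

static TraceResult trace_photon(Photon ph, const Scene& sc, const Optics& op,
                                double xf, double yf, double zf,
                                int max_events, bool mode2d, Rng& rng,
                                std::vector<double>* path) {
  TraceResult res{0, NA_REAL, NA_REAL, NA_REAL, NA_REAL};
  double z_lens = zf + 2.0 * op.f;
  if (path) { path->push_back(ph.x); path->push_back(ph.y); path->push_back(ph.z); }
  while (ph.n_events <= max_events) {
    // nearest cylinder hit
    int best = -1; double tbest = 0, nyb = 0, nzb = 0;
    for (size_t i = 0; i < sc.r.size(); ++i) {
      double ny, nz;
      double t = ray_cylinder(ph.y, ph.z, ph.dy, ph.dz,
                              sc.cy[i], sc.cz[i], sc.r[i], &ny, &nz);
      if (t > 0 && (best < 0 || t < tbest)) { best = (int)i; tbest = t; nyb = ny; nzb = nz; }
    }
    double t_lens = (ph.dz > 0) ? (z_lens - ph.z) / ph.dz : -1.0;
    if (best >= 0 && (t_lens < 0 || tbest < t_lens)) {
      ph.x += tbest * ph.dx; ph.y += tbest * ph.dy; ph.z += tbest * ph.dz;
      if (path) { path->push_back(ph.x); path->push_back(ph.y); path->push_back(ph.z); }
      // orient normal against the ray; set media
      double nx = 0, ny = nyb, nz = nzb;
      double n1, n2; int other;
      if (ph.dy * ny + ph.dz * nz < 0) {        // entering cylinder `best`
        n1 = sc.ns; n2 = sc.n[best]; other = best;
      } else {                                   // leaving it
        ny = -ny; nz = -nz;
        n1 = sc.n[best]; n2 = sc.ns; other = -1;
      }
      bool trans;
      fresnel_event(ph, nx, ny, nz, n1, n2, rng.u(), &trans);
      if (trans) ph.inside = other;
      continue;
    }
    if (t_lens >= 0) {
      double x1 = ph.x + t_lens * ph.dx;
      double y1 = ph.y + t_lens * ph.dy;
      double px = x1 - xf, py = y1 - yf;
      bool in_aperture = mode2d ? std::fabs(py) <= op.r_lens
                                : (px * px + py * py) <= op.r_lens * op.r_lens;
      if (!in_aperture) return res;            // misses the aperture: lost
      if (path) { path->push_back(x1); path->push_back(y1); path->push_back(z_lens); }
      // ABCD thin lens + translation by 2f, per transverse axis:
      //   tan a2 = -p1/f + tan a1,  p2 = p1 + 2 f tan a2
      double tanx1 = ph.dx / ph.dz, tany1 = ph.dy / ph.dz;
      double tanx2 = -px / op.f + tanx1;
      double tany2 = -py / op.f + tany1;
      double x2 = px + 2.0 * op.f * tanx2;
      double y2 = py + 2.0 * op.f * tany2;
      res.x1 = x1; res.y1 = y1; res.x2 = x2; res.y2 = y2;
      bool det = mode2d ? std::fabs(y2) < op.r_pin
                        : (x2 * x2 + y2 * y2) < op.r_pin * op.r_pin;
      res.status = det ? 1 : 2;
      return res;
    }
    return res;                                 // travelling down, nothing ahead
  }
  return res;                                   // event cap reached
}

static Scene scene_from(NumericMatrix cylinders, double ns) {
  Scene sc; sc.ns = ns;
  for (int i = 0; i < cylinders.nrow(); ++i) {
    sc.cy.push_back(cylinders(i, 0));
    sc.cz.push_back(cylinders(i, 1));
    sc.r.push_back(cylinders(i, 2));
    sc.n.push_back(cylinders(i, 3));
  }
  return sc;
}

// Launch a photon from the lens towards the focus.
static Photon launch(const Optics& op, double xf, double yf, double zf,
                     bool mode2d, bool literal, Rng& rng) {
  double x0, y0, z0 = zf + 2.0 * op.f;
  if (mode2d) {
    x0 = xf;
    y0 = yf + op.r_lens * (2.0 * rng.u() - 1.0);
  } else {
    double u1 = rng.u(), u2 = rng.u();
    double r0 = literal ? op.r_lens * u1 : op.r_lens * std::sqrt(u1);
    double phi = 2.0 * M_PI * u2;
    x0 = xf + r0 * std::cos(phi);
    y0 = yf + r0 * std::sin(phi);
  }
  double dx = xf - x0, dy = yf - y0, dz = zf - z0;
  double inv = 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
  return Photon{x0, y0, z0, dx * inv, dy * inv, dz * inv, -1, 0};
}

// [[Rcpp::export]]
NumericMatrix cpp_launch_positions(int n, double r_lens, double seed,
                                   bool literal) {
  Rng rng((uint64_t)(int64_t)seed);
  Optics op{r_lens, 1.0, 1.0};
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Photon ph = launch(op, 0, 0, -2.0, false, literal, rng);
    out(i, 0) = ph.x; out(i, 1) = ph.y; out(i, 2) = ph.z;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_trace_photon(NumericVector start, NumericVector dir,
                      NumericMatrix cylinders, double ns,
                      double r_lens, double f_um, double r_pin,
                      NumericVector focal, int max_events, bool mode2d,
                      double seed, bool keep_path) {
  Scene sc = scene_from(cylinders, ns);
  Optics op{r_lens, f_um, r_pin};
  double inv = 1.0 / std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  Photon ph{start[0], start[1], start[2],
            dir[0]*inv, dir[1]*inv, dir[2]*inv, -1, 0};
  // classify the starting medium
  for (size_t i = 0; i < sc.r.size(); ++i) {
    double oy = ph.y - sc.cy[i], oz = ph.z - sc.cz[i];
    if (oy*oy + oz*oz < sc.r[i]*sc.r[i]) ph.inside = (int)i;
  }
  Rng rng((uint64_t)(int64_t)seed);
  std::vector<double> path;
  TraceResult res = trace_photon(ph, sc, op, focal[0], focal[1], focal[2],
                                 max_events, mode2d,
                                 rng, keep_path ? &path : nullptr);
  List out = List::create(
    _["detected"] = (res.status == 1),
    _["reached_lens"] = (res.status >= 1),
    _["lens_hit"] = NumericVector::create(res.x1, res.y1),
    _["pinhole_pos"] = NumericVector::create(res.x2, res.y2));
  if (keep_path) {
    int nv = (int)path.size() / 3;
    NumericMatrix pm(nv, 3);
    for (int i = 0; i < nv; ++i)
      for (int j = 0; j < 3; ++j) pm(i, j) = path[3 * i + j];
    out["path"] = pm;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_pixel(NumericMatrix cylinders, double ns,
                        double r_lens, double f_um, double r_pin,
                        NumericVector focal, int n_photons,
                        double seed, bool mode2d, bool literal_launch,
                        int max_events, int collect_paths) {
  Scene sc = scene_from(cylinders, ns);
  Optics op{r_lens, f_um, r_pin};
  Rng rng((uint64_t)(int64_t)seed);
  int detected = 0;
  List paths(0);
  std::vector<NumericMatrix> kept;
  for (int i = 0; i < n_photons; ++i) {
    Photon ph = launch(op, focal[0], focal[1], focal[2], mode2d,
                       literal_launch, rng);
    bool want_path = (collect_paths > (int)kept.size());
    std::vector<double> path;
    TraceResult res = trace_photon(ph, sc, op, focal[0], focal[1], focal[2],
                                   max_events, mode2d, rng,
                                   want_path ? &path : nullptr);
    if (res.status == 1) {
      ++detected;
      if (want_path) {
        int nv = (int)path.size() / 3;
        NumericMatrix pm(nv, 3);
        for (int k = 0; k < nv; ++k)
          for (int j = 0; j < 3; ++j) pm(k, j) = path[3 * k + j];
        kept.push_back(pm);
      }
    }
  }
  if (collect_paths > 0) {
    paths = List((int)kept.size());
    for (size_t i = 0; i < kept.size(); ++i) paths[i] = kept[i];
  }
  return List::create(_["detected"] = detected,
                      _["n_photons"] = n_photons,
                      _["fraction"] = (double)detected / n_photons,
                      _["paths"] = paths);
}
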