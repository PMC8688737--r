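// Monte Carlo kernels: rigid-body geometry, separating-axis overlap tests,
// hard-core + square-well + dipolar pair energies, and the NVT Metropolis
// sweep loop.  All energies are reduced (beta*u, dimensionless); all lengths
// are in units of the circumscribed-sphere diameter sigma_HS = 1.
//
// Randomness comes from R's own RNG (unif_rand), so a single set.seed() on
// the R side makes whole trajectories reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// model type codes (kept in sync with .model_code() on the R side)
enum ModelType { MODEL_IDEAL = 0, MODEL_HS = 1, MODEL_PM = 2, MODEL_HT = 3 };

struct Model {
  int type;
  double box;
  int nsites;                      // body-frame sites beyond the center
  std::vector<double> soff;        // nsites x 3 body-frame offsets, row-major
  // primitive-model parameters (sigma_OO = 1)
  double dpp2, dnn2, rsw2, beta_eps, site_range2;
  // hard tetrahedron: insphere contact (sigma/3)^2
  double in2;
  // dipole handling
  int dmode;                       // 0 none, 1 screened, 2 full
  double epsq, rf_coef, rc, rc2, rc3, rlo, rhi;
  double rf_over_rc3, rlo2, rhi2;  // hoisted constants for the hot loop
  int iqp, iqm;                    // row indices (0-based) of +/- charges, -1 if none
};

static Model parse_model(const List &ml) {
  Model m;
  m.type = as<int>(ml["type"]);
  m.box = as<double>(ml["box"]);
  NumericMatrix s = ml["sites"];
  m.nsites = s.nrow();
  m.soff.resize((size_t)m.nsites * 3);
  for (int i = 0; i < m.nsites; ++i)
    for (int k = 0; k < 3; ++k) m.soff[(size_t)i * 3 + k] = s(i, k);
  m.dpp2 = as<double>(ml["dpp2"]);
  m.dnn2 = as<double>(ml["dnn2"]);
  m.rsw2 = as<double>(ml["rsw2"]);
  m.beta_eps = as<double>(ml["beta_eps"]);
  m.site_range2 = as<double>(ml["site_range2"]);
  m.in2 = 1.0 / 9.0;
  m.dmode = as<int>(ml["dmode"]);
  m.epsq = as<double>(ml["epsq"]);
  m.rf_coef = as<double>(ml["rf_coef"]);
  m.rc = as<double>(ml["rc"]);
  m.rc2 = m.rc * m.rc;
  m.rc3 = m.rc * m.rc * m.rc;
  m.rlo = as<double>(ml["rlo"]);
  m.rhi = as<double>(ml["rhi"]);
  m.rf_over_rc3 = m.rc3 > 0.0 ? m.rf_coef / m.rc3 : 0.0;
  m.rlo2 = m.rlo * m.rlo;
  m.rhi2 = m.rhi * m.rhi;
  m.iqp = as<int>(ml["iqp"]);
  m.iqm = as<int>(ml["iqm"]);
  return m;
}

static inline void min_image(double &x, double &y, double &z, double box) {
  if (!std::isfinite(box) || box <= 0) return;  // open (non-periodic) system
  double inv = 1.0 / box;
  x -= box * std::nearbyint(x * inv);
  y -= box * std::nearbyint(y * inv);
  z -= box * std::nearbyint(z * inv);
}

// rotate body-frame vector v by unit quaternion q = (w,x,y,z)
static inline void quat_rot(const double *q, const double *v, double *out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double tx = 2.0 * (y * v[2] - z * v[1]);
  double ty = 2.0 * (z * v[0] - x * v[2]);
  double tz = 2.0 * (x * v[1] - y * v[0]);
  out[0] = v[0] + w * tx + (y * tz - z * ty);
  out[1] = v[1] + w * ty + (z * tx - x * tz);
  out[2] = v[2] + w * tz + (x * ty - y * tx);
}

// Hamilton product a (x) b
static inline void quat_mul(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// ---------------------------------------------------------------------------
// separating-axis test for two congruent tetrahedra.
// va, vb: 4 lab-frame vertex offsets (row-major, relative to the own center);
// d: center separation (B - A).  Returns true when the solids intersect.
// ---------------------------------------------------------------------------
static bool sat_overlap_raw(const double *va, const double *vb, const double *d) {
  double A[4][3], B[4][3];
  for (int i = 0; i < 4; ++i)
    for (int k = 0; k < 3; ++k) {
      A[i][k] = va[i * 3 + k];
      B[i][k] = d[k] + vb[i * 3 + k];
    }
  // candidate axes: 4 + 4 face normals, then 6 x 6 edge-edge cross products
  static const int face[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  static const int edge[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  double axes[44][3];
  int na = 0;
  for (int f = 0; f < 4; ++f) {
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = A[face[f][1]][k] - A[face[f][0]][k];
      e2[k] = A[face[f][2]][k] - A[face[f][0]][k];
    }
    axes[na][0] = e1[1] * e2[2] - e1[2] * e2[1];
    axes[na][1] = e1[2] * e2[0] - e1[0] * e2[2];
    axes[na][2] = e1[0] * e2[1] - e1[1] * e2[0];
    ++na;
    for (int k = 0; k < 3; ++k) {
      e1[k] = B[face[f][1]][k] - B[face[f][0]][k];
      e2[k] = B[face[f][2]][k] - B[face[f][0]][k];
    }
    axes[na][0] = e1[1] * e2[2] - e1[2] * e2[1];
    axes[na][1] = e1[2] * e2[0] - e1[0] * e2[2];
    axes[na][2] = e1[0] * e2[1] - e1[1] * e2[0];
    ++na;
  }
  for (int ea = 0; ea < 6; ++ea) {
    double u[3];
    for (int k = 0; k < 3; ++k) u[k] = A[edge[ea][1]][k] - A[edge[ea][0]][k];
    for (int eb = 0; eb < 6; ++eb) {
      double v[3];
      for (int k = 0; k < 3; ++k) v[k] = B[edge[eb][1]][k] - B[edge[eb][0]][k];
      axes[na][0] = u[1] * v[2] - u[2] * v[1];
      axes[na][1] = u[2] * v[0] - u[0] * v[2];
      axes[na][2] = u[0] * v[1] - u[1] * v[0];
      ++na;
    }
  }
  for (int a = 0; a < na; ++a) {
    double n2 = axes[a][0] * axes[a][0] + axes[a][1] * axes[a][1] +
                axes[a][2] * axes[a][2];
    if (n2 < 1e-24) continue;  // parallel edges: degenerate axis, skip
    double loA = R_PosInf, hiA = R_NegInf, loB = R_PosInf, hiB = R_NegInf;
    for (int i = 0; i < 4; ++i) {
      double pa = A[i][0] * axes[a][0] + A[i][1] * axes[a][1] + A[i][2] * axes[a][2];
      double pb = B[i][0] * axes[a][0] + B[i][1] * axes[a][1] + B[i][2] * axes[a][2];
      if (pa < loA) loA = pa;
      if (pa > hiA) hiA = pa;
      if (pb < loB) loB = pb;
      if (pb > hiB) hiB = pb;
    }
    if (hiA < loB || hiB < loA) return false;  // separating axis found
  }
  return true;
}

static inline double switch_s(double r, double rlo, double rhi) {
  if (r <= rlo) return 0.0;
  if (r >= rhi) return 1.0;
  double w = rhi - rlo;
  double t = r - rlo;
  return t * t * (3.0 * rhi - rlo - 2.0 * r) / (w * w * w);
}

// ---------------------------------------------------------------------------
// pair energy between particles with centers ri, rj and cached lab-frame
// site offsets si, sj (nsites x 3 row-major).  Fills beta*u split into
// square-well (esw) and dipole-dipole (edd) parts.  Returns true on hard
// overlap (energies then undefined).
// ---------------------------------------------------------------------------
static bool pair_energy(const Model &m, const double *ri, const double *rj,
                        const double *si, const double *sj,
                        double &esw, double &edd) {
  esw = 0.0;
  edd = 0.0;
  if (m.type == MODEL_IDEAL) return false;
  double dx = rj[0] - ri[0], dy = rj[1] - ri[1], dz = rj[2] - ri[2];
  min_image(dx, dy, dz, m.box);
  double d2 = dx * dx + dy * dy + dz * dz;

  if (m.type == MODEL_HS || m.type == MODEL_PM) {
    if (d2 < 1.0) return true;  // O-O hard core, sigma_OO = 1
  } else if (m.type == MODEL_HT) {
    if (d2 < m.in2) return true;  // inside the insphere-contact bound
    if (d2 < 1.0) {
      double d[3] = {dx, dy, dz};
      if (sat_overlap_raw(si, sj, d)) return true;
    }
  }

  if (m.type == MODEL_PM && d2 < m.site_range2) {
    // sites: 0,1 = P (H-like), 2 = N (M-like); like pairs are hard,
    // unlike pairs carry the square well
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        double sx = dx + sj[b * 3] - si[a * 3];
        double sy = dy + sj[b * 3 + 1] - si[a * 3 + 1];
        double sz = dz + sj[b * 3 + 2] - si[a * 3 + 2];
        if (sx * sx + sy * sy + sz * sz < m.dpp2) return true;
      }
    {
      double sx = dx + sj[6] - si[6];
      double sy = dy + sj[7] - si[7];
      double sz = dz + sj[8] - si[8];
      if (sx * sx + sy * sy + sz * sz < m.dnn2) return true;
    }
    int nb = 0;
    for (int a = 0; a < 2; ++a) {  // P(i) - N(j)
      double sx = dx + sj[6] - si[a * 3];
      double sy = dy + sj[7] - si[a * 3 + 1];
      double sz = dz + sj[8] - si[a * 3 + 2];
      if (sx * sx + sy * sy + sz * sz < m.rsw2) ++nb;
    }
    for (int b = 0; b < 2; ++b) {  // N(i) - P(j)
      double sx = dx + sj[b * 3] - si[6];
      double sy = dy + sj[b * 3 + 1] - si[7];
      double sz = dz + sj[b * 3 + 2] - si[8];
      if (sx * sx + sy * sy + sz * sz < m.rsw2) ++nb;
    }
    esw = -m.beta_eps * nb;
  }

  if (m.dmode > 0 && d2 <= m.rc2) {
    // two +/- unit charges per molecule, reaction-field corrected; in
    // screened mode the switch factor is decided from d2 before any work
    double s = 1.0;
    if (m.dmode == 1) {
      if (d2 <= m.rlo2) return false;  // fully screened: edd stays 0
      if (d2 < m.rhi2) s = switch_s(std::sqrt(d2), m.rlo, m.rhi);
    }
    double e = 0.0;
    const int qi[2] = {m.iqp, m.iqm};
    const double qs[2] = {1.0, -1.0};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        double sx = dx + sj[qi[b] * 3] - si[qi[a] * 3];
        double sy = dy + sj[qi[b] * 3 + 1] - si[qi[a] * 3 + 1];
        double sz = dz + sj[qi[b] * 3 + 2] - si[qi[a] * 3 + 2];
        double r2 = sx * sx + sy * sy + sz * sz;
        e += qs[a] * qs[b] * (1.0 / std::sqrt(r2) + m.rf_over_rc3 * r2);
      }
    edd = e * m.epsq * s;
  }
  return false;
}

// lab-frame site offsets for all particles
static void build_offsets(const Model &m, const NumericMatrix &quat,
                          std::vector<double> &off) {
  int n = quat.nrow();
  off.assign((size_t)n * m.nsites * 3, 0.0);
  for (int i = 0; i < n; ++i) {
    double q[4] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
    for (int s = 0; s < m.nsites; ++s)
      quat_rot(q, &m.soff[(size_t)s * 3], &off[((size_t)i * m.nsites + s) * 3]);
  }
}

// [[Rcpp::export]]
bool cpp_sat_overlap(NumericVector rA, NumericVector qA, NumericVector rB,
                     NumericVector qB, NumericMatrix verts, double box) {
  double va[12], vb[12];
  double qa[4] = {qA[0], qA[1], qA[2], qA[3]};
  double qb[4] = {qB[0], qB[1], qB[2], qB[3]};
  for (int i = 0; i < 4; ++i) {
    double v[3] = {verts(i, 0), verts(i, 1), verts(i, 2)};
    quat_rot(qa, v, &va[i * 3]);
    quat_rot(qb, v, &vb[i * 3]);
  }
  double d[3] = {rB[0] - rA[0], rB[1] - rA[1], rB[2] - rA[2]};
  if (box > 0) min_image(d[0], d[1], d[2], box);
  return sat_overlap_raw(va, vb, d);
}

// [[Rcpp::export]]
LogicalVector cpp_sat_overlap_batch(NumericMatrix rA, NumericMatrix qA,
                                    NumericMatrix rB, NumericMatrix qB,
                                    NumericMatrix verts, double box) {
  int n = rA.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double va[12], vb[12];
    double qa[4] = {qA(i, 0), qA(i, 1), qA(i, 2), qA(i, 3)};
    double qb[4] = {qB(i, 0), qB(i, 1), qB(i, 2), qB(i, 3)};
    for (int k = 0; k < 4; ++k) {
      double v[3] = {verts(k, 0), verts(k, 1), verts(k, 2)};
      quat_rot(qa, v, &va[k * 3]);
      quat_rot(qb, v, &vb[k * 3]);
    }
    double d[3] = {rB(i, 0) - rA(i, 0), rB(i, 1) - rA(i, 1), rB(i, 2) - rA(i, 2)};
    if (box > 0) min_image(d[0], d[1], d[2], box);
    out[i] = sat_overlap_raw(va, vb, d);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pair_energy(List model, NumericVector rA, NumericVector qA,
                              NumericVector rB, NumericVector qB) {
  Model m = parse_model(model);
  NumericMatrix quat(2, 4);
  for (int k = 0; k < 4; ++k) {
    quat(0, k) = qA[k];
    quat(1, k) = qB[k];
  }
  std::vector<double> off;
  build_offsets(m, quat, off);
  double ra[3] = {rA[0], rA[1], rA[2]}, rb[3] = {rB[0], rB[1], rB[2]};
  double esw, edd;
  bool ov = pair_energy(m, ra, rb, &off[0], &off[(size_t)m.nsites * 3], esw, edd);
  return NumericVector::create(_["esw"] = esw, _["edd"] = edd,
                               _["overlap"] = ov ? 1.0 : 0.0);
}

// [[Rcpp::export]]
List cpp_config_energy(List model, NumericMatrix pos, NumericMatrix quat) {
  Model m = parse_model(model);
  int n = pos.nrow();
  std::vector<double> off;
  build_offsets(m, quat, off);
  double esw = 0.0, edd = 0.0;
  int nov = 0;
  size_t stride = (size_t)m.nsites * 3;
  for (int i = 0; i < n; ++i) {
    double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    for (int j = i + 1; j < n; ++j) {
      double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
      double es, ed;
      if (pair_energy(m, ri, rj, &off[i * stride], &off[j * stride], es, ed))
        ++nov;
      else {
        esw += es;
        edd += ed;
      }
    }
  }
  return List::create(_["esw"] = esw, _["edd"] = edd, _["n_overlap"] = nov);
}

// ---------------------------------------------------------------------------
// NVT Metropolis sweep loop with joint translation + rotation trial moves.
// Histograms: hist_spec is a list of lists with integer vectors `a`, `b`
// holding 0-based site indices (-1 = molecular center).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_mc_run(List model, NumericMatrix pos_in, NumericMatrix quat_in,
                int nsweeps, double dtrans, double drot, int sample_every,
                List hist_spec, double bin_width, int nbins, int nblocks,
                bool tune, int tune_every, int revalidate_every) {
  Model m = parse_model(model);
  NumericMatrix pos = clone(pos_in);
  NumericMatrix quat = clone(quat_in);
  int n = pos.nrow();
  size_t stride = (size_t)m.nsites * 3;
  std::vector<double> off;
  build_offsets(m, quat, off);

  // starting energy (must be overlap-free); the per-pair energies are kept
  // in symmetric n x n caches so a trial move only has to evaluate the
  // moved particle's *new* pair energies
  double E_sw = 0.0, E_dd = 0.0;
  std::vector<double> psw((size_t)n * n, 0.0), pdd((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    for (int j = i + 1; j < n; ++j) {
      double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
      double es, ed;
      if (pair_energy(m, ri, rj, &off[i * stride], &off[j * stride], es, ed))
        stop("starting configuration contains hard overlaps");
      E_sw += es;
      E_dd += ed;
      psw[(size_t)i * n + j] = psw[(size_t)j * n + i] = es;
      pdd[(size_t)i * n + j] = pdd[(size_t)j * n + i] = ed;
    }
  }
  std::vector<double> row_sw(n, 0.0), row_dd(n, 0.0);

  int nspec = hist_spec.size();
  std::vector<std::vector<int> > ga(nspec), gb(nspec);
  for (int s = 0; s < nspec; ++s) {
    List sp = hist_spec[s];
    ga[s] = as<std::vector<int> >(sp["a"]);
    gb[s] = as<std::vector<int> >(sp["b"]);
  }
  int nsamples_exp = sample_every > 0 ? nsweeps / sample_every : 0;
  if (nsamples_exp < 1) nsamples_exp = 1;
  std::vector<double> hist((size_t)nblocks * nspec * nbins, 0.0);
  std::vector<double> block_samples(nblocks, 0.0);

  NumericVector tr_sw(nsweeps), tr_dd(nsweeps), tr_acc(nsweeps);
  long acc_tune = 0, trials_tune = 0;
  double new_off[64 * 3];
  if (m.nsites > 64) stop("too many sites");
  int sample_count = 0;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    int acc_sweep = 0;
    for (int mv = 0; mv < n; ++mv) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
      double rnew[3];
      for (int k = 0; k < 3; ++k) {
        rnew[k] = ri[k] + dtrans * (2.0 * unif_rand() - 1.0);
        rnew[k] -= m.box * std::floor(rnew[k] / m.box);  // wrap into [0, box)
      }
      // random rotation: axis uniform on the sphere, angle uniform in [0, drot]
      double z = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double sxy = std::sqrt(std::max(0.0, 1.0 - z * z));
      double ang = drot * unif_rand();
      double sh = std::sin(0.5 * ang);
      double dq[4] = {std::cos(0.5 * ang), sh * sxy * std::cos(phi),
                      sh * sxy * std::sin(phi), sh * z};
      double qold[4] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
      double qnew[4];
      quat_mul(dq, qold, qnew);
      double qn = std::sqrt(qnew[0] * qnew[0] + qnew[1] * qnew[1] +
                            qnew[2] * qnew[2] + qnew[3] * qnew[3]);
      for (int k = 0; k < 4; ++k) qnew[k] /= qn;
      if (m.nsites > 0)
        for (int s = 0; s < m.nsites; ++s)
          quat_rot(qnew, &m.soff[(size_t)s * 3], &new_off[s * 3]);

      // single pass over partners: new pair energies are computed, old ones
      // come from the cache; a hard overlap in the trial state rejects
      // immediately, skipping the remaining partners entirely
      double desw = 0.0, dedd = 0.0;
      bool ok = true;
      const double *csw = &psw[(size_t)i * n];
      const double *cdd = &pdd[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
        double es_n, ed_n;
        if (pair_energy(m, rnew, rj, new_off, &off[j * stride], es_n, ed_n)) {
          ok = false;
          break;
        }
        row_sw[j] = es_n;
        row_dd[j] = ed_n;
        desw += es_n - csw[j];
        dedd += ed_n - cdd[j];
      }
      ++trials_tune;
      if (!ok) continue;  // hard overlap: reject
      double dE = desw + dedd;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        for (int k = 0; k < 3; ++k) pos(i, k) = rnew[k];
        for (int k = 0; k < 4; ++k) quat(i, k) = qnew[k];
        for (size_t k = 0; k < stride; ++k) off[i * stride + k] = new_off[k];
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          psw[(size_t)i * n + j] = psw[(size_t)j * n + i] = row_sw[j];
          pdd[(size_t)i * n + j] = pdd[(size_t)j * n + i] = row_dd[j];
        }
        E_sw += desw;
        E_dd += dedd;
        ++acc_sweep;
        ++acc_tune;
      }
    }
    tr_sw[sweep] = E_sw;
    tr_dd[sweep] = E_dd;
    tr_acc[sweep] = (double)acc_sweep / n;

    if (tune && tune_every > 0 && (sweep + 1) % tune_every == 0) {
      double rate = (double)acc_tune / (double)trials_tune;
      if (rate < 0.3 || rate > 0.5) {
        // rate-proportional step so even absurd starting amplitudes
        // converge to the window within a few hundred sweeps
        double f = rate / 0.4;
        if (f < 0.5) f = 0.5;
        if (f > 1.5) f = 1.5;
        dtrans = std::min(dtrans * f, m.box / 4.0);
        drot = std::min(drot * f, M_PI);
      }
      if (dtrans < 1e-4) dtrans = 1e-4;
      if (drot < 1e-4) drot = 1e-4;
      acc_tune = 0;
      trials_tune = 0;
    }

    if (sample_every > 0 && (sweep + 1) % sample_every == 0 && nspec > 0) {
      int blk = (int)((long)sample_count * nblocks / nsamples_exp);
      if (blk >= nblocks) blk = nblocks - 1;
      block_samples[blk] += 1.0;
      for (int s = 0; s < nspec; ++s) {
        size_t base = ((size_t)blk * nspec + s) * nbins;
        for (int i = 0; i < n; ++i) {
          double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
          for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
            for (size_t a = 0; a < ga[s].size(); ++a) {
              int sa = ga[s][a];
              double ax = ri[0] + (sa >= 0 ? off[i * stride + sa * 3] : 0.0);
              double ay = ri[1] + (sa >= 0 ? off[i * stride + sa * 3 + 1] : 0.0);
              double az = ri[2] + (sa >= 0 ? off[i * stride + sa * 3 + 2] : 0.0);
              for (size_t b = 0; b < gb[s].size(); ++b) {
                int sb = gb[s][b];
                double dx = rj[0] + (sb >= 0 ? off[j * stride + sb * 3] : 0.0) - ax;
                double dy = rj[1] + (sb >= 0 ? off[j * stride + sb * 3 + 1] : 0.0) - ay;
                double dz = rj[2] + (sb >= 0 ? off[j * stride + sb * 3 + 2] : 0.0) - az;
                min_image(dx, dy, dz, m.box);
                double r = std::sqrt(dx * dx + dy * dy + dz * dz);
                int bin = (int)(r / bin_width);
                if (bin < nbins) hist[base + bin] += 1.0;
              }
            }
          }
        }
      }
      ++sample_count;
    }

    if (revalidate_every > 0 && (sweep + 1) % revalidate_every == 0) {
      double esw_full = 0.0, edd_full = 0.0;
      for (int i = 0; i < n; ++i) {
        double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
        for (int j = i + 1; j < n; ++j) {
          double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
          double es, ed;
          if (pair_energy(m, ri, rj, &off[i * stride], &off[j * stride], es, ed))
            stop("hard overlap detected during revalidation");
          esw_full += es;
          edd_full += ed;
        }
      }
      double Eref = std::fabs(esw_full) + std::fabs(edd_full);
      double tol = 1e-8 * std::max(1.0, Eref);
      if (std::fabs(esw_full - E_sw) > tol || std::fabs(edd_full - E_dd) > tol)
        stop("incremental energy bookkeeping drifted beyond tolerance");
      E_sw = esw_full;  // reset accumulated round-off
      E_dd = edd_full;
    }
    if ((sweep & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector hist_out(hist.begin(), hist.end());
  hist_out.attr("dim") = IntegerVector::create(nbins, nspec, nblocks);
  return List::create(
      _["pos"] = pos, _["quat"] = quat, _["esw_trace"] = tr_sw,
      _["edd_trace"] = tr_dd, _["acc_trace"] = tr_acc,
      _["hist"] = hist_out,
      _["block_samples"] = NumericVector(block_samples.begin(), block_samples.end()),
      _["n_samples"] = sample_count, _["E_sw"] = E_sw, _["E_dd"] = E_dd,
      _["d_trans"] = dtrans, _["d_rot"] = drot);
}

// hard overlaps of particle i with all others (hard part only)
static int overlap_count_one(const Model &m, int i, const double *ri,
                             const double *si, const NumericMatrix &pos,
                             const std::vector<double> &off, int n) {
  size_t stride = (size_t)m.nsites * 3;
  int c = 0;
  double es, ed;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double rj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
    if (pair_energy(m, ri, rj, si, &off[j * stride], es, ed)) ++c;
  }
  return c;
}

// ---------------------------------------------------------------------------
// stepwise compression from box_from to box_target.  Each cycle shrinks the
// box and relaxes overlaps with moves accepted only when they do not
// increase the particle's overlap count.  Dipole terms are irrelevant here:
// the caller passes a hard-only model (dmode = 0).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_compress(List model, NumericMatrix pos_in, NumericMatrix quat_in,
                  double box_from, double box_target, double shrink,
                  int max_cycles, int relax_sweeps, double dtrans, double drot) {
  Model m = parse_model(model);
  NumericMatrix pos = clone(pos_in);
  NumericMatrix quat = clone(quat_in);
  int n = pos.nrow();
  size_t stride = (size_t)m.nsites * 3;
  std::vector<double> off;
  build_offsets(m, quat, off);
  double box = box_from;
  double new_off[64 * 3];
  int fails = 0;

  bool clean = false;  // current state verified overlap-free?
  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    if (clean) {  // shrink only from a verified overlap-free state
      if (box <= box_target) break;
      double box_new = std::max(box_target, box * shrink);
      double scale = box_new / box;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) pos(i, k) *= scale;
      box = box_new;
      m.box = box;
    }

    int total_ov = 0;
    for (int i = 0; i < n; ++i) {
      double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
      total_ov += overlap_count_one(m, i, ri, &off[i * stride], pos, off, n);
    }
    total_ov /= 2;
    int sw = 0;
    // keep sweeping a little after resolution: plain hard-core MC
    // (identical acceptance rule once the overlap count is zero) to
    // decorrelate before the next shrink step
    while (sw < relax_sweeps && (total_ov > 0 || sw < 5)) {
      for (int mv = 0; mv < n; ++mv) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        double ri[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
        int ov_old = overlap_count_one(m, i, ri, &off[i * stride], pos, off, n);
        double rnew[3];
        for (int k = 0; k < 3; ++k) {
          rnew[k] = ri[k] + dtrans * (2.0 * unif_rand() - 1.0);
          rnew[k] -= box * std::floor(rnew[k] / box);
        }
        double z = 2.0 * unif_rand() - 1.0;
        double phi = 2.0 * M_PI * unif_rand();
        double sxy = std::sqrt(std::max(0.0, 1.0 - z * z));
        double ang = drot * unif_rand();
        double sh = std::sin(0.5 * ang);
        double dq[4] = {std::cos(0.5 * ang), sh * sxy * std::cos(phi),
                        sh * sxy * std::sin(phi), sh * z};
        double qold[4] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
        double qnew[4];
        quat_mul(dq, qold, qnew);
        double qn = std::sqrt(qnew[0] * qnew[0] + qnew[1] * qnew[1] +
                              qnew[2] * qnew[2] + qnew[3] * qnew[3]);
        for (int k = 0; k < 4; ++k) qnew[k] /= qn;
        if (m.nsites > 0)
          for (int s = 0; s < m.nsites; ++s)
            quat_rot(qnew, &m.soff[(size_t)s * 3], &new_off[s * 3]);
        int ov_new = overlap_count_one(m, i, rnew, new_off, pos, off, n);
        if (ov_new <= ov_old) {
          for (int k = 0; k < 3; ++k) pos(i, k) = rnew[k];
          for (int k = 0; k < 4; ++k) quat(i, k) = qnew[k];
          for (size_t k = 0; k < stride; ++k) off[i * stride + k] = new_off[k];
          total_ov += ov_new - ov_old;
        }
      }
      ++sw;
    }
    if (total_ov > 0) {
      // stuck: expand one step and relax there on the next cycle before
      // attempting to shrink again; give up after many consecutive failures
      double scale_back = std::min(1.0 / shrink, box_from / box);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) pos(i, k) *= scale_back;
      box *= scale_back;
      m.box = box;
      clean = false;
      if (++fails > 60) break;
    } else {
      clean = true;
      fails = 0;
    }
    if ((cyc & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pos"] = pos, _["quat"] = quat, _["box"] = box,
                      _["reached"] =
                          (clean && box <= box_target * (1.0 + 1e-12)));
}
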