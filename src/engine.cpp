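#include <Rcpp.h>
using namespace Rcpp;

// Overdamped mass-spring relaxation and strain-threshold growth of a 2D
// polygonal cell mesh. Walls are linear-strain springs (tension =
// k * (l - l0) / l0); every cell applies an outward pressure force
// P * wall_length to each of its walls, split equally between the wall's
// endpoints. Vertices follow the net force with a Jacobi-preconditioned
// overdamped update x += dt * F / d, where d is the vertex's incident
// spring stiffness sum(k/l0) and dt a dimensionless step, until the
// maximum vertex force drops below tol.
// Growth adds irreversible rest length to every wall whose elastic strain
// exceeds the threshold: l0 *= 1 + ext * (strain - threshold).

namespace {

struct Mesh {
  std::vector<double> x, y;
  std::vector<int> wa, wb;          // wall endpoints (0-based)
  std::vector<double> k, l0, ext;   // per wall
  std::vector<int> coff;            // cell loop offsets (size ncell+1)
  std::vector<int> cloop;           // concatenated CCW vertex loops
  std::vector<double> P;            // per cell
};

double total_area(const Mesh& m) {
  double A = 0.0;
  int nc = (int)m.coff.size() - 1;
  for (int c = 0; c < nc; ++c) {
    double a = 0.0;
    for (int i = m.coff[c]; i < m.coff[c + 1]; ++i) {
      int j = (i + 1 < m.coff[c + 1]) ? i + 1 : m.coff[c];
      int va = m.cloop[i], vb = m.cloop[j];
      a += m.x[va] * m.y[vb] - m.x[vb] * m.y[va];
    }
    A += 0.5 * a;
  }
  return A;
}

double energy(const Mesh& m) {
  double E = 0.0;
  for (size_t w = 0; w < m.wa.size(); ++w) {
    double dx = m.x[m.wb[w]] - m.x[m.wa[w]];
    double dy = m.y[m.wb[w]] - m.y[m.wa[w]];
    double l = std::sqrt(dx * dx + dy * dy);
    double eps = (l - m.l0[w]) / m.l0[w];
    E += 0.5 * m.k[w] * eps * eps * m.l0[w];
  }
  int nc = (int)m.coff.size() - 1;
  for (int c = 0; c < nc; ++c) {
    double a = 0.0;
    for (int i = m.coff[c]; i < m.coff[c + 1]; ++i) {
      int j = (i + 1 < m.coff[c + 1]) ? i + 1 : m.coff[c];
      int va = m.cloop[i], vb = m.cloop[j];
      a += m.x[va] * m.y[vb] - m.x[vb] * m.y[va];
    }
    E -= m.P[c] * 0.5 * a;
  }
  return E;
}

// One force evaluation; returns max vertex force magnitude.
double forces(const Mesh& m, std::vector<double>& fx,
              std::vector<double>& fy) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  for (size_t w = 0; w < m.wa.size(); ++w) {
    int a = m.wa[w], b = m.wb[w];
    double dx = m.x[b] - m.x[a];
    double dy = m.y[b] - m.y[a];
    double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-300) continue;
    double T = m.k[w] * (l - m.l0[w]) / m.l0[w];
    double ux = dx / l, uy = dy / l;
    fx[a] += T * ux; fy[a] += T * uy;
    fx[b] -= T * ux; fy[b] -= T * uy;
  }
  int nc = (int)m.coff.size() - 1;
  for (int c = 0; c < nc; ++c) {
    double P = m.P[c];
    if (P == 0.0) continue;
    for (int i = m.coff[c]; i < m.coff[c + 1]; ++i) {
      int j = (i + 1 < m.coff[c + 1]) ? i + 1 : m.coff[c];
      int va = m.cloop[i], vb = m.cloop[j];
      double dx = m.x[vb] - m.x[va];
      double dy = m.y[vb] - m.y[va];
      // outward normal of a CCW edge is (dy, -dx); force P * length
      double gx = 0.5 * P * dy, gy = -0.5 * P * dx;
      fx[va] += gx; fy[va] += gy;
      fx[vb] += gx; fy[vb] += gy;
    }
  }
  double fmax = 0.0;
  for (size_t v = 0; v < fx.size(); ++v) {
    double f2 = fx[v] * fx[v] + fy[v] * fy[v];
    if (f2 > fmax) fmax = f2;
  }
  return std::sqrt(fmax);
}

// Per-vertex diagonal preconditioner: incident spring stiffness sum(k/l0).
void precondition(const Mesh& m, std::vector<double>& d) {
  std::fill(d.begin(), d.end(), 0.0);
  for (size_t w = 0; w < m.wa.size(); ++w) {
    double s = m.k[w] / m.l0[w];
    d[m.wa[w]] += s;
    d[m.wb[w]] += s;
  }
  for (size_t v = 0; v < d.size(); ++v) {
    if (d[v] <= 0.0) d[v] = 1.0;
  }
}

// Relax to quasi-equilibrium; returns iterations used (negative if the
// iteration cap was hit before reaching tol). method 0: plain
// preconditioned gradient descent (strict energy descent, used for energy
// audits); method 1: FIRE (fast inertial relaxation engine) on the
// preconditioned forces, the production minimizer.
long relax_loop(Mesh& m, double dt0, double tol, long max_iter, int method,
                std::vector<double>& fx, std::vector<double>& fy,
                const std::vector<double>& d,
                std::vector<double>* etrace) {
  long it = 0;
  if (method == 0) {
    for (; it < max_iter; ++it) {
      double fmax = forces(m, fx, fy);
      if (etrace) etrace->push_back(energy(m));
      if (fmax < tol) return it;
      for (size_t v = 0; v < fx.size(); ++v) {
        m.x[v] += dt0 * fx[v] / d[v];
        m.y[v] += dt0 * fy[v] / d[v];
      }
    }
    return -it;
  }
  // FIRE
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  const double dt_max = 20.0 * dt0;
  double dt = dt0, alpha = alpha0;
  int n_pos = 0;
  size_t nv = fx.size();
  std::vector<double> vx(nv, 0.0), vy(nv, 0.0);
  for (; it < max_iter; ++it) {
    double fmax = forces(m, fx, fy);
    if (etrace) etrace->push_back(energy(m));
    if (fmax < tol) return it;
    double power = 0.0;
    for (size_t v = 0; v < nv; ++v) power += fx[v] * vx[v] + fy[v] * vy[v];
    if (power > 0.0) {
      if (++n_pos > n_min) {
        dt = std::min(dt * f_inc, dt_max);
        alpha *= f_alpha;
      }
    } else {
      n_pos = 0;
      dt *= f_dec;
      alpha = alpha0;
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
    }
    double vnorm = 0.0, fnorm = 0.0;
    for (size_t v = 0; v < nv; ++v) {
      vx[v] += dt * fx[v] / d[v];
      vy[v] += dt * fy[v] / d[v];
      vnorm += vx[v] * vx[v] + vy[v] * vy[v];
      double gx = fx[v] / d[v], gy = fy[v] / d[v];
      fnorm += gx * gx + gy * gy;
    }
    vnorm = std::sqrt(vnorm);
    fnorm = std::sqrt(fnorm);
    if (fnorm > 1e-300) {
      double mix = alpha * vnorm / fnorm;
      for (size_t v = 0; v < nv; ++v) {
        vx[v] = (1.0 - alpha) * vx[v] + mix * fx[v] / d[v];
        vy[v] = (1.0 - alpha) * vy[v] + mix * fy[v] / d[v];
      }
    }
    for (size_t v = 0; v < nv; ++v) {
      m.x[v] += dt * vx[v];
      m.y[v] += dt * vy[v];
    }
  }
  return -it;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix verts, IntegerVector wall_a,
                  IntegerVector wall_b, NumericVector wall_k,
                  NumericVector wall_l0, NumericVector wall_ext,
                  IntegerVector cell_off, IntegerVector cell_loop,
                  NumericVector pressure, double threshold, double dt,
                  double tol, double relax_max_iter, int n_growth_steps,
                  double target_area, bool record_energy, int method) {
  Mesh m;
  int nv = verts.nrow();
  m.x.resize(nv); m.y.resize(nv);
  for (int v = 0; v < nv; ++v) { m.x[v] = verts(v, 0); m.y[v] = verts(v, 1); }
  m.wa.assign(wall_a.begin(), wall_a.end());
  m.wb.assign(wall_b.begin(), wall_b.end());
  m.k.assign(wall_k.begin(), wall_k.end());
  m.l0.assign(wall_l0.begin(), wall_l0.end());
  m.ext.assign(wall_ext.begin(), wall_ext.end());
  m.coff.assign(cell_off.begin(), cell_off.end());
  m.cloop.assign(cell_loop.begin(), cell_loop.end());
  m.P.assign(pressure.begin(), pressure.end());

  std::vector<double> fx(nv), fy(nv), diag(nv);
  std::vector<double> etrace;
  precondition(m, diag);
  std::vector<double>* et = record_energy ? &etrace : nullptr;
  long max_iter = (long)relax_max_iter;

  bool converged = true, stalled = false;
  long total_iters = 0;
  long it = relax_loop(m, dt, tol, max_iter, method, fx, fy, diag, et);
  if (it < 0) { converged = false; total_iters -= it; }
  else total_iters += it;

  std::vector<double> atrace;
  double A = total_area(m);
  atrace.push_back(A);
  int steps = 0;
  bool area_mode = R_finite(target_area) && target_area > 0;
  while (converged) {
    if (area_mode && A >= target_area * (1.0 - 1e-11)) break;
    if (!area_mode && steps >= n_growth_steps) break;
    if (area_mode && steps >= n_growth_steps) break;  // hard cap
    // growth: irreversible rest-length increase where strain > threshold
    for (size_t w = 0; w < m.wa.size(); ++w) {
      double dx = m.x[m.wb[w]] - m.x[m.wa[w]];
      double dy = m.y[m.wb[w]] - m.y[m.wa[w]];
      double l = std::sqrt(dx * dx + dy * dy);
      double eps = (l - m.l0[w]) / m.l0[w];
      if (eps > threshold) m.l0[w] *= 1.0 + m.ext[w] * (eps - threshold);
    }
    precondition(m, diag);
    it = relax_loop(m, dt, tol, max_iter, method, fx, fy, diag, nullptr);
    if (it < 0) { converged = false; total_iters -= it; break; }
    total_iters += it;
    ++steps;
    double Anew = total_area(m);
    atrace.push_back(Anew);
    if (area_mode && Anew - A < 1e-9) { stalled = true; break; }
    A = Anew;
  }

  NumericMatrix vout(nv, 2);
  for (int v = 0; v < nv; ++v) { vout(v, 0) = m.x[v]; vout(v, 1) = m.y[v]; }
  return List::create(
    _["vertices"] = vout,
    _["rest_length"] = NumericVector(m.l0.begin(), m.l0.end()),
    _["steps"] = steps,
    _["area_trace"] = NumericVector(atrace.begin(), atrace.end()),
    _["energy_trace"] = NumericVector(etrace.begin(), etrace.end()),
    _["converged"] = converged,
    _["stalled"] = stalled,
    _["relax_iterations"] = (double)total_iters,
    _["total_area"] = total_area(m));
}
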