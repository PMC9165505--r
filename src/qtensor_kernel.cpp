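// Lattice Landau-de Gennes Q-tensor gradient flow.
//
// State: per-site symmetric traceless 3x3 tensor stored as 5 components
// (qxx, qxy, qxz, qyy, qyz); qzz = -qxx - qyy by construction, so the
// traceless constraint holds exactly at all times.  The driving field is
// confined to the lattice plane (Ez = 0), and in-plane initial conditions
// stay in-plane (the xz/yz components have no source), which the per-site
// order diagnostics rely on.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lattice {
  int nx, ny, N;
  // nb[d][i]: index of neighbour of site i in direction d (+x,-x,+y,-y);
  // -1 when the bond is absent (Neumann edge).
  std::vector<int> nb[4];

  Lattice(int nx_, int ny_, bool neumann) : nx(nx_), ny(ny_), N(nx_ * ny_) {
    for (int d = 0; d < 4; ++d) nb[d].resize(N);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int s = i + nx * j;
        int ip = i + 1, im = i - 1, jp = j + 1, jm = j - 1;
        if (neumann) {
          nb[0][s] = (ip < nx) ? ip + nx * j : -1;
          nb[1][s] = (im >= 0) ? im + nx * j : -1;
          nb[2][s] = (jp < ny) ? i + nx * jp : -1;
          nb[3][s] = (jm >= 0) ? i + nx * jm : -1;
        } else {
          nb[0][s] = (ip % nx) + nx * j;
          nb[1][s] = ((im + nx) % nx) + nx * j;
          nb[2][s] = i + nx * (jp % ny);
          nb[3][s] = i + nx * ((jm + ny) % ny);
        }
      }
    }
  }
};

struct State {
  std::vector<double> q[5];  // qxx, qxy, qxz, qyy, qyz
  std::vector<double> b;     // per-site cubic coefficient sign (+/-1)
};

// Free energy of the discretised functional: bulk + dielectric terms summed
// per site (weight dx^2), elastic term summed over forward-difference bonds
// (the dx^2 site weight cancels the 1/dx^2 of the squared gradient).
double free_energy_impl(const State& st, const Lattice& lat,
                        double A, double C, double R1, double dx,
                        double deps, double ex, double ey, bool decouple) {
  const double e2 = ex * ex + ey * ey;
  double F = 0.0;
  for (int s = 0; s < lat.N; ++s) {
    const double q1 = st.q[0][s], q2 = st.q[1][s], q3 = st.q[2][s];
    const double q4 = st.q[3][s], q5 = st.q[4][s];
    const double qzz = -q1 - q4;
    const double tr2 = q1 * q1 + q4 * q4 + qzz * qzz +
                       2.0 * (q2 * q2 + q3 * q3 + q5 * q5);
    const double tr3 =
        q1 * q1 * q1 + q4 * q4 * q4 + qzz * qzz * qzz +
        3.0 * (q1 * (q2 * q2 + q3 * q3) + q4 * (q2 * q2 + q5 * q5) +
               qzz * (q3 * q3 + q5 * q5)) +
        6.0 * q2 * q3 * q5;
    const double eqe = q1 * ex * ex + 2.0 * q2 * ex * ey + q4 * ey * ey;
    F += dx * dx * (0.5 * A * tr2 + st.b[s] / 3.0 * tr3 +
                    0.25 * C * tr2 * tr2 - 0.5 * deps * eqe);
    // forward bonds only (+x, +y) to count each once
    for (int d = 0; d < 4; d += 2) {
      int n = lat.nb[d][s];
      if (n < 0) continue;
      if (decouple && st.b[n] != st.b[s]) continue;
      double g = 0.0;
      for (int c = 0; c < 5; ++c) {
        double dqc = st.q[c][n] - st.q[c][s];
        g += (c == 0 || c == 3) ? dqc * dqc : 2.0 * dqc * dqc;
      }
      double dqzz = (-st.q[0][n] - st.q[3][n]) - qzz;
      g += dqzz * dqzz;
      F += 0.5 * R1 * g;
    }
  }
  return F;
}

// One forward-Euler step Q <- Q + dt * Gamma * H into the same state
// (H evaluated from a snapshot held in h[]).
void step_impl(State& st, const Lattice& lat,
               double A, double C, double R1, double dx, double dt,
               double gamma, double deps, double ex, double ey,
               bool decouple, std::vector<double> h[5]) {
  const double e2 = ex * ex + ey * ey;
  const double hf1 = 0.5 * deps * (ex * ex - e2 / 3.0);
  const double hf2 = 0.5 * deps * (ex * ey);
  const double hf4 = 0.5 * deps * (ey * ey - e2 / 3.0);
  const double idx2 = 1.0 / (dx * dx);
  for (int s = 0; s < lat.N; ++s) {
    const double q1 = st.q[0][s], q2 = st.q[1][s], q3 = st.q[2][s];
    const double q4 = st.q[3][s], q5 = st.q[4][s];
    const double qzz = -q1 - q4;
    const double B = st.b[s];
    const double tr2 = q1 * q1 + q4 * q4 + qzz * qzz +
                       2.0 * (q2 * q2 + q3 * q3 + q5 * q5);
    // (Q^2) components
    const double s1 = q1 * q1 + q2 * q2 + q3 * q3;          // xx
    const double s2 = q1 * q2 + q2 * q4 + q3 * q5;          // xy
    const double s3 = q1 * q3 + q2 * q5 + q3 * qzz;         // xz
    const double s4 = q2 * q2 + q4 * q4 + q5 * q5;          // yy
    const double s5 = q2 * q3 + q4 * q5 + q5 * qzz;         // yz
    double lap[5] = {0, 0, 0, 0, 0};
    for (int d = 0; d < 4; ++d) {
      int n = lat.nb[d][s];
      if (n < 0) continue;
      if (decouple && st.b[n] != st.b[s]) continue;
      for (int c = 0; c < 5; ++c) lap[c] += st.q[c][n] - st.q[c][s];
    }
    h[0][s] = -(A * q1 + B * (s1 - tr2 / 3.0) + C * q1 * tr2) +
              R1 * lap[0] * idx2 + hf1;
    h[1][s] = -(A * q2 + B * s2 + C * q2 * tr2) + R1 * lap[1] * idx2 + hf2;
    h[2][s] = -(A * q3 + B * s3 + C * q3 * tr2) + R1 * lap[2] * idx2;
    h[3][s] = -(A * q4 + B * (s4 - tr2 / 3.0) + C * q4 * tr2) +
              R1 * lap[3] * idx2 + hf4;
    h[4][s] = -(A * q5 + B * s5 + C * q5 * tr2) + R1 * lap[4] * idx2;
  }
  const double a = dt * gamma;
  for (int c = 0; c < 5; ++c)
    for (int s = 0; s < lat.N; ++s) st.q[c][s] += a * h[c][s];
}

void check_stable(const State& st, int N, double dt) {
  for (int c = 0; c < 5; ++c)
    for (int s = 0; s < N; ++s)
      if (!std::isfinite(st.q[c][s]) || std::fabs(st.q[c][s]) > 10.0)
        stop("Q-tensor relaxation diverged (|Q| > 10); reduce dt = %f",
             dt);
}

// Per-site scalar order from the largest-magnitude eigenvalue,
// S = (3/2) * lambda; in-plane closed form (valid because xz/yz vanish).
// Director angle in degrees folded to [0, 90] vs the x axis; NaN when the
// distinguished eigenvalue is out of plane or the tensor is degenerate.
void site_order_impl(const State& st, int N,
                     std::vector<double>& S, std::vector<double>& ang) {
  for (int s = 0; s < N; ++s) {
    const double q1 = st.q[0][s], q2 = st.q[1][s], q4 = st.q[3][s];
    const double qzz = -q1 - q4;
    const double m = 0.5 * (q1 + q4);
    const double r = std::sqrt(0.25 * (q1 - q4) * (q1 - q4) + q2 * q2);
    const double mup = m + r, mum = m - r;
    double lam = mup;
    bool inplane = true;
    if (std::fabs(mum) > std::fabs(lam)) lam = mum;
    if (std::fabs(qzz) > std::fabs(lam)) { lam = qzz; inplane = false; }
    S[s] = 1.5 * lam;
    if (!inplane || r < 1e-14) {
      ang[s] = NA_REAL;
    } else {
      // eigenvector angle of the in-plane 2x2 block for eigenvalue lam
      double th = 0.5 * std::atan2(2.0 * q2, q1 - q4) * 180.0 / M_PI;
      if (lam == mum) th += 90.0;  // minor in-plane axis
      // th now lies in (-90, 180]; fold to [0, 90]
      if (th < 0) th += 180.0;
      if (th > 90.0) th = 180.0 - th;
      ang[s] = th;
    }
  }
}

double mean_director_angle(const State& st, int N) {
  double m1 = 0, m2 = 0, m4 = 0;
  for (int s = 0; s < N; ++s) {
    m1 += st.q[0][s]; m2 += st.q[1][s]; m4 += st.q[3][s];
  }
  m1 /= N; m2 /= N; m4 /= N;
  if (std::sqrt(0.25 * (m1 - m4) * (m1 - m4) + m2 * m2) < 1e-14)
    return NA_REAL;
  double th = 0.5 * std::atan2(2.0 * m2, m1 - m4) * 180.0 / M_PI;
  return std::fabs(th);  // atan2/2 lies in (-90, 90]
}

State unpack(NumericVector q, NumericMatrix b, int& nx, int& ny) {
  IntegerVector dim = q.attr("dim");
  if (dim.size() != 3 || dim[2] != 5)
    stop("q must be an nx x ny x 5 array");
  nx = dim[0]; ny = dim[1];
  const int N = nx * ny;
  if (b.nrow() != nx || b.ncol() != ny)
    stop("b_site dimensions do not match q");
  State st;
  for (int c = 0; c < 5; ++c) {
    st.q[c].resize(N);
    for (int s = 0; s < N; ++s) st.q[c][s] = q[s + N * c];
  }
  st.b.resize(N);
  for (int s = 0; s < N; ++s) st.b[s] = b[s];
  return st;
}

NumericVector pack(const State& st, int nx, int ny) {
  const int N = nx * ny;
  NumericVector out(N * 5);
  for (int c = 0; c < 5; ++c)
    for (int s = 0; s < N; ++s) out[s + N * c] = st.q[c][s];
  out.attr("dim") = IntegerVector::create(nx, ny, 5);
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_free_energy(NumericVector q, NumericMatrix b, double A, double C,
                       double R1, double dx, double deps, double ex,
                       double ey, bool neumann, bool decouple) {
  int nx, ny;
  State st = unpack(q, b, nx, ny);
  Lattice lat(nx, ny, neumann);
  return free_energy_impl(st, lat, A, C, R1, dx, deps, ex, ey, decouple);
}

// [[Rcpp::export]]
NumericVector cpp_step_n(NumericVector q, NumericMatrix b, int nsteps,
                         double A, double C, double R1, double dx, double dt,
                         double gamma, double deps, double ex, double ey,
                         bool neumann, bool decouple) {
  int nx, ny;
  State st = unpack(q, b, nx, ny);
  Lattice lat(nx, ny, neumann);
  std::vector<double> h[5];
  for (int c = 0; c < 5; ++c) h[c].resize(lat.N);
  for (int k = 0; k < nsteps; ++k) {
    step_impl(st, lat, A, C, R1, dx, dt, gamma, deps, ex, ey, decouple, h);
    check_stable(st, lat.N, dt);
  }
  return pack(st, nx, ny);
}

// [[Rcpp::export]]
List cpp_site_order(NumericVector q, NumericMatrix b) {
  int nx, ny;
  State st = unpack(q, b, nx, ny);
  std::vector<double> S(nx * ny), ang(nx * ny);
  site_order_impl(st, nx * ny, S, ang);
  NumericMatrix Sm(nx, ny), am(nx, ny);
  for (int s = 0; s < nx * ny; ++s) { Sm[s] = S[s]; am[s] = ang[s]; }
  return List::create(_["S"] = Sm, _["angle"] = am);
}

// Run a piecewise-constant-anisotropy schedule, recording the scalar trace
// (time, lattice-mean S, free energy, mean director angle) every
// trace_every steps and per-site S heatmaps every heatmap_every steps.
// [[Rcpp::export]]
List cpp_run(NumericVector q, NumericMatrix b, double A, double C, double R1,
             double dx, double dt, double gamma, double ex, double ey,
             NumericVector seg_deps, IntegerVector seg_steps,
             int trace_every, int heatmap_every, double t0, bool neumann,
             bool decouple) {
  if (seg_deps.size() != seg_steps.size())
    stop("schedule segments malformed");
  int nx, ny;
  State st = unpack(q, b, nx, ny);
  Lattice lat(nx, ny, neumann);
  const int N = lat.N;
  std::vector<double> h[5];
  for (int c = 0; c < 5; ++c) h[c].resize(N);
  std::vector<double> Ssite(N), angsite(N);

  std::vector<double> times, meanS, F, dirang;
  std::vector<double> hm_times;
  List heatmaps;

  auto record_scalar = [&](double t, double deps) {
    site_order_impl(st, N, Ssite, angsite);
    double ms = 0;
    for (int s = 0; s < N; ++s) ms += Ssite[s];
    times.push_back(t);
    meanS.push_back(ms / N);
    F.push_back(free_energy_impl(st, lat, A, C, R1, dx, deps, ex, ey,
                                 decouple));
    dirang.push_back(mean_director_angle(st, N));
  };
  auto record_heatmap = [&](double t) {
    site_order_impl(st, N, Ssite, angsite);
    NumericMatrix Sm(nx, ny);
    for (int s = 0; s < N; ++s) Sm[s] = Ssite[s];
    hm_times.push_back(t);
    heatmaps.push_back(Sm);
  };

  long gstep = 0;
  double t = t0;
  record_scalar(t, seg_deps[0]);
  record_heatmap(t);
  for (int seg = 0; seg < seg_deps.size(); ++seg) {
    const double deps = seg_deps[seg];
    for (int k = 0; k < seg_steps[seg]; ++k) {
      step_impl(st, lat, A, C, R1, dx, dt, gamma, deps, ex, ey, decouple, h);
      check_stable(st, N, dt);
      ++gstep;
      t = t0 + gstep * dt;
      bool last = (seg == seg_deps.size() - 1 && k == seg_steps[seg] - 1);
      if (gstep % trace_every == 0 || last) record_scalar(t, deps);
      if (gstep % heatmap_every == 0 || last) record_heatmap(t);
    }
    if (seg_steps[seg] > 0 && seg + 1 < seg_deps.size()) {
      // re-record at the switch so the free-energy jump is visible
      record_scalar(t, seg_deps[seg + 1]);
    }
  }
  return List::create(
      _["q"] = pack(st, nx, ny), _["time"] = wrap(times),
      _["mean_S"] = wrap(meanS), _["free_energy"] = wrap(F),
      _["director_angle"] = wrap(dirang), _["heatmap_times"] = wrap(hm_times),
      _["heatmaps"] = heatmaps);
}
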