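#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Labels are 0 (outside the mother mask), 1 (daughter A) or 2 (daughter B),
// stored in column-major order over a nx*ny*nz grid. Interface area is the
// sum of shared voxel-face areas between differently labelled foreground
// voxels under 6-connectivity; face areas follow the voxel calibration
// (dy*dz for x-normal faces, etc.).

static inline double face_area(int axis, const NumericVector& vd) {
  if (axis == 0) return vd[1] * vd[2];
  if (axis == 1) return vd[0] * vd[2];
  return vd[0] * vd[1];
}

// [[Rcpp::export]]
double cpp_interface_area(IntegerVector labels, IntegerVector dim,
                          NumericVector voxel_dims) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ax = face_area(0, voxel_dims), ay = face_area(1, voxel_dims),
               az = face_area(2, voxel_dims);
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        const int li = labels[i];
        if (li == 0) continue;
        if (x + 1 < nx) {
          const int lj = labels[i + 1];
          if (lj != 0 && lj != li) area += ax;
        }
        if (y + 1 < ny) {
          const int lj = labels[i + nx];
          if (lj != 0 && lj != li) area += ay;
        }
        if (z + 1 < nz) {
          const int lj = labels[i + nx * ny];
          if (lj != 0 && lj != li) area += az;
        }
      }
  return area;
}

// Area change induced by flipping voxel i from its current label to the
// other daughter: faces shared with same-labelled neighbours are created,
// faces shared with other-labelled neighbours vanish.
static inline double delta_area(const std::vector<int>& lab, int x, int y,
                                int z, int nx, int ny, int nz, double ax,
                                double ay, double az) {
  const int i = x + nx * (y + ny * z);
  const int li = lab[i];
  const int other = 3 - li;
  double d = 0.0;
  if (x > 0)      { int l = lab[i - 1];       if (l == li) d += ax; else if (l == other) d -= ax; }
  if (x + 1 < nx) { int l = lab[i + 1];       if (l == li) d += ax; else if (l == other) d -= ax; }
  if (y > 0)      { int l = lab[i - nx];      if (l == li) d += ay; else if (l == other) d -= ay; }
  if (y + 1 < ny) { int l = lab[i + nx];      if (l == li) d += ay; else if (l == other) d -= ay; }
  if (z > 0)      { int l = lab[i - nx * ny]; if (l == li) d += az; else if (l == other) d -= az; }
  if (z + 1 < nz) { int l = lab[i + nx * ny]; if (l == li) d += az; else if (l == other) d -= az; }
  return d;
}

// Run n_cycles Monte Carlo cycles of N single-voxel flip proposals each
// (N = foreground voxel count). Uses R's RNG so set.seed() controls runs.
// When adapt is true, beta is updated after each cycle with the
// multiplicative controller beta' = beta * (1 + kappa * (observed - target))
// on the acceptance fraction of area-increasing proposals, clamped to
// [beta_min, beta_max].
//
// vol_weight > 0 adds a volume tether to the energy,
//   E = A + vol_weight * |n_A - target_count|,
// which keeps the achieved volume ratio near the drawn one: single-voxel
// flips do not conserve volume, and without the tether the minority
// daughter shrinks by curvature flow on small masks. Acceptance statistics
// still count proposals by their area change alone.
// [[Rcpp::export]]
List cpp_metropolis(IntegerVector labels, IntegerVector dim,
                    NumericVector voxel_dims, int n_cycles, double beta0,
                    double target, double kappa, double beta_min,
                    double beta_max, bool adapt, double target_count,
                    double vol_weight, int cooling_cycles = 0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ax = face_area(0, voxel_dims), ay = face_area(1, voxel_dims),
               az = face_area(2, voxel_dims);
  std::vector<int> lab(labels.begin(), labels.end());
  std::vector<int> fg;
  fg.reserve(lab.size());
  for (size_t i = 0; i < lab.size(); ++i)
    if (lab[i] != 0) fg.push_back((int)i);
  const int N = (int)fg.size();
  if (N == 0) stop("empty mask");

  double beta = beta0;
  NumericVector beta_traj(n_cycles), area_traj(n_cycles), acc_frac(n_cycles);
  IntegerVector prop_up(n_cycles), acc_up(n_cycles);
  int n_a = 0;
  for (size_t i = 0; i < lab.size(); ++i)
    if (lab[i] == 1) ++n_a;

  auto run_cycle = [&](int* out_up, int* out_up_acc) {
    int n_up = 0, n_up_acc = 0;
    for (int s = 0; s < N; ++s) {
      int k = (int)std::floor(unif_rand() * N);
      if (k == N) k = N - 1;
      const int i = fg[k];
      const int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      const double dA = delta_area(lab, x, y, z, nx, ny, nz, ax, ay, az);
      double dE = dA;
      const int n_a_new = n_a + (lab[i] == 1 ? -1 : 1);
      if (vol_weight > 0.0)
        dE += vol_weight * (std::fabs(n_a_new - target_count) -
                            std::fabs(n_a - target_count));
      const bool up = dA > 0.0;
      if (up) ++n_up;
      bool accept;
      if (dE < 0.0) {
        accept = true;
      } else {
        accept = unif_rand() < std::exp(-beta * dE);
      }
      if (accept) {
        if (up) ++n_up_acc;
        lab[i] = 3 - lab[i];
        n_a = n_a_new;
      }
    }
    *out_up = n_up;
    *out_up_acc = n_up_acc;
  };

  for (int c = 0; c < n_cycles; ++c) {
    int n_up, n_up_acc;
    run_cycle(&n_up, &n_up_acc);
    prop_up[c] = n_up;
    acc_up[c] = n_up_acc;
    const double obs = n_up > 0 ? (double)n_up_acc / n_up : target;
    acc_frac[c] = obs;
    if (adapt) {
      beta *= 1.0 + kappa * (obs - target);
      if (beta < beta_min) beta = beta_min;
      if (beta > beta_max) beta = beta_max;
    }
    beta_traj[c] = beta;
    area_traj[c] = cpp_interface_area(
        IntegerVector(lab.begin(), lab.end()), dim, voxel_dims);
  }

  // cooling tail: the acceptance target decays geometrically to ~2% of the
  // setpoint, so the system settles into one local area minimum before any
  // final greedy quench; not part of the recorded setpoint-phase statistics
  for (int c = 0; c < cooling_cycles; ++c) {
    const double tc = target *
        std::pow(0.02, (c + 1.0) / (double)cooling_cycles);
    int n_up, n_up_acc;
    run_cycle(&n_up, &n_up_acc);
    const double obs = n_up > 0 ? (double)n_up_acc / n_up : tc;
    if (adapt) {
      beta *= 1.0 + kappa * (obs - tc);
      if (beta < beta_min) beta = beta_min;
      if (beta > beta_max) beta = beta_max;
    }
  }

  IntegerVector out(lab.begin(), lab.end());
  return List::create(
      _["labels"] = out,
      _["area"] = cpp_interface_area(out, dim, voxel_dims),
      _["beta"] = beta, _["beta_traj"] = beta_traj,
      _["area_traj"] = area_traj, _["acc_frac"] = acc_frac,
      _["prop_up"] = prop_up, _["acc_up"] = acc_up);
}

// 6-connected component labelling of the nonzero voxels of mask.
// Returns an integer vector with 0 outside and component ids 1..k inside.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector comp(n, 0);
  int next_id = 0;
  std::queue<int> q;
  for (int i0 = 0; i0 < n; ++i0) {
    if (mask[i0] == 0 || comp[i0] != 0) continue;
    const int value = mask[i0];
    comp[i0] = ++next_id;
    q.push(i0);
    while (!q.empty()) {
      const int i = q.front();
      q.pop();
      const int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      const int nbr[6] = {x > 0 ? i - 1 : -1,      x + 1 < nx ? i + 1 : -1,
                          y > 0 ? i - nx : -1,     y + 1 < ny ? i + nx : -1,
                          z > 0 ? i - nx * ny : -1, z + 1 < nz ? i + nx * ny : -1};
      for (int d = 0; d < 6; ++d) {
        const int j = nbr[d];
        if (j >= 0 && comp[j] == 0 && mask[j] == value) {
          comp[j] = next_id;
          q.push(j);
        }
      }
    }
  }
  return comp;
}
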