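// Overdamped-Langevin (Brownian) integrator for the coarse-grained toy
// pulling system: elastic-network receptor beads, a single ligand bead
// bound by Morse pairs, harmonic position restraints on a masked bead
// subset, and a constant-velocity harmonic pulling spring on the ligand
// along +Z.
//
// Update per bead and axis: dx = (F/gamma) dt + sqrt(2 kBT dt / gamma) xi.
//
// Randomness comes from a self-contained splitmix64 generator with
// Box-Muller normals, so trajectories are bit-reproducible for a given
// (seed, trajectory index) on any platform, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1]
  double unif() { return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0); }
  bool cached = false;
  double cache = 0.0;
  double norm() {
    if (cached) { cached = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    cache = r * std::sin(th);
    cached = true;
    return r * std::cos(th);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_pull")]]
List cpp_run_pull(NumericMatrix bead_xyz,   // n x 3, nm
                  NumericVector lig_xyz,    // length 3, nm
                  IntegerMatrix bonds,      // m x 2, 0-based bead indices
                  NumericVector bond_r0,    // m, nm
                  double k_net,             // kJ/mol/nm^2
                  IntegerVector morse_idx,  // 0-based bead indices
                  double morse_D,           // kJ/mol
                  double morse_a,           // 1/nm
                  double morse_r0,          // nm
                  IntegerVector mask,       // 0-based restrained beads
                  double k_restraint,       // kJ/mol/nm^2
                  double k_spring,          // kJ/mol/nm^2
                  double v,                 // nm/ps
                  double gamma,             // kJ mol^-1 ps nm^-2
                  double kBT,               // kJ/mol
                  double dt,                // ps
                  int n_steps,
                  int record_every,
                  int frame_every,
                  bool freeze_ligand,
                  double box_bound,
                  uint32_t seed,
                  uint32_t stream) {
  const int n = bead_xyz.nrow();
  const int m = bonds.nrow();
  std::vector<double> x(3 * (n + 1));
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = bead_xyz(i, d);
  for (int d = 0; d < 3; ++d) x[3 * n + d] = lig_xyz[d];
  std::vector<double> x0(x);  // restraint anchors + ligand start
  std::vector<double> f(3 * (n + 1));
  std::vector<char> restrained(n, 0);
  for (int i = 0; i < mask.size(); ++i) restrained[mask[i]] = 1;

  SplitMix rng(0x9e3779b97f4a7c15ULL * (uint64_t)seed +
               0xbf58476d1ce4e5b9ULL * (uint64_t)(stream + 1));

  const double z0 = x0[3 * n + 2];
  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_f(n_rec), rec_z(n_rec);
  const int n_frames = (frame_every > 0) ? n_steps / frame_every + 1 : 0;
  List frames(n_frames);
  const double mob = dt / gamma;
  const double sig = (kBT > 0.0) ? std::sqrt(2.0 * kBT * dt / gamma) : 0.0;

  int i_rec = 0, i_frame = 0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    // pulling spring on the ligand, along +Z
    const double f_pull = k_spring * (z0 + v * t - x[3 * n + 2]);

    if (step % record_every == 0) {
      rec_t[i_rec] = t;
      rec_f[i_rec] = f_pull;
      rec_z[i_rec] = x[3 * n + 2] - z0;
      ++i_rec;
    }
    if (frame_every > 0 && step % frame_every == 0) {
      NumericMatrix fr(n + 1, 3);
      for (int i = 0; i <= n; ++i)
        for (int d = 0; d < 3; ++d) fr(i, d) = x[3 * i + d];
      frames[i_frame++] = fr;
    }
    if (step == n_steps) break;

    std::fill(f.begin(), f.end(), 0.0);
    // elastic network
    for (int b = 0; b < m; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fmag = -k_net * (r - bond_r0[b]) / r;
      f[3 * i] += fmag * dx;     f[3 * j] -= fmag * dx;
      f[3 * i + 1] += fmag * dy; f[3 * j + 1] -= fmag * dy;
      f[3 * i + 2] += fmag * dz; f[3 * j + 2] -= fmag * dz;
    }
    // Morse binding between ligand and pocket beads
    if (morse_D > 0.0) {
      for (int q = 0; q < morse_idx.size(); ++q) {
        const int j = morse_idx[q];
        double dx = x[3 * n] - x[3 * j];
        double dy = x[3 * n + 1] - x[3 * j + 1];
        double dz = x[3 * n + 2] - x[3 * j + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-12) continue;
        double e = std::exp(-morse_a * (r - morse_r0));
        // dV/dr = 2 D a e (1 - e); force on ligand = -dV/dr * rhat
        double fmag = -2.0 * morse_D * morse_a * e * (1.0 - e) / r;
        f[3 * n] += fmag * dx;     f[3 * j] -= fmag * dx;
        f[3 * n + 1] += fmag * dy; f[3 * j + 1] -= fmag * dy;
        f[3 * n + 2] += fmag * dz; f[3 * j + 2] -= fmag * dz;
      }
    }
    // position restraints
    if (k_restraint > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (!restrained[i]) continue;
        for (int d = 0; d < 3; ++d)
          f[3 * i + d] += -k_restraint * (x[3 * i + d] - x0[3 * i + d]);
      }
    }
    // pulling spring
    f[3 * n + 2] += f_pull;

    for (int i = 0; i <= n; ++i) {
      if (freeze_ligand && i == n) continue;
      for (int d = 0; d < 3; ++d) {
        x[3 * i + d] += mob * f[3 * i + d] + sig * rng.norm();
        if (std::fabs(x[3 * i + d]) > box_bound)
          stop("numerical blow-up at step %d (bead %d)", step, i);
      }
    }
  }

  NumericMatrix final_xyz(n + 1, 3);
  for (int i = 0; i <= n; ++i)
    for (int d = 0; d < 3; ++d) final_xyz(i, d) = x[3 * i + d];

  return List::create(_["time"] = rec_t, _["force"] = rec_f,
                      _["displacement"] = rec_z, _["frames"] = frames,
                      _["final"] = final_xyz);
}
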