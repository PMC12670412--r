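#include <Rcpp.h>
using namespace Rcpp;

// Fold a coordinate into [0, L] by repeated specular reflection.
// This is the exact folding map, so the marginal law of the reflected
// Brownian path at the saved times is exact for any step size.
static inline double reflect(double z, double L) {
  if (z >= 0.0 && z <= L) return z;
  double p = std::fmod(z, 2.0 * L);
  if (p < 0.0) p += 2.0 * L;
  return (p <= L) ? p : 2.0 * L - p;
}

// Anisotropic Brownian propagator, optionally confined between reflecting
// walls at 0 and L along the third axis. Returns saved frames (including
// the initial one) as a [nSaved x nPart x 3] array. Lateral coordinates
// are returned unwrapped; wrapping into the periodic box is done in R.
// [[Rcpp::export(name = ".cppBrownian")]]
NumericVector cppBrownian(NumericMatrix x0, int nSteps, int saveStride,
                          double sigPar, double sigPerp, double L,
                          bool confined) {
  const int nPart = x0.nrow();
  const int nSaved = nSteps / saveStride + 1;
  NumericVector out(Dimension(nSaved, nPart, 3));
  std::vector<double> x(nPart), y(nPart), z(nPart);
  for (int i = 0; i < nPart; ++i) {
    x[i] = x0(i, 0);
    y[i] = x0(i, 1);
    z[i] = confined ? reflect(x0(i, 2), L) : x0(i, 2);
  }
  auto save = [&](int s) {
    for (int i = 0; i < nPart; ++i) {
      out[s + nSaved * i] = x[i];
      out[s + nSaved * (nPart + i)] = y[i];
      out[s + nSaved * (2 * nPart + i)] = z[i];
    }
  };
  save(0);
  int s = 1;
  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < nPart; ++i) {
      x[i] += sigPar * norm_rand();
      y[i] += sigPar * norm_rand();
      double zn = z[i] + sigPerp * norm_rand();
      z[i] = confined ? reflect(zn, L) : zn;
    }
    if (step % saveStride == 0) save(s++);
  }
  return out;
}

// Rotational diffusion on the unit sphere: tangent-space Gaussian step of
// scale sigma (= sqrt(2 D_r dt) per tangent component) followed by
// renormalization. Cone restriction (u . axis >= cosCone) by rejection of
// steps leaving the cone. Returns [nSaved x nRotor x 3].
// [[Rcpp::export(name = ".cppRotor")]]
NumericVector cppRotor(NumericMatrix u0, int nSteps, int saveStride,
                       double sigma, bool cone, double cosCone,
                       NumericVector axis) {
  const int nRot = u0.nrow();
  const int nSaved = nSteps / saveStride + 1;
  NumericVector out(Dimension(nSaved, nRot, 3));
  std::vector<double> ux(nRot), uy(nRot), uz(nRot);
  const double ax = axis[0], ay = axis[1], az = axis[2];
  for (int i = 0; i < nRot; ++i) {
    ux[i] = u0(i, 0); uy[i] = u0(i, 1); uz[i] = u0(i, 2);
  }
  auto save = [&](int s) {
    for (int i = 0; i < nRot; ++i) {
      out[s + nSaved * i] = ux[i];
      out[s + nSaved * (nRot + i)] = uy[i];
      out[s + nSaved * (2 * nRot + i)] = uz[i];
    }
  };
  save(0);
  int s = 1;
  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < nRot; ++i) {
      double gx = sigma * norm_rand();
      double gy = sigma * norm_rand();
      double gz = sigma * norm_rand();
      double dot = gx * ux[i] + gy * uy[i] + gz * uz[i];
      double vx = ux[i] + gx - dot * ux[i];
      double vy = uy[i] + gy - dot * uy[i];
      double vz = uz[i] + gz - dot * uz[i];
      double n = std::sqrt(vx * vx + vy * vy + vz * vz);
      vx /= n; vy /= n; vz /= n;
      if (!cone || vx * ax + vy * ay + vz * az >= cosCone) {
        ux[i] = vx; uy[i] = vy; uz[i] = vz;
      }
    }
    if (step % saveStride == 0) save(s++);
  }
  return out;
}
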