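// Reaction-diffusion core for the optical calcium-uncaging simulator.
//
// Operator-split loop per substep: photolysis -> explicit 5-point diffusion
// (zero-flux boundaries) -> per-pixel competitive binding equilibrium
// (rapid-buffering approximation) -> Hill-gated assembly relaxation.
// Calcium transport uses the standard rapid-buffer flux decomposition
//   dCa_total/dt = D_ca lap(free) + sum_j D_j lap(bound_j).
// Assembly is a phase change of the protein only: assembled material is
// immobile and capped at a maximum density, but keeps binding calcium with
// the same 1:1 equilibrium as the soluble pool, so only the soluble share
// of protein-bound calcium enters the transport flux.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monotone mass-balance solve: f + sum_j B_j f/(K_j+f) = T.
// Safeguarded Newton within [0, T]; falls back to bisection steps.
static inline double solve_pixel(const double T, const double *B,
                                 const double *K, const int ns,
                                 double f0, const double tol) {
  if (T <= 0.0) return 0.0;
  double lo = 0.0, hi = T;
  double f = (f0 > 0.0 && f0 < T) ? f0 : 0.5 * T;
  for (int it = 0; it < 200; ++it) {
    double g = f - T, gp = 1.0;
    for (int j = 0; j < ns; ++j) {
      const double d = K[j] + f;
      g += B[j] * f / d;
      gp += B[j] * K[j] / (d * d);
    }
    if (g > 0.0) hi = f; else lo = f;
    const double step = g / gp;
    double fn = f - step;
    if (fn <= lo || fn >= hi) fn = 0.5 * (lo + hi); // bisection safeguard
    if (std::fabs(fn - f) < tol && std::fabs(g) < 1e-10 * (T > 1.0 ? T : 1.0)) {
      f = fn;
      break;
    }
    f = fn;
  }
  return f;
}

// [[Rcpp::export]]
NumericVector solve_free_ca_cpp(NumericVector total, NumericMatrix B,
                                NumericVector K, double tol) {
  const int n = total.size(), ns = K.size();
  NumericVector out(n);
  std::vector<double> Brow(ns), Kv(K.begin(), K.end());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ns; ++j) Brow[j] = B(i, j);
    out[i] = solve_pixel(total[i], Brow.data(), Kv.data(), ns, -1.0, tol);
  }
  return out;
}

// Zero-flux 5-point Laplacian of src (ny x nx, column-major) scaled by
// coef, accumulated into dst.
static void add_laplacian(const double *src, double *dst, const int ny,
                          const int nx, const double coef) {
  if (coef == 0.0) return;
  for (int j = 0; j < nx; ++j) {
    const int jm = (j == 0) ? 0 : j - 1;
    const int jp = (j == nx - 1) ? nx - 1 : j + 1;
    for (int i = 0; i < ny; ++i) {
      const int im = (i == 0) ? 0 : i - 1;
      const int ip = (i == ny - 1) ? ny - 1 : i + 1;
      const double c = src[i + ny * j];
      dst[i + ny * j] += coef * (src[im + ny * j] + src[ip + ny * j] +
                                 src[i + ny * jm] + src[i + ny * jp] - 4.0 * c);
    }
  }
}

// [[Rcpp::export]]
List sim_core_run(List totals, NumericMatrix assembled, NumericMatrix caEx,
                  NumericMatrix freeInit, NumericVector Kd, NumericVector D,
                  double Dca, int idxCaged, int idxPhot, int idxTcb2,
                  int idxRhod, LogicalVector roiMask, double pixelSize,
                  double dt, int stepsPerFrame, int nFrames, double tStart,
                  double pulseStart, double pulseDur, double kEff,
                  double hillN, double hillK, double hyst, double kAsm,
                  double kDis, double cutoff, double capA, double tol) {
  const int ny = assembled.nrow(), nx = assembled.ncol(), npx = ny * nx;
  const int ns = Kd.size();
  const double inv_h2 = 1.0 / (pixelSize * pixelSize);

  // working copies (column-major vectors)
  std::vector<std::vector<double>> S(ns, std::vector<double>(npx));
  for (int j = 0; j < ns; ++j) {
    NumericMatrix m = totals[j];
    std::copy(m.begin(), m.end(), S[j].begin());
  }
  std::vector<double> A(assembled.begin(), assembled.end());
  std::vector<double> Ca(caEx.begin(), caEx.end());
  std::vector<double> F(freeInit.begin(), freeInit.end());
  std::vector<std::vector<double>> Bnd(ns, std::vector<double>(npx, 0.0));
  std::vector<double> scratch(npx);
  std::vector<double> Brow(ns), Kv(Kd.begin(), Kd.end());

  NumericVector outFree(npx * nFrames), outBoundRhod(npx * nFrames),
      outBoundT(npx * nFrames), outPhi(npx * nFrames);

  const double logK = std::log(hillK);

  // per-pixel equilibrium partition; updates F and Bnd. The protein's
  // binding capacity is soluble + assembled; Bnd[idxTcb2] holds the total.
  auto equilibrate = [&]() {
    for (int i = 0; i < npx; ++i) {
      for (int j = 0; j < ns; ++j) Brow[j] = S[j][i];
      if (idxTcb2 >= 0) Brow[idxTcb2] += A[i];
      const double f =
          solve_pixel(Ca[i], Brow.data(), Kv.data(), ns, F[i], tol);
      F[i] = f;
      for (int j = 0; j < ns; ++j) Bnd[j][i] = Brow[j] * f / (Kd[j] + f);
    }
  };

  equilibrate();
  double t = tStart;

  for (int fr = 0; fr < nFrames; ++fr) {
    for (int st = 0; st < stepsPerFrame; ++st) {
      // --- photolysis: caged -> photolyzed inside ROI during the pulse
      if (kEff > 0.0 && idxCaged >= 0 && idxPhot >= 0 &&
          t + 0.5 * dt >= pulseStart && t + 0.5 * dt < pulseStart + pulseDur) {
        const double frac = 1.0 - std::exp(-kEff * dt);
        std::vector<double> &C = S[idxCaged], &P = S[idxPhot];
        for (int i = 0; i < npx; ++i)
          if (roiMask[i]) {
            const double dm = C[i] * frac;
            C[i] -= dm;
            P[i] += dm;
          }
      }

      // --- diffusion (explicit, zero-flux)
      for (int j = 0; j < ns; ++j) {
        if (D[j] <= 0.0) continue;
        std::copy(S[j].begin(), S[j].end(), scratch.begin());
        add_laplacian(scratch.data(), S[j].data(), ny, nx,
                      D[j] * dt * inv_h2);
      }
      // calcium: flux through free + each mobile bound form
      std::copy(Ca.begin(), Ca.end(), scratch.begin());
      {
        std::vector<double> delta(npx, 0.0);
        add_laplacian(F.data(), delta.data(), ny, nx, Dca * dt * inv_h2);
        for (int j = 0; j < ns; ++j) {
          if (D[j] <= 0.0) continue;
          if (j == idxTcb2) {
            // only calcium on soluble monomers moves
            std::vector<double> mob(npx);
            for (int i = 0; i < npx; ++i) {
              const double tot = S[j][i] + A[i];
              mob[i] = (tot > 1e-12) ? Bnd[j][i] * S[j][i] / tot : 0.0;
            }
            add_laplacian(mob.data(), delta.data(), ny, nx, D[j] * dt * inv_h2);
          } else {
            add_laplacian(Bnd[j].data(), delta.data(), ny, nx,
                          D[j] * dt * inv_h2);
          }
        }
        for (int i = 0; i < npx; ++i) {
          Ca[i] = scratch[i] + delta[i];
          if (Ca[i] < 0.0) Ca[i] = 0.0;
        }
      }

      // --- rapid-buffering equilibrium
      equilibrate();

      // --- Hill-gated assembly relaxation with hysteresis: moves protein
      // between the soluble and the immobile assembled pools; calcium
      // binding re-equilibrates at the next substep.
      if (idxTcb2 >= 0 && (kAsm > 0.0 || kDis > 0.0)) {
        std::vector<double> &Ts = S[idxTcb2], &Bt = Bnd[idxTcb2];
        for (int i = 0; i < npx; ++i) {
          const double tot = Ts[i] + A[i];
          if (tot <= 1e-12) continue;
          double p = 0.0;
          if (Bt[i] > 0.0)
            p = 1.0 / (1.0 + std::exp(-hillN * (std::log(Bt[i]) - logK)));
          const double phi = A[i] / tot;
          if (p > phi && A[i] < capA) {
            double dA = kAsm * (p - phi) * tot * dt;
            if (dA > Ts[i]) dA = Ts[i];
            if (dA > capA - A[i]) dA = capA - A[i];
            A[i] += dA;
            Ts[i] -= dA;
          } else if (phi < cutoff && p < (1.0 - hyst) * phi) {
            double dA = kDis * (phi - p) * tot * dt;
            if (dA > A[i]) dA = A[i];
            A[i] -= dA;
            Ts[i] += dA;
          }
        }
      }
      t += dt;
    }

    // frame snapshot on a freshly equilibrated state
    equilibrate();
    double *pf = &outFree[npx * fr], *pr = &outBoundRhod[npx * fr];
    double *pb = &outBoundT[npx * fr], *pp = &outPhi[npx * fr];
    for (int i = 0; i < npx; ++i) {
      pf[i] = F[i];
      pr[i] = (idxRhod >= 0) ? Bnd[idxRhod][i] : 0.0;
      pb[i] = (idxTcb2 >= 0) ? Bnd[idxTcb2][i] : 0.0;
      const double tot = (idxTcb2 >= 0) ? S[idxTcb2][i] + A[i] : 0.0;
      pp[i] = (tot > 1e-12) ? A[i] / tot : 0.0;
    }
  }

  // final state back to R
  List outTotals(ns);
  for (int j = 0; j < ns; ++j) {
    NumericMatrix m(ny, nx);
    std::copy(S[j].begin(), S[j].end(), m.begin());
    outTotals[j] = m;
  }
  outTotals.names() = totals.names();
  NumericMatrix mA(ny, nx), mCa(ny, nx), mF(ny, nx);
  std::copy(A.begin(), A.end(), mA.begin());
  std::copy(Ca.begin(), Ca.end(), mCa.begin());
  std::copy(F.begin(), F.end(), mF.begin());

  IntegerVector dims = IntegerVector::create(ny, nx, nFrames);
  outFree.attr("dim") = dims;
  outBoundRhod.attr("dim") = dims;
  outBoundT.attr("dim") = dims;
  outPhi.attr("dim") = dims;

  return List::create(
      _["free"] = outFree, _["boundRhod"] = outBoundRhod,
      _["boundTcb2"] = outBoundT, _["phi"] = outPhi,
      _["finalTotals"] = outTotals, _["finalAssembled"] = mA,
      _["finalCaEx"] = mCa, _["finalFree"] = mF, _["elapsed"] = t);
}
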