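#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Release freed heap pages back to the OS after large transient
// allocations (frame buffers, label grids); no-op on non-glibc platforms.
// [[Rcpp::export]]
void cpp_release_memory() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// ---------------------------------------------------------------------------
// Random sequential adsorption of spheres with a cell list.
// Candidates (drawn in R so the RNG stream stays R-side) are tried in order;
// a candidate is accepted iff its center is at least r_i + r_j away from every
// accepted center. Stops after reaching `target_n` accepted spheres or
// `max_rej` consecutive rejections (jamming).
// [[Rcpp::export]]
List cpp_rsa_insert(NumericMatrix cand, NumericVector cand_r,
                    NumericMatrix acc, NumericVector acc_r,
                    NumericVector dims, int target_n, int max_rej,
                    int consec_rej) {
  const int nc = cand.nrow();
  int na = acc.nrow();
  double rmax = 1e-6;
  for (int i = 0; i < na; ++i) rmax = std::max(rmax, acc_r[i]);
  for (int i = 0; i < nc; ++i) rmax = std::max(rmax, cand_r[i]);
  const double cell = 2.0 * rmax;
  const int gx = std::max(1, (int)std::floor(dims[0] / cell));
  const int gy = std::max(1, (int)std::floor(dims[1] / cell));
  const int gz = std::max(1, (int)std::floor(dims[2] / cell));
  auto cidx = [&](double x, double y, double z) {
    int ix = std::min(gx - 1, std::max(0, (int)std::floor(x / dims[0] * gx)));
    int iy = std::min(gy - 1, std::max(0, (int)std::floor(y / dims[1] * gy)));
    int iz = std::min(gz - 1, std::max(0, (int)std::floor(z / dims[2] * gz)));
    return ix + gx * (iy + gy * iz);
  };
  std::vector<std::vector<int>> cells((size_t)gx * gy * gz);
  std::vector<double> X, Y, Z, R;
  X.reserve(na + nc); Y.reserve(na + nc); Z.reserve(na + nc); R.reserve(na + nc);
  for (int i = 0; i < na; ++i) {
    X.push_back(acc(i, 0)); Y.push_back(acc(i, 1)); Z.push_back(acc(i, 2));
    R.push_back(acc_r[i]);
    cells[cidx(acc(i, 0), acc(i, 1), acc(i, 2))].push_back(i);
  }
  std::vector<int> accepted;
  bool jammed = false, reached = (na >= target_n);
  for (int i = 0; i < nc && !jammed && !reached; ++i) {
    const double x = cand(i, 0), y = cand(i, 1), z = cand(i, 2), r = cand_r[i];
    bool ok = true;
    int ix0 = std::max(0, (int)std::floor(x / dims[0] * gx) - 1);
    int iy0 = std::max(0, (int)std::floor(y / dims[1] * gy) - 1);
    int iz0 = std::max(0, (int)std::floor(z / dims[2] * gz) - 1);
    int ix1 = std::min(gx - 1, ix0 + 2), iy1 = std::min(gy - 1, iy0 + 2),
        iz1 = std::min(gz - 1, iz0 + 2);
    for (int cz = iz0; cz <= iz1 && ok; ++cz)
      for (int cy = iy0; cy <= iy1 && ok; ++cy)
        for (int cx = ix0; cx <= ix1 && ok; ++cx) {
          for (int id : cells[cx + gx * (cy + gy * cz)]) {
            const double dx = x - X[id], dy = y - Y[id], dz = z - Z[id];
            const double s = r + R[id];
            if (dx * dx + dy * dy + dz * dz < s * s) { ok = false; break; }
          }
        }
    if (ok) {
      int id = (int)X.size();
      X.push_back(x); Y.push_back(y); Z.push_back(z); R.push_back(r);
      cells[cidx(x, y, z)].push_back(id);
      accepted.push_back(i + 1);  // 1-based index into candidates
      consec_rej = 0;
      if ((int)X.size() >= target_n) reached = true;
    } else {
      if (++consec_rej >= max_rej) jammed = true;
    }
  }
  return List::create(_["accepted"] = wrap(accepted),
                      _["consec_rej"] = consec_rej,
                      _["jammed"] = jammed, _["reached"] = reached);
}

// ---------------------------------------------------------------------------
// Voxel label grid: +id for the fluorescent shell of neuron id, -id for its
// nucleus, 0 elsewhere. Membership is tested at voxel centers; non-overlap of
// somata guarantees unique labels.
// [[Rcpp::export]]
IntegerVector cpp_label_grid(NumericVector x, NumericVector y, NumericVector z,
                             NumericVector soma, NumericVector nuc,
                             IntegerVector nvox, NumericVector vox) {
  const int nx = nvox[0], ny = nvox[1], nz = nvox[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < x.size(); ++j) {
    const double r = soma[j], rn = nuc[j];
    int ix0 = std::max(0, (int)std::floor((x[j] - r) / vox[0] - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((x[j] + r) / vox[0] - 0.5));
    int iy0 = std::max(0, (int)std::floor((y[j] - r) / vox[1] - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((y[j] + r) / vox[1] - 0.5));
    int iz0 = std::max(0, (int)std::floor((z[j] - r) / vox[2] - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((z[j] + r) / vox[2] - 0.5));
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = (iz + 0.5) * vox[2] - z[j];
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = (iy + 0.5) * vox[1] - y[j];
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = (ix + 0.5) * vox[0] - x[j];
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= r * r) {
            lab[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)] =
                d2 <= rn * rn ? -(j + 1) : (j + 1);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Scan excitation ellipsoids over the pixel grid. For pixel p the ellipsoid is
// centered at (cx,cy,cz)[p], its axial semi-axis (FWHM/2) directed along the
// unit normal (nx,ny,nz)[p]. `binary` support counts voxels inside the
// ellipsoid with weight 1; the Gaussian option weights voxels by
// exp(-4 ln2 (l2/lat^2 + t^2/ax^2)).
// Returns per-(pixel,neuron) shell and occupied weight sums plus per-pixel
// totals (all voxels in the excitation volume, including outside the grid).
// [[Rcpp::export]]
List cpp_scan_excitation(IntegerVector lab, IntegerVector nvox,
                         NumericVector voxsz, int n_neurons,
                         NumericVector cx, NumericVector cy, NumericVector cz,
                         NumericVector ux, NumericVector uy, NumericVector uz,
                         NumericVector lat_fwhm, NumericVector ax_fwhm,
                         bool binary) {
  const int nx = nvox[0], ny = nvox[1], nz = nvox[2];
  const int npx = cx.size();
  const double log16 = 4.0 * std::log(2.0);
  std::vector<double> shell_acc(n_neurons + 1, 0.0), occ_acc(n_neurons + 1, 0.0);
  std::vector<int> touched;
  std::vector<int> out_i, out_j;
  std::vector<double> out_shell, out_occ;
  NumericVector tot(npx), tot_in(npx);
  for (int p = 0; p < npx; ++p) {
    const double aL = lat_fwhm[p] / 2.0, aA = ax_fwhm[p] / 2.0;
    const double scale = binary ? 1.0 : 2.0;
    const double x0 = cx[p], y0 = cy[p], z0 = cz[p];
    const double nxv = ux[p], nyv = uy[p], nzv = uz[p];
    // per-axis half-extent of the tilted ellipsoid's bounding box:
    // h_e = sqrt(aA^2 n_e^2 + aL^2 (1 - n_e^2)) for unit axis e
    const double hx = scale * std::sqrt(aA * aA * nxv * nxv +
                                        aL * aL * (1.0 - nxv * nxv));
    const double hy = scale * std::sqrt(aA * aA * nyv * nyv +
                                        aL * aL * (1.0 - nyv * nyv));
    const double hz = scale * std::sqrt(aA * aA * nzv * nzv +
                                        aL * aL * (1.0 - nzv * nzv));
    int ix0 = (int)std::floor((x0 - hx) / voxsz[0] - 0.5);
    int ix1 = (int)std::ceil((x0 + hx) / voxsz[0] - 0.5);
    int iy0 = (int)std::floor((y0 - hy) / voxsz[1] - 0.5);
    int iy1 = (int)std::ceil((y0 + hy) / voxsz[1] - 0.5);
    int iz0 = (int)std::floor((z0 - hz) / voxsz[2] - 0.5);
    int iz1 = (int)std::ceil((z0 + hz) / voxsz[2] - 0.5);
    double totw = 0.0, totw_in = 0.0;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = (iz + 0.5) * voxsz[2] - z0;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = (iy + 0.5) * voxsz[1] - y0;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = (ix + 0.5) * voxsz[0] - x0;
          const double t = dx * nxv + dy * nyv + dz * nzv;
          const double l2 = dx * dx + dy * dy + dz * dz - t * t;
          double w;
          if (binary) {
            w = (l2 / (aL * aL) + (t * t) / (aA * aA) <= 1.0) ? 1.0 : 0.0;
          } else {
            const double e = l2 / (lat_fwhm[p] * lat_fwhm[p]) +
                             (t * t) / (ax_fwhm[p] * ax_fwhm[p]);
            w = e <= 4.0 ? std::exp(-log16 * e) : 0.0;
          }
          if (w <= 0.0) continue;
          totw += w;
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
            continue;
          totw_in += w;
          const int l = lab[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
          if (l != 0) {
            const int id = l > 0 ? l : -l;
            if (occ_acc[id] == 0.0 && shell_acc[id] == 0.0) touched.push_back(id);
            occ_acc[id] += w;
            if (l > 0) shell_acc[id] += w;
          }
        }
      }
    }
    if (totw == 0.0) {
      // degenerate support (ellipsoid smaller than the voxel spacing):
      // fall back to the voxel containing the ellipsoid center
      const int ix = (int)std::lround(x0 / voxsz[0] - 0.5);
      const int iy = (int)std::lround(y0 / voxsz[1] - 0.5);
      const int iz = (int)std::lround(z0 / voxsz[2] - 0.5);
      totw = 1.0;
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        totw_in = 1.0;
        const int l = lab[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
        if (l != 0) {
          const int id = l > 0 ? l : -l;
          if (occ_acc[id] == 0.0 && shell_acc[id] == 0.0) touched.push_back(id);
          occ_acc[id] += 1.0;
          if (l > 0) shell_acc[id] += 1.0;
        }
      }
    }
    tot[p] = totw;
    tot_in[p] = totw_in;
    for (int id : touched) {
      out_i.push_back(p + 1);
      out_j.push_back(id);
      out_shell.push_back(shell_acc[id]);
      out_occ.push_back(occ_acc[id]);
      shell_acc[id] = 0.0;
      occ_acc[id] = 0.0;
    }
    touched.clear();
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["shell"] = wrap(out_shell), _["occ"] = wrap(out_occ),
                      _["total"] = tot, _["total_inside"] = tot_in);
}

// ---------------------------------------------------------------------------
// Difference of two first-order recursive exponential filters: the exact
// discrete convolution of x with the difference-of-exponentials sensor
// kernel (up to the peak-normalizing gain applied in R).
// [[Rcpp::export]]
NumericVector cpp_double_exp(NumericVector x, double a_decay, double a_rise) {
  const int n = x.size();
  NumericVector out(n);
  double yd = 0.0, yr = 0.0;
  for (int i = 0; i < n; ++i) {
    yd = a_decay * yd + x[i];
    yr = a_rise * yr + x[i];
    out[i] = yd - yr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full linear sensor pipeline for a set of neurons: spike bins -> double
// exponential kernel drive -> baseline offset -> bin-averaged output grid.
// spike_list holds 1-based bin indices (repeated for multi-spike bins).
// [[Rcpp::export]]
NumericMatrix cpp_spikes_to_traces(List spike_list, int n_bins,
                                   double a_decay, double a_rise, double gain,
                                   double baseline, IntegerVector grp,
                                   int n_out) {
  const int nn = spike_list.size();
  NumericMatrix out(n_out, nn);
  std::vector<double> x(n_bins);
  std::vector<int> counts(n_out, 0);
  for (int i = 0; i < n_bins; ++i) counts[grp[i] - 1]++;
  const int *g = INTEGER(grp);
  for (int j = 0; j < nn; ++j) {
    std::fill(x.begin(), x.end(), 0.0);
    IntegerVector s = spike_list[j];
    for (int k = 0; k < s.size(); ++k) x[s[k] - 1] += 1.0;
    double *col = &out(0, j);
    double yd = 0.0, yr = 0.0;
    for (int i = 0; i < n_bins; ++i) {
      yd = a_decay * yd + x[i];
      yr = a_rise * yr + x[i];
      col[g[i] - 1] += yd - yr;
    }
    for (int r = 0; r < n_out; ++r)
      col[r] = baseline * (1.0 + gain * col[r] / counts[r]);
  }
  return out;
}

// type-7 quantile of buf (modified in place) for probability p
static double quantile7(std::vector<double> &buf, double p) {
  const int m = (int)buf.size();
  const double h = (m - 1) * p;
  const int k = (int)std::floor(h);
  std::nth_element(buf.begin(), buf.begin() + k, buf.end());
  double q = buf[k];
  if (h > k && k + 1 <= m - 1) {
    std::nth_element(buf.begin() + k + 1, buf.begin() + k + 1, buf.end());
    q += (h - k) * (buf[k + 1] - q);
  }
  return q;
}

// ---------------------------------------------------------------------------
// Per-frame extraction pass: for every frame (column of fr) compute each
// box's percentile-band ROI mean, the maximum intensity inside boxes, and
// the background (mean over pixels in no box, above the corner-noise mean
// and below the box maximum). Mirrors the R reference implementation
// (percentile_band_mean) exactly.
// [[Rcpp::export]]
List cpp_extract_chunk(NumericMatrix fr, List px_list, double lo, double hi,
                       LogicalVector in_box, IntegerVector edge_px) {
  const int nfr = fr.ncol(), npx = fr.nrow(), nb = px_list.size();
  NumericMatrix F(nfr, std::max(nb, 1));
  NumericVector bg(nfr);
  LogicalVector bg_ok(nfr);
  std::vector<std::vector<int>> boxes(nb);
  for (int b = 0; b < nb; ++b) {
    IntegerVector p = px_list[b];
    boxes[b].assign(p.begin(), p.end());
  }
  std::vector<double> vals, buf;
  for (int f = 0; f < nfr; ++f) {
    const double *v = &fr(0, f);
    double box_max = R_NegInf;
    for (int b = 0; b < nb; ++b) {
      const std::vector<int> &px = boxes[b];
      const int m = (int)px.size();
      vals.resize(m);
      for (int i = 0; i < m; ++i) {
        vals[i] = v[px[i] - 1];
        box_max = std::max(box_max, vals[i]);
      }
      buf = vals;
      // upper band edge first; the lower one is then found inside the left
      // partition, which holds the k2+1 smallest values
      const double h2 = (m - 1) * hi;
      const int k2 = (int)std::floor(h2);
      std::nth_element(buf.begin(), buf.begin() + k2, buf.end());
      double q2 = buf[k2];
      if (h2 > k2 && k2 + 1 <= m - 1) {
        std::nth_element(buf.begin() + k2 + 1, buf.begin() + k2 + 1, buf.end());
        q2 += (h2 - k2) * (buf[k2 + 1] - q2);
      }
      const double h1 = (m - 1) * lo;
      const int k1 = (int)std::floor(h1);
      std::nth_element(buf.begin(), buf.begin() + k1, buf.begin() + k2 + 1);
      double q1 = buf[k1];
      if (h1 > k1 && k1 + 1 <= m - 1) {
        auto hi_end = (k1 + 1 <= k2) ? buf.begin() + k2 + 1 : buf.end();
        std::nth_element(buf.begin() + k1 + 1, buf.begin() + k1 + 1, hi_end);
        q1 += (h1 - k1) * (buf[k1 + 1] - q1);
      }
      double s = 0.0;
      int c = 0;
      for (int i = 0; i < m; ++i)
        if (vals[i] >= q1 && vals[i] <= q2) { s += vals[i]; ++c; }
      if (c == 0) {
        // fallback: largest value not exceeding the lower band edge
        double vle = R_NegInf;
        for (int i = 0; i < m; ++i)
          if (vals[i] <= q1) vle = std::max(vle, vals[i]);
        for (int i = 0; i < m; ++i)
          if (vals[i] >= vle) { s += vals[i]; ++c; }
      }
      F(f, b) = s / c;
    }
    if (nb == 0) box_max = R_PosInf;
    double corner = R_NegInf;
    if (edge_px.size()) {
      double s = 0.0;
      for (int i = 0; i < edge_px.size(); ++i) s += v[edge_px[i] - 1];
      corner = s / edge_px.size();
    }
    double s = 0.0;
    int c = 0;
    for (int p = 0; p < npx; ++p)
      if (!in_box[p] && v[p] > corner && v[p] < box_max) { s += v[p]; ++c; }
    bg_ok[f] = c > 0;
    bg[f] = c > 0 ? s / c : NA_REAL;
  }
  return List::create(_["F"] = F, _["bg"] = bg, _["bg_ok"] = bg_ok);
}

// ---------------------------------------------------------------------------
// Sliding-window quantile (R type-7 convention) with windows truncated at the
// trace ends; used for the dF/F0 baseline.
// [[Rcpp::export]]
NumericVector cpp_running_quantile(NumericVector x, int halfwin, double p) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  for (int t = 0; t < n; ++t) {
    const int lo = std::max(0, t - halfwin), hi = std::min(n - 1, t + halfwin);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    out[t] = quantile7(buf, p);
  }
  return out;
}
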