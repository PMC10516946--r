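#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Z-buffer rasterizer for a triangle mesh already transformed into camera
// space (camera at origin, looking down -z, y up).  Perspective projection
// with square frames; pixel centers at half-integer coordinates, image
// origin top-left.  Returns camera-space face normals (flipped toward the
// camera: meshes may be open, so shading is two-sided), depth normalized
// over [near, far], and a per-pixel face-id buffer (1-based; 0 = background)
// that gives SurfGradCAM its exact pixel-to-face inverse mapping.
// [[Rcpp::export(name = ".rasterize_cpp")]]
List rasterize_cpp(NumericMatrix verts, IntegerMatrix faces, int res,
                   double tan_half_fov, double near_d, double far_d,
                   double clip_d) {
  const int nf = faces.nrow();
  NumericMatrix nx(res, res), ny(res, res), nz(res, res), depth(res, res);
  IntegerMatrix face_id(res, res);
  NumericMatrix zbuf(res, res);
  std::fill(zbuf.begin(), zbuf.end(), R_PosInf);
  std::fill(depth.begin(), depth.end(), 1.0);
  std::fill(nx.begin(), nx.end(), 0.5);
  std::fill(ny.begin(), ny.end(), 0.5);
  std::fill(nz.begin(), nz.end(), 0.5);

  const double half = res / 2.0;

  for (int f = 0; f < nf; ++f) {
    double vx[3], vy[3], vz[3], px[3], py[3], w[3];
    bool skip = false;
    for (int k = 0; k < 3; ++k) {
      int vi = faces(f, k) - 1;
      vx[k] = verts(vi, 0);
      vy[k] = verts(vi, 1);
      vz[k] = verts(vi, 2);
      if (vz[k] >= -clip_d) { skip = true; break; }  // behind clip plane
      w[k] = 1.0 / (-vz[k]);
      // NDC in [-1,1], then pixel coordinates (x right, y down)
      px[k] = (vx[k] * w[k] / tan_half_fov + 1.0) * half;
      py[k] = (1.0 - vy[k] * w[k] / tan_half_fov) * half;
    }
    if (skip) continue;

    // face normal in camera space, flipped toward the camera
    double e1x = vx[1] - vx[0], e1y = vy[1] - vy[0], e1z = vz[1] - vz[0];
    double e2x = vx[2] - vx[0], e2y = vy[2] - vy[0], e2z = vz[2] - vz[0];
    double fnx = e1y * e2z - e1z * e2y;
    double fny = e1z * e2x - e1x * e2z;
    double fnz = e1x * e2y - e1y * e2x;
    double nn = std::sqrt(fnx * fnx + fny * fny + fnz * fnz);
    if (nn < 1e-300) continue;  // degenerate triangle
    fnx /= nn; fny /= nn; fnz /= nn;
    double cx = (vx[0] + vx[1] + vx[2]) / 3.0;
    double cy = (vy[0] + vy[1] + vy[2]) / 3.0;
    double cz = (vz[0] + vz[1] + vz[2]) / 3.0;
    if (fnx * cx + fny * cy + fnz * cz > 0) { fnx = -fnx; fny = -fny; fnz = -fnz; }

    // signed area in pixel space; orient edge functions so inside > 0
    double area = (px[1] - px[0]) * (py[2] - py[0]) -
                  (py[1] - py[0]) * (px[2] - px[0]);
    if (std::fabs(area) < 1e-12) continue;
    double sgn = area > 0 ? 1.0 : -1.0;

    int jmin = std::max(0, (int)std::floor(std::min(std::min(px[0], px[1]), px[2]) - 0.5));
    int jmax = std::min(res - 1, (int)std::ceil(std::max(std::max(px[0], px[1]), px[2]) - 0.5));
    int imin = std::max(0, (int)std::floor(std::min(std::min(py[0], py[1]), py[2]) - 0.5));
    int imax = std::min(res - 1, (int)std::ceil(std::max(std::max(py[0], py[1]), py[2]) - 0.5));

    for (int i = imin; i <= imax; ++i) {
      double yc = i + 0.5;
      for (int j = jmin; j <= jmax; ++j) {
        double xc = j + 0.5;
        double e0 = sgn * ((px[1] - px[0]) * (yc - py[0]) -
                           (py[1] - py[0]) * (xc - px[0]));
        double e1 = sgn * ((px[2] - px[1]) * (yc - py[1]) -
                           (py[2] - py[1]) * (xc - px[1]));
        double e2 = sgn * ((px[0] - px[2]) * (yc - py[2]) -
                           (py[0] - py[2]) * (xc - px[2]));
        if (e0 < 0 || e1 < 0 || e2 < 0) continue;
        double asum = e0 + e1 + e2;
        if (asum <= 0) continue;
        // barycentric in screen space: weight opposite each vertex
        double b0 = e1 / asum, b1 = e2 / asum, b2 = e0 / asum;
        double winv = b0 * w[0] + b1 * w[1] + b2 * w[2];
        double zcam = 1.0 / winv;  // positive distance along -z
        if (zcam < zbuf(i, j)) {
          zbuf(i, j) = zcam;
          double d = (zcam - near_d) / (far_d - near_d);
          depth(i, j) = d < 0 ? 0.0 : (d > 1 ? 1.0 : d);
          nx(i, j) = (fnx + 1.0) / 2.0;
          ny(i, j) = (fny + 1.0) / 2.0;
          nz(i, j) = (fnz + 1.0) / 2.0;
          face_id(i, j) = f + 1;
        }
      }
    }
  }
  return List::create(_["nx"] = nx, _["ny"] = ny, _["nz"] = nz,
                      _["depth"] = depth, _["face_id"] = face_id);
}
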