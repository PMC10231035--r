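#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

// Inside test on the rasterized mask; an absent mask means free space.
// Matches the R-level semantics: floor cell within bounds and mask TRUE.
inline bool inside(const int *mask, int nx, int ny, int nz,
                   double x, double y, double z) {
  if (mask == nullptr) return true;
  double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
  if (fx < 0 || fy < 0 || fz < 0 || fx >= nx || fy >= ny || fz >= nz)
    return false;
  int ix = (int)fx, iy = (int)fy, iz = (int)fz;
  return mask[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] != 0;
}

} // namespace

// Walk one fiber: start position plus sequential increments; a step whose
// endpoint falls outside the allowed region is not carried out (the
// increment is consumed and the unchanged position is recorded).
// Returns the full trajectory (n_steps + 1 positions) and rejection count.
// [[Rcpp::export]]
List walk_fiber_cpp(NumericMatrix incr, NumericVector start,
                    Nullable<LogicalVector> mask_, IntegerVector dims) {
  const int n = incr.nrow();
  if (incr.ncol() != 3 || start.size() != 3)
    stop("increments must be n x 3 and start length 3");
  const int *mask = nullptr;
  int nx = 0, ny = 0, nz = 0;
  LogicalVector mv;
  if (mask_.isNotNull()) {
    mv = mask_.get();
    if (dims.size() != 3) stop("dims must have length 3");
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    if ((R_xlen_t)nx * ny * nz != mv.size()) stop("mask size mismatch");
    mask = LOGICAL(mv);
  }
  double x = start[0], y = start[1], z = start[2];
  if (!inside(mask, nx, ny, nz, x, y, z))
    stop("internal invariant violated: start position is outside the volume");
  NumericMatrix pos(n + 1, 3);
  pos(0, 0) = x; pos(0, 1) = y; pos(0, 2) = z;
  int rejected = 0;
  for (int s = 0; s < n; ++s) {
    double cx = x + incr(s, 0), cy = y + incr(s, 1), cz = z + incr(s, 2);
    if (inside(mask, nx, ny, nz, cx, cy, cz)) {
      x = cx; y = cy; z = cz;
    } else {
      ++rejected;
    }
    pos(s + 1, 0) = x; pos(s + 1, 1) = y; pos(s + 1, 2) = z;
  }
  return List::create(_["positions"] = pos, _["rejected"] = rejected);
}

// Walk one fiber and stream its positions straight into pooled bin counts
// (bins of bin_cells^3 grid cells) without retaining the trajectory.
// The starting position is tallied; a rejected step tallies the unchanged
// position unless count_rejected is false. Returns the rejection count.
// [[Rcpp::export]]
int walk_accumulate_cpp(NumericMatrix incr, NumericVector start,
                        LogicalVector mask, IntegerVector dims,
                        IntegerVector counts, IntegerVector bin_dims,
                        int bin_cells, bool count_rejected) {
  const int n = incr.nrow();
  if (incr.ncol() != 3 || start.size() != 3)
    stop("increments must be n x 3 and start length 3");
  if (dims.size() != 3 || bin_dims.size() != 3 || bin_cells < 1)
    stop("bad binning arguments");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != mask.size()) stop("mask size mismatch");
  const int bx = bin_dims[0], by = bin_dims[1], bz = bin_dims[2];
  if ((R_xlen_t)bx * by * bz != counts.size()) stop("counts size mismatch");
  const int *m = LOGICAL(mask);
  int *cnt = INTEGER(counts);
  double x = start[0], y = start[1], z = start[2];
  if (!inside(m, nx, ny, nz, x, y, z))
    stop("internal invariant violated: start position is outside the volume");
  auto tally = [&](double px, double py, double pz) {
    int ix = (int)std::floor(px) / bin_cells;
    int iy = (int)std::floor(py) / bin_cells;
    int iz = (int)std::floor(pz) / bin_cells;
    cnt[ix + (R_xlen_t)bx * (iy + (R_xlen_t)by * iz)] += 1;
  };
  tally(x, y, z);
  int rejected = 0;
  for (int s = 0; s < n; ++s) {
    double cx = x + incr(s, 0), cy = y + incr(s, 1), cz = z + incr(s, 2);
    if (inside(m, nx, ny, nz, cx, cy, cz)) {
      x = cx; y = cy; z = cz;
      tally(x, y, z);
    } else {
      ++rejected;
      if (count_rejected) tally(x, y, z);
    }
  }
  return rejected;
}
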