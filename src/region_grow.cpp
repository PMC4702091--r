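#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// Best-first seeded region growing on one axial slice.
//
// The region mean is initialized from the 3x3 neighbourhood of the seed
// (count 1) and updated incrementally as voxels are admitted. At each step
// the highest-intensity frontier voxel (4-connectivity) is examined; it is
// admitted iff its intensity >= frac * current region mean. Best-first order
// makes the stopping rule order-deterministic: when the best candidate
// fails, every other frontier candidate fails too, and growth stops.
//
// img: nx x ny slice; si, sj: 1-based seed indices; frac: criterion fraction.
// [[Rcpp::export(name = ".growRegionCpp")]]
List growRegionCpp(NumericMatrix img, int si, int sj, double frac) {
  const int nx = img.nrow(), ny = img.ncol();
  if (si < 1 || si > nx || sj < 1 || sj > ny)
    stop("seed outside slice");
  if (si == 1 || si == nx || sj == 1 || sj == ny)
    stop("seed lies on the slice border");
  const int s0 = si - 1, s1 = sj - 1;

  double nb = 0.0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      nb += img(s0 + di, s1 + dj);
  nb /= 9.0;

  const double seedVal = img(s0, s1);
  if (seedVal <= 0.0)
    stop("seed intensity must be positive");

  std::vector<int> regI, regJ;
  std::vector<double> accI, accT;

  // degenerate seed: its own intensity fails the criterion against the
  // neighbourhood mean; return a single-voxel region for QC to flag
  bool degenerate = seedVal < frac * nb;

  // state: 0 unseen, 2 member (frontier entries may duplicate; checked on pop)
  std::vector<unsigned char> state((size_t)nx * ny, 0);
  typedef std::pair<double, int> QE; // (intensity, linear index)
  std::priority_queue<QE> pq;

  double sum = nb; // seed contributes the neighbourhood mean
  int cnt = 1;
  state[(size_t)s1 * nx + s0] = 2;
  regI.push_back(s0); regJ.push_back(s1);
  accI.push_back(seedVal); accT.push_back(frac * nb);

  const int DI[4] = {1, -1, 0, 0};
  const int DJ[4] = {0, 0, 1, -1};

  if (!degenerate) {
    for (int k = 0; k < 4; ++k) {
      int i = s0 + DI[k], j = s1 + DJ[k];
      if (i >= 0 && i < nx && j >= 0 && j < ny)
        pq.push(QE(img(i, j), j * nx + i));
    }
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int lin = top.second;
      if (state[lin] == 2) continue;
      double thr = frac * sum / cnt;
      if (top.first < thr) break; // best candidate fails -> all fail
      int i = lin % nx, j = lin / nx;
      state[lin] = 2;
      regI.push_back(i); regJ.push_back(j);
      accI.push_back(top.first); accT.push_back(thr);
      sum += top.first; ++cnt;
      for (int k = 0; k < 4; ++k) {
        int i2 = i + DI[k], j2 = j + DJ[k];
        if (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny) {
          int lin2 = j2 * nx + i2;
          if (state[lin2] != 2) pq.push(QE(img(i2, j2), lin2));
        }
      }
    }
  }

  const int n = (int)regI.size();
  IntegerMatrix region(n, 2);
  bool border = false;
  for (int r = 0; r < n; ++r) {
    region(r, 0) = regI[r] + 1;
    region(r, 1) = regJ[r] + 1;
    if (regI[r] == 0 || regI[r] == nx - 1 || regJ[r] == 0 || regJ[r] == ny - 1)
      border = true;
  }

  return List::create(
    _["region"] = region,
    _["regionMean"] = sum / cnt,
    _["acceptIntensity"] = NumericVector(accI.begin(), accI.end()),
    _["acceptThreshold"] = NumericVector(accT.begin(), accT.end()),
    _["touchesBorder"] = border,
    _["degenerate"] = degenerate);
}
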