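#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Iso-surface of a binary 3D field at level 0.5 by tetrahedral decomposition:
// each grid cell (8 voxel centers) is split into six tetrahedra around the
// main diagonal, and each tetrahedron is triangulated independently. The
// 6-tet split triangulates every cell face with the same diagonal as its
// neighbour, so the mesh is watertight by construction and has none of the
// ambiguous cases of cube-based lookup tables. Crossing vertices lie at edge
// midpoints (binary field), so coordinates are exact multiples of 0.5 in
// index space and welding is exact.

namespace {

struct VertexWelder {
  std::unordered_map<uint64_t, int> map;
  std::vector<double> coords; // x,y,z triples in index space
  uint64_t stride_y, stride_z;
  VertexWelder(int nx, int ny, int) {
    stride_y = (uint64_t)(2 * nx + 2);
    stride_z = stride_y * (uint64_t)(2 * ny + 2);
  }
  int add(double x, double y, double z) {
    uint64_t kx = (uint64_t)(2.0 * x + 0.5);
    uint64_t ky = (uint64_t)(2.0 * y + 0.5);
    uint64_t kz = (uint64_t)(2.0 * z + 0.5);
    uint64_t key = kx + ky * stride_y + kz * stride_z;
    auto it = map.find(key);
    if (it != map.end()) return it->second;
    int id = (int)(coords.size() / 3);
    map.emplace(key, id);
    coords.push_back(x); coords.push_back(y); coords.push_back(z);
    return id;
  }
};

inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

} // namespace

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *m = LOGICAL(mask);
  auto at = [&](int x, int y, int z) -> bool {
    return m[x + (size_t)nx * (y + (size_t)ny * z)] != 0;
  };

  // 6 tetrahedra around the main diagonal corner0 -> corner7
  // corner index bit layout: bit0 = +x, bit1 = +y, bit2 = +z
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };

  VertexWelder weld(nx, ny, nz);
  std::vector<int> faces; // 0-based vertex id triples

  double cpos[8][3];
  bool cin[8];

  // emit triangle (a,b,c), orienting the normal from inside toward outside
  auto emit = [&](const double *pa, const double *pb, const double *pc,
                  const double inC[3], const double outC[3]) {
    double e1[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
    double e2[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
    double n[3];
    cross3(e1, e2, n);
    double d[3] = {outC[0] - inC[0], outC[1] - inC[1], outC[2] - inC[2]};
    double s = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    int ia = weld.add(pa[0], pa[1], pa[2]);
    int ib = weld.add(pb[0], pb[1], pb[2]);
    int ic = weld.add(pc[0], pc[1], pc[2]);
    if (s >= 0) { faces.push_back(ia); faces.push_back(ib); faces.push_back(ic); }
    else        { faces.push_back(ia); faces.push_back(ic); faces.push_back(ib); }
  };

  for (int z = 0; z + 1 < nz; ++z)
  for (int y = 0; y + 1 < ny; ++y)
  for (int x = 0; x + 1 < nx; ++x) {
    int nin = 0;
    for (int c = 0; c < 8; ++c) {
      int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
      cpos[c][0] = x + dx; cpos[c][1] = y + dy; cpos[c][2] = z + dz;
      cin[c] = at(x + dx, y + dy, z + dz);
      nin += cin[c];
    }
    if (nin == 0 || nin == 8) continue;

    for (int t = 0; t < 6; ++t) {
      const int *tv = tets[t];
      int ins[4], outs[4], ni = 0, no = 0;
      for (int k = 0; k < 4; ++k) {
        if (cin[tv[k]]) ins[ni++] = tv[k]; else outs[no++] = tv[k];
      }
      if (ni == 0 || ni == 4) continue;

      double inC[3] = {0, 0, 0}, outC[3] = {0, 0, 0};
      for (int k = 0; k < ni; ++k)
        for (int d = 0; d < 3; ++d) inC[d] += cpos[ins[k]][d] / ni;
      for (int k = 0; k < no; ++k)
        for (int d = 0; d < 3; ++d) outC[d] += cpos[outs[k]][d] / no;

      auto mid = [&](int a, int b, double out[3]) {
        out[0] = 0.5 * (cpos[a][0] + cpos[b][0]);
        out[1] = 0.5 * (cpos[a][1] + cpos[b][1]);
        out[2] = 0.5 * (cpos[a][2] + cpos[b][2]);
      };

      if (ni == 1 || ni == 3) {
        // one vertex isolated on its side: single triangle of edge midpoints
        int apex = (ni == 1) ? ins[0] : outs[0];
        const int *other = (ni == 1) ? outs : ins;
        double p0[3], p1[3], p2[3];
        mid(apex, other[0], p0);
        mid(apex, other[1], p1);
        mid(apex, other[2], p2);
        emit(p0, p1, p2, inC, outC);
      } else {
        // 2 in / 2 out: quad split into two triangles
        double q0[3], q1[3], q2[3], q3[3];
        mid(ins[0], outs[0], q0);
        mid(ins[0], outs[1], q1);
        mid(ins[1], outs[1], q2);
        mid(ins[1], outs[0], q3);
        emit(q0, q1, q2, inC, outC);
        emit(q0, q2, q3, inC, outC);
      }
    }
  }

  int nv = (int)(weld.coords.size() / 3);
  int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = weld.coords[3 * i];
    V(i, 1) = weld.coords[3 * i + 1];
    V(i, 2) = weld.coords[3 * i + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i] + 1; // 1-based for R
    F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
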