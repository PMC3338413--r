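#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Element-by-element kernels. Conventions shared with the R side:
//  - K is the 24x24 unit-modulus element kernel (column-major, as R stores it)
//  - `dofs` is 24 x Ne: 1-based free-variable ids, 0 marks a prescribed dof
//  - `vals` is 24 x Ne: prescribed displacement at the 0-slots (0 elsewhere)
//  - `gdofs` is 24 x Ne: 1-based indices into the full (3 x Vx x Vy x Vz)
//    displacement/force array, defined for every slot
// All loops run in fixed element order so results are bit-reproducible.

// y = A u on free dofs (prescribed dofs contribute nothing)
// [[Rcpp::export]]
NumericVector ebe_apply_cpp(const NumericMatrix& K, const IntegerMatrix& dofs,
                            const NumericVector& mod, const NumericVector& u,
                            const int n_free) {
  const int ne = dofs.ncol();
  if (u.size() != n_free) stop("displacement vector has wrong length");
  NumericVector out(n_free);
  const double* Kp = K.begin();
  double ul[24], f[24];
  for (int e = 0; e < ne; ++e) {
    const double m = mod[e];
    const int* de = &dofs(0, e);
    for (int l = 0; l < 24; ++l) ul[l] = de[l] > 0 ? u[de[l] - 1] : 0.0;
    for (int r = 0; r < 24; ++r) f[r] = 0.0;
    for (int c = 0; c < 24; ++c) {
      const double uc = ul[c];
      if (uc == 0.0) continue;
      const double* Kc = Kp + 24 * c;
      for (int r = 0; r < 24; ++r) f[r] += Kc[r] * uc;
    }
    for (int l = 0; l < 24; ++l)
      if (de[l] > 0) out[de[l] - 1] += m * f[l];
  }
  return out;
}

// B = -(forces induced on free dofs when prescribed dofs take their values)
// [[Rcpp::export]]
NumericVector ebe_rhs_cpp(const NumericMatrix& K, const IntegerMatrix& dofs,
                          const NumericMatrix& vals, const NumericVector& mod,
                          const int n_free) {
  const int ne = dofs.ncol();
  NumericVector out(n_free);
  const double* Kp = K.begin();
  double ul[24], f[24];
  for (int e = 0; e < ne; ++e) {
    const double m = mod[e];
    const int* de = &dofs(0, e);
    const double* ve = &vals(0, e);
    bool any = false;
    for (int l = 0; l < 24; ++l) {
      ul[l] = de[l] > 0 ? 0.0 : ve[l];
      if (ul[l] != 0.0) any = true;
    }
    if (!any) continue;
    for (int r = 0; r < 24; ++r) f[r] = 0.0;
    for (int c = 0; c < 24; ++c) {
      const double uc = ul[c];
      if (uc == 0.0) continue;
      const double* Kc = Kp + 24 * c;
      for (int r = 0; r < 24; ++r) f[r] += Kc[r] * uc;
    }
    for (int l = 0; l < 24; ++l)
      if (de[l] > 0) out[de[l] - 1] -= m * f[l];
  }
  return out;
}

// assembled diagonal of A on free dofs
// [[Rcpp::export]]
NumericVector ebe_diag_cpp(const NumericVector& Kdiag, const IntegerMatrix& dofs,
                           const NumericVector& mod, const int n_free) {
  const int ne = dofs.ncol();
  NumericVector out(n_free);
  for (int e = 0; e < ne; ++e) {
    const double m = mod[e];
    const int* de = &dofs(0, e);
    for (int l = 0; l < 24; ++l)
      if (de[l] > 0) out[de[l] - 1] += m * Kdiag[l];
  }
  return out;
}

// total vertex forces from a full displacement field (all dofs, incl. prescribed)
// [[Rcpp::export]]
NumericVector ebe_forces_full_cpp(const NumericMatrix& K, const IntegerMatrix& gdofs,
                                  const NumericVector& mod, const NumericVector& full_u,
                                  const int n_total) {
  const int ne = gdofs.ncol();
  NumericVector out(n_total);
  const double* Kp = K.begin();
  double ul[24], f[24];
  for (int e = 0; e < ne; ++e) {
    const double m = mod[e];
    const int* ge = &gdofs(0, e);
    for (int l = 0; l < 24; ++l) ul[l] = full_u[ge[l] - 1];
    for (int r = 0; r < 24; ++r) f[r] = 0.0;
    for (int c = 0; c < 24; ++c) {
      const double uc = ul[c];
      if (uc == 0.0) continue;
      const double* Kc = Kp + 24 * c;
      for (int r = 0; r < 24; ++r) f[r] += Kc[r] * uc;
    }
    for (int l = 0; l < 24; ++l) out[ge[l] - 1] += m * f[l];
  }
  return out;
}

// per-element strain energy 0.5 m u'Ku from a full displacement field
// [[Rcpp::export]]
NumericVector ebe_energy_cpp(const NumericMatrix& K, const IntegerMatrix& gdofs,
                             const NumericVector& mod, const NumericVector& full_u) {
  const int ne = gdofs.ncol();
  NumericVector out(ne);
  const double* Kp = K.begin();
  double ul[24];
  for (int e = 0; e < ne; ++e) {
    const int* ge = &gdofs(0, e);
    for (int l = 0; l < 24; ++l) ul[l] = full_u[ge[l] - 1];
    double en = 0.0;
    for (int c = 0; c < 24; ++c) {
      const double uc = ul[c];
      if (uc == 0.0) continue;
      const double* Kc = Kp + 24 * c;
      double s = 0.0;
      for (int r = 0; r < 24; ++r) s += Kc[r] * ul[r];
      en += s * uc;
    }
    out[e] = 0.5 * mod[e] * en;
  }
  return out;
}

// summed force over marked slots (used by the per-iteration stress monitor on
// the loaded-face element subset); prescribed slots take their boundary values
// [[Rcpp::export]]
double ebe_face_force_cpp(const NumericMatrix& K, const IntegerMatrix& dofs,
                          const NumericMatrix& vals, const NumericVector& mod,
                          const NumericVector& u, const IntegerMatrix& mask) {
  const int ne = dofs.ncol();
  const double* Kp = K.begin();
  double ul[24];
  double total = 0.0;
  for (int e = 0; e < ne; ++e) {
    const double m = mod[e];
    const int* de = &dofs(0, e);
    const double* ve = &vals(0, e);
    const int* me = &mask(0, e);
    for (int l = 0; l < 24; ++l) ul[l] = de[l] > 0 ? u[de[l] - 1] : ve[l];
    for (int r = 0; r < 24; ++r) {
      if (!me[r]) continue;
      const double* Kr = Kp + r;
      double s = 0.0;
      for (int c = 0; c < 24; ++c) s += Kr[24 * c] * ul[c];
      total += m * s;
    }
  }
  return total;
}

// connected-component labels of active voxels under vertex-sharing
// (26-neighbour) connectivity; 0 = inactive, components numbered from 1
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector& active, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = active.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!active[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int i = (int)(v % nx);
      const int j = (int)((v / nx) % ny);
      const int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (active[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
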