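// Voxel hexahedral finite-element kernels.
//
// All elements are identical cubes of edge h, so a single reference
// stiffness matrix (unit modulus) is cached and scaled per element by its
// modulus.  The solver is a matrix-free Jacobi-preconditioned conjugate
// gradient: the operator product gathers element displacement vectors into
// a 24 x n_e matrix, multiplies by the reference stiffness with one dgemm,
// scales columns by element moduli and scatter-adds.  Dirichlet constraints
// are homogeneous and enforced by projection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// local corner offsets (dx, dy, dz) consistent with the natural coordinate
// signs used when building the reference stiffness
static const int HEX_DX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
static const int HEX_DY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int HEX_DZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

// [[Rcpp::export]]
arma::mat cpp_hex8_stiffness(double nu, double h) {
  // 8-node trilinear hexahedron, E = 1, edge length h (mm), 2x2x2 Gauss
  arma::mat K(24, 24, arma::fill::zeros);
  const double g = 1.0 / std::sqrt(3.0);
  const double xi_a[8]   = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double eta_a[8]  = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double zeta_a[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

  arma::mat D(6, 6, arma::fill::zeros);
  const double c = 1.0 / ((1.0 + nu) * (1.0 - 2.0 * nu));
  D(0, 0) = D(1, 1) = D(2, 2) = (1.0 - nu) * c;
  D(0, 1) = D(0, 2) = D(1, 0) = D(1, 2) = D(2, 0) = D(2, 1) = nu * c;
  D(3, 3) = D(4, 4) = D(5, 5) = 0.5 / (1.0 + nu);

  const double jac = h / 2.0;          // dx/dxi
  const double detJ = jac * jac * jac; // per Gauss point (weights are 1)

  for (int gx = 0; gx < 2; ++gx)
    for (int gy = 0; gy < 2; ++gy)
      for (int gz = 0; gz < 2; ++gz) {
        const double xi = (gx == 0 ? -g : g);
        const double eta = (gy == 0 ? -g : g);
        const double zeta = (gz == 0 ? -g : g);
        arma::mat B(6, 24, arma::fill::zeros);
        for (int a = 0; a < 8; ++a) {
          const double dNdxi = 0.125 * xi_a[a] * (1 + eta_a[a] * eta) *
                               (1 + zeta_a[a] * zeta) / jac;
          const double dNdeta = 0.125 * (1 + xi_a[a] * xi) * eta_a[a] *
                                (1 + zeta_a[a] * zeta) / jac;
          const double dNdzeta = 0.125 * (1 + xi_a[a] * xi) *
                                 (1 + eta_a[a] * eta) * zeta_a[a] / jac;
          B(0, 3 * a) = dNdxi;
          B(1, 3 * a + 1) = dNdeta;
          B(2, 3 * a + 2) = dNdzeta;
          B(3, 3 * a) = dNdeta;     B(3, 3 * a + 1) = dNdxi;
          B(4, 3 * a + 1) = dNdzeta; B(4, 3 * a + 2) = dNdeta;
          B(5, 3 * a) = dNdzeta;    B(5, 3 * a + 2) = dNdxi;
        }
        K += B.t() * D * B * detJ;
      }
  return K;
}

// gather per-element displacement columns
static void gather_u(const arma::ivec &en, const arma::vec &u, arma::mat &Ug) {
  const arma::uword ne = Ug.n_cols;
  for (arma::uword e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) {
      const arma::sword n = en[e * 8 + a];
      Ug(3 * a, e) = u[3 * n];
      Ug(3 * a + 1, e) = u[3 * n + 1];
      Ug(3 * a + 2, e) = u[3 * n + 2];
    }
  }
}

// y = K u (matrix-free), fixed dofs projected out by the caller
static void apply_K(const arma::mat &Kref, const arma::ivec &en,
                    const arma::vec &E, const arma::vec &u, arma::mat &Ug,
                    arma::mat &KU, arma::vec &y) {
  const arma::uword ne = E.n_elem;
  gather_u(en, u, Ug);
  KU = Kref * Ug;
  y.zeros();
  for (arma::uword e = 0; e < ne; ++e) {
    const double Ee = E[e];
    for (int a = 0; a < 8; ++a) {
      const arma::sword n = en[e * 8 + a];
      y[3 * n] += Ee * KU(3 * a, e);
      y[3 * n + 1] += Ee * KU(3 * a + 1, e);
      y[3 * n + 2] += Ee * KU(3 * a + 2, e);
    }
  }
}

// [[Rcpp::export]]
List cpp_fe_pcg(const arma::mat &Kref, const arma::imat &elem_nodes,
                const arma::vec &E, arma::vec f,
                const arma::uvec &fixed_dofs, double tol, int maxit,
                Nullable<NumericVector> u0 = R_NilValue) {
  const arma::uword ne = elem_nodes.n_rows;
  const arma::uword ndof = f.n_elem;
  if (E.n_elem != ne) stop("element modulus vector length mismatch");

  // flatten element connectivity row-major (element-contiguous)
  arma::ivec en(ne * 8);
  for (arma::uword e = 0; e < ne; ++e)
    for (int a = 0; a < 8; ++a) en[e * 8 + a] = elem_nodes(e, a);

  // Jacobi preconditioner from scattered reference diagonal
  arma::vec Kdiag = Kref.diag();
  arma::vec diag(ndof, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e)
    for (int a = 0; a < 8; ++a) {
      const arma::sword n = en[e * 8 + a];
      diag[3 * n] += E[e] * Kdiag[3 * a];
      diag[3 * n + 1] += E[e] * Kdiag[3 * a + 1];
      diag[3 * n + 2] += E[e] * Kdiag[3 * a + 2];
    }
  diag.elem(arma::find(diag == 0.0)).ones();
  for (arma::uword k = 0; k < fixed_dofs.n_elem; ++k) diag[fixed_dofs[k]] = 1.0;
  f.elem(fixed_dofs).zeros();

  arma::vec u(ndof, arma::fill::zeros);
  if (u0.isNotNull()) {
    u = as<arma::vec>(u0.get());
    if (u.n_elem != ndof) stop("warm-start vector length mismatch");
    u.elem(fixed_dofs).zeros();
  }

  const double normf = arma::norm(f);
  std::vector<double> history;
  if (normf == 0.0) {
    return List::create(_["u"] = arma::vec(ndof, arma::fill::zeros),
                        _["iterations"] = 0, _["relres"] = 0.0,
                        _["history"] = history, _["converged"] = true);
  }

  arma::mat Ug(24, ne), KU(24, ne);
  arma::vec r(ndof), q(ndof);
  apply_K(Kref, en, E, u, Ug, KU, q);
  q.elem(fixed_dofs).zeros();
  r = f - q;
  arma::vec z = r / diag;
  arma::vec p = z;
  double rz = arma::dot(r, z);
  double relres = arma::norm(r) / normf;
  int it = 0;
  bool converged = relres <= tol;

  while (!converged && it < maxit) {
    ++it;
    apply_K(Kref, en, E, p, Ug, KU, q);
    q.elem(fixed_dofs).zeros();
    const double pq = arma::dot(p, q);
    if (pq <= 0.0) stop("system matrix not positive definite (missing constraints?)");
    const double alpha = rz / pq;
    u += alpha * p;
    r -= alpha * q;
    relres = arma::norm(r) / normf;
    history.push_back(relres);
    if (relres <= tol) { converged = true; break; }
    z = r / diag;
    const double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }

  return List::create(_["u"] = u, _["iterations"] = it, _["relres"] = relres,
                      _["history"] = history, _["converged"] = converged);
}

// [[Rcpp::export]]
arma::vec cpp_element_energy(const arma::mat &Kref,
                             const arma::imat &elem_nodes, const arma::vec &E,
                             const arma::vec &u) {
  const arma::uword ne = elem_nodes.n_rows;
  arma::ivec en(ne * 8);
  for (arma::uword e = 0; e < ne; ++e)
    for (int a = 0; a < 8; ++a) en[e * 8 + a] = elem_nodes(e, a);
  arma::mat Ug(24, ne), KU(24, ne);
  gather_u(en, u, Ug);
  KU = Kref * Ug;
  arma::vec energy(ne);
  for (arma::uword e = 0; e < ne; ++e)
    energy[e] = 0.5 * E[e] * arma::dot(Ug.col(e), KU.col(e));
  return energy;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector &mask,
                                   const IntegerVector &dims,
                                   int connectivity = 6) {
  // connected component labelling on a 3-D voxel mask (6 or 26 neighbours)
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  const R_xlen_t sz = (R_xlen_t)nx * ny;

  std::vector<R_xlen_t> off;
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx + (R_xlen_t)dy * nx + (R_xlen_t)dz * sz);
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }
  const int nnb = (int)off.size();

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / sz);
      for (int k = 0; k < nnb; ++k) {
        const int xx = x + odx[k], yy = y + ody[k], zz = z + odz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t w = v + off[k];
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
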