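#' Solver settings for the voxel FE solve
#'
#' @param tol relative residual tolerance in (0, 1).
#' @param maxit maximum PCG iterations.
#' @param preconditioner currently `"jacobi"`.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-6, maxit = 20000,
                            preconditioner = "jacobi") {
  if (tol <= 0 || tol >= 1) stop("tolerance must lie in (0, 1)")
  preconditioner <- match.arg(preconditioner, "jacobi")
  structure(list(tol = tol, maxit = as.integer(maxit),
                 preconditioner = preconditioner),
            class = "solver_settings")
}

#' Low-level voxel FE model constructor
#'
#' Builds the node numbering, element connectivity and constraint set for
#' a set of cubic voxel elements on a regular grid.  One trilinear 8-node
#' hexahedral element per voxel; all elements share a cached unit-modulus
#' reference stiffness matrix scaled per element by its modulus.
#'
#' @param elem_ijk n_e x 3 integer matrix of voxel indices (1-based) on the
#'   grid.
#' @param dims length-3 voxel grid dimensions.
#' @param voxel_size element edge length (mm).
#' @param E element elastic moduli (MPa); scalar or length n_e.
#' @param poisson Poisson ratio (in [0, 0.5); the incompressible limit is
#'   unsupported).
#' @param constraint function taking an n_nodes x 3 matrix of node
#'   coordinates (mm, grid corner at 0) and returning an n_nodes x 3
#'   logical matrix of constrained displacement components.
#' @param labels optional per-element integer labels (e.g. 1 bone,
#'   2 cartilage).
#' @return object of class `fe_model`.
#' @export
fe_model <- function(elem_ijk, dims, voxel_size, E, poisson = 0.3,
                     constraint, labels = NULL) {
  elem_ijk <- as.matrix(elem_ijk)
  storage.mode(elem_ijk) <- "integer"
  if (poisson >= 0.5 || poisson < 0)
    stop("Poisson ratio must lie in [0, 0.5); the incompressible limit is unsupported")
  n_e <- nrow(elem_ijk)
  if (n_e < 1L) stop("model has no elements")
  if (length(E) == 1L) E <- rep(E, n_e)
  if (length(E) != n_e) stop("modulus vector length mismatch")
  if (any(E <= 0)) stop("element moduli must be positive")
  nd <- as.integer(dims) + 1L

  ## corner nodes of each element on the (dims + 1) node grid
  offs <- cbind(c(0L,1L,1L,0L,0L,1L,1L,0L),
                c(0L,0L,1L,1L,0L,0L,1L,1L),
                c(0L,0L,0L,0L,1L,1L,1L,1L))
  node_lin <- matrix(0L, n_e, 8)
  for (a in 1:8) {
    i <- elem_ijk[, 1] + offs[a, 1]
    j <- elem_ijk[, 2] + offs[a, 2]
    k <- elem_ijk[, 3] + offs[a, 3]
    node_lin[, a] <- (k - 1L) * (nd[1] * nd[2]) + (j - 1L) * nd[1] + i
  }
  used <- sort(unique(as.integer(node_lin)))
  lookup <- integer(prod(nd))
  lookup[used] <- seq_along(used)
  elem_nodes <- matrix(lookup[node_lin], n_e, 8)

  kk <- (used - 1L) %/% (nd[1] * nd[2])
  jj <- ((used - 1L) %% (nd[1] * nd[2])) %/% nd[1]
  ii <- (used - 1L) %% nd[1]
  node_xyz <- cbind(ii, jj, kk) * voxel_size

  fixed <- constraint(node_xyz)
  if (!is.matrix(fixed) || !identical(dim(fixed), c(length(used), 3L)))
    stop("constraint function must return an n_nodes x 3 logical matrix")
  fixed_dofs <- which(t(fixed))  # dof order (x, y, z) per node
  if (!length(fixed_dofs)) stop("constrained node set is empty")

  structure(list(
    elem_ijk = elem_ijk, elem_nodes = elem_nodes, dims = as.integer(dims),
    voxel_size = voxel_size, E = as.numeric(E), poisson = poisson,
    labels = if (is.null(labels)) rep(1L, n_e) else as.integer(labels),
    node_xyz = node_xyz, node_grid_id = used, node_lookup = lookup,
    n_nodes = length(used), fixed_dofs = as.integer(fixed_dofs),
    Kref = cpp_hex8_stiffness(poisson, voxel_size)),
    class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d elements, %d nodes (%d dofs), %d constrained dofs\n",
              nrow(x$elem_nodes), x$n_nodes, 3 * x$n_nodes,
              length(x$fixed_dofs)))
  invisible(x)
}

#' Build a voxel FE model from a segmented model
#'
#' One element per bone or cartilage voxel, linear elastic isotropic
#' materials, nodes on the lateral (x = 0) and distal (z = 0) crop faces
#' fully constrained.  Element components not connected (6-connectivity)
#' to a constrained face are removed with a warning.
#'
#' @param model a `segmented_model`.
#' @param bone_modulus bone elastic modulus (MPa; 10 GPa = 10000).
#' @param cartilage_modulus cartilage elastic modulus (MPa).
#' @param poisson Poisson ratio for both materials.
#' @return an `fe_model`; the element ordering fixes the element set shared
#'   by all SED fields of this model.
#' @export
build_model <- function(model, bone_modulus = 10000, cartilage_modulus = 10,
                        poisson = 0.3) {
  stopifnot(inherits(model, "segmented_model"))
  lab <- model$labels
  mask <- lab > 0L
  ## 26-connectivity: elements sharing any node are coupled
  comp <- cpp_label_components(mask, dim(lab), 26L)
  ## components touching the lateral (i = 1) or distal (k = 1) crop face
  face_labels <- setdiff(unique(c(comp[1, , ], comp[, , 1])), 0L)
  if (!length(face_labels))
    stop("no material connected to the constrained lateral/distal faces")
  keep <- mask & array(comp %in% face_labels, dim(lab))
  n_removed <- sum(mask) - sum(keep)
  if (n_removed > 0)
    warning(sprintf("removed %d floating voxel(s) not connected to the constrained boundary",
                    n_removed))
  idx <- which(keep)
  elem_ijk <- arrayInd(idx, dim(lab))
  labels <- lab[idx]
  E <- ifelse(labels == 1L, bone_modulus, cartilage_modulus)
  h <- model$voxel_size
  tol <- h * 1e-6
  fe <- fe_model(elem_ijk, dim(lab), h, E, poisson,
                 constraint = function(xyz) {
                   on_face <- xyz[, 1] < tol | xyz[, 3] < tol
                   matrix(on_face, length(on_face), 3)
                 },
                 labels = labels)
  fe$head_centre <- model$head_centre
  fe$head_radius <- model$head_radius
  fe$n_floating_removed <- n_removed
  fe
}

#' Solve one unit load case
#'
#' Matrix-free Jacobi-preconditioned conjugate gradient solve of
#' `K u = f`, followed by per-element strain energy density recovery
#' `U_e = (1/2 u_e' K_e u_e) / V_e` (MPa).
#'
#' @param fe an `fe_model`.
#' @param lc a `load_case` (nodal forces on the corner-node grid of the
#'   same segmented model), or a raw force vector of length
#'   `3 * fe$n_nodes`.
#' @param settings a `solver_settings`.
#' @param warm_start optional displacement vector from a previous solve.
#' @return object of class `sed_field`: per-element SED (all elements of
#'   the model, cartilage values flagged via `labels`), solver diagnostics
#'   and the load-case metadata needed downstream (reported resultant,
#'   inclination).
#' @export
solve_load_case <- function(fe, lc, settings = solver_settings(),
                            warm_start = NULL) {
  stopifnot(inherits(fe, "fe_model"))
  ndof <- 3L * fe$n_nodes
  if (inherits(lc, "load_case")) {
    cn <- fe$node_lookup[lc$nodes]
    if (any(cn == 0L))
      stop("load case references nodes outside the FE model")
    f <- numeric(ndof)
    for (c0 in 1:3) f[3L * (cn - 1L) + c0] <- f[3L * (cn - 1L) + c0] + lc$forces[, c0]
    meta <- list(resultant = lc$resultant, inclination = lc$inclination,
                 magnitude = lc$magnitude, spec = lc$spec)
  } else {
    f <- as.numeric(lc)
    if (length(f) != ndof) stop("force vector length mismatch")
    meta <- list(resultant = NULL, inclination = NA_real_,
                 magnitude = NA_real_, spec = NULL)
  }
  sol <- cpp_fe_pcg(fe$Kref, fe$elem_nodes - 1L, fe$E, f,
                    fe$fixed_dofs - 1L, settings$tol, settings$maxit,
                    warm_start)
  if (!sol$converged) {
    cond <- structure(
      class = c("femload_solver_error", "error", "condition"),
      list(message = sprintf("PCG did not converge in %d iterations (relres %.3g)",
                             sol$iterations, sol$relres),
           call = sys.call(), history = sol$history))
    stop(cond)
  }
  V <- fe$voxel_size^3
  energy <- cpp_element_energy(fe$Kref, fe$elem_nodes - 1L, fe$E, sol$u)
  structure(list(
    values = energy / V, labels = fe$labels,
    element_volume = V, n_elements = nrow(fe$elem_nodes),
    load_case_id = if (!is.null(meta$spec)) meta$inclination else NA_real_,
    resultant = meta$resultant, inclination = meta$inclination,
    magnitude = meta$magnitude,
    u = sol$u, f = f, iterations = sol$iterations, relres = sol$relres,
    history = sol$history), class = "sed_field")
}

#' @export
print.sed_field <- function(x, ...) {
  cat(sprintf("<sed_field> %d elements, inclination %s deg, PCG %d its (relres %.2g)\n",
              x$n_elements,
              ifelse(is.na(x$inclination), "?", format(x$inclination)),
              x$iterations, x$relres))
  invisible(x)
}

#' Write an SED field as a flat table
#'
#' @param sed a `sed_field`.
#' @param path output path (element index, label, SED in MPa).
#' @export
write_sed_table <- function(sed, path) {
  utils::write.table(
    data.frame(element = seq_len(sed$n_elements), label = sed$labels,
               sed_MPa = sed$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
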