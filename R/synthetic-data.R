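# Synthetic inputs: remodelling-adapted mini-joint structures with a known
# load history, CT-like grayscale renderings, and instrumented-prosthesis
# style load traces.

#' Forward remodelling parameters
#'
#' Parameters of the intermediate-density forward adaptation rule used to
#' grow synthetic structures: element modulus `E = base_modulus * rho^p`,
#' stimulus `S = U / rho` (SED per unit density), update
#' `rho <- clip(rho + step_size (S - target)/target, floor, 1)`.
#'
#' @param base_modulus full-density elastic modulus (MPa).
#' @param density_exponent modulus-density power `p`.
#' @param density_floor minimum relative density, in (0, 1).
#' @param step_size update gain (> 0).
#' @param target_stimulus remodelling equilibrium stimulus (MPa, > 0).
#' @param max_iterations iteration cap.
#' @param convergence_tol convergence threshold on mean |delta rho|.
#' @param seed RNG seed for the initial density perturbation.
#' @return object of class `remodelling_params`.
#' @export
remodelling_params <- function(base_modulus = 10000, density_exponent = 3,
                               density_floor = 0.1, step_size = 0.1,
                               target_stimulus = 0.02, max_iterations = 60,
                               convergence_tol = 1e-3, seed = 1) {
  if (density_floor <= 0 || density_floor >= 1)
    stop("density_floor must lie in (0, 1)")
  if (step_size <= 0) stop("step_size must be positive")
  if (target_stimulus <= 0) stop("target_stimulus must be positive")
  structure(list(base_modulus = base_modulus,
                 density_exponent = density_exponent,
                 density_floor = density_floor, step_size = step_size,
                 target_stimulus = target_stimulus,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol, seed = as.integer(seed)),
            class = "remodelling_params")
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Mini-joint synthetic domain
#'
#' A desk-scale stand-in for a proximal femur: a spherical head with a
#' hemispherical articular cap, an inclined cylindrical neck (narrower
#' than the head, giving the interior cross-section minimum the frame
#' construction relies on) and a distal support block whose bottom acts as
#' the fixed boundary.  Geometry is evaluated analytically at voxel
#' centres, so a rotated copy is exact rather than resampled.
#'
#' @param domain_shape integer voxel extents (length 1 or 3).
#' @param voxel_size voxel edge length (mm).
#' @param rotation 3 x 3 rotation applied to the canonical geometry about
#'   the domain centre; its columns are the true (medio-lateral,
#'   anterior-posterior, vertical) axes of the specimen.
#' @return list with `envelope` (logical array), `shell` (its one-voxel
#'   surface, the cortical-shell stand-in held at full density during
#'   remodelling), `head_centre`, `head_radius`, `neck_midpoint`,
#'   `neck_radius`, `axes`, `voxel_size`, `block_top` and `constraint`
#'   (node-constraint function for the distal block bottom).
#' @export
mini_joint_geometry <- function(domain_shape = c(48, 48, 48),
                                voxel_size = 0.5, rotation = diag(3)) {
  if (length(domain_shape) == 1L) domain_shape <- rep(domain_shape, 3L)
  d <- as.integer(domain_shape)
  h <- voxel_size
  Lv <- d * h
  L <- min(Lv)
  ctr <- Lv / 2

  C <- c(0.64 * Lv[1], 0.50 * Lv[2], 0.68 * Lv[3])
  R <- 0.20 * L
  r_neck <- 0.10 * L
  u <- c(-0.6, 0, -0.8)                # neck axis, head -> block
  block_lo <- c(0.06 * Lv[1], 0.22 * Lv[2], 0.04 * Lv[3])
  block_hi <- c(0.62 * Lv[1], 0.78 * Lv[2], 0.30 * Lv[3])
  t_end <- (C[3] - block_hi[3]) / (-u[3])

  ## voxel centres mapped into canonical coordinates
  gx <- (seq_len(d[1]) - 0.5) * h
  gy <- (seq_len(d[2]) - 0.5) * h
  gz <- (seq_len(d[3]) - 0.5) * h
  x <- cbind(rep(gx, times = d[2] * d[3]),
             rep(rep(gy, each = d[1]), times = d[3]),
             rep(gz, each = d[1] * d[2]))
  q <- sweep(sweep(x, 2, ctr) %*% rotation, 2, ctr, "+")

  rel <- sweep(q, 2, C)
  head <- rowSums(rel^2) <= R^2
  tt <- as.numeric(rel %*% u)
  rad2 <- rowSums((rel - outer(tt, u))^2)
  neck <- tt >= 0 & tt <= t_end & rad2 <= r_neck^2
  block <- q[, 1] >= block_lo[1] & q[, 1] <= block_hi[1] &
           q[, 2] >= block_lo[2] & q[, 2] <= block_hi[2] &
           q[, 3] >= block_lo[3] & q[, 3] <= block_hi[3]
  env <- array(head | neck | block, d)
  shell <- surface_mask(env)  # cortical shell, held at full density

  to_image <- function(p) as.numeric(rotation %*% (p - ctr) + ctr)
  z_cut <- block_lo[3] + 1.5 * h
  constraint <- function(node_xyz) {
    qz <- (sweep(node_xyz, 2, ctr) %*% rotation)[, 3] + ctr[3]
    matrix(qz <= z_cut, nrow(node_xyz), 3)
  }

  list(envelope = env, shell = shell, voxel_size = h,
       head_centre = to_image(C), head_radius = R,
       neck_midpoint = to_image(C + u * 0.5 * t_end), neck_radius = r_neck,
       axes = rotation, block_top = block_hi[3], domain_shape = d,
       constraint = constraint)
}

# 6-neighbourhood dilation of a logical 3-D mask
dilate6 <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (ax in 1:3) for (o in c(-1L, 1L)) {
    idx <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])
    out <- out | switch(ax, m[idx, , , drop = FALSE],
                        m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
  }
  out
}

# uniform parallel 1000 N unit load on the envelope head surface, returned
# as a full dof-force vector for the envelope FE model
envelope_unit_force <- function(fe, geom, inclination_deg,
                                opening_deg = 40, magnitude = 1000) {
  dvec <- as.numeric(geom$axes %*% frontal_direction(inclination_deg))
  pos <- sweep(fe$node_xyz, 2, geom$head_centre)
  rad <- sqrt(rowSums(pos^2))
  surf_vox <- surface_mask(geom$envelope)
  surf_nodes <- node_stamp(surf_vox)
  on_surf <- surf_nodes[fe$node_grid_id]
  cosang <- as.numeric(pos %*% dvec) / pmax(rad, 1e-12)
  half <- opening_deg / 2 * pi / 180
  sel <- which(on_surf & cosang >= cos(half) & rad <= 1.15 * geom$head_radius)
  if (!length(sel)) stop("empty generator load patch")
  f <- numeric(3L * fe$n_nodes)
  per <- -dvec * magnitude / length(sel)
  for (c0 in 1:3) f[3L * (sel - 1L) + c0] <- per[c0]
  f
}

#' Forward remodelling engine
#'
#' Iterates the density adaptation rule on a fixed element set: solve each
#' active unit load case, superimpose SED fields with the combined factors
#' `s`, update densities towards the target stimulus, and stop when the
#' mean absolute density change falls below the tolerance.
#'
#' @param fe an `fe_model` (its `E` field is ignored; moduli follow the
#'   density field).
#' @param forces list of dof-force vectors, one per unit load case.
#' @param s combined scaling factors weighting the SED superposition
#'   (`s_i = (alpha_i^2) m_i / m_tot`).
#' @param params a `remodelling_params`.
#' @param settings PCG settings for the per-iteration solves.
#' @param init_density starting density (scalar), perturbed by +/-
#'   `init_noise` uniform noise under `params$seed`.
#' @param init_noise amplitude of the seeded initial perturbation.
#' @param fixed_full optional logical per element: elements held at full
#'   density throughout (cortical-shell emulation), exempt from the
#'   adaptation rule.
#' @param stimulus_smoothing standard deviation (voxels) of the Gaussian
#'   sensor-influence kernel applied to the stimulus field before the
#'   density update (0 disables).  Purely local sensing lets struts
#'   saturate far above the target stimulus because floor-density
#'   neighbours sense almost nothing and are never recruited; a
#'   sensor-influence distance of about one voxel restores marginal
#'   recruitment and drives the converged struts towards the target.
#' @return list with `density`, `iterations`, `delta_history`,
#'   `stimulus` (final per-element stimulus), `converged`.  Raises an
#'   error of class `femload_convergence_error` when the iteration cap is
#'   reached.
#' @export
remodel_structure <- function(fe, forces, s, params = remodelling_params(),
                              settings = solver_settings(tol = 3e-4),
                              init_density = 0.5, init_noise = 0.15,
                              fixed_full = NULL, stimulus_smoothing = 1) {
  stopifnot(inherits(fe, "fe_model"), length(forces) == length(s))
  active <- which(s > 0)
  if (!length(active)) stop("at least one combined factor must be positive")
  n_e <- nrow(fe$elem_nodes)
  V <- fe$voxel_size^3
  rho <- with_seed(params$seed,
    pmin(pmax(init_density + stats::runif(n_e, -init_noise, init_noise),
              params$density_floor), 1))
  if (is.null(fixed_full)) fixed_full <- rep(FALSE, n_e)
  rho[fixed_full] <- 1

  ## sensor-influence smoothing: normalized Gaussian over the element set
  d <- fe$dims
  elem_lin <- (fe$elem_ijk[, 3] - 1L) * (d[1] * d[2]) +
    (fe$elem_ijk[, 2] - 1L) * d[1] + fe$elem_ijk[, 1]
  smooth_field <- NULL
  if (stimulus_smoothing > 0) {
    blur <- function(a) gaussian_filter3(
      voxel_image(a, 1), support = max(2L, ceiling(2 * stimulus_smoothing)),
      sigma = stimulus_smoothing)$values
    mask_arr <- array(0, d)
    mask_arr[elem_lin] <- 1
    wnorm <- blur(mask_arr)[elem_lin]
    smooth_field <- function(v) {
      a <- array(0, d)
      a[elem_lin] <- v
      blur(a)[elem_lin] / wnorm
    }
  }
  warm <- vector("list", length(forces))
  deltas <- numeric(0)
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    E <- params$base_modulus * rho^params$density_exponent
    U <- numeric(n_e)
    for (i in active) {
      sol <- cpp_fe_pcg(fe$Kref, fe$elem_nodes - 1L, E, forces[[i]],
                        fe$fixed_dofs - 1L, settings$tol, settings$maxit,
                        warm[[i]])
      if (!sol$converged)
        stop("FE solve did not converge during remodelling")
      warm[[i]] <- sol$u
      U <- U + s[i] * cpp_element_energy(fe$Kref, fe$elem_nodes - 1L, E,
                                         sol$u) / V
    }
    S <- U / rho
    if (!is.null(smooth_field)) S <- smooth_field(S)
    rho_new <- pmin(pmax(rho + params$step_size *
                           (S - params$target_stimulus) /
                           params$target_stimulus,
                         params$density_floor), 1)
    rho_new[fixed_full] <- 1
    deltas <- c(deltas, mean(abs(rho_new - rho)))
    rho <- rho_new
    if (deltas[it] < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("femload_convergence_error", "error", "condition"),
      list(message = sprintf(
        "forward remodelling did not converge in %d iterations (last mean |drho| = %.3g)",
        params$max_iterations, deltas[length(deltas)]),
        call = sys.call(), delta_history = deltas))
    stop(cond)
  }
  list(density = rho, iterations = length(deltas), delta_history = deltas,
       stimulus = S, converged = converged)
}

#' Generate a remodelling-adapted synthetic specimen
#'
#' Builds the mini-joint envelope, applies the true load mix as uniform
#' parallel patch loads on the head surface, runs the forward remodelling
#' engine to equilibrium (the one-voxel cortical shell of the envelope is
#' held at full density, like the subchondral and cortical bone a scanner
#' would see), binarizes the converged density field at 0.5 (keeping the
#' largest connected component), and finally polishes the binary
#' structure by surface remodelling — depositing elements where the
#' sensed stimulus exceeds the lazy band and resorbing surface elements
#' below it — so the full-modulus binary structure itself is near
#' remodelling equilibrium, which is the state the inverse algorithm
#' assumes.  Each mix entry is one
#' of `n = length(load_mix)` equally-cycled load cases
#' (`m_i/m_tot = 1/n`), so the combined factors are
#' `s_i = (magnitude_i/1000)^2 / n` — the same convention the inverse
#' algorithm assumes, which makes recovered magnitudes directly
#' comparable to the generating ones.
#'
#' @param domain_shape voxel extents (<= ~64 per axis).
#' @param load_mix data frame (or list of pairs) with columns `angle`
#'   (frontal-plane inclination, degrees) and `magnitude` (N, >= 0; at
#'   least one positive).  Zero-magnitude entries count towards the cycle
#'   share but skip their FE solve.
#' @param params a `remodelling_params`.
#' @param voxel_size voxel edge length (mm).
#' @param rotation rotation of the canonical geometry (known true axes).
#' @param opening_deg cone opening angle of the generator load patches.
#' @param stimulus_smoothing sensor-influence kernel SD in voxels, see
#'   [remodel_structure()].
#' @param polish_iterations cap on binary surface-polish iterations
#'   (0 disables the polish phase).
#' @param polish_band lazy band of the polish phase as multiples of the
#'   target stimulus: surface elements sensing below `polish_band[1]`
#'   times the target are resorbed, vacant envelope neighbours sensing
#'   above `polish_band[2]` times the target are deposited.
#' @param settings PCG settings for the remodelling solves.
#' @return object of class `synthetic_specimen`: `binary_structure` and
#'   `density` (voxel images), `frame` (the known generating frame),
#'   `true_load_mix`, `params`, `geometry`, convergence diagnostics.
#' @export
generate_adapted_structure <- function(domain_shape = c(48, 48, 48),
                                       load_mix,
                                       params = remodelling_params(),
                                       voxel_size = 0.5,
                                       rotation = diag(3),
                                       opening_deg = 40,
                                       settings = solver_settings(tol = 3e-4),
                                       stimulus_smoothing = 1,
                                       polish_iterations = 12,
                                       polish_band = c(0.7, 1.3)) {
  if (is.list(load_mix) && !is.data.frame(load_mix))
    load_mix <- do.call(rbind, lapply(load_mix, function(p)
      data.frame(angle = p[[1]], magnitude = p[[2]])))
  stopifnot(all(c("angle", "magnitude") %in% names(load_mix)))
  if (any(load_mix$magnitude < 0)) stop("load mix magnitudes must be >= 0")
  if (!any(load_mix$magnitude > 0))
    stop("at least one load mix magnitude must be positive")
  if (length(domain_shape) == 1L) domain_shape <- rep(domain_shape, 3L)
  if (any(domain_shape > 72))
    stop("domain exceeds desk scale (<= ~64 voxels per axis)")

  geom <- mini_joint_geometry(domain_shape, voxel_size, rotation)
  if (!any(geom$envelope)) stop("empty structure envelope")
  idx <- which(geom$envelope)
  fe <- fe_model(arrayInd(idx, dim(geom$envelope)), dim(geom$envelope),
                 voxel_size, E = 1, poisson = 0.3,
                 constraint = geom$constraint)
  n_mix <- nrow(load_mix)
  forces <- vector("list", n_mix)
  for (i in seq_len(n_mix))
    if (load_mix$magnitude[i] > 0)
      forces[[i]] <- envelope_unit_force(fe, geom, load_mix$angle[i],
                                         opening_deg = opening_deg)
  s_true <- (load_mix$magnitude / 1000)^2 / n_mix

  rem <- remodel_structure(fe, forces, s_true, params, settings,
                           fixed_full = geom$shell[idx],
                           stimulus_smoothing = stimulus_smoothing)

  dens <- array(0, dim(geom$envelope))
  dens[idx] <- rem$density
  bin <- dens >= 0.5
  if (!any(bin)) stop("adapted structure is empty after binarization")
  bin <- largest_component(bin, connectivity = 26)

  ## surface polish: drive the *binary* structure towards equilibrium
  ## (deposit where the sensed stimulus exceeds the lazy band, resorb
  ## surface elements below it), so the stimulus the inverse algorithm
  ## sees on the binarized structure is near the target
  active <- which(load_mix$magnitude > 0)
  d <- dim(geom$envelope)
  polish_steps <- 0L
  if (polish_iterations > 0) {
    Ut <- params$target_stimulus
    ngrid3 <- 3L * prod(d + 1L)
    ugrid <- vector("list", n_mix)
    blur1 <- function(a) gaussian_filter3(voxel_image(a, 1),
                                          support = 2, sigma = 1)$values
    bone <- bin | geom$shell
    for (k in seq_len(polish_iterations)) {
      idxb <- which(bone)
      feb <- fe_model(arrayInd(idxb, d), d, voxel_size,
                      E = params$base_modulus, poisson = 0.3,
                      constraint = geom$constraint)
      gidx <- rep(3L * (feb$node_grid_id - 1L), each = 3L) +
        rep(1:3, times = feb$n_nodes)
      U <- numeric(length(idxb))
      for (i in active) {
        fi <- envelope_unit_force(feb, geom, load_mix$angle[i],
                                  opening_deg = opening_deg)
        u0 <- if (!is.null(ugrid[[i]])) ugrid[[i]][gidx]
        sol <- cpp_fe_pcg(feb$Kref, feb$elem_nodes - 1L, feb$E, fi,
                          feb$fixed_dofs - 1L, settings$tol,
                          settings$maxit, u0)
        if (!sol$converged) stop("FE solve did not converge during polish")
        vg <- numeric(ngrid3)
        vg[gidx] <- sol$u
        ugrid[[i]] <- vg
        U <- U + s_true[i] *
          cpp_element_energy(feb$Kref, feb$elem_nodes - 1L, feb$E, sol$u) /
          voxel_size^3
      }
      Ua <- array(0, d)
      Ua[idxb] <- U
      Wb <- blur1(bone * 1)
      Ub <- blur1(Ua)
      sensed <- array(0, d)
      ok <- Wb > 0.05
      sensed[ok] <- Ub[ok] / Wb[ok]
      surf <- bone & dilate6(!bone) & !geom$shell
      resorb <- surf & (sensed < polish_band[1] * Ut)
      depos <- !bone & geom$envelope & dilate6(bone) &
        (sensed > polish_band[2] * Ut)
      polish_steps <- k
      if (!any(resorb) && !any(depos)) break
      bone[resorb] <- FALSE
      bone[depos] <- TRUE
      bone <- bone | geom$shell
      bone <- largest_component(bone, connectivity = 26)
    }
    bin <- bone
  }

  frame <- anatomical_frame(head_centre = geom$head_centre,
                            head_radius = geom$head_radius,
                            neck_midpoint = geom$neck_midpoint,
                            axes = geom$axes)
  structure(list(
    binary_structure = voxel_image(bin, voxel_size),
    density = voxel_image(dens, voxel_size),
    frame = frame, true_load_mix = load_mix, params = params,
    geometry = geom, iterations = rem$iterations,
    polish_iterations = polish_steps,
    delta_history = rem$delta_history, converged = rem$converged),
    class = "synthetic_specimen")
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("<synthetic_specimen> %s voxels, %d foreground, %d remodelling iterations\n",
              paste(dim(x$binary_structure$values), collapse = " x "),
              sum(x$binary_structure$values), x$iterations))
  invisible(x)
}

#' Calibrate a physiologic load magnitude for the mini joint
#'
#' The mini joint is an order of magnitude smaller than a femur, so
#' paper-scale forces would saturate the density field.  This helper
#' returns the magnitude at which a single load case holds the most
#' loaded tissue of the head/neck core (upper-decile probe stimulus) at
#' the equilibrium stimulus for a uniform probe density.  Calibrating to
#' the upper decile rather than the median respects the load-path
#' bottleneck (the neck cross-section and the contact zone): a magnitude
#' calibrated to the median would exceed what the adapted structure can
#' carry without saturating.  Deterministic (one FE solve at uniform
#' density).
#'
#' @param domain_shape,voxel_size,rotation as in
#'   [generate_adapted_structure()].
#' @param angle load inclination (degrees).
#' @param params a `remodelling_params`.
#' @param n_mix cycle-share divisor the mix will use.
#' @param probe_density uniform density of the probe solve.
#' @param probe_quantile quantile of the core probe stimulus the
#'   calibration pins to the target (default 0.9, the most loaded
#'   tissue).
#' @param opening_deg generator patch opening angle.
#' @param settings PCG settings.
#' @return magnitude in N.
#' @export
calibrate_load_magnitude <- function(domain_shape = c(48, 48, 48),
                                     voxel_size = 0.5, angle = 20,
                                     params = remodelling_params(),
                                     n_mix = 4, probe_density = 0.5,
                                     probe_quantile = 0.9,
                                     rotation = diag(3), opening_deg = 40,
                                     settings = solver_settings(tol = 1e-5)) {
  geom <- mini_joint_geometry(domain_shape, voxel_size, rotation)
  idx <- which(geom$envelope)
  fe <- fe_model(arrayInd(idx, dim(geom$envelope)), dim(geom$envelope),
                 voxel_size, E = 1, poisson = 0.3,
                 constraint = geom$constraint)
  f <- envelope_unit_force(fe, geom, angle, opening_deg = opening_deg)
  E <- rep(params$base_modulus * probe_density^params$density_exponent,
           nrow(fe$elem_nodes))
  sol <- cpp_fe_pcg(fe$Kref, fe$elem_nodes - 1L, E, f, fe$fixed_dofs - 1L,
                    settings$tol, settings$maxit, NULL)
  if (!sol$converged) stop("calibration solve did not converge")
  U <- cpp_element_energy(fe$Kref, fe$elem_nodes - 1L, E, sol$u) /
    voxel_size^3
  cen <- sweep((arrayInd(idx, dim(geom$envelope)) - 0.5) * voxel_size,
               2, geom$head_centre)
  dist <- sqrt(rowSums(cen^2))
  core <- dist > 0.3 * geom$head_radius & dist < 1.6 * geom$head_radius
  U_core <- stats::quantile(U[core], probe_quantile, names = FALSE)
  if (U_core <= 0) stop("degenerate calibration: zero core SED")
  1000 * sqrt(n_mix * params$target_stimulus * probe_density / U_core)
}

#' Render a binary structure as a CT-like grayscale volume
#'
#' Two grey levels, optional Gaussian blur (partial-volume surrogate) and
#' seeded additive Gaussian noise.
#'
#' @param structure binary `voxel_image` (0/1 values).
#' @param bone_grey,background_grey grey values; `bone_grey` must exceed
#'   `background_grey`.
#' @param blur_sigma Gaussian blur in voxels (0 = none).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed; identical seeds give bit-identical images.
#' @return grayscale `voxel_image`.
#' @export
synthesize_grayscale <- function(structure, bone_grey = 6000,
                                 background_grey = 1000, blur_sigma = 0,
                                 noise_sd = 0, seed = 1) {
  stopifnot(is_voxel_image(structure))
  if (bone_grey <= background_grey)
    stop("bone_grey must exceed background_grey")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  vals <- background_grey +
    (bone_grey - background_grey) * (structure$values > 0)
  img <- voxel_image(vals * 1.0, structure$voxel_size, structure$origin)
  if (blur_sigma > 0)
    img <- gaussian_filter3(img, support = max(1L, ceiling(2 * blur_sigma)),
                            sigma = blur_sigma)
  if (noise_sd > 0)
    img$values <- img$values +
      with_seed(seed, array(stats::rnorm(length(img$values), 0, noise_sd),
                            dim(img$values)))
  img
}

#' Default activity specifications for load-trace emulation
#'
#' Peak magnitudes and frontal-plane inclinations chosen to emulate
#' instrumented-prosthesis daily-activity summaries: the largest peak is
#' level walking (~2700 N near 18 deg) and the activity inclinations span
#' 3.7 to 66.6 deg.
#'
#' @return data frame with columns `activity`, `peak_N`,
#'   `inclination_deg`, `duration_s`, `rate_hz`.
#' @export
default_activity_specs <- function() {
  data.frame(
    activity = c("walking", "stair_climb", "stair_descend", "stand_up",
                 "sit_down", "one_leg_stance"),
    peak_N = c(2700, 2550, 2600, 1900, 1700, 2300),
    inclination_deg = c(18.2, 25, 3.7, 50, 66.6, 12),
    duration_s = c(1.1, 1.4, 1.3, 2.0, 2.0, 2.0),
    rate_hz = c(100, 100, 100, 50, 50, 50))
}

#' Generate instrumented-prosthesis style load traces
#'
#' Half-sine force magnitude profiles per activity cycle with a fixed
#' per-activity direction in the implant frame; subject-level variability
#' is Gaussian jitter on the peak magnitude only.
#'
#' @param activity_specs data frame as [default_activity_specs()].
#' @param n_subjects number of subjects.
#' @param seed RNG seed (bit-reproducible tables).
#' @param magnitude_jitter_sd SD (N) of the per-subject peak jitter
#'   (default 0: peaks exactly as configured).
#' @return data frame with columns `subject`, `activity`, `time_s`,
#'   `f_ml_N`, `f_ap_N`, `f_vert_N`.
#' @export
generate_load_traces <- function(activity_specs = default_activity_specs(),
                                 n_subjects = 10, seed = 1,
                                 magnitude_jitter_sd = 0) {
  if (is.null(activity_specs) || nrow(activity_specs) == 0L)
    stop("activity_specs must contain at least one activity")
  if (any(activity_specs$peak_N <= 0)) stop("peak magnitudes must be positive")
  if (any(activity_specs$rate_hz <= 0)) stop("sample rates must be positive")
  with_seed(seed, {
    out <- vector("list", n_subjects * nrow(activity_specs))
    k <- 0L
    for (s in seq_len(n_subjects)) {
      for (a in seq_len(nrow(activity_specs))) {
        sp <- activity_specs[a, ]
        peak <- sp$peak_N +
          if (magnitude_jitter_sd > 0)
            stats::rnorm(1, 0, magnitude_jitter_sd) else 0
        peak <- max(peak, 1)
        tt <- sort(unique(c(seq(0, sp$duration_s, by = 1 / sp$rate_hz),
                            sp$duration_s / 2)))
        mag <- peak * sin(pi * tt / sp$duration_s)
        d <- frontal_direction(sp$inclination_deg)
        k <- k + 1L
        out[[k]] <- data.frame(
          subject = sprintf("S%02d", s), activity = sp$activity,
          time_s = tt, f_ml_N = mag * d[1], f_ap_N = mag * d[2],
          f_vert_N = mag * d[3])
      }
    }
    do.call(rbind, out)
  })
}

#' Write / read load-trace tables
#'
#' CSV with header columns subject, activity, time_s, f_ml_N, f_ap_N,
#' f_vert_N.
#'
#' @param traces trace data frame.
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-specimen scaling factors and CoV values
#'
#' The packaged table of optimized load magnitude scaling factors
#' (alpha_1..alpha_4) and tissue-loading CoV before/after optimization for
#' the ten cadaver femora, shipped as a versioned text fixture.
#'
#' @return data frame with 10 rows and columns `specimen`, `alpha_1`,
#'   `alpha_2`, `alpha_3`, `alpha_4`, `cov_init`, `cov_opt`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_alpha_cov.csv", package = "femload",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  stopifnot(nrow(df) == 10L,
            all(c("specimen", paste0("alpha_", 1:4), "cov_init",
                  "cov_opt") %in% names(df)),
            all(df[paste0("alpha_", 1:4)] >= 0),
            all(df$cov_init > 0), all(df$cov_opt > 0))
  df
}
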