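# Independent oracles used across the suite.

# Adaptive non-negative grid search for min ||b - A s||^2, s >= 0.
# Convex problem, so a shrinking grid around the running optimum converges
# to the global minimum; independent of any least-squares machinery.
nnls_grid_oracle <- function(A, b, rounds = 14, points = 11) {
  n <- ncol(A)
  obj <- function(s) sum((b - A %*% s)^2)
  s_up <- max(1e-8, 2 * max(abs(crossprod(A, b))) / max(colSums(A^2)))
  centre <- rep(s_up / 2, n)
  width <- rep(s_up, n)
  best <- centre
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(n), function(j)
      pmax(seq(centre[j] - width[j] / 2, centre[j] + width[j] / 2,
               length.out = points), 0))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, obj)
    best <- cand[which.min(vals), ]
    centre <- best
    width <- width * (2.2 / (points - 1))  # keep one grid step of slack
  }
  as.numeric(best)
}

# Two-pass coefficient of variation (population SD), in percent
cov_oracle <- function(x) {
  m <- sum(x) / length(x)
  100 * sqrt(sum((x - m)^2) / length(x)) / m
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
wilcoxon_enum_oracle <- function(before, after) {
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% rk
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  min(p, 1)
}

# Solid block FE model with symmetry boundary conditions (x=0: ux, y=0: uy,
# z=0: uz fixed) -- admits the exact uniform uniaxial stress solution
make_block_fe <- function(n, h = 1, E = 10000, nu = 0.3) {
  ijk <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  fe_model(ijk, c(n, n, n), h, E = E, poisson = nu,
           constraint = function(xyz) {
             tol <- 1e-9
             cbind(xyz[, 1] < tol, xyz[, 2] < tol, xyz[, 3] < tol)
           })
}

# uniform compressive traction sigma (MPa) on the top face, as consistent
# nodal forces (tributary areas)
block_top_traction <- function(fe, sigma = 1) {
  n <- max(fe$elem_ijk[, 1])
  h <- fe$voxel_size
  xyz <- fe$node_xyz
  top <- which(abs(xyz[, 3] - n * h) < 1e-9)
  wx <- ifelse(abs(xyz[top, 1]) < 1e-9 | abs(xyz[top, 1] - n * h) < 1e-9,
               0.5, 1)
  wy <- ifelse(abs(xyz[top, 2]) < 1e-9 | abs(xyz[top, 2] - n * h) < 1e-9,
               0.5, 1)
  f <- numeric(3 * fe$n_nodes)
  f[3 * (top - 1) + 3] <- -sigma * wx * wy * h^2
  f
}

# solid digital ball as a binary voxel image
make_ball_image <- function(R = 10, h = 0.5, pad = 4, centre = NULL) {
  n <- ceiling(2 * (R + pad * h) / h)
  if (is.null(centre)) centre <- rep(n * h / 2, 3)
  g <- (seq_len(n) - 0.5) * h
  dist2 <- outer(outer((g - centre[1])^2, (g - centre[2])^2, "+"),
                 (g - centre[3])^2, "+")
  voxel_image(dist2 <= R^2, h)
}

# segmented ball model with a cartilage cap, built directly from a
# hand-made frame (no frame construction involved)
make_ball_model <- function(R = 10, h = 0.5, thickness = 2.2,
                            articular_limit_deg = 115) {
  img <- make_ball_image(R = R, h = h)
  n <- dim(img$values)[1]
  centre <- rep(n * h / 2, 3)
  frame <- anatomical_frame(head_centre = centre, head_radius = R,
                            neck_midpoint = centre - c(0, 0, R),
                            axes = diag(3))
  align_crop_cartilage(img, frame, crop_factor = 1.5,
                       cartilage_thickness = thickness,
                       articular_limit_deg = articular_limit_deg)
}

# minimal SED-field stand-in for optimizer-level tests
make_sed <- function(values, inclination, magnitude = 1000) {
  structure(list(values = as.numeric(values), labels = rep(1L, length(values)),
                 element_volume = 1, n_elements = length(values),
                 load_case_id = inclination, resultant = NULL,
                 inclination = inclination, magnitude = magnitude),
            class = "sed_field")
}

# memoized small adapted specimen for cross-module tests
.test_cache <- new.env(parent = emptyenv())
get_test_specimen <- function(n = 36, seed = 1) {
  key <- sprintf("spec_%d_%d", n, seed)
  if (!exists(key, .test_cache)) {
    M <- get_test_magnitude(n)
    mix <- data.frame(angle = c(-20, 20, 60, 100),
                      magnitude = c(0, M, 0, 0))
    assign(key, generate_adapted_structure(
      rep(n, 3), mix, remodelling_params(seed = seed)), .test_cache)
  }
  get(key, .test_cache)
}
get_test_magnitude <- function(n = 36) {
  key <- sprintf("mag_%d", n)
  if (!exists(key, .test_cache))
    assign(key, calibrate_load_magnitude(rep(n, 3), 0.5, angle = 20,
                                         n_mix = 4), .test_cache)
  get(key, .test_cache)
}
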