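#' Frontal-plane load direction
#'
#' Inclination is the signed angle from the vertical axis within the
#' frontal (medio-lateral / vertical) plane; positive rotates towards
#' medial, so -20 degrees is lateral of vertical.
#'
#' @param inclination_deg inclination in degrees.
#' @return unit length-3 vector `(ml, ap, vert)`.
#' @export
frontal_direction <- function(inclination_deg) {
  th <- inclination_deg * pi / 180
  c(sin(th), 0, cos(th))
}

#' Signed frontal-plane inclination of a force vector
#'
#' The anterior-posterior component is ignored (projection onto the
#' frontal plane).
#'
#' @param v length-3 vector or n x 3 matrix `(ml, ap, vert)`.
#' @return inclination(s) in degrees, measured from the vertical axis.
#' @export
frontal_inclination <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, 1)
  atan2(v[, 1], v[, 3]) * 180 / pi
}

#' Spherical-cap contact area
#'
#' Area of the intersection of a sphere of radius `R` with a cone of full
#' apex (opening) angle `opening_deg` centred on the sphere centre:
#' `2 pi R^2 (1 - cos(opening/2))`.
#'
#' @param R sphere radius (mm).
#' @param opening_deg full cone opening angle (degrees).
#' @return area in mm^2.
#' @export
cap_area <- function(R, opening_deg) {
  2 * pi * R^2 * (1 - cos(opening_deg / 2 * pi / 180))
}

#' Cone opening angle for a target cap area
#'
#' Inverse of [cap_area()]; used to realize load-area variations that are
#' stated as areas rather than angles.
#'
#' @param R sphere radius (mm).
#' @param area target cap area (mm^2), must not exceed the full sphere.
#' @return full opening angle in degrees.
#' @export
cone_opening_for_area <- function(R, area) {
  c_half <- 1 - area / (2 * pi * R^2)
  if (c_half <= -1) stop("target area exceeds the sphere surface")
  2 * acos(pmin(c_half, 1)) * 180 / pi
}

#' Load patch specification
#'
#' @param inclination frontal-plane inclination of the resultant (degrees).
#' @param opening_angle full cone opening angle (degrees, in (0, 180)).
#' @param distribution nodal force distribution: `"uniform_normal"`
#'   (uniform magnitudes along inward surface normals),
#'   `"uniform_parallel"` (equal parallel vectors) or `"hertz_parallel"`
#'   (parallel vectors with ellipsoidal Hertz-type weights).
#' @param rotation_offset additional rotation about the anterior-posterior
#'   axis (degrees), added to the inclination.
#' @return object of class `load_patch_spec`.
#' @export
load_patch_spec <- function(inclination, opening_angle = 40,
                            distribution = c("uniform_normal",
                                             "uniform_parallel",
                                             "hertz_parallel"),
                            rotation_offset = 0) {
  distribution <- match.arg(distribution)
  if (opening_angle <= 0 || opening_angle >= 180)
    stop("opening_angle must lie in (0, 180) degrees")
  structure(list(inclination = inclination, opening_angle = opening_angle,
                 distribution = distribution,
                 rotation_offset = rotation_offset),
            class = "load_patch_spec")
}

#' Construct a set of equally spaced unit-load specifications
#'
#' `n_loads` inclinations at equal angular spacing, inclusive of both
#' endpoints; a rotation offset is added to every inclination.
#'
#' @param n_loads number of load cases (>= 1).
#' @param angle_min,angle_max inclination range endpoints (degrees).
#' @param rotation_offset rotation about the AP axis added to all cases.
#' @param opening_angle,distribution passed to [load_patch_spec()].
#' @return list of `load_patch_spec`.
#' @export
make_load_set <- function(n_loads, angle_min = -20, angle_max = 100,
                          rotation_offset = 0, opening_angle = 40,
                          distribution = "uniform_normal") {
  if (n_loads < 1) stop("n_loads must be >= 1")
  if (n_loads == 1L) {
    if (angle_min != angle_max)
      warning("single load case: using angle_min only")
    angles <- angle_min
  } else {
    if (angle_min >= angle_max) stop("angle_min must be < angle_max")
    angles <- seq(angle_min, angle_max, length.out = n_loads)
  }
  lapply(angles, load_patch_spec, opening_angle = opening_angle,
         distribution = distribution, rotation_offset = rotation_offset)
}

# stamp voxel mask onto the (n+1)^3 corner-node grid: node is TRUE if any
# incident voxel is TRUE
node_stamp <- function(mask) {
  d <- dim(mask)
  nd <- d + 1L
  out <- array(FALSE, nd)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    out[(1:d[1]) + dx, (1:d[2]) + dy, (1:d[3]) + dz] <-
      out[(1:d[1]) + dx, (1:d[2]) + dy, (1:d[3]) + dz] | mask
  }
  out
}

# Tributary surface areas on the corner-node grid, split by face
# orientation: every exposed face of a region voxel (facing background or
# the grid boundary) contributes a quarter of its area h^2 to each of its
# four corner nodes, in the column of its axis.  Weighting these by the
# components of the smooth surface normal (|n . e_ax|) approximates the
# true surface measure of the underlying smooth surface: raw staircase
# area over-weights oblique regions by up to sqrt(3).
face_node_areas <- function(labels, region_label, voxel_size,
                            background_label = 0L) {
  d <- dim(labels)
  nd <- d + 1L
  w <- matrix(0, prod(nd), 3)
  reg <- labels == region_label
  bg <- labels == background_label
  shift_bg <- function(ax, o) {
    n <- d[ax]
    idx <- seq_len(n) + o
    edge <- idx < 1L | idx > n
    idx <- pmin(pmax(idx, 1L), n)
    out <- switch(ax, bg[idx, , , drop = FALSE], bg[, idx, , drop = FALSE],
                  bg[, , idx, drop = FALSE])
    switch(ax,
           out[edge, , ] <- TRUE,
           out[, edge, ] <- TRUE,
           out[, , edge] <- TRUE)
    out
  }
  for (ax in 1:3) for (o in c(-1L, 1L)) {
    faces <- which(reg & shift_bg(ax, o))
    if (!length(faces)) next
    ijk <- arrayInd(faces, d)
    base <- ijk
    base[, ax] <- base[, ax] + (o + 1L) %/% 2L  # face plane node index
    ax2 <- setdiff(1:3, ax)
    for (da in 0:1) for (db in 0:1) {
      corner <- base
      corner[, ax2[1]] <- corner[, ax2[1]] + da
      corner[, ax2[2]] <- corner[, ax2[2]] + db
      lin <- (corner[, 3] - 1L) * (nd[1] * nd[2]) +
        (corner[, 2] - 1L) * nd[1] + corner[, 1]
      w[lin, ax] <- w[lin, ax] + voxel_size^2 / 4
    }
  }
  w
}

# outer-surface nodes of a voxel label region: nodes incident to `region`
# and to background (or the grid boundary)
outer_surface_nodes <- function(labels, region_label, background_label = 0L) {
  d <- dim(labels)
  reg <- node_stamp(labels == region_label)
  bg <- array(FALSE, d + 1L)
  bg[node_stamp(labels == background_label)] <- TRUE
  bg[1, , ] <- TRUE; bg[d[1] + 1L, , ] <- TRUE
  bg[, 1, ] <- TRUE; bg[, d[2] + 1L, ] <- TRUE
  bg[, , 1] <- TRUE; bg[, , d[3] + 1L] <- TRUE
  which(reg & bg)
}

#' Build a unit load case on the cartilage surface
#'
#' The load patch is the set of cartilage outer-surface nodes whose
#' direction from the head centre lies within half the cone opening angle
#' of the load direction.  Nodal force vectors follow the requested
#' distribution and are rescaled so the resultant magnitude is met to
#' 1e-9 relative.  For `uniform_normal` the "uniform distribution" is a
#' uniform pressure: nodal magnitudes carry tributary surface-area
#' weights, which keeps the resultant of a symmetric cap on the cone
#' axis despite the staircase surface.  Nodal forces are compressive (they push into the head,
#' i.e. the applied resultant lies along `-d`); the reported `resultant`
#' uses the outward `+d` joint-load sign convention.
#'
#' @param model a `segmented_model` with a cartilage layer.
#' @param spec a `load_patch_spec`.
#' @param resultant_magnitude resultant force magnitude (N).
#' @return object of class `load_case`: node indices (into the corner-node
#'   grid of the model), per-node force vectors (N), reported resultant
#'   and the realized patch geometry.
#' @export
build_load_case <- function(model, spec, resultant_magnitude = 1000) {
  stopifnot(inherits(model, "segmented_model"),
            inherits(spec, "load_patch_spec"))
  if (!any(model$labels == 2L))
    stop("model has no cartilage layer to load")
  h <- model$voxel_size
  d <- dim(model$labels)
  nodes <- outer_surface_nodes(model$labels, 2L)
  ijk <- arrayInd(nodes, d + 1L)
  pos <- sweep((ijk - 1L) * h, 2, model$head_centre)  # node coords rel. head centre
  rad <- sqrt(rowSums(pos^2))
  dvec <- frontal_direction(spec$inclination + spec$rotation_offset)
  cosang <- as.numeric(pos %*% dvec) / pmax(rad, 1e-12)
  half <- spec$opening_angle / 2 * pi / 180
  inpatch <- cosang >= cos(half)
  if (!any(inpatch))
    stop("empty load patch: no cartilage surface nodes inside the cone")
  ijk <- ijk[inpatch, , drop = FALSE]
  nodes <- nodes[inpatch]
  pos <- pos[inpatch, , drop = FALSE]
  rad <- rad[inpatch]

  w <- rep(1, length(nodes))
  if (spec$distribution == "uniform_normal") {
    dirs <- -pos / rad
    areas <- face_node_areas(model$labels, 2L, h)[nodes, , drop = FALSE]
    wproj <- rowSums(areas * abs(dirs))  # projected tributary areas
    if (any(wproj > 0)) w <- wproj
  } else {
    dirs <- matrix(dvec, length(nodes), 3, byrow = TRUE) * -1
    if (spec$distribution == "hertz_parallel") {
      r_in <- sqrt(pmax(rowSums((pos - outer(as.numeric(pos %*% dvec), dvec))^2), 0))
      a <- stats::median(rad) * sin(half)
      w <- sqrt(pmax(1 - (r_in / a)^2, 0))
      if (sum(w) <= 0) stop("all Hertz weights vanished on the patch")
    }
  }
  forces <- dirs * w
  res <- colSums(forces)
  nres <- sqrt(sum(res^2))
  if (nres <= 0) stop("degenerate patch: zero resultant before scaling")
  forces <- forces * (resultant_magnitude / nres)
  achieved <- -colSums(forces)  # along +d if symmetric
  mis <- acos(pmin(1, sum(achieved * dvec) / resultant_magnitude)) * 180 / pi
  if (mis > 2)
    warning(sprintf(paste0("asymmetrically clipped patch: achieved resultant ",
                           "direction deviates %.1f deg from the target ",
                           "(achieved inclination %.1f deg)"),
                    mis, frontal_inclination(achieved)))

  structure(list(
    spec = spec, nodes = as.integer(nodes), node_ijk = ijk,
    forces = forces,
    resultant = dvec * resultant_magnitude,
    resultant_applied = colSums(forces),
    magnitude = resultant_magnitude,
    direction = dvec,
    inclination = spec$inclination + spec$rotation_offset,
    n_patch_nodes = length(nodes),
    patch_area = cap_area(model$head_radius, spec$opening_angle),
    misalignment_deg = mis), class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("<load_case> %.0f N at %+.1f deg, %s, %d patch nodes\n",
              x$magnitude, x$inclination, x$spec$distribution,
              x$n_patch_nodes))
  invisible(x)
}

#' Serialize a load case to a structured text file
#'
#' @param lc a `load_case`.
#' @param path output path (whitespace-separated columns: node i j k and
#'   three force components in N).
#' @export
write_load_case <- function(lc, path) {
  df <- data.frame(node = lc$nodes, i = lc$node_ijk[, 1],
                   j = lc$node_ijk[, 2], k = lc$node_ijk[, 3],
                   fx_N = lc$forces[, 1], fy_N = lc$forces[, 2],
                   fz_N = lc$forces[, 3])
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
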