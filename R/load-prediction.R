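#' Load prediction configuration
#'
#' @param equilibrium_stimulus remodelling equilibrium SED (MPa); the
#'   level at which bone is neither formed nor resorbed (default 0.02).
#' @param roi_reduction distance (mm) by which the region of interest is
#'   pulled back from the lateral and distal boundaries.
#' @return object of class `load_prediction_config`.  The load-cycle
#'   assumption is a constant number of cycles for all n unit load cases
#'   (m_i / m_tot = 1/n), so magnitudes follow alpha_i = sqrt(n s_i).
#' @export
load_prediction_config <- function(equilibrium_stimulus = 0.02,
                                   roi_reduction = 0) {
  if (equilibrium_stimulus <= 0) stop("equilibrium stimulus must be positive")
  if (roi_reduction < 0) stop("roi_reduction must be >= 0")
  structure(list(equilibrium_stimulus = equilibrium_stimulus,
                 roi_reduction = roi_reduction),
            class = "load_prediction_config")
}

#' Region of interest over bone elements
#'
#' Bone elements whose centres lie farther than `reduction` from the
#' lateral (x = 0) and distal (z = 0) crop faces; cartilage is always
#' excluded.
#'
#' @param fe an `fe_model` built by [build_model()].
#' @param reduction pull-back distance in mm (>= 0).
#' @return object of class `roi_mask` with the included element indices.
#' @export
make_roi <- function(fe, reduction = 0) {
  stopifnot(inherits(fe, "fe_model"))
  if (reduction < 0) stop("reduction must be >= 0")
  h <- fe$voxel_size
  cx <- (fe$elem_ijk[, 1] - 0.5) * h
  cz <- (fe$elem_ijk[, 3] - 0.5) * h
  keep <- fe$labels == 1L & cx > reduction & cz > reduction
  if (!any(keep))
    stop("empty ROI: reduction removes every bone element")
  structure(list(elements = which(keep), reduction = reduction),
            class = "roi_mask")
}

#' Combined mechanical stimulus field
#'
#' `U(x) = sum_i s_i U_i(x)` per element; the combined scaling factor
#' `s_i = alpha_i^2 m_i / m_tot` absorbs both load magnitude and cycle
#' share.
#'
#' @param sed_set list of `sed_field` objects on the same element set.
#' @param s non-negative weights, one per field.
#' @return numeric vector of combined SED per element (MPa).
#' @export
combined_stimulus <- function(sed_set, s) {
  if (length(sed_set) != length(s)) stop("s length must match sed_set")
  if (any(s < 0)) stop("s must be non-negative")
  n_el <- vapply(sed_set, function(x) x$n_elements, integer(1))
  if (length(unique(n_el)) != 1L)
    stop("SED fields are defined on mismatched element sets")
  out <- numeric(n_el[1])
  for (i in seq_along(sed_set)) out <- out + s[i] * sed_set[[i]]$values
  out
}

#' Coefficient of variation of a stimulus field
#'
#' `100 * population SD / mean` over the ROI elements (population SD:
#' divisor n); invariant under positive rescaling of the field.
#'
#' @param field numeric per-element field (MPa).
#' @param roi `roi_mask` or integer element indices; default all elements.
#' @return CoV in percent.
#' @export
compute_cov <- function(field, roi = NULL) {
  v <- if (is.null(roi)) field
       else if (inherits(roi, "roi_mask")) field[roi$elements]
       else field[roi]
  m <- mean(v)
  if (m <= 0) stop("ROI mean must be positive for the CoV")
  100 * sqrt(mean((v - m)^2)) / m
}

#' Peak and mean joint load vectors from scaling factors
#'
#' Each unit-load resultant (magnitude `magnitude`, frontal-plane
#' inclination `directions_deg`, reported along the outward +d convention)
#' is multiplied by its load magnitude scaling factor alpha.  The peak
#' vector is the scaled vector of maximal magnitude (ties broken by lowest
#' load-case index); the mean vector is the vector sum divided by the
#' number of load cases.
#'
#' @param alpha load magnitude scaling factors (>= 0).
#' @param directions_deg frontal-plane inclinations of the unit loads.
#' @param magnitude unit-load resultant magnitude (N, default 1000).
#' @return list with `scaled_vectors` (n x 3), `magnitudes`,
#'   `inclinations`, `peak_vector`, `peak_magnitude`, `peak_inclination`,
#'   `peak_index`, `mean_vector`, `mean_magnitude`, `mean_inclination`,
#'   and `degenerate` (TRUE when every alpha is zero, in which case the
#'   peak is undefined).
#' @export
vectors_and_angles <- function(alpha, directions_deg, magnitude = 1000) {
  if (length(alpha) != length(directions_deg))
    stop("alpha and directions must have equal length")
  dirs <- t(vapply(directions_deg, frontal_direction, numeric(3)))
  sv <- dirs * (alpha * magnitude)
  mags <- sqrt(rowSums(sv^2))
  degenerate <- all(alpha == 0)
  if (degenerate) {
    warning("all scaling factors are zero: peak vector undefined")
    peak_i <- NA_integer_
    peak <- rep(NA_real_, 3)
  } else {
    peak_i <- which.max(mags)  # which.max: lowest index on ties
    peak <- sv[peak_i, ]
  }
  mv <- colSums(sv) / length(alpha)
  list(scaled_vectors = sv, magnitudes = mags,
       inclinations = ifelse(alpha > 0, directions_deg, NA_real_),
       peak_vector = peak,
       peak_magnitude = if (degenerate) NA_real_ else mags[peak_i],
       peak_inclination = if (degenerate) NA_real_
                          else frontal_inclination(peak),
       peak_index = peak_i,
       mean_vector = mv, mean_magnitude = sqrt(sum(mv^2)),
       mean_inclination = frontal_inclination(mv),
       degenerate = degenerate)
}

#' Magnitude rescaling under a changed equilibrium stimulus
#'
#' The optimization objective is linear in the equilibrium stimulus, so
#' the optimal combined factors scale proportionally and predicted load
#' magnitudes follow a square-root law:
#' `alpha(k U~) = sqrt(k) alpha(U~)`, directions unchanged.
#'
#' @param magnitude predicted magnitude (N) at `stimulus_from`.
#' @param stimulus_from,stimulus_to equilibrium stimuli (MPa).
#' @return rescaled magnitude (N).
#' @export
stimulus_scaled_magnitude <- function(magnitude, stimulus_from, stimulus_to) {
  if (stimulus_from <= 0 || stimulus_to <= 0)
    stop("equilibrium stimuli must be positive")
  magnitude * sqrt(stimulus_to / stimulus_from)
}

#' Inverse-remodelling joint load prediction
#'
#' Finds the non-negative combined scaling factors `s` minimizing
#' `sum_x (U~ - sum_i s_i U_i(x))^2` over the ROI (non-negative least
#' squares, Lawson-Hanson active set), converts them to load magnitudes
#' `alpha_i = sqrt(n s_i)`, and reports scaled, peak and mean joint load
#' vectors together with the coefficient of variation of the tissue
#' stimulus before (uniform scaling) and after optimization.
#'
#' @param sed_set list of `sed_field` objects (one per unit load case, all
#'   on the same element set, with resultant metadata).
#' @param roi a `roi_mask` from [make_roi()].
#' @param config a `load_prediction_config`.
#' @return object of class `load_prediction` with fields `s`, `alpha`,
#'   `scaled_vectors`, `peak_vector`, `peak_magnitude`,
#'   `peak_inclination`, `mean_vector`, `mean_magnitude`,
#'   `mean_inclination`, `cov_init`, `cov_opt`, `objective_init`,
#'   `objective_opt`, `inclinations`, `degenerate`.
#' @export
predict_loads <- function(sed_set, roi, config = load_prediction_config()) {
  n <- length(sed_set)
  if (n < 1L) stop("need at least one SED field")
  stopifnot(inherits(roi, "roi_mask"))
  Ut <- config$equilibrium_stimulus
  A <- vapply(sed_set, function(sf) sf$values[roi$elements],
              numeric(length(roi$elements)))
  A <- matrix(A, ncol = n)
  if (all(A == 0)) stop("all SED fields are zero over the ROI")
  degenerate <- qr(A)$rank < n
  if (degenerate)
    warning("rank-deficient design (overlapping load patches?): solution is not unique")
  b <- rep(Ut, nrow(A))
  s <- as.numeric(pracma::lsqnonneg(A, b)$x)
  s[s < 0] <- 0  # guard against tiny negative round-off
  alpha <- sqrt(n * s)

  s0 <- rep(1 / n, n)
  u_init <- as.numeric(A %*% s0)
  u_opt <- as.numeric(A %*% s)
  incl <- vapply(sed_set, function(sf) sf$inclination, numeric(1))
  mag <- sed_set[[1]]$magnitude
  if (is.na(mag)) mag <- 1000
  va <- vectors_and_angles(alpha, incl, mag)

  structure(c(list(
    s = s, alpha = alpha, n_load_cases = n,
    equilibrium_stimulus = Ut,
    cov_init = compute_cov(u_init), cov_opt = compute_cov(u_opt),
    objective_init = sum((Ut - u_init)^2),
    objective_opt = sum((Ut - u_opt)^2),
    roi_size = nrow(A), degenerate_design = degenerate),
    va), class = "load_prediction")
}

#' @export
print.load_prediction <- function(x, ...) {
  cat(sprintf("<load_prediction> %d load cases over %d ROI elements\n",
              x$n_load_cases, x$roi_size))
  cat(sprintf("  alpha: %s\n", paste(sprintf("%.2f", x$alpha), collapse = " ")))
  cat(sprintf("  peak: %.1f N at %+.1f deg; mean: %.1f N at %+.1f deg\n",
              x$peak_magnitude, x$peak_inclination,
              x$mean_magnitude, x$mean_inclination))
  cat(sprintf("  CoV %.1f%% -> %.1f%%\n", x$cov_init, x$cov_opt))
  invisible(x)
}

#' Write a load prediction result as structured text
#'
#' @param result a `load_prediction`.
#' @param path output path.
#' @export
write_prediction <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("equilibrium_stimulus_MPa = %.6g", result$equilibrium_stimulus),
    sprintf("cov_init_pct = %.6g", result$cov_init),
    sprintf("cov_opt_pct = %.6g", result$cov_opt),
    sprintf("objective_init = %.6g", result$objective_init),
    sprintf("objective_opt = %.6g", result$objective_opt),
    sprintf("peak_N = %.6g at %.6g deg", result$peak_magnitude,
            result$peak_inclination),
    sprintf("mean_N = %.6g at %.6g deg", result$mean_magnitude,
            result$mean_inclination),
    "case s alpha f_ml_N f_ap_N f_vert_N"), con)
  for (i in seq_len(result$n_load_cases))
    writeLines(sprintf("%d %.8g %.8g %.6g %.6g %.6g", i, result$s[i],
                       result$alpha[i], result$scaled_vectors[i, 1],
                       result$scaled_vectors[i, 2],
                       result$scaled_vectors[i, 3]), con)
  invisible(path)
}
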