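#' Reference configuration for the sensitivity analysis
#'
#' All pipeline parameters at their reference values: threshold 3000,
#' 40-degree cone (full-femur equivalent area 215.1 mm^2), uniform
#' surface-normal nodal forces, 10 GPa bone / 10 MPa cartilage, four unit
#' loads between -20 and 100 degrees, no location offset, full-model ROI,
#' 0.02 MPa equilibrium stimulus.
#'
#' @return named list of reference parameter values.
#' @export
reference_config <- function() {
  list(threshold = 3000, area_ratio = 1, reference_area = 215.1,
       distribution = "uniform_normal", bone_modulus = 10000,
       cartilage_modulus = 10, poisson = 0.3, n_unit_loads = 4L,
       rotation_offset = 0, roi_reduction = 0, equilibrium_stimulus = 0.02,
       angle_min = -20, angle_max = 100, resultant_N = 1000,
       opening_deg = 40, crop_factor = 1.5, cartilage_thickness = 2.2,
       shaft_section_length = 40, filter_support = 2, filter_sigma = 1.6,
       resample_factor = 1)
}

#' One-at-a-time sensitivity design
#'
#' Nine parameters with two variations each.  Load-area variations are
#' stated as absolute areas of the full-scale reference (215.1 mm^2 for a
#' 40-degree cone); they are realized as area ratios converted to the cone
#' half-angle yielding the target area on the fitted head sphere, so the
#' same design applies to desk-scale synthetic specimens.
#'
#' @return data frame with columns `parameter`, `variation`, `value`
#'   (character; parsed per parameter).
#' @export
table1_design <- function() {
  data.frame(
    parameter = rep(c("threshold", "load_area", "force_distribution",
                      "bone_modulus", "cartilage_modulus", "n_unit_loads",
                      "load_location", "roi", "equilibrium_stimulus"),
                    each = 2),
    variation = rep(1:2, times = 9),
    value = c("3300", "2700",
              "121.5", "54.2",
              "uniform_parallel", "hertz_parallel",
              "5000", "20000",
              "100", "1000",
              "7", "13",
              "10", "-10",
              "5", "10",
              "0.01", "0.04"),
    stringsAsFactors = FALSE)
}

sensitivity_vocabulary <- c("threshold", "load_area", "force_distribution",
                            "bone_modulus", "cartilage_modulus",
                            "n_unit_loads", "load_location", "roi",
                            "equilibrium_stimulus")

apply_variation <- function(cfg, parameter, value) {
  switch(parameter,
    threshold = { cfg$threshold <- as.numeric(value) },
    load_area = { cfg$area_ratio <- as.numeric(value) / cfg$reference_area },
    force_distribution = { cfg$distribution <- value },
    bone_modulus = { cfg$bone_modulus <- as.numeric(value) },
    cartilage_modulus = { cfg$cartilage_modulus <- as.numeric(value) },
    n_unit_loads = { cfg$n_unit_loads <- as.integer(value) },
    load_location = { cfg$rotation_offset <- as.numeric(value) },
    roi = { cfg$roi_reduction <- as.numeric(value) },
    equilibrium_stimulus = { cfg$equilibrium_stimulus <- as.numeric(value) },
    stop("unknown sensitivity parameter: ", parameter))
  cfg
}

#' Run the one-at-a-time parameter sensitivity analysis
#'
#' Executes the full prediction pipeline (segment, frame, crop +
#' cartilage, unit-load FE solves, inverse load scaling) for the reference
#' configuration and every design row, varying one parameter at a time.
#' SED fields are cached by their FE-relevant key (threshold, moduli,
#' distribution, cone angle, inclination), so variations that do not alter
#' the FE solution — equilibrium stimulus, ROI — reuse the reference
#' fields and trigger zero additional solves; shared inclinations between
#' unit-load-count variations are likewise reused.
#'
#' @param specimen a `synthetic_specimen` (rendered to grayscale
#'   internally) or a grayscale `voxel_image`.
#' @param design data frame as [table1_design()] (may be empty: reference
#'   run only).
#' @param base_config reference values, see [reference_config()].
#' @param length_scale scale factor applied to full-femur lengths (ROI
#'   reductions, shaft section) for desk-scale domains.
#' @param settings PCG settings for the unit-load solves.
#' @param gray_seed seed for the internal grayscale rendering of a
#'   `synthetic_specimen`.
#' @return object of class `sensitivity_report`: a data frame with one row
#'   per run (reference has `variation = 0`) holding peak/mean vector
#'   magnitudes and inclinations, CoV values, per-run new FE solve counts
#'   and deltas against the reference; per-run alpha profiles in
#'   `attr(, "alphas")`.
#' @export
run_sensitivity <- function(specimen, design = table1_design(),
                            base_config = reference_config(),
                            length_scale = 1,
                            settings = solver_settings(tol = 1e-5),
                            gray_seed = 7) {
  if (nrow(design) > 0 &&
      !all(design$parameter %in% sensitivity_vocabulary))
    stop("unknown sensitivity parameter(s): ",
         paste(setdiff(design$parameter, sensitivity_vocabulary),
               collapse = ", "))

  gray <- if (inherits(specimen, "synthetic_specimen")) {
    synthesize_grayscale(specimen$binary_structure, bone_grey = 6000,
                         background_grey = 1000, blur_sigma = 0.7,
                         noise_sd = 150, seed = gray_seed)
  } else if (is_voxel_image(specimen)) specimen
  else stop("specimen must be a synthetic_specimen or a grayscale voxel_image")

  sed_cache <- new.env(parent = emptyenv())
  geom_cache <- new.env(parent = emptyenv())
  solve_count <- 0L

  run_once <- function(cfg) {
    h <- gray$voxel_size
    gkey <- sprintf("thr%.6g", cfg$threshold)
    if (!exists(gkey, geom_cache)) {
      bin <- preprocess(gray, filter_support = cfg$filter_support,
                        filter_sigma = cfg$filter_sigma,
                        resample_factor = cfg$resample_factor,
                        threshold = cfg$threshold)
      frame <- build_frame(bin,
                           shaft_section_length =
                             cfg$shaft_section_length * length_scale)
      thick <- max(2 * h, cfg$cartilage_thickness * length_scale)
      model <- align_crop_cartilage(bin, frame,
                                    crop_factor = cfg$crop_factor,
                                    cartilage_thickness = thick)
      assign(gkey, list(model = model, frame = frame), geom_cache)
    }
    geo <- get(gkey, geom_cache)
    fkey <- sprintf("%s_Eb%.6g_Ec%.6g", gkey, cfg$bone_modulus,
                    cfg$cartilage_modulus)
    if (!exists(fkey, geom_cache))
      assign(fkey, suppressWarnings(
        build_model(geo$model, cfg$bone_modulus, cfg$cartilage_modulus,
                    cfg$poisson)), geom_cache)
    fe <- get(fkey, geom_cache)

    R_fit <- geo$frame$head_radius
    opening <- if (cfg$area_ratio == 1) cfg$opening_deg
               else cone_opening_for_area(
                 R_fit, cfg$area_ratio * cap_area(R_fit, cfg$opening_deg))
    specs <- make_load_set(cfg$n_unit_loads, cfg$angle_min, cfg$angle_max,
                           rotation_offset = cfg$rotation_offset,
                           opening_angle = opening,
                           distribution = cfg$distribution)
    sed_set <- lapply(specs, function(sp) {
      skey <- sprintf("%s_%s_o%.6g_i%.6g", fkey, sp$distribution, opening,
                      sp$inclination + sp$rotation_offset)
      if (!exists(skey, sed_cache)) {
        lc <- build_load_case(geo$model, sp, cfg$resultant_N)
        solve_count <<- solve_count + 1L
        assign(skey, solve_load_case(fe, lc, settings), sed_cache)
      }
      get(skey, sed_cache)
    })
    roi <- make_roi(fe, cfg$roi_reduction * length_scale)
    predict_loads(sed_set, roi,
                  load_prediction_config(cfg$equilibrium_stimulus))
  }

  n_runs <- 1L + nrow(design)
  rows <- vector("list", n_runs)
  alphas <- vector("list", n_runs)
  before <- solve_count
  ref <- run_once(base_config)
  rows[[1]] <- data.frame(parameter = "reference", variation = 0L,
                          level = "reference",
                          peak_N = ref$peak_magnitude,
                          peak_deg = ref$peak_inclination,
                          mean_N = ref$mean_magnitude,
                          mean_deg = ref$mean_inclination,
                          cov_init = ref$cov_init, cov_opt = ref$cov_opt,
                          new_solves = solve_count - before,
                          stringsAsFactors = FALSE)
  alphas[[1]] <- ref$alpha

  if (nrow(design) > 0) {
    for (r in seq_len(nrow(design))) {
      cfg <- apply_variation(base_config, design$parameter[r],
                             design$value[r])
      before <- solve_count
      res <- run_once(cfg)
      rows[[r + 1L]] <- data.frame(parameter = design$parameter[r],
                                   variation = design$variation[r],
                                   level = design$value[r],
                                   peak_N = res$peak_magnitude,
                                   peak_deg = res$peak_inclination,
                                   mean_N = res$mean_magnitude,
                                   mean_deg = res$mean_inclination,
                                   cov_init = res$cov_init,
                                   cov_opt = res$cov_opt,
                                   new_solves = solve_count - before,
                                   stringsAsFactors = FALSE)
      alphas[[r + 1L]] <- res$alpha
    }
  }
  rep <- do.call(rbind, rows)
  for (cl in c("peak_N", "peak_deg", "mean_N", "mean_deg"))
    rep[[paste0("d_", cl)]] <- rep[[cl]] - rep[[cl]][1]
  attr(rep, "alphas") <- alphas
  attr(rep, "total_solves") <- solve_count
  class(rep) <- c("sensitivity_report", class(rep))
  rep
}

#' Write a sensitivity report as CSV
#'
#' @param report a `sensitivity_report`.
#' @param path output path.
#' @export
write_sensitivity_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
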