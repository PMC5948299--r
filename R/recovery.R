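#' Run the full inverse pipeline on a synthetic specimen
#'
#' Renders the specimen as a CT-like grayscale volume, segments it,
#' rebuilds the anatomical frame from the image alone (the known
#' generating frame is not used), crops and caps it with cartilage,
#' solves the unit load cases and predicts the joint loads.  This is the
#' forward/inverse consistency harness: the result can be compared
#' against the specimen's `true_load_mix`.
#'
#' @param specimen a `synthetic_specimen` from
#'   [generate_adapted_structure()].
#' @param gray_seed seed for the grayscale rendering noise (default:
#'   the specimen's remodelling seed + 1000).
#' @param bone_grey,background_grey,blur_sigma,noise_sd rendering
#'   parameters, see [synthesize_grayscale()].  The default blur is mild
#'   because the renderer's blur already stands for the scanner PSF at
#'   this coarse voxel size.
#' @param threshold,filter_sigma,filter_support segmentation parameters,
#'   see [preprocess()].  No additional smoothing is applied by default:
#'   at a grey-level contrast of 5000 and noise SD 150 the threshold is
#'   13 noise SDs away from both grey levels.
#' @param shaft_section_length distal section for the shaft line fit
#'   (mm); default a quarter of the domain extent.
#' @param crop_factor,cartilage_thickness,articular_limit_deg see
#'   [align_crop_cartilage()]; the default thickness is two voxels.
#' @param bone_modulus,cartilage_modulus,poisson materials, see
#'   [build_model()].
#' @param n_loads,angle_min,angle_max,opening_angle,distribution unit
#'   load set, see [make_load_set()].
#' @param equilibrium_stimulus,roi_reduction prediction configuration.
#' @param settings PCG settings for the unit-load solves.
#' @return list with `prediction` (a `load_prediction`), `frame`,
#'   `model`, `fe` and `sed_set`.
#' @export
invert_specimen <- function(specimen, gray_seed = NULL,
                            bone_grey = 6000, background_grey = 1000,
                            blur_sigma = 0.35, noise_sd = 150,
                            threshold = 3000, filter_sigma = 0,
                            filter_support = 2,
                            shaft_section_length = NULL,
                            crop_factor = 1.5, cartilage_thickness = NULL,
                            articular_limit_deg = 115,
                            bone_modulus = 10000, cartilage_modulus = 10,
                            poisson = 0.3,
                            n_loads = 4, angle_min = -20, angle_max = 100,
                            opening_angle = 40,
                            distribution = "uniform_normal",
                            equilibrium_stimulus = 0.02, roi_reduction = 0,
                            settings = solver_settings(tol = 1e-5)) {
  stopifnot(inherits(specimen, "synthetic_specimen"))
  h <- specimen$binary_structure$voxel_size
  if (is.null(gray_seed)) gray_seed <- specimen$params$seed + 1000L
  if (is.null(cartilage_thickness)) cartilage_thickness <- 2 * h
  if (is.null(shaft_section_length))
    shaft_section_length <- 0.2 * min(dim(specimen$binary_structure$values)) * h

  gray <- synthesize_grayscale(specimen$binary_structure,
                               bone_grey = bone_grey,
                               background_grey = background_grey,
                               blur_sigma = blur_sigma, noise_sd = noise_sd,
                               seed = gray_seed)
  bin <- preprocess(gray, filter_support = filter_support,
                    filter_sigma = filter_sigma, resample_factor = 1,
                    threshold = threshold)
  frame <- build_frame(bin, shaft_section_length = shaft_section_length)
  model <- align_crop_cartilage(bin, frame, crop_factor = crop_factor,
                                cartilage_thickness = cartilage_thickness,
                                articular_limit_deg = articular_limit_deg)
  fe <- suppressWarnings(
    build_model(model, bone_modulus, cartilage_modulus, poisson))
  specs <- make_load_set(n_loads, angle_min, angle_max,
                         opening_angle = opening_angle,
                         distribution = distribution)
  sed_set <- lapply(specs, function(sp)
    suppressWarnings(
      solve_load_case(fe, build_load_case(model, sp), settings)))
  roi <- make_roi(fe, roi_reduction)
  pred <- predict_loads(sed_set, roi,
                        load_prediction_config(equilibrium_stimulus))
  list(prediction = pred, frame = frame, model = model, fe = fe,
       sed_set = sed_set)
}
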