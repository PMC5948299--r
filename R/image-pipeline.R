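#' Separable 3-D Gaussian filter
#'
#' Truncated Gaussian kernel applied along each image axis in turn.  The
#' `support` is the truncation radius in voxels (the kernel covers
#' `2 * support + 1` voxels), matching the scanner-software convention of
#' quoting Gaussian filters as "support + sigma".
#'
#' @param img a `voxel_image`.
#' @param support truncation radius in voxels (integer >= 1).
#' @param sigma Gaussian standard deviation in voxels.
#' @param boundary `"replicate"` (edge values extended) or `"periodic"`
#'   (wrap-around; conserves the image mean exactly).
#' @return filtered `voxel_image`.
#' @export
gaussian_filter3 <- function(img, support = 2, sigma = 1.6,
                             boundary = c("replicate", "periodic")) {
  stopifnot(is_voxel_image(img))
  boundary <- match.arg(boundary)
  if (sigma <= 0) return(img)
  support <- as.integer(support)
  offs <- -support:support
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  vals <- img$values
  d <- dim(vals)
  for (ax in 1:3) {
    n <- d[ax]
    acc <- array(0, d)
    base <- seq_len(n)
    for (j in seq_along(offs)) {
      idx <- base + offs[j]
      idx <- if (boundary == "periodic") ((idx - 1L) %% n) + 1L
             else pmin(pmax(idx, 1L), n)
      acc <- acc + w[j] * switch(ax,
        vals[idx, , , drop = FALSE],
        vals[, idx, , drop = FALSE],
        vals[, , idx, drop = FALSE])
    }
    vals <- acc
  }
  img$values <- vals
  img
}

#' Block-mean downsampling
#'
#' Grey values are averaged over `factor^3` blocks; trailing voxels that do
#' not fill a complete block are dropped.
#'
#' @param img a `voxel_image`.
#' @param factor integer resampling factor (>= 1).
#' @return resampled `voxel_image` with `voxel_size * factor`.
#' @export
block_mean_resample <- function(img, factor) {
  stopifnot(is_voxel_image(img))
  if (factor != round(factor)) stop("resampling factor must be an integer")
  factor <- as.integer(factor)
  if (factor < 1L) stop("resampling factor must be >= 1")
  if (factor == 1L) return(img)
  d <- dim(img$values)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("image smaller than one block")
  v <- img$values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  voxel_image(out, voxel_size = img$voxel_size * factor, origin = img$origin)
}

#' Grayscale volume to binary bone segmentation
#'
#' Standard micro-CT preprocessing: block-mean resampling, Gaussian noise
#' filtering, then a fixed global threshold (inclusive: grey value >=
#' threshold is bone).
#'
#' @param img grayscale `voxel_image`.
#' @param filter_support Gaussian truncation radius in voxels.
#' @param filter_sigma Gaussian standard deviation in voxels; 0 disables
#'   filtering.
#' @param resample_factor integer block-mean factor (1 = no resampling).
#' @param threshold segmentation grey value.
#' @param boundary filter boundary handling, see [gaussian_filter3()].
#' @return binary `voxel_image` (logical values).  If the segmentation is
#'   empty the result carries `meta$all_background = TRUE` and a warning is
#'   issued.
#' @export
preprocess <- function(img, filter_support = 2, filter_sigma = 1.6,
                       resample_factor = 2, threshold = 3000,
                       boundary = "replicate") {
  stopifnot(is_voxel_image(img))
  out <- block_mean_resample(img, resample_factor)
  if (filter_sigma > 0)
    out <- gaussian_filter3(out, support = filter_support,
                            sigma = filter_sigma, boundary = boundary)
  bin <- out$values >= threshold
  res <- voxel_image(bin, voxel_size = out$voxel_size, origin = out$origin)
  res$meta <- list(all_background = !any(bin), threshold = threshold)
  if (res$meta$all_background)
    warning("segmentation produced an all-background image")
  res
}

#' Least-squares sphere fit to a point cloud
#'
#' Algebraic (Kasa) fit: linear least squares on
#' `|p|^2 = 2 c . p + (R^2 - |c|^2)`.
#'
#' @param pts n x 3 matrix of point coordinates (mm), n >= 4, not coplanar.
#' @return list with `centre`, `radius`, `rms` (radial residual RMS) and
#'   `n_points`.
#' @export
fit_sphere_points <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * pts, 1)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate point set (coplanar or collinear): sphere fit underdetermined")
  b <- rowSums(pts^2)
  sol <- qr.coef(qrA, b)
  centre <- sol[1:3]
  radius <- sqrt(sol[4] + sum(centre^2))
  r <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  list(centre = unname(centre), radius = unname(radius),
       rms = sqrt(mean((r - radius)^2)), n_points = nrow(pts))
}

surface_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(m, ax, o) {
    n <- d[ax]
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    bg_edge <- if (o > 0) n else 1L
    out <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                  m[, , idx, drop = FALSE])
    # voxels at the array edge see background outside
    switch(ax,
           out[bg_edge, , ] <- FALSE,
           out[, bg_edge, ] <- FALSE,
           out[, , bg_edge] <- FALSE)
    out
  }
  for (ax in 1:3) for (o in c(-1L, 1L))
    interior <- interior & shift_and(mask, ax, o)
  mask & !interior
}

# foreground voxels visible from outside: adjacent (6-conn) to background
# that is itself connected to the image boundary; interior pore surfaces
# are excluded
outer_surface_voxels <- function(mask) {
  d <- dim(mask)
  labs <- cpp_label_components(!mask, as.integer(d))
  edge <- setdiff(unique(c(labs[1, , ], labs[d[1], , ], labs[, 1, ],
                           labs[, d[2], ], labs[, , 1], labs[, , d[3]])), 0L)
  out_bg <- array(labs %in% edge, d)
  grown <- out_bg
  shift_or <- function(m, ax, o) {
    n <- d[ax]
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
           m[, , idx, drop = FALSE])
  }
  for (ax in 1:3) for (o in c(-1L, 1L))
    grown <- grown | shift_or(out_bg, ax, o)
  # voxels on the array boundary face the outside as well
  grown[1, , ] <- TRUE; grown[d[1], , ] <- TRUE
  grown[, 1, ] <- TRUE; grown[, d[2], ] <- TRUE
  grown[, , 1] <- TRUE; grown[, , d[3]] <- TRUE
  mask & grown
}

#' Fit the femoral head sphere
#'
#' Extracts bone surface voxels visible from outside (interior pore
#' surfaces are excluded), restricts them to the proximal head region and
#' fits a least-squares sphere.  The head surface point selection is a
#' documented approximation: an initial fit on the proximal outer-surface
#' band is refined by keeping points on the proximal hemisphere within a
#' radial band around the fitted surface.
#'
#' @param binary binary `voxel_image`.
#' @param head_region_hint optional list with `lo` and `hi` (mm corners) of
#'   a box known to contain the head surface; overrides the proximal-band
#'   heuristic.
#' @param proximal_frac initial selection: surface voxels within this top
#'   fraction of the specimen's vertical extent.
#' @param refine number of refinement passes.
#' @return list with `centre` (mm), `radius` (mm), `rms`, `n_points`.
#' @export
fit_head_sphere <- function(binary, head_region_hint = NULL,
                            proximal_frac = 0.45, refine = 2) {
  stopifnot(is_voxel_image(binary))
  mask <- as.logical(binary$values)
  dim(mask) <- dim(binary$values)
  surf <- which(outer_surface_voxels(mask))
  if (length(surf) < 4L) stop("fewer than 4 surface points")
  pts <- voxel_centres(binary, surf)
  if (!is.null(head_region_hint)) {
    lo <- head_region_hint$lo; hi <- head_region_hint$hi
    keep <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
            pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
            pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    pts <- pts[keep, , drop = FALSE]
  } else {
    zr <- range(pts[, 3])
    pts <- pts[pts[, 3] >= zr[2] - proximal_frac * diff(zr), , drop = FALSE]
  }
  fit <- fit_sphere_points(pts)
  for (k in seq_len(refine)) {
    rel <- sweep(pts, 2, fit$centre)
    r <- sqrt(rowSums(rel^2))
    keep <- abs(r - fit$radius) < 0.25 * fit$radius & rel[, 3] > 0
    if (sum(keep) < 4L) break
    fit <- fit_sphere_points(pts[keep, , drop = FALSE])
  }
  fit
}

#' Anatomical frame constructor
#'
#' Implant-style axis triad: columns of `axes` are the medio-lateral
#' (+medial), anterior-posterior (+anterior) and vertical (+proximal) unit
#' vectors expressed in image coordinates.
#'
#' @param head_centre,neck_midpoint length-3 coordinates (mm).
#' @param head_radius femoral head radius (mm, > 0).
#' @param axes 3 x 3 matrix, orthonormal to 1e-9, right-handed.
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(head_centre, head_radius, neck_midpoint, axes) {
  axes <- as.matrix(axes)
  if (head_radius <= 0) stop("head radius must be positive")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("axes must be orthonormal to 1e-9")
  if (det(axes) < 0) stop("axes must form a right-handed triad")
  structure(list(head_centre = as.numeric(head_centre),
                 head_radius = as.numeric(head_radius),
                 neck_midpoint = as.numeric(neck_midpoint),
                 axes = axes),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> head centre (%.2f, %.2f, %.2f) mm, R = %.2f mm\n",
              x$head_centre[1], x$head_centre[2], x$head_centre[3],
              x$head_radius))
  invisible(x)
}

#' Serialize an anatomical frame to a structured text file
#'
#' @param frame an `anatomical_frame`.
#' @param path output path.
#' @return `read_frame` returns the `anatomical_frame`.
#' @export
write_frame <- function(frame, path) {
  fmt <- function(v) paste(sprintf("%.12g", v), collapse = " ")
  writeLines(c("# anatomical frame (mm)",
               paste("head_centre =", fmt(frame$head_centre)),
               paste("head_radius =", fmt(frame$head_radius)),
               paste("neck_midpoint =", fmt(frame$neck_midpoint)),
               paste("axes_ml =", fmt(frame$axes[, 1])),
               paste("axes_ap =", fmt(frame$axes[, 2])),
               paste("axes_vert =", fmt(frame$axes[, 3]))), path)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    l <- grep(paste0("^", key, " *="), lines, value = TRUE)
    as.numeric(strsplit(trimws(sub("^[^=]*=", "", l[1])), " +")[[1]])
  }
  anatomical_frame(get("head_centre"), get("head_radius"),
                   get("neck_midpoint"),
                   cbind(get("axes_ml"), get("axes_ap"), get("axes_vert")))
}

#' Build the implant-style anatomical frame
#'
#' The vertical axis is the shaft axis (line fit through slice centroids of
#' a distal section), the neck axis connects the head centre to the
#' midpoint of the smallest neck cross-section, the anterior-posterior axis
#' is `vertical x neck` and the medio-lateral axis `ap x vertical`
#' (right-handed triad, orthonormal by construction).
#'
#' @param binary binary `voxel_image`, z axis roughly vertical with the
#'   distal end at low z.
#' @param shaft_section_length length (mm) of the distal section used for
#'   the shaft line fit.
#' @param neck_search_range cross-section search interval along the neck
#'   axis, as multiples of the head radius.
#' @param head_region_hint passed to [fit_head_sphere()].
#' @return an `anatomical_frame`.
#' @export
build_frame <- function(binary, shaft_section_length = 40,
                        neck_search_range = c(0.6, 2.8),
                        head_region_hint = NULL) {
  stopifnot(is_voxel_image(binary))
  h <- binary$voxel_size
  mask <- as.logical(binary$values)
  dim(mask) <- dim(binary$values)
  idx <- which(mask)
  if (!length(idx)) stop("empty structure")
  pts <- voxel_centres(binary, idx)

  sph <- fit_head_sphere(binary, head_region_hint = head_region_hint)
  C <- sph$centre; R <- sph$radius

  ## shaft line: slice-centroid fit over the distal section.  Slicing is
  ## along the image z axis (specimens are assumed roughly upright, tilt
  ## below ~15 degrees).  Partial slices (the wedges a tilted specimen
  ## presents at the section ends) and slices off the line
  ## (neck/trochanter contamination) are dropped before refitting.
  fit_line <- function(cent) {
    cc <- scale(cent, scale = FALSE)
    v <- svd(cc, nu = 0, nv = 1)$v[, 1]
    if (v[3] < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  z <- pts[, 3]
  zlo <- min(z)
  sel <- z <= zlo + shaft_section_length
  ks <- round((z[sel] - zlo) / h)
  counts <- tapply(rep(1, sum(sel)), ks, sum)
  cent <- cbind(tapply(pts[sel, 1], ks, mean),
                tapply(pts[sel, 2], ks, mean),
                tapply(pts[sel, 3], ks, mean))
  full <- counts >= 0.8 * max(counts)
  if (sum(full) >= 3L) cent <- cent[full, , drop = FALSE]
  if (nrow(cent) < 3L) stop("distal shaft section too short for a line fit")
  v <- fit_line(cent)
  for (pass in 1:2) {
    cc <- scale(cent, scale = FALSE)
    resid <- sqrt(rowSums((cc - outer(as.numeric(cc %*% v), v))^2))
    keep <- resid <= max(2 * stats::median(resid), 0.75 * h)
    if (sum(keep) < 3L || all(keep)) break
    cent <- cent[keep, , drop = FALSE]
    v <- fit_line(cent)
  }

  ## neck: smallest cross-section between head centre and shaft
  a <- C - colMeans(cent)
  a <- a / sqrt(sum(a^2))
  neck <- NULL
  for (pass in 1:2) {
    ts <- seq(neck_search_range[1] * R, neck_search_range[2] * R, by = h)
    proj <- as.numeric(sweep(pts, 2, C) %*% (-a))
    areas <- numeric(length(ts))
    for (i in seq_along(ts))
      areas[i] <- sum(abs(proj - ts[i]) <= h / 2) * h^2
    sm <- stats::filter(areas, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- areas[is.na(sm)]
    interior <- 3:(length(ts) - 2)
    if (length(interior) < 1L) stop("neck search interval too short")
    imin <- interior[which.min(sm[interior])]
    end_min <- min(sm[c(1, 2, length(ts) - 1, length(ts))])
    if (!(sm[imin] < end_min * (1 - 1e-9)))
      stop("no interior minimum of cross-sectional area along the neck axis ",
           "(constant or monotone cross-section)")
    slab <- abs(proj - ts[imin]) <= h / 2
    neck <- colMeans(pts[slab, , drop = FALSE])
    a <- C - neck
    a <- a / sqrt(sum(a^2))
  }

  w <- a  # neck axis, pointing from neck midpoint to head centre
  apv <- c(v[2] * w[3] - v[3] * w[2],
           v[3] * w[1] - v[1] * w[3],
           v[1] * w[2] - v[2] * w[1])  # vertical x neck
  napv <- sqrt(sum(apv^2))
  if (napv < 1e-6) stop("neck axis parallel to shaft axis: frame undefined")
  apv <- apv / napv
  ml <- c(apv[2] * v[3] - apv[3] * v[2],
          apv[3] * v[1] - apv[1] * v[3],
          apv[1] * v[2] - apv[2] * v[1])  # ap x vertical
  ml <- ml / sqrt(sum(ml^2))
  anatomical_frame(head_centre = C, head_radius = R, neck_midpoint = neck,
                   axes = cbind(ml, apv, v))
}

#' Align, crop and add the cartilage layer
#'
#' Resamples the binary image into the anatomical frame (nearest
#' neighbour), crops to a box extending `crop_factor * R` lateral and
#' distal of the head centre, keeps the largest connected bone component,
#' and fills a spherical cartilage layer between the bone surface and the
#' outer sphere of radius `R + cartilage_thickness` over the articular
#' region.  Verifies that no bone penetrates the cartilage surface.
#'
#' @param binary binary `voxel_image` in image coordinates.
#' @param frame an `anatomical_frame` for the same image.
#' @param crop_factor box extent lateral/distal of the head centre, as a
#'   multiple of the head radius (>= 1).
#' @param cartilage_thickness cartilage layer thickness (mm, > 0).
#' @param articular_limit_deg polar angle from the vertical axis up to
#'   which the cartilage cap is laid (degrees).
#' @param margin extra voxels of padding on the medial/proximal/AP sides.
#' @return object of class `segmented_model` with fields `labels`
#'   (0 background, 1 bone, 2 cartilage), `voxel_size`, `head_centre`
#'   (mm, in the cropped grid), `head_radius`, `cartilage_thickness`,
#'   `frame`, and `meta`.
#' @export
align_crop_cartilage <- function(binary, frame, crop_factor = 1.5,
                                 cartilage_thickness = 2.2,
                                 articular_limit_deg = 115, margin = 2) {
  stopifnot(is_voxel_image(binary), inherits(frame, "anatomical_frame"))
  if (crop_factor < 1) stop("crop_factor must be >= 1")
  if (cartilage_thickness <= 0) stop("cartilage_thickness must be positive")
  h <- binary$voxel_size
  R <- frame$head_radius
  t <- cartilage_thickness
  m <- margin * h
  lo <- c(-crop_factor * R, -(R + t + m), -crop_factor * R)
  hi <- c(R + t + m, R + t + m, R + t + m)
  nd <- pmax(as.integer(ceiling((hi - lo) / h)), 1L)

  ## output voxel centres in frame coordinates (relative to head centre)
  gx <- lo[1] + (seq_len(nd[1]) - 0.5) * h
  gy <- lo[2] + (seq_len(nd[2]) - 0.5) * h
  gz <- lo[3] + (seq_len(nd[3]) - 0.5) * h
  q <- cbind(rep(gx, times = nd[2] * nd[3]),
             rep(rep(gy, each = nd[1]), times = nd[3]),
             rep(gz, each = nd[1] * nd[2]))
  p <- q %*% t(frame$axes)
  p <- sweep(p, 2, frame$head_centre, "+")
  src <- floor(sweep(p, 2, binary$origin) / h) + 1L
  d0 <- dim(binary$values)
  ok <- src[, 1] >= 1L & src[, 1] <= d0[1] &
        src[, 2] >= 1L & src[, 2] <= d0[2] &
        src[, 3] >= 1L & src[, 3] <= d0[3]
  bone <- logical(nrow(src))
  lin <- (src[ok, 3] - 1L) * (d0[1] * d0[2]) + (src[ok, 2] - 1L) * d0[1] + src[ok, 1]
  bone[ok] <- as.logical(binary$values)[lin]
  dim(bone) <- nd

  n_before <- sum(bone)
  bone <- largest_component(bone, connectivity = 26)
  n_removed <- n_before - sum(bone)
  if (!any(bone)) stop("no bone left after cropping")

  centre_local <- -lo  # head centre in cropped-grid mm coordinates
  dist <- sqrt(outer(outer((gx)^2, (gy)^2, "+"), (gz)^2, "+"))
  cosang <- outer(outer(gx * 0, gy * 0, "+"), gz, "+") / pmax(dist, 1e-12)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  in_cap <- ang <= articular_limit_deg

  viol <- bone & in_cap & dist > (R + t)
  if (any(viol))
    stop(sprintf(paste0("%d bone voxel(s) penetrate the outer sphere ",
                        "R + thickness = %.2f mm; increase cartilage_thickness"),
                 sum(viol), R + t))

  outside <- !bone
  labs <- cpp_label_components(outside, as.integer(nd))
  edge_labels <- unique(c(labs[1, , ], labs[nd[1], , ], labs[, 1, ],
                          labs[, nd[2], ], labs[, , 1], labs[, , nd[3]]))
  edge_labels <- setdiff(edge_labels, 0L)
  out_bg <- array(labs %in% edge_labels, nd)

  cart <- out_bg & in_cap & dist <= (R + t)
  labels <- array(0L, nd)
  labels[bone] <- 1L
  labels[cart] <- 2L

  structure(list(labels = labels, voxel_size = h,
                 head_centre = centre_local, head_radius = R,
                 cartilage_thickness = t, frame = frame,
                 crop_lo = lo, crop_hi = lo + nd * h,
                 meta = list(floating_voxels_removed = n_removed,
                             articular_limit_deg = articular_limit_deg)),
            class = "segmented_model")
}

#' @export
print.segmented_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<segmented_model> %d x %d x %d voxels (%.3g mm), %d bone, %d cartilage\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$labels == 1L),
              sum(x$labels == 2L)))
  invisible(x)
}
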