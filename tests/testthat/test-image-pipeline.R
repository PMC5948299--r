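test_that("segmentation follows the inclusive threshold rule", {
  img <- voxel_image(array(3500, c(4, 4, 4)), 1)
  bin <- preprocess(img, filter_sigma = 0, resample_factor = 1,
                    threshold = 3000)
  expect_true(all(bin$values))

  ## alternating {0, 6000} checkerboard block-means to exactly 3000
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  chk <- array(ifelse(rowSums(idx) %% 2 == 0, 6000, 0), c(4, 4, 4))
  bin2 <- preprocess(voxel_image(chk, 1), filter_sigma = 0,
                     resample_factor = 2, threshold = 3000)
  expect_equal(dim(bin2$values), c(2L, 2L, 2L))
  expect_true(all(bin2$values))           # >= rule: 3000 is bone
  expect_equal(bin2$voxel_size, 2)
})

test_that("Gaussian filtering conserves the mean under periodic boundaries", {
  set.seed(4)
  img <- voxel_image(array(runif(10^3, 0, 6000), c(10, 10, 10)), 1)
  out <- gaussian_filter3(img, support = 2, sigma = 1.6,
                          boundary = "periodic")
  expect_lt(abs(mean(out$values) - mean(img$values)), 1e-9)
})

test_that("preprocess is idempotent on binary images", {
  set.seed(5)
  img <- voxel_image(array(runif(6^3) > 0.5, c(6, 6, 6)), 1)
  out <- preprocess(img, filter_sigma = 0, resample_factor = 1,
                    threshold = 0.5)
  expect_equal(out$values, img$values)
})

test_that("preprocess flags empty segmentations and bad factors", {
  img <- voxel_image(array(100, c(4, 4, 4)), 1)
  expect_warning(bin <- preprocess(img, filter_sigma = 0,
                                   resample_factor = 1, threshold = 3000),
                 "all-background")
  expect_true(bin$meta$all_background)
  expect_error(preprocess(img, resample_factor = 1.5), "integer")
})

test_that("sphere fit recovers an exact digital sphere within half a voxel", {
  img <- make_ball_image(R = 24.3, h = 1, centre = c(30, 30, 30))
  fit <- fit_head_sphere(img, proximal_frac = 1)
  expect_lt(max(abs(fit$centre - c(30, 30, 30))), 0.5)
  expect_lt(abs(fit$radius - 24.3), 0.5)
  expect_true(fit$rms < 0.5)
})

test_that("hemisphere point clouds with radial noise fit within 0.2 mm", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 600
    z <- runif(n)                      # upper hemisphere
    phi <- runif(n, 0, 2 * pi)
    r <- 24.3 + rnorm(n, 0, 0.1)
    pts <- cbind(r * sqrt(1 - z^2) * cos(phi),
                 r * sqrt(1 - z^2) * sin(phi), r * z)
    pts <- sweep(pts, 2, c(30, 30, 30), "+")
    fit <- fit_sphere_points(pts)
    sqrt(sum((fit$centre - c(30, 30, 30))^2))
  }, numeric(1))
  expect_lt(mean(errs), 0.2)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_sphere_points(diag(3)), "at least 4")
  coplanar <- cbind(runif(20), runif(20), 1)
  expect_error(fit_sphere_points(coplanar), "degenerate")
})

test_that("sphere fit is invariant to rigid translation", {
  img1 <- make_ball_image(R = 8, h = 0.5)
  f1 <- fit_head_sphere(img1, proximal_frac = 1)
  img2 <- img1
  img2$origin <- img1$origin + c(5, -3, 2)
  f2 <- fit_head_sphere(img2, proximal_frac = 1)
  expect_equal(f2$centre, f1$centre + c(5, -3, 2), tolerance = 1e-9)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)
})

test_that("frame construction recovers known axes within 1 degree", {
  geom <- mini_joint_geometry(c(40, 40, 40), 0.5)
  img <- voxel_image(geom$envelope, 0.5)
  fr <- build_frame(img, shaft_section_length = 5)
  ang <- acos(pmin(1, diag(crossprod(fr$axes, geom$axes)))) * 180 / pi
  expect_true(all(ang < 1))
  expect_lt(max(abs(crossprod(fr$axes) - diag(3))), 1e-9)
  expect_lt(sqrt(sum((fr$head_centre - geom$head_centre)^2)), 0.5)
})

test_that("frame construction is equivariant under rotation", {
  th <- 8 * pi / 180   # rotation about the AP axis
  Q <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  geom <- mini_joint_geometry(c(40, 40, 40), 0.5, rotation = Q)
  img <- voxel_image(geom$envelope, 0.5)
  fr <- build_frame(img, shaft_section_length = 5)
  ang <- acos(pmin(1, diag(crossprod(fr$axes, Q)))) * 180 / pi
  expect_true(all(ang < 1))
})

test_that("a constant cross-section cylinder has no neck minimum", {
  n <- 40
  g <- (seq_len(n) - 0.5)
  r2 <- outer((g - n / 2)^2, (g - n / 2)^2, "+")
  cyl <- array(rep(r2 <= 8^2, n), c(n, n, n))
  ball <- array(outer(r2, (g - 32)^2, "+") <= 7.9^2, c(n, n, n))
  expect_error(build_frame(voxel_image(cyl | ball, 1),
                           shaft_section_length = 8),
               "no interior minimum")
})

test_that("cartilage cap has the requested radial extent on an ideal ball", {
  R <- 10; h <- 0.5; t <- 2.2
  model <- make_ball_model(R = R, h = h, thickness = t)
  cart <- which(model$labels == 2L)
  d <- dim(model$labels)
  pos <- (arrayInd(cart, d) - 0.5) * h
  dist <- sqrt(rowSums(sweep(pos, 2, model$head_centre)^2))
  expect_true(all(dist <= R + t + h))
  expect_true(all(dist >= R - h))
  ## radial thickness along the polar axis ~ t
  up <- abs(pos[, 1] - model$head_centre[1]) < h &
        abs(pos[, 2] - model$head_centre[2]) < h &
        pos[, 3] > model$head_centre[3]
  expect_equal(max(dist[up]) - min(dist[up]), t, tolerance = 2 * h)
})

test_that("bone beyond the outer sphere raises the thickness error", {
  img <- make_ball_image(R = 10, h = 0.5, pad = 10)
  n <- dim(img$values)[1]
  centre <- rep(n * 0.5 / 2, 3)
  ## bump sticking out beyond the outer sphere R + thickness
  k <- round(centre[3] / 0.5) + seq(19, 26)
  img$values[round(centre[1] / 0.5), round(centre[2] / 0.5), k] <- TRUE
  frame <- anatomical_frame(centre, 10, centre - c(0, 0, 10), diag(3))
  expect_error(align_crop_cartilage(img, frame, cartilage_thickness = 2.2),
               "penetrate")
})

test_that("crop box edges sit at crop_factor times the head radius", {
  R <- 10; h <- 0.5
  model <- make_ball_model(R = R, h = h)
  ## head centre measured from the box corner equals 1.5 R lateral/distal
  expect_equal(model$head_centre[1], 1.5 * R, tolerance = h)
  expect_equal(model$head_centre[3], 1.5 * R, tolerance = h)
  expect_equal(model$crop_hi[1] - model$crop_lo[1],
               dim(model$labels)[1] * h)
})
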