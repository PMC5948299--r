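test_that("load sets are equally spaced inclusive of endpoints", {
  s4 <- make_load_set(4, -20, 100)
  expect_equal(vapply(s4, `[[`, numeric(1), "inclination"),
               c(-20, 20, 60, 100))
  s13 <- make_load_set(13, -20, 100)
  incl <- vapply(s13, `[[`, numeric(1), "inclination")
  expect_equal(incl, seq(-20, 100, by = 10))
  off <- make_load_set(4, -20, 100, rotation_offset = 10)
  expect_equal(vapply(off, function(s) s$inclination + s$rotation_offset,
                      numeric(1)), c(-10, 30, 70, 110))
  expect_warning(s1 <- make_load_set(1, -20, 100), "single")
  expect_equal(s1[[1]]$inclination, -20)
  expect_error(load_patch_spec(20, opening_angle = 190), "0, 180")
})

test_that("cap area matches the closed form and inverts", {
  ## full-femur scale: 40 degree cone on R ~ 24.3 mm is within the printed
  ## patch-area band 224.24 +/- 23.44 mm^2
  a <- cap_area(24.3, 40)
  expect_lt(abs(a - 224.24), 23.44)
  expect_equal(cone_opening_for_area(24.3, a), 40, tolerance = 1e-12)
  expect_error(cone_opening_for_area(5, 1000), "exceeds")
})

test_that("nodal forces hit the resultant magnitude to 1e-9 relative", {
  model <- make_ball_model()
  for (mode in c("uniform_normal", "uniform_parallel", "hertz_parallel")) {
    lc <- build_load_case(model, load_patch_spec(20, distribution = mode))
    expect_lt(abs(sqrt(sum(colSums(lc$forces)^2)) - 1000) / 1000, 1e-9)
  }
})

test_that("uniform normal forces on a symmetric cap align with the axis", {
  model <- make_ball_model()
  lc <- build_load_case(model, load_patch_spec(20))
  achieved <- -colSums(lc$forces)
  mis <- acos(sum(achieved * lc$direction) /
                sqrt(sum(achieved^2))) * 180 / pi
  expect_lt(mis, 0.5)
})

test_that("uniform parallel nodal forces are exactly equal", {
  model <- make_ball_model()
  lc <- build_load_case(model,
                        load_patch_spec(20, distribution = "uniform_parallel"))
  expect_equal(max(lc$forces[, 1]), min(lc$forces[, 1]))
  expect_equal(lc$forces[1, ],
               -lc$direction * 1000 / lc$n_patch_nodes, tolerance = 1e-12)
})

test_that("Hertz weights vanish at the rim and peak at the pole", {
  model <- make_ball_model()
  lc <- build_load_case(model,
                        load_patch_spec(20, distribution = "hertz_parallel"))
  mag <- sqrt(rowSums(lc$forces^2))
  d <- dim(model$labels)
  pos <- sweep((lc$node_ijk - 1) * model$voxel_size, 2, model$head_centre)
  ang <- acos(pmin(1, as.numeric(pos %*% lc$direction) /
                     sqrt(rowSums(pos^2)))) * 180 / pi
  ## one voxel of angular tolerance at the rim: h / (R + t) ~ 2.3 degrees
  rim <- ang > 19
  pole <- ang < 4
  expect_true(any(rim))
  expect_lt(max(mag[rim]), 0.35 * max(mag))
  expect_gt(min(mag[pole]), 0.8 * max(mag))
})

test_that("patch membership grows monotonically with the opening angle", {
  model <- make_ball_model()
  nodes <- lapply(c(20, 30, 40, 60), function(o)
    build_load_case(model, load_patch_spec(20, opening_angle = o))$nodes)
  for (k in 1:3)
    expect_true(all(nodes[[k]] %in% nodes[[k + 1]]))
})

test_that("an empty patch raises an error", {
  model <- make_ball_model()
  expect_error(build_load_case(model, load_patch_spec(-178,
                                                      opening_angle = 10)),
               "empty load patch")
})

test_that("load cases serialize to a text table", {
  model <- make_ball_model()
  lc <- build_load_case(model, load_patch_spec(20))
  p <- file.path(tempdir(), "lc.txt")
  write_load_case(lc, p)
  tab <- utils::read.table(p, header = TRUE)
  expect_equal(nrow(tab), lc$n_patch_nodes)
  expect_equal(sum(tab$fz_N), sum(lc$forces[, 3]), tolerance = 1e-9)
})
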