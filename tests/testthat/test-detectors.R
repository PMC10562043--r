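test_that("closed-form volumes match the published scintillator values", {
  lib <- fixture_lib()
  # 1 mm diameter fibres, 1 and 3 mm long: volumes determined by designation
  expect_equal(round(volume(lib[["Exradin W2 1x1"]]), 3), 0.785)
  expect_equal(round(volume(lib[["Exradin W2 1x3"]]), 3), 2.356)
  box <- detector_geometry("unit box", "box", dx = 1, dy = 1, dz = 1)
  expect_identical(volume(box), 1)
  # chamber closed form: cylinder + hemisphere - electrode
  ch <- detector_geometry("test chamber", "chamber", cavity_radius = 2,
                          cavity_length = 3, cap = TRUE,
                          electrode_radius = 0.5, electrode_length = 2)
  expect_equal(volume(ch), pi * 4 * 3 + 2 / 3 * pi * 8 - pi * 0.25 * 2,
               tolerance = 1e-12)
})

test_that("the shipped library has the expected composition", {
  lib <- fixture_lib()
  expect_length(lib, 14)
  types <- vapply(lib, `[[`, "", "type")
  expect_equal(sum(types == "ionization chamber"), 6)
  expect_equal(sum(types == "semiconductor"), 5)
  expect_equal(sum(types == "diamond"), 1)
  expect_equal(sum(types == "plastic scintillator"), 2)
  # Diode P and Diode E share one active-volume geometry
  p <- lib[["Diode P T60016"]]; e <- lib[["Diode E T60017"]]
  expect_identical(c(p$radius, p$thickness), c(e$radius, e$thickness))
  # published dimensional constraints
  pp <- lib[["PinPoint T31014"]]
  expect_equal((pp$cavity_length + pp$cavity_radius) / (2 * pp$cavity_radius),
               2.5, tolerance = 1e-9)   # active length 5 mm, R = 2.5
  cc <- lib[["IBA CC04"]]
  expect_equal(cc$cavity_length + cc$cavity_radius, 3.6, tolerance = 1e-9)
  expect_equal((cc$cavity_length + cc$cavity_radius) / (2 * cc$cavity_radius),
               0.9, tolerance = 1e-9)
  pp3 <- lib[["PinPoint 3D T31022"]]
  expect_equal((pp3$cavity_length + pp3$cavity_radius) /
                 (2 * pp3$cavity_radius), 1.23, tolerance = 1e-9)
  md <- lib[["microDiamond T60019"]]
  expect_equal(c(2 * md$radius, md$thickness), c(2.2, 0.001))
})

test_that("every shipped volume is within 10% of its nominal value", {
  lib <- fixture_lib()
  for (g in lib) {
    expect_true(is.finite(g$nominal_volume_mm3))
    expect_lt(abs(volume(g) - g$nominal_volume_mm3),
              0.10 * g$nominal_volume_mm3 + 1e-12)
  }
})

test_that("contains implements body-plus-cap-minus-electrode with closed boundary", {
  ch <- detector_geometry("ch", "chamber", cavity_radius = 2,
                          cavity_length = 4, cap = TRUE,
                          electrode_radius = 0.4, electrode_length = 4)
  zc <- gkvol:::.centroid_z(ch)
  # electrode spans the whole cavity axis: the origin is excluded
  expect_false(contains(ch, c(0, 0, 0)))
  # just outside the electrode radius, inside the cavity
  expect_true(contains(ch, c(0.41, 0, 0)))
  # cap apex (local coordinates shift by the centroid offset)
  expect_true(contains(ch, c(0, 0, 2 + 2 - zc)))
  expect_false(contains(ch, c(0, 0, 2 + 2 - zc + 1e-6)))
  # boundary counts as inside
  expect_true(contains(ch, c(2, 0, -zc)))
  expect_false(contains(ch, c(2 + 1e-9, 0, -zc)))
  # no electrode: the axis is inside
  ch2 <- detector_geometry("ch2", "chamber", cavity_radius = 2,
                           cavity_length = 4)
  expect_true(contains(ch2, c(0, 0, 0)))
})

test_that("contains is invariant under rotation about z for round shapes", {
  lib <- fixture_lib()
  set.seed(11)
  for (nm in c("Semiflex T31010", "microDiamond T60019", "Exradin W2 1x3")) {
    g <- lib[[nm]]
    bb <- gkvol:::.bounding_box(g)
    pts <- cbind(runif(500, bb[1, 1], bb[1, 2]),
                 runif(500, bb[2, 1], bb[2, 2]),
                 runif(500, bb[3, 1], bb[3, 2]))
    th <- 1.234
    rot <- cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
                 pts[, 1] * sin(th) + pts[, 2] * cos(th), pts[, 3])
    expect_identical(contains(g, pts), contains(g, rot))
  }
})

test_that("Monte Carlo volumes agree with the closed forms within 3 SE", {
  lib <- fixture_lib()
  for (g in lib) {
    est <- mc_volume(g, n = 2e5, seed = 17)
    expect_lte(abs(est$volume - volume(g)), 3 * est$se)
  }
})

test_that("library loading validates schema and rejects bad input", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(load_detector_library(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: mystery", "  shape: sphere", "  radius: 1"), bad)
  expect_error(load_detector_library(bad), "unknown shape.*mystery")
  expect_error(detector_geometry("x", "chamber", cavity_radius = 1,
                                 cavity_length = 2, electrode_radius = 1.5),
               "electrode_radius")
  expect_error(detector_geometry("x", "disk", radius = -1, thickness = 1),
               "positive")
})
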