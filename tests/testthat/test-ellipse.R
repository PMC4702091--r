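test_that("points on a circle recover radius and area to machine-level", {
  f <- fitEllipse(ellipsePoints(5, 5, n = 36))
  expect_equal(f@semiMajor, 5, tolerance = 1e-6)
  expect_equal(f@semiMinor, 5, tolerance = 1e-6)
  expect_equal(f@area, 78.53982, tolerance = 1e-5)
  expect_equal(f@rmsResidual, 0, tolerance = 1e-6)
  expect_identical(f@method, "ellipse")
})

test_that("rotated ellipse parameters are recovered exactly from exact points", {
  f <- fitEllipse(ellipsePoints(6, 3, theta = pi / 6, cx = 12, cy = -4))
  expect_equal(f@semiMajor, 6, tolerance = 1e-6)
  expect_equal(f@semiMinor, 3, tolerance = 1e-6)
  expect_equal(f@center, c(12, -4), tolerance = 1e-6)
  expect_equal(f@orientation, pi / 6, tolerance = 1e-6)
  expect_equal(f@area, pi * 18, tolerance = 1e-6)
})

test_that("voxel-to-mm scaling is applied before fitting", {
  pts <- ellipsePoints(8, 4, cx = 20, cy = 20) # in voxel units
  f <- fitEllipse(pts, voxelSize = c(0.5, 0.5))
  expect_equal(f@semiMajor, 4, tolerance = 1e-6)
  expect_equal(f@semiMinor, 2, tolerance = 1e-6)
})

test_that("under-determined or collinear inputs are errors", {
  expect_error(fitEllipse(ellipsePoints(5, 5, n = 4)), "at least 5")
  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(fitEllipse(line), "collinear|degenerate")
})

test_that("width assignment by axis projection matches the control geometry", {
  # LR semi-axis 4.9 (major, along x), AP semi-axis 4.35
  f <- fitEllipse(ellipsePoints(4.9, 4.35, theta = 0))
  f <- assignWidths(f, orientationLabels = c("LR", "AP"))
  expect_equal(f@lrw, 9.8, tolerance = 1e-6)
  expect_equal(f@apw, 8.7, tolerance = 1e-6)
})

test_that("a circle has equal widths regardless of orientation", {
  for (th in c(0, pi / 3)) {
    f <- fitEllipse(ellipsePoints(4, 4, theta = th))
    f <- assignWidths(f)
    expect_equal(f@apw, 8, tolerance = 1e-6)
    expect_equal(f@lrw, 8, tolerance = 1e-6)
  }
})

test_that("rotating an ellipse by 90 degrees swaps the projected widths", {
  f0 <- assignWidths(fitEllipse(ellipsePoints(6, 3, theta = 0)))
  f90 <- assignWidths(fitEllipse(ellipsePoints(6, 3, theta = pi / 2)))
  expect_equal(f0@apw, f90@lrw, tolerance = 1e-6)
  expect_equal(f0@lrw, f90@apw, tolerance = 1e-6)
  expect_equal(f0@lrw, 12, tolerance = 1e-6)
})

test_that("projected widths follow the rotated-width closed form", {
  for (th in c(0.2, 0.9, 1.4)) {
    f <- assignWidths(fitEllipse(ellipsePoints(6, 3, theta = th)))
    expect_equal(f@lrw, ellipseWidth(6, 3, th, 0), tolerance = 1e-6)
    expect_equal(f@apw, ellipseWidth(6, 3, th, pi / 2), tolerance = 1e-6)
    # independent oracle: support width of a dense boundary sample
    dense <- ellipsePoints(6, 3, theta = th, n = 20000)
    expect_equal(f@lrw, bruteWidth(dense, 0), tolerance = 1e-4)
    expect_equal(f@apw, bruteWidth(dense, pi / 2), tolerance = 1e-4)
  }
})

test_that("the axis-label convention assigns the long axis to APW", {
  f <- assignWidths(fitEllipse(ellipsePoints(6, 3, theta = 0.4)),
                    mode = "axis-label")
  expect_equal(f@apw, 12, tolerance = 1e-6)
  expect_equal(f@lrw, 6, tolerance = 1e-6)
  expect_error(assignWidths(fitEllipse(ellipsePoints(6, 3)),
                            orientationLabels = c("x", "y")), "LR and AP")
})
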