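# Feature oracles: area/diameter identity, bounding rectangle, moments,
# geodesic length, thickness, circularity, elongatedness, feature chains.

px_mask <- function(bits, px = 0.5) ifc_mask(bits, "object", px)

test_that("area and equivalent diameter follow the exact identity", {
  one <- matrix(FALSE, 20, 20); one[10, 10] <- TRUE
  expect_equal(compute_area(px_mask(one)), 0.25)
  expect_equal(compute_area(px_mask(one, 1.0)), 4 * 0.25 / 1)  # units scale
  d <- disk_mask(20)
  a <- compute_area(px_mask(d))
  expect_equal(a, pi * 10^2, tolerance = 0.02)
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(100), 2 * sqrt(100 / pi))
  expect_equal(equivalent_diameter(a)^2 * pi / 4, a,
               tolerance = 1e-14)  # machine precision
  expect_error(equivalent_diameter(0), "positive")
  expect_error(compute_area(px_mask(one & FALSE)), "empty")
})

test_that("bounding rectangle matches exact and rotated rectangles", {
  r <- rect_mask(20, 10)
  expect_equal(bounding_rect(px_mask(r)), c(height_um = 10, width_um = 5))
  # rotated rectangle: rasterize a 20 x 10 px rectangle at 45 degrees
  n <- 41; c0 <- 21
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- (ij$j - c0) / sqrt(2) + (ij$i - c0) / sqrt(2)
  y <- -(ij$j - c0) / sqrt(2) + (ij$i - c0) / sqrt(2)
  r45 <- matrix(abs(x) <= 10 & abs(y) <= 5, n, n)
  hw <- bounding_rect(px_mask(r45))
  expect_equal(unname(hw[1]), 10, tolerance = 0.5 / 10)  # within 1 px
  expect_equal(unname(hw[2]), 5, tolerance = 0.5 / 5)
  hwd <- bounding_rect(px_mask(disk_mask(20)))  # radius 20 px = 20 um across
  expect_equal(unname(hwd[1]), 20, tolerance = 0.06)
  expect_equal(unname(hwd[1]), unname(hwd[2]), tolerance = 0.03)
  one <- matrix(FALSE, 20, 20); one[10, 10] <- TRUE
  expect_equal(unname(bounding_rect(px_mask(one))), c(0.5, 0.5))
})

test_that("major axis matches closed forms for disk and square", {
  expect_equal(major_axis(px_mask(disk_mask(20))), 20, tolerance = 0.03)
  sq <- rect_mask(15, 15)
  expect_equal(major_axis(px_mask(sq, 1)), 15 * sqrt(4 / 3), tolerance = 0.01)
  ell <- ellipse_mask(60, 20, angle = 0.4)
  expect_equal(major_axis(px_mask(ell, 1)), 120, tolerance = 0.03)
})

test_that("geodesic length: straight segments, convex Feret, horseshoe", {
  seg <- matrix(FALSE, 8, 60); seg[4, 6:55] <- TRUE
  expect_equal(geodesic_length(px_mask(seg)), 25.0)  # 50 px at 0.5 um

  for (bits in list(disk_mask(15), ellipse_mask(25, 10, angle = 0.7),
                    rect_mask(30, 12))) {
    gl <- geodesic_length(px_mask(bits, 1))
    feret <- feret_oracle(bits)
    expect_lt(abs(gl - feret) / feret, 0.02)
  }

  hs <- horseshoe_mask(16, 6)
  gl <- geodesic_length(px_mask(hs, 1))
  expect_gt(gl, feret_oracle(hs))
  expect_equal(gl, geodesic_oracle(hs) + 1, tolerance = 1e-9)
  expect_equal(gl, pi * 16 + 6, tolerance = 0.10 * (pi * 16 + 6))
})

test_that("farthest-point sweep agrees with the exact mode on a disk", {
  d <- disk_mask(18)
  exact <- geodesic_length(px_mask(d, 1))
  sweep <- geodesic_length(px_mask(d, 1), exact_limit = 10L)
  expect_equal(sweep, exact, tolerance = 0.02)
})

test_that("thickness max gives the shorter side / inscribed diameter", {
  expect_equal(thickness_max(px_mask(rect_mask(20, 10))), 5.0,
               tolerance = 0.5 / 5)
  expect_equal(thickness_max(px_mask(disk_mask(20))), 20, tolerance = 0.05)
  # saccate-like union: max over the lobes' inscribed disks
  sp <- synthetic_object_spec("saccate", 68, psf_sigma_um = 0, noise_sd = 0)
  p <- render_pollen(sp, pixel_size_um = 0.5, seed = 3)
  bits <- p$image$pixels < 0.5
  corpus_d <- 68 / 1.7
  expect_equal(thickness_max(px_mask(bits)), corpus_d, tolerance = 0.03)
})

test_that("circularity ranks disk > ellipse > doublet and is scale-free", {
  d <- circularity(px_mask(disk_mask(20)))
  e <- circularity(px_mask(ellipse_mask(20, 10)))
  sp <- synthetic_object_spec("doublet", 30, psf_sigma_um = 0, noise_sd = 0)
  dbl <- circularity(px_mask(render_pollen(sp, seed = 4)$image$pixels < 0.5))
  expect_gt(d, e)
  expect_gt(e, dbl)
  # scale invariance where the boundary-radius spread is shape-driven
  # (for near-perfect disks the spread is pure discretization, so the score
  # grows with size until it caps)
  expect_equal(circularity(px_mask(ellipse_mask(40, 20))),
               circularity(px_mask(ellipse_mask(20, 10))), tolerance = 0.1)
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_true(is.na(circularity(px_mask(tiny))))
})

test_that("elongatedness is the bounding-rectangle aspect", {
  expect_equal(elongatedness(px_mask(rect_mask(15, 15))), 1.0)
  expect_equal(elongatedness(px_mask(rect_mask(30, 15))), 2.0)
  ob <- oblate_features()
  tr <- merge(ob, oblate_gallery()$truth, by = "object_id")
  pol <- tr$elongatedness[tr$true_view == "polar"]
  eq <- tr$elongatedness[tr$true_view == "equatorial"]
  expect_lt(median(pol), 1.15)
  expect_equal(median(eq), 1.6, tolerance = 0.08)
})

test_that("all size features are monotone under dilation and chained", {
  shapes <- list(disk_mask(12), ellipse_mask(20, 9, 0.5), rect_mask(25, 10),
                 horseshoe_mask(14, 5))
  for (bits in shapes) {
    m <- px_mask(bits)
    big <- px_mask(ifcpollen:::.fill_holes(ifcpollen:::.dilate_px(bits, 2L)))
    feats <- function(mm) c(compute_area(mm), bounding_rect(mm),
                            major_axis(mm), geodesic_length(mm),
                            thickness_max(mm))
    expect_true(all(feats(big) >= feats(m) - 1e-9))
    hw <- bounding_rect(m)
    expect_lte(thickness_max(m), hw["width_um"] + 2 * 0.5)
    expect_lte(hw["width_um"], hw["height_um"])
    expect_lte(hw["height_um"], geodesic_length(m) + 0.5)
  }
})

test_that("extract_features flags cropped objects and conserves failures", {
  sp <- synthetic_object_spec("cropped", 25)
  p <- render_pollen(sp, seed = 8)
  f <- extract_features(p$image)
  expect_true(f$border_touch)
  blank <- obj_image(matrix(0.75, 48, 48), 0.5)
  f2 <- extract_features(blank, object_id = "blank1")
  expect_equal(f2$status, "empty_object")
  expect_equal(f2$object_id, "blank1")
  expect_true(is.na(f2$length_um))
})

test_that("all six size features of a rendered bead agree with its diameter", {
  b <- render_bead(30, seed = 10)
  f <- extract_features(b$image)
  for (col in c("diameter_um", "height_um", "width_um", "major_axis_um",
                "length_um", "thickness_max_um"))
    expect_equal(f[[col]], 30, tolerance = 0.03)
  expect_identical(f$diameter_um, equivalent_diameter(f$area_um2))
})
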