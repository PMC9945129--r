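test_that("study geometry reproduces the printed design numbers", {
  geo <- study_geometry()
  expect_equal(geo$px_per_deg, 918 / 32.4)
  # visible-area fractions for the printed fragment sizes/counts
  expect_equal(round(100 * visible_area_fraction(2.4, 10, geo), 1), 7.5)
  expect_equal(round(100 * visible_area_fraction(0.6, 10, geo), 2), 0.47)
  expect_equal(round(100 * visible_area_fraction(2.4, 1, geo), 2), 0.75)
  expect_equal(round(100 * visible_area_fraction(0.3, 10, geo), 2), 0.12)
  expect_equal(round(100 * visible_area_fraction(1.2, 1, geo), 1), 0.2)
  expect_equal(visible_area_fraction(2.4, 0, geo), 0)
  # a 3x3-pixel feature subtends ~0.1 deg
  expect_equal(round(feature_subtense_deg(geo), 1), 0.1)
})

test_that("degree-to-pixel conversion rounds ties toward the smaller value", {
  geo <- study_geometry()
  expect_equal(deg_to_px(c(2.4, 1.2, 0.6, 0.3), geo), c(68L, 34L, 17L, 8L))
  expect_error(display_geometry(width_px = 918, height_px = 672,
                                width_deg = 32.4, height_deg = 30),
               "inconsistent")
})

test_that("fragment placement satisfies frame, quota and disjointness rules", {
  geo <- study_geometry(); fr <- study_frame()
  quotas <- c(top = 3, bottom = 3, left = 2, right = 2)
  cfg <- place_fragments(geo, fr, 2.4, 10, quotas, seed = 7)
  expect_equal(nrow(cfg$boxes), 10)
  expect_equal(cfg$fragment_size_px, 68)
  chk <- check_fragment_configuration(cfg, geo, fr)
  expect_true(chk$ok)
  got_quota <- table(cfg$boxes$side)[c("top", "bottom", "left", "right")]
  expect_equal(as.integer(got_quota), unname(quotas))

  # deterministic given the seed
  cfg2 <- place_fragments(geo, fr, 2.4, 10, quotas, seed = 7)
  expect_identical(cfg$boxes, cfg2$boxes)
  cfg3 <- place_fragments(geo, fr, 2.4, 10, quotas, seed = 8)
  expect_false(identical(cfg$boxes, cfg3$boxes))

  expect_equal(nrow(place_fragments(geo, fr, 2.4, 0, seed = 1)$boxes), 0)

  # 200 fragments of 2.4 deg cannot fit in the band area
  expect_error(place_fragments(geo, fr, 2.4, 200, seed = 1), "placement|area")
})

test_that("the checker flags violated configurations", {
  geo <- study_geometry(); fr <- study_frame()
  cfg <- place_fragments(geo, fr, 2.4, 5, seed = 3)
  bad <- cfg
  bad$boxes$x[2] <- bad$boxes$x[1]   # force overlap
  bad$boxes$y[2] <- bad$boxes$y[1]
  chk <- check_fragment_configuration(bad, geo, fr)
  expect_false(chk$ok)
  expect_true(any(grepl("overlap", chk$violations)))

  bad2 <- cfg
  bad2$boxes$x[1] <- round(geo$width_px / 2) - 10L  # center: inside inner square
  bad2$boxes$y[1] <- round(geo$height_px / 2) - 10L
  expect_false(check_fragment_configuration(bad2, geo, fr)$ok)
})

test_that("rendering masks everything outside the fragment boxes", {
  geo <- study_geometry(); fr <- study_frame()
  img <- stripe_image()
  whole <- structure(list(boxes = data.frame(x = 0L, y = 0L, w = 6L, h = 6L,
                                             side = "top"),
                          fragment_size_deg = NA, fragment_size_px = 6L,
                          side_quotas = NULL, seed = 0L),
                     class = "fragment_configuration")
  expect_identical(render_stimulus(img, whole), img)

  none <- whole; none$boxes <- none$boxes[0, ]
  expect_true(all(render_stimulus(img, none) == 127L))

  one <- whole; one$boxes <- data.frame(x = 1L, y = 2L, w = 3L, h = 3L, side = "top")
  out <- render_stimulus(img, one)
  expect_equal(sum(out != 127L), 9)
  expect_identical(out[3:5, 2:4], img[3:5, 2:4])

  oob <- whole; oob$boxes$w <- 9L
  expect_error(render_stimulus(img, oob), "bounds")
})

test_that("nominal visible area matches pixel counting after rounding", {
  geo <- study_geometry(); fr <- study_frame()
  img <- matrix(0L, geo$height_px, geo$width_px)
  for (cond in list(c(2.4, 10), c(1.2, 10), c(0.6, 40))) {
    cfg <- place_fragments(geo, fr, cond[1], cond[2],
                           seed = 100 + cond[2])
    st <- render_stimulus(img, cfg)
    pix_frac <- mean(st != 127L)
    nominal <- visible_area_fraction(cond[1], cond[2], geo)
    expect_lt(abs(pix_frac - nominal), 0.001)  # < 0.1 percentage points
  }
})

test_that("the frame stimulus keeps only the square annulus", {
  geo <- study_geometry(); fr <- study_frame()
  img <- matrix(255L, geo$height_px, geo$width_px)
  out <- render_frame_stimulus(img, fr, geo)
  frac <- mean(out != 127L)
  expect_equal(frac, frame_area_fraction(fr, geo), tolerance = 0.01)
  # image center (eccentricity 0) is masked, mid-band is visible
  expect_equal(out[336, 459], 127L)
  mid_px <- round(geo$width_px / 2 + 6.8 * geo$px_per_deg)
  expect_equal(out[336, mid_px], 255L)
})
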