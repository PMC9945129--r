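test_that("Weber contrast follows the black/white/gray arithmetic", {
  expect_equal(fragment_weber_contrast(matrix(0L, 4, 4)), 1.0)
  expect_equal(fragment_weber_contrast(matrix(255L, 4, 4)), 128 / 127)
  expect_equal(fragment_weber_contrast(matrix(127L, 2, 2)), 0)
  # mean at the background level cancels regardless of texture
  expect_equal(fragment_weber_contrast(matrix(c(0, 255, 127, 126), 2, 2)), 0)
  expect_error(fragment_weber_contrast(numeric(0)), "empty")
  expect_error(fragment_weber_contrast(matrix(1, 2, 2), background = 0), "background")
})

test_that("fragment SNR is the optimal-tile fraction over complete tiles", {
  img <- stripe_image()
  full_bank <- feature_bank(0:511, n_max = 512)
  none_bank <- feature_bank(integer(0), n_max = 0)
  expect_equal(fragment_snr(img, full_bank)$snr, 1)
  expect_equal(fragment_snr(img, none_bank)$snr, 0)

  # 6x6 fragment = 4 tiles; a bank holding only the all-black pattern
  # matches exactly the 2 left tiles
  black_bank <- feature_bank(0, n_max = 1)
  m <- fragment_snr(img, black_bank)
  expect_equal(m$n_tiles, 4)
  expect_equal(m$n_optimal, 2)
  expect_equal(m$snr, 0.5)

  # exactly one matching tile among four -> 0.25
  img2 <- matrix(255L, 6, 6); img2[1:3, 1:3] <- 0L
  expect_equal(fragment_snr(img2, black_bank)$snr, 0.25)

  expect_error(fragment_snr(matrix(0L, 2, 2), black_bank), "tile")
})

test_that("SNR depends on content, not fragment position, and stays in [0,1]", {
  set.seed(31)
  frag <- matrix(sample(c(0L, 255L), 36, TRUE), 6, 6)
  bank <- feature_bank(sample(0:511, 50), n_max = 50)
  base <- fragment_snr(frag, bank)$snr
  big <- matrix(127L, 40, 40)
  for (off in list(c(0, 0), c(10, 3), c(30, 34))) {
    at <- big
    at[off[1] + 1:6, off[2] + 1:6] <- frag
    got <- fragment_snr(at[off[1] + 1:6, off[2] + 1:6], bank)$snr
    expect_equal(got, base)
  }
  expect_gte(base, 0); expect_lte(base, 1)
})

test_that("inversion-closed banks give inversion-invariant SNR", {
  set.seed(32)
  half <- sample(0:511, 40)
  closed <- feature_bank(union(half, 511 - half), n_max = 512)
  frag <- matrix(sample(c(0L, 255L), 81, TRUE), 9, 9)
  expect_equal(fragment_snr(invert_contrast(frag), closed)$snr,
               fragment_snr(frag, closed)$snr)
  expect_equal(fragment_weber_contrast(invert_contrast(matrix(0L, 3, 3))),
               128 / 127)
})

test_that("stimulus saliency is the unweighted mean over fragments", {
  geo <- study_geometry()
  img <- matrix(0L, 12, 12)
  img[1:6, 7:12] <- 255L
  cfg <- structure(list(boxes = data.frame(x = c(0L, 6L), y = c(0L, 0L),
                                           w = 6L, h = 6L, side = c("left", "right")),
                        fragment_size_deg = NA, fragment_size_px = 6L,
                        side_quotas = NULL, seed = 0L),
                   class = "fragment_configuration")
  black_bank <- feature_bank(0, n_max = 1)
  s <- stimulus_saliency(img, cfg, black_bank)
  # fragment 1 all black: snr 1, contrast 1; fragment 2 all white: snr 0, 128/127
  expect_equal(s$mean_snr, 0.5)
  expect_equal(s$mean_contrast, mean(c(1, 128 / 127)))
  expect_equal(s$fragments$snr, c(1, 0))

  one <- cfg; one$boxes <- one$boxes[1, ]
  s1 <- stimulus_saliency(img, one, black_bank)
  expect_equal(s1$mean_snr, s$fragments$snr[1])

  none <- cfg; none$boxes <- none$boxes[0, ]
  expect_error(stimulus_saliency(img, none, black_bank), "empty")
})

test_that("binned performance uses half-open bins and binomial SDs", {
  trials <- data.frame(
    mean_snr = c(rep(0.02, 100), rep(0.07, 50)),
    mean_contrast = 0.5, d = NA_real_,
    response_correct = c(rep(TRUE, 63), rep(FALSE, 37), rep(TRUE, 50))
  )
  b <- bin_performance(trials, "snr")
  expect_equal(nrow(b), 2)
  expect_equal(b$bin_lo, c(0, 0.05))
  expect_equal(b$n_trials, c(100, 50))
  expect_equal(b$proportion[1], 0.63)
  expect_equal(b$binomial_sd[1], sqrt(0.63 * 0.37 / 100), tolerance = 1e-12)
  expect_equal(b$proportion[2], 1)
  expect_equal(b$binomial_sd[2], 0)
  expect_equal(sum(b$n_trials), nrow(trials))

  # signed variable anchored at the pooled minimum
  trials$d <- c(rep(-1.2, 100), rep(0.4, 50))
  bd <- bin_performance(trials, "d", bin_width = 0.5)
  expect_equal(bd$bin_lo[1], -1.2)
  expect_equal(sum(bd$n_trials), 150)

  # trials without a defined measurement are excluded
  trials$mean_snr[1] <- NA
  expect_equal(sum(bin_performance(trials, "snr")$n_trials), 149)
  expect_error(bin_performance(trials[0, ], "snr"), "no trials")
})

test_that("Pearson correlation matches hand computation and rejects constants", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  pc <- pearson_correlation(x, y)
  expect_equal(pc$r, 0.8, tolerance = 1e-12)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("pool measurement table joins identically to direct measurement", {
  st <- small_study()
  des <- main_design("inverted")
  tbl <- measure_stimulus_pool(des, st$images, st$pool, st$bank)
  expect_equal(nrow(tbl), 4 * 6 * 5)  # conditions x images x configurations
  sch <- build_trial_schedule(des, 1:6, seed = 77)
  direct <- measure_schedule(sch, st$images, st$pool, st$bank)
  joined <- measure_schedule(sch, table = tbl)
  expect_identical(direct, joined)
  expect_error(measure_schedule(sch, table = tbl[1:3, ]), "cover")
})
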