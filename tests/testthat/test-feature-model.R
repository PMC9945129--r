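test_that("pattern distribution counts non-overlapping tiles from the top-left", {
  d <- pattern_distribution(matrix(0L, 9, 9))
  expect_equal(d$n_tiles, 9)
  expect_equal(d$probs[1], 1)
  expect_equal(sum(d$probs), 1)

  d2 <- pattern_distribution(stripe_image())
  expect_equal(d2$n_tiles, 4)
  expect_equal(d2$probs[1], 0.5)    # all-black pattern
  expect_equal(d2$probs[512], 0.5)  # all-white pattern

  # incomplete edge tiles are dropped; counts pool over images
  d3 <- pattern_distribution(list(matrix(0L, 10, 11), matrix(255L, 3, 3)))
  expect_equal(d3$n_tiles, 9 + 1)
  expect_equal(sum(d3$counts), d3$n_tiles)
  expect_equal(sum(d3$probs), 1, tolerance = 1e-12)

  expect_error(pattern_distribution(matrix(0L, 2, 5)), "tile")
})

test_that("selection maximizes entropy under count and bandwidth budgets", {
  # uniform over all 16 2x2 patterns, 4 features allowed: H = 4/16 * 4 = 1 bit
  b <- select_optimal_features(toy_distribution(rep(1 / 16, 16)),
                               n_max = 4, bandwidth_max = 1)
  expect_equal(length(b$patterns), 4)
  expect_equal(b$achieved_entropy_bits, 1)

  # bandwidth excludes the most probable symbol despite its high p
  p <- c(0.7, 0.2, 0.06, 0.04, rep(0, 12))
  b2 <- select_optimal_features(toy_distribution(p), n_max = 2, bandwidth_max = 0.3)
  expect_equal(b2$patterns, c(1, 2))  # ids of the 0.2 and 0.06 symbols
  expect_equal(b2$achieved_entropy_bits,
               0.2 * log2(5) + 0.06 * log2(1 / 0.06), tolerance = 1e-12)

  # bandwidth below the smallest positive p: nothing is feasible
  b3 <- select_optimal_features(toy_distribution(p), n_max = 4, bandwidth_max = 0.01)
  expect_equal(length(b3$patterns), 0)
  expect_equal(b3$achieved_entropy_bits, 0)

  # zero-probability patterns are never selected
  expect_false(any(c(4:15) %in% b2$patterns))

  expect_error(select_optimal_features(toy_distribution(p), n_max = -1), "n_max")
  expect_error(select_optimal_features(toy_distribution(p), bandwidth_max = 1.2),
               "bandwidth_max")
})

test_that("default selection equals exhaustive search on 16-pattern alphabets", {
  set.seed(401)
  grid <- expand.grid(n_max = c(2, 5, 16), B = c(0.15, 0.4, 1.0))
  for (rep in 1:40) {
    probs <- random_probs16(n_zero = sample(0:4, 1))
    d <- toy_distribution(probs)
    for (g in seq_len(nrow(grid))) {
      ref <- oracle_select(probs, grid$n_max[g], grid$B[g])
      got <- select_optimal_features(d, grid$n_max[g], grid$B[g])  # auto -> exact
      expect_equal(got$achieved_entropy_bits, ref$H, tolerance = 1e-9,
                   info = sprintf("rep %d grid %d", rep, g))
      expect_equal(got$patterns, ref$ids,
                   info = sprintf("rep %d grid %d", rep, g))
    }
  }
})

test_that("the large-alphabet heuristic is feasible, bounded and exact in its guaranteed regimes", {
  set.seed(405)
  for (rep in 1:40) {
    probs <- random_probs16(n_zero = sample(0:4, 1))
    d <- toy_distribution(probs)
    for (n_max in c(2, 5, 16)) for (B in c(0.15, 0.4, 1.0)) {
      got <- select_optimal_features(d, n_max, B, method = "greedy")
      ref <- oracle_select(probs, n_max, B)
      # always feasible, never above the optimum
      expect_lte(length(got$patterns), n_max)
      expect_lte(got$bandwidth_used, B + 1e-12)
      expect_lte(got$achieved_entropy_bits, ref$H + 1e-9)
      # exact when the bandwidth budget is slack or at most two features
      if (B >= 1 || n_max <= 2) {
        expect_equal(got$achieved_entropy_bits, ref$H, tolerance = 1e-9,
                     info = sprintf("rep %d n_max %d B %g", rep, n_max, B))
      }
    }
  }
})

test_that("achieved entropy is monotone in both budgets", {
  set.seed(402)
  for (rep in 1:10) {
    d <- toy_distribution(random_probs16())
    H_n <- vapply(c(1, 2, 4, 8, 16), function(n)
      select_optimal_features(d, n, 0.5)$achieved_entropy_bits, numeric(1))
    expect_true(all(diff(H_n) >= -1e-12))
    H_b <- vapply(c(0.05, 0.15, 0.4, 0.8, 1), function(b)
      select_optimal_features(d, 8, b)$achieved_entropy_bits, numeric(1))
    expect_true(all(diff(H_b) >= -1e-12))
  }
})

test_that("sketching keeps exactly the tiles whose pattern is in the bank", {
  img <- stripe_image()
  full_bank <- feature_bank(0:511, n_max = 512)
  expect_identical(sketch_image(img, full_bank), img)

  empty_bank <- feature_bank(integer(0), n_max = 0)
  expect_true(all(sketch_image(img, empty_bank) == 127L))

  black_only <- feature_bank(0, n_max = 1)
  sk <- sketch_image(img, black_only)
  expect_true(all(sk[, 1:3] == 0L))
  expect_true(all(sk[, 4:6] == 127L))

  # incomplete-edge pixels are background even with the full bank
  img2 <- matrix(255L, 7, 7)
  sk2 <- sketch_image(img2, full_bank)
  expect_true(all(sk2[1:6, 1:6] == 255L))
  expect_true(all(sk2[7, ] == 127L))
})

test_that("feature-bank files round-trip and reject malformed lines", {
  set.seed(403)
  ids <- sort(sample(0:511, 50))
  bank <- feature_bank(ids, n_max = 50, bandwidth_max = 0.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_feature_bank(bank, path)
  got <- read_feature_bank(path)
  expect_equal(got$patterns, bank$patterns)
  expect_equal(got$n_max, bank$n_max)
  expect_equal(got$bandwidth_max, bank$bandwidth_max)

  # comments and blank lines are tolerated
  writeLines(c("# a comment", "size=3 n_max=2 bandwidth_max=0.5", "",
               "000000001  # trailing comment"), path)
  expect_equal(read_feature_bank(path)$patterns, 1)

  writeLines(c("size=3 n_max=2 bandwidth_max=0.5", "00000001"), path)
  expect_error(read_feature_bank(path), "line 2")
  writeLines(c("size=3 nmax=2", "000000001"), path)
  expect_error(read_feature_bank(path), "header")
})
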