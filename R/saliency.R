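#' Weber contrast of a fragment
#'
#' Mean pixel level of the fragment (black = 0, white = 255) minus the
#' background level, as an absolute fraction of the background:
#' `|mean(pixels) - background| / background`. An all-black fragment has
#' contrast 1; an all-white fragment 128/127.
#'
#' @param fragment matrix (or vector) of pixel levels.
#' @param background background level (default gray 127).
#' @return Non-negative contrast value.
#' @export
fragment_weber_contrast <- function(fragment, background = 127) {
  if (!length(fragment)) stop("empty fragment", call. = FALSE)
  assert_scalar_number(background, "background", 1e-12, Inf)
  abs(mean(fragment) - background) / background
}

#' Optimal-feature SNR of a fragment
#'
#' The fragment's saliency score under the constrained maximum-entropy
#' model: the number of optimal features it contains over the total number
#' of features, where features are the complete non-overlapping 3x3 tiles
#' of the fragment (anchored at its top-left corner, incomplete edge tiles
#' dropped — the same partition convention used to estimate the pattern
#' distribution).
#'
#' @param fragment binary image region, at least one tile in each
#'   dimension.
#' @param bank a [feature_bank].
#' @return List with `snr` (fraction in \[0, 1\]), `n_tiles`, `n_optimal`.
#' @export
fragment_snr <- function(fragment, bank) {
  stopifnot(inherits(bank, "feature_bank"))
  ids <- tile_pattern_ids(fragment, bank$pattern_size)
  n_tiles <- length(ids)
  n_opt <- sum(bank_contains(bank, ids))
  list(snr = n_opt / n_tiles, n_tiles = n_tiles, n_optimal = n_opt)
}

#' Saliency and contrast of a fragment-occluded stimulus
#'
#' Computes per-fragment optimal-feature SNR and Weber contrast for every
#' box of a configuration and aggregates them as unweighted means across
#' fragments (for ten-fragment stimuli the study considered the average
#' SNR and the average contrast of the fragments).
#'
#' @param image binary source image.
#' @param config a [fragment_configuration] with at least one box.
#' @param bank a [feature_bank].
#' @param background background level used for the contrast reference.
#' @return List with `mean_snr`, `mean_contrast`, and a `fragments`
#'   data.frame of per-fragment measurements.
#' @export
stimulus_saliency <- function(image, config, bank, background = 127) {
  stopifnot(inherits(config, "fragment_configuration"))
  b <- config$boxes
  if (!nrow(b)) stop("empty configuration", call. = FALSE)
  snr <- numeric(nrow(b)); con <- numeric(nrow(b))
  nt <- integer(nrow(b)); no <- integer(nrow(b))
  for (k in seq_len(nrow(b))) {
    frag <- image[(b$y[k] + 1L):(b$y[k] + b$h[k]),
                  (b$x[k] + 1L):(b$x[k] + b$w[k]), drop = FALSE]
    m <- fragment_snr(frag, bank)
    snr[k] <- m$snr; nt[k] <- m$n_tiles; no[k] <- m$n_optimal
    con[k] <- fragment_weber_contrast(frag, background)
  }
  list(mean_snr = mean(snr), mean_contrast = mean(con),
       fragments = data.frame(snr = snr, weber_contrast = con,
                              n_tiles = nt, n_optimal = no))
}

#' Fill per-trial saliency measurements into a schedule
#'
#' For every trial, computes the mean fragment SNR and mean Weber contrast
#' of the target stimulus (its image under the trial's fragment
#' configuration). Each (condition, image, configuration) triple is
#' measured once and reused. Full-image trials are measured on the whole
#' image as a single fragment; frame trials carry no fragment measurement
#' (NA).
#'
#' @param schedule schedule data.frame from [build_trial_schedule()].
#' @param images list of binary image matrices; `stimulus_image_id` indexes
#'   into it.
#' @param pool configuration pool from [build_configuration_pool()].
#' @param bank a [feature_bank].
#' @param background background level.
#' @param table optional precomputed measurement table from
#'   [measure_stimulus_pool()]; when given, measurements are joined from it
#'   and `images`/`pool`/`bank` are not consulted (useful when many
#'   schedules share one stimulus pool).
#' @return The schedule with `mean_snr` and `mean_contrast` filled.
#' @export
measure_schedule <- function(schedule, images, pool, bank, background = 127,
                             table = NULL) {
  key <- paste(schedule$condition, schedule$stimulus_image_id,
               schedule$configuration_id, sep = "\r")
  if (!is.null(table)) {
    tkey <- paste(table$condition, table$stimulus_image_id,
                  table$configuration_id, sep = "\r")
    idx <- match(key, tkey)
    if (anyNA(idx)) stop("measurement table does not cover the schedule",
                         call. = FALSE)
    schedule$mean_snr <- table$mean_snr[idx]
    schedule$mean_contrast <- table$mean_contrast[idx]
    return(schedule)
  }
  stopifnot(inherits(bank, "feature_bank"))
  uniq <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    val <- measure_one_stimulus(schedule$type[i], schedule$condition[i],
                                schedule$stimulus_image_id[i],
                                schedule$configuration_id[i],
                                images, pool, bank, background)
    assign(key[i], val, envir = cache)
  }
  vals <- vapply(key, function(k) get(k, envir = cache), numeric(2),
                 USE.NAMES = FALSE)
  schedule$mean_snr <- vals[1, ]
  schedule$mean_contrast <- vals[2, ]
  schedule
}

measure_one_stimulus <- function(type, condition, image_id, config_id,
                                 images, pool, bank, background) {
  img <- images[[image_id]]
  if (type == "fragments") {
    cfg <- pool[[condition]][[image_id]][[config_id]]
    s <- stimulus_saliency(img, cfg, bank, background)
    c(s$mean_snr, s$mean_contrast)
  } else if (type == "full") {
    c(fragment_snr(img, bank)$snr, fragment_weber_contrast(img, background))
  } else {
    c(NA_real_, NA_real_)
  }
}

#' Measure every stimulus of a design's configuration pool
#'
#' Computes the mean fragment SNR and mean Weber contrast of every
#' (condition, image, configuration) stimulus a design can present, so
#' that many schedules over the same pool can be measured by a cheap join
#' (see the `table` argument of [measure_schedule()]).
#'
#' @param design an [experiment_design].
#' @param images list of binary image matrices.
#' @param pool configuration pool from [build_configuration_pool()].
#' @param bank a [feature_bank].
#' @param background background level.
#' @return data.frame with columns `condition`, `stimulus_image_id`,
#'   `configuration_id`, `mean_snr`, `mean_contrast`.
#' @export
measure_stimulus_pool <- function(design, images, pool, bank,
                                  background = 127) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(bank, "feature_bank"))
  cond <- design$conditions
  rows <- list()
  for (r in seq_len(nrow(cond))) {
    for (img in seq_along(images)) {
      for (cfg in seq_len(design$configs_per_image)) {
        val <- measure_one_stimulus(cond$type[r], cond$condition[r], img, cfg,
                                    images, pool, bank, background)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond$condition[r], stimulus_image_id = img,
          configuration_id = cfg, mean_snr = val[1], mean_contrast = val[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Bin trial performance by a stimulus variable
#'
#' Left-closed, right-open bins of the chosen variable, anchored at 0 for
#' the non-negative variables (`snr`, binned at 0.05 in the study;
#' `contrast`, binned at 0.2) and at the pooled minimum for the signed
#' standardized difference `d`. Reports per-bin trial counts, proportion
#' correct and the binomial standard deviation `sqrt(p(1-p)/n)`. Trials
#' without a defined measurement are dropped.
#'
#' @param trials schedule data.frame with responses and measurements.
#' @param variable `"snr"`, `"contrast"` or `"d"`.
#' @param bin_width positive bin width (defaults: 0.05 for SNR, 0.2 for
#'   contrast, 0.5 for `d`).
#' @return data.frame of class `binned_performance` with columns
#'   `bin_lo`, `bin_hi`, `bin_mid`, `n_trials`, `n_correct`, `proportion`,
#'   `binomial_sd`.
#' @export
bin_performance <- function(trials, variable = c("snr", "contrast", "d"),
                            bin_width = NULL) {
  variable <- match.arg(variable)
  col <- switch(variable, snr = "mean_snr", contrast = "mean_contrast", d = "d")
  bin_width <- bin_width %||% switch(variable, snr = 0.05, contrast = 0.2, d = 0.5)
  assert_scalar_number(bin_width, "bin_width", 1e-12, Inf)
  if (!col %in% names(trials)) stop("trials lack column ", col, call. = FALSE)
  x <- trials[[col]]
  y <- trials$response_correct
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stop("no trials with defined ", variable, call. = FALSE)
  x <- x[keep]; y <- y[keep]
  anchor <- if (variable == "d") min(x) else 0
  idx <- floor((x - anchor) / bin_width + 1e-9)
  agg <- tapply(y, idx, function(v) c(length(v), sum(v)))
  idx_u <- as.integer(names(agg))
  m <- do.call(rbind, agg)
  p <- m[, 2] / m[, 1]
  out <- data.frame(
    bin_lo = anchor + idx_u * bin_width,
    bin_hi = anchor + (idx_u + 1) * bin_width,
    bin_mid = anchor + (idx_u + 0.5) * bin_width,
    n_trials = m[, 1], n_correct = m[, 2],
    proportion = p, binomial_sd = sqrt(p * (1 - p) / m[, 1])
  )
  out <- out[order(out$bin_lo), ]
  rownames(out) <- NULL
  class(out) <- c("binned_performance", "data.frame")
  out
}

#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation between two variables (e.g. per-stimulus
#' mean SNR and mean Weber contrast) with the two-sided p-value from the
#' t transform, via [stats::cor.test()]. Constant input is an error.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
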