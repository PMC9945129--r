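#' Synthetic binarized image specification
#'
#' Describes a set of thresholded power-law (1/f^beta) Gaussian noise
#' images standing in for binarized naturalistic photographs. Each image is
#' an isotropic Gaussian random field whose power spectrum falls as
#' `1/f^beta`, thresholded at the `black_fraction` quantile. At the default
#' `beta = 2` (the spectral slope typical of natural scenes) the binarized
#' fields reproduce the pattern statistics the feature model relies on:
#' the two uniform 3x3 patterns (all black, all white) dominate the
#' distribution and its entropy is far below the 9-bit maximum.
#'
#' @param n_images number of images (default 327, the study's set size).
#' @param width_px,height_px image size in pixels (defaults 918 x 672).
#' @param spectral_exponent power-spectrum exponent beta >= 0 (0 gives
#'   white noise).
#' @param black_fraction target fraction of black pixels, in (0, 1).
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(n_images = 327L, width_px = 918L,
                                 height_px = 672L, spectral_exponent = 2,
                                 black_fraction = 0.5, seed = 1L) {
  assert_scalar_number(n_images, "n_images", 1, Inf)
  assert_scalar_number(width_px, "width_px", 1, Inf)
  assert_scalar_number(height_px, "height_px", 1, Inf)
  assert_scalar_number(spectral_exponent, "spectral_exponent", 0, Inf)
  if (black_fraction <= 0 || black_fraction >= 1) {
    stop("`black_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_images = as.integer(n_images), width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         spectral_exponent = spectral_exponent,
         black_fraction = black_fraction, seed = as.integer(seed)),
    class = "synthetic_image_spec"
  )
}

# One thresholded power-law field; RNG state is the caller's.
power_law_binary_field <- function(width_px, height_px, beta, black_fraction) {
  z <- matrix(stats::rnorm(width_px * height_px), height_px, width_px)
  if (beta > 0) {
    fx <- (seq_len(width_px) - 1) / width_px
    fx[fx > 0.5] <- fx[fx > 0.5] - 1
    fy <- (seq_len(height_px) - 1) / height_px
    fy[fy > 0.5] <- fy[fy > 0.5] - 1
    fr2 <- outer(fy^2, fx^2, `+`)
    amp <- fr2^(-beta / 4)  # power ~ 1/f^beta => amplitude ~ f^(-beta/2)
    amp[1, 1] <- 0          # zero the DC component
    z <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE))
  }
  thr <- stats::quantile(z, black_fraction, names = FALSE)
  matrix(ifelse(z > thr, 255L, 0L), height_px, width_px)
}

#' Generate a synthetic binarized image set
#'
#' @param spec a [synthetic_image_spec].
#' @return List of binary image matrices; deterministic given `spec$seed`.
#' @export
generate_image_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_images), function(i) {
      power_law_binary_field(spec$width_px, spec$height_px,
                             spec$spectral_exponent, spec$black_fraction)
    })
  })
}

#' Generative observer parameters
#'
#' The simulated observer mirrors the binomial GLMM fitted by the analysis:
#' on each trial the probability of a correct response is
#' `plogis(beta0 + beta_d * d + beta_order * [interval == 1] +
#' beta_rep * log(1 + rep) + beta_inv * [target inverted] + u + v)`,
#' where `d` is the standardized SNR-minus-contrast difference, `rep` the
#' target image's running repetition count, and `u ~ N(0, sigma_subject^2)`,
#' `v ~ N(0, sigma_stimulus^2)` are participant and stimulus random
#' intercepts. Defaults give chance-to-~70% performance comparable to the
#' study's observers, with qualitatively matching order, repetition and
#' inversion effects.
#'
#' @param beta0 intercept (log-odds of a correct response at baseline).
#' @param beta_d coefficient on the standardized SNR-contrast difference.
#' @param beta_order effect of the target appearing in interval 1.
#' @param beta_rep effect per unit `log(1 + repetition count)`.
#' @param beta_inv effect of an inverted-contrast target.
#' @param sigma_subject,sigma_stimulus random-intercept SDs (>= 0).
#' @param seed integer RNG seed for the response draws.
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(beta0 = 0.5, beta_d = 0.4, beta_order = 0.1,
                            beta_rep = 0.05, beta_inv = -0.2,
                            sigma_subject = 0.3, sigma_stimulus = 0.3,
                            seed = 1L) {
  assert_scalar_number(sigma_subject, "sigma_subject", 0, Inf)
  assert_scalar_number(sigma_stimulus, "sigma_stimulus", 0, Inf)
  structure(
    list(beta0 = beta0, beta_d = beta_d, beta_order = beta_order,
         beta_rep = beta_rep, beta_inv = beta_inv,
         sigma_subject = sigma_subject, sigma_stimulus = sigma_stimulus,
         seed = as.integer(seed)),
    class = "observer_params"
  )
}

#' Simulate observer responses on a measured schedule
#'
#' Fills `response_correct` with Bernoulli draws from the generative
#' observer model. The SNR-contrast difference is standardized over the
#' schedule being simulated (trials without measurements contribute `d = 0`
#' and are excluded from the standardization). Participant and stimulus
#' random intercepts are drawn once per level. Deterministic given
#' `params$seed`.
#'
#' @param schedule measured schedule (from [measure_schedule()]).
#' @param params an [observer_params].
#' @return The schedule with `d` and `response_correct` filled.
#' @export
simulate_observer <- function(schedule, params) {
  stopifnot(inherits(params, "observer_params"))
  if (!nrow(schedule)) stop("empty schedule", call. = FALSE)
  if (all(is.na(schedule$mean_snr))) {
    stop("schedule carries no measurements; run measure_schedule() first",
         call. = FALSE)
  }
  sched <- standardized_difference(schedule)
  d <- ifelse(is.na(sched$d), 0, sched$d)
  subj <- factor(sched$participant)
  stim <- factor(sched$stimulus_image_id)
  with_seed(params$seed, {
    u <- stats::rnorm(nlevels(subj), 0, params$sigma_subject)
    v <- stats::rnorm(nlevels(stim), 0, params$sigma_stimulus)
    eta <- params$beta0 +
      params$beta_d * d +
      params$beta_order * (sched$target_interval == 1L) +
      params$beta_rep * log1p(sched$repetition_target) +
      params$beta_inv * sched$target_inverted +
      u[as.integer(subj)] + v[as.integer(stim)]
    sched$response_correct <- stats::runif(nrow(sched)) < stats::plogis(eta)
    sched
  })
}

#' Generate a complete synthetic study
#'
#' End-to-end synthetic dataset with the pipeline's full structure:
#' synthetic binarized images, the constrained maximum-entropy feature
#' bank extracted from their pooled pattern statistics, per-participant
#' 2IFC trial schedules with seeded fragment-configuration pools, saliency
#' measurements, and simulated observer responses. Fully reproducible from
#' `seed` (stage seeds are derived from it).
#'
#' @param design an [experiment_design] (default: the inverted-contrast
#'   main task).
#' @param image_spec a [synthetic_image_spec].
#' @param observer an [observer_params] (its `seed` is overridden by a
#'   derived stage seed).
#' @param n_participants number of observers (default 10, as in the study).
#' @param geometry a [display_geometry].
#' @param frame a [frame_region].
#' @param n_max,bandwidth_max feature-selection limits.
#' @param seed master RNG seed.
#' @return List with `images`, `distribution`, `bank`, `pool`, `schedule`
#'   (all participants stacked, measured, with responses).
#' @export
generate_study <- function(design = main_design("inverted"),
                           image_spec = synthetic_image_spec(),
                           observer = observer_params(),
                           n_participants = 10L,
                           geometry = display_geometry(),
                           frame = frame_region(),
                           n_max = 50, bandwidth_max = 0.2,
                           seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  if (image_spec$width_px != geometry$width_px ||
      image_spec$height_px != geometry$height_px) {
    stop("image_spec dimensions must match the display geometry", call. = FALSE)
  }
  image_spec$seed <- derive_seed(seed, 1L)
  images <- generate_image_set(image_spec)
  dist <- pattern_distribution(images)
  bank <- select_optimal_features(dist, n_max = n_max,
                                  bandwidth_max = bandwidth_max)
  pool <- build_configuration_pool(design, geometry, frame,
                                   image_spec$n_images,
                                   seed = derive_seed(seed, 2L))
  schedules <- lapply(seq_len(n_participants), function(p) {
    build_trial_schedule(design, seq_len(image_spec$n_images),
                         seed = derive_seed(seed, 10L + p),
                         participant_id = p)
  })
  schedule <- do.call(rbind, schedules)
  schedule <- measure_schedule(schedule, images, pool, bank,
                               background = geometry$background_level)
  observer$seed <- derive_seed(seed, 3L)
  schedule <- simulate_observer(schedule, observer)
  list(images = images, distribution = dist, bank = bank, pool = pool,
       schedule = schedule)
}
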