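#' Experiment designs
#'
#' An experiment design names the stimulus conditions (type, fragment count
#' and size, per-condition trial counts), the size of the per-image
#' configuration pool, the contrast-inversion mode, and presentation
#' metadata. Constructors for the three study designs are provided.
#'
#' @param name design label.
#' @param conditions data.frame with columns `condition` (label), `type`
#'   (`"full"`, `"frame"` or `"fragments"`), `n_trials`, `n_fragments`,
#'   `size_deg`, and quota columns `q_top`, `q_bottom`, `q_left`, `q_right`
#'   (NA for unconstrained placement).
#' @param configs_per_image number of pre-built fragment configurations per
#'   image and condition (the study used 5).
#' @param inversion_mode `"none"`, or `"independent"`: each of target and
#'   distractor has its contrast inverted independently with probability
#'   `inversion_p` on every trial.
#' @param inversion_p per-image inversion probability.
#' @param displacement_px magnitude of the random diagonal displacement of
#'   the comparison images (10 px in the study).
#' @param timing presentation timing metadata in ms (carried only; nothing
#'   is rendered in time).
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(name, conditions, configs_per_image = 5L,
                              inversion_mode = c("none", "independent"),
                              inversion_p = 0.5, displacement_px = 10L,
                              timing = list(fixation = 300, stimulus = 25,
                                            mask = 500, comparison = 350)) {
  inversion_mode <- match.arg(inversion_mode)
  need <- c("condition", "type", "n_trials", "n_fragments", "size_deg",
            "q_top", "q_bottom", "q_left", "q_right")
  if (!is.data.frame(conditions) || !all(need %in% names(conditions))) {
    stop("`conditions` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(conditions$condition)) {
    stop("condition labels must be unique", call. = FALSE)
  }
  structure(
    list(name = name, conditions = conditions,
         configs_per_image = as.integer(configs_per_image),
         inversion_mode = inversion_mode, inversion_p = inversion_p,
         displacement_px = as.integer(displacement_px), timing = timing),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design '%s': %d conditions, %d trials, inversion %s\n",
              x$name, nrow(x$conditions), total_trials(x), x$inversion_mode))
  print(x$conditions[, c("condition", "type", "n_trials", "n_fragments", "size_deg")],
        row.names = FALSE)
  invisible(x)
}

condition_row <- function(condition, type, n_trials, n_fragments = 0L,
                          size_deg = NA_real_, quotas = NULL) {
  q <- if (is.null(quotas)) rep(NA_integer_, 4) else as.integer(quotas)
  data.frame(condition = condition, type = type, n_trials = as.integer(n_trials),
             n_fragments = as.integer(n_fragments), size_deg = size_deg,
             q_top = q[1], q_bottom = q[2], q_left = q[3], q_right = q[4],
             stringsAsFactors = FALSE)
}

#' @rdname experiment_design
#' @details `preliminary1_design()`: whole image and frame controls (300
#'   trials each) plus ten-fragment conditions at 2.4, 1.2, 0.6 and 0.3 deg
#'   (600 trials each; 3,000 trials total). `preliminary2_design()`: six
#'   fragment conditions matching 2% and 7.5% visible area with varying
#'   fragment number/size (600 trials each; 3,600 total).
#'   `main_design(task)`: ten or one fragment at 2.4 and 1.2 deg (300
#'   trials per condition, 1,200 per task), with independent contrast
#'   inversion in the `"inverted"` task.
#' @export
preliminary1_design <- function() {
  q10 <- c(3, 3, 2, 2)
  conditions <- rbind(
    condition_row("full", "full", 300),
    condition_row("frame", "frame", 300),
    condition_row("frag_2.4x10", "fragments", 600, 10, 2.4, q10),
    condition_row("frag_1.2x10", "fragments", 600, 10, 1.2, q10),
    condition_row("frag_0.6x10", "fragments", 600, 10, 0.6, q10),
    condition_row("frag_0.3x10", "fragments", 600, 10, 0.3, q10)
  )
  experiment_design("preliminary1", conditions, inversion_mode = "none")
}

#' @rdname experiment_design
#' @export
preliminary2_design <- function() {
  conditions <- rbind(
    condition_row("a2_2.4x3", "fragments", 600, 3, 2.4, NULL),
    condition_row("a2_1.2x10", "fragments", 600, 10, 1.2, c(3, 3, 2, 2)),
    condition_row("a2_0.6x40", "fragments", 600, 40, 0.6, c(12, 12, 8, 8)),
    condition_row("a7.5_2.4x10", "fragments", 600, 10, 2.4, c(3, 3, 2, 2)),
    condition_row("a7.5_1.2x40", "fragments", 600, 40, 1.2, c(12, 12, 8, 8)),
    condition_row("a7.5_0.6x160", "fragments", 600, 160, 0.6, c(40, 40, 40, 40))
  )
  experiment_design("preliminary2", conditions, inversion_mode = "none")
}

#' @rdname experiment_design
#' @param task `"original"` or `"inverted"` contrast task of the main
#'   experiment.
#' @export
main_design <- function(task = c("original", "inverted")) {
  task <- match.arg(task)
  q10 <- c(3, 3, 2, 2)
  conditions <- rbind(
    condition_row("frag_2.4x10", "fragments", 300, 10, 2.4, q10),
    condition_row("frag_1.2x10", "fragments", 300, 10, 1.2, q10),
    condition_row("frag_2.4x1", "fragments", 300, 1, 2.4, NULL),
    condition_row("frag_1.2x1", "fragments", 300, 1, 1.2, NULL)
  )
  experiment_design(paste0("main_", task), conditions,
                    inversion_mode = if (task == "inverted") "independent" else "none")
}

#' Total trials of a design
#' @param design an [experiment_design].
#' @return Integer trial count (per observer).
#' @export
total_trials <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  sum(design$conditions$n_trials)
}

#' Stimulus pool size per area condition
#'
#' With `configs_per_image` pre-built fragment configurations for each
#' image, each area condition has `n_images * configs_per_image` distinct
#' stimuli (327 x 5 = 1,635 in the study).
#'
#' @param n_images number of source images.
#' @param configs_per_image configurations per image.
#' @return Integer stimulus count.
#' @export
stimulus_pool_size <- function(n_images, configs_per_image = 5L) {
  as.integer(n_images) * as.integer(configs_per_image)
}

#' Build a 2IFC trial schedule
#'
#' Expands a design into per-trial records for one observer: per-condition
#' trial counts are exact; the target image, its fragment configuration,
#' the distractor (uniform over the other images), the target interval, the
#' diagonal displacement corner and (in the inverted task) the per-image
#' contrast inversions are drawn independently; trial order is shuffled
#' across conditions. Running repetition counters record, for each trial,
#' how often its target and distractor images have occurred in either role
#' up to and including that trial. The schedule is exactly reproducible
#' from (design, image set, seed).
#'
#' @param design an [experiment_design].
#' @param image_ids vector of image identifiers (at least 2).
#' @param seed integer RNG seed.
#' @param participant_id observer identifier stored with each trial.
#' @return data.frame with one row per trial: identifiers, condition
#'   descriptors, interval/inversion/displacement draws, repetition
#'   counters, and `mean_snr`, `mean_contrast`, `d`, `response_correct`
#'   columns initialized to NA.
#' @export
build_trial_schedule <- function(design, image_ids, seed = 1L,
                                 participant_id = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  n_img <- length(image_ids)
  if (nrow(design$conditions) == 0L) return(empty_schedule())
  if (n_img < 2L) stop("need at least 2 images for a 2IFC schedule", call. = FALSE)

  cond <- design$conditions
  n <- sum(cond$n_trials)
  ci <- rep(seq_len(nrow(cond)), times = cond$n_trials)

  with_seed(seed, {
    ci <- sample(ci)
    target_idx <- sample.int(n_img, n, replace = TRUE)
    # distractor uniform over the other images
    distractor_idx <- sample.int(n_img - 1L, n, replace = TRUE)
    distractor_idx <- distractor_idx + (distractor_idx >= target_idx)
    config_id <- sample.int(design$configs_per_image, n, replace = TRUE)
    target_interval <- sample(c(1L, 2L), n, replace = TRUE)
    corner <- sample.int(4L, n, replace = TRUE)
    if (design$inversion_mode == "independent") {
      target_inverted <- stats::runif(n) < design$inversion_p
      distractor_inverted <- stats::runif(n) < design$inversion_p
    } else {
      target_inverted <- rep(FALSE, n)
      distractor_inverted <- rep(FALSE, n)
    }
    # running occurrence counts (as target or distractor), inclusive
    counts <- integer(n_img)
    rep_t <- integer(n); rep_d <- integer(n)
    for (i in seq_len(n)) {
      t <- target_idx[i]; d <- distractor_idx[i]
      counts[t] <- counts[t] + 1L
      counts[d] <- counts[d] + 1L
      rep_t[i] <- counts[t]
      rep_d[i] <- counts[d]
    }
    dx <- ifelse(corner %in% c(1L, 3L), -1L, 1L) * design$displacement_px
    dy <- ifelse(corner %in% c(1L, 2L), -1L, 1L) * design$displacement_px
    data.frame(
      participant = participant_id,
      trial_index = seq_len(n),
      condition = cond$condition[ci],
      type = cond$type[ci],
      n_fragments = cond$n_fragments[ci],
      size_deg = cond$size_deg[ci],
      stimulus_image_id = image_ids[target_idx],
      configuration_id = config_id,
      target_id = image_ids[target_idx],
      distractor_id = image_ids[distractor_idx],
      target_interval = target_interval,
      target_inverted = target_inverted,
      distractor_inverted = distractor_inverted,
      displacement_dx = dx,
      displacement_dy = dy,
      repetition_target = rep_t,
      repetition_distractor = rep_d,
      mean_snr = NA_real_,
      mean_contrast = NA_real_,
      d = NA_real_,
      response_correct = NA,
      stringsAsFactors = FALSE
    )
  })
}

empty_schedule <- function() {
  data.frame(
    participant = integer(0), trial_index = integer(0),
    condition = character(0), type = character(0),
    n_fragments = integer(0), size_deg = numeric(0),
    stimulus_image_id = integer(0), configuration_id = integer(0),
    target_id = integer(0), distractor_id = integer(0),
    target_interval = integer(0), target_inverted = logical(0),
    distractor_inverted = logical(0), displacement_dx = integer(0),
    displacement_dy = integer(0), repetition_target = integer(0),
    repetition_distractor = integer(0), mean_snr = numeric(0),
    mean_contrast = numeric(0), d = numeric(0), response_correct = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Build the per-image fragment-configuration pools of a design
#'
#' For every fragment condition and every image, draws
#' `design$configs_per_image` seeded configurations, so each area condition
#' has `n_images * configs_per_image` distinct stimuli.
#'
#' @param design an [experiment_design].
#' @param geometry a [display_geometry].
#' @param frame a [frame_region].
#' @param n_images number of images.
#' @param seed integer RNG seed (per-configuration seeds are derived).
#' @return Named list: `pool[[condition]][[image]][[config_id]]` is a
#'   [fragment_configuration]. Non-fragment conditions get `NULL`.
#' @export
build_configuration_pool <- function(design, geometry, frame, n_images,
                                     seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  cond <- design$conditions
  pool <- vector("list", nrow(cond))
  names(pool) <- cond$condition
  k <- 0L
  for (r in seq_len(nrow(cond))) {
    if (cond$type[r] != "fragments") next
    quotas <- if (!is.na(cond$q_top[r])) {
      c(top = cond$q_top[r], bottom = cond$q_bottom[r],
        left = cond$q_left[r], right = cond$q_right[r])
    } else NULL
    pool[[r]] <- lapply(seq_len(n_images), function(img) {
      lapply(seq_len(design$configs_per_image), function(cfg) {
        k_local <- (r * 100000L) + (img * 100L) + cfg
        place_fragments(geometry, frame, cond$size_deg[r], cond$n_fragments[r],
                        side_quotas = quotas,
                        seed = derive_seed(seed, 1L) %% 100000000L + k_local)
      })
    })
  }
  pool
}

# Schedule CSV IO: comma-separated, header row, booleans as 0/1, floats at
# full precision so write -> read is the identity.
schedule_bool_cols <- c("target_inverted", "distractor_inverted", "response_correct")
schedule_real_cols <- c("size_deg", "mean_snr", "mean_contrast", "d")

#' Read and write trial-schedule CSV files
#'
#' UTF-8 comma-separated with a header row; booleans serialized as 0/1,
#' reals at full precision. `read_schedule(write_schedule(x))` reproduces
#' `x` exactly.
#'
#' @param schedule a schedule data.frame from [build_trial_schedule()].
#' @param path file path.
#' @return `read_schedule()` returns the schedule data.frame;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  out <- schedule
  for (cl in intersect(schedule_bool_cols, names(out))) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_integer_, as.integer(out[[cl]]))
  }
  for (cl in intersect(schedule_real_cols, names(out))) {
    out[[cl]] <- format_full(out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (cl in intersect(schedule_bool_cols, names(x))) {
    x[[cl]] <- as.logical(x[[cl]])
  }
  for (cl in intersect(schedule_real_cols, names(x))) {
    x[[cl]] <- as.numeric(x[[cl]])
  }
  x
}
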