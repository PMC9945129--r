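#' Fragment placement in the eccentricity frame
#'
#' Samples `count` square fragment boxes satisfying the three stimulus
#' constraints: (i) each box lies entirely inside the square-annulus
#' eccentricity frame; (ii) boxes are evenly distributed over the four
#' sides of the frame — when side quotas are given, each box is assigned to
#' the top, bottom, left or right sector (the band partitioned by its
#' diagonals, judged at the box center); (iii) boxes are pairwise disjoint.
#' Sampling is seeded rejection sampling with a bounded retry budget; an
#' infeasible request raises a placement-failure error.
#'
#' Coordinates are 0-based pixels, origin at the top-left of the image,
#' boxes half-open `[x, x + w) x [y, y + h)`.
#'
#' @param geometry a [display_geometry].
#' @param frame a [frame_region].
#' @param size_deg fragment side in degrees (converted with [deg_to_px()]).
#' @param count number of fragments (>= 0).
#' @param side_quotas `NULL` for unconstrained placement, or a named
#'   integer vector with entries `top`, `bottom`, `left`, `right` summing
#'   to `count` (e.g. `c(top = 3, bottom = 3, left = 2, right = 2)` for the
#'   study's ten-fragment conditions).
#' @param seed integer RNG seed; placement is deterministic given the seed.
#' @param max_tries per-box rejection budget.
#' @param max_restarts whole-configuration restarts before failing.
#' @return Object of class `fragment_configuration`: a list with `boxes`
#'   (data.frame `x`, `y`, `w`, `h`, `side`), `fragment_size_deg`,
#'   `fragment_size_px` and `seed`.
#' @export
place_fragments <- function(geometry, frame, size_deg, count,
                            side_quotas = NULL, seed = 1L,
                            max_tries = 400L, max_restarts = 50L) {
  stopifnot(inherits(geometry, "display_geometry"), inherits(frame, "frame_region"))
  assert_scalar_number(count, "count", 0, Inf)
  count <- as.integer(count)
  w <- deg_to_px(size_deg, geometry)
  if (count > 0L && w < 1L) stop("fragment size rounds to zero pixels", call. = FALSE)

  if (!is.null(side_quotas)) {
    need <- c("top", "bottom", "left", "right")
    if (!all(need %in% names(side_quotas))) {
      stop("`side_quotas` must name top, bottom, left and right", call. = FALSE)
    }
    side_quotas <- side_quotas[need]
    if (sum(side_quotas) != count) {
      stop("side quotas must sum to `count`", call. = FALSE)
    }
  }

  band_area_deg <- 4 * (frame$outer_deg^2 - frame$inner_deg^2)
  if (count * size_deg^2 > band_area_deg) {
    stop(sprintf("cannot place %d disjoint %.2f-deg fragments: required area %.1f deg^2 exceeds the %.1f deg^2 frame band",
                 count, size_deg, count * size_deg^2, band_area_deg), call. = FALSE)
  }

  ppd <- geometry$px_per_deg
  cx <- geometry$width_px / 2
  cy <- geometry$height_px / 2
  r_in <- frame$inner_deg * ppd
  r_out <- frame$outer_deg * ppd

  # integer top-left ranges keeping the box inside the outer square
  x_lo <- ceiling(cx - r_out); x_hi <- floor(cx + r_out - w)
  y_lo <- ceiling(cy - r_out); y_hi <- floor(cy + r_out - w)
  if (count > 0L && (x_hi < x_lo || y_hi < y_lo)) {
    stop("fragment does not fit inside the outer frame square", call. = FALSE)
  }

  inner_clear <- function(x, y) {
    # box must not intersect the open inner square
    !(x < cx + r_in && x + w > cx - r_in && y < cy + r_in && y + w > cy - r_in)
  }
  side_of <- function(x, y) {
    dx <- x + w / 2 - cx
    dy <- y + w / 2 - cy
    if (dy < 0 && -dy >= abs(dx)) return("top")
    if (dy > 0 && dy >= abs(dx)) return("bottom")
    if (dx < 0 && -dx > abs(dy)) return("left")
    "right"
  }
  # per-side sampling windows for the top-left corner (necessary conditions
  # only; the full predicate re-checks)
  side_window <- function(side) {
    switch(side,
      top = list(x = c(x_lo, x_hi), y = c(y_lo, floor(cy - r_in - w / 2))),
      bottom = list(x = c(x_lo, x_hi), y = c(ceiling(cy + r_in - w / 2), y_hi)),
      left = list(x = c(x_lo, floor(cx - r_in - w / 2)), y = c(y_lo, y_hi)),
      right = list(x = c(ceiling(cx + r_in - w / 2), x_hi), y = c(y_lo, y_hi)),
      all = list(x = c(x_lo, x_hi), y = c(y_lo, y_hi))
    )
  }

  wanted <- if (is.null(side_quotas)) {
    rep("all", count)
  } else {
    rep(c("top", "bottom", "left", "right"), times = side_quotas)
  }

  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      bx <- integer(0); by <- integer(0); bs <- character(0)
      ok <- TRUE
      for (want in wanted) {
        win <- side_window(want)
        placed <- FALSE
        if (win$x[2] >= win$x[1] && win$y[2] >= win$y[1]) {
          for (try in seq_len(max_tries)) {
            x <- sample.int(win$x[2] - win$x[1] + 1L, 1L) + win$x[1] - 1L
            y <- sample.int(win$y[2] - win$y[1] + 1L, 1L) + win$y[1] - 1L
            if (!inner_clear(x, y)) next
            if (want != "all" && side_of(x, y) != want) next
            if (length(bx) &&
                any(x < bx + w & x + w > bx & y < by + w & y + w > by)) next
            bx <- c(bx, x); by <- c(by, y)
            bs <- c(bs, if (want == "all") side_of(x, y) else want)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        boxes <- data.frame(x = bx, y = by, w = rep(w, count),
                            h = rep(w, count), side = bs,
                            stringsAsFactors = FALSE)
        return(structure(
          list(boxes = boxes, fragment_size_deg = size_deg,
               fragment_size_px = w, side_quotas = side_quotas, seed = seed),
          class = "fragment_configuration"))
      }
    }
    stop(sprintf("placement failure: could not place %d disjoint %.2f-deg fragments after %d restarts",
                 count, size_deg, max_restarts), call. = FALSE)
  })
}

#' @export
print.fragment_configuration <- function(x, ...) {
  cat(sprintf("Fragment configuration: %d boxes of %d px (%.2f deg), seed %d\n",
              nrow(x$boxes), x$fragment_size_px, x$fragment_size_deg, x$seed))
  if (nrow(x$boxes)) print(table(x$boxes$side))
  invisible(x)
}

#' Verify a fragment configuration against the placement constraints
#'
#' Independent checker, implemented separately from the sampler: eccentricity
#' containment is tested through the extrema of the Chebyshev distance over
#' each box (over a product set, `min max(|x|,|y|) = max(min|x|, min|y|)`),
#' disjointness over all pairs, and side quotas by re-deriving each box's
#' sector from its center.
#'
#' @param config a [fragment_configuration].
#' @param geometry a [display_geometry].
#' @param frame a [frame_region].
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
check_fragment_configuration <- function(config, geometry, frame) {
  stopifnot(inherits(config, "fragment_configuration"),
            inherits(geometry, "display_geometry"),
            inherits(frame, "frame_region"))
  b <- config$boxes
  viol <- character(0)
  if (nrow(b)) {
    ppd <- geometry$px_per_deg
    # degree coordinates of box edges relative to image center
    x0 <- (b$x - geometry$width_px / 2) / ppd
    x1 <- (b$x + b$w - geometry$width_px / 2) / ppd
    y0 <- (b$y - geometry$height_px / 2) / ppd
    y1 <- (b$y + b$h - geometry$height_px / 2) / ppd
    min_abs <- function(lo, hi) ifelse(lo <= 0 & hi >= 0, 0, pmin(abs(lo), abs(hi)))
    max_abs <- function(lo, hi) pmax(abs(lo), abs(hi))
    ecc_min <- pmax(min_abs(x0, x1), min_abs(y0, y1))
    ecc_max <- pmax(max_abs(x0, x1), max_abs(y0, y1))
    tol <- 1e-9
    if (any(ecc_max > frame$outer_deg + tol)) {
      viol <- c(viol, sprintf("box %s extends beyond the outer eccentricity bound",
                              paste(which(ecc_max > frame$outer_deg + tol), collapse = ",")))
    }
    if (any(ecc_min < frame$inner_deg - tol)) {
      viol <- c(viol, sprintf("box %s intrudes into the inner square",
                              paste(which(ecc_min < frame$inner_deg - tol), collapse = ",")))
    }
    if (nrow(b) > 1L) {
      pairs <- utils::combn(nrow(b), 2L)
      i <- pairs[1, ]; j <- pairs[2, ]
      overlap <- b$x[i] < b$x[j] + b$w[j] & b$x[i] + b$w[i] > b$x[j] &
        b$y[i] < b$y[j] + b$h[j] & b$y[i] + b$h[i] > b$y[j]
      if (any(overlap)) {
        viol <- c(viol, sprintf("overlapping box pairs: %s",
                                paste(sprintf("(%d,%d)", i[overlap], j[overlap]), collapse = " ")))
      }
    }
    # sector of each box center, re-derived (band partitioned by diagonals)
    cxd <- (b$x + b$w / 2 - geometry$width_px / 2) / ppd
    cyd <- (b$y + b$h / 2 - geometry$height_px / 2) / ppd
    side <- ifelse(cyd < 0 & -cyd >= abs(cxd), "top",
            ifelse(cyd > 0 & cyd >= abs(cxd), "bottom",
            ifelse(cxd < 0 & -cxd > abs(cyd), "left", "right")))
    if (!all(side == b$side)) {
      viol <- c(viol, sprintf("side label mismatch for box %s",
                              paste(which(side != b$side), collapse = ",")))
    }
    if (!is.null(config$side_quotas)) {
      got <- table(factor(b$side, levels = c("top", "bottom", "left", "right")))
      want <- config$side_quotas[c("top", "bottom", "left", "right")]
      if (!all(as.integer(got) == as.integer(want))) {
        viol <- c(viol, "side quotas not satisfied")
      }
    }
  }
  list(ok = length(viol) == 0L, violations = viol)
}

#' Render a fragment-occluded stimulus
#'
#' Copies source pixels inside the configuration's boxes; every other pixel
#' is set to the uniform gray background.
#'
#' @param image binary image matrix.
#' @param config a [fragment_configuration].
#' @param background background level (default gray 127).
#' @return Matrix with source levels inside boxes and background elsewhere.
#' @export
render_stimulus <- function(image, config, background = 127L) {
  stopifnot(inherits(config, "fragment_configuration"))
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  b <- config$boxes
  if (nrow(b) && (any(b$x < 0) || any(b$y < 0) ||
                  any(b$x + b$w > ncol(image)) || any(b$y + b$h > nrow(image)))) {
    stop("fragment box out of image bounds", call. = FALSE)
  }
  out <- matrix(as.integer(background), nrow(image), ncol(image))
  for (k in seq_len(nrow(b))) {
    rows <- (b$y[k] + 1L):(b$y[k] + b$h[k])
    cols <- (b$x[k] + 1L):(b$x[k] + b$w[k])
    out[rows, cols] <- image[rows, cols]
  }
  out
}

#' Render the frame-condition stimulus
#'
#' Keeps pixels whose center lies inside the square-annulus frame and
#' masks the rest with the background level.
#'
#' @inheritParams render_stimulus
#' @param geometry a [display_geometry].
#' @param frame a [frame_region].
#' @export
render_frame_stimulus <- function(image, frame, geometry, background = 127L) {
  stopifnot(inherits(frame, "frame_region"), inherits(geometry, "display_geometry"))
  ppd <- geometry$px_per_deg
  xd <- (seq_len(ncol(image)) - 0.5 - geometry$width_px / 2) / ppd
  yd <- (seq_len(nrow(image)) - 0.5 - geometry$height_px / 2) / ppd
  ecc <- outer(abs(yd), abs(xd), pmax)
  out <- matrix(as.integer(background), nrow(image), ncol(image))
  keep <- ecc >= frame$inner_deg & ecc <= frame$outer_deg
  out[keep] <- image[keep]
  out
}
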