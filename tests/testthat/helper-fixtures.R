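# Shared fixtures and independent oracles, built in code at test time.

# 6x6 vertical stripe image: columns 1-3 black, columns 4-6 white.
stripe_image <- function() {
  matrix(rep(c(0L, 255L), each = 18), nrow = 6, ncol = 6)
}

# A pattern_distribution with prescribed probabilities over the 2x2
# (16-pattern) alphabet, bypassing image counting.
toy_distribution <- function(probs16, n_tiles = 1000L) {
  stopifnot(length(probs16) == 16L, abs(sum(probs16) - 1) < 1e-9)
  structure(
    list(pattern_size = 2L, probs = probs16,
         counts = probs16 * n_tiles, n_tiles = n_tiles),
    class = "pattern_distribution"
  )
}

# Independent exhaustive knapsack oracle: enumerates all subset sums by
# recursive doubling (add one item at a time, doubling the sum vectors),
# deliberately a different algorithm than the package solver. Returns
# list(ids, H); on value ties within 1e-12 prefers fewer items, then
# lexicographically smaller id sets.
oracle_select <- function(probs, n_max, bandwidth_max) {
  cand <- which(probs > 0)
  p <- probs[cand]
  v <- -p * log2(p)
  m <- length(cand)
  if (m == 0L) return(list(ids = integer(0), H = 0))
  vals <- 0; wts <- 0; sizes <- 0L
  for (i in seq_len(m)) {      # mask order: item i toggles bit i-1
    vals <- c(vals, vals + v[i])
    wts <- c(wts, wts + p[i])
    sizes <- c(sizes, sizes + 1L)
  }
  feas <- sizes <= n_max & wts <= bandwidth_max + 1e-12
  vals[!feas] <- -Inf
  ties <- which(vals >= max(vals) - 1e-12)
  decode <- function(mask) which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
  better <- function(a, b) {
    if (length(a) != length(b)) return(length(a) < length(b))
    d <- which(a != b)
    length(d) > 0L && a[d[1]] < b[d[1]]
  }
  best <- decode(ties[1] - 1L)
  for (t in ties[-1]) {
    items <- decode(t - 1L)
    if (better(items, best)) best <- items
  }
  list(ids = sort(cand[best] - 1L), H = sum(v[best]))
}

# Random probability vector over 16 patterns with a controllable number of
# zero entries, normalized.
random_probs16 <- function(n_zero = 0L) {
  x <- stats::rexp(16)
  if (n_zero > 0L) x[sample.int(16, n_zero)] <- 0
  x / sum(x)
}

study_geometry <- function() display_geometry()
study_frame <- function() frame_region()

# Small full-geometry synthetic study shared by the heavier unit tests;
# built lazily and cached for the session.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(
        design = main_design("inverted"),
        image_spec = synthetic_image_spec(n_images = 6),
        n_participants = 3,
        seed = 11
      )
    }
    cache
  }
})
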