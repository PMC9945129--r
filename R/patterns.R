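#' Binary pattern coding
#'
#' A pattern is a `size x size` binary block; its id is the integer obtained
#' by reading the block row-major as a binary number with bit = 1 for white
#' pixels and the top-left pixel as the most significant bit. For the
#' default 3x3 size, ids run 0 (all black) to 511 (all white).
#'
#' @param pattern matrix with entries in \{0, 255\} (or \{0, 1\}).
#' @return `pattern_to_id()`: integer id. `pattern_from_id()`: integer
#'   matrix with levels 0/255.
#' @export
pattern_to_id <- function(pattern) {
  if (!is.matrix(pattern) || nrow(pattern) != ncol(pattern)) {
    stop("`pattern` must be a square matrix", call. = FALSE)
  }
  bits <- as.integer(t(pattern) != 0L)  # row-major order
  sum(bits * 2^(rev(seq_along(bits)) - 1L))
}

#' @rdname pattern_to_id
#' @param id integer pattern id in `[0, 2^(size^2) - 1]`.
#' @param size pattern side length.
#' @export
pattern_from_id <- function(id, size = 3L) {
  n <- size * size
  assert_scalar_number(id, "id", 0, 2^n - 1)
  bits <- as.integer(intToBits(id))[seq_len(n)]  # little-endian
  m <- matrix(rev(bits), nrow = size, ncol = size, byrow = TRUE)
  m * 255L
}

# Pattern ids of all complete non-overlapping size x size tiles, anchored at
# the top-left corner; incomplete edge tiles are dropped. Returns a matrix
# of ids with one entry per tile.
tile_pattern_ids <- function(image, size = 3L) {
  nr <- nrow(image) %/% size
  nc <- ncol(image) %/% size
  if (nr == 0L || nc == 0L) {
    stop("image smaller than one ", size, "x", size, " tile", call. = FALSE)
  }
  ids <- matrix(0, nr, nc)
  b <- (image != 0L) * 1
  n2 <- size * size
  for (dr in seq_len(size) - 1L) {
    for (dc in seq_len(size) - 1L) {
      w <- 2^(n2 - 1L - (dr * size + dc))
      ids <- ids + b[size * (seq_len(nr) - 1L) + 1L + dr,
                     size * (seq_len(nc) - 1L) + 1L + dc, drop = FALSE] * w
    }
  }
  ids
}

#' Pooled pattern distribution of binary images
#'
#' Partitions each image into non-overlapping `pattern_size x pattern_size`
#' tiles starting at the top-left corner (incomplete edge tiles dropped),
#' pools tile counts over all images, and normalizes to a probability
#' distribution over the `2^(pattern_size^2)` possible binary patterns.
#'
#' @param images a binary image matrix or a list of them.
#' @param pattern_size tile side length (default 3, i.e. 3x3 patterns);
#'   limited to 4 so the alphabet stays enumerable.
#' @return Object of class `pattern_distribution` with elements
#'   `pattern_size`, `probs` and `counts` (vectors indexed by id + 1),
#'   and `n_tiles`.
#' @examples
#' img <- matrix(rep(c(0L, 255L), each = 18), 6, 6)  # vertical stripes
#' pattern_distribution(img)$probs[c(1, 512)]
#' @export
pattern_distribution <- function(images, pattern_size = 3L) {
  assert_scalar_number(pattern_size, "pattern_size", 1, 4)
  if (is.matrix(images)) images <- list(images)
  if (!length(images)) stop("no images supplied", call. = FALSE)
  n_pat <- 2L^(pattern_size * pattern_size)
  counts <- numeric(n_pat)
  for (img in images) {
    assert_binary_image(img)
    ids <- tile_pattern_ids(img, pattern_size)
    counts <- counts + tabulate(as.integer(ids) + 1L, nbins = n_pat)
  }
  n_tiles <- sum(counts)
  structure(
    list(pattern_size = as.integer(pattern_size),
         probs = counts / n_tiles,
         counts = counts,
         n_tiles = n_tiles),
    class = "pattern_distribution"
  )
}

#' @export
print.pattern_distribution <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf("Pattern distribution: %dx%d patterns, %d tiles, %d/%d patterns observed\n",
              x$pattern_size, x$pattern_size, x$n_tiles, nz, length(x$probs)))
  cat(sprintf("  Shannon entropy: %.3f bits\n", shannon_entropy_bits(x$probs)))
  top <- order(x$probs, decreasing = TRUE)[1:5]
  cat("  top patterns (id: p):",
      paste(sprintf("%d: %.3g", top - 1L, x$probs[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Shannon entropy of a probability vector, in bits
#'
#' @param probs non-negative numeric vector summing to at most 1 (zero
#'   entries contribute nothing).
#' @return Entropy `sum(p * log2(1/p))` over positive entries.
#' @export
shannon_entropy_bits <- function(probs) {
  p <- probs[probs > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}
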