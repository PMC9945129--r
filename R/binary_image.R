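#' Binary images
#'
#' A binary image is an integer matrix with pixel levels 0 (black) and 255
#' (white); rows index the vertical (y) axis, columns the horizontal (x)
#' axis. Rendered stimuli may additionally contain a uniform background
#' level (127 by default) outside the visible regions.
#'
#' @name binary_image
NULL

assert_binary_image <- function(image, allow_background = FALSE,
                                background = 127L) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty matrix", call. = FALSE)
  }
  levels_ok <- image == 0L | image == 255L
  if (allow_background) levels_ok <- levels_ok | image == background
  if (!all(levels_ok)) {
    stop("image must contain only levels 0 and 255",
         if (allow_background) sprintf(" (or background %d)", background),
         call. = FALSE)
  }
  invisible(image)
}

#' Binarize an 8-bit grayscale image
#'
#' Reduces an 8-bit grayscale raster to a 1-bit black/white rendition, the
#' unit consumed by all later pipeline stages. The default rule thresholds
#' each image at its own median: pixels strictly above the median become
#' white (255), all others black (0).
#'
#' @param gray numeric matrix of 8-bit levels (0-255).
#' @param method `"median"` (per-image median threshold) or `"fixed"`.
#' @param threshold fixed threshold in \[0, 255\], required for
#'   `method = "fixed"`; pixels strictly above it become white.
#' @return Integer matrix with levels 0 and 255.
#' @examples
#' g <- matrix(c(10, 20, 200, 210), 2, 2)
#' binarize_image(g)
#' @export
binarize_image <- function(gray, method = c("median", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(gray) || length(gray) == 0L) {
    stop("`gray` must be a non-empty matrix", call. = FALSE)
  }
  t <- switch(method,
    median = stats::median(gray),
    fixed = {
      if (is.null(threshold)) {
        stop("`threshold` is required for method = \"fixed\"", call. = FALSE)
      }
      assert_scalar_number(threshold, "threshold", 0, 255)
      threshold
    }
  )
  out <- matrix(ifelse(gray > t, 255L, 0L), nrow(gray), ncol(gray))
  out
}

#' Invert the contrast of a binary image
#'
#' Swaps black (0) and white (255); any other level (e.g. the gray
#' background of a rendered stimulus) is left unchanged. The operation is
#' an involution.
#'
#' @param image binary image matrix (a background level may be present).
#' @return Matrix with 0 and 255 exchanged.
#' @export
invert_contrast <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  out <- image
  out[image == 0L] <- 255L
  out[image == 255L] <- 0L
  out
}

#' Read a grayscale image from PNG or PGM
#'
#' PNG files are read through the \pkg{png} package; PGM files (plain `P2`
#' or raw `P5`, 8-bit) with a built-in reader. Color PNGs are converted to
#' grayscale by channel averaging.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return Integer matrix of 8-bit levels.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3]))], c(1, 2), mean)
    return(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write a grayscale image to PNG or PGM
#'
#' @param image integer matrix of 8-bit levels.
#' @param path destination path ending in `.png` or `.pgm`; PGM output is
#'   plain-text `P2`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(image < 0 | image > 255)) {
    stop("pixel levels must be in [0, 255]", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

# Plain/raw PGM IO. No installed package reads PGM; the format is a
# three-token header plus pixel data.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  }
  tokens <- character(0)
  buf <- character(0)
  # read header tokens (width, height, maxval), skipping '#' comments
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 == "\n" || c2 == "") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  if (is.na(w) || is.na(h) || is.na(mx) || w <= 0L || h <= 0L) {
    stop("malformed PGM header: ", path, call. = FALSE)
  }
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", w * h))
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    px <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  }
  if (length(px) < w * h) stop("truncated PGM pixel data: ", path, call. = FALSE)
  matrix(px[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  rows <- apply(image, 1L, paste, collapse = " ")
  writeLines(rows, con)
  invisible(path)
}
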