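#' Optimal feature banks
#'
#' A feature bank is the set of binary patterns designated "optimal": the
#' best information carriers a capacity-limited early filter can transmit.
#' Selection maximizes the transmitted Shannon entropy
#' `H(D) = sum_{i in D} p_i log2(1/p_i)` subject to the two computing
#' limitations the model posits: at most `n_max` distinct features stored,
#' and total transmitted probability (output bandwidth)
#' `sum_{i in D} p_i <= bandwidth_max`.
#'
#' @param patterns integer vector of pattern ids.
#' @param pattern_size pattern side length.
#' @param n_max feature-count limit used at selection.
#' @param bandwidth_max output-bandwidth limit in \[0, 1\].
#' @param achieved_entropy_bits entropy of the selected set under the
#'   selection-time distribution (NA when loaded without one).
#' @param bandwidth_used total probability of the selected set (optional).
#' @return Object of class `feature_bank`.
#' @export
feature_bank <- function(patterns, pattern_size = 3L, n_max = length(patterns),
                         bandwidth_max = 1, achieved_entropy_bits = NA_real_,
                         bandwidth_used = NA_real_) {
  assert_scalar_number(pattern_size, "pattern_size", 1, 4)
  assert_scalar_number(n_max, "n_max", 0, Inf)
  assert_scalar_number(bandwidth_max, "bandwidth_max", 0, 1)
  patterns <- sort(unique(as.integer(patterns)))
  n_pat <- 2^(pattern_size * pattern_size)
  if (length(patterns) && (min(patterns) < 0 || max(patterns) >= n_pat)) {
    stop("pattern ids must be in [0, ", n_pat - 1, "]", call. = FALSE)
  }
  if (length(patterns) > n_max) {
    stop("bank holds more patterns than `n_max`", call. = FALSE)
  }
  structure(
    list(pattern_size = as.integer(pattern_size),
         patterns = patterns,
         n_max = as.integer(n_max),
         bandwidth_max = bandwidth_max,
         achieved_entropy_bits = achieved_entropy_bits,
         bandwidth_used = bandwidth_used),
    class = "feature_bank"
  )
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("Feature bank: %d of at most %d %dx%d patterns\n",
              length(x$patterns), x$n_max, x$pattern_size, x$pattern_size))
  cat(sprintf("  bandwidth limit %.4g (used %.4g), entropy %.4g bits\n",
              x$bandwidth_max, x$bandwidth_used, x$achieved_entropy_bits))
  invisible(x)
}

#' Membership of pattern ids in a feature bank
#'
#' @param bank a `feature_bank`.
#' @param ids integer vector of pattern ids.
#' @return Logical vector; deterministic.
#' @export
bank_contains <- function(bank, ids) {
  stopifnot(inherits(bank, "feature_bank"))
  as.integer(ids) %in% bank$patterns
}

#' Select the constrained maximum-entropy feature bank
#'
#' Finds the subset `D` of patterns maximizing the transmitted entropy
#' `H(D) = sum_{i in D} p_i log2(1/p_i)` subject to `|D| <= n_max` and
#' `sum_{i in D} p_i <= bandwidth_max` — a budgeted knapsack with per-item
#' value `p log2(1/p)` and weight `p`. Patterns with `p = 0` are never
#' selected. The bandwidth cap is what excludes the very frequent uniform
#' (all-black/all-white) patterns of binarized natural scenes; the value
#' term makes vanishing-probability "noisy" patterns worthless.
#'
#' For alphabets of at most 16 patterns the exact exhaustive optimum is
#' returned. For larger alphabets (e.g. the 512-pattern 3x3 alphabet),
#' where enumeration is infeasible, a local-search heuristic is used:
#' greedy fills from three orderings (value, value-to-weight ratio,
#' weight) and from every single-item seed, refined by add, single-swap
#' and drop-and-refill moves. The heuristic always returns a feasible
#' bank, is exact whenever the bandwidth budget is slack (the bank is then
#' the `n_max` highest-value patterns) and whenever `n_max <= 2`; for
#' budget-tight multi-feature optima it is a documented approximation.
#' Ties are broken toward smaller pattern ids.
#'
#' @param dist a [pattern_distribution].
#' @param n_max maximum number of features (the published set used 50).
#' @param bandwidth_max output-bandwidth limit in \[0, 1\].
#' @param method `"auto"` (exact for alphabets <= 16, else heuristic),
#'   `"exact"`, or `"greedy"`.
#' @return A [feature_bank] with `achieved_entropy_bits` filled in.
#' @examples
#' img <- matrix(rep(c(0L, 255L), each = 18), 6, 6)
#' d <- pattern_distribution(img)
#' select_optimal_features(d, n_max = 1, bandwidth_max = 1)
#' @export
select_optimal_features <- function(dist, n_max = 50,
                                    bandwidth_max = 0.2,
                                    method = c("auto", "exact", "greedy")) {
  stopifnot(inherits(dist, "pattern_distribution"))
  method <- match.arg(method)
  if (n_max < 0) stop("`n_max` must be >= 0", call. = FALSE)
  assert_scalar_number(bandwidth_max, "bandwidth_max", 0, 1)
  p_all <- dist$probs
  n_alpha <- length(p_all)
  if (method == "auto") method <- if (n_alpha <= 16L) "exact" else "greedy"

  cand <- which(p_all > 0)
  p <- p_all[cand]
  v <- -p * log2(p)
  sel_idx <- if (length(cand) == 0L || n_max == 0L) {
    integer(0)
  } else if (method == "exact") {
    knapsack_exact(v, p, n_max, bandwidth_max)
  } else {
    knapsack_local_search(v, p, n_max, bandwidth_max)
  }
  ids <- sort(cand[sel_idx] - 1L)
  feature_bank(ids, pattern_size = dist$pattern_size, n_max = n_max,
               bandwidth_max = bandwidth_max,
               achieved_entropy_bits = sum(v[sel_idx]),
               bandwidth_used = sum(p[sel_idx]))
}

# Exhaustive optimum by subset enumeration (items already restricted to
# p > 0). Feasible subsets: size <= n_max, weight <= budget + 1e-12.
# Among value ties (1e-12) prefers fewer items, then lexicographically
# smaller id sets. The 0/1 enumeration matrix is cached per item count.
.knapsack_cache <- new.env(parent = emptyenv())

subset_matrix <- function(m) {
  key <- as.character(m)
  if (!is.null(.knapsack_cache[[key]])) return(.knapsack_cache[[key]])
  bits <- matrix(as.integer(intToBits(0:(2^m - 1))), nrow = 32L)[seq_len(m), , drop = FALSE]
  out <- list(bits = bits, sizes = colSums(bits))
  .knapsack_cache[[key]] <- out
  out
}

knapsack_exact <- function(v, w, n_max, budget) {
  m <- length(v)
  if (m > 18L) stop("exact selection infeasible for alphabets this large; use method = \"greedy\"",
                    call. = FALSE)
  sm <- subset_matrix(m)
  B <- sm$bits                               # m x 2^m membership matrix
  vals <- as.numeric(v %*% B)
  wts <- as.numeric(w %*% B)
  sizes <- sm$sizes
  feasible <- sizes <= n_max & wts <= budget + 1e-12
  vals[!feasible] <- -Inf
  best_val <- max(vals)
  ties <- which(vals > best_val - 1e-12)
  best <- which(B[, ties[1]] == 1L)
  for (t in ties[-1]) {
    items <- which(B[, t] == 1L)
    if (prefer_subset(items, best)) best <- items
  }
  best
}

# TRUE when `a` is preferred to `b` under the deterministic tie-break:
# fewer items first, then lexicographically smaller sorted id vector.
prefer_subset <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  a <- sort(a); b <- sort(b)
  d <- which(a != b)
  length(d) > 0L && a[d[1]] < b[d[1]]
}

# Heuristic for large alphabets: greedy fills from several orderings and
# from every single-item seed (which makes two-feature optima exact),
# refined by a local search with add, best-single-swap, drop-and-refill
# and (for small solutions) pair-drop-and-refill moves.
knapsack_local_search <- function(v, w, n_max, budget, max_iter = 500L) {
  m <- length(v)
  eps <- 1e-12
  # orderings break ties toward smaller ids via the secondary sort key
  ord_value <- order(-v, seq_len(m))
  ord_ratio <- order(-(v / w), seq_len(m))
  ord_weight <- order(w, seq_len(m))
  greedy_fill <- function(sel, ord = ord_value) {
    ws <- sum(w[sel])
    in_sel <- logical(m); in_sel[sel] <- TRUE
    for (i in ord) {
      if (length(sel) >= n_max) break
      if (!in_sel[i] && ws + w[i] <= budget + eps) {
        sel <- c(sel, i); in_sel[i] <- TRUE; ws <- ws + w[i]
      }
    }
    sel
  }
  local_search <- function(sel) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) break
      improved <- FALSE
      ws <- sum(w[sel])
      in_sel <- logical(m); in_sel[sel] <- TRUE
      out <- which(!in_sel)
      # add
      if (length(sel) < n_max && length(out)) {
        fits <- out[ws + w[out] <= budget + eps]
        if (length(fits)) {
          j <- fits[order(-v[fits], fits)][1]
          sel <- c(sel, j); improved <- TRUE
        }
      }
      # best single swap
      if (!improved && length(sel) && length(out)) {
        best_gain <- eps; bi <- 0L; bj <- 0L
        for (k in seq_along(sel)) {
          i <- sel[k]
          room <- budget - (ws - w[i])
          fits <- out[w[out] <= room + eps]
          if (!length(fits)) next
          j <- fits[order(-v[fits], fits)][1]
          gain <- v[j] - v[i]
          if (gain > best_gain) { best_gain <- gain; bi <- k; bj <- j }
        }
        if (bi > 0L) { sel[bi] <- bj; improved <- TRUE }
      }
      # drop one item (or a pair, when the solution is small) and refill
      if (!improved && length(sel)) {
        cur_val <- sum(v[sel])
        for (k in seq_along(sel)) {
          alt <- greedy_fill(sel[-k])
          if (sum(v[alt]) > cur_val + eps) {
            sel <- alt; improved <- TRUE; break
          }
        }
        if (!improved && length(sel) >= 2L && length(sel) <= 20L) {
          pairs <- utils::combn(length(sel), 2L)
          for (q in seq_len(ncol(pairs))) {
            alt <- greedy_fill(sel[-pairs[, q]])
            if (sum(v[alt]) > cur_val + eps) {
              sel <- alt; improved <- TRUE; break
            }
          }
        }
      }
      if (!improved) break
    }
    sel
  }
  best <- integer(0); best_val <- 0
  consider <- function(sel) {
    val <- sum(v[sel])
    if (val > best_val + eps ||
        (val > best_val - eps && prefer_subset(sort(sel), sort(best)))) {
      best_val <<- val; best <<- sel
    }
  }
  for (ord in list(ord_value, ord_ratio, ord_weight)) {
    consider(local_search(greedy_fill(integer(0), ord)))
  }
  if (n_max >= 1L) {
    # one seeded fill per item; local-search the best of them
    seed_best <- integer(0); seed_val <- -1
    for (i in seq_len(m)) {
      if (w[i] > budget + eps) next
      sel <- greedy_fill(i)
      val <- sum(v[sel])
      if (val > seed_val + eps ||
          (val > seed_val - eps && prefer_subset(sort(sel), sort(seed_best)))) {
        seed_val <- val; seed_best <- sel
      }
    }
    if (length(seed_best)) {
      consider(seed_best)
      consider(local_search(seed_best))
    }
  }
  sort(best)
}

#' Sketch of an image under a feature bank
#'
#' Reduces a binary image to its "primal sketch": each complete tile whose
#' pattern is in the bank is copied verbatim, every other pixel is set to
#' the background level. With the full 512-pattern bank the sketch equals
#' the input on the tiled region; with an empty bank it is uniform
#' background.
#'
#' @param image binary image matrix.
#' @param bank a [feature_bank].
#' @param background level for non-retained pixels (default gray 127).
#' @return Matrix with levels \{0, 255, background\}.
#' @export
sketch_image <- function(image, bank, background = 127L) {
  assert_binary_image(image)
  stopifnot(inherits(bank, "feature_bank"))
  s <- bank$pattern_size
  ids <- tile_pattern_ids(image, s)
  keep <- matrix(bank_contains(bank, ids), nrow(ids), ncol(ids))
  out <- matrix(as.integer(background), nrow(image), ncol(image))
  for (i in seq_len(nrow(ids))) {
    for (j in seq_len(ncol(ids))) {
      if (keep[i, j]) {
        r <- (i - 1L) * s + seq_len(s)
        c <- (j - 1L) * s + seq_len(s)
        out[r, c] <- image[r, c]
      }
    }
  }
  out
}

#' Read and write feature-bank files
#'
#' Plain-text format: a header line `size=<int> n_max=<int>
#' bandwidth_max=<float>`, then one pattern per line as `size^2` characters
#' in \{0, 1\} (row-major, 1 = white); `#` starts a comment.
#'
#' @param bank a [feature_bank].
#' @param path file path.
#' @return `read_feature_bank()` returns a [feature_bank];
#'   `write_feature_bank()` returns `path` invisibly.
#' @export
write_feature_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  s <- bank$pattern_size
  n2 <- s * s
  lines <- c(
    sprintf("size=%d n_max=%d bandwidth_max=%s", s, bank$n_max,
            format_full(bank$bandwidth_max)),
    vapply(bank$patterns, function(id) {
      bits <- as.integer(intToBits(id))[seq_len(n2)]
      paste(rev(bits), collapse = "")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_bank
#' @export
read_feature_bank <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty feature-bank file: ", path, call. = FALSE)
  header <- lines[idx[1]]
  hm <- regmatches(header, regexec(
    "^size=([0-9]+)\\s+n_max=([0-9]+)\\s+bandwidth_max=([0-9.eE+-]+)$", header))[[1]]
  if (length(hm) != 4L) {
    stop(sprintf("malformed header at line %d of %s: '%s'", idx[1], path, header),
         call. = FALSE)
  }
  s <- as.integer(hm[2]); n_max <- as.integer(hm[3]); bmax <- as.numeric(hm[4])
  n2 <- s * s
  body <- idx[-1]
  ids <- integer(0)
  for (ln in body) {
    pat <- lines[ln]
    if (!grepl(sprintf("^[01]{%d}$", n2), pat)) {
      stop(sprintf("malformed pattern at line %d of %s: expected %d characters in {0,1}, got '%s'",
                   ln, path, n2, pat), call. = FALSE)
    }
    bits <- as.integer(strsplit(pat, "")[[1]])
    ids <- c(ids, sum(bits * 2^(rev(seq_len(n2)) - 1L)))
  }
  feature_bank(ids, pattern_size = s, n_max = n_max, bandwidth_max = bmax)
}
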