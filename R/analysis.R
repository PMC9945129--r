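#' Standardized SNR-minus-contrast difference
#'
#' Because per-stimulus SNR and Weber contrast are strongly
#' (anti-)correlated, their separate contributions to performance are
#' disentangled through a single derived regressor: each variable is
#' z-scored over the pooled trial set (all visible-area conditions
#' together) and the trial-wise difference `d = z(snr) - z(contrast)` is
#' taken. Sample standard deviations (denominator n - 1) are used. Trials
#' without measurements get `d = NA` and are excluded from the
#' standardization.
#'
#' @param trials schedule data.frame with `mean_snr` and `mean_contrast`.
#' @return The trials with a `d` column; `mean(d) = 0` over measured
#'   trials.
#' @export
standardized_difference <- function(trials) {
  if (!all(c("mean_snr", "mean_contrast") %in% names(trials))) {
    stop("trials must carry mean_snr and mean_contrast", call. = FALSE)
  }
  ok <- !is.na(trials$mean_snr) & !is.na(trials$mean_contrast)
  if (sum(ok) < 2L) stop("need at least 2 measured trials", call. = FALSE)
  s <- trials$mean_snr[ok]; c0 <- trials$mean_contrast[ok]
  if (stats::sd(s) == 0 || stats::sd(c0) == 0) {
    stop("cannot standardize a constant variable", call. = FALSE)
  }
  d <- rep(NA_real_, nrow(trials))
  d[ok] <- (s - mean(s)) / stats::sd(s) - (c0 - mean(c0)) / stats::sd(c0)
  trials$d <- d
  trials
}

# Model-matrix columns for the named fixed factors.
glmm_terms <- c(d = "d", order = "order1", repetition = "log_rep",
                inversion = "inverted")

glmm_frame <- function(trials) {
  data.frame(
    y = as.integer(trials$response_correct),
    d = trials$d,
    order1 = as.integer(trials$target_interval == 1L),
    log_rep = log1p(trials$repetition_target),
    inverted = as.integer(trials$target_inverted),
    participant = factor(trials$participant),
    stimulus = factor(trials$stimulus_image_id)
  )
}

#' Fit the binomial mixed model of discrimination performance
#'
#' Logit-link Bernoulli GLMM for `response_correct` with the study's fixed
#' factors — standardized SNR-contrast difference (`"d"`), target order
#' (`"order"`, indicator of interval 1), image repetition number
#' (`"repetition"`, entered as `log(1 + count)`), and optionally target
#' contrast inversion (`"inversion"`) — and random intercepts for
#' participants and stimuli, estimated with [lme4::glmer()]. Per-factor
#' chi-square statistics are likelihood-ratio tests against the model
#' without that factor, refitted with the same estimation settings.
#'
#' If the trials carry no `d` column it is derived with
#' [standardized_difference()]. With fewer than 2 levels in a random
#' grouping the model falls back to a fixed-effects-only [stats::glm()]
#' fit, with a warning and `fallback_fixed_only = TRUE`.
#'
#' @param trials measured schedule with responses.
#' @param fixed character subset of `c("d", "order", "repetition",
#'   "inversion")`.
#' @param random character subset of `c("participant", "stimulus")`.
#' @param lrt_factors factors to test by likelihood ratio (default: all
#'   fixed factors); use fewer to save refits.
#' @param nAGQ integration setting passed to [lme4::glmer()] (0 for the
#'   fast adaptive-least-squares approximation, 1 for the Laplace
#'   approximation).
#' @return Object of class `fragsal_glmm`: coefficients with standard
#'   errors and Wald z, random-effect SDs, per-factor LRT table, log
#'   likelihood, convergence flag, and the underlying fit.
#' @export
fit_binomial_glmm <- function(trials,
                              fixed = c("d", "order", "repetition"),
                              random = c("participant", "stimulus"),
                              lrt_factors = fixed, nAGQ = 1L) {
  fixed <- match.arg(fixed, names(glmm_terms), several.ok = TRUE)
  random <- match.arg(random, c("participant", "stimulus"), several.ok = TRUE)
  lrt_factors <- if (length(lrt_factors)) {
    match.arg(lrt_factors, fixed, several.ok = TRUE)
  } else character(0)
  if (!"d" %in% names(trials) || all(is.na(trials$d))) {
    trials <- standardized_difference(trials)
  }
  df <- glmm_frame(trials)
  df <- df[stats::complete.cases(df[c("y", glmm_terms[fixed])]), ]
  if (!nrow(df)) stop("no complete trials to fit", call. = FALSE)
  if (all(df$y == df$y[1])) {
    stop("complete separation: all responses identical", call. = FALSE)
  }

  usable <- random[vapply(random, function(g) nlevels(droplevels(df[[g]])) >= 2L,
                          logical(1))]
  fallback <- length(usable) == 0L
  if (fallback && length(random)) {
    warning("fewer than 2 levels in every random grouping; fitting fixed effects only")
  }

  rhs <- function(terms) {
    fe <- if (length(terms)) paste(glmm_terms[terms], collapse = " + ") else "1"
    re <- if (!fallback) paste(sprintf("(1 | %s)", usable), collapse = " + ") else NULL
    paste(c(fe, re), collapse = " + ")
  }
  fit_one <- function(terms) {
    f <- stats::as.formula(paste("y ~", rhs(terms)))
    if (fallback) {
      stats::glm(f, family = stats::binomial(), data = df)
    } else {
      lme4::glmer(f, family = stats::binomial(), data = df, nAGQ = nAGQ)
    }
  }
  full <- fit_one(fixed)

  if (fallback) {
    sm <- summary(full)
    coefs <- sm$coefficients[, 1:3, drop = FALSE]
    ranef_sd <- numeric(0)
    ll <- as.numeric(stats::logLik(full))
    converged <- full$converged
  } else {
    sm <- summary(full)
    coefs <- sm$coefficients[, 1:3, drop = FALSE]
    vc <- lme4::VarCorr(full)
    ranef_sd <- vapply(vc, function(m) sqrt(m[1, 1]), numeric(1))
    ll <- as.numeric(stats::logLik(full))
    converged <- length(full@optinfo$conv$lme4) == 0L &&
      full@optinfo$conv$opt == 0L
  }
  colnames(coefs) <- c("estimate", "se", "z")

  tests <- NULL
  if (length(lrt_factors)) {
    rows <- lapply(lrt_factors, function(f) {
      reduced <- fit_one(setdiff(fixed, f))
      chisq <- max(0, 2 * (ll - as.numeric(stats::logLik(reduced))))
      data.frame(factor = f, chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
  }

  structure(
    list(coefficients = coefs, ranef_sd = ranef_sd, tests = tests,
         logLik = ll, converged = converged, n = nrow(df),
         fixed = fixed, random = if (fallback) character(0) else usable,
         fallback_fixed_only = fallback, nAGQ = nAGQ, model = full),
    class = "fragsal_glmm"
  )
}

#' @export
print.fragsal_glmm <- function(x, ...) {
  cat(sprintf("Binomial GLMM (logit link), %d trials%s\n", x$n,
              if (x$fallback_fixed_only) " [fixed effects only]" else ""))
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  if (length(x$ranef_sd)) {
    cat("Random-intercept SDs:\n")
    print(round(x$ranef_sd, 4))
  }
  if (!is.null(x$tests)) {
    cat("Likelihood-ratio tests:\n")
    print(transform(x$tests, chisq = round(chisq, 2),
                    p_value = signif(p_value, 3)), row.names = FALSE)
  }
  cat(sprintf("logLik %.1f, converged: %s\n", x$logLik, x$converged))
  invisible(x)
}

#' @export
coef.fragsal_glmm <- function(object, ...) {
  stats::setNames(object$coefficients[, "estimate"],
                  rownames(object$coefficients))
}

#' @export
summary.fragsal_glmm <- function(object, ...) object

#' Two-proportion z-test with unpooled binomial standard errors
#'
#' `z = (p1 - p2) / sqrt(p1 (1 - p1) / n1 + p2 (1 - p2) / n2)` with a
#' two-sided normal p-value — the comparison of correct-response
#' probabilities with binomial standard deviations. The standard error is
#' undefined when both sample proportions are 0 or 1.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return Object of class `fragsal_test` with `statistic` (z), `p_value`
#'   and `effect` (difference of proportions).
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  for (v in list(c(k1, n1), c(k2, n2))) {
    if (v[2] <= 0 || v[1] < 0 || v[1] > v[2]) {
      stop("need 0 <= k <= n with n > 0", call. = FALSE)
    }
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  se2 <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  if (se2 == 0) stop("undefined standard error: both proportions are 0 or 1",
                     call. = FALSE)
  z <- (p1 - p2) / sqrt(se2)
  structure(
    list(method = "two-proportion z-test (unpooled)", statistic = z,
         df = NA_real_, p_value = 2 * stats::pnorm(-abs(z)),
         effect = p1 - p2, effect_name = "difference of proportions"),
    class = "fragsal_test"
  )
}

#' Friedman rank test with Kendall's W
#'
#' Non-parametric one-way repeated-measures ANOVA on a subjects-by-
#' conditions matrix: values are ranked within each subject (ties get
#' average ranks) and the tie-adjusted chi-square statistic
#' `(k - 1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` is computed, where `R_j`
#' are rank column sums, `A` the sum of squared ranks and
#' `C = n k (k+1)^2 / 4`; without ties this reduces to the classical
#' `12 / (n k (k+1)) * sum_j (R_j - n(k+1)/2)^2`. The effect size is
#' Kendall's coefficient of concordance `W = chisq / (n (k - 1))`. The
#' p-value is chi-square with `k - 1` df, or exact by full enumeration of
#' within-subject permutations when requested (feasible for small
#' matrices).
#'
#' @param block_matrix numeric matrix, subjects in rows, conditions in
#'   columns (>= 2 of each).
#' @param exact `NULL` (exact when `(k!)^n <= 1e5`), `TRUE` or `FALSE`.
#' @return Object of class `fragsal_test` with `statistic` (chi-square),
#'   `df`, `p_value` and `effect` (Kendall's W).
#' @export
friedman_test <- function(block_matrix, exact = NULL) {
  x <- as.matrix(block_matrix)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  r <- t(apply(x, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  dev <- sum((Rj - n * (k + 1) / 2)^2)
  if (A == C) {  # all values tied within every subject
    chisq <- 0
  } else {
    chisq <- (k - 1) * dev / (A - C)
  }
  W <- chisq / (n * (k - 1))
  do_exact <- exact %||% (factorial(k)^n <= 1e5)
  p <- if (do_exact) {
    friedman_exact_p(x, chisq)
  } else {
    stats::pchisq(chisq, k - 1, lower.tail = FALSE)
  }
  structure(
    list(method = if (do_exact) "Friedman rank test (exact)" else "Friedman rank test",
         statistic = chisq, df = k - 1, p_value = p,
         effect = W, effect_name = "Kendall's W"),
    class = "fragsal_test"
  )
}

# Exact permutation p: enumerate all within-subject orderings of each row
# and count statistics >= observed.
friedman_exact_p <- function(x, observed) {
  n <- nrow(x); k <- ncol(x)
  perms <- permutations_of(k)
  stat_of <- function(rows) {
    xx <- do.call(rbind, rows)
    ft <- friedman_stat_only(xx)
    ft
  }
  idx <- vector("list", n)
  count <- 0L; total <- 0L
  grid <- rep(list(seq_len(nrow(perms))), n)
  combos <- do.call(expand.grid, grid)
  for (i in seq_len(nrow(combos))) {
    rows <- lapply(seq_len(n), function(s) x[s, perms[combos[i, s], ]])
    st <- stat_of(rows)
    total <- total + 1L
    if (st >= observed - 1e-12) count <- count + 1L
  }
  count / total
}

friedman_stat_only <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) return(0)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- (seq_len(k))[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests whether per-subject proportions differ from the chance level
#' (default 0.5) with [stats::wilcox.test()]: exact p-value for n <= 15
#' (no ties or zeros), normal approximation otherwise. The statistic is
#' the positive-rank sum, whose maximum `n(n+1)/2` (55 for ten subjects)
#' obtains when every subject is above chance.
#'
#' @param values per-subject proportions.
#' @param mu chance level.
#' @return Object of class `fragsal_test` with `statistic` (V), `p_value`
#'   and `effect` (median difference from `mu`).
#' @export
wilcoxon_vs_chance <- function(values, mu = 0.5) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (all(values == mu)) stop("all values equal the chance level", call. = FALSE)
  exact <- n <= 15L && !any(values == mu) && !anyDuplicated(abs(values - mu))
  wt <- suppressWarnings(
    stats::wilcox.test(values, mu = mu, exact = exact, correct = !exact)
  )
  structure(
    list(method = "one-sample Wilcoxon signed-rank test",
         statistic = unname(wt$statistic), df = n - 1,
         p_value = wt$p.value,
         effect = stats::median(values) - mu,
         effect_name = "median difference from chance"),
    class = "fragsal_test"
  )
}

#' @export
print.fragsal_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.4g\n", x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  cat(sprintf("  %s = %.4g\n", x$effect_name, x$effect))
  invisible(x)
}
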