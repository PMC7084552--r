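# Two-group comparison of per-subject fit parameters. Normally distributed
# groups (Shapiro-Wilk at 0.05 in both) are compared with Student's t-test
# and summarized as mean +/- SD; otherwise the Mann-Whitney U test is used
# with median (IQR) summaries. The primary hypothesis is directional, so the
# default is a one-tailed test at significance level 0.05.

summarize_group <- function(v, normal) {
  if (normal) {
    sprintf("%.4g ± %.4g", mean(v), stats::sd(v))
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.4g (%.4g-%.4g)", q[2], q[1], q[3])
  }
}

shapiro_ok <- function(v) {
  if (length(unique(v)) < 3L || length(v) < 3L || length(v) > 5000L) return(FALSE)
  tryCatch(stats::shapiro.test(v)$p.value > 0.05, error = function(e) FALSE)
}

#' Compare a biomarker between two groups
#'
#' Routes to Student's t-test when both groups pass Shapiro-Wilk normality
#' at 0.05, otherwise to the Mann-Whitney U test; `test` can force either.
#' With `tail = "one"` the alternative is directional: `direction =
#' "greater"` tests whether the first group (first factor level of `group`)
#' is shifted above the second. Degenerate input in which every value of
#' both groups is identical yields statistic 0 and the null p-value (0.5
#' one-tailed, 1 two-tailed).
#'
#' @param data A data frame with one row per subject.
#' @param value Name of the numeric biomarker column (string).
#' @param group Name of the grouping column; must contain exactly two groups.
#' @param tail `"one"` (default) or `"two"`.
#' @param direction For one-tailed tests: `"greater"` (default) or `"less"`,
#'   referring to the first group relative to the second.
#' @param test `"auto"` (normality routing, default), `"t"` or
#'   `"mann-whitney"`.
#' @param alpha_level Significance level (default 0.05, significance accepted
#'   for p <= 0.05).
#' @return A one-row tibble of class `group_comparison`: `test`, `tail`,
#'   `statistic`, `p_value`, `significant`, `n_a`, `n_b`, `summary_a`,
#'   `summary_b`, `group_a`, `group_b`.
#' @export
#' @examples
#' d <- data.frame(beta = c(rnorm(10), rnorm(10, 1)),
#'                 group = rep(c("case", "control"), each = 10))
#' compare_groups(d, "beta", "group", tail = "two")
compare_groups <- function(data, value = "beta", group = "group",
                           tail = c("one", "two"),
                           direction = c("greater", "less"),
                           test = c("auto", "t", "mann-whitney"),
                           alpha_level = 0.05) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  test <- match.arg(test)
  stopifnot(is.data.frame(data), all(c(value, group) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("exactly two groups are required", call. = FALSE)
  a <- as.numeric(data[[value]][g == levels(g)[1]])
  b <- as.numeric(data[[value]][g == levels(g)[2]])
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 finite values", call. = FALSE)
  }

  normal <- shapiro_ok(a) && shapiro_ok(b)
  use_t <- switch(test, auto = normal, t = TRUE, `mann-whitney` = FALSE)
  alternative <- if (tail == "two") "two.sided" else direction

  if (stats::var(c(a, b)) == 0) {
    statistic <- 0
    p <- if (tail == "one") 0.5 else 1
    test_name <- if (use_t) "t" else "mann-whitney"
  } else if (use_t) {
    ht <- stats::t.test(a, b, alternative = alternative, var.equal = TRUE)
    statistic <- unname(ht$statistic); p <- ht$p.value; test_name <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = FALSE,
                         correct = TRUE))
    statistic <- unname(ht$statistic); p <- ht$p.value
    test_name <- "mann-whitney"
  }

  out <- tibble::tibble(
    test = test_name, tail = tail,
    direction = if (tail == "one") direction else NA_character_,
    statistic = statistic, p_value = p, significant = p <= alpha_level,
    n_a = length(a), n_b = length(b),
    group_a = levels(g)[1], group_b = levels(g)[2],
    summary_a = summarize_group(a, use_t), summary_b = summarize_group(b, use_t)
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Randomized-split (label-shuffling) control analysis
#'
#' Repeatedly shuffles the pooled subjects into two mixed groups of the
#' original sizes and re-runs [compare_groups()]; on a cohort whose
#' difference is genuine, the mixed groups should rarely reach
#' significance. Deterministic given `seed`.
#'
#' @inheritParams compare_groups
#' @param n_repeats Number of random splits (default 20).
#' @param seed Integer seed.
#' @return A list of class `randomized_split`: `p_values` tibble
#'   (`repeat_id`, `test`, `p_value`), `frac_significant`, `n_repeats`,
#'   `observed_p` (the true-label p-value under the same settings).
#' @export
randomized_split_test <- function(data, value = "beta", group = "group",
                                  n_repeats = 20L, seed = 1L,
                                  tail = c("one", "two"),
                                  direction = c("greater", "less"),
                                  test = c("auto", "t", "mann-whitney"),
                                  alpha_level = 0.05) {
  tail <- match.arg(tail); direction <- match.arg(direction)
  test <- match.arg(test)
  stopifnot(n_repeats >= 1L)
  observed <- compare_groups(data, value, group, tail = tail,
                             direction = direction, test = test,
                             alpha_level = alpha_level)
  shuffled <- withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      d <- data
      d[[group]] <- sample(d[[group]])
      cmp <- compare_groups(d, value, group, tail = tail,
                            direction = direction, test = test,
                            alpha_level = alpha_level)
      tibble::tibble(repeat_id = r, test = cmp$test, p_value = cmp$p_value)
    })
  })
  p_values <- dplyr::bind_rows(shuffled)
  structure(list(p_values = p_values,
                 frac_significant = mean(p_values$p_value <= alpha_level),
                 n_repeats = as.integer(n_repeats),
                 observed_p = observed$p_value),
            class = "randomized_split")
}

#' @export
print.randomized_split <- function(x, ...) {
  cat("<randomized_split> ", x$n_repeats, " repeats: ",
      round(100 * x$frac_significant, 1), "% significant at 0.05",
      " (true-label p = ", signif(x$observed_p, 3), ")\n", sep = "")
  invisible(x)
}

#' Flag alpha outliers and non-hyperbolic fits for exclusion
#'
#' Subjects whose fitted `alpha` exceeds the pooled upper Tukey fence
#' (Q3 + `fence_multiplier` * IQR, computed over all finite alphas unless a
#' frozen `threshold` is supplied) are flagged `high_alpha`; subjects whose
#' curve was judged non-hyperbola-like are flagged `non_hyperbolic`. With
#' zero pooled IQR no alpha outliers are declared.
#'
#' @param results Data frame with columns `alpha` and (optionally)
#'   `hyperbolic`.
#' @param fence_multiplier Tukey fence multiplier (default 1.5).
#' @param threshold Optional frozen alpha cutoff overriding the fence
#'   computation (used to re-apply an earlier exclusion decision).
#' @return `results` with added logical `excluded` and character
#'   `exclusion_reason`, plus the applied cutoff in attribute
#'   `alpha_threshold`.
#' @export
exclude_alpha_outliers <- function(results, fence_multiplier = 1.5,
                                   threshold = NULL) {
  stopifnot(is.data.frame(results), "alpha" %in% names(results))
  alpha <- results$alpha
  if (is.null(threshold)) {
    ok <- is.finite(alpha)
    q <- stats::quantile(alpha[ok], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    threshold <- if (iqr > 0) q[2] + fence_multiplier * iqr else Inf
  }
  high <- is.finite(alpha) & alpha > threshold
  nonhyp <- if ("hyperbolic" %in% names(results)) !results$hyperbolic else
    rep(FALSE, nrow(results))
  bad_fit <- is.na(alpha) | nonhyp
  out <- results
  out$excluded <- high | bad_fit
  out$exclusion_reason <- dplyr::case_when(
    high & bad_fit ~ "high_alpha;non_hyperbolic",
    high ~ "high_alpha",
    bad_fit ~ "non_hyperbolic",
    TRUE ~ NA_character_
  )
  attr(out, "alpha_threshold") <- threshold
  out
}
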