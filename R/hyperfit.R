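# Hyperbola model for lacunarity curves: L(b; alpha, beta, gamma) =
# beta / b^alpha + gamma with all three parameters positive. alpha tracks
# the fractal-dimension-like decay rate, beta is the lacunarity biomarker,
# gamma the large-scale asymptote. The least-squares problem is mildly
# non-convex in alpha, so the bounded Levenberg-Marquardt solve is
# multi-started over a small alpha grid and the lowest-SSE solution kept.

#' Fit the hyperbola model to a lacunarity curve
#'
#' Minimizes `sum_b (Lambda(b) - beta/b^alpha - gamma)^2` over positive
#' parameters, using bounded Levenberg-Marquardt (lower bounds 1e-12)
#' multi-started from `alpha0` with closed-form anchors `gamma0 = min
#' Lambda - eps` and `beta0 = (Lambda(b_min) - gamma0) * b_min^alpha0`.
#' Missing curve points are dropped before fitting.
#'
#' @param curve A [lacunarity_curve()] or any data frame with columns `b`
#'   and `lambda`; at least 4 non-missing points are required.
#' @param alpha0 Numeric vector of alpha starting values.
#' @param rel_sse_max Relative-SSE threshold above which the curve is
#'   declared non-hyperbola-like (see [assess_hyperbolic()]).
#' @param max_iter Maximum optimizer iterations per start.
#' @return An object of class `hyperbola_fit`: list with `alpha`, `beta`,
#'   `gamma`, `sse`, `rel_sse`, `converged`, `hyperbolic`, `n` (points
#'   used), `data` (the points), and `source_id`.
#' @export
#' @examples
#' b <- 3:16
#' fit <- fit_hyperbola(data.frame(b = b, lambda = 0.5 / b^1.2 + 1))
#' glance(fit)
fit_hyperbola <- function(curve, alpha0 = c(0.5, 1, 1.5, 2),
                          rel_sse_max = 0.2, max_iter = 5000L) {
  stopifnot(is.data.frame(curve), all(c("b", "lambda") %in% names(curve)))
  pts <- curve[is.finite(curve$b) & is.finite(curve$lambda), c("b", "lambda")]
  pts <- pts[order(pts$b), ]
  if (nrow(pts) < 4L) {
    stop("need at least 4 non-missing curve points to fit 3 parameters",
         call. = FALSE)
  }
  b <- as.numeric(pts$b); lam <- as.numeric(pts$lambda)
  resid_fn <- function(par) lam - (par[2] / b^par[1] + par[3])
  lower <- rep(1e-12, 3L)

  best <- NULL
  for (a0 in alpha0) {
    g0 <- max(min(lam) - 0.01 * max(diff(range(lam)), 1e-6), 1e-9)
    b0 <- max((lam[1] - g0) * b[1]^a0, 1e-9)
    # iteration-cap warnings are expected on pathological curves; the
    # converged flag captures them
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(a0, b0, g0), lower = lower, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, gtol = 1e-12,
          maxiter = min(1024L, max_iter), maxfev = max_iter)
      )),
      error = function(e) NULL
    )
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = res$par, sse = sse,
                   converged = res$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    best <- list(par = c(NA_real_, NA_real_, NA_real_), sse = Inf,
                 converged = FALSE)
  }
  fit <- structure(list(
    alpha = best$par[1], beta = best$par[2], gamma = best$par[3],
    sse = best$sse, rel_sse = NA_real_, converged = best$converged,
    hyperbolic = FALSE, n = nrow(pts), data = tibble::as_tibble(pts),
    source_id = attr(curve, "source_id") %||% "curve"
  ), class = "hyperbola_fit")
  verdict <- assess_hyperbolic(pts, fit, rel_sse_max = rel_sse_max)
  fit$rel_sse <- verdict$rel_sse
  fit$hyperbolic <- verdict$hyperbolic
  fit
}

#' Judge whether a lacunarity curve is hyperbola-like
#'
#' A curve passes when (i) the fit converged, (ii) the relative SSE
#' `SSE / sum((Lambda - mean Lambda)^2)` is at most `rel_sse_max`, and
#' (iii) the fitted model actually decreases over the observed box-size
#' range (a fitted amplitude `beta (b_min^-alpha - b_max^-alpha)` above a
#' tiny floor). Curves with no variation at all carry no hyperbola signal
#' and are declared non-hyperbolic.
#'
#' @param curve Data frame with columns `b` and `lambda`.
#' @param fit A [hyperbola_fit][fit_hyperbola].
#' @param rel_sse_max Relative-SSE threshold (default 0.2).
#' @return A list with `hyperbolic` (flag), `rel_sse` (score), and
#'   `decreasing`.
#' @export
assess_hyperbolic <- function(curve, fit, rel_sse_max = 0.2) {
  lam <- curve$lambda[is.finite(curve$lambda)]
  b <- curve$b[is.finite(curve$lambda)]
  ss_tot <- sum((lam - mean(lam))^2)
  rel_sse <- if (ss_tot > 1e-12) fit$sse / ss_tot else NA_real_
  amplitude <- if (is.finite(fit$alpha)) {
    fit$beta * (min(b)^(-fit$alpha) - max(b)^(-fit$alpha))
  } else {
    NA_real_
  }
  decreasing <- is.finite(amplitude) && amplitude > 1e-8
  hyperbolic <- isTRUE(fit$converged) && decreasing &&
    is.finite(rel_sse) && rel_sse <= rel_sse_max
  list(hyperbolic = hyperbolic, rel_sse = rel_sse, decreasing = decreasing)
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat("<hyperbola_fit> ", x$source_id, "\n", sep = "")
  cat(sprintf("  alpha = %.6g  beta = %.6g  gamma = %.6g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  sse = %.4g (relative %.4g), converged: %s, hyperbola-like: %s\n",
              x$sse, x$rel_sse, x$converged, x$hyperbolic))
  invisible(x)
}

#' Tidy a hyperbola fit into one row per parameter
#'
#' @param x A `hyperbola_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate`.
#' @method tidy hyperbola_fit
#' @export
tidy.hyperbola_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta", "gamma"),
                 estimate = c(x$alpha, x$beta, x$gamma))
}

#' One-row summary of a hyperbola fit
#'
#' @param x A `hyperbola_fit`.
#' @param ... Unused.
#' @return One-row tibble with parameters and diagnostics.
#' @method glance hyperbola_fit
#' @export
glance.hyperbola_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, gamma = x$gamma,
                 sse = x$sse, rel_sse = x$rel_sse, n = x$n,
                 converged = x$converged, hyperbolic = x$hyperbolic)
}

#' Predicted lacunarity from a hyperbola fit
#'
#' @param object A `hyperbola_fit`.
#' @param newdata Optional data frame with a `b` column; defaults to the
#'   fitted points.
#' @param ... Unused.
#' @return Numeric vector of model values `beta/b^alpha + gamma`.
#' @export
predict.hyperbola_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$data$b else newdata$b
  object$beta / b^object$alpha + object$gamma
}

#' @method autoplot hyperbola_fit
#' @export
autoplot.hyperbola_fit <- function(object, ...) {
  curve <- object$data
  attr(curve, "source_id") <- object$source_id
  class(curve) <- c("lacunarity_curve", class(curve))
  autoplot.lacunarity_curve(curve, fit = object)
}
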