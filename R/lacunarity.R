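# Gliding-box lacunarity of a gray-scale matrix. A b x b box glides over the
# matrix one unit at a time (no wrap, no edge overhang); the lacunarity at
# scale b is the ratio of the second moment to the squared first moment of
# the box masses, Lambda(b) = Z2/Z1^2 >= 1, with equality when all box
# masses coincide. Before gliding, the raw CGR counts are regularized with a
# logistic transform J = 1/(1 + exp(-k (I - sigma))) that pushes the image
# toward a binarization as k grows; sigma sits between fractional
# heteroplasmic deposits (< 1) and integer counts (>= 1).

#' Sigmoid (logistic) regularization of a CGR matrix
#'
#' Replaces each entry I by `1 / (1 + exp(-k * (I - sigma)))`. With the
#' defaults k = 7, sigma = 0.7 the transform discriminates fractional
#' heteroplasmic weights from whole counts; increasing `k` approaches a hard
#' binarization at threshold `sigma`.
#'
#' @param x A [cgr_matrix][build_cgr] or a plain numeric matrix with finite,
#'   nonnegative entries.
#' @param k Steepness (> 0).
#' @param sigma Threshold (> 0).
#' @param normalize If `TRUE`, entries are divided by their maximum before
#'   the transform (sensitivity-analysis mode); default applies the sigmoid
#'   to the raw weighted counts.
#' @return A numeric matrix with entries in (0, 1).
#' @export
#' @examples
#' sigmoid_transform(matrix(c(0, 0.7, 1, 2), 2), k = 7, sigma = 0.7)
sigmoid_transform <- function(x, k = 7, sigma = 0.7, normalize = FALSE) {
  m <- if (inherits(x, "cgr_matrix")) x$entries else x
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(!is.finite(m))) stop("matrix entries must be finite", call. = FALSE)
  if (any(m < 0)) stop("matrix entries must be nonnegative", call. = FALSE)
  stopifnot(k > 0, sigma > 0)
  if (normalize) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
  }
  1 / (1 + exp(-k * (m - sigma)))
}

# All b x b gliding-box masses at unit stride via a summed-area table
# (integral image); returns the (order - b + 1)^2 masses column by column.
box_masses <- function(m, b) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  order_ <- nrow(m)
  b <- as.integer(b)
  if (b < 1L || b > order_) {
    stop("box size b must lie in [1, ", order_, "]", call. = FALSE)
  }
  if (b == 1L) return(as.vector(m))
  # sat[i+1, j+1] = sum of m[1:i, 1:j], padded with a zero row/column
  sat <- matrix(0, order_ + 1L, order_ + 1L)
  sat[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  n1 <- order_ - b + 1L
  i <- seq_len(n1)
  as.vector(sat[i + b, i + b, drop = FALSE] - sat[i, i + b, drop = FALSE] -
              sat[i + b, i, drop = FALSE] + sat[i, i, drop = FALSE])
}

#' Box-mass distribution at one gliding-box scale
#'
#' @param m Numeric square matrix (typically a sigmoid-transformed CGR).
#' @param b Box side length, between 1 and the matrix order.
#' @return A list of class `box_mass_distribution`: `b`, `masses` (one per
#'   gliding position), `n_boxes` = (order - b + 1)^2, and `distribution`, a
#'   tibble of the distinct masses with their frequencies.
#' @export
#' @examples
#' box_mass_distribution(diag(2), b = 1)$masses
box_mass_distribution <- function(m, b) {
  masses <- box_masses(m, b)
  agg <- sort(unique(masses))
  structure(list(
    b = as.integer(b), masses = masses, n_boxes = length(masses),
    distribution = tibble::tibble(
      mass = agg,
      freq = as.integer(tabulate(match(masses, agg), nbins = length(agg)))
    )
  ), class = "box_mass_distribution")
}

#' @export
print.box_mass_distribution <- function(x, ...) {
  cat("<box_mass_distribution> b=", x$b, ", ", x$n_boxes, " boxes, ",
      nrow(x$distribution), " distinct masses\n", sep = "")
  invisible(x)
}

#' Lacunarity of one box-mass distribution
#'
#' `Lambda(b) = Z2 / Z1^2` with `Zq` the q-th raw moment of the box mass over
#' all gliding positions. Returns `NA` when the total mass is zero (the
#' ratio is undefined and the point is treated as missing downstream).
#'
#' @param dist A [box_mass_distribution()], or a bare numeric vector of box
#'   masses.
#' @return A single number >= 1, or `NA_real_` when undefined.
#' @export
#' @examples
#' lacunarity_value(c(0, 2, 0, 2))
lacunarity_value <- function(dist) {
  masses <- if (inherits(dist, "box_mass_distribution")) dist$masses else dist
  stopifnot(is.numeric(masses), length(masses) >= 1L)
  z1 <- mean(masses)
  if (z1 <= 0) return(NA_real_)
  mean(masses^2) / z1^2
}

#' Gliding-box lacunarity curve
#'
#' Evaluates `Lambda(b)` at every integer box size in `[b_min, b_max]`.
#'
#' @param x A numeric square matrix, or a [cgr_matrix][build_cgr] (in which
#'   case the sigmoid transform is applied first with the `k`, `sigma`,
#'   `normalize` arguments).
#' @param b_min,b_max Integer box-size bounds; `b_max` defaults to half the
#'   matrix order, keeping at least (order/2 + 1)^2 boxes per scale.
#' @param k,sigma,normalize Passed to [sigmoid_transform()] when `x` is a
#'   `cgr_matrix`.
#' @param source_id Provenance label.
#' @return A tibble of class `lacunarity_curve` with columns `b`, `lambda`,
#'   `n_boxes`; undefined scales carry `NA` lambda.
#' @export
#' @examples
#' m <- matrix(rep(c(1, 0), 8), 4)  # checkerboard columns
#' lacunarity_curve(m, b_min = 1, b_max = 2)
lacunarity_curve <- function(x, b_min = 3L, b_max = NULL, k = 7, sigma = 0.7,
                             normalize = FALSE, source_id = NULL) {
  if (inherits(x, "cgr_matrix")) {
    if (is.null(source_id)) source_id <- x$source_id
    m <- sigmoid_transform(x, k = k, sigma = sigma, normalize = normalize)
  } else {
    m <- x
    if (is.null(source_id)) source_id <- "matrix"
  }
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  order_ <- nrow(m)
  if (is.null(b_max)) b_max <- max(1L, order_ %/% 2L)
  b_min <- as.integer(b_min); b_max <- as.integer(b_max)
  if (b_min < 1L || b_min > b_max || b_max > order_) {
    stop("need 1 <= b_min <= b_max <= ", order_, call. = FALSE)
  }
  bs <- seq.int(b_min, b_max)
  vals <- vapply(bs, function(b) lacunarity_value(box_masses(m, b)), numeric(1))
  out <- tibble::tibble(b = bs, lambda = vals,
                        n_boxes = (order_ - bs + 1L)^2)
  attr(out, "source_id") <- source_id
  class(out) <- c("lacunarity_curve", class(out))
  out
}

#' Plot a lacunarity curve, optionally with a hyperbola fit overlaid
#'
#' @param object A `lacunarity_curve`.
#' @param fit Optional [hyperbola_fit][fit_hyperbola] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lacunarity_curve
#' @export
autoplot.lacunarity_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$b, y = .data$lambda)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(linetype = "dotted", na.rm = TRUE) +
    ggplot2::labs(x = "box size b", y = expression(Lambda(b)),
                  title = attr(object, "source_id")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(b = seq(min(object$b), max(object$b), length.out = 200))
    grid$lambda <- fit$beta / grid$b^fit$alpha + fit$gamma
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
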