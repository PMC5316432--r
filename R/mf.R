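#' Membership functions
#'
#' Parameterized unimodal fuzzy sets used by every system in the package.
#' Three families are supported, matching the per-system assignment of the
#' confidence model: `triangular` (peakness subsystem), `gauss2` -- a
#' two-sided Gaussian with a flat top (height subsystem and main system) --
#' and `trapezoidal` (spacing subsystem).
#'
#' Parameter conventions:
#' \describe{
#'   \item{triangular}{`c(a, b, c)` with `a <= b <= c`: left foot, apex,
#'     right foot. Degree 1 exactly at `b`.}
#'   \item{trapezoidal}{`c(a, b, c, d)` with `a <= b <= c <= d`: feet and
#'     shoulders. Degree 1 on `[b, c]`.}
#'   \item{gauss2}{`c(sigma1, c1, sigma2, c2)` with `sigma1, sigma2 > 0` and
#'     `c1 <= c2`: left/right Gaussian flanks around the plateau `[c1, c2]`.}
#' }
#'
#' Invalid parameters (ordering violations, non-positive sigma) are rejected
#' at construction; evaluation assumes a valid object.
#'
#' @param family one of `"triangular"`, `"trapezoidal"`, `"gauss2"`.
#' @param params numeric parameter vector, see conventions above.
#' @return an object of class `anfis_mf`.
#' @examples
#' mf <- membership_function("triangular", c(0, 0.5, 1))
#' mf_eval(mf, c(0.25, 0.5, 2))
#' @export
membership_function <- function(family, params) {
  family <- match.arg(family, mf_families())
  params <- as.numeric(params)
  msg <- mf_param_problem(family, params)
  if (!is.null(msg)) abort_validation("invalid %s parameters: %s", family, msg)
  structure(list(family = family, params = params), class = "anfis_mf")
}

#' @rdname membership_function
#' @export
mf_families <- function() c("triangular", "trapezoidal", "gauss2")

mf_param_problem <- function(family, params) {
  if (any(!is.finite(params))) return("parameters must be finite")
  switch(family,
    triangular = {
      if (length(params) != 3L) return("need c(a, b, c)")
      if (is.unsorted(params)) return("need a <= b <= c")
      if (params[3] <= params[1]) return("support must have positive width")
      NULL
    },
    trapezoidal = {
      if (length(params) != 4L) return("need c(a, b, c, d)")
      if (is.unsorted(params)) return("need a <= b <= c <= d")
      if (params[4] <= params[1]) return("support must have positive width")
      NULL
    },
    gauss2 = {
      if (length(params) != 4L) return("need c(sigma1, c1, sigma2, c2)")
      if (params[1] <= 0 || params[3] <= 0) return("sigmas must be positive")
      if (params[2] > params[4]) return("need c1 <= c2")
      NULL
    })
}

#' Evaluate a membership function
#'
#' Vectorized over `x`; returns degrees in `[0, 1]`, continuous in `x`.
#'
#' @param mf an `anfis_mf` object.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of membership degrees in `[0, 1]`.
#' @export
mf_eval <- function(mf, x) {
  stopifnot(inherits(mf, "anfis_mf"))
  p <- mf$params
  x <- as.numeric(x)
  switch(mf$family,
    triangular = {
      a <- p[1]; b <- p[2]; cc <- p[3]
      mu <- numeric(length(x))
      up <- x > a & x < b
      mu[up] <- (x[up] - a) / (b - a)
      dn <- x > b & x < cc
      mu[dn] <- (cc - x[dn]) / (cc - b)
      mu[x == b] <- 1
      mu
    },
    trapezoidal = {
      a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
      mu <- numeric(length(x))
      mu[x >= b & x <= cc] <- 1
      up <- x > a & x < b
      mu[up] <- (x[up] - a) / (b - a)
      dn <- x > cc & x < d
      mu[dn] <- (d - x[dn]) / (d - cc)
      mu
    },
    gauss2 = {
      s1 <- p[1]; c1 <- p[2]; s2 <- p[3]; c2 <- p[4]
      mu <- rep(1, length(x))
      l <- x < c1
      mu[l] <- exp(-(x[l] - c1)^2 / (2 * s1^2))
      r <- x > c2
      mu[r] <- exp(-(x[r] - c2)^2 / (2 * s2^2))
      mu
    })
}

# Center of the degree-1 region; used for ordering checks and initialization.
mf_center <- function(mf) {
  p <- mf$params
  switch(mf$family,
    triangular  = p[2],
    trapezoidal = (p[2] + p[3]) / 2,
    gauss2      = (p[2] + p[4]) / 2)
}

# d mu / d params, a length(x) x n_params matrix. Piecewise-linear families
# use the interior subgradient (zero at kinks), gauss2 is smooth off the
# plateau; this is the standard ANFIS premise gradient.
mf_grad <- function(mf, x) {
  p <- mf$params
  n <- length(x)
  g <- matrix(0, n, length(p))
  switch(mf$family,
    triangular = {
      a <- p[1]; b <- p[2]; cc <- p[3]
      up <- x > a & x < b
      if (any(up)) {
        g[up, 1] <- (x[up] - b) / (b - a)^2
        g[up, 2] <- -(x[up] - a) / (b - a)^2
      }
      dn <- x > b & x < cc
      if (any(dn)) {
        g[dn, 2] <- (cc - x[dn]) / (cc - b)^2
        g[dn, 3] <- (x[dn] - b) / (cc - b)^2
      }
    },
    trapezoidal = {
      a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
      up <- x > a & x < b
      if (any(up)) {
        g[up, 1] <- (x[up] - b) / (b - a)^2
        g[up, 2] <- -(x[up] - a) / (b - a)^2
      }
      dn <- x > cc & x < d
      if (any(dn)) {
        g[dn, 3] <- (d - x[dn]) / (d - cc)^2
        g[dn, 4] <- (x[dn] - cc) / (d - cc)^2
      }
    },
    gauss2 = {
      s1 <- p[1]; c1 <- p[2]; s2 <- p[3]; c2 <- p[4]
      l <- x < c1
      if (any(l)) {
        mu <- exp(-(x[l] - c1)^2 / (2 * s1^2))
        g[l, 1] <- mu * (x[l] - c1)^2 / s1^3
        g[l, 2] <- mu * (x[l] - c1) / s1^2
      }
      r <- x > c2
      if (any(r)) {
        mu <- exp(-(x[r] - c2)^2 / (2 * s2^2))
        g[r, 3] <- mu * (x[r] - c2)^2 / s2^3
        g[r, 4] <- mu * (x[r] - c2) / s2^2
      }
    })
  g
}

# Project a parameter vector back onto the feasible set after a gradient
# update: sort-and-clamp for the piecewise-linear families, sigma floor and
# swap-projection (c1 <= c2) for gauss2. Degenerate zero-width supports are
# opened by a hair so evaluation stays well defined.
mf_project <- function(family, params, sigma_floor = 1e-3, width_floor = 1e-6) {
  switch(family,
    triangular = {
      p <- sort(params)
      if (p[3] - p[1] < width_floor) p[3] <- p[1] + width_floor
      p
    },
    trapezoidal = {
      p <- sort(params)
      if (p[4] - p[1] < width_floor) p[4] <- p[1] + width_floor
      p
    },
    gauss2 = {
      p <- params
      if (p[2] > p[4]) p[c(2, 4)] <- mean(p[c(2, 4)])  # collapse the plateau
      p[1] <- max(p[1], sigma_floor)
      p[3] <- max(p[3], sigma_floor)
      p
    })
}

#' @export
print.anfis_mf <- function(x, ...) {
  cat(sprintf("<%s MF> params: %s\n", x$family,
              paste(format(x$params, digits = 4), collapse = ", ")))
  invisible(x)
}
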