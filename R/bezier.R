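#' Construct a Bezier segment
#'
#' A Bezier segment of degree `n` is defined by `n + 1` ordered control points
#' \eqn{P_0, \dots, P_n} through the Bernstein form
#' \deqn{B(t) = \sum_{i=0}^{n} \binom{n}{i} (1-t)^{n-i} t^i P_i, \quad t \in [0,1].}
#' The curve interpolates its first and last control points; interior control
#' points shape the curve without lying on it.
#'
#' @param control_points numeric matrix with `n + 1` rows and 2 columns
#'   (`x`, `y`), in pixel units.
#' @param degree curve degree `n`; defaults to `nrow(control_points) - 1`.
#' @return an object of class `bezier_segment`.
#' @export
#' @examples
#' seg <- bezier_segment(rbind(c(0, 0), c(1, 2), c(2, 0)))
#' evaluate_bernstein(seg, 0.5)
bezier_segment <- function(control_points, degree = nrow(control_points) - 1L) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 2L) {
    abort_bs("control_points must have two columns (x, y)", "usage_error")
  }
  if (!is.numeric(control_points) || !all(is.finite(control_points))) {
    abort_bs("control point coordinates must be finite numbers", "usage_error")
  }
  degree <- as.integer(degree)
  if (degree < 1L || nrow(control_points) != degree + 1L) {
    abort_bs("need degree >= 1 and exactly degree + 1 control points", "usage_error")
  }
  colnames(control_points) <- c("x", "y")
  structure(list(control_points = control_points, degree = degree),
            class = "bezier_segment")
}

#' @export
print.bezier_segment <- function(x, ...) {
  cat("<bezier_segment> degree", x$degree, "\n")
  print(x$control_points)
  invisible(x)
}

check_t <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || anyNA(t) || any(t < 0 | t > 1)) {
    abort_bs("curve parameter t must lie in [0, 1]", "usage_error")
  }
  as.numeric(t)
}

#' Bernstein basis matrix
#'
#' Row `i` holds the `n + 1` Bernstein polynomials
#' \eqn{b_{j,n}(t_i) = \binom{n}{j}(1-t_i)^{n-j} t_i^j}, `j = 0..n`, evaluated
#' at `t[i]`. Binomial coefficients come from [choose()] (exact integers at the
#' small degrees used here). Rows for `t = 0` and `t = 1` are set to exact unit
#' vectors so endpoint evaluation short-circuits to the endpoints.
#'
#' @param degree curve degree `n`.
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return a `length(t)` by `degree + 1` numeric matrix; rows sum to 1.
#' @export
bernstein_basis <- function(degree, t) {
  t <- check_t(t)
  n <- as.integer(degree)
  j <- 0:n
  B <- vapply(j, function(jj) choose(n, jj) * (1 - t)^(n - jj) * t^jj,
              numeric(length(t)))
  B <- matrix(B, nrow = length(t), ncol = n + 1L)
  # exact endpoint rows (avoids any 0^0 reliance)
  B[t == 0, ] <- rep(c(1, numeric(n)), each = sum(t == 0))
  B[t == 1, ] <- rep(c(numeric(n), 1), each = sum(t == 1))
  B
}

#' Evaluate a Bezier segment in Bernstein form
#'
#' @param segment a [bezier_segment()].
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return a `length(t)` by 2 matrix of (x, y) points.
#' @export
evaluate_bernstein <- function(segment, t) {
  stopifnot(inherits(segment, "bezier_segment"))
  B <- bernstein_basis(segment$degree, t)
  pts <- B %*% segment$control_points
  colnames(pts) <- c("x", "y")
  pts
}

#' Evaluate a Bezier segment by De Casteljau's construction
#'
#' Repeated linear interpolation of consecutive control points with ratio
#' `t : (1 - t)` until a single point remains. Numerically stable and, up to
#' rounding, identical to the Bernstein form.
#'
#' @inheritParams evaluate_bernstein
#' @param t a single parameter in `[0, 1]`.
#' @return a length-2 named numeric vector (x, y).
#' @export
evaluate_decasteljau <- function(segment, t) {
  stopifnot(inherits(segment, "bezier_segment"))
  t <- check_t(t)
  if (length(t) != 1L) abort_bs("t must be a single value", "usage_error")
  P <- segment$control_points
  while (nrow(P) > 1L) {
    P <- (1 - t) * P[-nrow(P), , drop = FALSE] + t * P[-1L, , drop = FALSE]
  }
  c(x = P[1, 1], y = P[1, 2])
}

#' Sample a Bezier segment at given parameters
#'
#' @inheritParams evaluate_bernstein
#' @param ts nonempty numeric vector of parameters in `[0, 1]`; order preserved.
#' @return a `length(ts)` by 2 matrix of points.
#' @export
sample_curve <- function(segment, ts) {
  if (length(ts) == 0L) abort_bs("ts must be nonempty", "usage_error")
  evaluate_bernstein(segment, ts)
}
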