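# Gaussian-expectation machinery shared by the solvers and metrics.
#
# Single-variable expectations of a bounded nonlinearity against the standard
# normal weight are computed by fixed-order Gauss-Legendre quadrature on
# [-6, 6] with the normal density made explicit in the integrand.  Double
# (cross) expectations use the change of variables
#   <f1 f2>_rho = E_{x,y~N(0,1)} [ f1(x) f2(sqrt(1-rho^2) y + rho x) ]
# so that rho -> 1 is numerically stable (the kernel degenerates to a delta).

.quad_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-xmax, xmax], premultiplied by the
# standard-normal density: sum(gw * g(gx)) approximates E[g(Y)], Y~N(0,1).
normal_quad <- function(n = 200L, xmax = 6) {
  key <- sprintf("gl_%d_%g", n, xmax)
  q <- .quad_cache[[key]]
  if (is.null(q)) {
    gl <- pracma::gaussLegendre(n, -xmax, xmax)
    q <- list(x = gl$x, w = gl$w * stats::dnorm(gl$x))
    .quad_cache[[key]] <- q
  }
  q
}

#' Gaussian expectations of one or two nonlinearities
#'
#' Computes the standard-normal expectations entering the optimal-decoder
#' algebra, for nonlinearities expressed in rescaled (unit input variance)
#' coordinates: the mean \eqn{\langle \tilde f \rangle}, the signal overlap
#' \eqn{\langle y \tilde f(y) \rangle}, the second moment
#' \eqn{\langle \tilde f^2 \rangle}, and, when a second nonlinearity is
#' supplied, the cross expectation
#' \eqn{\langle \tilde f_1(y_1) \tilde f_2(y_2) \rangle} for jointly
#' standard-normal \eqn{(y_1, y_2)} with correlation `rho`.
#'
#' @param f1 A `nonlinearity` (rescaled coordinates).
#' @param f2 Optional second `nonlinearity`.
#' @param rho Correlation at which the cross expectation is evaluated.
#' @param n_quad Quadrature order (Gauss-Legendre on \[-6, 6\]).
#' @return A list with `mean_f`, `y_f`, `f_sq`, and, with `f2`, also
#'   `mean_f2`, `y_f2`, `f_sq2`, `cross`, `rho_used`.
#' @examples
#' e <- gaussian_expectations(piecewise_nonlinearity(0, 1))
#' e$y_f  # pnorm(1) - pnorm(0)
#' @export
gaussian_expectations <- function(f1, f2 = NULL, rho = 0, n_quad = 200L) {
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  q <- normal_quad(n_quad)
  v1 <- predict(f1, q$x)
  out <- list(mean_f = sum(q$w * v1),
              y_f = sum(q$w * q$x * v1),
              f_sq = sum(q$w * v1^2))
  if (!is.null(f2)) {
    v2 <- predict(f2, q$x)
    out$mean_f2 <- sum(q$w * v2)
    out$y_f2 <- sum(q$w * q$x * v2)
    out$f_sq2 <- sum(q$w * v2^2)
    out$cross <- cross_expectation(f1, f2, rho, n_quad)
    out$rho_used <- rho
  }
  out
}

# <f1(y1) f2(y2)> at correlation rho by tensor-product quadrature.
cross_expectation <- function(f1, f2, rho, n_quad = 200L) {
  q <- normal_quad(n_quad)
  v1 <- predict(f1, q$x)
  if (abs(abs(rho) - 1) < 1e-14) {     # delta kernel
    v2 <- predict(f2, sign(rho) * q$x)
    return(sum(q$w * v1 * v2))
  }
  # K(x) = E_y[ f2(sqrt(1-rho^2) y + rho x) ]
  arg <- outer(rho * q$x, sqrt(1 - rho^2) * q$x, "+")
  K <- as.vector(matrix(predict(f2, as.vector(arg)), nrow = n_quad) %*% q$w)
  sum(q$w * v1 * K)
}

# Closed-form standard-normal moments of the clipped ramp with kinks x0 < x1
# (ON form): mean <f>, signal overlap <y f>, and second moment <f^2>.
# Used by the exact single-pathway solver; the quadrature path above serves
# as its independent check in the tests.
ramp_moments <- function(x0, x1) {
  w <- x1 - x0
  F0 <- stats::pnorm(x0); F1 <- stats::pnorm(x1)
  d0 <- stats::dnorm(x0); d1 <- stats::dnorm(x1)
  dF <- F1 - F0
  mean_f <- (d0 - d1 - x0 * dF) / w + 1 - F1
  y_f <- dF / w
  f_sq <- ((1 + x0^2) * dF - x0 * d0 + (2 * x0 - x1) * d1) / w^2 + 1 - F1
  list(mean_f = mean_f, y_f = y_f, f_sq = f_sq)
}
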