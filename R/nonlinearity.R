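#' Bounded nonlinearities
#'
#' A nonlinearity is a transfer function mapping total input (stimulus plus
#' upstream noise) to the mean of the stochastic response stage, constrained
#' to the range \[0, 1\].  Three representations are supported:
#'
#' * **piecewise linear**: \eqn{f(z) = \Xi((z - z_0)/(z_1 - z_0))} where
#'   \eqn{\Xi} clips to \[0, 1\]; this is the shape of the exact
#'   MSE-optimal single-pathway solution.
#' * **logistic**: \eqn{f(z) = 1 / (1 + e^{-\nu (z - \phi)})} with slope
#'   parameter \eqn{\nu > 0} and offset \eqn{\phi}; the smooth form used in
#'   parametric sweeps.
#' * **tabulated**: values on an ordered grid, interpolated by a natural
#'   cubic spline and clipped to \[0, 1\]; the representation of converged
#'   two-pathway solutions.
#'
#' OFF polarity is stored as a flag on the ON-form parameters: an OFF
#' nonlinearity evaluates the ON form at \eqn{-z} (falling instead of rising).
#' ON and OFF encoders are mirror images and achieve identical decoding error.
#'
#' @param z0,z1 Lower and upper kink of the piecewise-linear form (`z1 > z0`).
#' @param nu Logistic slope parameter (> 0; polarity carries the sign).
#' @param phi Logistic offset parameter.
#' @param x,f Grid abscissae (strictly increasing) and values in \[0, 1\] for
#'   the tabulated form.
#' @param polarity `"ON"` (rising) or `"OFF"` (falling).
#' @return An object of class `nonlinearity` (subclass `nl_piecewise`,
#'   `nl_logistic`, or `nl_tabulated`).
#' @examples
#' f <- piecewise_nonlinearity(0, 1)
#' predict(f, c(-3, 0.5, 7))   # 0, 0.5, 1
#' @name nonlinearity
NULL

#' @rdname nonlinearity
#' @export
piecewise_nonlinearity <- function(z0, z1, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(is.finite(z0), is.finite(z1))
  if (z1 <= z0) stop("piecewise form requires z1 > z0 (use polarity = \"OFF\" ",
                     "for a falling nonlinearity)", call. = FALSE)
  structure(list(z0 = z0, z1 = z1, polarity = polarity),
            class = c("nl_piecewise", "nonlinearity"))
}

#' @rdname nonlinearity
#' @export
logistic_nonlinearity <- function(nu, phi = 0, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(is.finite(nu), is.finite(phi))
  if (nu < 0) {  # negative slope is just the OFF form
    nu <- -nu
    phi <- -phi
    polarity <- if (polarity == "ON") "OFF" else "ON"
  }
  if (nu == 0) stop("logistic slope `nu` must be nonzero", call. = FALSE)
  structure(list(nu = nu, phi = phi, polarity = polarity),
            class = c("nl_logistic", "nonlinearity"))
}

#' @rdname nonlinearity
#' @export
tabulated_nonlinearity <- function(x, f, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(length(x) == length(f), length(x) >= 4L, all(is.finite(x)),
            all(is.finite(f)))
  if (any(diff(x) <= 0)) stop("grid_x must be strictly increasing",
                              call. = FALSE)
  structure(list(x = as.numeric(x), f = pmin(1, pmax(0, as.numeric(f))),
                 polarity = polarity),
            class = c("nl_tabulated", "nonlinearity"))
}

#' Default tabulation grid
#'
#' Symmetric grid on \[-6, 6\] in rescaled (unit-variance) input units with
#' 241 points, covering more than six standard deviations of any Gaussian
#' input mixture used by the solvers and matching the integral truncation of
#' the quadrature rules.
#'
#' @param n Number of grid points.
#' @param xmax Half-width of the grid.
#' @export
nl_grid <- function(n = 241L, xmax = 6) seq(-xmax, xmax, length.out = n)

#' Evaluate a nonlinearity
#'
#' Returns \eqn{f(z)} elementwise, always in \[0, 1\].  OFF polarity
#' evaluates the stored ON form at \eqn{-z}.  Tabulated nonlinearities are
#' interpolated with a natural cubic spline, clipped to \[0, 1\]; outside
#' the grid the boundary value is carried on.
#'
#' @param object A `nonlinearity`.
#' @param z Numeric vector of input values.
#' @param ... Unused.
#' @return Numeric vector of values in \[0, 1\].
#' @export
predict.nonlinearity <- function(object, z, ...) {
  if (object$polarity == "OFF") z <- -z
  eval_on(object, z)
}

eval_on <- function(object, z) UseMethod("eval_on")

#' @export
eval_on.nl_piecewise <- function(object, z) {
  pmin(1, pmax(0, (z - object$z0) / (object$z1 - object$z0)))
}

#' @export
eval_on.nl_logistic <- function(object, z) {
  stats::plogis(object$nu * (z - object$phi))
}

#' @export
eval_on.nl_tabulated <- function(object, z) {
  sp <- nl_spline(object)
  out <- numeric(length(z))
  lo <- z < object$x[1L]
  hi <- z > object$x[length(object$x)]
  mid <- !(lo | hi)
  out[lo] <- object$f[1L]
  out[hi] <- object$f[length(object$f)]
  if (any(mid)) out[mid] <- sp(z[mid])
  pmin(1, pmax(0, out))
}

# cached spline constructor (rebuilt if values changed)
nl_spline <- function(object) {
  stats::splinefun(object$x, object$f, method = "natural")
}

#' @export
print.nonlinearity <- function(x, ...) {
  desc <- switch(class(x)[1L],
    nl_piecewise = sprintf("piecewise linear, z0 = %.4g, z1 = %.4g", x$z0, x$z1),
    nl_logistic  = sprintf("logistic, nu = %.4g, phi = %.4g", x$nu, x$phi),
    nl_tabulated = sprintf("tabulated on [%g, %g] (%d points)",
                           x$x[1L], x$x[length(x$x)], length(x$x)))
  cat(sprintf("Nonlinearity (%s, %s polarity)\n", desc, x$polarity))
  invisible(x)
}

#' @export
plot.nonlinearity <- function(x, from = NULL, to = NULL, n = 401L, ...) {
  if (inherits(x, "nl_tabulated")) {
    if (is.null(from)) from <- x$x[1L]
    if (is.null(to)) to <- x$x[length(x$x)]
  } else {
    if (is.null(from)) from <- -4
    if (is.null(to)) to <- 4
  }
  z <- seq(from, to, length.out = n)
  graphics::plot(z, predict(x, z), type = "l", ylim = c(0, 1),
                 xlab = "input z", ylab = "f(z)", ...)
  invisible(x)
}

#' Rescale a nonlinearity between raw and normalized input coordinates
#'
#' The optimal encoder normalizes its input by the total input standard
#' deviation \eqn{\sigma_z = \sqrt{\sigma_s^2 + \sigma_{up}^2}}: the
#' rescaled nonlinearity \eqn{\tilde f(x) = f(\sigma_z x)} is independent of
#' \eqn{\sigma_s} and \eqn{\sigma_{up}}.  This maps kinks, offsets, and grids
#' linearly; the round trip is the identity.
#'
#' @param f A `nonlinearity`.
#' @param p A `circuit_params` object supplying \eqn{\sigma_s, \sigma_{up}}.
#' @param direction `"to_rescaled"` (raw z to x = z / sigma_z) or `"to_raw"`.
#' @return The transformed `nonlinearity` (same representation).
#' @export
rescale_nonlinearity <- function(f, p,
                                 direction = c("to_rescaled", "to_raw")) {
  direction <- match.arg(direction)
  s <- input_scale(p)
  a <- if (direction == "to_rescaled") 1 / s else s
  switch(class(f)[1L],
    nl_piecewise = piecewise_nonlinearity(f$z0 * a, f$z1 * a, f$polarity),
    nl_logistic  = logistic_nonlinearity(f$nu / a, f$phi * a, f$polarity),
    nl_tabulated = tabulated_nonlinearity(f$x * a, f$f, f$polarity),
    stop("unknown nonlinearity representation"))
}

#' Convert a nonlinearity to tabulated form
#'
#' @param f A `nonlinearity`.
#' @param x Grid on which to tabulate (default [nl_grid()]).
#' @export
as_tabulated <- function(f, x = nl_grid()) {
  if (inherits(f, "nl_tabulated")) return(f)
  tabulated_nonlinearity(x, predict(f, x))
}

#' Read and write nonlinearities as plain-text tables
#'
#' `write_nonlinearity()` writes a two-column whitespace-separated table
#' (`x`, `f`); `read_nonlinearity()` reads one back as a tabulated
#' nonlinearity.  `nl_to_json()` / `nl_from_json()` serialize the parameter
#' record of any representation.
#'
#' @param f A `nonlinearity`.
#' @param path File path.
#' @param x Tabulation grid used when `f` is not already tabulated.
#' @export
write_nonlinearity <- function(f, path, x = nl_grid()) {
  tb <- as_tabulated(f, x)
  utils::write.table(data.frame(x = tb$x, f = tb$f), path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nonlinearity
#' @export
read_nonlinearity <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  tabulated_nonlinearity(d$x, d$f)
}

#' @rdname write_nonlinearity
#' @export
nl_to_json <- function(f, path = NULL) {
  rec <- c(list(representation = sub("^nl_", "", class(f)[1L])), unclass(f))
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_nonlinearity
#' @export
nl_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  switch(rec$representation,
    piecewise = piecewise_nonlinearity(rec$z0, rec$z1, rec$polarity),
    logistic  = logistic_nonlinearity(rec$nu, rec$phi, rec$polarity),
    tabulated = tabulated_nonlinearity(rec$x, rec$f, rec$polarity),
    stop("unknown representation in file: ", rec$representation))
}
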