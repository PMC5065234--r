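#' Exact MSE-optimal nonlinearity for a single pathway
#'
#' Solves the variational (KKT) conditions for the nonlinearity that
#' minimizes the mean squared error of the optimal linear stimulus decoder.
#' The optimum is piecewise linear, \eqn{f(z) = \Xi((z - z_0)/(z_1 - z_0))}
#' with \eqn{\Xi} clipping to \[0, 1\], and in rescaled coordinates
#' \eqn{x = z / \sqrt{\sigma_s^2 + \sigma_{up}^2}} the kinks \eqn{(x_0, x_1)}
#' depend only on \eqn{\kappa} and \eqn{\sigma_{down}}.  They satisfy the
#' self-consistency relations
#' \deqn{x_1 - x_0 = \tilde D, \qquad
#'       x_0 = (x_1 - x_0)\,(\kappa/2 - \langle f \rangle),}
#' with the rescaled decoding weight \eqn{\tilde D} obeying
#' \eqn{\tilde D (\kappa \langle f \rangle + var[f] + \sigma_{down}^2) =
#' \langle y \tilde f \rangle}.  These transcendental equations are solved by
#' a damped Newton iteration on \eqn{(x_0, x_1)} seeded from a coarse grid
#' scan, using closed-form normal-CDF expressions for the ramp expectations.
#'
#' @param p A `circuit_params` object (only `sigma_s`, `sigma_up`, `kappa`,
#'   `sigma_down` are used).
#' @param control Optional list: `tol` (residual tolerance, default `1e-8`),
#'   `max_iter` (default 200), `grid_n` (seeding-scan resolution, default 41).
#' @return An object of class `single_solution`: fields `f` (raw-coordinate
#'   piecewise-linear `nonlinearity`), `f_rescaled`, `x0`, `x1`, `z0`, `z1`,
#'   `D` (`decoding_weights`, raw units), `D_rescaled`, `mse`, `snr`,
#'   `residual`, `converged`, `params`.
#' @examples
#' sol <- solve_single(circuit_params(sigma_up = 0.5, kappa = 0.1,
#'                                    sigma_down = 0.1))
#' coef(sol)
#' @export
solve_single <- function(p, control = list()) {
  validate_circuit_params(p)
  ctl <- modifyList(list(tol = 1e-8, max_iter = 200L, grid_n = 41L), control)
  kappa <- p$kappa; sd2 <- p$sigma_down^2

  if (kappa == 0 && sd2 == 0) {
    # no response-stage or downstream noise: widening the ramp always helps
    # and the optimal width diverges (MSE approaches the upstream-noise
    # floor asymptotically)
    warning("solution width diverges with kappa = 0 and sigma_down = 0; ",
            "solver did not converge")
    sz <- input_scale(p)
    w <- 1e3
    return(structure(list(
      f = piecewise_nonlinearity(-sz * w / 2, sz * w / 2),
      f_rescaled = piecewise_nonlinearity(-w / 2, w / 2),
      x0 = -w / 2, x1 = w / 2, z0 = -sz * w / 2, z1 = sz * w / 2,
      D = structure(list(D = NA_real_, D0 = NA_real_, degenerate = TRUE),
                    class = "decoding_weights"),
      D_rescaled = w,
      mse = p$sigma_s^2 * p$sigma_up^2 / (p$sigma_s^2 + p$sigma_up^2),
      snr = NA_real_, residual = NA_real_, n_iterations = 0L,
      converged = FALSE, params = p), class = "single_solution"))
  }

  resid <- function(th) {            # th = c(midpoint, log width)
    w <- exp(th[2L])
    x0 <- th[1L] - w / 2
    m <- ramp_moments(x0, x0 + w)
    vf <- m$f_sq - m$mean_f^2
    c(w * (kappa * m$mean_f + vf + sd2) - m$y_f,
      x0 - w * (kappa / 2 - m$mean_f))
  }
  # MSE of the best ramp at its own optimal weight (up to constants):
  # larger y_f^2 / A means lower error; the KKT root is its maximizer, so
  # minimizing this first avoids the spurious quasi-roots in the far tails
  # where every expectation is exponentially small
  negT <- function(th) {
    w <- exp(th[2L])
    x0 <- th[1L] - w / 2
    m <- ramp_moments(x0, x0 + w)
    A <- kappa * m$mean_f + (m$f_sq - m$mean_f^2) + sd2
    if (!is.finite(A) || A <= 0) return(Inf)
    -m$y_f^2 / A
  }

  midg <- seq(-4, 4, length.out = ctl$grid_n)
  lwg <- seq(log(0.02), log(200), length.out = ctl$grid_n)
  best <- NULL; bestv <- Inf
  for (mid in midg) for (lw in lwg) {
    v <- negT(c(mid, lw))
    if (is.finite(v) && v < bestv) { bestv <- v; best <- c(mid, lw) }
  }
  opt <- stats::optim(best, negT, control = list(reltol = 1e-12,
                                                 maxit = 500L))
  th <- opt$par
  r <- resid(th)
  iter <- 0L
  while (max(abs(r)) > ctl$tol && iter < ctl$max_iter) {
    iter <- iter + 1L
    J <- numjac(resid, th, r)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {                          # damping: require residual decrease
      th_new <- th + lambda * step
      r_new <- resid(th_new)
      if (all(is.finite(r_new)) &&
          (sum(r_new^2) < sum(r^2) || lambda < 1e-6)) break
      lambda <- lambda / 2
    }
    th <- th_new; r <- r_new
  }

  w <- exp(th[2L]); x0 <- th[1L] - w / 2; x1 <- x0 + w
  converged <- max(abs(r)) <= ctl$tol && w < 500
  if (max(abs(r)) <= ctl$tol && w >= 500)
    warning("solution width diverges (noise sources ~ 0); ",
            "solver did not converge")

  sz <- input_scale(p)
  f_res <- piecewise_nonlinearity(x0, x1)
  f_raw <- piecewise_nonlinearity(sz * x0, sz * x1)
  m <- ramp_moments(x0, x1)
  D_res <- w                                      # rescaled weight
  D_raw <- p$sigma_s^2 * D_res / sz
  chi2 <- p$sigma_s^2 *
    (1 - p$sigma_s^2 / sz^2 * D_res * m$y_f)
  structure(list(
    f = f_raw, f_rescaled = f_res,
    x0 = x0, x1 = x1, z0 = sz * x0, z1 = sz * x1,
    D = structure(list(D = D_raw, D0 = -D_raw * m$mean_f,
                       degenerate = FALSE), class = "decoding_weights"),
    D_rescaled = D_res,
    mse = chi2, snr = snr(p, f_raw),
    residual = max(abs(r)), n_iterations = iter, converged = converged,
    params = p), class = "single_solution")
}

# forward-difference Jacobian
numjac <- function(fn, th, r0 = fn(th), h = 1e-7) {
  J <- matrix(0, length(r0), length(th))
  for (j in seq_along(th)) {
    thj <- th; thj[j] <- thj[j] + h
    J[, j] <- (fn(thj) - r0) / h
  }
  J
}

#' @export
print.single_solution <- function(x, ...) {
  cat("Single-pathway MSE-optimal nonlinearity\n")
  cat(sprintf("  kinks (raw): z0 = %.5g, z1 = %.5g;  (rescaled): x0 = %.5g, x1 = %.5g\n",
              x$z0, x$z1, x$x0, x$x1))
  cat(sprintf("  D = %.5g,  MSE = %.5g,  SNR = %.4g\n",
              x$D$D, x$mse, x$snr))
  cat(sprintf("  residual = %.2e (%s in %d iterations)\n", x$residual,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @export
summary.single_solution <- function(object, ...) {
  so_raw <- slope_offset(object)
  so_res <- slope_offset(object, rescaled = TRUE)
  out <- c(coef(object),
           slope = so_raw[["slope"]], offset = so_raw[["offset"]],
           slope_rescaled = so_res[["slope"]],
           offset_rescaled = so_res[["offset"]])
  print(object)
  cat(sprintf("  slope = %.5g (rescaled %.5g), offset = %.5g (rescaled %.5g)\n",
              out[["slope"]], out[["slope_rescaled"]], out[["offset"]],
              out[["offset_rescaled"]]))
  invisible(out)
}

#' @export
coef.single_solution <- function(object, ...) {
  c(x0 = object$x0, x1 = object$x1, z0 = object$z0, z1 = object$z1,
    D = object$D$D, D0 = object$D$D0, mse = object$mse, snr = object$snr)
}

#' @export
predict.single_solution <- function(object, z, ...) predict(object$f, z, ...)

#' @export
plot.single_solution <- function(x, rescaled = FALSE, ...) {
  f <- if (rescaled) x$f_rescaled else x$f
  sz <- if (rescaled) 1 else input_scale(x$params)
  zz <- seq(-4 * sz, 4 * sz, length.out = 401L)
  graphics::plot(zz, predict(f, zz), type = "l", ylim = c(0, 1),
                 xlab = if (rescaled) "rescaled input x" else "input z",
                 ylab = "f", ...)
  graphics::lines(zz, stats::dnorm(zz, 0, sz) * sz, lty = 3)
  invisible(x)
}

#' @export
simulate.single_solution <- function(object, nsim = 1, seed = NULL, n = 1e4,
                                     ...) {
  if (is.null(seed)) seed <- 1L
  if (nsim == 1L) return(simulate_circuit(object$params, object$f, n, seed))
  lapply(seq_len(nsim),
         function(i) simulate_circuit(object$params, object$f, n,
                                      seed + i - 1L))
}

#' @export
residuals.single_solution <- function(object, n = 1e4, seed = 1L, ...) {
  d <- simulate_circuit(object$params, object$f, n, seed)
  s_est <- object$D$D0 + object$D$D * d$r_1
  d$s - s_est
}

#' Slope and offset of a solved or parametric nonlinearity
#'
#' For a piecewise-linear solution the slope is \eqn{1/(z_1 - z_0)} and the
#' offset the kink midpoint \eqn{(z_0 + z_1)/2}; for a logistic nonlinearity
#' the slope is the derivative at the midpoint (\eqn{\nu/4}) and the offset
#' \eqn{\phi}; tabulated shapes are summarized by their 0.25/0.75 level
#' crossings.  With `rescaled = TRUE` the slope is multiplied, and the offset
#' divided, by \eqn{\sqrt{\sigma_s^2 + \sigma_{up}^2}}.
#'
#' @param x A `single_solution` or a `nonlinearity`.
#' @param rescaled Report in rescaled units?
#' @param p `circuit_params` needed to rescale a bare `nonlinearity`.
#' @return Named vector `c(slope, offset)` (slope is the magnitude; the sign
#'   of an OFF nonlinearity is carried by its polarity).
#' @export
slope_offset <- function(x, rescaled = FALSE, p = NULL) {
  if (inherits(x, "single_solution")) {
    f <- if (rescaled) x$f_rescaled else x$f
    return(nl_slope_offset(f))
  }
  stopifnot(inherits(x, "nonlinearity"))
  if (rescaled && !is.null(p)) x <- rescale_nonlinearity(x, p, "to_rescaled")
  nl_slope_offset(x)
}

nl_slope_offset <- function(f) {
  if (inherits(f, "nl_piecewise")) {
    return(c(slope = 1 / (f$z1 - f$z0), offset = (f$z0 + f$z1) / 2))
  }
  if (inherits(f, "nl_logistic")) {
    return(c(slope = f$nu / 4, offset = if (f$polarity == "OFF") -f$phi
             else f$phi))
  }
  # tabulated: quartile crossings; a falling curve is mirrored first and its
  # slope reported with negative sign
  x <- f$x; v <- f$f
  falling <- v[length(v)] < v[1L]
  if (falling) { x <- -rev(x); v <- rev(v) }
  if (f$polarity == "OFF") falling <- !falling
  cross <- function(level) {
    i <- which(v[-1L] >= level & v[-length(v)] < level)
    if (!length(i)) return(NA_real_)
    i <- i[1L]
    x[i] + (level - v[i]) * (x[i + 1L] - x[i]) / (v[i + 1L] - v[i])
  }
  x25 <- cross(0.25); x75 <- cross(0.75)
  off <- (x25 + x75) / 2
  c(slope = (if (falling) -0.5 else 0.5) / (x75 - x25),
    offset = if (falling) -off else off)
}
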