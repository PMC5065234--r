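#' Solve the coupled integral equations for a pair of pathways
#'
#' Finds a fixed point of the iterated maps for the two rescaled decoding
#' weights and the two rescaled nonlinearities of a two-pathway encoder.
#' Each iteration (i) solves the 2x2 optimal-weight system explicitly from
#' the current nonlinearities and (ii) updates each nonlinearity on a grid by
#' the clipped variational expression
#' \deqn{\tilde f_1(x) \leftarrow \Xi\Big( \frac{x}{\tilde D_1} -
#'   \frac{\kappa}{2} + \langle \tilde f_1 \rangle +
#'   \frac{\tilde D_2}{\tilde D_1} \big( \langle \tilde f_2 \rangle -
#'   E_y[\tilde f_2(\sqrt{1-\rho_{eff}^2}\, y + \rho_{eff} x)] \big) \Big)}
#' (and symmetrically for pathway 2), where the kernel expectation has been
#' re-expressed so that \eqn{\rho_{eff} \to 1} is numerically stable
#' (reducing to a delta kernel).  Iteration stops when every weight and every
#' grid value changes by less than `tol` (Picard iteration; convergence is
#' checked, not proven, so multiple random initializations are used by
#' [multi_seed_solve()]).
#'
#' After rescaling, the fixed point depends only on
#' \eqn{(\rho_{eff}, \kappa, \sigma_{down}, \rho_{down})}; the supplied
#' \eqn{\sigma_s, \sigma_{up}} determine the raw-unit weights and the MSE.
#'
#' Initialization: weights are drawn \eqn{N(\pm 1, 0.5^2)} with the sign
#' pattern of the requested class (`on_off`: \eqn{D_1 > 0 > D_2}; `on_on`:
#' both positive); nonlinearity values are drawn independently per grid point
#' by taking a uniform random value for the kernel-integral term and clipping
#' the resulting update to \[0, 1\].
#'
#' @param p A two-pathway `circuit_params` object.
#' @param init_class `"on_off"` or `"on_on"`: sign pattern of the initial
#'   weight guess (either class of fixed point may still be reached
#'   occasionally; the result is classified after convergence).
#' @param seed Integer seed for the random initialization.
#' @param control Optional list overriding: `grid_n` (241), `xmax` (6),
#'   `n_quad` (200), `tol` (1e-4), `max_iter` (2000), `relax` (1; values
#'   < 1 damp the update for stiff corners such as `rho_eff` near 1 with
#'   small noise).
#' @return An object of class `dual_solution` with fields `f1`, `f2`
#'   (tabulated rescaled nonlinearities), `D1`, `D2` (rescaled weights),
#'   `D_raw` (`decoding_weights` in response units), `mse`, `readout_term`
#'   (\eqn{\tilde D_1 \langle y \tilde f_1 \rangle + \tilde D_2 \langle y
#'   \tilde f_2 \rangle}, from which the MSE at any realization of
#'   \eqn{\rho_{eff}} follows), `strategy`, `n_iterations`, `converged`,
#'   `change_trace`, `seed`, `params`.
#' @seealso [multi_seed_solve()], [classify_solution()], [solution_residual()]
#' @export
picard_solve <- function(p, init_class = c("on_off", "on_on"), seed = 1L,
                         control = list()) {
  validate_circuit_params(p)
  if (p$n_pathways != 2L)
    stop("picard_solve() requires a two-pathway model", call. = FALSE)
  init_class <- match.arg(init_class)
  ctl <- modifyList(list(grid_n = 241L, xmax = 6, n_quad = 200L,
                         tol = 1e-4, max_iter = 2000L, relax = 1), control)
  rho <- effective_correlation(p)
  fit <- picard_core(rho_eff = rho, kappa = p$kappa,
                     sigma_down = p$sigma_down, rho_down = p$rho_down,
                     init_class = init_class, seed = seed, ctl = ctl)
  finish_dual(fit, p, seed)
}

# ---- rescaled-space Picard iteration ---------------------------------------

picard_core <- function(rho_eff, kappa, sigma_down, rho_down,
                        init_class, seed, ctl) {
  xg <- nl_grid(ctl$grid_n, ctl$xmax)
  q <- normal_quad(ctl$n_quad, ctl$xmax)
  sd2 <- sigma_down^2
  delta_kernel <- abs(abs(rho_eff) - 1) < 1e-12
  zero_kernel <- abs(rho_eff) < 1e-12
  if (!delta_kernel && !zero_kernel) {
    # fixed argument grids for the kernel expectation, at the tabulation grid
    # and at the quadrature nodes (the latter feed the cross expectation)
    argg <- outer(rho_eff * xg, sqrt(1 - rho_eff^2) * q$x, "+")
    argq <- outer(rho_eff * q$x, sqrt(1 - rho_eff^2) * q$x, "+")
  }

  set.seed(seed)
  sgn <- if (init_class == "on_off") c(1, -1) else c(1, 1)
  D <- stats::rnorm(2L, mean = sgn, sd = 0.5)
  # keep the requested sign pattern for the very first update
  D <- ifelse(sign(D) == sgn | D == 0, D, sgn * 0.1)
  # uniform random kernel-integral term per grid point, clipped update
  f1 <- pmin(1, pmax(0, xg / D[1L] - kappa / 2 + stats::runif(ctl$grid_n)))
  f2 <- pmin(1, pmax(0, xg / D[2L] - kappa / 2 + stats::runif(ctl$grid_n)))
  f1 <- pmin(1, pmax(0, f1)); f2 <- pmin(1, pmax(0, f2))

  eval_tab <- function(v, at) {
    sp <- stats::splinefun(xg, v, method = "natural")
    out <- sp(at)
    out[at < xg[1L]] <- v[1L]
    out[at > xg[length(xg)]] <- v[length(v)]
    pmin(1, pmax(0, out))
  }

  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    fq1 <- eval_tab(f1, q$x); fq2 <- eval_tab(f2, q$x)
    m1 <- sum(q$w * fq1); m2 <- sum(q$w * fq2)
    y1 <- sum(q$w * q$x * fq1); y2 <- sum(q$w * q$x * fq2)
    v1 <- sum(q$w * fq1^2) - m1^2; v2 <- sum(q$w * fq2^2) - m2^2
    if (delta_kernel) {
      Kg1 <- f1; Kg2 <- f2
      cross <- sum(q$w * fq1 * fq2)
    } else if (zero_kernel) {
      Kg1 <- rep(m1, length(xg)); Kg2 <- rep(m2, length(xg))
      cross <- m1 * m2
    } else {
      Kg1 <- as.vector(matrix(eval_tab(f1, as.vector(argg)),
                              nrow = length(xg)) %*% q$w)
      Kg2 <- as.vector(matrix(eval_tab(f2, as.vector(argg)),
                              nrow = length(xg)) %*% q$w)
      Kq2 <- as.vector(matrix(eval_tab(f2, as.vector(argq)),
                              nrow = length(q$x)) %*% q$w)
      cross <- sum(q$w * fq1 * Kq2)
    }
    A1 <- kappa * m1 + v1 + sd2
    A2 <- kappa * m2 + v2 + sd2
    B <- (cross - m1 * m2) + sd2 * rho_down
    det <- A1 * A2 - B^2
    D_new <- if (abs(det) > .Machine$double.eps^2) {
      c(A2 * y1 - B * y2, A1 * y2 - B * y1) / det
    } else D
    # nonlinearity updates use the current (old) weights, per the fixed-point
    # maps; guard against a transiently tiny weight
    Dsafe <- ifelse(abs(D) < 1e-8, sign(D + (D == 0)) * 1e-8, D)
    u1 <- xg / Dsafe[1L] - kappa / 2 + m1 + (Dsafe[2L] / Dsafe[1L]) * (m2 - Kg2)
    u2 <- xg / Dsafe[2L] - kappa / 2 + m2 + (Dsafe[1L] / Dsafe[2L]) * (m1 - Kg1)
    f1_new <- pmin(1, pmax(0, u1))
    f2_new <- pmin(1, pmax(0, u2))
    if (ctl$relax < 1) {
      f1_new <- f1 + ctl$relax * (f1_new - f1)
      f2_new <- f2 + ctl$relax * (f2_new - f2)
      D_new <- D + ctl$relax * (D_new - D)
    }
    delta <- max(abs(D_new - D), abs(f1_new - f1), abs(f2_new - f2))
    trace <- c(trace, delta)
    D <- D_new; f1 <- f1_new; f2 <- f2_new
    if (delta < ctl$tol) { converged <- TRUE; break }
    if (iter >= ctl$max_iter) break
  }

  # consistent final weights and readout term for the converged shapes
  fq1 <- eval_tab(f1, q$x); fq2 <- eval_tab(f2, q$x)
  m1 <- sum(q$w * fq1); m2 <- sum(q$w * fq2)
  y1 <- sum(q$w * q$x * fq1); y2 <- sum(q$w * q$x * fq2)
  v1 <- sum(q$w * fq1^2) - m1^2; v2 <- sum(q$w * fq2^2) - m2^2
  cross <- if (delta_kernel) sum(q$w * fq1 * fq2)
           else if (zero_kernel) m1 * m2
           else {
             Kq2 <- as.vector(matrix(eval_tab(f2, as.vector(argq)),
                                     nrow = length(q$x)) %*% q$w)
             sum(q$w * fq1 * Kq2)
           }
  A1 <- kappa * m1 + v1 + sd2; A2 <- kappa * m2 + v2 + sd2
  B <- (cross - m1 * m2) + sd2 * rho_down
  det <- A1 * A2 - B^2
  Dfin <- if (abs(det) > .Machine$double.eps^2)
    c(A2 * y1 - B * y2, A1 * y2 - B * y1) / det else D
  list(x = xg, f1 = f1, f2 = f2, D = Dfin,
       means = c(m1, m2), y_f = c(y1, y2),
       readout_term = Dfin[1L] * y1 + Dfin[2L] * y2,
       rho_eff = rho_eff, kappa = kappa, sigma_down = sigma_down,
       rho_down = rho_down,
       n_iterations = iter, converged = converged,
       change_trace = trace, ctl = ctl)
}

finish_dual <- function(fit, p, seed) {
  sz <- input_scale(p)
  c_eff <- p$sigma_s^2 / sz^2
  sol <- structure(list(
    f1 = tabulated_nonlinearity(fit$x, fit$f1),
    f2 = tabulated_nonlinearity(fit$x, fit$f2),
    D1 = fit$D[1L], D2 = fit$D[2L],
    D_raw = structure(list(D = p$sigma_s^2 * fit$D / sz,
                           D0 = -sum(p$sigma_s^2 * fit$D / sz * fit$means),
                           degenerate = FALSE), class = "decoding_weights"),
    readout_term = fit$readout_term,
    mse = p$sigma_s^2 * (1 - c_eff * fit$readout_term),
    rho_eff = fit$rho_eff,
    n_iterations = fit$n_iterations, converged = fit$converged,
    change_trace = fit$change_trace, seed = as.integer(seed),
    params = p, control = fit$ctl), class = "dual_solution")
  sol$strategy <- classify_solution(sol)
  sol
}

#' Classify a converged pair of nonlinearities
#'
#' The polarity class follows the signs of the decoding weights: opposite
#' signs give an ON-OFF (or OFF-ON) pair, equal signs an ON-ON (or OFF-OFF)
#' pair.  Same-sign pairs are subclassified as identical
#' (`sup-norm(f1 - f2) < tol` on the rescaled grid) or split.  For ON-OFF
#' pairs the anti-symmetry defect `sup-norm(f1(x) - f2(-x))` is attached as
#' attribute `"antisymmetry"`.
#'
#' @param sol A `dual_solution`.
#' @param tol Sup-norm tolerance for the identical/split subclassification.
#' @return One of `"ON_OFF"`, `"OFF_ON"`, `"ON_ON_identical"`,
#'   `"ON_ON_split"`, `"OFF_OFF"`.
#' @export
classify_solution <- function(sol, tol = 1e-2) {
  s1 <- sign(sol$D1); s2 <- sign(sol$D2)
  v1 <- sol$f1$f; v2 <- sol$f2$f
  if (s1 != s2) {
    lab <- if (s1 > 0) "ON_OFF" else "OFF_ON"
    out <- lab
    attr(out, "antisymmetry") <- max(abs(v1 - rev(v2)))
    return(out)
  }
  if (s1 < 0) return("OFF_OFF")
  if (max(abs(v1 - v2)) < tol) "ON_ON_identical" else "ON_ON_split"
}

#' Independent residual check of a converged fixed point
#'
#' Re-evaluates the optimality conditions for a converged solution with a
#' quadrature rule of a different (higher) order than the one used during
#' iteration, and reports the largest violation: the weight-equation defect
#' and the sup-norm difference between each nonlinearity and its variational
#' update.
#'
#' @param sol A `dual_solution`.
#' @param n_quad Quadrature order for the check (different from the solver's).
#' @return Largest absolute residual (numeric scalar).
#' @export
solution_residual <- function(sol, n_quad = 400L) {
  p <- sol$params
  ctl <- sol$control
  q <- normal_quad(n_quad, ctl$xmax)
  rho <- sol$rho_eff
  sd2 <- p$sigma_down^2
  xg <- sol$f1$x
  ev <- function(f, at) predict(f, at)
  fq1 <- ev(sol$f1, q$x); fq2 <- ev(sol$f2, q$x)
  m1 <- sum(q$w * fq1); m2 <- sum(q$w * fq2)
  y1 <- sum(q$w * q$x * fq1); y2 <- sum(q$w * q$x * fq2)
  v1 <- sum(q$w * fq1^2) - m1^2; v2 <- sum(q$w * fq2^2) - m2^2
  cross <- cross_expectation(sol$f1, sol$f2, rho, n_quad)
  A1 <- p$kappa * m1 + v1 + sd2; A2 <- p$kappa * m2 + v2 + sd2
  B <- (cross - m1 * m2) + sd2 * p$rho_down
  rw <- c(sol$D1 * A1 + sol$D2 * B - y1,
          sol$D2 * A2 + sol$D1 * B - y2)
  kern <- function(f, at) {
    if (abs(abs(rho) - 1) < 1e-12) return(ev(f, sign(rho) * at))
    if (abs(rho) < 1e-12) return(rep(sum(q$w * ev(f, q$x)), length(at)))
    arg <- outer(rho * at, sqrt(1 - rho^2) * q$x, "+")
    as.vector(matrix(ev(f, as.vector(arg)), nrow = length(at)) %*% q$w)
  }
  u1 <- xg / sol$D1 - p$kappa / 2 + m1 + (sol$D2 / sol$D1) * (m2 - kern(sol$f2, xg))
  u2 <- xg / sol$D2 - p$kappa / 2 + m2 + (sol$D1 / sol$D2) * (m1 - kern(sol$f1, xg))
  rf <- c(max(abs(sol$f1$f - pmin(1, pmax(0, u1)))),
          max(abs(sol$f2$f - pmin(1, pmax(0, u2)))))
  max(abs(c(rw, rf)))
}

#' Best solution per strategy class over multiple random initializations
#'
#' Runs [picard_solve()] for `n_seeds` random initializations of each
#' requested class and returns the lowest-MSE converged solution for every
#' strategy label encountered, together with a dispersion report (the
#' maximum pairwise sup-norm distance among solutions that converged to the
#' same label).
#'
#' @param p A two-pathway `circuit_params` object.
#' @param n_seeds Number of random initializations per class.
#' @param init_classes Which initialization classes to run.
#' @param seed Base seed; run `i` of class `k` uses `seed + (i - 1)` offset
#'   by a fixed stride per class.
#' @param control Passed to [picard_solve()].
#' @return An object of class `dual_ensemble`: `best` (named list of
#'   `dual_solution` by strategy label), `dispersion` (named numeric),
#'   `n_converged`, `n_failed`.
#' @export
multi_seed_solve <- function(p, n_seeds = 20L,
                             init_classes = c("on_off", "on_on"),
                             seed = 1L, control = list()) {
  stopifnot(n_seeds >= 1L)
  sols <- list()
  n_failed <- 0L
  for (k in seq_along(init_classes)) {
    for (i in seq_len(n_seeds)) {
      s <- picard_solve(p, init_classes[k],
                        seed = seed + (i - 1L) + (k - 1L) * 1000L,
                        control = control)
      if (!s$converged) {
        # plain Picard can enter a period-2 cycle in stiff corners
        # (rho_eff near 1); retry once with a damped update
        relax0 <- if (is.null(control$relax)) 1 else control$relax
        s <- picard_solve(p, init_classes[k],
                          seed = seed + (i - 1L) + (k - 1L) * 1000L,
                          control = modifyList(control,
                                               list(relax = relax0 / 2)))
      }
      if (s$converged) sols[[length(sols) + 1L]] <- s
      else n_failed <- n_failed + 1L
    }
  }
  if (!length(sols))
    stop("no initialization converged; inspect picard_solve() change traces",
         call. = FALSE)
  labels <- vapply(sols, function(s) as.character(s$strategy), character(1))
  best <- list(); disp <- numeric(0)
  for (lab in unique(labels)) {
    grp <- sols[labels == lab]
    ms <- vapply(grp, function(s) s$mse, numeric(1))
    best[[lab]] <- grp[[which.min(ms)]]
    dmax <- 0
    if (length(grp) > 1L) {
      for (a in seq_len(length(grp) - 1L)) for (b in (a + 1L):length(grp)) {
        dmax <- max(dmax,
                    max(abs(grp[[a]]$f1$f - grp[[b]]$f1$f)),
                    max(abs(grp[[a]]$f2$f - grp[[b]]$f2$f)))
      }
    }
    disp[lab] <- dmax
  }
  structure(list(best = best, dispersion = disp,
                 n_converged = length(sols), n_failed = n_failed,
                 params = p), class = "dual_ensemble")
}

#' @export
print.dual_ensemble <- function(x, ...) {
  cat(sprintf("Two-pathway solutions (%d converged, %d failed)\n",
              x$n_converged, x$n_failed))
  for (lab in names(x$best)) {
    cat(sprintf("  %-16s MSE = %.6g  (dispersion %.2e)\n", lab,
                x$best[[lab]]$mse, x$dispersion[lab]))
  }
  invisible(x)
}

#' @export
print.dual_solution <- function(x, ...) {
  cat("Two-pathway optimal nonlinearities (Picard fixed point)\n")
  cat(sprintf("  strategy: %s;  rho_eff = %.4g\n", x$strategy, x$rho_eff))
  cat(sprintf("  rescaled weights: D1 = %.5g, D2 = %.5g;  MSE = %.6g\n",
              x$D1, x$D2, x$mse))
  cat(sprintf("  %s in %d iterations (final change %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (length(x$change_trace)) utils::tail(x$change_trace, 1L)
              else NA_real_))
  invisible(x)
}

#' @export
coef.dual_solution <- function(object, ...) {
  c(D1 = object$D1, D2 = object$D2, mse = object$mse,
    rho_eff = object$rho_eff)
}

#' @export
predict.dual_solution <- function(object, z, pathway = 1L, rescaled = TRUE,
                                  ...) {
  f <- if (pathway == 1L) object$f1 else object$f2
  if (!rescaled) z <- z / input_scale(object$params)
  predict(f, z)
}

#' @export
plot.dual_solution <- function(x, ...) {
  xg <- x$f1$x
  graphics::plot(xg, x$f1$f, type = "l", ylim = c(0, 1),
                 xlab = "rescaled input x", ylab = "f", ...)
  graphics::lines(xg, x$f2$f, lty = 2)
  graphics::lines(xg, stats::dnorm(xg), lty = 3)
  graphics::legend("topleft", c("pathway 1", "pathway 2"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' @export
simulate.dual_solution <- function(object, nsim = 1, seed = NULL, n = 1e4,
                                   ...) {
  if (is.null(seed)) seed <- 1L
  sz <- input_scale(object$params)
  f_raw <- list(rescale_nonlinearity(object$f1, object$params, "to_raw"),
                rescale_nonlinearity(object$f2, object$params, "to_raw"))
  if (nsim == 1L)
    return(simulate_circuit(object$params, f_raw, n, seed))
  lapply(seq_len(nsim),
         function(i) simulate_circuit(object$params, f_raw, n, seed + i - 1L))
}

#' Serialize a dual solution
#'
#' Writes a JSON record (parameters, weights, MSE, strategy, convergence
#' diagnostics) plus two-column text tables of both nonlinearities next to
#' it (`<path>_f1.txt`, `<path>_f2.txt`).
#'
#' @param sol A `dual_solution`.
#' @param path Path of the JSON file (directory must exist).
#' @export
write_dual_solution <- function(sol, path) {
  rec <- list(params = unclass(sol$params), D1 = sol$D1, D2 = sol$D2,
              mse = sol$mse, readout_term = sol$readout_term,
              strategy = as.character(sol$strategy),
              rho_eff = sol$rho_eff, n_iterations = sol$n_iterations,
              converged = sol$converged, seed = sol$seed)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), path)
  base <- sub("\\.json$", "", path)
  write_nonlinearity(sol$f1, paste0(base, "_f1.txt"))
  write_nonlinearity(sol$f2, paste0(base, "_f2.txt"))
  invisible(path)
}
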