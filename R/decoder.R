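#' Optimal linear decoding weights
#'
#' The stimulus is decoded linearly from the responses,
#' \eqn{\hat s = D_0 + \sum_i D_i r_i}, and the mean squared error is
#' minimized over the weights.  For a single pathway
#' \deqn{D \,(\kappa \langle f \rangle + var[f] + \sigma_{down}^2)
#'       = \langle s f(s+\eta) \rangle,}
#' and for two pathways the analogous 2x2 linear system couples the pathways
#' through \eqn{cov[f_1, f_2] + \sigma_{down}^2 \rho_{down}}.  The optimal
#' offset is \eqn{D_0 = -\sum_i D_i \langle r_i \rangle}.
#'
#' @param p A `circuit_params` object.
#' @param f A `nonlinearity` (raw input coordinates), or a list of two for a
#'   two-pathway model.
#' @param n_quad Quadrature order.
#' @return An object of class `decoding_weights`: fields `D` (per-pathway
#'   weights), `D0`, and `degenerate` (`TRUE` when all channels are constant
#'   and the weights are set to 0).
#' @export
optimal_weights <- function(p, f, n_quad = 200L) {
  validate_circuit_params(p)
  sz <- input_scale(p)
  gain <- p$sigma_s^2 / sz               # <s f> = gain * <y f~>
  if (p$n_pathways == 1L) {
    f <- if (is.list(f) && !inherits(f, "nonlinearity")) f[[1L]] else f
    ft <- rescale_nonlinearity(f, p, "to_rescaled")
    e <- gaussian_expectations(ft, n_quad = n_quad)
    denom <- p$kappa * e$mean_f + (e$f_sq - e$mean_f^2) + p$sigma_down^2
    if (denom <= 1e-9) {   # below quadrature accuracy: constant channel
      return(structure(list(D = 0, D0 = 0, degenerate = TRUE),
                       class = "decoding_weights"))
    }
    D <- gain * e$y_f / denom
    return(structure(list(D = D, D0 = -D * e$mean_f, degenerate = FALSE),
                     class = "decoding_weights"))
  }
  stopifnot(is.list(f), length(f) == 2L)
  ft1 <- rescale_nonlinearity(f[[1L]], p, "to_rescaled")
  ft2 <- rescale_nonlinearity(f[[2L]], p, "to_rescaled")
  rho <- effective_correlation(p)
  e <- gaussian_expectations(ft1, ft2, rho = rho, n_quad = n_quad)
  A1 <- p$kappa * e$mean_f + (e$f_sq - e$mean_f^2) + p$sigma_down^2
  A2 <- p$kappa * e$mean_f2 + (e$f_sq2 - e$mean_f2^2) + p$sigma_down^2
  B <- (e$cross - e$mean_f * e$mean_f2) + p$sigma_down^2 * p$rho_down
  det <- A1 * A2 - B^2
  if (abs(det) <= 1e-15 || (A1 <= 1e-9 && A2 <= 1e-9)) {
    return(structure(list(D = c(0, 0), D0 = 0, degenerate = TRUE),
                     class = "decoding_weights"))
  }
  b1 <- gain * e$y_f; b2 <- gain * e$y_f2
  D <- c(A2 * b1 - B * b2, A1 * b2 - B * b1) / det
  structure(list(D = D, D0 = -sum(D * c(e$mean_f, e$mean_f2)),
                 degenerate = FALSE),
            class = "decoding_weights")
}

#' @export
print.decoding_weights <- function(x, ...) {
  cat("Optimal linear decoding weights\n")
  cat("  D  =", paste(signif(x$D, 6), collapse = ", "), "\n")
  cat("  D0 =", signif(x$D0, 6), "\n")
  if (x$degenerate) cat("  (degenerate: all channels constant)\n")
  invisible(x)
}

#' Mean squared error of the linear readout
#'
#' Computes \eqn{\chi^2 = \langle (s - \hat s)^2 \rangle} either in closed
#' form, via Gaussian-expectation quadrature of
#' \deqn{\chi^2 = \sigma_s^2 - 2\sum_i D_i \langle s f_i \rangle +
#'   \sum_i D_i^2 (\kappa \langle f_i \rangle + var[f_i] + \sigma_{down}^2) +
#'   2 D_1 D_2 (cov[f_1, f_2] + \sigma_{down}^2 \rho_{down}),}
#' or by Monte Carlo simulation of the full encoding model.  At the optimal
#' weights the closed form reduces to
#' \eqn{\chi^2 = \sigma_s^2 (1 - \frac{\sigma_s^2}{\sigma_s^2+\sigma_{up}^2}
#' \sum_i \tilde D_i \langle y \tilde f_i \rangle)}.
#'
#' @param p A `circuit_params` object.
#' @param f A `nonlinearity` or list of two (raw coordinates).
#' @param D Optional `decoding_weights` (or bare numeric vector); the optimal
#'   weights are used when omitted.
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param n,reps Monte Carlo draw count and number of repetitions averaged.
#' @param seed Seed for the Monte Carlo method.
#' @param n_quad Quadrature order for the closed form.
#' @return The MSE (numeric scalar).  For the Monte Carlo method the standard
#'   error across repetitions is attached as attribute `"se"`.
#' @export
mse <- function(p, f, D = NULL, method = c("closed_form", "monte_carlo"),
                n = 1e7, reps = 5, seed = 1, n_quad = 200L) {
  validate_circuit_params(p)
  method <- match.arg(method)
  flist <- if (inherits(f, "nonlinearity")) list(f) else f
  stopifnot(length(flist) == p$n_pathways)
  if (is.null(D)) D <- optimal_weights(p, f, n_quad = n_quad)
  Dvec <- if (inherits(D, "decoding_weights")) D$D else as.numeric(D)

  if (method == "monte_carlo") {
    vals <- vapply(seq_len(reps), function(i) {
      d <- simulate_circuit(p, f, n = n, seed = seed + i - 1L)
      r <- as.matrix(d[, grep("^r_", names(d)), drop = FALSE])
      rc <- sweep(r, 2L, colMeans(r))
      mean((d$s - as.vector(rc %*% Dvec))^2)
    }, numeric(1))
    out <- mean(vals)
    attr(out, "se") <- if (reps > 1) stats::sd(vals) / sqrt(reps) else NA_real_
    return(out)
  }

  sz <- input_scale(p)
  gain <- p$sigma_s^2 / sz
  if (p$n_pathways == 1L) {
    ft <- rescale_nonlinearity(flist[[1L]], p, "to_rescaled")
    e <- gaussian_expectations(ft, n_quad = n_quad)
    A <- p$kappa * e$mean_f + (e$f_sq - e$mean_f^2) + p$sigma_down^2
    return(p$sigma_s^2 - 2 * Dvec * gain * e$y_f + Dvec^2 * A)
  }
  ft1 <- rescale_nonlinearity(flist[[1L]], p, "to_rescaled")
  ft2 <- rescale_nonlinearity(flist[[2L]], p, "to_rescaled")
  e <- gaussian_expectations(ft1, ft2, rho = effective_correlation(p),
                             n_quad = n_quad)
  A1 <- p$kappa * e$mean_f + (e$f_sq - e$mean_f^2) + p$sigma_down^2
  A2 <- p$kappa * e$mean_f2 + (e$f_sq2 - e$mean_f2^2) + p$sigma_down^2
  B <- (e$cross - e$mean_f * e$mean_f2) + p$sigma_down^2 * p$rho_down
  p$sigma_s^2 - 2 * Dvec[1L] * gain * e$y_f - 2 * Dvec[2L] * gain * e$y_f2 +
    Dvec[1L]^2 * A1 + Dvec[2L]^2 * A2 + 2 * Dvec[1L] * Dvec[2L] * B
}

#' Signal-to-noise ratio of a single pathway
#'
#' \deqn{SNR = \frac{var_s[E[r|s]]}{E_s[var[r|s]]}.}
#' In terms of rescaled expectations, the numerator is
#' \eqn{\langle \tilde f(y_1) \tilde f(y_2) \rangle_\rho - \langle \tilde f
#' \rangle^2} and the denominator
#' \eqn{\langle \tilde f^2 \rangle - \langle \tilde f(y_1) \tilde f(y_2)
#' \rangle_\rho + \kappa \langle \tilde f \rangle + \sigma_{down}^2}, where
#' the cross term is evaluated at \eqn{\rho = \sigma_s^2 / (\sigma_s^2 +
#' \sigma_{up}^2)} (averaging over the upstream noise at fixed stimulus
#' introduces two conditionally independent noise draws; the term is not an
#' actual covariance).
#'
#' @param p A single-pathway `circuit_params` object.
#' @param f A `nonlinearity` (raw coordinates).
#' @param n_quad Quadrature order.
#' @return The SNR; `Inf` with a warning if the denominator vanishes.
#' @export
snr <- function(p, f, n_quad = 200L) {
  validate_circuit_params(p)
  if (p$n_pathways != 1L)
    stop("snr() is defined for a single pathway", call. = FALSE)
  ft <- rescale_nonlinearity(f, p, "to_rescaled")
  rho <- p$sigma_s^2 / (p$sigma_s^2 + p$sigma_up^2)
  e <- gaussian_expectations(ft, ft, rho = rho, n_quad = n_quad)
  num <- e$cross - e$mean_f^2
  den <- e$f_sq - e$cross + p$kappa * e$mean_f + p$sigma_down^2
  if (den <= .Machine$double.eps) {
    warning("zero conditional response variance: SNR is infinite")
    return(Inf)
  }
  num / den
}
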