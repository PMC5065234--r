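#' Circuit parameters for the noisy encoding model
#'
#' Parameterises a one- or two-pathway encoder in which a Gaussian stimulus
#' \eqn{s \sim N(0, \sigma_s^2)} is corrupted by additive Gaussian upstream
#' noise \eqn{\eta} (variance \eqn{\sigma_{up}^2}, correlation \eqn{\rho_{up}}
#' across pathways), passed through a bounded nonlinearity \eqn{f \in [0,1]}
#' that sets the mean of a stochastic response stage, and finally corrupted by
#' additive Gaussian downstream noise \eqn{\zeta} (variance
#' \eqn{\sigma_{down}^2}, correlation \eqn{\rho_{down}}).  The response stage
#' is by default scaled-Poisson: the response is \eqn{\kappa m} with
#' \eqn{m \sim Pois(f/\kappa)}, so its conditional mean is \eqn{f} and its
#' conditional variance \eqn{\kappa f}.
#'
#' @param sigma_s Stimulus standard deviation (> 0).
#' @param sigma_up Upstream noise standard deviation (>= 0).
#' @param kappa Scaled-Poisson quantal size (>= 0); `kappa = 0` makes the
#'   response stage deterministic.
#' @param sigma_down Downstream noise standard deviation (>= 0).
#' @param rho_up Upstream noise correlation across pathways, in \[-1, 1\].
#' @param rho_down Downstream noise correlation across pathways, in \[-1, 1\].
#' @param n_pathways 1 or 2.
#' @param poisson_variant Distribution of the stochastic response stage:
#'   `"scaled_poisson"` (default), `"multiplicative_gaussian"` (zero-mean
#'   Gaussian with variance `kappa * f` added to `f`), or `"binomial"`
#'   (`Binomial(binomial_n, f) / binomial_n`).
#' @param binomial_n Number of events for the binomial variant.
#'
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params(sigma_up = 2, rho_up = 0.0625, n_pathways = 2)
#' effective_correlation(p)  # 0.25
#' @export
circuit_params <- function(sigma_s = 1, sigma_up = 0, kappa = 0,
                           sigma_down = 0, rho_up = 0, rho_down = 0,
                           n_pathways = 1,
                           poisson_variant = c("scaled_poisson",
                                               "multiplicative_gaussian",
                                               "binomial"),
                           binomial_n = 10L) {
  poisson_variant <- match.arg(poisson_variant)
  p <- structure(list(sigma_s = sigma_s, sigma_up = sigma_up, kappa = kappa,
                      sigma_down = sigma_down, rho_up = rho_up,
                      rho_down = rho_down, n_pathways = as.integer(n_pathways),
                      poisson_variant = poisson_variant,
                      binomial_n = as.integer(binomial_n)),
                 class = "circuit_params")
  validate_circuit_params(p)
}

#' @rdname circuit_params
#' @param p A `circuit_params` object (or a bare list with the same fields).
#' @export
validate_circuit_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$sigma_s) && p$sigma_s > 0, "sigma_s", "must be a single value > 0")
  chk(num1(p$sigma_up) && p$sigma_up >= 0, "sigma_up", "must be >= 0")
  chk(num1(p$kappa) && p$kappa >= 0, "kappa", "must be >= 0")
  chk(num1(p$sigma_down) && p$sigma_down >= 0, "sigma_down", "must be >= 0")
  chk(num1(p$rho_up) && abs(p$rho_up) <= 1, "rho_up", "must lie in [-1, 1]")
  chk(num1(p$rho_down) && abs(p$rho_down) <= 1, "rho_down",
      "must lie in [-1, 1]")
  chk(p$n_pathways %in% c(1L, 2L), "n_pathways", "must be 1 or 2")
  chk(p$poisson_variant %in% c("scaled_poisson", "multiplicative_gaussian",
                               "binomial"),
      "poisson_variant", "unknown variant")
  if (p$poisson_variant == "binomial")
    chk(num1(p$binomial_n) && p$binomial_n >= 1, "binomial_n",
        "must be a positive integer")
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("Circuit parameters (%d pathway%s, %s stage)\n", x$n_pathways,
              if (x$n_pathways > 1L) "s" else "", x$poisson_variant))
  cat(sprintf("  sigma_s = %g, sigma_up = %g, kappa = %g, sigma_down = %g\n",
              x$sigma_s, x$sigma_up, x$kappa, x$sigma_down))
  if (x$n_pathways == 2L) {
    cat(sprintf("  rho_up = %g, rho_down = %g  (rho_eff = %.4g)\n",
                x$rho_up, x$rho_down, effective_correlation(x)))
  }
  invisible(x)
}

#' Effective correlation of the total inputs across two pathways
#'
#' The total inputs \eqn{s + \eta_1} and \eqn{s + \eta_2} to the two
#' nonlinearities share the stimulus but have (possibly correlated) private
#' noise; their correlation coefficient is
#' \deqn{\rho_{eff} = \frac{\sigma_s^2 + \sigma_{up}^2 \rho_{up}}
#'                         {\sigma_s^2 + \sigma_{up}^2}.}
#' After rescaling inputs by their standard deviation
#' \eqn{\sqrt{\sigma_s^2 + \sigma_{up}^2}}, the optimal nonlinearities depend
#' on the stimulus and upstream-noise parameters only through this quantity.
#'
#' @param p A two-pathway `circuit_params` object.
#' @return The effective input correlation, in \[-1, 1\].
#' @export
effective_correlation <- function(p) {
  validate_circuit_params(p)
  if (p$n_pathways != 2L)
    stop("effective_correlation() requires a two-pathway model", call. = FALSE)
  (p$sigma_s^2 + p$sigma_up^2 * p$rho_up) / (p$sigma_s^2 + p$sigma_up^2)
}

#' Upstream correlation realizing a target effective correlation
#'
#' Inverts [effective_correlation()]: given `rho_eff` and fixed `sigma_s`,
#' `sigma_up`, returns the `rho_up` for which the total inputs have the
#' requested correlation.  Requires `sigma_up^2 >= sigma_s^2 *
#' (1 - rho_eff) / (1 + rho_eff)` so the result is a valid correlation
#' (e.g. `rho_eff = 0` needs upstream noise variance at least the stimulus
#' variance).
#'
#' @param rho_eff Target effective input correlation.
#' @param sigma_s,sigma_up Stimulus and upstream noise standard deviations.
#' @return The required `rho_up`.
#' @export
rho_up_for_effective <- function(rho_eff, sigma_s = 1, sigma_up = 2) {
  if (sigma_up == 0) {
    if (abs(rho_eff - 1) > 1e-12)
      stop("with sigma_up = 0 only rho_eff = 1 is realizable", call. = FALSE)
    return(0)
  }
  rho_up <- (rho_eff * (sigma_s^2 + sigma_up^2) - sigma_s^2) / sigma_up^2
  if (abs(rho_up) > 1 + 1e-12)
    stop(sprintf(
      "rho_eff = %g not realizable at sigma_s = %g, sigma_up = %g (rho_up = %g)",
      rho_eff, sigma_s, sigma_up, rho_up), call. = FALSE)
  min(1, max(-1, rho_up))
}

# total input sd sqrt(sigma_s^2 + sigma_up^2)
input_scale <- function(p) sqrt(p$sigma_s^2 + p$sigma_up^2)

#' Serialize circuit parameters
#'
#' `params_to_json()` writes a flat JSON mapping with the constructor field
#' names; `params_from_json()` and `params_from_yaml()` read one back (YAML
#' files with the same flat mapping are accepted).
#'
#' @param p A `circuit_params` object.
#' @param path File path; for `params_to_json()`, `NULL` returns the JSON
#'   string instead of writing.
#' @return `params_to_json()`: the path (or JSON string) invisibly; the
#'   readers return a `circuit_params` object.
#' @export
params_to_json <- function(p, path = NULL) {
  validate_circuit_params(p)
  txt <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  as_circuit_params(jsonlite::fromJSON(path))
}

#' @rdname params_to_json
#' @export
params_from_yaml <- function(path) {
  as_circuit_params(yaml::read_yaml(path))
}

#' @rdname params_to_json
#' @param x A list of parameter fields (unknown fields rejected).
#' @export
as_circuit_params <- function(x) {
  if (inherits(x, "circuit_params")) return(validate_circuit_params(x))
  known <- names(formals(circuit_params))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(circuit_params, x)
}
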