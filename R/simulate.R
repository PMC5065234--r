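#' Simulate draws from the noisy encoding model
#'
#' Generates `n` Monte Carlo draws of stimulus, noises, and responses.  The
#' draw order is fixed and documented for reproducibility: stimulus `s`,
#' then upstream noise per pathway (jointly for two pathways), then the
#' stochastic response stage per pathway, then downstream noise.  The total
#' response is `r = stage + zeta`.
#'
#' Response-stage variants (conditional on total input `z`, with `fz = f(z)`):
#' * `scaled_poisson`: `kappa * rpois(n, fz / kappa)` — mean `fz`, variance
#'   `kappa * fz`; deterministic (`fz` exactly) when `kappa = 0`.
#' * `multiplicative_gaussian`: `fz + rnorm(n, 0, sqrt(kappa * fz))` — same
#'   conditional mean and variance as the scaled-Poisson stage at matched
#'   strength; not clipped to \[0, 1\].
#' * `binomial`: `rbinom(n, N, fz) / N` — mean `fz`, variance
#'   `fz * (1 - fz) / N`, with `N = binomial_n`.
#'
#' @param p A `circuit_params` object.
#' @param f A `nonlinearity`, or a list of two for a two-pathway model.
#' @param n Number of draws.
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   draw set bit-for-bit.
#' @return A `data.frame` of class `draw_set` with columns `s`,
#'   `eta_<i>`, `stage_<i>`, `zeta_<i>`, `r_<i>`, and attributes `params`
#'   and `seed`.
#' @examples
#' p <- circuit_params(kappa = 0.25, sigma_down = 0.1)
#' d <- simulate_circuit(p, piecewise_nonlinearity(-1, 1), n = 1000, seed = 1)
#' colMeans(d)
#' @export
simulate_circuit <- function(p, f, n, seed = 1L) {
  validate_circuit_params(p)
  stopifnot(n >= 1)
  flist <- if (inherits(f, "nonlinearity")) list(f) else f
  stopifnot(length(flist) == p$n_pathways)
  set.seed(seed)
  np <- p$n_pathways
  s <- stats::rnorm(n, 0, p$sigma_s)
  eta <- correlated_gaussians(n, np, p$sigma_up, p$rho_up)
  stage <- matrix(0, n, np)
  for (i in seq_len(np)) {
    stage[, i] <- stage_draw(p, predict(flist[[i]], s + eta[, i]))
  }
  zeta <- correlated_gaussians(n, np, p$sigma_down, p$rho_down)
  r <- stage + zeta
  out <- data.frame(s = s)
  for (i in seq_len(np)) out[[paste0("eta_", i)]] <- eta[, i]
  for (i in seq_len(np)) out[[paste0("stage_", i)]] <- stage[, i]
  for (i in seq_len(np)) out[[paste0("zeta_", i)]] <- zeta[, i]
  for (i in seq_len(np)) out[[paste0("r_", i)]] <- r[, i]
  structure(out, params = p, seed = as.integer(seed),
            class = c("draw_set", "data.frame"))
}

# n x k matrix of zero-mean Gaussians with common sd and pairwise correlation
correlated_gaussians <- function(n, k, sd, rho) {
  if (sd == 0) return(matrix(0, n, k))
  if (k == 1L) return(matrix(stats::rnorm(n, 0, sd), n, 1L))
  z <- matrix(stats::rnorm(n * k), n, k)
  rho <- min(1, max(-1, rho))
  # Cholesky of [[1, rho], [rho, 1]]
  x2 <- rho * z[, 1L] + sqrt(max(0, 1 - rho^2)) * z[, 2L]
  cbind(z[, 1L], x2) * sd
}

# one stochastic-stage draw vector given the conditional means fz in [0, 1]
stage_draw <- function(p, fz) {
  n <- length(fz)
  switch(p$poisson_variant,
    scaled_poisson = {
      if (p$kappa == 0) fz
      else p$kappa * stats::rpois(n, fz / p$kappa)
    },
    multiplicative_gaussian = {
      if (p$kappa == 0) fz
      else fz + stats::rnorm(n, 0, sqrt(p$kappa * fz))
    },
    binomial = stats::rbinom(n, p$binomial_n, fz) / p$binomial_n)
}

#' Conditional response moments at fixed total input
#'
#' Mean and variance of the single-pathway response `r` given the total
#' input `z = s + eta`: the mean is `f(z)` for every variant; the variance is
#' `kappa * f(z) + sigma_down^2` (scaled-Poisson and multiplicative-Gaussian
#' stages) or `f(z)(1 - f(z)) / binomial_n + sigma_down^2` (binomial stage).
#'
#' @param p A single-pathway `circuit_params` object.
#' @param f A `nonlinearity`.
#' @param z Total input value(s).
#' @return A list with elements `mean` and `variance` (vectors over `z`).
#' @export
conditional_moments <- function(p, f, z) {
  validate_circuit_params(p)
  if (p$n_pathways != 1L)
    stop("conditional_moments() is defined for a single pathway",
         call. = FALSE)
  fz <- predict(f, z)
  v <- switch(p$poisson_variant,
    scaled_poisson = p$kappa * fz,
    multiplicative_gaussian = p$kappa * fz,
    binomial = fz * (1 - fz) / p$binomial_n)
  list(mean = fz, variance = v + p$sigma_down^2)
}

#' Export a draw set to CSV with a JSON sidecar
#'
#' Writes the draws as CSV and the generating parameters and seed as
#' `<path>.json`.
#'
#' @param d A `draw_set`.
#' @param path CSV file path.
#' @export
write_draws <- function(d, path) {
  stopifnot(inherits(d, "draw_set"))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  side <- list(params = unclass(attr(d, "params")), seed = attr(d, "seed"),
               n = nrow(d))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}
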