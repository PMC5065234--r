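# Differential entropy and mutual information estimators (bits throughout).

euler_gamma <- -digamma(1)

#' Binless (nearest-neighbour) differential entropy estimate
#'
#' Kozachenko-Leonenko style estimator from Euclidean nearest-neighbour
#' distances \eqn{\lambda_j}:
#' \deqn{H \approx \log_2\!\frac{S_d (M-1)}{d} + \frac{\gamma}{\ln 2} +
#'       \frac{d}{M} \sum_j \log_2 \lambda_j,}
#' where \eqn{d} is the dimensionality, \eqn{M} the sample count, \eqn{S_d}
#' the surface area of the unit \eqn{d}-sphere (\eqn{S_1 = 2},
#' \eqn{S_2 = 2\pi}), and \eqn{\gamma} the Euler-Mascheroni constant.
#' The estimator requires all samples to be distinct; duplicated samples
#' (exact floating-point equality) raise an error of class
#' `"effcoding_duplicate_samples"` recommending the binned estimator.
#'
#' @param samples Numeric vector (d = 1) or matrix with one row per sample.
#' @return An object of class `entropy_estimate`: `value` (bits),
#'   `estimator`, `d`, `n_samples`, `settings`.
#' @examples
#' set.seed(1)
#' entropy_binless(rnorm(2000))$value  # ~ 0.5 * log2(2 * pi * exp(1))
#' @export
entropy_binless <- function(samples) {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1L)
  M <- nrow(x); d <- ncol(x)
  if (M < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyDuplicated(x)) {
    stop(structure(class = c("effcoding_duplicate_samples", "error",
                             "condition"),
                   list(message = paste("duplicate samples: the binless",
                                        "estimator requires distinct points;",
                                        "use entropy_binned()"),
                        call = sys.call(-1L))))
  }
  nn <- RANN::nn2(x, k = 2L, searchtype = "standard", eps = 0)
  lambda <- nn$nn.dists[, 2L]
  S_d <- 2 * pi^(d / 2) / gamma(d / 2)
  H <- log2(S_d * (M - 1) / d) + euler_gamma / log(2) +
    (d / M) * sum(log2(lambda))
  structure(list(value = H, estimator = "binless", d = d, n_samples = M,
                 settings = list(neighbor_order = 1L)),
            class = "entropy_estimate")
}

#' Binned differential entropy estimate (1-D)
#'
#' Histogram estimate with the bin-width correction: with bin probabilities
#' \eqn{P_j} and common width \eqn{w},
#' \eqn{H \approx -\sum_j P_j \log_2 (P_j / w)}; empty bins contribute zero.
#'
#' @param samples Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @param range Bin span `c(lo, hi)`; default the data range.
#' @return An `entropy_estimate` (bits).
#' @export
entropy_binned <- function(samples, n_bins = 50L, range = NULL) {
  stopifnot(n_bins >= 2L)
  x <- as.numeric(samples)
  if (is.null(range)) range <- base::range(x)
  if (diff(range) <= 0) {
    # degenerate support: a differential entropy is not defined
    stop("all samples identical: differential entropy undefined for a ",
         "point mass", call. = FALSE)
  }
  br <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  w <- diff(range) / n_bins
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  P <- cnt / length(x)
  nz <- P > 0
  H <- -sum(P[nz] * log2(P[nz] / w))
  structure(list(value = H, estimator = "binned", d = 1L,
                 n_samples = length(x),
                 settings = list(n_bins = n_bins, bin_width = w,
                                 range = range)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Differential entropy: %.4f bits (%s, d = %d, n = %d)\n",
              x$value, x$estimator, x$d, x$n_samples))
  invisible(x)
}

#' Mutual information between stimulus and responses
#'
#' Estimates \eqn{MI(S; R) = H(R) - \langle H(R|S) \rangle_S} by Monte
#' Carlo: the response entropy from one response to each of `n_stimuli`
#' stimulus draws, and the conditional (noise) entropy by averaging the
#' entropy of `n_repeats` repeated responses to each of `n_cond` fixed
#' stimuli.  The whole procedure is repeated `n_reps` times and averaged.
#'
#' The estimator is chosen automatically: binless (nearest-neighbour) in
#' general, falling back to the binned estimator when responses are
#' effectively discretized (nonzero `kappa` with very small downstream
#' noise makes many responses exactly equal).  The binned estimator is 1-D,
#' so the fallback applies per-pathway plus, for two pathways, nothing
#' further (two-pathway MI uses the binless estimator; supply enough
#' downstream noise to keep responses continuous).
#'
#' @param p A `circuit_params` object.
#' @param f A `nonlinearity` or list of two (raw coordinates).
#' @param n_stimuli Stimulus draws for the response entropy.
#' @param n_repeats Response draws per conditioning stimulus.
#' @param n_cond Number of conditioning stimuli for the noise entropy.
#' @param n_reps Independent repetitions averaged.
#' @param seed Base seed.
#' @param estimator `"auto"`, `"binless"`, or `"binned"`.
#' @param n_bins Bins for the binned estimator.
#' @return MI in bits, with attributes `"se"` (repetition standard error)
#'   and `"estimator"`.
#' @export
mutual_information <- function(p, f, n_stimuli = 1e4, n_repeats = 1e4,
                               n_cond = 50L, n_reps = 10L, seed = 1L,
                               estimator = c("auto", "binless", "binned"),
                               n_bins = 50L) {
  validate_circuit_params(p)
  estimator <- match.arg(estimator)
  flist <- if (inherits(f, "nonlinearity")) list(f) else f
  stopifnot(length(flist) == p$n_pathways)
  discretized <- p$kappa > 0 && p$sigma_down < 1e-6
  if (estimator == "auto")
    estimator <- if (discretized && p$n_pathways == 1L) "binned" else "binless"

  # binned entropies share one data-driven bin range (marginal response
  # range padded by 3 sigma_down) so marginal and conditional terms are
  # measured with a common bin width
  est_H <- function(R, range = NULL) {
    if (estimator == "binned") {
      if (NCOL(R) > 1L)
        stop("binned estimator is 1-D; two-pathway responses need the ",
             "binless estimator", call. = FALSE)
      return(entropy_binned(as.numeric(R), n_bins = n_bins,
                            range = range)$value)
    }
    tryCatch(entropy_binless(R)$value,
             effcoding_duplicate_samples = function(e) {
               if (NCOL(R) > 1L) stop(e)
               entropy_binned(as.numeric(R), n_bins = n_bins,
                              range = range)$value
             })
  }

  vals <- vapply(seq_len(n_reps), function(rep) {
    sd_rep <- seed + (rep - 1L) * 7919L
    d <- simulate_circuit(p, flist, n = n_stimuli, seed = sd_rep)
    R <- as.matrix(d[, grep("^r_", names(d)), drop = FALSE])
    shared_range <- range(R[, 1L]) + c(-3, 3) * p$sigma_down
    if (diff(shared_range) <= 0) shared_range <- NULL
    HR <- est_H(if (p$n_pathways == 1L) R[, 1L] else R, shared_range)
    set.seed(sd_rep + 1L)
    s_cond <- stats::rnorm(n_cond, 0, p$sigma_s)
    Hc <- vapply(seq_len(n_cond), function(i) {
      pc <- p
      pc$sigma_s <- 1e-12        # pin the stimulus: conditional responses
      dcond <- simulate_circuit(pc, lapply(flist, shift_input, s_cond[i]),
                                n = n_repeats, seed = sd_rep + 1L + i)
      Rc <- as.matrix(dcond[, grep("^r_", names(dcond)), drop = FALSE])
      est_H(if (p$n_pathways == 1L) Rc[, 1L] else Rc, shared_range)
    }, numeric(1))
    HR - mean(Hc)
  }, numeric(1))
  out <- mean(vals)
  attr(out, "se") <- if (n_reps > 1) stats::sd(vals) / sqrt(n_reps) else NA_real_
  attr(out, "estimator") <- estimator
  out
}

# nonlinearity evaluated at (z + s0): freezes the stimulus at s0 while the
# simulator keeps drawing the noise
shift_input <- function(f, s0) {
  structure(list(base = f, s0 = s0),
            class = c("nl_shifted", "nonlinearity"))
}

#' @export
predict.nl_shifted <- function(object, z, ...) {
  predict(object$base, z + object$s0)
}
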