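#' Fit the optimal encoder for a parameter set
#'
#' Umbrella fitting function: dispatches to the exact single-pathway solver
#' ([solve_single()]) or the multi-seed Picard solver for a pair of pathways
#' ([multi_seed_solve()]), returning the classed solution object.
#'
#' @param p A `circuit_params` object.
#' @param ... Passed on to the underlying solver.
#' @return A `single_solution` or `dual_ensemble`.
#' @examples
#' optimal_encoder(circuit_params(sigma_up = 0.5, sigma_down = 0.1))
#' @export
optimal_encoder <- function(p, ...) {
  validate_circuit_params(p)
  if (p$n_pathways == 1L) solve_single(p, ...) else multi_seed_solve(p, ...)
}

#' Named noise-regime parameter presets
#'
#' Named parameter presets used throughout the worked examples: for a
#' single pathway, one column per noise level (SNR 5, 1, 0.1) with one
#' dominant noise source per row group; a smaller set contrasting optimal
#' and suboptimal shapes; and the two-pathway sets (low/high noise per
#' dominant source).  `sigma_s = 1` throughout.
#'
#' @param which `"single"` (3 sources x 3 noise levels),
#'   `"single_contrast"` (3 sources, one level), or `"dual"` (3 sources x
#'   low/high noise, two pathways).
#' @return A data.frame of parameter sets, one row each, with a `label`
#'   column.
#' @export
noise_regime_presets <- function(which = c("single", "single_contrast",
                                           "dual")) {
  which <- match.arg(which)
  if (which == "single") {
    d <- expand.grid(source = c("upstream", "poisson", "downstream"),
                     level = c("low", "medium", "high"),
                     stringsAsFactors = FALSE)
    d$snr_nominal <- rep(c(5, 1, 0.1), each = 3)
    d$sigma_up <- c(0.375, 0.05, 0.05, 0.92, 0.05, 0.05, 3.1, 0.05, 0.05)
    d$kappa <- c(1e-3, 0.0395, 1e-3, 1e-3, 0.5, 1e-3, 1e-3, 6.6, 1e-3)
    d$sigma_down <- c(0.05, 0.05, 0.135, 0.05, 0.05, 0.4175,
                      0.05, 0.05, 1.54)
  } else if (which == "single_contrast") {
    d <- data.frame(source = c("upstream", "poisson", "downstream"),
                    sigma_up = c(0.8, 0, 0.05),
                    kappa = c(0, 0.2, 0),
                    sigma_down = c(0.005, 0.005, 0.3),
                    stringsAsFactors = FALSE)
  } else {
    d <- expand.grid(source = c("upstream", "poisson", "downstream"),
                     level = c("low", "high"), stringsAsFactors = FALSE)
    d$sigma_up <- c(0.85, 0.25, 0.25, 0.85, 0.25, 0.25)
    d$rho_up <- c(0.9762, -0.7, -0.7, -0.9073, -0.7, -0.7)
    d$kappa <- c(0.1, 0.25, 0.1, 0.1, 0.9, 0.1)
    d$sigma_down <- c(0.1, 0.1, 0.25, 0.1, 0.1, 0.9)
    d$rho_down <- 0
  }
  d$sigma_s <- 1
  d$label <- if ("level" %in% names(d))
    paste(d$source, d$level, sep = "_") else d$source
  d
}

preset_params <- function(row, n_pathways = 1L) {
  circuit_params(sigma_s = row$sigma_s, sigma_up = row$sigma_up,
                 kappa = row$kappa, sigma_down = row$sigma_down,
                 rho_up = if ("rho_up" %in% names(row)) row$rho_up else 0,
                 rho_down = if ("rho_down" %in% names(row)) row$rho_down
                            else 0,
                 n_pathways = n_pathways)
}

#' Run a configured task
#'
#' Dispatches one of the package workflows from a configuration list or a
#' YAML/JSON file and (optionally) writes its outputs.  Recognized fields:
#' `task` (one of `"solve_single"`, `"solve_dual"`, `"sweep"`,
#' `"phase_map"`, `"simulate"`, `"mi"`, `"fixtures"`), `params` (a mapping
#' of [circuit_params()] fields), `seed`, `out` (output directory), plus
#' task-specific settings (`n`, `n_seeds`, `nu_grid`, `phi_grid`, `grids`,
#' `objective`, `n_draws`, `n_reps`, `control`, ...).  All randomness flows
#' from `seed`; identical configs and seeds give identical outputs for the
#' deterministic tasks.
#'
#' @param config A named list, or path to a YAML/JSON file with one.
#' @return The task result, invisibly; outputs are written under
#'   `config$out` when given (JSON records, CSV grids, two-column
#'   nonlinearity tables).
#' @export
run <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$task))
  task <- match.arg(config$task,
                    c("solve_single", "solve_dual", "sweep", "phase_map",
                      "simulate", "mi", "fixtures"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  p <- if (!is.null(config$params)) as_circuit_params(config$params)
  outdir <- config$out
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  save <- function(writer, x, name) {
    if (!is.null(outdir)) writer(x, file.path(outdir, name))
    x
  }

  res <- switch(task,
    solve_single = {
      sol <- solve_single(p, control = config$control %||% list())
      if (!is.null(outdir)) {
        writeLines(jsonlite::toJSON(
          list(params = unclass(p), x0 = sol$x0, x1 = sol$x1,
               z0 = sol$z0, z1 = sol$z1, D = sol$D$D, D0 = sol$D$D0,
               mse = sol$mse, snr = sol$snr, residual = sol$residual,
               converged = sol$converged),
          auto_unbox = TRUE, digits = NA),
          file.path(outdir, "single_solution.json"))
        write_nonlinearity(sol$f_rescaled,
                           file.path(outdir, "single_nonlinearity.txt"))
      }
      sol
    },
    solve_dual = {
      ens <- multi_seed_solve(p, n_seeds = config$n_seeds %||% 20L,
                              seed = seed,
                              control = config$control %||% list())
      if (!is.null(outdir)) {
        for (lab in names(ens$best))
          write_dual_solution(ens$best[[lab]],
                              file.path(outdir, paste0("dual_", lab,
                                                       ".json")))
      }
      ens
    },
    sweep = {
      sw <- sweep_logistic(p, objective = config$objective %||% "mse",
                           nu_grid = config$nu_grid,
                           phi_grid = config$phi_grid,
                           n_draws = config$n_draws %||% 1e7,
                           n_reps = config$n_reps %||% 5L, seed = seed,
                           method = config$method %||% "monte_carlo")
      save(write_sweep_result, sw, "sweep.csv")
    },
    phase_map = {
      g <- config$grids %||% list()
      pm <- phase_map(rho_eff = g$rho_eff %||% c(0, 0.25, 0.5, 0.75, 1),
                      kappa = g$kappa %||% 1,
                      sigma_down = g$sigma_down %||% c(0.1, 0.25, 0.5,
                                                       0.75, 1),
                      rho_down = g$rho_down %||% seq(-1, 1, by = 0.25),
                      sigma_s = config$sigma_s %||% 1,
                      sigma_up = config$sigma_up %||% 2,
                      n_seeds = config$n_seeds %||% 20L, seed = seed,
                      control = config$control %||% list())
      save(write_phase_map, pm, "phase_map.csv")
    },
    simulate = {
      f <- config_nonlinearity(config, p)
      d <- simulate_circuit(p, f, n = config$n %||% 1e4, seed = seed)
      save(write_draws, d, "draws.csv")
    },
    mi = {
      f <- config_nonlinearity(config, p)
      mutual_information(p, f,
                         n_stimuli = config$n_stimuli %||% 1e4,
                         n_repeats = config$n_repeats %||% 1e4,
                         n_cond = config$n_cond %||% 50L,
                         n_reps = config$n_reps %||% 10L, seed = seed)
    },
    fixtures = generate_fixtures(seed = seed, n = config$n %||% 1e4,
                                 dir = outdir))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build the nonlinearity (or pair) named in a config
config_nonlinearity <- function(config, p) {
  nl_one <- function(spec) {
    stopifnot(!is.null(spec$representation))
    switch(spec$representation,
      piecewise = piecewise_nonlinearity(spec$z0, spec$z1,
                                         spec$polarity %||% "ON"),
      logistic = logistic_nonlinearity(spec$nu, spec$phi %||% 0,
                                       spec$polarity %||% "ON"),
      tabulated = tabulated_nonlinearity(spec$x, spec$f,
                                         spec$polarity %||% "ON"),
      stop("unknown nonlinearity representation in config: ",
           spec$representation, call. = FALSE))
  }
  nl <- config$nonlinearity
  if (is.null(nl)) stop("config field `nonlinearity` is required",
                        call. = FALSE)
  if (p$n_pathways == 2L) {
    if (is.null(names(nl)) && length(nl) == 2L)
      return(lapply(nl, nl_one))
    return(list(nl_one(nl), nl_one(nl)))
  }
  nl_one(nl)
}

#' Frozen-seed fixtures for the preset parameter sets
#'
#' Generates draw sets and solved single-pathway references for the named
#' parameter presets at a reduced draw count, for regression testing.
#' Regeneration from the same seed is bit-identical.
#'
#' @param seed Base seed.
#' @param n Draws per fixture.
#' @param dir Optional directory to write CSV/JSON fixtures into.
#' @return A list with `draws` (named list of `draw_set`), `references`
#'   (named list of solved `single_solution` summaries), `seed`.
#' @export
generate_fixtures <- function(seed = 20171L, n = 1e4, dir = NULL) {
  pres <- noise_regime_presets("single")
  draws <- list(); refs <- list()
  for (i in seq_len(nrow(pres))) {
    lab <- pres$label[i]
    p <- preset_params(pres[i, ])
    sol <- solve_single(p)
    draws[[lab]] <- simulate_circuit(p, sol$f, n = n, seed = seed + i)
    refs[[lab]] <- list(params = unclass(p), x0 = sol$x0, x1 = sol$x1,
                        mse = sol$mse, snr = sol$snr)
  }
  dual <- noise_regime_presets("dual")
  for (i in seq_len(nrow(dual))) {
    lab <- paste0("dual_", dual$label[i])
    p <- preset_params(dual[i, ], n_pathways = 2L)
    refs[[lab]] <- list(params = unclass(p),
                        rho_eff = effective_correlation(p))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (lab in names(draws))
      write_draws(draws[[lab]], file.path(dir, paste0(lab, ".csv")))
    writeLines(jsonlite::toJSON(refs, auto_unbox = TRUE, digits = NA),
               file.path(dir, "references.json"))
  }
  list(draws = draws, references = refs, seed = seed)
}
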