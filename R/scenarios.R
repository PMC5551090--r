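base_policy <- function() acceptance_policy(A0 = 0.8, Ac = 0.1,
                                            As = 0.1, Acs = 0.01)

# The published parasite start vector for the fig3/fig4 settings,
# (0, 0, 0.3, 0.2), carries total mass 0.5; it is rescaled to unit
# mass here.  The recursion is scale-invariant within each population
# (both updates divide by their own weighted mean), so the rescaling
# leaves the trajectory from generation 1 unchanged.
host_init <- c(0.225, 0.275, 0.2, 0.3)
parasite_init_full <- c(0.275, 0.225, 0.3, 0.2)
parasite_init_spotted <- c(0, 0, 0.3, 0.2) / 0.5

#' Names of the built-in scenario presets
#'
#' @return Character vector of preset identifiers.
#' @examples
#' preset_names()
#' @export
preset_names <- function() c("fig2a", "fig2b", "fig2c",
                             "fig3a", "fig3b", "fig4")

#' Built-in scenario presets
#'
#' Named parameter/initial-condition bundles covering the model's three
#' dynamical regimes and the two biological questions it answers.  All
#' presets share the acceptance policy `A0 = 0.8`, `Ac = As = 0.1`,
#' `Acs = 0.01` and the parasitism rate `P = 0.05`; the host always
#' starts at `(0.225, 0.275, 0.2, 0.3)`.
#' \describe{
#'   \item{fig2a}{`mc = ms = 1e-10`, all four types present in the
#'     parasite: heteroclinic-like cycling.}
#'   \item{fig2b}{`mc = ms = 1e-4`: sustained multimode oscillation.}
#'   \item{fig2c}{`mc = ms = 4e-3` (above the critical mutation rate):
#'     convergence to equal coexistence of all four types.}
#'   \item{fig3a}{`mc = 1e-4`, `ms = 0`, parasite starts with spotted
#'     types only: spotted hosts die out, the remaining immaculate
#'     hosts and spotted parasites oscillate around 1/2.}
#'   \item{fig3b}{`mc = 4e-3`, `ms = 0`, same start: spotted hosts die
#'     out and the system converges, immaculate white and blue each at
#'     exactly 1/2 in the host.}
#'   \item{fig4}{`mc = ms = 1e-4`, parasite starts with spotted types
#'     only: mutation creates immaculate parasite eggs, which invade.}
#' }
#' The oscillatory presets run for the standard 1,000 generations.
#' The stationary ones run longer (5,000 for `fig2c`, 3,000 for
#' `fig3b`) because their approach to equilibrium only crosses the
#' `1e-10` convergence tolerance after a few thousand generations.
#'
#' @param name one of [preset_names()].
#' @return A list with `name`, `params` ([model_params()]), `init`
#'   ([population_state()]), `n_generations` and `expected_regime`.
#' @examples
#' scenario_preset("fig2b")$params
#' @export
scenario_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% preset_names()))
    stop("unknown preset `", paste(name, collapse = ","),
         "`; available: ", paste(preset_names(), collapse = ", "),
         call. = FALSE)
  pol <- base_policy()
  cfg <- switch(name,
    fig2a = list(mc = 1e-10, ms = 1e-10, p0 = parasite_init_full,
                 n = 1000L, regime = "heteroclinic_like"),
    fig2b = list(mc = 1e-4, ms = 1e-4, p0 = parasite_init_full,
                 n = 1000L, regime = "oscillating"),
    fig2c = list(mc = 4e-3, ms = 4e-3, p0 = parasite_init_full,
                 n = 5000L, regime = "converged"),
    fig3a = list(mc = 1e-4, ms = 0, p0 = parasite_init_spotted,
                 n = 1000L, regime = "oscillating"),
    fig3b = list(mc = 4e-3, ms = 0, p0 = parasite_init_spotted,
                 n = 3000L, regime = "converged"),
    fig4  = list(mc = 1e-4, ms = 1e-4, p0 = parasite_init_spotted,
                 n = 1000L, regime = "oscillating"))
  list(name = name,
       params = model_params(pol, P = 0.05, mc = cfg$mc, ms = cfg$ms),
       init = population_state(host_init, cfg$p0),
       n_generations = cfg$n,
       expected_regime = cfg$regime)
}

state_to_list <- function(st) {
  if (is.null(st)) return(NULL)
  list(h = st$h, p = st$p, generation = st$generation)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

regime_to_list <- function(rep) {
  list(regime = rep$regime,
       limit_state = state_to_list(rep$limit_state),
       period_estimate = if (is.na(rep$period_estimate)) NULL else
         rep$period_estimate,
       amplitude_host = rep$amplitude_host,
       amplitude_parasite = rep$amplitude_parasite)
}

stability_to_list <- function(rep) {
  list(equilibrium = state_to_list(rep$equilibrium),
       eigenvalues = lapply(rep$eigenvalues,
                            function(z) c(Re(z), Im(z))),
       spectral_radius = rep$spectral_radius,
       stable = rep$stable,
       predicted_period = if (is.na(rep$predicted_period)) NULL else
         rep$predicted_period)
}

threshold_to_list <- function(res) {
  list(trait = res$trait, m_star = res$m_star,
       bracket = res$bracket, tolerance = res$tolerance,
       direction = res$direction,
       trace = res$trace)
}

run_log_lines <- function(params, init, n_generations, expected_regime) {
  c(sprintf("eggmorph version: %s",
            as.character(utils::packageVersion("eggmorph"))),
    sprintf("A0 = %.17g", params$policy$A0),
    sprintf("Ac = %.17g", params$policy$Ac),
    sprintf("As = %.17g", params$policy$As),
    sprintf("Acs = %.17g", params$policy$Acs),
    sprintf("P = %.17g", params$P),
    sprintf("mc = %.17g", params$mc),
    sprintf("ms = %.17g", params$ms),
    sprintf("h_init = %s", paste(sprintf("%.17g", init$h), collapse = ", ")),
    sprintf("p_init = %s", paste(sprintf("%.17g", init$p), collapse = ", ")),
    sprintf("n_generations = %d", n_generations),
    sprintf("expected_regime = %s",
            if (is.null(expected_regime)) "(none)" else expected_regime))
}

run_core <- function(params, init, n_generations, expected_regime,
                     out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  traj <- simulate_dynamics(params, init, n_generations)
  regime <- classify_regime(traj)
  stab <- stability_report(params, internal_equilibrium())

  paths <- list(trajectory = file.path(out_dir, "trajectory.csv"),
                regime = file.path(out_dir, "regime.json"),
                stability = file.path(out_dir, "stability.json"),
                log = file.path(out_dir, "run.log"))
  write_trajectory(traj, paths$trajectory)
  write_json_report(regime_to_list(regime), paths$regime)
  write_json_report(stability_to_list(stab), paths$stability)
  ok <- is.null(expected_regime) || identical(regime$regime, expected_regime)
  writeLines(c(run_log_lines(params, init, n_generations, expected_regime),
               sprintf("observed_regime = %s", regime$regime),
               sprintf("regime_matches_expected = %s",
                       if (is.null(expected_regime)) "not-checked"
                       else tolower(ok))),
             paths$log)
  invisible(list(ok = ok, trajectory = traj, regime = regime,
                 stability = stab, paths = paths))
}

#' Run a named scenario end-to-end
#'
#' Simulates a preset, classifies its regime, linearizes at the uniform
#' equilibrium, and writes four artifacts into `out_dir`:
#' `trajectory.csv` (full-precision time series), `regime.json`,
#' `stability.json` and `run.log` (complete parameter set and package
#' version; no timestamps, so re-runs are byte-identical).  The result
#' flags `ok = FALSE` when the observed regime contradicts the
#' preset's expectation.
#'
#' @param name a preset identifier, see [preset_names()].
#' @param out_dir output directory (created if absent).
#' @param n_generations optional horizon override; defaults to the
#'   preset's own.
#' @return Invisibly, a list with `ok`, `trajectory`, `regime`,
#'   `stability` and the written `paths`.
#' @examples
#' \donttest{
#' res <- run_scenario("fig2c", tempfile("fig2c_"))
#' res$regime$regime
#' }
#' @export
run_scenario <- function(name, out_dir, n_generations = NULL) {
  preset <- scenario_preset(name)
  n <- if (is.null(n_generations)) preset$n_generations else n_generations
  run_core(preset$params, preset$init, n, preset$expected_regime, out_dir)
}

config_field <- function(cfg, field, len = 1L, file = "config") {
  if (is.null(cfg[[field]]))
    stop(sprintf("config is missing required field `%s`", field),
         call. = FALSE)
  v <- cfg[[field]]
  if (!is.numeric(v) || length(v) != len || anyNA(v))
    stop(sprintf("config field `%s` must be numeric of length %d",
                 field, len), call. = FALSE)
  v
}

#' Read a model configuration file
#'
#' Parses a flat JSON configuration into model objects.  Every
#' scientific parameter must be present explicitly - there are no
#' hidden defaults for acceptance probabilities, parasitism or
#' mutation rates.  Validation failures name the offending field.
#'
#' Required fields: `A0`, `Ac`, `As`, `Acs`, `P`, `mc`, `ms`; with
#' `require_init = TRUE` also `h_init`, `p_init` (length-4 arrays
#' summing to 1) and `n_generations`.  An optional `expected_regime`
#' string is passed through.
#'
#' @param path path to a JSON file (or a pre-parsed named list).
#' @param require_init whether initial vectors and the horizon are
#'   required (they are for simulation runs; threshold and scaling
#'   analyses need only the parameters).
#' @return List with `params` ([model_params()]), and when requested
#'   `init` ([population_state()]), `n_generations`,
#'   `expected_regime` (or `NULL`).
#' @export
read_model_config <- function(path, require_init = TRUE) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  pol <- tryCatch(
    acceptance_policy(config_field(cfg, "A0"), config_field(cfg, "Ac"),
                      config_field(cfg, "As"), config_field(cfg, "Acs")),
    error = function(e) stop("config acceptance policy invalid: ",
                             conditionMessage(e), call. = FALSE))
  params <- tryCatch(
    model_params(pol, config_field(cfg, "P"),
                 config_field(cfg, "mc"), config_field(cfg, "ms")),
    error = function(e) stop("config parameters invalid: ",
                             conditionMessage(e), call. = FALSE))
  out <- list(params = params)
  if (require_init) {
    h <- config_field(cfg, "h_init", len = 4L)
    p <- config_field(cfg, "p_init", len = 4L)
    out$init <- tryCatch(population_state(h, p),
      error = function(e) stop("config initial frequencies invalid: ",
                               conditionMessage(e), call. = FALSE))
    out$n_generations <- config_field(cfg, "n_generations")
    out$expected_regime <- if (is.null(cfg$expected_regime)) NULL
                           else as.character(cfg$expected_regime)
  }
  out
}

#' Run a custom configuration end-to-end
#'
#' Same artifact set as [run_scenario()], for a parameter set supplied
#' in a JSON configuration file.  A configuration that restates a
#' preset byte-for-byte yields byte-identical outputs.
#'
#' @param config path to a JSON config (see [read_model_config()]) or
#'   a pre-parsed list.
#' @param out_dir output directory.
#' @return Invisibly, the same structure as [run_scenario()].
#' @export
run_custom <- function(config, out_dir) {
  cfg <- read_model_config(config, require_init = TRUE)
  run_core(cfg$params, cfg$init, cfg$n_generations,
           cfg$expected_regime, out_dir)
}

#' Threshold search driven by a configuration file
#'
#' Runs [mutation_threshold()] for the parameters in `config` and
#' serializes the result - including the full bisection trace, for
#' audit - to `out_path`.  A search that fails because the spectral
#' radius never crosses 1 inside the bracket (for instance the
#' spottiness threshold under a policy where spots do not affect
#' acceptance) is written as a structured error object
#' `{"error": "no_straddle", ...}` rather than raised.
#'
#' @param config path to a JSON config; only the parameter fields are
#'   required.
#' @param mode as in [mutation_threshold()].
#' @param out_path JSON file to write.
#' @param bracket,tol as in [mutation_threshold()].
#' @return Invisibly, a list with `ok` and either `result` (a
#'   `"threshold_result"`) or `error` (the structured error object).
#' @export
run_threshold <- function(config, mode = "both_equal", out_path,
                          bracket = c(1e-8, 0.2), tol = 1e-9) {
  cfg <- read_model_config(config, require_init = FALSE)
  res <- tryCatch(
    mutation_threshold(cfg$params, mode = mode, bracket = bracket,
                       tol = tol),
    error = function(e) e)
  if (inherits(res, "error")) {
    err <- list(error = if (grepl("no straddle", conditionMessage(res)))
                  "no_straddle" else "threshold_failed",
                message = conditionMessage(res),
                mode = mode, bracket = bracket)
    write_json_report(err, out_path)
    return(invisible(list(ok = FALSE, error = err)))
  }
  write_json_report(threshold_to_list(res), out_path)
  invisible(list(ok = TRUE, result = res))
}

#' Period-scaling analysis driven by a configuration file
#'
#' Runs [period_scaling()] for the parameters in `config` over the
#' given parasitism rates and writes the exponent and the per-rate
#' periods to `out_path` as JSON.
#'
#' @param config path to a JSON config; only the parameter fields are
#'   required.
#' @param P_values parasitism rates to sweep (at least 4).
#' @param out_path JSON file to write.
#' @return Invisibly, the `"period_scaling"` object.
#' @export
run_scaling <- function(config, P_values, out_path) {
  cfg <- read_model_config(config, require_init = FALSE)
  res <- period_scaling(cfg$params, P_values)
  write_json_report(list(exponent = res$exponent,
                         P_values = res$P_values,
                         periods = res$periods,
                         spectral_radii = res$spectral_radii),
                    out_path)
  invisible(res)
}
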