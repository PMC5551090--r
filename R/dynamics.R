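# Internal constructor; h/p are (n+1) x 4 matrices, wbar vectors length n+1.
new_trajectory <- function(params, h, p, w_bar_H, w_bar_P) {
  colnames(h) <- paste0("h", 1:4)
  colnames(p) <- paste0("p", 1:4)
  structure(list(params = params,
                 generation = 0:(nrow(h) - 1L),
                 h = h, p = p,
                 w_bar_H = w_bar_H, w_bar_P = w_bar_P),
            class = "egg_trajectory")
}

#' Iterate the recursion over many generations
#'
#' Runs the deterministic one-generation map from an initial state for
#' `n_generations` generations and records every state together with
#' the mean fitness of both populations evaluated at that state.  The
#' model is an infinite-population recursion: there is no randomness
#' anywhere, so re-running with the same inputs is bit-identical.
#'
#' @param params an [model_params()] object.
#' @param init a [population_state()] giving generation-0 frequencies.
#' @param n_generations positive integer number of generations to step.
#' @return An object of class `"egg_trajectory"`: a list with `params`,
#'   `generation` (0..n), matrices `h` and `p` of dimension
#'   `(n+1) x 4`, and vectors `w_bar_H`, `w_bar_P` of mean fitnesses.
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 1e-4, ms = 1e-4)
#' tr <- simulate_dynamics(pars,
#'         population_state(c(0.225, 0.275, 0.2, 0.3),
#'                          c(0.275, 0.225, 0.3, 0.2)), 200)
#' tail(as.data.frame(tr))
#' @export
simulate_dynamics <- function(params, init, n_generations) {
  if (!inherits(params, "egg_model_params"))
    stop("`params` must be an egg_model_params object", call. = FALSE)
  if (!inherits(init, "population_state"))
    stop("`init` must be a population_state object", call. = FALSE)
  if (!is.numeric(n_generations) || length(n_generations) != 1L ||
      n_generations < 1 || n_generations != floor(n_generations))
    stop("`n_generations` must be a positive integer", call. = FALSE)
  n <- as.integer(n_generations)

  A <- acceptance_matrix(params$policy)
  M <- mutation_matrix(params$mc, params$ms)
  P <- params$P

  H <- matrix(NA_real_, n + 1L, 4L)
  Pm <- matrix(NA_real_, n + 1L, 4L)
  wbH <- numeric(n + 1L)
  wbP <- numeric(n + 1L)
  h <- init$h; p <- init$p
  H[1L, ] <- h; Pm[1L, ] <- p
  for (g in seq_len(n)) {
    out <- step_core(h, p, A, M, P)
    if (is.null(out))
      stop(sprintf(
        "parasite mean fitness reached zero at generation %d: recursion undefined",
        g), call. = FALSE)
    wbH[g] <- out$w_bar_H
    wbP[g] <- out$w_bar_P
    h <- out$h; p <- out$p
    H[g + 1L, ] <- h; Pm[g + 1L, ] <- p
  }
  # mean fitness at the final recorded state
  wbH[n + 1L] <- sum(h * as.numeric(1 - P * (A %*% p)))
  wbP[n + 1L] <- sum(p * as.numeric(crossprod(A, h)))
  new_trajectory(params, H, Pm, wbH, wbP)
}

#' @export
print.egg_trajectory <- function(x, ...) {
  n <- length(x$generation) - 1L
  cat(sprintf("Egg-phenotype trajectory: %d generations\n", n))
  print(x$params)
  cat("Final state:\n")
  m <- rbind(host = x$h[n + 1L, ], parasite = x$p[n + 1L, ])
  colnames(m) <- c("imm.white", "imm.blue", "sp.white", "sp.blue")
  print(round(m, 6))
  invisible(x)
}

#' @export
as.data.frame.egg_trajectory <- function(x, ...) {
  data.frame(generation = x$generation,
             x$h, x$p,
             wbarH = x$w_bar_H, wbarP = x$w_bar_P)
}

# state recorded at generation `gen` of a trajectory
state_at <- function(traj, gen) {
  i <- gen + 1L
  population_state(traj$h[i, ], traj$p[i, ], gen)
}

trailing_window <- function(traj, window_fraction) {
  n <- length(traj$generation)
  start <- max(1L, n - floor((n - 1L) * window_fraction))
  start:n
}

#' Write / read a trajectory as CSV
#'
#' One row per generation with header
#' `generation,h1,h2,h3,h4,p1,p2,p3,p4,wbarH,wbarP`, numbers printed
#' with 17 significant digits so the file round-trips to full double
#' precision and regression outputs are byte-stable.
#'
#' @param traj an `"egg_trajectory"` from [simulate_dynamics()].
#' @param path file path to write to / read from.
#' @param params optional [model_params()] to attach on read (the CSV
#'   itself carries only the time series).
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `"egg_trajectory"`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(
    "generation,h1,h2,h3,h4,p1,p2,p3,p4,wbarH,wbarP",
    paste(df$generation,
          fmt(df$h1), fmt(df$h2), fmt(df$h3), fmt(df$h4),
          fmt(df$p1), fmt(df$p2), fmt(df$p3), fmt(df$p4),
          fmt(df$wbarH), fmt(df$wbarP), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, params = NULL) {
  df <- utils::read.csv(path)
  need <- c("generation", paste0("h", 1:4), paste0("p", 1:4),
            "wbarH", "wbarP")
  if (!identical(names(df), need))
    stop("unexpected trajectory CSV header in ", path, call. = FALSE)
  new_trajectory(params,
                 as.matrix(df[paste0("h", 1:4)]),
                 as.matrix(df[paste0("p", 1:4)]),
                 df$wbarH, df$wbarP)
}

# Local maxima of a series with a simple prominence filter: a peak is
# kept when it rises at least `min_prominence` above the higher of the
# two valleys separating it from its neighbors (window edges count as
# valleys).  Plateaus take the first index.
find_peaks <- function(x, min_prominence = 1e-4) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # strip zero steps by carrying the previous sign so plateaus resolve
  s <- sign(d)
  for (k in seq_along(s)) if (s[k] == 0 && k > 1L) s[k] <- s[k - 1L]
  cand <- which(diff(s) == -2) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- logical(length(cand))
  bounds <- c(1L, cand, n)
  for (k in seq_along(cand)) {
    left <- min(x[bounds[k]:cand[k]])
    right <- min(x[cand[k]:bounds[k + 2L]])
    keep[k] <- (x[cand[k]] - max(left, right)) >= min_prominence
  }
  cand[keep]
}

#' Oscillation period from peak spacing
#'
#' Estimates the period of one phenotype-frequency series as the mean
#' spacing (in generations) between successive local maxima over the
#' trailing window of a trajectory.  Peaks below a small prominence
#' floor are ignored so numerical ripple does not masquerade as a
#' cycle.  At least three peaks are required; fewer is an error, never
#' a fabricated number.
#'
#' The default series is the first host component (immaculate white).
#' When the unstable linearization carries several complex eigenvalue
#' pairs the oscillation is multimode and different components can give
#' somewhat different spacings; the first-component estimate tracks the
#' leading (fastest-growing) mode.
#'
#' @param traj an `"egg_trajectory"`.
#' @param population `"host"` or `"parasite"`.
#' @param series phenotype index 1..4 selecting the frequency series.
#' @param window_fraction fraction of the trajectory (from the end)
#'   used for the estimate; default the trailing half.
#' @param min_prominence minimum peak prominence, default `1e-4`.
#' @return Estimated period in generations (a real number).
#' @export
estimate_period <- function(traj, population = c("host", "parasite"),
                            series = 1L, window_fraction = 0.5,
                            min_prominence = 1e-4) {
  population <- match.arg(population)
  stopifnot(series %in% 1:4)
  idx <- trailing_window(traj, window_fraction)
  x <- if (population == "host") traj$h[idx, series] else traj$p[idx, series]
  pk <- find_peaks(x, min_prominence)
  if (length(pk) < 3L)
    stop(sprintf(
      "no period: only %d local maxima (>= 3 needed) in the %s series %d window",
      length(pk), population, series), call. = FALSE)
  mean(diff(traj$generation[idx][pk]))
}

#' Oscillation amplitude of host and parasite
#'
#' Max-minus-min of the dominant (largest-range) frequency component of
#' each population over the trailing window.  In the oscillatory
#' regimes the parasite swings harder than the host: every parasite egg
#' faces the host's accept/reject decision while only a fraction `P`
#' of host nests is under parasitic pressure.
#'
#' @inheritParams estimate_period
#' @return Named numeric vector `c(host = ..., parasite = ...)`.
#' @export
oscillation_amplitudes <- function(traj, window_fraction = 0.5) {
  idx <- trailing_window(traj, window_fraction)
  rng <- function(m) max(apply(m[idx, , drop = FALSE], 2,
                               function(v) diff(range(v))))
  c(host = rng(traj$h), parasite = rng(traj$p))
}

#' Classify the dynamical regime of a trajectory
#'
#' Operationalizes the three regimes the recursion exhibits:
#' \describe{
#'   \item{converged}{the final per-generation change (max norm over
#'     both populations) is below `tol_converged`; the last state is
#'     reported as the limit.}
#'   \item{heteroclinic_like}{not converged, and some frequency exceeds
#'     0.99 inside the trailing window: the system lingers near a
#'     sequence of near-monomorphic states.}
#'   \item{oscillating}{anything else: sustained bounded oscillation.}
#' }
#' Convergence is judged on the final step rather than the whole
#' window because near-critical parameters decay slowly: demanding
#' sub-tolerance change across the entire trailing half would postpone
#' a verdict by thousands of generations after the state is
#' numerically stationary.
#'
#' @param traj an `"egg_trajectory"` of at least 100 generations.
#' @param window_fraction trailing fraction used for the oscillation
#'   statistics and the near-fixation scan; default 0.5.
#' @param tol_converged max-norm per-generation change below which the
#'   run is declared converged; default `1e-10`.
#' @return An object of class `"regime_report"`: list with `regime`,
#'   `limit_state` (a [population_state()] or `NULL`),
#'   `period_estimate` (generations, or `NA` when fewer than 3 peaks),
#'   `amplitude_host`, `amplitude_parasite`.
#' @export
classify_regime <- function(traj, window_fraction = 0.5,
                            tol_converged = 1e-10) {
  n <- length(traj$generation) - 1L
  if (n < 100L)
    stop("trajectory too short to classify: need >= 100 generations",
         call. = FALSE)
  idx <- trailing_window(traj, window_fraction)
  last_change <- max(abs(traj$h[n + 1L, ] - traj$h[n, ]),
                     abs(traj$p[n + 1L, ] - traj$p[n, ]))
  amp <- oscillation_amplitudes(traj, window_fraction)

  if (last_change < tol_converged) {
    regime <- "converged"
    limit <- state_at(traj, n)
  } else {
    limit <- NULL
    near_fix <- max(traj$h[idx, ], traj$p[idx, ]) > 0.99
    regime <- if (near_fix) "heteroclinic_like" else "oscillating"
  }
  period <- if (regime == "converged") NA_real_ else
    tryCatch(estimate_period(traj, window_fraction = window_fraction),
             error = function(e) NA_real_)
  structure(list(regime = regime, limit_state = limit,
                 period_estimate = period,
                 amplitude_host = unname(amp["host"]),
                 amplitude_parasite = unname(amp["parasite"])),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Regime:", x$regime, "\n")
  if (!is.null(x$limit_state)) print(x$limit_state)
  if (!is.na(x$period_estimate))
    cat(sprintf("Estimated period: %.1f generations\n", x$period_estimate))
  cat(sprintf("Oscillation amplitude: host %.4g, parasite %.4g\n",
              x$amplitude_host, x$amplitude_parasite))
  invisible(x)
}
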