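#' Internal all-types equilibrium
#'
#' With nonzero mutation in both traits the recursion has a unique
#' internal fixed point where all four phenotypes coexist at equal
#' frequency in both populations, `h = p = (1/4, 1/4, 1/4, 1/4)`.  It
#' is a fixed point for every valid parameter set by the label
#' symmetry of the model.
#'
#' @return A [population_state()] with uniform host and parasite
#'   frequencies.
#' @examples
#' internal_equilibrium()
#' @export
internal_equilibrium <- function() {
  population_state(rep(0.25, 4), rep(0.25, 4))
}

#' Semi-internal equilibrium without immaculate parasites
#'
#' The candidate fixed point in which the parasite carries only the
#' spotted types, `h = (1/4, 1/4, 1/4, 1/4)`, `p = (0, 0, 1/2, 1/2)`,
#' matching the field observation that immaculate parasite eggs are
#' absent.  It exists only in the degenerate case where spottiness
#' plays no role in egg discrimination (`A0 = As` and `Ac = Acs`);
#' whenever hosts discriminate on spots this state is not an
#' equilibrium at all, even with zero spottiness mutation.
#'
#' @param policy an [acceptance_policy()].
#' @param tol tolerance on the two equalities; default `1e-9`.
#' @return A list with `exists` (logical) and `state` (the
#'   [population_state()] when it exists, otherwise `NULL`).
#' @examples
#' semi_internal_equilibrium(acceptance_policy(0.8, 0.1, 0.8, 0.1))
#' semi_internal_equilibrium(acceptance_policy(0.8, 0.1, 0.1, 0.01))
#' @export
semi_internal_equilibrium <- function(policy, tol = 1e-9) {
  if (!inherits(policy, "acceptance_policy"))
    stop("`policy` must be an acceptance_policy object", call. = FALSE)
  exists <- abs(policy$A0 - policy$As) <= tol &&
            abs(policy$Ac - policy$Acs) <= tol
  list(exists = exists,
       state = if (exists)
         population_state(rep(0.25, 4), c(0, 0, 0.5, 0.5)) else NULL)
}

# One-generation map on the 6 free coordinates (h1..h3, p1..p3); the
# fourth entry of each population is recovered from the unit-sum
# constraint.  Used for the reduced Jacobian.
reduced_map <- function(x, A, M, P) {
  h <- c(x[1:3], 1 - sum(x[1:3]))
  p <- c(x[4:6], 1 - sum(x[4:6]))
  out <- step_core(h, p, A, M, P)
  if (is.null(out))
    stop("parasite mean fitness is zero during linearization", call. = FALSE)
  c(out$h[1:3], out$p[1:3])
}

# Raw map on all 8 coordinates, no constraint enforcement.
raw_map <- function(x, A, M, P) {
  out <- step_core(x[1:4], x[5:8], A, M, P)
  if (is.null(out))
    stop("parasite mean fitness is zero during linearization", call. = FALSE)
  c(out$h, out$p)
}

central_jacobian <- function(f, x0, h_step) {
  n <- length(x0)
  J <- matrix(NA_real_, n, n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- h_step
    J[, k] <- (f(x0 + e) - f(x0 - e)) / (2 * h_step)
  }
  J
}

#' Jacobian of the one-generation map at a fixed point
#'
#' Linearizes the coupled recursion around a fixed point by central
#' finite differences.  Two forms are returned: the
#' constraint-reduced 6x6 Jacobian, in which each population is
#' parameterized by its first three frequencies and the fourth is
#' eliminated through the unit-sum constraint, and the raw 8x8
#' Jacobian over all frequencies.  Local stability is read off the
#' reduced spectrum; the raw spectrum additionally contains spurious
#' modes along the constraint directions and is kept for diagnostics
#' only.
#'
#' @param params an [model_params()] object.
#' @param at a [population_state()] that is a fixed point of the map
#'   under `params` (verified to `fp_tol`, else an error).
#' @param h_step finite-difference perturbation per coordinate,
#'   default `1e-7`.
#' @param fp_tol fixed-point verification tolerance, default `1e-10`.
#' @return List with `reduced` (6x6 matrix) and `raw` (8x8 matrix).
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 1e-4, ms = 1e-4)
#' J <- map_jacobian(pars, internal_equilibrium())
#' eigen(J$reduced, only.values = TRUE)$values
#' @export
map_jacobian <- function(params, at, h_step = 1e-7, fp_tol = 1e-10) {
  if (!inherits(params, "egg_model_params"))
    stop("`params` must be an egg_model_params object", call. = FALSE)
  if (!inherits(at, "population_state"))
    stop("`at` must be a population_state object", call. = FALSE)
  A <- acceptance_matrix(params$policy)
  M <- mutation_matrix(params$mc, params$ms)
  P <- params$P
  nxt <- step_core(at$h, at$p, A, M, P)
  if (is.null(nxt))
    stop("parasite mean fitness is zero at `at`", call. = FALSE)
  if (max(abs(nxt$h - at$h), abs(nxt$p - at$p)) > fp_tol)
    stop(sprintf(
      "`at` is not a fixed point under `params` (one-step change %.3g > %g)",
      max(abs(nxt$h - at$h), abs(nxt$p - at$p)), fp_tol), call. = FALSE)
  list(
    reduced = central_jacobian(function(x) reduced_map(x, A, M, P),
                               c(at$h[1:3], at$p[1:3]), h_step),
    raw = central_jacobian(function(x) raw_map(x, A, M, P),
                           c(at$h, at$p), h_step)
  )
}

#' Eigenvalue stability report at a fixed point
#'
#' Computes the eigenvalues of the constraint-reduced Jacobian at a
#' fixed point.  The fixed point of the discrete-time map is locally
#' stable iff the spectral radius is strictly below 1.  When the
#' leading eigenvalue (largest modulus) is non-real, the linear theory
#' predicts oscillation with period `2 * pi / |arg(lambda)|`
#' generations, which is reported as `predicted_period`.
#'
#' @inheritParams map_jacobian
#' @return An object of class `"stability_report"`: list with
#'   `equilibrium`, `eigenvalues` (complex, decreasing modulus),
#'   `spectral_radius`, `stable` (logical) and `predicted_period`
#'   (`NA` when the leading eigenvalue is real).
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 4e-3, ms = 4e-3)
#' stability_report(pars)
#' @export
stability_report <- function(params, at = internal_equilibrium(),
                             h_step = 1e-7, fp_tol = 1e-10) {
  J <- map_jacobian(params, at, h_step = h_step, fp_tol = fp_tol)
  ev <- eigen(J$reduced, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  lead <- ev[1L]
  rho <- Mod(lead)
  structure(list(
    equilibrium = at,
    eigenvalues = ev,
    spectral_radius = rho,
    stable = rho < 1,
    predicted_period = if (Im(lead) != 0) 2 * pi / abs(Arg(lead)) else NA_real_
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Spectral radius %.6f => %s\n", x$spectral_radius,
              if (x$stable) "locally stable" else "unstable"))
  if (!is.na(x$predicted_period))
    cat(sprintf("Leading pair predicts a %.1f-generation oscillation\n",
                x$predicted_period))
  cat("Eigenvalues (decreasing modulus):\n")
  print(signif(x$eigenvalues, 6))
  invisible(x)
}

with_mutation <- function(params, mode, m) {
  switch(mode,
         both_equal = model_params(params$policy, params$P, m, m),
         color_only = model_params(params$policy, params$P, m, params$ms),
         spottiness_only = model_params(params$policy, params$P, params$mc, m))
}

#' Critical mutation probability by bisection
#'
#' The uniform coexistence equilibrium is stabilized by sufficiently
#' strong mutation: the spectral radius of the reduced Jacobian falls
#' below 1 once the varied mutation probability exceeds a threshold
#' `m*`.  This routine locates `m*` by bisection on
#' `spectral_radius - 1`.  In mode `"both_equal"` the two trait
#' mutation probabilities are varied jointly (`mc = ms = m`); the
#' single-trait modes vary one probability and hold the other at its
#' value in `params_base`.
#'
#' @param params_base an [model_params()] object supplying the policy,
#'   `P`, and any held-fixed mutation probability.
#' @param mode `"both_equal"`, `"color_only"` or `"spottiness_only"`.
#' @param bracket numeric length-2 initial bracket for `m`; the
#'   spectral radius must straddle 1 across it, else an error
#'   reporting both endpoint radii.
#' @param tol absolute bracket width at which bisection stops,
#'   default `1e-9`.
#' @return An object of class `"threshold_result"`: list with `trait`
#'   (the mode), `m_star` (bracket midpoint), `bracket` (final),
#'   `tolerance`, `direction` (`"radius_decreasing"` when the radius
#'   falls with `m`, `"radius_increasing"` otherwise) and `trace`
#'   (data frame of every `(m, radius)` evaluated, for audit).
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 1e-4, ms = 1e-4)
#' mutation_threshold(pars)$m_star   # ~1.944e-3
#' @export
mutation_threshold <- function(params_base,
                               mode = c("both_equal", "color_only",
                                        "spottiness_only"),
                               bracket = c(1e-8, 0.2), tol = 1e-9) {
  mode <- match.arg(mode)
  if (!is.numeric(bracket) || length(bracket) != 2L ||
      bracket[1] >= bracket[2])
    stop("`bracket` must be an increasing pair (low, high)", call. = FALSE)
  radius_at <- function(m)
    stability_report(with_mutation(params_base, mode, m))$spectral_radius

  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- radius_at(lo); r_hi <- radius_at(hi)
  trace_m <- c(lo, hi); trace_r <- c(r_lo, r_hi)
  if ((r_lo - 1) * (r_hi - 1) >= 0)
    stop(sprintf(
      "no straddle: spectral radius is %.8f at m = %g and %.8f at m = %g (neither side crosses 1)",
      r_lo, lo, r_hi, hi), call. = FALSE)
  direction <- if (r_lo > 1) "radius_decreasing" else "radius_increasing"

  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r_mid <- radius_at(mid)
    trace_m <- c(trace_m, mid); trace_r <- c(trace_r, r_mid)
    if ((r_mid - 1) * (r_lo - 1) > 0) {
      lo <- mid; r_lo <- r_mid
    } else {
      hi <- mid; r_hi <- r_mid
    }
  }
  # empirical monotonicity check of the radius inside the bracket;
  # slack covers the finite-difference noise floor of the Jacobian
  ord <- order(trace_m)
  rr <- trace_r[ord]
  mono <- if (direction == "radius_decreasing") all(diff(rr) <= 1e-8)
          else all(diff(rr) >= -1e-8)
  if (!mono)
    warning("spectral radius is not monotone across the evaluated points; ",
            "the reported m_star is one crossing of 1, possibly not unique",
            call. = FALSE)
  structure(list(trait = mode, m_star = (lo + hi) / 2,
                 bracket = c(lo, hi), tolerance = hi - lo,
                 direction = direction,
                 trace = data.frame(m = trace_m, radius = trace_r)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Critical mutation probability (%s): m* = %.6g\n",
              x$trait, x$m_star))
  cat(sprintf("  final bracket [%.6g, %.6g], %s\n",
              x$bracket[1], x$bracket[2], x$direction))
  invisible(x)
}

#' Slope of a log-log power-law fit
#'
#' Least-squares slope of `log(y)` on `log(x)`; the exponent `b` of a
#' power law `y = c * x^b`.  Exposed so the scaling analysis can be
#' self-tested on exact synthetic laws.
#'
#' @param x,y positive numeric vectors of equal length (>= 2).
#' @return The fitted exponent (slope), a single number.
#' @examples
#' power_law_exponent(1:10, 3 * (1:10)^-0.5)  # -0.5
#' @export
power_law_exponent <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(x > 0), all(y > 0))
  unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
}

#' Scaling of the oscillation period with the parasitism rate
#'
#' For each parasitism rate in `P_values`, linearizes the map at the
#' uniform equilibrium and takes the predicted period
#' `2 * pi / |arg(lambda_lead)|`, then fits `log(T)` against `log(P)`.
#' In the unstable (oscillatory) regime the period grows like
#' `1 / sqrt(P)`, so the fitted exponent is close to -0.5.
#'
#' @param params_base an [model_params()] object; its mutation
#'   probabilities and policy are held fixed while `P` is swept.
#' @param P_values at least four parasitism rates, each of which must
#'   put the uniform equilibrium in the unstable regime with a complex
#'   leading eigenvalue; offenders are reported in an error.
#' @return An object of class `"period_scaling"`: list with
#'   `exponent`, `P_values`, `periods`, and `spectral_radii`.
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 1e-4, ms = 1e-4)
#' period_scaling(pars, c(0.0125, 0.025, 0.05, 0.1, 0.2))$exponent
#' @export
period_scaling <- function(params_base, P_values) {
  if (length(P_values) < 4L)
    stop("need at least 4 parasitism rates to fit a scaling law",
         call. = FALSE)
  reports <- lapply(P_values, function(pv)
    stability_report(model_params(params_base$policy, pv,
                                  params_base$mc, params_base$ms)))
  ok <- vapply(reports, function(r)
    !r$stable && !is.na(r$predicted_period), logical(1))
  if (!all(ok))
    stop("these parasitism rates leave the equilibrium stable or without ",
         "a complex leading pair (no oscillation period): ",
         paste(P_values[!ok], collapse = ", "), call. = FALSE)
  periods <- vapply(reports, function(r) r$predicted_period, numeric(1))
  structure(list(
    exponent = power_law_exponent(P_values, periods),
    P_values = P_values, periods = periods,
    spectral_radii = vapply(reports, function(r) r$spectral_radius,
                            numeric(1))
  ), class = "period_scaling")
}

#' @export
print.period_scaling <- function(x, ...) {
  cat(sprintf("Period-vs-parasitism scaling exponent: %.4f\n", x$exponent))
  print(data.frame(P = x$P_values, period = round(x$periods, 2)))
  invisible(x)
}
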