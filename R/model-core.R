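#' Acceptance policy for foreign eggs
#'
#' A host laying eggs of phenotype i accepts a parasitic egg of
#' phenotype j with a probability that depends only on how the two
#' phenotypes differ: `A0` when they match in both traits, `Ac` when
#' only the background color differs, `As` when only spottiness
#' differs, and `Acs` when both differ.  Rejection ability improves
#' with mismatch, so the constructor enforces
#' `1 >= A0 >= Ac`, `A0 >= As`, `Ac >= Acs >= 0` and `As >= Acs`.
#'
#' @param A0 acceptance probability for a matching egg.
#' @param Ac acceptance probability when only color differs.
#' @param As acceptance probability when only spottiness differs.
#' @param Acs acceptance probability when both traits differ.
#' @return An object of class `"acceptance_policy"`.
#' @examples
#' acceptance_policy(A0 = 0.8, Ac = 0.1, As = 0.1, Acs = 0.01)
#' @export
acceptance_policy <- function(A0, Ac, As, Acs) {
  for (nm in c("A0", "Ac", "As", "Acs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a single probability in [0, 1]", nm),
           call. = FALSE)
  }
  if (!(A0 >= Ac && A0 >= As && Ac >= Acs && As >= Acs))
    stop("acceptance probabilities must satisfy 1 >= A0 >= Ac, As and ",
         "Ac, As >= Acs >= 0 (mismatch can only lower acceptance)",
         call. = FALSE)
  structure(list(A0 = A0, Ac = Ac, As = As, Acs = Acs),
            class = "acceptance_policy")
}

#' @export
print.acceptance_policy <- function(x, ...) {
  cat(sprintf(
    "Egg acceptance policy: A0 = %g (match), Ac = %g (color), As = %g (spots), Acs = %g (both)\n",
    x$A0, x$Ac, x$As, x$Acs))
  invisible(x)
}

#' Full model parameter set
#'
#' Bundles the acceptance policy with the parasitism rate `P`
#' (fraction of host nests receiving exactly one parasite egg per
#' generation, phenotype-independent) and the per-generation reciprocal
#' mutation probabilities of the two traits, `mc` (color) and `ms`
#' (spottiness).  Host and parasite share the mutation probabilities.
#'
#' @param policy an [acceptance_policy()].
#' @param P parasitism rate, strictly between 0 and 1.
#' @param mc color mutation probability per lineage per generation,
#'   in `[0, 0.5]`.
#' @param ms spottiness mutation probability, in `[0, 0.5]`.
#' @return An object of class `"egg_model_params"`.
#' @examples
#' model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'              P = 0.05, mc = 1e-4, ms = 1e-4)
#' @export
model_params <- function(policy, P, mc, ms) {
  if (!inherits(policy, "acceptance_policy"))
    stop("`policy` must be an acceptance_policy object", call. = FALSE)
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || P <= 0 || P >= 1)
    stop("`P` must satisfy 0 < P < 1", call. = FALSE)
  for (nm in c("mc", "ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 0.5)
      stop(sprintf("`%s` must lie in [0, 0.5]", nm), call. = FALSE)
  }
  structure(list(policy = policy, P = P, mc = mc, ms = ms),
            class = "egg_model_params")
}

#' @export
print.egg_model_params <- function(x, ...) {
  print(x$policy)
  cat(sprintf("Parasitism rate P = %g; mutation mc = %g, ms = %g\n",
              x$P, x$mc, x$ms))
  invisible(x)
}

# Validate + exactly renormalize a length-4 frequency vector.
# Sums within `tol` of 1 are rescaled; worse is an error.
check_frequencies <- function(x, what = "frequency vector", tol = 1e-9) {
  if (!is.numeric(x) || length(x) != 4L || anyNA(x))
    stop(sprintf("%s must be a numeric vector of 4 frequencies", what),
         call. = FALSE)
  if (any(x < 0) || any(x > 1))
    stop(sprintf("%s has entries outside [0, 1]", what), call. = FALSE)
  s <- sum(x)
  if (abs(s - 1) > tol)
    stop(sprintf("%s sums to %.12g, not 1 (tolerance %g)", what, s, tol),
         call. = FALSE)
  as.numeric(x) / s
}

#' Paired host/parasite population state
#'
#' The state of the coupled system at one generation: the host
#' phenotype-frequency vector `h` and the parasite vector `p`, each of
#' length 4 in the fixed phenotype order (see [egg_phenotypes()]),
#' non-negative and summing to 1 (inputs within `1e-9` of unit mass are
#' renormalized exactly).
#'
#' @param h host frequencies, length 4.
#' @param p parasite frequencies, length 4.
#' @param generation non-negative integer generation counter.
#' @return An object of class `"population_state"` with fields `h`,
#'   `p`, `generation`.
#' @examples
#' population_state(h = c(0.225, 0.275, 0.2, 0.3),
#'                  p = c(0.275, 0.225, 0.3, 0.2))
#' @export
population_state <- function(h, p, generation = 0L) {
  if (!is.numeric(generation) || length(generation) != 1L ||
      is.na(generation) || generation < 0 || generation != floor(generation))
    stop("`generation` must be a non-negative integer", call. = FALSE)
  structure(list(h = check_frequencies(h, "host vector `h`"),
                 p = check_frequencies(p, "parasite vector `p`"),
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state, generation %d\n", x$generation))
  m <- rbind(host = x$h, parasite = x$p)
  colnames(m) <- c("imm.white", "imm.blue", "sp.white", "sp.blue")
  print(round(m, 6))
  invisible(x)
}

#' Acceptance matrix over the four phenotypes
#'
#' Expands an [acceptance_policy()] into the 4x4 matrix `A` with
#' `A[i, j]` the probability that a host of phenotype `i` accepts a
#' parasite egg of phenotype `j`.  Because acceptance depends only on
#' which traits differ, `A` is symmetric with `A0` on the diagonal.
#'
#' @param policy an [acceptance_policy()].
#' @return A symmetric 4x4 numeric matrix with dimnames
#'   `host`/`parasite`.
#' @examples
#' acceptance_matrix(acceptance_policy(0.8, 0.1, 0.1, 0.01))
#' @export
acceptance_matrix <- function(policy) {
  if (!inherits(policy, "acceptance_policy"))
    stop("`policy` must be an acceptance_policy object", call. = FALSE)
  col <- phenotype_color(1:4)
  spot <- phenotype_spottiness(1:4)
  A <- matrix(NA_real_, 4, 4,
              dimnames = list(host = 1:4, parasite = 1:4))
  for (i in 1:4) {
    for (j in 1:4) {
      same_c <- col[i] == col[j]
      same_s <- spot[i] == spot[j]
      A[i, j] <- if (same_c && same_s) policy$A0
                 else if (!same_c && same_s) policy$Ac
                 else if (same_c && !same_s) policy$As
                 else policy$Acs
    }
  }
  A
}

#' Two-trait reciprocal mutation matrix
#'
#' Color and spottiness mutate independently and reciprocally with
#' per-generation probabilities `mc` and `ms`.  Under the fixed
#' phenotype order the joint 4x4 matrix is the Kronecker product of the
#' two 2x2 single-trait matrices (spottiness slow, color fast), so a
#' simultaneous double mutation has probability `mc * ms`.  The result
#' is symmetric and doubly stochastic.
#'
#' @param mc color mutation probability, in `[0, 0.5]`.
#' @param ms spottiness mutation probability, in `[0, 0.5]`.
#' @return A symmetric, doubly stochastic 4x4 matrix `M` with
#'   `M[i, j]` the probability that a type-`j` mother leaves a
#'   type-`i` daughter.
#' @examples
#' mutation_matrix(1e-4, 1e-4)
#' mutation_matrix(0, 0)        # identity: no mutation
#' @export
mutation_matrix <- function(mc, ms) {
  for (nm in c("mc", "ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 0.5)
      stop(sprintf("`%s` must lie in [0, 0.5]", nm), call. = FALSE)
  }
  Mc <- matrix(c(1 - mc, mc, mc, 1 - mc), 2, 2)
  Ms <- matrix(c(1 - ms, ms, ms, 1 - ms), 2, 2)
  kronecker(Ms, Mc)
}

#' Host fitness under random parasitism
#'
#' A host nest escapes parasitism with probability `1 - P` and then
#' fledges normally; a parasitized nest (probability `P`) fails iff the
#' foreign egg is accepted, since an accepted parasite chick costs the
#' whole brood.  Averaging over the parasite phenotype distribution,
#' the fitness of a type-`i` host is
#' `w_H[i] = 1 - P * sum_j p[j] * A[i, j]`.
#'
#' @param p parasite frequency vector, length 4 (sums to 1).
#' @param params an [model_params()] object (supplies `P`).
#' @param A acceptance matrix from [acceptance_matrix()]; computed from
#'   `params$policy` when omitted.
#' @return Numeric length-4 vector of host fitnesses, each in
#'   `(1 - P, 1]`.
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 0, ms = 0)
#' host_fitness(c(0, 0, 0.6, 0.4), pars)
#' @export
host_fitness <- function(p, params, A = acceptance_matrix(params$policy)) {
  p <- check_frequencies(p, "parasite vector `p`")
  as.numeric(1 - params$P * (A %*% p))
}

#' Parasite fitness under host rejection
#'
#' Every parasite egg is laid in some host nest and survives iff that
#' host accepts it, so the fitness of a type-`j` parasite is the
#' host-frequency-weighted acceptance `w_P[j] = sum_i h[i] * A[i, j]`.
#' If every entry is zero (total rejection) the next-generation
#' parasite distribution is undefined and an error is raised.
#'
#' @param h host frequency vector, length 4 (sums to 1).
#' @param A acceptance matrix from [acceptance_matrix()].
#' @return Numeric length-4 vector of parasite fitnesses in `[0, 1]`.
#' @examples
#' A <- acceptance_matrix(acceptance_policy(0.8, 0.1, 0.1, 0.01))
#' parasite_fitness(c(1, 0, 0, 0), A)  # reads off host row 1
#' @export
parasite_fitness <- function(h, A) {
  h <- check_frequencies(h, "host vector `h`")
  w <- as.numeric(crossprod(A, h))   # t(A) %*% h; A symmetric anyway
  if (all(w == 0))
    stop("degenerate case: every parasite phenotype is rejected with ",
         "certainty (all parasite fitnesses are zero)", call. = FALSE)
  w
}

# Unchecked inner update shared by simulate/jacobian hot loops.
# h, p need not be normalized: the recursion is scale-invariant per
# population because each output is divided by its own weighted mean.
step_core <- function(h, p, A, M, P) {
  wH <- as.numeric(1 - P * (A %*% p))
  wP <- as.numeric(crossprod(A, h))
  wbarH <- sum(wH * h)
  wbarP <- sum(wP * p)
  if (wbarP <= 0)
    return(NULL)   # caller turns this into an informative error
  h2 <- as.numeric(M %*% (wH * h)) / wbarH
  p2 <- as.numeric(M %*% (wP * p)) / wbarP
  list(h = h2 / sum(h2), p = p2 / sum(p2),
       w_H = wH, w_P = wP, w_bar_H = wbarH, w_bar_P = wbarP)
}

#' One generation of the coupled selection-mutation recursion
#'
#' Advances the paired host/parasite state by one generation:
#' selection first (`diag(w)` with the fitnesses of [host_fitness()]
#' and [parasite_fitness()]), then mutation (`M` from
#' [mutation_matrix()]), then division by the mean fitness, i.e.
#' `h' = M W_H h / wbar_H` and `p' = M W_P p / wbar_P`.  Outputs are
#' renormalized to sum exactly 1 to absorb floating-point drift.
#'
#' @param state a [population_state()].
#' @param params an [model_params()] object.
#' @return A list with components `state` (the next
#'   [population_state()], generation incremented) and `diagnostics`
#'   (list with `w_H`, `w_P`, `w_bar_H`, `w_bar_P`).
#' @examples
#' pars <- model_params(acceptance_policy(0.8, 0.1, 0.1, 0.01),
#'                      P = 0.05, mc = 1e-4, ms = 1e-4)
#' st <- population_state(c(0.225, 0.275, 0.2, 0.3),
#'                        c(0.275, 0.225, 0.3, 0.2))
#' step_generation(st, pars)$state
#' @export
step_generation <- function(state, params) {
  if (!inherits(state, "population_state"))
    stop("`state` must be a population_state object", call. = FALSE)
  if (!inherits(params, "egg_model_params"))
    stop("`params` must be an egg_model_params object", call. = FALSE)
  A <- acceptance_matrix(params$policy)
  M <- mutation_matrix(params$mc, params$ms)
  out <- step_core(state$h, state$p, A, M, params$P)
  if (is.null(out))
    stop("parasite mean fitness is zero: the recursion for p' is ",
         "undefined (parasite effectively extinct)", call. = FALSE)
  list(
    state = population_state(out$h, out$p, state$generation + 1L),
    diagnostics = list(w_H = out$w_H, w_P = out$w_P,
                       w_bar_H = out$w_bar_H, w_bar_P = out$w_bar_P)
  )
}
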