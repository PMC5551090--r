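# Brute-force scalar-loop oracle for the one-generation update,
# written independently of the package's matrix formulation: every sum
# is an explicit loop and the acceptance/mutation entries are computed
# per (i, j) pair from the trait definitions.
oracle_step <- function(h, p, pol, P, mc, ms) {
  col <- c(1, 2, 1, 2)   # 1 = white, 2 = blue
  spt <- c(1, 1, 2, 2)   # 1 = immaculate, 2 = spotted
  acc <- function(i, j) {
    same_c <- col[i] == col[j]
    same_s <- spt[i] == spt[j]
    if (same_c && same_s) pol$A0
    else if (!same_c && same_s) pol$Ac
    else if (same_c && !same_s) pol$As
    else pol$Acs
  }
  mut <- function(i, j) {
    pc <- if (col[i] == col[j]) 1 - mc else mc
    ps <- if (spt[i] == spt[j]) 1 - ms else ms
    pc * ps
  }
  wH <- numeric(4); wP <- numeric(4)
  for (i in 1:4) {
    s <- 0
    for (j in 1:4) s <- s + p[j] * acc(i, j)
    wH[i] <- 1 - P * s
  }
  for (j in 1:4) {
    s <- 0
    for (i in 1:4) s <- s + h[i] * acc(i, j)
    wP[j] <- s
  }
  wbarH <- 0; wbarP <- 0
  for (i in 1:4) wbarH <- wbarH + wH[i] * h[i]
  for (j in 1:4) wbarP <- wbarP + wP[j] * p[j]
  hn <- numeric(4); pn <- numeric(4)
  for (i in 1:4) {
    sh <- 0; sp <- 0
    for (j in 1:4) {
      sh <- sh + mut(i, j) * wH[j] * h[j]
      sp <- sp + mut(i, j) * wP[j] * p[j]
    }
    hn[i] <- sh / wbarH
    pn[i] <- sp / wbarP
  }
  list(h = hn / sum(hn), p = pn / sum(pn))
}

random_policy <- function() {
  A0 <- runif(1, 0.5, 1)
  Ac <- runif(1, 0, A0)
  As <- runif(1, 0, A0)
  Acs <- runif(1, 0, min(Ac, As))
  acceptance_policy(A0, Ac, As, Acs)
}

random_params <- function() {
  model_params(random_policy(), P = runif(1, 0.01, 0.5),
               mc = runif(1, 0, 0.1), ms = runif(1, 0, 0.1))
}

random_state <- function() {
  h <- runif(4, 0.05, 1); p <- runif(4, 0.05, 1)
  population_state(h / sum(h), p / sum(p))
}

fig_policy <- function() acceptance_policy(0.8, 0.1, 0.1, 0.01)

fig2_params <- function(m) model_params(fig_policy(), P = 0.05,
                                        mc = m, ms = m)

fig2_init <- function() population_state(c(0.225, 0.275, 0.2, 0.3),
                                         c(0.275, 0.225, 0.3, 0.2))
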