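# Independent oracles and small generators used across tests.

# Exhaustive latent-path likelihood: sums over every latent state sequence
# (S/W/D per primary after release) the product of transition and observation
# probabilities. Kept deliberately independent of the forward recursion.
oracle_loglik <- function(seen, nS, nu, release = 1L, phi, psi, p, delta,
                          p_weaned = p) {
  TT <- length(seen)
  phi <- rep_len(phi, max(TT - 1L, 1L))
  psi <- rep_len(psi, max(TT - 1L, 1L))
  p <- rep_len(p, TT); pw <- rep_len(p_weaned, TT); delta <- rep_len(delta, TT)
  later <- seq_len(TT)[seq_len(TT) > release]
  if (!length(later)) return(0)
  grids <- expand.grid(rep(list(c("S", "W", "D")), length(later)),
                       stringsAsFactors = FALSE)
  tot <- 0
  for (r in seq_len(nrow(grids))) {
    path <- c("S", unlist(grids[r, ], use.names = FALSE))
    prob <- 1
    for (k in seq_along(later)) {
      t <- later[k]
      from <- path[k]; to <- path[k + 1L]
      ph <- phi[t - 1L]; ps <- psi[t - 1L]
      tr <- switch(paste0(from, to),
                   SS = ph * (1 - ps), SW = ph * ps, SD = 1 - ph,
                   WS = 0, WW = ph, WD = 1 - ph,
                   DS = 0, DW = 0, DD = 1)
      ob <- if (to == "S") {
        if (seen[t]) p[t] * delta[t]^nS[t] * (1 - delta[t])^nu[t] else 1 - p[t]
      } else if (to == "W") {
        if (seen[t]) (if (nS[t] > 0L) 0 else pw[t]) else 1 - pw[t]
      } else {
        if (seen[t]) 0 else 1
      }
      prob <- prob * tr * ob
    }
    tot <- tot + prob
  }
  log(tot)
}

# random observation history on TT primaries with at most `max_sec` codes
rand_history <- function(TT, max_sec = 2L) {
  seen <- c(TRUE, stats::runif(TT - 1L) < 0.7)
  k <- ifelse(seen, sample(seq_len(max_sec), TT, replace = TRUE), 0L)
  nS <- vapply(k, function(x) if (x) sample(0:x, 1L) else 0L, 1L)
  list(seen = seen, nS = nS, nu = k - nS)
}

# small ready-made simulated dataset for fitting tests
small_sim_data <- function(n = 600L, seed = 42L, psi = c(0.6, 0.6, 0.9)) {
  sc <- sim_scenario(n_individuals = n, n_cohorts = 2L, n_years = 5L,
                     psi_by_age = psi, seed = seed)
  sim <- simulate_encounters(sc)
  ds <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = seed + 1L)
  list(scenario = sc, sim = sim, data = as_mvms_data(ds))
}

# closed-form Deming (orthogonal) slope, written out independently
deming_oracle <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# structural EIV negative log-likelihood (test-side copy for invariants)
eiv_nll_oracle <- function(par, x, y, sx, sy) {
  a <- par[1L]; b <- par[2L]; mu <- par[3L]; t2 <- exp(par[4L])
  v11 <- t2 + sx^2; v22 <- b^2 * t2 + sy^2; v12 <- b * t2
  dt <- v11 * v22 - v12^2
  dx <- x - mu; dy <- y - a - b * mu
  0.5 * sum(2 * log(2 * pi) + log(dt) +
            (v22 * dx^2 - 2 * v12 * dx * dy + v11 * dy^2) / dt)
}
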