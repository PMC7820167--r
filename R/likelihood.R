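#' Forward-algorithm log-likelihood for one capture history
#'
#' Computes the hidden-Markov log-probability of one robust-design capture
#' history conditional on release in the unweaned state (Cormack-Jolly-Seber
#' conditioning). Latent states are S (alive, unweaned), W (alive, weaned;
#' absorbing) and D (dead; absorbing). Between primaries the animal survives
#' with probability `phi` and, given survival, weans with probability `psi`.
#' Within a primary, the animal is seen at all with probability `p` (`p_weaned`
#' for a weaned animal); each of the retained secondary codes of a truly
#' unweaned seen animal is "S" with probability `delta` and "u" otherwise,
#' while a weaned animal can only produce "u" codes, so the probability of at
#' least one definitive code among `ns` sightings is `1 - (1 - delta)^ns`.
#'
#' @param seen logical vector over primaries: seen at all in that primary.
#' @param nS,nu integer vectors over primaries: number of retained "S" and
#'   "u" codes (at most five in total per primary).
#' @param release index of the release primary; occasions before it are
#'   ignored and the release observation itself is conditioned on.
#' @param phi,psi numeric vectors over the intervals between primaries
#'   (length one less than the number of primaries), or scalars.
#' @param p,delta,p_weaned numeric vectors over primaries or scalars;
#'   `p_weaned` defaults to `p`.
#' @return the log-likelihood (log of a probability in (0, 1]).
#' @examples
#' # release-only history: probability 1
#' forward_loglik(seen = c(TRUE, FALSE), nS = c(1, 0), nu = c(0, 0),
#'                release = 1, phi = 0.8, psi = 0.5, p = 0, delta = 0.3)
#' @export
forward_loglik <- function(seen, nS, nu, release = 1L, phi, psi, p, delta,
                           p_weaned = p) {
  TT <- length(seen)
  stopifnot(length(nS) == TT, length(nu) == TT, release >= 1L, release <= TT)
  phi <- rep_len(phi, max(TT - 1L, 1L))
  psi <- rep_len(psi, max(TT - 1L, 1L))
  p <- rep_len(p, TT)
  p_weaned <- rep_len(p_weaned, TT)
  delta <- rep_len(delta, TT)

  aS <- 1; aW <- 0; aD <- 0
  ll <- 0
  if (release < TT) for (t in seq.int(release + 1L, TT)) {
    s2 <- aS * phi[t - 1L] * (1 - psi[t - 1L])
    w2 <- aS * phi[t - 1L] * psi[t - 1L] + aW * phi[t - 1L]
    d2 <- aD + (aS + aW) * (1 - phi[t - 1L])
    if (seen[t]) {
      oS <- p[t] * delta[t]^nS[t] * (1 - delta[t])^nu[t]
      oW <- if (nS[t] > 0L) 0 else p_weaned[t]
      oD <- 0
    } else {
      oS <- 1 - p[t]
      oW <- 1 - p_weaned[t]
      oD <- 1
    }
    aS <- s2 * oS; aW <- w2 * oW; aD <- d2 * oD
    tot <- aS + aW + aD
    if (tot <= 0) return(-Inf)
    ll <- ll + log(tot)
    aS <- aS / tot; aW <- aW / tot; aD <- aD / tot
  }
  ll
}

# vectorised dataset log-likelihood given slot probability matrices
forward_loglik_all <- function(data, pr) {
  n <- data$n; TT <- data$T
  release <- data$release
  seen <- data$seen; nS <- data$nS; nu <- data$nu
  aS <- as.numeric(release == 1L)
  aW <- numeric(n); aD <- numeric(n)
  ll <- numeric(n)
  for (t in seq_len(TT)[-1L]) {
    act <- which(release < t)
    if (length(act)) {
      phiS <- pr$phi_S[act, t - 1L]; phiW <- pr$phi_W[act, t - 1L]
      psi <- pr$psi_S[act, t - 1L]
      s2 <- aS[act] * phiS * (1 - psi)
      w2 <- aS[act] * phiS * psi + aW[act] * phiW
      d2 <- aD[act] + aS[act] * (1 - phiS) + aW[act] * (1 - phiW)
      sn <- seen[act, t]
      kS <- nS[act, t]; ku <- nu[act, t]
      pS <- pr$p_S[act, t]; pW <- pr$p_W[act, t]
      dl <- pr$delta_S[act, t]
      oS <- ifelse(sn, pS * dl^kS * (1 - dl)^ku, 1 - pS)
      oW <- ifelse(sn, ifelse(kS > 0L, 0, pW), 1 - pW)
      oD <- as.numeric(!sn)
      aS[act] <- s2 * oS; aW[act] <- w2 * oW; aD[act] <- d2 * oD
      tot <- aS[act] + aW[act] + aD[act]
      ll[act] <- ll[act] + log(tot)
      bad <- tot <= 0
      tot[bad] <- 1
      aS[act] <- aS[act] / tot; aW[act] <- aW[act] / tot; aD[act] <- aD[act] / tot
    }
    rel <- release == t
    aS[rel] <- 1; aW[rel] <- 0; aD[rel] <- 0
  }
  ll
}

#' Dataset log-likelihood at a given coefficient vector
#'
#' Sum of [forward_loglik()] contributions over all animals, computed from a
#' fitted or prospective model structure.
#'
#' @param fit an `mvms_fit` (or the `prep`/`data` pair stored inside one).
#' @param theta coefficient vector on the link scale; defaults to the MLE.
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(fit, theta = stats::coef(fit)) {
  stopifnot(inherits(fit, "mvms_fit"))
  if (length(theta) != fit$prep$k)
    stop(sprintf("theta has length %d; model has %d free coefficients",
                 length(theta), fit$prep$k), call. = FALSE)
  sum(forward_loglik_all(fit$data, slot_probs(fit$prep, theta)))
}
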