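#' Exact neutral-drift fixation probability of a configuration
#'
#' Under neutral drift (`delta = 0`) the death-birth process is a
#' voter-model-like martingale in the reproductive-value-weighted fraction
#' of cooperators, so the fixation probability of a binary configuration
#' `xi` is exactly its RV-weighted average `sum_i pi_i xi_i`.
#'
#' @param net a [static_network()].
#' @param xi binary vector (1 = cooperator) on the nodes of `net`.
#' @return the fixation probability.
#' @export
neutral_fixation_config <- function(net, xi) {
  if (!all(xi %in% c(0, 1))) stop("'xi' must be binary")
  rv_weighted_value(net, xi)
}

# tie tolerance for promotion verdicts on floating-point inputs
.neutral_tol <- 1e-12

promotion_verdict <- function(rho_T, rho_S) {
  if (abs(rho_T - rho_S) <= .neutral_tol) list(promotes = FALSE, tie = TRUE)
  else list(promotes = rho_T > rho_S, tie = FALSE)
}

#' Neutral-drift fixation probability of a sequential temporal network
#'
#' Under the fast-evolution regime (each snapshot evolves to absorption
#' before the next newcomers arrive), fixation of cooperation on the whole
#' temporal network requires fixation in every snapshot, giving the exact
#' chain product
#' \deqn{\rho_T = \rho_{G(1)}^{\mu} \prod_{l=2}^{L} \rho_{G(l)}^{a^{(l-1)}},}
#' where each factor is the RV-weighted value of the previous snapshot's
#' node set on the current snapshot.  Works for arbitrary weights and for
#' edges internal to a newcomer batch.
#'
#' @param T a [seq_temporal_network()].
#' @return a list with `rho_T`, `rho_S = 1/N`, the per-transition
#'   `factors`, a `promotes` verdict (`rho_T > rho_S`) and a `tie` flag.
#' @export
neutral_chain <- function(T) {
  fa <- T$schedule$first_active
  W <- T$net$W
  factors <- numeric(0)
  if (T$L > 1) {
    for (l in 2:T$L) {
      act <- which(fa <= l)
      old <- which(fa <= l - 1)
      if (length(old) == length(act)) { factors <- c(factors, 1); next }
      Wl <- W[act, act, drop = FALSE]
      w <- Matrix::rowSums(Wl)
      factors <- c(factors, sum(w[act %in% old]) / sum(w))
    }
  }
  m1 <- sum(fa == 1)
  rho_T <- prod(factors) / m1
  rho_S <- 1 / T$n
  c(list(rho_T = rho_T, rho_S = rho_S, factors = factors),
    promotion_verdict(rho_T, rho_S))
}

#' Closed-form neutral growth rule for a single transition
#'
#' For an unweighted (or weighted) two-snapshot growth step with no edges
#' among the newcomers, the neutral chain value has the closed form
#' `rho_T = (1/m) (m k1 + dK) / (m k1 + 2 dK)` against `rho_S = 1/(m+dm)`,
#' and the promotion verdict reduces to one of two printed conditions:
#' a large newcomer batch (`dm >= m`) always promotes, and a small batch
#' promotes iff `dK/dm < m k1 / (m - dm)`.  For `dm << m` the bound tends
#' to `k1`.
#'
#' @param m oldtimer count (at least 2).
#' @param k1 average degree (or, with `weighted = TRUE`, average node
#'   strength) of the first snapshot.
#' @param dm newcomer count.
#' @param dK total weight of newcomer-oldtimer edges.
#' @param weighted flag only affecting how `k1` is documented; the formula
#'   is identical with strengths in place of degrees.
#' @return a list with `rho_T`, `rho_S`, `promotes`, `tie` and `rule`
#'   (`"large-batch"` or `"bounded-edges"` when promoting).
#' @export
closed_form_L2 <- function(m, k1, dm, dK, weighted = FALSE) {
  stopifnot(m >= 2, dm >= 1, dK > 0, k1 > 0)
  rho_T <- (m * k1 + dK) / (m * k1 + 2 * dK) / m
  rho_S <- 1 / (m + dm)
  rule <- if (dm >= m) "large-batch"
          else if (dK / dm < m * k1 / (m - dm)) "bounded-edges"
          else "none"
  c(list(rho_T = rho_T, rho_S = rho_S, rule = rule),
    promotion_verdict(rho_T, rho_S))
}

#' Closed-form neutral rule with internal newcomer edges
#'
#' Generalizes [closed_form_L2()] to an unweighted transition whose `dm`
#' newcomers carry `g1` edges among themselves and `g2` edges to the
#' oldtimers: `rho_T = (1/m) (m k1 + g2) / (m k1 + 2 g2 + 2 g1)`.
#' The verdict reports which of the three printed cases holds.
#'
#' @inheritParams closed_form_L2
#' @param g1 total number of internal (newcomer-newcomer) edges.
#' @param g2 total number of newcomer-oldtimer edges.
#' @return as [closed_form_L2()], with `rule` in
#'   `"dense-internal"` / `"large-batch"` / `"bounded-edges"` / `"none"`.
#' @export
closed_form_internal <- function(m, k1, dm, g1, g2) {
  stopifnot(m >= 2, dm >= 1, g2 > 0, g1 >= 0, k1 > 0)
  rho_T <- (m * k1 + g2) / (m * k1 + 2 * g2 + 2 * g1) / m
  rho_S <- 1 / (m + dm)
  half <- dm * k1 / 2
  rule <- if (g1 >= half && dm > m && g2 > (2 * m * g1 - m * dm * k1) / (dm - m))
    "dense-internal"
  else if (g1 < half && dm >= m) "large-batch"
  else if (g1 < half && dm < m && g2 < (m * dm * k1 - 2 * m * g1) / (m - dm))
    "bounded-edges"
  else "none"
  c(list(rho_T = rho_T, rho_S = rho_S, rule = rule), promotion_verdict(rho_T, rho_S))
}

#' Closed-form neutral chain for arbitrary length
#'
#' For an unweighted sequential temporal network whose newcomers never link
#' to each other, the chain value depends only on the per-snapshot node
#' counts `m_l` and average degrees `k_l`:
#' \deqn{\rho_T = \frac{1}{m_1} \prod_{l=2}^{L}
#'   \frac{m_{l-1} k_{l-1} + m_l k_l}{2 m_l k_l}.}
#'
#' @param m integer vector of snapshot sizes (strictly increasing after
#'   equal entries are dropped).
#' @param k numeric vector of snapshot average degrees (`m_l k_l` must be
#'   the degree sum, i.e. twice the edge count).
#' @return the fixation probability `rho_T`.
#' @export
closed_form_chain <- function(m, k) {
  stopifnot(length(m) == length(k), length(m) >= 1)
  d <- m * k
  if (any(diff(m) < 0) || any(diff(d) < 0))
    stop("snapshot sizes and degree sums must be non-decreasing")
  if (length(m) == 1) return(1 / m)
  prod((d[-length(d)] + d[-1]) / (2 * d[-1])) / m[1]
}

#' Deterministic neutral fixation probability at finite switching time
#'
#' In the finite-timescale regime each of the snapshots `1..L-1` runs
#' exactly `g` death-birth updates before the next newcomers (defectors)
#' arrive, and the final snapshot runs to absorption.  Under neutral drift
#' one update maps expected states linearly,
#' `E[x'] = ((n-1)/n) x + (1/n) p^(1) x` on the `n` active nodes, so the
#' fixation probability can be propagated exactly without simulation:
#' start from expectation `1/m_1` on the first snapshot's nodes, apply `g`
#' linear updates per intermediate snapshot, and return the RV-weighted
#' value on the final snapshot.
#'
#' @param T a [seq_temporal_network()].
#' @param g number of updates per intermediate snapshot (`g >= 0`).
#' @return the fixation probability.
#' @export
neutral_finite_g <- function(T, g) {
  stopifnot(g >= 0, g == round(g))
  fa <- T$schedule$first_active
  W <- T$net$W
  x <- numeric(T$n)
  x[fa == 1] <- 1 / sum(fa == 1)
  if (T$L > 1 && g > 0) {
    for (l in seq_len(T$L - 1)) {
      act <- which(fa <= l)
      n <- length(act)
      Wl <- W[act, act, drop = FALSE]
      P <- Wl / Matrix::rowSums(Wl)
      xa <- x[act]
      for (s in seq_len(g)) xa <- ((n - 1) / n) * xa + as.numeric(P %*% xa) / n
      x[act] <- xa
    }
  }
  rv_weighted_value(T$net, x)
}
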