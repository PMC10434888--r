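# Mean-field approximation of weak-selection fixation probabilities.
#
# All quantities are built from structural summaries only -- node-strength
# moments mu1, mu2, the return weight Lambda, and for a configuration start
# the matrix t_ij = N (xihat - xi_i xi_j) / 2 with its contractions B0 and
# C_k = sum_ij w_i p^(k)_ij t_ij -- so no linear systems are solved.

#' Configuration statistics for the mean-field expansion
#'
#' @param net a [static_network()].
#' @param xi binary configuration on the nodes.
#' @return a list with the matrix `t`, and scalars `B0`, `C0`, `C1`, `C2`.
#' @export
config_stats <- function(net, xi) {
  if (length(xi) != net$n) stop("configuration length mismatch")
  wq <- walk_probs(net, 2)
  w <- node_strengths(net)
  xihat <- sum(wq$pi * xi)
  tmat <- net$n * (xihat - outer(xi, xi)) / 2
  list(t = tmat,
       B0 = sum(outer(wq$pi, wq$pi) * tmat),
       C0 = sum(w * diag(tmat)),
       C1 = sum(w * rowSums(wq$P[[2]] * tmat)),
       C2 = sum(w * rowSums(wq$P[[3]] * tmat)))
}

#' Mean-field gamma terms, uniform initialization
#'
#' The three structural coefficients entering the mean-field first-order
#' term for a uniformly placed single cooperator:
#' `gamma1 = N mu1^2/(2 mu2) - 1/2`, `gamma2 = N mu1^2/(2 mu2) - 1`,
#' `gamma3 = N mu1^2/(2 mu2) + Lambda mu1/(2 mu2) - 3/2`.  The fixation
#' probability expands as
#' `rho ~ 1/N + (delta/N) (-c gamma2 + b (gamma3 - gamma1))`.
#'
#' @param net a [static_network()].
#' @return named vector `c(g1, g2, g3)`.
#' @export
gamma_uniform <- function(net) {
  wq <- walk_probs(net, 2)
  base <- net$n * wq$mu1^2 / (2 * wq$mu2)
  c(g1 = base - 1 / 2,
    g2 = base - 1,
    g3 = base + wq$Lambda * wq$mu1 / (2 * wq$mu2) - 3 / 2)
}

#' Mean-field gamma terms for a configuration start
#'
#' @inheritParams config_stats
#' @return named vector `c(g1, g2, g3)`; the fixation probability expands
#'   as `rho ~ xihat + (delta/N) (-c g2 + b (g3 - g1))`.
#' @export
gamma_config <- function(net, xi) {
  wq <- walk_probs(net, 2)
  cs <- config_stats(net, xi)
  base <- cs$B0 * net$n * wq$mu1^2 / wq$mu2
  nm <- net$n * wq$mu1
  c(g1 = base - cs$C0 / nm,
    g2 = base - (cs$C0 + cs$C1) / nm,
    g3 = base + cs$B0 * wq$mu1 * wq$Lambda / wq$mu2 -
         (cs$C0 + cs$C1 + cs$C2) / nm)
}

#' Mean-field fixation probability
#'
#' First-order expansion in the selection intensity: neutral value plus
#' `(delta/N) (-c gamma2 + b (gamma3 - gamma1))`, clipped to `[0, 1]` with
#' a warning flag when the linear prediction exits the interval (the
#' expansion is then being used outside its range).
#'
#' @param net a [static_network()].
#' @param init `"uniform"` or a binary configuration.
#' @param b,c,delta game parameters (`delta >= 0`).
#' @return the approximate fixation probability, with attribute
#'   `clipped = TRUE` when clipping occurred.
#' @export
mf_fixation <- function(net, init = "uniform", b, c, delta) {
  stopifnot(delta >= 0)
  if (identical(init, "uniform")) {
    g <- gamma_uniform(net)
    rho0 <- 1 / net$n
  } else {
    g <- gamma_config(net, init)
    rho0 <- neutral_fixation_config(net, init)
  }
  rho <- rho0 + (delta / net$n) * (-c * g[["g2"]] + b * (g[["g3"]] - g[["g1"]]))
  if (rho < 0 || rho > 1)
    structure(min(max(rho, 0), 1), clipped = TRUE)
  else rho
}

#' Mean-field critical benefit-to-cost ratio (uniform start)
#'
#' `(N mu1^2 - 2 mu2) / (Lambda mu1 - 2 mu2)`.  Exact for unweighted
#' regular graphs, where it reduces to `k (N-2) / (N - 2k)`.
#'
#' @param net a [static_network()].
#' @return the ratio; `Inf` with attribute `boundary = TRUE` if the
#'   denominator vanishes.
#' @export
mf_critical_uniform <- function(net) {
  wq <- walk_probs(net, 2)
  den <- wq$Lambda * wq$mu1 - 2 * wq$mu2
  if (abs(den) < 1e-12) return(structure(Inf, boundary = TRUE))
  (net$n * wq$mu1^2 - 2 * wq$mu2) / den
}

#' Mean-field critical ratio for a configuration start
#'
#' The root in `b/c` of the mean-field first-order bracket,
#' `gamma2 / (gamma3 - gamma1)`.
#'
#' @inheritParams config_stats
#' @return the ratio; errors on an absorbing configuration.
#' @export
mf_critical_config <- function(net, xi) {
  if (all(xi == 0) || all(xi == 1))
    stop("critical ratio undefined for an absorbing configuration")
  g <- gamma_config(net, xi)
  den <- g[["g3"]] - g[["g1"]]
  if (abs(den) < 1e-12) return(structure(Inf, boundary = TRUE))
  g[["g2"]] / den
}

# per-snapshot mean-field pieces shared by the temporal aggregate
mf_snapshot_terms <- function(T) {
  fa <- T$schedule$first_active
  out <- data.frame(l = integer(0), n = integer(0), A = numeric(0),
                    g2 = numeric(0), g31 = numeric(0))
  for (l in seq_len(T$L)) {
    G <- snapshot(T, l)
    if (l == 1) {
      A <- 1 / G$n
      g <- gamma_uniform(G)
    } else {
      act <- active_nodes(T, l)
      prev <- active_nodes(T, l - 1)
      xi <- as.numeric(act %in% prev)
      A <- neutral_fixation_config(G, xi)
      g <- if (all(xi == 1)) c(g1 = 0, g2 = 0, g3 = 0) else gamma_config(G, xi)
    }
    out[nrow(out) + 1, ] <- list(l, G$n, A, g[["g2"]], g[["g3"]] - g[["g1"]])
  }
  out
}

#' Mean-field critical ratio of a sequential temporal network
#'
#' Aggregates the per-snapshot mean-field brackets with the neutral chain
#' weights: each snapshot `l` contributes its `gamma` terms divided by its
#' own size, weighted by the product of all other snapshots' neutral
#' factors.
#'
#' @param T a [seq_temporal_network()].
#' @return the approximate critical ratio; `Inf` with a `boundary`
#'   attribute if the aggregated denominator vanishes.
#' @export
mf_critical_temporal <- function(T) {
  tm <- mf_snapshot_terms(T)
  Atilde <- vapply(seq_len(T$L), function(l) prod(tm$A[-l]), 0)
  num <- sum(Atilde * tm$g2 / tm$n)
  den <- sum(Atilde * tm$g31 / tm$n)
  if (abs(den) < 1e-12) return(structure(Inf, boundary = TRUE))
  num / den
}

#' Mean-field two-snapshot comparison under tied neutral values
#'
#' Evaluates, with mean-field coefficients, whether the first-order term
#' of the temporal network exceeds that of its static counterpart at the
#' given `(b, c)`:
#' `A1 (-c C2 + b B2) + A2 (-c C1 + b B1) > (-c CS + b BS)`, where
#' `(C, B) = (gamma2, gamma3 - gamma1) / n` for each network and the `A`s
#' are the neutral chain factors.
#'
#' @param T a [seq_temporal_network()] with `L = 2`.
#' @param b,c game parameters.
#' @return `TRUE` if growth is predicted to help cooperation at `(b, c)`.
#' @export
mf_compare_L2 <- function(T, b, c) {
  if (T$L != 2) stop("mf_compare_L2() needs a two-snapshot network")
  tm <- mf_snapshot_terms(T)
  gS <- gamma_uniform(T$net)
  lhs <- tm$A[2] * (-c * tm$g2[1] + b * tm$g31[1]) / tm$n[1] +
         tm$A[1] * (-c * tm$g2[2] + b * tm$g31[2]) / tm$n[2]
  rhs <- (-c * gS[["g2"]] + b * (gS[["g3"]] - gS[["g1"]])) / T$n
  lhs > rhs
}
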