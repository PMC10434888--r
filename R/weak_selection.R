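# Exact weak-selection machinery.
#
# Everything here rests on two linear systems over unordered node pairs:
#
#  * coalescence times   2 tau_ab - sum_k p_ak tau_kb - sum_k p_bk tau_ak = 2
#    with tau_aa = 0;
#  * configuration sums  2 S_ab - sum_k p_ak S_kb - sum_k p_bk S_ak
#                          = N (xihat - xi_a xi_b)  for a != b,
#    whose diagonal solves (I - P) s = N (xihat - xi) with the stationary
#    average of s pinned to zero.
#
# S_ab is the summed deviation of the pair correlation E[x_a x_b] from its
# martingale limit along the neutral trajectory started at xi; for the
# uniform single-cooperator average it reduces to tau/2.  The first-order
# coefficients of the fixation probability follow by summing the selection
# drift of the RV-weighted cooperator fraction over the neutral trajectory:
#   d rho / d delta = (1/N) (-c C + b B)
#   C = tr(Pi P S P')   - tr(Pi S)
#   B = tr(Pi P S P2')  - tr(Pi P S)
# with Pi = diag(pi).  For the uniform initialization reversibility gives
# C = t2/2 and B = (t3 - t1)/2, hence the classic critical ratio
# (b/c)* = t2 / (t3 - t1).

# index bookkeeping for unordered pairs of 1..n
pair_index <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  lut <- matrix(0L, n, n)
  lut[idx] <- seq_len(nrow(idx))
  lut <- lut + t(lut)
  list(idx = idx, lut = lut)
}

# LHS matrix of the pair system (shared by tau and S solves); the diagonal
# entries of the unknown matrix are moved to the RHS by the caller.
pair_system_matrix <- function(P) {
  n <- nrow(P)
  px <- pair_index(n)
  np <- nrow(px$idx)
  A <- matrix(0, np, np)
  for (r in seq_len(np)) {
    a <- px$idx[r, 1]; b <- px$idx[r, 2]
    A[r, r] <- A[r, r] + 2
    for (k in seq_len(n)) {
      if (P[a, k] > 0 && k != b) A[r, px$lut[k, b]] <- A[r, px$lut[k, b]] - P[a, k]
      if (P[b, k] > 0 && k != a) A[r, px$lut[k, a]] <- A[r, px$lut[k, a]] - P[b, k]
    }
  }
  A
}

solve_pair_system <- function(P, rhs_fun, diag_vals) {
  # rhs_fun(a, b) gives the inhomogeneous term; diag_vals are the known
  # diagonal entries entering through walks that land on the partner node
  n <- nrow(P)
  px <- pair_index(n)
  np <- nrow(px$idx)
  A <- pair_system_matrix(P)
  rhs <- numeric(np)
  for (r in seq_len(np)) {
    a <- px$idx[r, 1]; b <- px$idx[r, 2]
    rhs[r] <- rhs_fun(a, b) + P[a, b] * diag_vals[b] + P[b, a] * diag_vals[a]
  }
  x <- solve(A, rhs)
  M <- diag(diag_vals)
  M[px$idx] <- x
  M[px$idx[, 2:1, drop = FALSE]] <- x
  M
}

#' Pairwise coalescence times of the edge-weighted random walk
#'
#' `tau_ij` is the expected number of update steps until two coalescing
#' random walkers started at `i` and `j` first meet, when at each step one
#' of the two walkers (chosen with probability 1/2) takes one edge-weighted
#' step.  These times are the building blocks of the exact weak-selection
#' coefficients.  Also returns the remeeting summaries
#' `t_n = sum_i pi_i sum_j p^(n)_ij tau_ij` for `n = 1, 2, 3`.
#'
#' @param net a connected [static_network()].
#' @return a list with the symmetric matrix `tau` and scalars `t1`, `t2`,
#'   `t3`.
#' @export
coalescence_times <- function(net) {
  wq <- walk_probs(net, 3)
  P <- wq$P[[2]]
  tau <- solve_pair_system(P, function(a, b) 2, numeric(net$n))
  tns <- vapply(1:3, function(k) sum(wq$pi * rowSums(wq$P[[k + 1]] * tau)), 0)
  list(tau = tau, t1 = tns[1], t2 = tns[2], t3 = tns[3])
}

#' Critical benefit-to-cost ratio of a static network (uniform start)
#'
#' The benefit-to-cost ratio at which the first-order (in `delta`) term of
#' the fixation probability of a uniformly placed single cooperator changes
#' sign: `(b/c)* = t2 / (t3 - t1)`.  Low positive values favour
#' cooperation; negative values indicate a spite-favouring structure.
#'
#' @param net a connected [static_network()] with at least 3 nodes.
#' @return the critical ratio; `Inf` with attribute `boundary = TRUE` when
#'   `t3 - t1` vanishes (structures exactly at the spite/cooperation
#'   boundary).
#' @export
critical_ratio_static <- function(net) {
  ct <- coalescence_times(net)
  denom <- ct$t3 - ct$t1
  if (abs(denom) < 1e-12)
    return(structure(Inf, boundary = TRUE))
  ct$t2 / denom
}

# S-matrix of summed pair-correlation deviations for configuration xi
config_pair_sums <- function(net, xi) {
  wq <- walk_probs(net, 1)
  P <- wq$P[[2]]
  pi <- wq$pi
  n <- net$n
  xihat <- sum(pi * xi)
  # diagonal: (I - P) s = N (xihat - xi), sum_i pi_i s_i = 0
  M <- rbind(diag(n) - P, pi)
  s <- qr.solve(M, c(n * (xihat - xi), 0))
  solve_pair_system(P, function(a, b) n * (xihat - xi[a] * xi[b]), s)
}

first_order_from_S <- function(net, S) {
  wq <- walk_probs(net, 2)
  P <- wq$P[[2]]; P2 <- wq$P[[3]]; pi <- wq$pi
  PS <- P %*% S
  C <- sum(pi * diag(PS %*% t(P))) - sum(pi * diag(S))
  B <- sum(pi * diag(PS %*% t(P2))) - sum(pi * diag(PS))
  list(C = C, B = B)
}

#' Exact first-order fixation-probability coefficients
#'
#' Returns the pair `(C, B)` such that under death-birth updating the
#' fixation probability expands as
#' `rho(delta) = rho(0) + (delta / N) (-c C + b B) + O(delta^2)`.
#' For the uniform initialization `C = t2/2` and `B = (t3 - t1)/2`; for a
#' configuration start the coefficients come from the configuration pair
#' system (see the header of this file).
#'
#' @param net a connected [static_network()].
#' @param init either the string `"uniform"` or a binary configuration
#'   vector.
#' @return a list with `C`, `B`, the critical ratio `bc = C/B` (`Inf` with
#'   a `boundary` attribute when `|B|` underflows), and `absorbing = TRUE`
#'   with zero coefficients when `init` is all-cooperator or all-defector.
#' @export
first_order_static <- function(net, init = "uniform") {
  if (identical(init, "uniform")) {
    ct <- coalescence_times(net)
    out <- list(C = ct$t2 / 2, B = (ct$t3 - ct$t1) / 2, absorbing = FALSE)
  } else {
    xi <- init
    if (!all(xi %in% c(0, 1))) stop("'init' must be \"uniform\" or a binary vector")
    if (length(xi) != net$n) stop("configuration length mismatch")
    if (all(xi == 0) || all(xi == 1))
      return(list(C = 0, B = 0, bc = NaN, absorbing = TRUE))
    out <- c(first_order_from_S(net, config_pair_sums(net, xi)),
             list(absorbing = FALSE))
  }
  out$bc <- if (abs(out$B) < 1e-12) structure(Inf, boundary = TRUE) else out$C / out$B
  out
}

#' Exact first-order coefficients of a sequential temporal network
#'
#' Differentiating the chain product of per-snapshot fixation
#' probabilities at `delta = 0` gives
#' `d rho_T / d delta = sum_l Atilde_l * d rho_l / d delta`, where
#' `Atilde_l` is the product of all neutral factors except snapshot `l`'s.
#' Snapshot 1 uses the uniform initialization; snapshot `l > 1` the
#' configuration of the previous snapshot's node set.  The result is
#' scaled so that `d rho_T / d delta = (1/N) (-c C + b B)` with `N` the
#' final population size, hence `bc = C/B` is the critical ratio of the
#' temporal network.
#'
#' @param T a [seq_temporal_network()].
#' @return a list with aggregated `C`, `B`, critical ratio `bc`, and a
#'   data frame `per_snapshot` of neutral factors and per-snapshot
#'   coefficients.
#' @export
first_order_temporal <- function(T) {
  fa <- T$schedule$first_active
  # neutral factor of each snapshot: A_1 = 1/m_1, A_l = RV weight of the
  # previous active set on snapshot l (no-op transitions contribute 1)
  snaps <- list(); inits <- list(); Avals <- numeric(0)
  for (l in seq_len(T$L)) {
    G <- snapshot(T, l)
    act <- active_nodes(T, l)
    if (l == 1) {
      A <- 1 / G$n
      init <- "uniform"
    } else {
      prev <- active_nodes(T, l - 1)
      init <- as.numeric(act %in% prev)
      A <- neutral_fixation_config(G, init)
    }
    snaps[[l]] <- G; inits[[l]] <- init; Avals[l] <- A
  }
  Atilde <- vapply(seq_len(T$L), function(l) prod(Avals[-l]), 0)
  Cl <- numeric(T$L); Bl <- numeric(T$L)
  for (l in seq_len(T$L)) {
    if (!identical(inits[[l]], "uniform") &&
        (all(inits[[l]] == 1) || all(inits[[l]] == 0))) next  # no-op transition
    fo <- first_order_static(snaps[[l]], inits[[l]])
    Cl[l] <- fo$C; Bl[l] <- fo$B
  }
  ns <- vapply(snaps, function(G) G$n, 0)
  C <- T$n * sum(Atilde * Cl / ns)
  B <- T$n * sum(Atilde * Bl / ns)
  bc <- if (abs(B) < 1e-12) structure(Inf, boundary = TRUE) else C / B
  list(C = C, B = B, bc = bc,
       per_snapshot = data.frame(l = seq_len(T$L), n = ns, A = Avals,
                                 Atilde = Atilde, C = Cl, B = Bl))
}

#' Critical benefit-to-cost ratio of a sequential temporal network
#'
#' @param T a [seq_temporal_network()].
#' @return `first_order_temporal(T)$bc`.
#' @export
critical_ratio_temporal <- function(T) first_order_temporal(T)$bc

#' Does growth promote cooperation at given game parameters?
#'
#' Compares the temporal network with its static counterpart: first by the
#' exact neutral-drift fixation probabilities; if those tie, by the exact
#' first-order terms at the given `(b, c)`.  Also reports both critical
#' ratios with their sign-aware ordering (a temporal network is more
#' favourable when `bc_S > bc_T > 0` or `bc_T > 0 > bc_S`).
#'
#' @param T a [seq_temporal_network()].
#' @param b benefit (any sign).
#' @param c cost (positive).
#' @return a list with `verdict` (`"promotes"`, `"suppresses"` or
#'   `"equal"`), `order` (`"neutral"` or `"first-order"`), neutral values,
#'   both critical ratios and the first-order derivatives at `(b, c)`.
#' @export
compare_networks <- function(T, b, c) {
  stopifnot(c > 0)
  nc <- neutral_chain(T)
  foT <- first_order_temporal(T)
  foS <- first_order_static(T$net, "uniform")
  dT <- (-c * foT$C + b * foT$B) / T$n
  dS <- (-c * foS$C + b * foS$B) / T$n
  if (!nc$tie) {
    verdict <- if (nc$promotes) "promotes" else "suppresses"
    order <- "neutral"
  } else {
    order <- "first-order"
    verdict <- if (abs(dT - dS) <= 1e-12) "equal"
               else if (dT > dS) "promotes" else "suppresses"
  }
  list(verdict = verdict, order = order,
       rho_T_neutral = nc$rho_T, rho_S_neutral = nc$rho_S,
       bc_T = foT$bc, bc_S = foS$bc,
       drho_T = dT, drho_S = dS)
}
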