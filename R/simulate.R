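#' Donation-game and selection parameters
#'
#' @param b benefit delivered by a cooperator to a neighbour (any sign).
#' @param c cost paid by a cooperator per neighbour (positive).
#' @param delta selection intensity (`>= 0`); fitness is
#'   `F = 1 + delta * payoff` and must stay positive for all achievable
#'   payoffs, which requires `delta * max(|b| + c, |b|, c) < 1`.
#' @param g number of update rounds per intermediate snapshot: a positive
#'   integer for the finite-timescale regime, or `Inf` (default) for the
#'   fast-evolution regime in which every snapshot runs to absorption.
#' @return an object of class `game_params`.
#' @export
game_params <- function(b, c, delta = 0, g = Inf) {
  stopifnot(c > 0, delta >= 0)
  if (delta * max(abs(b) + c, abs(b), c) >= 1)
    stop("fitness 1 + delta*u can reach zero; reduce delta (need delta * max(|b|+c, |b|, c) < 1)")
  if (!identical(g, Inf)) stopifnot(g >= 1, g == round(g))
  structure(list(b = b, c = c, delta = delta, g = g), class = "game_params")
}

#' Edge-weighted average payoffs of the donation game
#'
#' `u_i = -c x_i + b sum_j p^(1)_ij x_j`: a cooperator pays `c` once (its
#' cost is averaged over neighbours) and every individual receives `b`
#' times the random-walk-weighted cooperator fraction of its neighbourhood.
#'
#' @param net a [static_network()].
#' @param x binary strategy vector (1 = cooperate).
#' @param params a [game_params()].
#' @return numeric payoff vector.
#' @export
payoffs <- function(net, x, params) {
  if (length(x) != net$n) stop("strategy vector length mismatch")
  P1 <- net$W / Matrix::rowSums(net$W)
  -params$c * x + params$b * as.numeric(P1 %*% x)
}

#' One death-birth update (reference implementation)
#'
#' A uniformly chosen individual adopts the strategy of a neighbour drawn
#' with probability proportional to the neighbour's fitness times the
#' connecting edge weight.  This plain-R single step exists for testing
#' and illustration; simulations use the compiled engine in
#' [estimate_fixation()].
#'
#' @inheritParams payoffs
#' @return the updated strategy vector.
#' @export
db_step <- function(net, x, params) {
  u <- payoffs(net, x, params)
  F <- 1 + params$delta * u
  if (any(F <= 0)) stop("non-positive fitness; reduce delta")
  i <- sample.int(net$n, 1)
  w <- as.numeric(net$W[i, ]) * F
  j <- sample.int(net$n, 1, prob = w)
  x[i] <- x[j]
  x
}

#' Monte-Carlo estimate of the fixation probability
#'
#' Repeats the growth-and-evolution process: a single cooperator appears
#' at a uniformly random node of the first snapshot in a population of
#' defectors; each snapshot evolves by death-birth updating (to absorption
#' when `params$g` is `Inf`, else for exactly `g` updates) and newcomers
#' enter as defectors; the run fixates when the final snapshot reaches the
#' all-cooperator state.  All-defector is globally absorbing and ends a
#' run immediately.
#'
#' @param T a [seq_temporal_network()] (use `L = 1` for a static network).
#' @param params a [game_params()].
#' @param n_runs number of independent runs.
#' @param seed optional integer seed (applied with [set.seed()]); identical
#'   seeds reproduce identical estimates bit for bit.
#' @param max_steps per-run safety cap on update steps.
#' @return an object of class `fixation_estimate`: a list with `p_hat`,
#'   `stderr`, `n_runs`, and mean absorbing times (in update steps)
#'   conditional on cooperation (`t_C`), on defection (`t_D`) and
#'   unconditional (`t_all`).
#' @export
estimate_fixation <- function(T, params, n_runs, seed = NULL, max_steps = 1e8) {
  stopifnot(inherits(T, "seq_temporal_network"), inherits(params, "game_params"),
            n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  fa <- T$schedule$first_active
  ord <- order(fa)
  W <- T$net$W[ord, ord, drop = FALSE]
  W <- methods::as(W, "CsparseMatrix")
  # CSR of the symmetric matrix via its CSC slots
  ptr <- W@p
  nbr <- W@i
  wgt <- W@x
  fa_sorted <- fa[ord]
  snap_sizes <- vapply(seq_len(T$L), function(l) sum(fa_sorted <= l), 0L)
  process <- if (identical(params$g, Inf)) 1L else 2L
  res <- .sim_engine(T$n, ptr, nbr, wgt, as.integer(fa_sorted),
                     as.integer(snap_sizes),
                     params$b, params$c, params$delta,
                     process, if (process == 1L) 0 else params$g,
                     as.integer(n_runs), max_steps)
  p <- res$n_fix / n_runs
  structure(list(p_hat = p,
                 stderr = sqrt(p * (1 - p) / n_runs),
                 n_runs = n_runs,
                 t_C = res$t_C, t_D = res$t_D, t_all = res$t_all),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("fixation estimate: p = %.4g (se %.2g, %d runs); mean steps %.4g\n",
              x$p_hat, x$stderr, x$n_runs, x$t_all))
  invisible(x)
}

#' Wrap a static network as a one-snapshot temporal network
#'
#' Convenience for simulating ordinary static-network dynamics with the
#' same engine.
#'
#' @param net a [static_network()].
#' @return a [seq_temporal_network()] with `L = 1`.
#' @export
as_static_chain <- function(net) {
  seq_temporal_network(net, activation_schedule(rep(1L, net$n), 1L))
}
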