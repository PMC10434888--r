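# Small networks used across the suite, built in code.

net_k2 <- function() static_network(matrix(c(0, 1, 1, 0), 2))

net_k <- function(n) static_network(matrix(1, n, n) - diag(n))

net_path <- function(n) static_network(data.frame(i = 1:(n - 1), j = 2:n))

net_star <- function(leaves) {
  static_network(data.frame(i = rep(1, leaves), j = 1 + seq_len(leaves)))
}

net_cycle <- function(n) static_network(data.frame(i = 1:n, j = c(2:n, 1)))

# random connected unweighted graph
rand_net <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && min(igraph::degree(g)) > 0)
      return(static_network(as.matrix(igraph::as_adjacency_matrix(g))))
  }
}

# random two-stage growth instance with the requested counts:
# G(1) = connected graph on m nodes with e1 edges, dm newcomers carrying
# g2 edges to oldtimers (each newcomer at least one) and g1 internal edges
rand_growth_instance <- function(m, e1, dm, g2, g1 = 0) {
  stopifnot(e1 >= m - 1, g2 >= dm, g2 <= dm * m)
  repeat {
    g <- igraph::sample_gnm(m, e1)
    if (igraph::is_connected(g)) break
  }
  W <- matrix(0, m + dm, m + dm)
  W[1:m, 1:m] <- as.matrix(igraph::as_adjacency_matrix(g))
  new_ids <- m + seq_len(dm)
  # one oldtimer edge per newcomer, then the remaining g2 - dm at random
  anchors <- sample.int(m, dm, replace = TRUE)
  for (v in seq_len(dm)) W[new_ids[v], anchors[v]] <- W[anchors[v], new_ids[v]] <- 1
  extra <- g2 - dm
  while (extra > 0) {
    v <- new_ids[sample.int(dm, 1)]; o <- sample.int(m, 1)
    if (W[v, o] == 0) { W[v, o] <- W[o, v] <- 1; extra <- extra - 1 }
  }
  if (g1 > 0) {
    pairs <- utils::combn(new_ids, 2)
    stopifnot(ncol(pairs) >= g1)
    take <- sample.int(ncol(pairs), g1)
    for (s in take) W[pairs[1, s], pairs[2, s]] <- W[pairs[2, s], pairs[1, s]] <- 1
  }
  net <- static_network(W)
  seq_temporal_network(net, activation_schedule(c(rep(1L, m), rep(2L, dm))))
}

# Brute-force fixation probability of configuration xi under death-birth
# updating at selection intensity delta, by solving the full 2^n absorbing
# Markov chain.  Independent of the package's analytic machinery; n <= 12.
rho_chain_exact <- function(net, xi, b, c, delta) {
  n <- net$n
  W <- as.matrix(net$W)
  P1 <- W / rowSums(W)
  S <- 2^n
  trans <- setdiff(0:(S - 1), c(0, S - 1))
  nt <- length(trans)
  pos <- integer(S); pos[trans + 1] <- seq_len(nt)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  rhs <- numeric(nt)
  for (t in seq_len(nt)) {
    s <- trans[t]
    x <- as.integer(intToBits(s))[1:n]
    u <- -c * x + b * as.vector(P1 %*% x)
    F <- 1 + delta * u
    row <- numeric(S); stay <- 0
    for (i in 1:n) {
      pr <- W[i, ] * F
      pr <- pr / sum(pr) / n
      for (j in which(pr > 0)) {
        if (x[j] == x[i]) stay <- stay + pr[j]
        else {
          s2 <- if (x[j] == 1) s + bitwShiftL(1L, i - 1L) else s - bitwShiftL(1L, i - 1L)
          row[s2 + 1] <- row[s2 + 1] + pr[j]
        }
      }
    }
    row[s + 1] <- row[s + 1] + stay
    for (s2 in which(row > 0) - 1) {
      if (s2 == S - 1) rhs[t] <- rhs[t] + row[s2 + 1]
      else if (s2 != 0) {
        ti <- c(ti, t); tj <- c(tj, pos[s2 + 1]); tx <- c(tx, row[s2 + 1])
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nt, nt))
  sol <- as.vector(Matrix::solve(Matrix::Diagonal(nt) - A, rhs))
  s0 <- sum(xi * 2^(seq_len(n) - 1))
  if (s0 == 0) 0 else if (s0 == S - 1) 1 else sol[pos[s0 + 1]]
}
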