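# Growth-schedule generators for the four synthetic families studied in
# the package: periodic square lattices grown in a clockwise spiral from a
# central 2x2 seed, random regular graphs grown in a random
# connectivity-preserving order, and preferential-attachment families
# (Barabasi-Albert and initial-attractiveness) whose construction order is
# the schedule itself.

#' Square-lattice temporal network (spiral growth)
#'
#' Builds a `side x side` square lattice with periodic boundaries and a
#' growth schedule: the central 2x2 block is active in the first snapshot,
#' then one node is activated per snapshot, clockwise ring by ring,
#' starting directly north of the seed's north-east cell.  The length is
#' `L = N - 3`.
#'
#' @param side lattice side (`>= 3`).
#' @return a [seq_temporal_network()].
#' @export
lattice_temporal <- function(side) {
  stopifnot(side >= 3)
  n <- side^2
  id <- function(r, c) (r %% side) * side + (c %% side) + 1
  ii <- integer(0); jj <- integer(0)
  for (r in 0:(side - 1)) for (cc in 0:(side - 1)) {
    ii <- c(ii, id(r, cc), id(r, cc))
    jj <- c(jj, id(r + 1, cc), id(r, cc + 1))
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  net <- static_network(as.matrix(W))
  r0 <- (side - 2) %/% 2; c0 <- r0
  seed <- c(id(r0, c0), id(r0, c0 + 1), id(r0 + 1, c0), id(r0 + 1, c0 + 1))
  active <- rep(FALSE, n); active[seed] <- TRUE
  ord <- integer(0)
  for (rad in seq_len(side)) {
    top <- r0 - rad; bot <- r0 + 1 + rad
    left <- c0 - rad; right <- c0 + 1 + rad
    path <- rbind(
      cbind(top, (c0 + 1):right),          # east along the top row
      cbind((top + 1):bot, right),         # south along the east side
      cbind(bot, (right - 1):left),        # west along the bottom row
      cbind((bot - 1):top, left),          # north along the west side
      cbind(top, (left + 1):c0))           # east back to the start
    for (p in seq_len(nrow(path))) {
      i <- id(path[p, 1], path[p, 2])
      if (!active[i]) { active[i] <- TRUE; ord <- c(ord, i) }
    }
    if (all(active)) break
  }
  fa <- integer(n)
  fa[seed] <- 1L
  fa[ord] <- 1L + seq_along(ord)
  seq_temporal_network(net, activation_schedule(fa))
}

# shared growth loop for the preferential-attachment families:
# attachment probability proportional to degree + a (a = 0 recovers the
# classic rich-get-richer rule)
pa_growth <- function(n, m, a, m0, seed = NULL) {
  stopifnot(m >= 1, m0 >= m, n > m0, a > -m)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  W[seq_len(m0), seq_len(m0)] <- 1
  diag(W) <- 0
  deg <- c(rep(m0 - 1, m0), rep(0, n - m0))
  for (v in (m0 + 1):n) {
    old <- seq_len(v - 1)
    targets <- sample(old, m, prob = deg[old] + a)
    W[v, targets] <- 1; W[targets, v] <- 1
    deg[targets] <- deg[targets] + 1
    deg[v] <- m
  }
  fa <- c(rep(1L, m0), 2L:(n - m0 + 1L))
  seq_temporal_network(static_network(W), activation_schedule(fa))
}

#' Barabasi-Albert temporal network
#'
#' Growth with preferential attachment, recorded as a schedule: snapshot 1
#' is a complete seed graph on `m0` nodes; each later snapshot adds one
#' node with `m` edges to existing nodes chosen with probability
#' proportional to degree.  Newcomers never link to each other, so the
#' closed-form neutral chain applies exactly.  `L = n - m0 + 1`.
#'
#' @param n final size.
#' @param m edges per newcomer.
#' @param m0 seed size (`>= m`, default `m`).
#' @param seed optional RNG seed.
#' @return a [seq_temporal_network()].
#' @export
ba_temporal <- function(n, m, m0 = max(m, 2), seed = NULL)
  pa_growth(n, m, 0, m0, seed)

#' Initial-attractiveness temporal network
#'
#' Like [ba_temporal()] but with attachment probability proportional to
#' `degree + a`; large `a` approaches uniform attachment and flattens the
#' degree distribution.
#'
#' @inheritParams ba_temporal
#' @param a initial attractiveness (`> -m`).
#' @export
attractiveness_temporal <- function(n, m, a, m0 = max(m, 2), seed = NULL)
  pa_growth(n, m, a, m0, seed)

# random activation order keeping every prefix connected: repeatedly pick a
# uniformly random node adjacent to the current prefix
random_connected_order <- function(net) {
  g <- as_igraph(net)
  n <- net$n
  adj <- igraph::as_adj_list(g)
  start <- sample.int(n, 1)
  ord <- start
  nb <- as.integer(adj[[start]])
  frontier <- rep(FALSE, n); frontier[nb] <- TRUE
  in_ord <- rep(FALSE, n); in_ord[start] <- TRUE
  while (length(ord) < n) {
    cand <- which(frontier)
    v <- if (length(cand) == 1) cand else sample(cand, 1)
    ord <- c(ord, v)
    in_ord[v] <- TRUE; frontier[v] <- FALSE
    nbv <- as.integer(adj[[v]])
    frontier[nbv[!in_ord[nbv]]] <- TRUE
  }
  ord
}

#' Random-regular temporal network
#'
#' A random `k`-regular static network grown in a uniformly random order
#' constrained to keep every prefix connected (each next node is drawn
#' uniformly from the neighbours of the already-active set).  Snapshot 1
#' holds the first two nodes; each later snapshot adds one node, so
#' `L = n - 1`.
#'
#' @param n final size (`n * k` must be even).
#' @param k degree.
#' @param seed optional RNG seed.
#' @return a [seq_temporal_network()].
#' @export
rr_temporal <- function(n, k, seed = NULL) {
  if ((n * k) %% 2 != 0) stop("n * k must be even for a k-regular graph")
  stopifnot(k >= 2, n > k)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_degseq(rep(k, n), method = "vl")
  net <- static_network(as.matrix(igraph::as_adjacency_matrix(g)))
  ord <- random_connected_order(net)
  schedule_from_order(net, ord, c(2, rep(1, n - 2)))
}

#' Neutral-drift scan over random-graph ensembles
#'
#' Samples random static networks (Erdos-Renyi, Watts-Strogatz with
#' rewiring probability 0.3, or Barabasi-Albert), grows each through a
#' random connectivity-preserving full-length schedule, derives shorter
#' schedules that keep the first and final snapshots and a uniform sample
#' of interior stages, and tabulates how often the temporal network beats,
#' ties or loses to its static counterpart under neutral drift.
#'
#' @param n_samples graphs per family.
#' @param L_values schedule lengths to evaluate (`1` allowed; `NA` entries
#'   are replaced by the full length).
#' @param families subset of `c("erdos_renyi", "watts_strogatz", "ba")`.
#' @param n_range,k_range ranges from which size and mean degree are drawn.
#' @param seed optional RNG seed.
#' @return a data frame with one row per family and length: fractions of
#'   samples with `rho_T` above, equal to and below `1/N`, and the mean
#'   `rho_T * N` ratio.
#' @export
ensemble_scan <- function(n_samples, L_values,
                          families = c("erdos_renyi", "watts_strogatz", "ba"),
                          n_range = c(20, 50), k_range = c(4, NA),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- expand.grid(family = families, L = L_values,
                     stringsAsFactors = FALSE)
  res$greater <- 0; res$equal <- 0; res$less <- 0; res$mean_ratio <- 0
  for (fam in families) {
    for (s in seq_len(n_samples)) {
      n <- sample(n_range[1]:n_range[2], 1)
      kmax <- if (is.na(k_range[2])) floor(n / 2) else k_range[2]
      k <- sample(k_range[1]:kmax, 1)
      net <- sample_static(fam, n, k)
      ord <- random_connected_order(net)
      for (r in which(res$family == fam)) {
        L <- res$L[r]
        if (is.na(L)) L <- n - 1
        L <- min(L, n - 1)
        T <- subsampled_schedule(net, ord, L)
        rho <- neutral_chain(T)
        cmp <- rho$rho_T * n - 1
        res$greater[r] <- res$greater[r] + (cmp > .neutral_tol)
        res$equal[r] <- res$equal[r] + (abs(cmp) <= .neutral_tol)
        res$less[r] <- res$less[r] + (cmp < -.neutral_tol)
        res$mean_ratio[r] <- res$mean_ratio[r] + rho$rho_T * n
      }
    }
  }
  res$greater <- res$greater / n_samples
  res$equal <- res$equal / n_samples
  res$less <- res$less / n_samples
  res$mean_ratio <- res$mean_ratio / n_samples
  res
}

sample_static <- function(family, n, k) {
  repeat {
    g <- switch(family,
      erdos_renyi = igraph::sample_gnp(n, min(k / (n - 1), 1)),
      watts_strogatz = igraph::sample_smallworld(1, n, max(1, round(k / 2)), 0.3),
      ba = igraph::sample_pa(n, m = max(1, round(k / 2)), directed = FALSE),
      stop("unknown family: ", family))
    g <- igraph::simplify(g)
    if (igraph::is_connected(g) && min(igraph::degree(g)) > 0)
      return(static_network(as.matrix(igraph::as_adjacency_matrix(g))))
  }
}

# length-L schedule sharing the first and final snapshots of the full-length
# one and a uniform sample of its interior stages
subsampled_schedule <- function(net, ord, L) {
  n <- net$n
  if (L == 1) return(as_static_chain(net))
  stages_full <- 2:n                       # prefix sizes of the full schedule
  interior <- setdiff(stages_full, c(2, n))
  keep <- sort(c(2, if (L > 2) sort(sample(interior, L - 2)), n))
  batch <- diff(c(0, keep))
  schedule_from_order(net, ord, batch)
}

#' Worked-example temporal networks
#'
#' Four small growing networks used throughout the documentation and the
#' test suite, transcribed from worked examples so that every printed
#' growth increment is reproduced exactly (the transcriptions are
#' validated at construction):
#' \describe{
#'   \item{`doubling`}{sizes 2 -> 5 -> 11; each newcomer batch at least
#'     doubles the population, so growth promotes cooperation via the
#'     large-batch rule.}
#'   \item{`ring_sparse`}{a 6-cycle gaining 1 then 2 nodes with few edges
#'     (dK = 2 then 6); promotes via the bounded-edges rule.}
#'   \item{`ring_dense`}{same sizes but denser newcomers (dK = 3 then 8);
#'     growth suppresses cooperation.}
#'   \item{`ring_regular`}{a 6-cycle gaining two degree-3 nodes to form a
#'     cubic graph on 8 nodes; neutral values tie exactly and the
#'     comparison is decided at first order in the selection intensity.}
#' }
#'
#' @return a named list of [seq_temporal_network()] objects.
#' @export
example_temporal_networks <- function() {
  out <- list(
    doubling = example_net(
      edges = rbind(c(1, 2),
                    c(3, 1), c(4, 2), c(5, 1),
                    c(6, 1), c(6, 2), c(6, 3), c(7, 1), c(7, 2), c(7, 4),
                    c(8, 1), c(8, 5), c(9, 2), c(9, 3), c(10, 1), c(10, 4),
                    c(11, 2), c(11, 5)),
      fa = c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3),
      want = data.frame(m = c(2, 5), dm = c(3, 6), dK = c(3, 14), g1 = c(0, 0))),
    ring_sparse = example_net(
      edges = rbind(ring6(), c(7, 1), c(7, 2),
                    c(8, 3), c(8, 4), c(8, 7), c(9, 5), c(9, 6), c(9, 7)),
      fa = c(1, 1, 1, 1, 1, 1, 2, 3, 3),
      want = data.frame(m = c(6, 7), dm = c(1, 2), dK = c(2, 6), g1 = c(0, 0))),
    ring_dense = example_net(
      edges = rbind(ring6(), c(7, 1), c(7, 2), c(7, 4),
                    c(8, 3), c(8, 4), c(8, 5), c(8, 7),
                    c(9, 6), c(9, 1), c(9, 2), c(9, 7)),
      fa = c(1, 1, 1, 1, 1, 1, 2, 3, 3),
      want = data.frame(m = c(6, 7), dm = c(1, 2), dK = c(3, 8), g1 = c(0, 0))),
    ring_regular = example_net(
      edges = rbind(ring6(), c(7, 1), c(7, 3), c(7, 5),
                    c(8, 2), c(8, 4), c(8, 6)),
      fa = c(1, 1, 1, 1, 1, 1, 2, 2),
      want = data.frame(m = 6, dm = 2, dK = 6, g1 = 0)))
  out
}

ring6 <- function() cbind(1:6, c(2:6, 1))

example_net <- function(edges, fa, want) {
  net <- static_network(data.frame(i = edges[, 1], j = edges[, 2]),
                        labels = as.character(seq_len(length(fa))))
  T <- seq_temporal_network(net, activation_schedule(fa))
  inc <- increments(T)
  if (!isTRUE(all.equal(inc[, c("m", "dm", "dK", "g1")], want,
                        check.attributes = FALSE)))
    stop("fixture failed its transcription assertion")
  T
}
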