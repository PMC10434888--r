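#' Activation schedule of a growing population
#'
#' A schedule assigns every node of a static network the index of the first
#' snapshot in which it is active.  Because nodes never leave, this compact
#' form is equivalent to the monotone sequence of binary activation vectors
#' `a^(1) <= a^(2) <= ... <= a^(L) = (1, ..., 1)`.
#'
#' @param first_active integer vector: for each node, the 1-based index of
#'   the snapshot where it first appears.
#' @param L number of snapshots; defaults to `max(first_active)`.
#' @return an object of class `activation_schedule`.
#' @export
activation_schedule <- function(first_active, L = max(first_active)) {
  fa <- as.integer(first_active)
  if (any(is.na(fa)) || any(fa < 1)) stop("first-activation indices must be positive integers")
  if (L < max(fa)) stop("'L' is smaller than the largest first-activation index")
  if (sum(fa == 1) < 2) stop("the first snapshot must contain at least 2 active nodes")
  structure(list(first_active = fa, L = as.integer(L)), class = "activation_schedule")
}

#' @param a matrix with one column per snapshot and one row per node,
#'   containing the binary activation vectors.
#' @rdname activation_schedule
#' @details `activation_schedule_from_vectors()` accepts the explicit
#'   activation vectors and checks the monotone ("sequential") partial
#'   order and that the final vector is all-ones.
#' @export
activation_schedule_from_vectors <- function(a) {
  a <- as.matrix(a)
  if (!all(a %in% c(0, 1))) stop("activation vectors must be binary")
  mono <- all(apply(a, 1, function(row) all(diff(row) >= 0)))
  if (!mono) stop("activation vectors are not monotone: a node becomes inactive")
  if (!all(a[, ncol(a)] == 1)) stop("final activation vector must be all-ones")
  fa <- apply(a, 1, function(row) which(row == 1)[1])
  if (anyNA(fa)) stop("some node is never active")
  activation_schedule(fa, ncol(a))
}

#' Sequential temporal network
#'
#' Bundles a static network `S` with an activation schedule.  Snapshot `l`
#' is the subgraph of `S` induced by the nodes active at time `l`; the
#' final snapshot equals `S`.  Every snapshot must be connected (the
#' death-birth update is undefined for a node with no active neighbour).
#'
#' @param net a [static_network()] (the final snapshot).
#' @param schedule an [activation_schedule()] or a bare vector of
#'   first-activation indices.
#' @return an object of class `seq_temporal_network`.
#' @export
seq_temporal_network <- function(net, schedule) {
  if (!inherits(schedule, "activation_schedule"))
    schedule <- activation_schedule(schedule)
  if (length(schedule$first_active) != net$n)
    stop("schedule covers ", length(schedule$first_active),
         " nodes but the network has ", net$n)
  T <- structure(list(net = net, schedule = schedule,
                      L = schedule$L, n = net$n),
                 class = "seq_temporal_network")
  # connectivity of every snapshot; transitions with no newcomers are no-ops
  g <- as_igraph(net)
  for (l in unique(sort(schedule$first_active))) {
    act <- which(schedule$first_active <= l)
    if (length(act) < 2) stop("snapshot ", l, " has fewer than 2 active nodes")
    sub <- igraph::induced_subgraph(g, act)
    comp <- igraph::components(sub)
    if (comp$no > 1)
      stop("snapshot ", l, " is disconnected (component sizes: ",
           paste(comp$csize, collapse = ", "), ")")
  }
  T
}

#' @export
print.seq_temporal_network <- function(x, ...) {
  m <- vapply(seq_len(x$L), function(l) sum(x$schedule$first_active <= l), 0L)
  cat(sprintf("sequential temporal network: L = %d snapshots, sizes %s\n",
              x$L, paste(m, collapse = " -> ")))
  invisible(x)
}

active_nodes <- function(T, l) which(T$schedule$first_active <= l)

#' Extract one snapshot as a static network
#'
#' @param T a [seq_temporal_network()].
#' @param l snapshot index in `1..L`.
#' @return a [static_network()] on the active nodes (labels preserved).
#' @export
snapshot <- function(T, l) {
  if (l < 1 || l > T$L) stop("snapshot index out of range 1..", T$L)
  act <- active_nodes(T, l)
  static_network(as.matrix(T$net$W[act, act, drop = FALSE]),
                 labels = T$net$labels[act])
}

#' Per-transition growth increments
#'
#' For each transition `l -> l+1` reports the previous active count `m`,
#' the newcomer count `dm`, the total weight `dK` of newcomer-oldtimer
#' edges, and the total weight `g1` of edges internal to the newcomers.
#' These are exactly the counts entering the closed-form neutral growth
#' rules.
#'
#' @param T a [seq_temporal_network()].
#' @return a data frame with one row per transition (empty when `L = 1`).
#' @export
increments <- function(T) {
  W <- T$net$W
  fa <- T$schedule$first_active
  out <- data.frame(l = integer(0), m = integer(0), dm = integer(0),
                    dK = numeric(0), g1 = numeric(0))
  if (T$L == 1) return(out)
  for (l in seq_len(T$L - 1)) {
    old <- which(fa <= l); new <- which(fa == l + 1)
    out[nrow(out) + 1, ] <- list(l, length(old), length(new),
                                 sum(W[new, old, drop = FALSE]),
                                 sum(W[new, new, drop = FALSE]) / 2)
  }
  out
}

#' Build a schedule from an activation order
#'
#' Activates nodes in the given order, in batches: snapshot `l` contains
#' the first `batch_sizes[1] + ... + batch_sizes[l]` nodes of `order`.
#'
#' @param net a [static_network()].
#' @param order a permutation of `1..n` (or of the node labels).
#' @param batch_sizes positive integers summing to `n`; the first batch
#'   must be at least 2.
#' @return a [seq_temporal_network()].
#' @export
schedule_from_order <- function(net, order, batch_sizes) {
  if (is.character(order)) order <- match(order, net$labels)
  if (anyNA(order) || !setequal(order, seq_len(net$n)))
    stop("'order' must be a permutation of the nodes")
  if (sum(batch_sizes) != net$n) stop("batch sizes must sum to the number of nodes")
  if (any(batch_sizes < 1) || batch_sizes[1] < 2)
    stop("batch sizes must be positive and the first batch at least 2")
  fa <- integer(net$n)
  fa[order] <- rep(seq_along(batch_sizes), batch_sizes)
  # name the offending prefix on failure
  g <- as_igraph(net)
  csum <- cumsum(batch_sizes)
  for (l in seq_along(csum)) {
    pre <- order[seq_len(csum[l])]
    if (igraph::components(igraph::induced_subgraph(g, pre))$no > 1)
      stop("prefix of length ", csum[l], " induces a disconnected snapshot")
  }
  seq_temporal_network(net, activation_schedule(fa, length(batch_sizes)))
}

#' Read or write an activation schedule
#'
#' Two-column TSV: node label and 1-based first-activation snapshot.
#'
#' @param path file path.
#' @param net the [static_network()] whose nodes the schedule refers to.
#' @return `read_schedule()` returns a [seq_temporal_network()].
#' @export
read_schedule <- function(path, net) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("label", "snapshot"),
                          colClasses = c("character", "integer"))
  idx <- match(net$labels, df$label)
  if (anyNA(idx)) stop("schedule is missing node(s): ",
                       paste(net$labels[is.na(idx)], collapse = ", "))
  seq_temporal_network(net, activation_schedule(df$snapshot[idx]))
}

#' @param T a [seq_temporal_network()].
#' @rdname read_schedule
#' @export
write_schedule <- function(T, path) {
  utils::write.table(
    data.frame(label = T$net$labels, snapshot = T$schedule$first_active),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write or read a temporal-network bundle
#'
#' A bundle directory holds `edges.tsv` (edge list), `schedule.tsv`
#' (first-activation table) and `manifest.json` with `n` and `L`.
#'
#' @param T a [seq_temporal_network()].
#' @param dir directory path (created if needed).
#' @return `read_bundle()` returns a [seq_temporal_network()].
#' @export
write_bundle <- function(T, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edgelist(T$net, file.path(dir, "edges.tsv"))
  write_schedule(T, file.path(dir, "schedule.tsv"))
  writeLines(sprintf('{"n": %d, "L": %d}', T$n, T$L),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  net <- read_edgelist(file.path(dir, "edges.tsv"))
  read_schedule(file.path(dir, "schedule.tsv"), net)
}
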