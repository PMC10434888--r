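#' Construct a static network
#'
#' A static network is an undirected, connected, weighted graph without
#' self-loops, given by a symmetric non-negative weight matrix `w_ij`.  It is
#' the basic object on which games are played and random-walk quantities are
#' defined; in the temporal setting it is the final snapshot of a growing
#' population.
#'
#' @param x either a symmetric numeric matrix of edge weights (zero
#'   diagonal), or a data frame / two- or three-column matrix of edges
#'   `(i, j[, w])` with one row per undirected edge.  Missing weights
#'   default to 1.
#' @param labels optional character vector of node labels.  For edge-list
#'   input the labels are taken from the edge endpoints themselves.
#'
#' @return an object of class `static_network` with fields `W` (sparse
#'   symmetric weight matrix), `n` (number of nodes) and `labels`.
#'
#' @details Nodes of zero strength (no incident weight) and disconnected
#'   graphs are rejected: fixation of a single mutant is not defined on
#'   them.  Internally nodes are indexed `1..n` in the order of `labels`.
#'
#' @examples
#' net <- static_network(data.frame(i = c("a", "b"), j = c("b", "c")))
#' rv_weights(net)
#' @export
static_network <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    el <- as.data.frame(x)
    if (ncol(el) < 2) stop("edge list needs at least two columns (i, j)")
    i <- as.character(el[[1]]); j <- as.character(el[[2]])
    w <- if (ncol(el) >= 3) as.numeric(el[[3]]) else rep(1, length(i))
    if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive and finite")
    if (any(i == j)) stop("self-loops are not allowed")
    labs <- if (is.null(labels)) unique(c(i, j)) else labels
    n <- length(labs)
    ii <- match(i, labs); jj <- match(j, labs)
    if (anyNA(ii) || anyNA(jj)) stop("edge endpoints not covered by 'labels'")
    W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                              dims = c(n, n), use.last.ij = FALSE)
  } else {
    W <- as.matrix(x)
    if (nrow(W) != ncol(W)) stop("weight matrix must be square")
    if (!isSymmetric(unname(W), tol = 1e-12)) stop("weight matrix must be symmetric")
    if (any(diag(W) != 0)) stop("self-loops are not allowed (w_ii must be 0)")
    if (any(W < 0)) stop("edge weights must be non-negative")
    n <- nrow(W)
    labs <- if (!is.null(labels)) labels else
      if (!is.null(rownames(W))) rownames(W) else as.character(seq_len(n))
    W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  }
  if (length(labs) != nrow(W)) stop("length of 'labels' does not match the number of nodes")
  net <- structure(list(W = W, n = nrow(W), labels = as.character(labs)),
                   class = "static_network")
  validate_static_network(net)
  net
}

validate_static_network <- function(net) {
  w <- node_strengths(net)
  if (any(w <= 0)) {
    bad <- net$labels[w <= 0]
    stop("node(s) with zero strength (isolated): ", paste(bad, collapse = ", "))
  }
  comp <- igraph::components(as_igraph(net))
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("network is disconnected (component sizes: ", sizes, ")")
  }
  invisible(net)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$W, mode = "undirected", weighted = TRUE)
}

#' @export
print.static_network <- function(x, ...) {
  m <- Matrix::nnzero(x$W) / 2
  cat(sprintf("static network: %d nodes, %g edges, total weight %g\n",
              x$n, m, sum(x$W) / 2))
  invisible(x)
}

# dense weight matrix, used by the linear-algebra kernels (n is small there)
dense_W <- function(net) as.matrix(net$W)

node_strengths <- function(net) as.numeric(Matrix::rowSums(net$W))

#' Reproductive values (stationary random-walk weights)
#'
#' The reproductive value of node `i` is `pi_i = w_i / sum_k w_k`, the
#' stationary distribution of the edge-weighted random walk.  Under neutral
#' drift the fixation probability of a set of cooperators is the sum of
#' their reproductive values.
#'
#' @param net a [static_network()].
#' @return numeric vector summing to 1, named by node labels.
#' @export
rv_weights <- function(net) {
  w <- node_strengths(net)
  stats::setNames(w / sum(w), net$labels)
}

#' Random-walk step probabilities and strength moments
#'
#' Computes the `n`-step random-walk matrices `p^(0) = I`,
#' `p^(n) = (p^(1))^n` with `p^(1)_ij = w_ij / w_i`, the first two moments
#' `mu1`, `mu2` of the node-strength distribution, and the return weight
#' `Lambda = sum_i w_i p^(2)_ii`.
#'
#' @param net a [static_network()].
#' @param n_max largest step count (default 3, all that the theory needs).
#' @return a list with elements `pi`, `P` (list of matrices `p^(0)` ..
#'   `p^(n_max)`), `mu1`, `mu2`, `Lambda`.
#' @export
walk_probs <- function(net, n_max = 3) {
  stopifnot(n_max >= 1)
  w <- node_strengths(net)
  W <- dense_W(net)
  P1 <- W / w
  P <- vector("list", n_max + 1)
  P[[1]] <- diag(net$n)
  P[[2]] <- P1
  if (n_max >= 2) for (k in 2:n_max) P[[k + 1]] <- P[[k]] %*% P1
  Lambda <- if (n_max >= 2) sum(w * diag(P[[3]])) else sum(w * diag(P1 %*% P1))
  list(pi = w / sum(w), P = P,
       mu1 = mean(w), mu2 = mean(w^2), Lambda = Lambda)
}

#' Reproductive-value-weighted average
#'
#' Returns `sum_i pi_i y_i`, the average of a node quantity `y` weighted by
#' reproductive values.  For a binary configuration this is its exact
#' neutral-drift fixation probability.
#'
#' @param net a [static_network()].
#' @param y numeric vector of length `n`.
#' @return a scalar.
#' @export
rv_weighted_value <- function(net, y) {
  if (length(y) != net$n)
    stop("'y' must have length ", net$n, " (one value per node)")
  sum(rv_weights(net) * y)
}

#' Read or write a network edge list
#'
#' Plain-text edge lists with lines `i j [w]` (whitespace separated,
#' `#` comments, default weight 1, each undirected edge listed once).
#'
#' @param path file path.
#' @return `read_edgelist()` returns a [static_network()].
#' @export
read_edgelist <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("empty edge list: ", path)
  parts <- strsplit(ln, "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 3))
    stop("malformed edge list line(s): ", paste(which(nf < 2 | nf > 3), collapse = ", "))
  el <- data.frame(i = vapply(parts, `[[`, "", 1L),
                   j = vapply(parts, `[[`, "", 2L),
                   w = vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[[3]]) else 1, 0))
  static_network(el)
}

#' @param net a [static_network()].
#' @rdname read_edgelist
#' @export
write_edgelist <- function(net, path) {
  idx <- Matrix::which(Matrix::triu(net$W) != 0, arr.ind = TRUE)
  df <- data.frame(i = net$labels[idx[, 1]], j = net$labels[idx[, 2]],
                   w = net$W[idx])
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
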