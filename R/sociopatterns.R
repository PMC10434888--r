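#' Read a contact-triplet file as a sequential temporal network
#'
#' Parses plain-text lines `t i j` (whitespace or comma separated,
#' `#` comments): individual `i` contacted `j` at time `t`.  The static
#' network is the union of all contact pairs (unweighted by default, or
#' weighted by contact counts); a node's activation time is its first
#' appearance.  Snapshots are formed from time bins of width `window`
#' (default: one snapshot per bin that introduces at least one new node);
#' bins whose induced subgraph would be disconnected are merged forward
#' into the next bin, and the merges are recorded.
#'
#' @param path triplet file.
#' @param window bin width in the file's time units; `NULL` bins on the
#'   distinct first-appearance times themselves.
#' @param weighted if `TRUE`, edge weights are contact counts.
#' @return a [seq_temporal_network()]; attribute `merged_bins` gives the
#'   number of forward merges performed to keep snapshots connected.
#' @export
read_sociopatterns <- function(path, window = NULL, weighted = FALSE) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*", "", ln))
  keep <- nzchar(ln)
  if (!any(keep)) stop("empty triplet file: ", path)
  parts <- strsplit(ln[keep], "[,[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed triplet line(s): ", paste(which(keep)[bad], collapse = ", "))
  t <- as.numeric(vapply(parts, `[[`, "", 1L))
  i <- vapply(parts, `[[`, "", 2L)
  j <- vapply(parts, `[[`, "", 3L)
  if (anyNA(t)) stop("non-numeric contact times")
  if (any(i == j)) stop("self-contacts are not allowed")
  labs <- unique(c(rbind(i, j)))  # order of first appearance
  key <- paste(pmin(i, j), pmax(i, j))
  w <- if (weighted) as.numeric(table(key)[unique(key)]) else 1
  first <- !duplicated(key)
  el <- data.frame(i = i[first], j = j[first], w = w)
  net <- static_network(el, labels = labs)

  # first appearance time of each node
  tfirst <- vapply(labs, function(v) min(t[i == v | j == v]), 0)
  bins <- if (is.null(window)) match(tfirst, sort(unique(tfirst)))
          else floor((tfirst - min(t)) / window) + 1
  # renumber to consecutive snapshots that each add at least one node
  fa <- match(bins, sort(unique(bins)))
  # merge snapshots forward until every snapshot is connected and starts
  # with at least 2 nodes
  g <- as_igraph(net)
  merged <- 0L
  repeat {
    L <- max(fa)
    ok <- TRUE
    for (l in seq_len(L - 1)) {
      act <- which(fa <= l)
      if (length(act) < 2 ||
          igraph::components(igraph::induced_subgraph(g, act))$no > 1) {
        fa[fa == l] <- l + 1L
        fa <- match(fa, sort(unique(fa)))
        merged <- merged + 1L
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  T <- seq_temporal_network(net, activation_schedule(fa))
  attr(T, "merged_bins") <- merged
  T
}
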