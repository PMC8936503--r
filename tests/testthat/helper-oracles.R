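# independent oracles used across test files

# triangle count through each node by exhaustive triple enumeration
brute_triangles <- function(g) {
  nodes <- g$nodes
  has_edge <- function(x, y) {
    key <- if (x < y) c(x, y) else c(y, x)
    any(g$edges[, 1] == key[1] & g$edges[, 2] == key[2])
  }
  tri <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (length(nodes) < 3) return(tri)
  for (trip in utils::combn(nodes, 3, simplify = FALSE)) {
    if (has_edge(trip[1], trip[2]) && has_edge(trip[2], trip[3]) &&
        has_edge(trip[1], trip[3]))
      tri[trip] <- tri[trip] + 1L
  }
  tri
}

# igraph-based root connectivity of an edge subset (independent of the
# union-find enumeration inside the package)
roots_connected_igraph <- function(g, subset) {
  el <- g$edges[subset, , drop = FALSE]
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(g$nodes)
  if (nrow(el)) gr <- igraph::add_edges(gr, as.vector(t(el)))
  is.finite(igraph::distances(gr, v = g$roots[1], to = g$roots[2])[1, 1])
}

# s_m oracle by full enumeration through igraph
oracle_s_counts <- function(g) {
  m <- nrow(g$edges)
  s <- integer(m + 1)
  for (code in 0:(2^m - 1)) {
    subset <- which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) > 0)
    if (roots_connected_igraph(g, subset))
      s[length(subset) + 1L] <- s[length(subset) + 1L] + 1L
  }
  s
}

fixture_set <- function() {
  list(A = builtin_generator("A"),
       B = builtin_generator("B"),
       C = builtin_generator("C"),
       flower22 = builtin_generator("flower", u = 2, v = 2),
       flower32 = builtin_generator("flower", u = 3, v = 2),
       shm2 = builtin_generator("shm", z = 2))
}
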