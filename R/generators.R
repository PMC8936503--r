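#' Construct a generator graph
#'
#' A generator is a small connected, undirected, simple graph with two
#' designated root nodes. Copies of the generator replace every edge of the
#' previous-generation network during growth, the roots being identified with
#' the endpoints of the replaced edge. All structural theory of the grown
#' networks is a function of this one object.
#'
#' @param nodes character vector of node labels (opaque strings).
#' @param edges two-column character matrix (or list of 2-element vectors) of
#'   undirected edges; no self-loops, no duplicates.
#' @param roots character vector of length 2, the root pair \code{(r1, r2)}.
#'   The order matters only for asymmetric generators.
#' @param name optional display name.
#'
#' @return An object of class \code{fsfn_generator} with elements
#'   \code{nodes}, \code{edges} (sorted two-column character matrix),
#'   \code{roots}, \code{name}, and \code{graph} (the igraph representation).
#' @export
#' @examples
#' g <- fsfn_generator(
#'   nodes = c("r1", "r2", "x", "y"),
#'   edges = rbind(c("r1", "x"), c("x", "r2"), c("r1", "y"), c("y", "r2")),
#'   roots = c("r1", "r2")
#' )
fsfn_generator <- function(nodes, edges, roots, name = NULL) {
  nodes <- as.character(nodes)
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, as.character))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  roots <- as.character(roots)

  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (length(roots) != 2L) stop("exactly two root nodes are required")
  if (roots[1] == roots[2]) stop("the two root nodes must be distinct")
  if (!all(roots %in% nodes)) stop("root label not in node list: ",
                                   paste(setdiff(roots, nodes), collapse = ", "))
  bad <- setdiff(as.vector(edges), nodes)
  if (length(bad)) stop("edge references unknown label: ", paste(bad, collapse = ", "))
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")

  # canonical unordered form, lexicographically sorted
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edge")

  graph <- igraph::graph_from_edgelist(edges, directed = FALSE)
  graph <- graph + igraph::vertices(setdiff(nodes, igraph::V(graph)$name))
  if (!igraph::is_connected(graph)) stop("generator graph is not connected")

  structure(
    list(nodes = nodes, edges = edges, roots = roots,
         name = if (is.null(name)) "custom" else name, graph = graph),
    class = "fsfn_generator"
  )
}

#' @export
print.fsfn_generator <- function(x, ...) {
  cat("<fsfn_generator>", x$name, "\n")
  cat("  nodes:", length(x$nodes), " edges:", nrow(x$edges),
      " roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Load a generator from a structured text file
#'
#' The file is JSON with three keys: \code{nodes} (list of labels),
#' \code{edges} (list of 2-label lists) and \code{roots} (2-label list).
#'
#' @param source path to the generator file.
#' @return A validated [fsfn_generator()].
#' @export
load_generator <- function(source) {
  gspec <- tryCatch(jsonlite::read_json(source, simplifyVector = TRUE),
                   error = function(e) stop("cannot parse generator file '",
                                            source, "': ", conditionMessage(e)))
  for (key in c("nodes", "edges", "roots"))
    if (is.null(gspec[[key]])) stop("generator file lacks key '", key, "'")
  fsfn_generator(gspec$nodes, gspec$edges, gspec$roots,
                 name = basename(source))
}

#' Write a generator to its structured text representation
#'
#' @param g an [fsfn_generator()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_generator <- function(g, path) {
  stopifnot(inherits(g, "fsfn_generator"))
  gspec <- list(nodes = g$nodes,
               edges = lapply(seq_len(nrow(g$edges)), function(i) g$edges[i, ]),
               roots = g$roots)
  jsonlite::write_json(gspec, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Test root symmetry of a generator
#'
#' The two roots are symmetric when the graph obtained by deleting r1 and its
#' incident edges is isomorphic to the graph obtained by deleting r2 and its
#' incident edges. Symmetric generators yield deterministic networks;
#' asymmetric ones require a random orientation per replaced edge.
#'
#' @param g an [fsfn_generator()].
#' @param size_cap maximum number of generator nodes accepted for the exact
#'   isomorphism test (default 32).
#' @return logical.
#' @export
is_symmetric <- function(g, size_cap = 32L) {
  stopifnot(inherits(g, "fsfn_generator"))
  if (length(g$nodes) > size_cap)
    stop("generator larger than the isomorphism size cap (", size_cap, " nodes)")
  g1 <- igraph::delete_vertices(g$graph, g$roots[1])
  g2 <- igraph::delete_vertices(g$graph, g$roots[2])
  igraph::isomorphic(g1, g2, method = "vf2")
}

#' Check the three admissibility conditions of a generator
#'
#' Condition 1: both root degrees are at least 2 (scale-free property).
#' Condition 2: the roots are not adjacent, i.e. their shortest-path distance
#' is at least 2 (fractality). Condition 3: the roots are symmetric
#' (deterministic growth). Violations are reported as warnings, not errors:
#' sizes, clustering and percolation theory remain valid regardless, only the
#' scale-free/fractal/degree-correlation sections become inapplicable.
#'
#' @param g an [fsfn_generator()].
#' @return A list of class \code{fsfn_conditions} with logical fields
#'   \code{cond1}, \code{cond2}, \code{cond3}, a combined \code{all_met}, and
#'   human-readable \code{messages}.
#' @export
validate_conditions <- function(g) {
  stopifnot(inherits(g, "fsfn_generator"))
  deg <- igraph::degree(g$graph)
  k1 <- deg[g$roots[1]]; k2 <- deg[g$roots[2]]
  lambda <- igraph::distances(g$graph, v = g$roots[1], to = g$roots[2])[1, 1]
  cond1 <- min(k1, k2) >= 2
  cond2 <- lambda >= 2
  cond3 <- is_symmetric(g)
  messages <- character()
  if (!cond1) messages <- c(messages,
    "root degree below 2: degree distribution will be exponentially damped, not scale-free")
  if (!cond2) messages <- c(messages,
    "roots are adjacent (lambda = 1): network is small-world, not fractal")
  if (!cond3) messages <- c(messages,
    "roots are asymmetric: growth is stochastic (fair orientation flips)")
  structure(list(cond1 = cond1, cond2 = cond2, cond3 = cond3,
                 all_met = cond1 && cond2 && cond3, messages = messages),
            class = "fsfn_conditions")
}

#' @export
print.fsfn_conditions <- function(x, ...) {
  cat("generator conditions: root degree >= 2:", x$cond1,
      "| root distance >= 2:", x$cond2, "| symmetric roots:", x$cond3, "\n")
  for (m in x$messages) cat("  note:", m, "\n")
  invisible(x)
}

#' Core subgraph of a generator
#'
#' Returns the subgraph containing exactly the edges lying on at least one
#' simple path between the two roots. The two-terminal reliability polynomial,
#' and hence the percolation critical point and exponents, depend only on this
#' core: generators with the same core have identical percolation behaviour.
#'
#' @param g an [fsfn_generator()].
#' @return An [fsfn_generator()] restricted to the core edges (roots kept).
#' @export
core_subgraph <- function(g) {
  stopifnot(inherits(g, "fsfn_generator"))
  paths <- igraph::all_simple_paths(g$graph, from = g$roots[1], to = g$roots[2])
  on_path <- character(0)
  for (p in paths) {
    v <- names(p)
    a <- v[-length(v)]; b <- v[-1]
    key <- ifelse(a < b, paste(a, b), paste(b, a))
    on_path <- union(on_path, key)
  }
  keep <- paste(g$edges[, 1], g$edges[, 2]) %in% on_path
  edges <- g$edges[keep, , drop = FALSE]
  fsfn_generator(unique(c(g$roots, as.vector(edges))), edges, g$roots,
                 name = paste0("core(", g$name, ")"))
}

#' Compute the descriptor bundle of a generator
#'
#' All closed-form theory of the grown networks is expressed through these
#' integer descriptors: edge and node counts, root degrees, root distance,
#' remaining-node degrees and triangle counts, local clustering of the
#' remaining nodes, root neighbourhood degree profiles and the census of edges
#' between remaining nodes.
#'
#' @param g an [fsfn_generator()].
#' @return A list of class \code{fsfn_descriptors}:
#' \describe{
#'   \item{m_gen, n_gen, n_rem}{edge count, node count, remaining-node count.}
#'   \item{kappa1, kappa2, kappa_bar, kappa_check}{root degrees, their mean
#'     \eqn{(\kappa_1+\kappa_2)/2} and half-difference \eqn{|\kappa_1-\kappa_2|/2}.}
#'   \item{lambda}{shortest-path distance between the roots.}
#'   \item{k_rem}{named integer vector of remaining-node degrees.}
#'   \item{K2rem}{sum of squared remaining-node degrees.}
#'   \item{Delta_gen, Delta_R1, Delta_R2, Delta_rem}{triangle counts: total,
#'     through each root, per remaining node.}
#'   \item{C_rem}{mean local clustering coefficient over remaining nodes.}
#'   \item{mu1, mu2}{named counts of degree-k neighbours of each root.}
#'   \item{m_rem}{data frame (k, kp, count) of edges joining two remaining
#'     nodes of degrees k and kp (unordered, k <= kp).}
#'   \item{symmetric}{root-symmetry flag.}
#'   \item{k_mean_gen, k2_mean_gen}{first two degree moments of the generator.}
#' }
#' @export
generator_descriptors <- function(g) {
  stopifnot(inherits(g, "fsfn_generator"))
  gr <- g$graph
  deg <- igraph::degree(gr)
  rem <- setdiff(g$nodes, g$roots)
  tri <- igraph::count_triangles(gr)
  names(tri) <- igraph::V(gr)$name
  k_rem <- deg[rem]
  loc <- ifelse(k_rem >= 2, 2 * tri[rem] / (k_rem * (k_rem - 1)), 0)

  mu_of <- function(root) {
    nb <- igraph::neighbors(gr, root)$name
    tab <- table(deg[nb])
    stats::setNames(as.integer(tab), names(tab))
  }
  # census of edges between two remaining nodes, by degree pair
  both_rem <- g$edges[, 1] %in% rem & g$edges[, 2] %in% rem
  m_rem <- if (any(both_rem)) {
    da <- deg[g$edges[both_rem, 1]]; db <- deg[g$edges[both_rem, 2]]
    k <- pmin(da, db); kp <- pmax(da, db)
    agg <- stats::aggregate(list(count = rep(1L, length(k))),
                            by = list(k = k, kp = kp), FUN = sum)
    agg[order(agg$k, agg$kp), , drop = FALSE]
  } else {
    data.frame(k = integer(0), kp = integer(0), count = integer(0))
  }

  structure(list(
    m_gen = nrow(g$edges),
    n_gen = length(g$nodes),
    n_rem = length(rem),
    kappa1 = unname(deg[g$roots[1]]),
    kappa2 = unname(deg[g$roots[2]]),
    kappa_bar = unname((deg[g$roots[1]] + deg[g$roots[2]]) / 2),
    kappa_check = unname(abs(deg[g$roots[1]] - deg[g$roots[2]]) / 2),
    lambda = unname(igraph::distances(gr, v = g$roots[1], to = g$roots[2])[1, 1]),
    k_rem = k_rem,
    K2rem = sum(k_rem^2),
    Delta_gen = sum(tri) / 3,
    Delta_R1 = unname(tri[g$roots[1]]),
    Delta_R2 = unname(tri[g$roots[2]]),
    Delta_rem = tri[rem],
    C_rem = if (length(rem)) mean(loc) else 0,
    mu1 = mu_of(g$roots[1]),
    mu2 = mu_of(g$roots[2]),
    m_rem = m_rem,
    symmetric = is_symmetric(g),
    k_mean_gen = mean(deg),
    k2_mean_gen = mean(deg^2)
  ), class = "fsfn_descriptors")
}

#' @export
print.fsfn_descriptors <- function(x, ...) {
  cat("<fsfn_descriptors>\n")
  cat(sprintf("  m_gen=%d n_gen=%d n_rem=%d kappa=(%d,%d) lambda=%d\n",
              x$m_gen, x$n_gen, x$n_rem, x$kappa1, x$kappa2, x$lambda))
  cat(sprintf("  K2rem=%d Delta_gen=%d Delta_R=(%d,%d) C_rem=%s symmetric=%s\n",
              x$K2rem, x$Delta_gen, x$Delta_R1, x$Delta_R2,
              format_fraction(x$C_rem), x$symmetric))
  invisible(x)
}

#' Built-in generator fixtures
#'
#' Provides the reference generators used throughout the package:
#' \describe{
#'   \item{A}{6 nodes, 8 edges, symmetric, two triangles; root degree 2, root
#'     distance 3, all remaining degrees 3.}
#'   \item{B}{same counts as A but triangle-free (clustering zero at every
#'     generation); symmetric.}
#'   \item{C}{5 nodes, 7 edges, asymmetric (root degrees 3 and 2, distance 2),
#'     two triangles.}
#'   \item{flower(u, v)}{a cycle of u + v nodes with roots at cyclic distance
#'     min(u, v); reproduces the (u,v)-flower model.}
#'   \item{shm(z)}{two stars of z leaves whose centres are the roots, joined
#'     by one leaf-leaf bridge; reproduces the Song-Havlin-Makse model.}
#' }
#'
#' @param name one of \code{"A"}, \code{"B"}, \code{"C"}, \code{"flower"},
#'   \code{"shm"}.
#' @param u,v flower parameters, integers with \code{u >= v >= 2}.
#' @param z star size for \code{shm}, integer \code{>= 2}.
#' @return An [fsfn_generator()].
#' @export
builtin_generator <- function(name, u = NULL, v = NULL, z = NULL) {
  switch(name,
    A = fsfn_generator(
      nodes = c("r1", "r2", "a", "b", "c", "d"),
      edges = rbind(c("r1", "a"), c("r1", "b"), c("a", "b"), c("a", "c"),
                    c("b", "d"), c("c", "d"), c("r2", "c"), c("r2", "d")),
      roots = c("r1", "r2"), name = "A"),
    B = fsfn_generator(
      nodes = c("r1", "r2", "a", "b", "c", "d"),
      edges = rbind(c("r1", "a"), c("r1", "b"), c("a", "c"), c("a", "d"),
                    c("b", "c"), c("b", "d"), c("r2", "c"), c("r2", "d")),
      roots = c("r1", "r2"), name = "B"),
    C = fsfn_generator(
      nodes = c("R1", "R2", "a", "b", "c"),
      edges = rbind(c("R1", "a"), c("R1", "b"), c("R1", "c"), c("a", "b"),
                    c("b", "c"), c("R2", "a"), c("R2", "c")),
      roots = c("R1", "R2"), name = "C"),
    flower = {
      if (is.null(u) || is.null(v)) stop("flower generator needs u and v")
      if (!(u >= v && v >= 2)) stop("flower parameters require u >= v >= 2")
      n <- u + v
      lab <- paste0("n", seq_len(n))
      edges <- cbind(lab, lab[c(2:n, 1)])
      fsfn_generator(lab, edges, roots = c(lab[1], lab[1 + v]),
                     name = sprintf("flower(%d,%d)", u, v))
    },
    shm = {
      if (is.null(z)) stop("shm generator needs z")
      if (z < 2) stop("shm parameter requires z >= 2")
      al <- paste0("a", seq_len(z)); bl <- paste0("b", seq_len(z))
      edges <- rbind(cbind("r1", al), cbind("r2", bl), c("a1", "b1"))
      fsfn_generator(c("r1", "r2", al, bl), edges, roots = c("r1", "r2"),
                     name = sprintf("shm(%d)", z))
    },
    stop("unknown builtin generator '", name, "'")
  )
}
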