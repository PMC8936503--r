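#' Networks grown by iterated edge replacement
#'
#' [build_network()] grows the generation-\code{t} network from an initial
#' graph (by default a single edge) by replacing, \code{t} times, every edge
#' with a fresh copy of a generator whose roots are identified with the edge
#' endpoints. With a single symmetric generator the construction is
#' deterministic and seed-independent; with an asymmetric generator each
#' replacement orientation is a fair coin flip, and with several generators
#' each edge independently draws its generator from the supplied
#' probabilities.
#'
#' New node identifiers are deterministic functions of (generation,
#' parent-edge index in the lexicographically sorted edge list, local
#' generator label), so builds are reproducible and diff-able.
#'
#' @param generators an [fsfn_generator()] or a list of them.
#' @param t generation (non-negative integer).
#' @param seed integer seed for the orientation / generator-choice stream.
#'   Required when the construction is stochastic; ignored (and the result is
#'   bit-identical for any value) for a single symmetric generator.
#' @param prob generator selection probabilities (must sum to 1); default
#'   uniform.
#' @param g0 optional initial network as a two-column character edge matrix;
#'   default a single edge. The closed-form size formulas assume the default.
#' @param node_cap resource guard on the node count (default 1e7).
#'
#' @return An object of class \code{fsfn_network}: a list with \code{edges}
#'   (sorted two-column character matrix), \code{birth} (named integer vector,
#'   node id to generation of first appearance), \code{t}, \code{rrn} (the two
#'   generation-0 node ids), \code{generator} (names), and \code{seed}.
#' @export
#' @examples
#' net <- build_network(builtin_generator("A"), t = 2)
#' nrow(net$edges)  # 64 edges = 8^2
build_network <- function(generators, t, seed = NULL, prob = NULL,
                          g0 = NULL, node_cap = 1e7) {
  if (inherits(generators, "fsfn_generator")) generators <- list(generators)
  stopifnot(length(generators) >= 1, all(vapply(generators, inherits,
                                                TRUE, "fsfn_generator")))
  if (t < 0) stop("generation t must be non-negative")
  if (is.null(prob)) prob <- rep(1 / length(generators), length(generators))
  if (abs(sum(prob) - 1) > 1e-12) stop("generator probabilities must sum to 1")

  sym <- vapply(generators, is_symmetric, TRUE)
  stochastic <- length(generators) > 1 || any(!sym)
  if (stochastic) {
    if (is.null(seed)) stop("a seed is required for stochastic construction")
    set.seed(as.integer(seed))
  }

  custom_g0 <- !is.null(g0)
  if (custom_g0) {
    edges <- as.matrix(g0); storage.mode(edges) <- "character"
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    ids <- sort(unique(as.vector(edges)))
  } else {
    edges <- matrix(c("0.rrnA", "0.rrnB"), 1, 2)
    ids <- c("0.rrnA", "0.rrnB")
  }
  net <- structure(list(
    edges = edges,
    birth = stats::setNames(rep(0L, length(ids)), ids),
    t = 0L,
    rrn = if (custom_g0) ids[1:2] else ids,
    generator = vapply(generators, function(g) g$name, ""),
    seed = seed,
    custom_g0 = custom_g0
  ), class = "fsfn_network")

  for (gen in seq_len(t)) {
    net <- expand_once(net, generators, prob = prob)
    if (length(net$birth) > node_cap)
      stop("node cap exceeded (", length(net$birth), " > ", node_cap, ")")
  }
  net
}

#' Replace every edge of a network with a generator copy
#'
#' One growth step. Operates on the edge list in lexicographic order; draws,
#' where needed, one generator index and one orientation flip per edge from
#' the current RNG stream (seed it via [build_network()] or [set.seed()]).
#'
#' @param net an \code{fsfn_network}.
#' @param generators list of [fsfn_generator()].
#' @param prob generator selection probabilities.
#' @return The expanded \code{fsfn_network} at generation \code{net$t + 1}.
#' @export
expand_once <- function(net, generators, prob = NULL) {
  stopifnot(inherits(net, "fsfn_network"))
  if (inherits(generators, "fsfn_generator")) generators <- list(generators)
  if (!length(generators)) stop("empty generator list")
  if (is.null(prob)) prob <- rep(1 / length(generators), length(generators))
  if (abs(sum(prob) - 1) > 1e-12) stop("generator probabilities must sum to 1")

  E <- net$edges
  n <- nrow(E)
  tnew <- net$t + 1L
  sym <- vapply(generators, is_symmetric, TRUE)

  gi <- if (length(generators) > 1)
    sample.int(length(generators), n, replace = TRUE, prob = prob)
  else rep(1L, n)
  forward <- rep(TRUE, n)
  needs_flip <- !sym[gi]
  if (any(needs_flip))
    forward[needs_flip] <- stats::runif(sum(needs_flip)) < 0.5

  out_e1 <- vector("list", 0); out_e2 <- vector("list", 0)
  new_ids <- vector("list", 0)
  for (gidx in unique(gi)) {
    g <- generators[[gidx]]
    rem <- setdiff(g$nodes, g$roots)
    for (fwd in unique(forward[gi == gidx])) {
      idx <- which(gi == gidx & forward == fwd)
      if (!length(idx)) next
      u <- if (fwd) E[idx, 1] else E[idx, 2]
      v <- if (fwd) E[idx, 2] else E[idx, 1]
      resolve <- function(lab) {
        if (lab == g$roots[1]) u
        else if (lab == g$roots[2]) v
        else paste0(tnew, ".", idx, ".", lab)
      }
      for (k in seq_len(nrow(g$edges))) {
        out_e1 <- c(out_e1, list(resolve(g$edges[k, 1])))
        out_e2 <- c(out_e2, list(resolve(g$edges[k, 2])))
      }
      for (lab in rem) new_ids <- c(new_ids, list(paste0(tnew, ".", idx, ".", lab)))
    }
  }
  e1 <- unlist(out_e1); e2 <- unlist(out_e2)
  swap <- e1 > e2
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  o <- order(e1, e2)
  net$edges <- cbind(e1[o], e2[o])
  fresh <- unlist(new_ids)
  net$birth <- c(net$birth, stats::setNames(rep(tnew, length(fresh)), fresh))
  net$t <- tnew
  net
}

#' @export
print.fsfn_network <- function(x, ...) {
  cat("<fsfn_network> generation", x$t, "built from",
      paste(x$generator, collapse = "+"), "\n")
  cat("  nodes:", length(x$birth), " edges:", nrow(x$edges),
      " RRNs:", paste(x$rrn, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a grown network to an igraph object
#'
#' Node attributes \code{birth_generation} and \code{is_rrn} are attached.
#'
#' @param net an \code{fsfn_network}.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "fsfn_network"))
  gr <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  gr <- gr + igraph::vertices(setdiff(names(net$birth), igraph::V(gr)$name))
  igraph::V(gr)$birth_generation <- unname(net$birth[igraph::V(gr)$name])
  igraph::V(gr)$is_rrn <- igraph::V(gr)$name %in% net$rrn
  gr
}

#' Exact degree census of a built network
#'
#' @param net an \code{fsfn_network}.
#' @return data frame with columns \code{k} (degree) and \code{count},
#'   ascending in \code{k}. Isolated nodes cannot occur by construction.
#' @export
degree_census <- function(net) {
  stopifnot(inherits(net, "fsfn_network"))
  deg <- table(factor(c(net$edges[, 1], net$edges[, 2])))
  tab <- table(as.integer(deg))
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Per-node triangle counts of a built network
#'
#' @param net an \code{fsfn_network}.
#' @return named integer vector, node id to number of triangles through it.
#' @export
triangle_census <- function(net) {
  gr <- as_igraph(net)
  stats::setNames(igraph::count_triangles(gr), igraph::V(gr)$name)
}
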