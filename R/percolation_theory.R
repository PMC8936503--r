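#' Two-terminal connectivity counts of a generator
#'
#' Enumerates all \eqn{2^{m}} edge subsets of the core subgraph and counts,
#' for each subset size \eqn{m}, the subgraphs in which the two roots lie in
#' one connected component. These integers \eqn{s_m} are the coefficients of
#' the two-terminal reliability polynomial
#' \deqn{\pi(p) = \sum_{m=\lambda}^{m_{gen}} s_m\, p^m (1-p)^{m_{gen}-m},}
#' the probability that the roots stay connected when each edge survives
#' independently with probability \eqn{p}. Generators sharing a core subgraph
#' share \eqn{\pi} and hence all percolation quantities.
#'
#' @param g an [fsfn_generator()].
#' @param reduce drop edges on no root-to-root path first (default TRUE).
#' @param enumeration_cap refuse generators with more core edges than this.
#' @return list of class \code{fsfn_connectivity}: \code{s} (integer vector
#'   indexed 0..m by subset size), \code{m_gen} (core edge count),
#'   \code{lambda}, \code{generator}.
#' @export
root_connectivity_counts <- function(g, reduce = TRUE, enumeration_cap = 24L) {
  stopifnot(inherits(g, "fsfn_generator"))
  core <- if (reduce) core_subgraph(g) else g
  E <- core$edges
  m <- nrow(E)
  if (m > enumeration_cap)
    stop("core subgraph has ", m, " edges, above the enumeration cap")
  nodes <- sort(unique(c(as.vector(E), core$roots)))
  a <- match(E[, 1], nodes); b <- match(E[, 2], nodes)
  r1 <- match(core$roots[1], nodes); r2 <- match(core$roots[2], nodes)
  nn <- length(nodes)

  s <- integer(m + 1)
  for (code in 0:(2^m - 1)) {
    inset <- bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) > 0
    # union-find over included edges
    parent <- seq_len(nn)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in which(inset)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
    if (find(r1) == find(r2)) s[sum(inset) + 1L] <- s[sum(inset) + 1L] + 1L
  }
  lambda <- unname(igraph::distances(core$graph, v = core$roots[1],
                                     to = core$roots[2])[1, 1])
  structure(list(s = s, m_gen = m, lambda = lambda, generator = g$name),
            class = "fsfn_connectivity")
}

#' @export
print.fsfn_connectivity <- function(x, ...) {
  nz <- which(x$s > 0) - 1
  cat("<fsfn_connectivity>", x$generator, " m_gen =", x$m_gen, "\n")
  cat("  s_m:", paste0("s", nz, "=", x$s[nz + 1], collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the reliability polynomial and its renormalization iterates
#'
#' \code{pi_eval} computes \eqn{\pi(p)}; \code{pi_deriv} its first
#' derivative; \code{pi_iterate} the \code{t}-fold composition
#' \eqn{R_t(p) = \pi[R_{t-1}(p)]} with \eqn{R_0 = p}, the probability that
#' the two oldest nodes of the generation-\code{t} network remain connected.
#'
#' @param poly an [root_connectivity_counts()] result.
#' @param p occupation probability (vectorized), in \eqn{[0, 1]}.
#' @param t number of iterations.
#' @return numeric probability (or derivative value).
#' @export
pi_eval <- function(poly, p) {
  stopifnot(inherits(poly, "fsfn_connectivity"))
  M <- poly$m_gen
  ms <- 0:M
  vapply(p, function(pp) sum(poly$s * pp^ms * (1 - pp)^(M - ms)), 0)
}

#' @rdname pi_eval
#' @export
pi_deriv <- function(poly, p) {
  M <- poly$m_gen
  ms <- 0:M
  vapply(p, function(pp) {
    up <- ifelse(ms >= 1, ms * pp^pmax(ms - 1, 0) * (1 - pp)^(M - ms), 0)
    dn <- ifelse(M - ms >= 1, (M - ms) * pp^ms * (1 - pp)^pmax(M - ms - 1, 0), 0)
    sum(poly$s * (up - dn))
  }, 0)
}

#' @rdname pi_eval
#' @export
pi_iterate <- function(poly, p, t) {
  stopifnot(t >= 0)
  r <- p
  for (i in seq_len(t)) r <- pi_eval(poly, r)
  r
}

#' Bond-percolation critical point
#'
#' The critical point of the infinite network is the unstable fixed point of
#' the reliability polynomial: the root of \eqn{\pi(p) = p} in (0, 1) with
#' \eqn{\pi'(p_c) > 1}. Roots are bracketed by a sign scan on a 1e4-point
#' grid and refined by bisection to \code{tol}. A generator whose polynomial
#' has no unstable fixed point below 1 (e.g. any tree-like core) never
#' percolates at \eqn{p < 1} and \code{p_c = 1} is reported.
#'
#' @param poly an [root_connectivity_counts()] result.
#' @param tol bisection tolerance (default 1e-12).
#' @return list with \code{p_c}, \code{dpi} (\eqn{\pi'(p_c)}), logical
#'   \code{transition} (FALSE for the tree-like case).
#' @export
critical_point <- function(poly, tol = 1e-12) {
  stopifnot(inherits(poly, "fsfn_connectivity"))
  f <- function(p) pi_eval(poly, p) - p
  grid <- seq(1e-4, 1 - 1e-4, length.out = 10000)
  v <- f(grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1))
    if (v[i] == 0 || v[i] * v[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                       tol = tol)$root)
  roots <- roots[!duplicated(round(roots, 9))]
  unstable <- roots[pi_deriv(poly, roots) > 1]
  if (length(unstable) == 0)
    return(list(p_c = 1, dpi = pi_deriv(poly, 1), transition = FALSE))
  if (length(unstable) > 1)
    stop("multiple unstable fixed points in (0,1): ",
         paste(signif(unstable, 8), collapse = ", "))
  list(p_c = unstable, dpi = pi_deriv(poly, unstable), transition = TRUE)
}

#' Correlation length and volume exponents
#'
#' One renormalization step shrinks lengths by \eqn{\lambda} and node counts
#' by \eqn{m_{gen}} while mapping \eqn{p \to \pi(p)}, so
#' \eqn{\nu = \log\lambda / \log\pi'(p_c)} and
#' \eqn{\tilde\nu = \log m_{gen} / \log\pi'(p_c) = D_f\,\nu}.
#'
#' @param poly an [root_connectivity_counts()] result.
#' @param p_c critical point (from [critical_point()]).
#' @return list with \code{nu}, \code{nu_tilde}, \code{dpi}.
#' @export
correlation_exponents <- function(poly, p_c) {
  stopifnot(inherits(poly, "fsfn_connectivity"), p_c > 0, p_c < 1)
  dpi <- pi_deriv(poly, p_c)
  if (dpi <= 1) stop("pi'(p_c) <= 1: not an unstable fixed point")
  list(nu = log(poly$lambda) / log(dpi),
       nu_tilde = log(poly$m_gen) / log(dpi),
       dpi = dpi)
}

#' Transfer-matrix coefficients for the order parameter
#'
#' A randomly chosen node lives inside one edge-copy \eqn{e_0} of the
#' coarse-grained generator; it is connected to one (state S) or both
#' (state T) of the network's two oldest nodes. One growth step maps
#' \eqn{(S, T)} linearly by a 2x2 matrix \eqn{W} whose entries are
#' polynomials in the copy-connection probability with integer coefficients
#' \eqn{c_{ij}(m)}: for every removed edge \eqn{e_0} and every subset of the
#' remaining edges (a subset edge = a copy whose own terminals are
#' connected), \eqn{c_{ij}(m)} counts the \eqn{m}-edge subsets in which
#' exactly \eqn{i} roots are reachable from the attachment set -- one
#' terminal of \eqn{e_0} for \eqn{j = 1} (both terminal choices counted,
#' normalized by 2), both terminals treated as internally connected for
#' \eqn{j = 2}.
#'
#' @param g an [fsfn_generator()].
#' @param enumeration_cap refuse generators with more edges than this.
#' @return list of class \code{fsfn_transfer_matrix} with \code{c11},
#'   \code{c12}, \code{c21}, \code{c22} (integer vectors indexed by
#'   \eqn{m = 0..m_{gen}-1}) and \code{m_gen}.
#' @export
transfer_matrix_coefficients <- function(g, enumeration_cap = 24L) {
  stopifnot(inherits(g, "fsfn_generator"))
  E <- g$edges
  m <- nrow(E)
  if (m > enumeration_cap)
    stop("generator has ", m, " edges, above the enumeration cap")
  nodes <- g$nodes
  a <- match(E[, 1], nodes); b <- match(E[, 2], nodes)
  r1 <- match(g$roots[1], nodes); r2 <- match(g$roots[2], nodes)
  nn <- length(nodes)
  c11 <- c12 <- c21 <- c22 <- integer(m)

  reach_roots <- function(edge_ids, start) {
    parent <- seq_len(nn)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in edge_ids) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(start) == 2) {
      ra <- find(start[1]); rb <- find(start[2])
      if (ra != rb) parent[ra] <- rb
    }
    comp <- find(start[1])
    (find(r1) == comp) + (find(r2) == comp)
  }

  for (e0 in seq_len(m)) {
    rest <- setdiff(seq_len(m), e0)
    u <- a[e0]; v <- b[e0]
    for (code in 0:(2^(m - 1) - 1)) {
      sel <- if (m == 1) integer(0)
             else rest[bitwAnd(code, bitwShiftL(1L, 0:(m - 2))) > 0]
      k <- length(sel) + 1L   # slot for m occupied copies (index m+1 = count m)
      for (start in c(u, v)) {            # j = 1: one terminal, copy internally open
        i <- reach_roots(sel, start)
        if (i == 1) c11[k] <- c11[k] + 1L
        if (i == 2) c21[k] <- c21[k] + 1L
      }
      i <- reach_roots(sel, c(u, v))      # j = 2: terminals merged
      if (i == 1) c12[k] <- c12[k] + 1L
      if (i == 2) c22[k] <- c22[k] + 1L
    }
  }
  structure(list(c11 = c11, c12 = c12, c21 = c21, c22 = c22, m_gen = m,
                 generator = g$name),
            class = "fsfn_transfer_matrix")
}

#' Evaluate the transfer matrix at an occupation probability
#'
#' @param tm an [transfer_matrix_coefficients()] result.
#' @param p copy-connection probability (at criticality, \eqn{p = p_c}).
#' @return 2x2 numeric matrix \eqn{W}.
#' @export
transfer_matrix_at <- function(tm, p) {
  stopifnot(inherits(tm, "fsfn_transfer_matrix"))
  M <- tm$m_gen
  ms <- 0:(M - 1)
  w <- function(cvec, j)
    sum(cvec * p^ms * (1 - p)^(M - 1 - ms)) / (M * (1 + (j == 1)))
  matrix(c(w(tm$c11, 1), w(tm$c12, 2),
           w(tm$c21, 1), w(tm$c22, 2)), 2, 2, byrow = TRUE)
}

#' Order-parameter exponent from the transfer matrix
#'
#' The largest eigenvalue \eqn{\omega_c} of \eqn{W(p_c)} is the asymptotic
#' ratio of largest-component fractions between successive generations at
#' criticality, giving \eqn{\beta = -\log\omega_c / \log\pi'(p_c)}. The
#' eigenvalue is computed in closed form from the 2x2 characteristic
#' polynomial.
#'
#' @param tm an [transfer_matrix_coefficients()] result.
#' @param poly an [root_connectivity_counts()] result.
#' @param p_c critical point.
#' @return list with \code{omega_c}, \code{beta}, \code{W}.
#' @export
order_parameter_exponent <- function(tm, poly, p_c) {
  stopifnot(p_c > 0, p_c < 1)
  W <- transfer_matrix_at(tm, p_c)
  tr <- W[1, 1] + W[2, 2]; dt <- W[1, 1] * W[2, 2] - W[1, 2] * W[2, 1]
  omega <- (tr + sqrt(tr^2 - 4 * dt)) / 2
  if (omega <= 0 || omega >= 1)
    stop("largest transfer-matrix eigenvalue outside (0,1): ", omega)
  dpi <- pi_deriv(poly, p_c)
  list(omega_c = omega, beta = -log(omega) / log(dpi), W = W)
}

#' Full bond-percolation report for a generator
#'
#' Runs the complete renormalization pipeline: core-subgraph reduction,
#' subset enumeration for the reliability polynomial, fixed-point search,
#' correlation exponents, transfer matrix and order-parameter exponent.
#'
#' @param g an [fsfn_generator()].
#' @return list of class \code{fsfn_percolation_report} with \code{p_c},
#'   \code{dpi}, \code{nu}, \code{nu_tilde}, \code{omega_c}, \code{beta},
#'   \code{s} (connectivity counts), \code{tm} (transfer coefficients),
#'   \code{transition}.
#' @export
percolation_report <- function(g) {
  stopifnot(inherits(g, "fsfn_generator"))
  poly <- root_connectivity_counts(g)
  cp <- critical_point(poly)
  if (!cp$transition) {
    return(structure(list(generator = g$name, p_c = 1, dpi = cp$dpi,
                          nu = NA_real_, nu_tilde = NA_real_,
                          omega_c = NA_real_, beta = NA_real_,
                          s = poly, tm = NULL, transition = FALSE),
                     class = "fsfn_percolation_report"))
  }
  ce <- correlation_exponents(poly, cp$p_c)
  tm <- transfer_matrix_coefficients(g)
  op <- order_parameter_exponent(tm, poly, cp$p_c)
  structure(list(generator = g$name, p_c = cp$p_c, dpi = cp$dpi,
                 nu = ce$nu, nu_tilde = ce$nu_tilde,
                 omega_c = op$omega_c, beta = op$beta,
                 s = poly, tm = tm, transition = TRUE),
            class = "fsfn_percolation_report")
}

#' @export
print.fsfn_percolation_report <- function(x, ...) {
  cat("<fsfn_percolation_report>", x$generator, "\n")
  if (!x$transition) {
    cat("  no percolation transition below p = 1 (tree-like core)\n")
    return(invisible(x))
  }
  cat(sprintf("  p_c=%.4f pi'(p_c)=%.4f\n", x$p_c, x$dpi))
  cat(sprintf("  nu=%.4f nu_tilde=%.4f omega_c=%.4f beta=%.4f\n",
              x$nu, x$nu_tilde, x$omega_c, x$beta))
  invisible(x)
}
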