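#' Bond percolation on a built network
#'
#' Keeps each edge independently with probability \code{p} (edges are removed
#' with probability \eqn{1 - p}).
#'
#' @param net an \code{fsfn_network}.
#' @param p occupation probability in \eqn{[0, 1]}.
#' @return logical vector over the rows of \code{net$edges}: kept edges.
#' @export
bond_percolate <- function(net, p) {
  stopifnot(inherits(net, "fsfn_network"), p >= 0, p <= 1)
  stats::runif(nrow(net$edges)) < p
}

# internal: membership vector of the percolated graph (all nodes kept)
percolated_membership <- function(gr, keep) {
  sub <- igraph::subgraph_from_edges(gr, igraph::E(gr)[keep],
                                     delete.vertices = FALSE)
  igraph::components(sub)$membership
}

#' Monte-Carlo estimate of the RRN connection probability
#'
#' Estimates \eqn{R_t(p)}, the probability that the two renormalized root
#' nodes (the two generation-0 nodes) remain connected after bond
#' percolation. The exact value is the \code{t}-fold iterate of the
#' reliability polynomial, [pi_iterate()].
#'
#' @param net an \code{fsfn_network} (carries the RRN markers).
#' @param p occupation probability.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return list with \code{estimate}, \code{se}, \code{reps}.
#' @export
rrn_connectivity <- function(net, p, reps = 2000, seed = 1) {
  stopifnot(inherits(net, "fsfn_network"), reps >= 1)
  if (is.null(net$rrn) || !all(net$rrn %in% names(net$birth)))
    stop("network lacks RRN markers")
  set.seed(as.integer(seed))
  gr <- as_igraph(net)
  idx <- match(net$rrn, igraph::V(gr)$name)
  hits <- logical(reps)
  for (i in seq_len(reps)) {
    memb <- percolated_membership(gr, bond_percolate(net, p))
    hits[i] <- memb[idx[1]] == memb[idx[2]]
  }
  est <- mean(hits)
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps)
}

#' Order-parameter curve from Monte-Carlo bond percolation
#'
#' For each occupation probability, replicates bond percolation and records
#' the fraction of nodes in the largest connected component (the finite-size
#' order parameter \eqn{P_t(p, N_t)}).
#'
#' @param net an \code{fsfn_network}.
#' @param p_grid vector of occupation probabilities.
#' @param reps replicates per grid point.
#' @param seed RNG seed.
#' @return data frame of class \code{fsfn_order_parameter_curve} with
#'   columns \code{p}, \code{mean}, \code{se}, \code{reps}; attributes
#'   \code{t}, \code{N}.
#' @export
order_parameter_curve <- function(net, p_grid, reps = 20, seed = 1) {
  stopifnot(inherits(net, "fsfn_network"), reps >= 1)
  set.seed(as.integer(seed))
  gr <- as_igraph(net)
  N <- igraph::vcount(gr)
  mean_ <- se_ <- numeric(length(p_grid))
  for (j in seq_along(p_grid)) {
    fr <- numeric(reps)
    for (i in seq_len(reps)) {
      memb <- percolated_membership(gr, bond_percolate(net, p_grid[j]))
      fr[i] <- max(tabulate(memb)) / N
    }
    mean_[j] <- mean(fr)
    se_[j] <- if (reps > 1) stats::sd(fr) / sqrt(reps) else NA_real_
  }
  out <- data.frame(p = unname(p_grid), mean = mean_, se = se_,
                    reps = unname(reps), row.names = NULL)
  attr(out, "t") <- net$t
  attr(out, "N") <- N
  class(out) <- c("fsfn_order_parameter_curve", "data.frame")
  out
}

#' Finite-size scaling collapse of order-parameter curves
#'
#' Rescales each curve to \eqn{y = P_t N_t^{\beta/\tilde\nu}} against
#' \eqn{x = (p - p_c) N_t^{1/\tilde\nu}} and measures the collapse quality
#' as the mean squared vertical spread between generation curves after
#' interpolation onto the common abscissa range, normalized at each abscissa
#' by the squared mean level (otherwise shrinking \eqn{\beta/\tilde\nu}
#' would shrink the absolute spread trivially). Correct exponents make
#' curves from different generations fall on one master curve; the score is
#' used as a soft test against deliberately perturbed exponents.
#'
#' @param curves list of [order_parameter_curve()] results (>= 2 generations;
#'   a single curve collapses onto itself with quality 0).
#' @param p_c,beta,nu_tilde critical point and exponents to test.
#' @param n_grid number of common-abscissa interpolation points.
#' @return list with \code{table} (rescaled coordinates) and \code{quality}
#'   (mean squared spread; smaller is better).
#' @export
scaling_collapse <- function(curves, p_c, beta, nu_tilde, n_grid = 50) {
  stopifnot(length(curves) >= 1)
  resc <- lapply(curves, function(cv) {
    N <- attr(cv, "N")
    data.frame(t = attr(cv, "t"), N = N,
               x = (cv$p - p_c) * N^(1 / nu_tilde),
               y = cv$mean * N^(beta / nu_tilde))
  })
  tab <- do.call(rbind, resc)
  if (length(curves) == 1) return(list(table = tab, quality = 0))
  lo <- max(vapply(resc, function(r) min(r$x), 0))
  hi <- min(vapply(resc, function(r) max(r$x), 0))
  if (lo >= hi) stop("rescaled abscissa ranges do not overlap")
  xs <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(resc, function(r) stats::approx(r$x, r$y, xout = xs)$y,
               numeric(n_grid))
  spread <- apply(ys, 1, function(row) mean((row - mean(row))^2) / mean(row)^2)
  list(table = tab, quality = mean(spread))
}

#' Empirical structural measurements of a built network
#'
#' Degree histogram, average and global clustering by direct count, and --
#' when a generator and generation range are supplied -- the diameter
#' sequence across generations with the least-squares fractal-dimension
#' estimate from \eqn{\log N_t} against \eqn{\log L_t}.
#'
#' @param net an \code{fsfn_network}.
#' @return list with \code{degree_census}, \code{C_avg}, \code{C_global},
#'   \code{diameter}.
#' @export
empirical_structure_suite <- function(net) {
  stopifnot(inherits(net, "fsfn_network"))
  gr <- as_igraph(net)
  list(
    degree_census = degree_census(net),
    C_avg = igraph::transitivity(gr, type = "localaverage", isolates = "zero"),
    C_global = igraph::transitivity(gr, type = "global"),
    diameter = igraph::diameter(gr)
  )
}

#' Fractal-dimension estimate from the generation sequence
#'
#' Builds generations \code{1..t_max} and measures exact diameters. Because
#' the diameter recursion carries an additive offset (\eqn{L_t = \lambda
#' L_{t-1} + L_0}), a raw log-log fit over small generations is biased
#' towards smaller dimensions; the offset cancels in successive ratios, so
#' the headline estimate is
#' \eqn{\hat D_f = \log(N_t/N_{t-1}) / \log(L_t/L_{t-1})} at the largest
#' generation. The least-squares slope over all generations is also returned
#' for reference.
#'
#' @param generator an [fsfn_generator()] (or list, see [build_network()]).
#' @param t_max largest generation (keep moderate; diameters are exact).
#' @param seed seed for stochastic builds.
#' @return list with \code{D_f_hat} (last-ratio estimate), \code{D_f_fit}
#'   (log-log regression slope), \code{table} (t, N, L).
#' @export
estimate_fractal_dimension <- function(generator, t_max = 4, seed = 1) {
  stopifnot(t_max >= 2)
  Ns <- Ls <- numeric(t_max)
  for (tt in seq_len(t_max)) {
    net <- build_network(generator, tt, seed = seed)
    Ns[tt] <- length(net$birth)
    Ls[tt] <- igraph::diameter(as_igraph(net))
  }
  fit <- stats::lm(log(Ns) ~ log(Ls))
  ratio <- log(Ns[t_max] / Ns[t_max - 1]) / log(Ls[t_max] / Ls[t_max - 1])
  list(D_f_hat = ratio,
       D_f_fit = unname(stats::coef(fit)[2]),
       table = data.frame(t = seq_len(t_max), N = Ns, L = Ls))
}
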