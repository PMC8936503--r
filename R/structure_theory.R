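#' Closed-form node and edge counts
#'
#' With the default single-edge initial graph, the generation-\code{t} network
#' has exactly \eqn{M_t = m_{gen}^t} edges and
#' \eqn{N_t = 2 + n_{rem}(m_{gen}^t - 1)/(m_{gen} - 1)} nodes, independently
#' of the generator's internal topology or symmetry.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, non-negative integer.
#' @return list with integers \code{N} and \code{M}.
#' @export
closed_form_sizes <- function(d, t) {
  stopifnot(inherits(d, "fsfn_descriptors"), t >= 0)
  M <- d$m_gen^t
  N <- 2 + d$n_rem * (M - 1) / (d$m_gen - 1)
  list(N = N, M = M)
}

#' Expected degree-count table N_t(k)
#'
#' For a symmetric generator the table is exact and integer-valued: the two
#' oldest nodes carry degree \eqn{\kappa^t}, and each remaining node of
#' generator degree \eqn{k_n} born at generation \eqn{t'} contributes
#' \eqn{m_{gen}^{t'-1}} nodes of degree \eqn{\kappa^{t-t'} k_n}. For an
#' asymmetric generator the table is the expectation over the fair
#' orientation flips: each node of degree \eqn{k'} sees \eqn{k_1} of its
#' edges replaced one way (binomial with probability 1/2) and acquires degree
#' \eqn{\kappa_1 k_1 + \kappa_2 (k'-k_1)}.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, \code{t >= 0}.
#' @param mode \code{"auto"} (from the symmetry flag), \code{"symmetric"} or
#'   \code{"asymmetric"}.
#' @param max_entries guard on the materialized table size.
#' @return data frame with columns \code{k}, \code{count}, attribute
#'   \code{t}; class \code{fsfn_degree_table}.
#' @export
degree_count_table <- function(d, t, mode = c("auto", "symmetric", "asymmetric"),
                               max_entries = 5e7) {
  stopifnot(inherits(d, "fsfn_descriptors"), t >= 0)
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (d$symmetric) "symmetric" else "asymmetric"
  if (mode == "symmetric" && !d$symmetric)
    stop("symmetric mode requested for an asymmetric generator")
  out <- if (t == 0) {
    data.frame(k = 1, count = 2)
  } else if (mode == "symmetric") {
    kap <- d$kappa1
    ks <- kap^t
    cnt <- 2
    for (tp in seq_len(t)) {
      ks <- c(ks, kap^(t - tp) * unname(d$k_rem))
      cnt <- c(cnt, rep(d$m_gen^(tp - 1), d$n_rem))
    }
    s <- rowsum(cnt, ks)
    data.frame(k = as.numeric(rownames(s)), count = as.vector(s))
  } else {
    N <- asym_degree_vector(d, t, max_entries)
    nz <- which(N > 0)
    data.frame(k = nz, count = N[nz])
  }
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "t") <- t
  class(out) <- c("fsfn_degree_table", "data.frame")
  out
}

# dense expected-count vector indexed by degree, asymmetric recurrence
asym_degree_vector <- function(d, t, max_entries = 5e7) {
  maxk <- max(d$kappa1, d$kappa2, d$k_rem)
  N <- numeric(maxk)
  for (k in c(d$kappa1, d$kappa2, unname(d$k_rem))) N[k] <- N[k] + 1
  if (t == 1) return(N)
  for (tt in 2:t) {
    size <- max(d$kappa1, d$kappa2) * length(N)
    if (size > max_entries) stop("degree table too large to materialize")
    ks <- which(N > 0)
    newk <- vector("list", length(ks)); w <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      kp <- ks[i]
      k1 <- binom_support(kp)
      newk[[i]] <- d$kappa1 * k1 + d$kappa2 * (kp - k1)
      w[[i]] <- stats::dbinom(k1, kp, 0.5) * N[kp]
    }
    agg <- rowsum(unlist(w), unlist(newk))
    N <- numeric(size)
    N[as.integer(rownames(agg))] <- as.vector(agg)
    for (kn in unname(d$k_rem)) N[kn] <- N[kn] + d$m_gen^(tt - 1)
  }
  N
}

#' Degree moments of the generation-t or infinite network
#'
#' The first moment is \eqn{2 M_t / N_t} for any generator. The second moment
#' follows the closed forms for symmetric generators (with the
#' \eqn{m_{gen} = \kappa^2} branch) and the orientation-averaged table for
#' asymmetric ones; the infinite-generation second moment is finite only when
#' \eqn{m_{gen} > \bar\kappa^2} (equivalently \eqn{\gamma > 3}).
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, or \code{Inf} for the thermodynamic limit.
#' @return list with \code{k_mean}, \code{k2_mean} (\code{Inf} when
#'   divergent) and logical \code{k2_divergent}.
#' @export
degree_moments <- function(d, t = Inf) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  m <- d$m_gen; nrem <- d$n_rem; kb <- d$kappa_bar
  if (is.infinite(t)) {
    k_mean <- 2 * (m - 1) / nrem
    if (m > kb^2) {
      k2_mean <- if (d$symmetric)
        d$K2rem * (m - 1) / (nrem * (m - d$kappa1^2))
      else
        (m - 1) * (2 * d$kappa_check^2 + d$K2rem) / (nrem * (m - kb^2))
      return(list(k_mean = k_mean, k2_mean = k2_mean, k2_divergent = FALSE))
    }
    return(list(k_mean = k_mean, k2_mean = Inf, k2_divergent = TRUE))
  }
  sz <- closed_form_sizes(d, t)
  k_mean <- 2 * sz$M / sz$N
  k2_mean <- if (d$symmetric) {
    kap <- d$kappa1
    if (m != kap^2) {
      (m - 1) * (2 * kap^(2 * t) * (m - kap^2) + d$K2rem * (m^t - kap^(2 * t))) /
        ((m - kap^2) * (2 * (m - 1) + nrem * (m^t - 1)))
    } else {
      kap^(2 * (t - 1)) * (kap^2 - 1) * (2 * kap^2 + t * d$K2rem) /
        (2 * (kap^2 - 1) + nrem * (kap^(2 * t) - 1))
    }
  } else {
    tab <- degree_count_table(d, t)
    sum(tab$k^2 * tab$count) / sz$N
  }
  list(k_mean = k_mean, k2_mean = k2_mean, k2_divergent = FALSE)
}

#' Power-law degree exponents
#'
#' \eqn{\gamma = 1 + \log m_{gen} / \log \bar\kappa} describes the envelope
#' of the degree distribution; the count exponent \eqn{\gamma'} equals
#' \eqn{\gamma - 1} when the two root degrees coincide (degrees are then
#' exponentially discretized) and \eqn{\gamma} otherwise. The network is
#' scale-free whenever \eqn{\bar\kappa > 1}; \eqn{\gamma \ge 2} always.
#'
#' @param d an [generator_descriptors()] bundle.
#' @return list with \code{gamma}, \code{gamma_prime}, logical
#'   \code{scale_free}.
#' @export
degree_exponents <- function(d) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  if (d$kappa_bar <= 1)
    return(list(gamma = NA_real_, gamma_prime = NA_real_, scale_free = FALSE))
  gamma <- 1 + log(d$m_gen) / log(d$kappa_bar)
  gp <- if (d$kappa1 == d$kappa2) gamma - 1 else gamma
  list(gamma = gamma, gamma_prime = gp, scale_free = TRUE)
}

#' Fractal dimension
#'
#' \eqn{D_f = \log m_{gen} / \log \lambda}: the diameter grows by a factor
#' \eqn{\lambda} per generation while the node count grows by
#' \eqn{m_{gen}}. Adjacent roots (\eqn{\lambda = 1}) make the network
#' small-world instead of fractal and the dimension diverges.
#'
#' @param d an [generator_descriptors()] bundle.
#' @return list with \code{D_f} (\code{Inf} when divergent) and logical
#'   \code{small_world}.
#' @export
fractal_dimension <- function(d) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  if (d$lambda <= 1) return(list(D_f = Inf, small_world = TRUE))
  list(D_f = log(d$m_gen) / log(d$lambda), small_world = FALSE)
}

#' Average clustering coefficient
#'
#' Every triangle of the grown network is created inside some generator copy.
#' Newly born nodes contribute the generator's remaining-node mean local
#' clustering; a node inherited with previous degree \eqn{k} sits in
#' \eqn{k \Delta_R} triangles at degree \eqn{\kappa k} (symmetric case), or
#' in a binomial orientation mixture of \eqn{\Delta_{R1}} and
#' \eqn{\Delta_{R2}} triangles (asymmetric case). The infinite-generation
#' value for symmetric generators is the closed-form series
#' \deqn{C_\infty = \frac{m-1}{m}\Big[C_{rem} + \frac{2\Delta_R}{n_{rem}\kappa}
#'   \sum_n \sum_{s\ge1} \frac{1}{(\kappa m)^s k_n - m^s}\Big],}
#' truncated when terms fall below \code{series_tol}; for asymmetric
#' generators it is obtained by iterating the finite-generation recurrence to
#' convergence.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, or \code{Inf}.
#' @param series_tol truncation threshold for the symmetric series.
#' @param tol convergence threshold for the asymmetric infinite limit.
#' @return numeric clustering coefficient.
#' @export
clustering_average <- function(d, t = Inf, series_tol = 1e-15, tol = 1e-6) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  if (d$Delta_gen == 0) return(0)
  m <- d$m_gen
  if (is.infinite(t)) {
    if (d$symmetric) {
      kap <- d$kappa1
      acc <- 0
      for (kn in unname(d$k_rem)) {
        s <- 1
        repeat {
          term <- 1 / ((kap * m)^s * kn - m^s)
          acc <- acc + term
          if (term < series_tol) break
          s <- s + 1
        }
      }
      return((m - 1) / m *
               (d$C_rem + 2 * d$Delta_R1 / (d$n_rem * kap) * acc))
    }
    prev <- clustering_average(d, 2)
    tt <- 3
    repeat {
      cur <- clustering_average(d, tt)
      if (abs(cur - prev) < tol) return(cur)
      prev <- cur
      tt <- tt + 1
      if (tt > 40) stop("asymmetric clustering limit failed to converge")
    }
  }
  if (t == 0) return(0)
  Nt <- closed_form_sizes(d, t)$N
  newborn <- d$n_rem * m^(t - 1) * d$C_rem
  tab <- degree_count_table(d, t - 1)
  inherited <- if (d$symmetric) {
    kap <- d$kappa1
    2 * d$Delta_R1 * sum(tab$count / (kap * (kap * tab$k - 1)))
  } else {
    acc <- 0
    for (i in seq_len(nrow(tab))) {
      k <- tab$k[i]
      k1 <- binom_support(k)
      h <- d$kappa1 * k1 + d$kappa2 * (k - k1)
      w <- 2 * stats::dbinom(k1, k, 0.5)  # choose(k, k1) / 2^(k-1)
      acc <- acc + tab$count[i] *
        sum(w * (d$Delta_R1 * k1 + d$Delta_R2 * (k - k1)) / (h * (h - 1)))
    }
    acc
  }
  (newborn + inherited) / Nt
}

#' Global clustering coefficient
#'
#' Three times the triangle count over the number of connected triplets:
#' \eqn{C^\triangle_t = 3\Delta_{gen}\langle k\rangle_t /
#' [m_{gen}(\langle k^2\rangle_t - \langle k\rangle_t)]}. The infinite limit
#' is finite only when \eqn{m_{gen} > \bar\kappa^2}; otherwise the second
#' moment diverges and the coefficient vanishes.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, or \code{Inf}.
#' @return numeric global clustering coefficient.
#' @export
clustering_global <- function(d, t = Inf) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  if (d$Delta_gen == 0) return(0)
  m <- d$m_gen
  if (is.infinite(t)) {
    if (m <= d$kappa_bar^2) return(0)
    return(6 * (m - d$kappa_bar^2) * d$Delta_gen /
             (d$n_gen * m * (d$k2_mean_gen - d$k_mean_gen)))
  }
  if (t == 0) return(0)
  mom <- degree_moments(d, t)
  3 * d$Delta_gen * mom$k_mean / (m * (mom$k2_mean - mom$k_mean))
}

#' Joint degree distribution of edge endpoints
#'
#' Probability \eqn{P_t(k, k')} that a uniformly random edge joins endpoints
#' of degrees \eqn{k} and \eqn{k'} (ordered pairs; the table is symmetric and
#' sums to 1). One contribution comes from edges between two newly born
#' remaining nodes, the other from edges between an inherited node and the
#' root-adjacent remaining nodes of its copies; for asymmetric generators the
#' inherited degree is the binomial orientation mixture and the two root
#' neighbourhood profiles \eqn{\mu_1, \mu_2} enter separately.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param t generation, \code{t >= 1}.
#' @param mode \code{"auto"}, \code{"symmetric"} or \code{"asymmetric"}.
#' @return data frame with columns \code{k}, \code{kp}, \code{p}; class
#'   \code{fsfn_joint_table}; attribute \code{t}.
#' @export
joint_degree_distribution <- function(d, t,
                                      mode = c("auto", "symmetric", "asymmetric")) {
  stopifnot(inherits(d, "fsfn_descriptors"), t >= 1)
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (d$symmetric) "symmetric" else "asymmetric"
  m <- d$m_gen
  K <- numeric(0); KP <- numeric(0); P <- numeric(0)
  # edges between two remaining nodes of the same copy
  for (i in seq_len(nrow(d$m_rem))) {
    k <- d$m_rem$k[i]; kp <- d$m_rem$kp[i]; cnt <- d$m_rem$count[i]
    if (k == kp) {
      K <- c(K, k); KP <- c(KP, kp); P <- c(P, cnt / m)
    } else {
      K <- c(K, k, kp); KP <- c(KP, kp, k); P <- c(P, cnt / (2 * m), cnt / (2 * m))
    }
  }
  pref <- 1 / (2 * m^t)
  tab <- degree_count_table(d, t - 1,
                            mode = if (mode == "symmetric") "symmetric" else "asymmetric")
  if (mode == "symmetric") {
    kap <- d$kappa1
    for (i in seq_len(nrow(tab))) {
      k <- kap * tab$k[i]
      for (j in seq_along(d$mu1)) {
        kn <- as.numeric(names(d$mu1)[j])
        v <- pref * k * unname(d$mu1[j]) / kap * tab$count[i]
        K <- c(K, k, kn); KP <- c(KP, kn, k); P <- c(P, v, v)
      }
    }
  } else {
    mu_deg <- sort(unique(as.numeric(c(names(d$mu1), names(d$mu2)))))
    lookup <- function(mu, s) { v <- mu[s]; if (length(v) != 1 || is.na(v)) 0 else as.numeric(v) }
    mu1v <- vapply(as.character(mu_deg), function(s) lookup(d$mu1, s), 0)
    mu2v <- vapply(as.character(mu_deg), function(s) lookup(d$mu2, s), 0)
    for (j in seq_along(mu_deg)) {
      hs <- vector("list", nrow(tab)); vs <- vector("list", nrow(tab))
      for (i in seq_len(nrow(tab))) {
        kpp <- tab$k[i]
        k1 <- binom_support(kpp)
        w <- stats::dbinom(k1, kpp, 0.5) * tab$count[i]
        hs[[i]] <- d$kappa1 * k1 + d$kappa2 * (kpp - k1)
        vs[[i]] <- pref * w * (k1 * mu1v[j] + (kpp - k1) * mu2v[j])
      }
      agg <- rowsum(unlist(vs), unlist(hs))
      hval <- as.numeric(rownames(agg)); vval <- as.vector(agg)
      keep <- vval > 0
      hval <- hval[keep]; vval <- vval[keep]
      K <- c(K, rep(mu_deg[j], length(hval)), hval)
      KP <- c(KP, hval, rep(mu_deg[j], length(hval)))
      P <- c(P, vval, vval)
    }
  }
  out <- aggregate_pairs(K, KP, P)
  attr(out, "t") <- t
  class(out) <- c("fsfn_joint_table", "data.frame")
  out
}

#' Assortativity and Spearman rank correlation from a joint degree table
#'
#' The assortativity \code{r} is the Pearson correlation of the two endpoint
#' degrees of a random edge; the Spearman coefficient \code{rho} is the
#' Pearson correlation of their mid-ranks (ties resolved by mid-ranks
#' computed from the endpoint-degree marginal).
#'
#' @param jt an [joint_degree_distribution()] table.
#' @return list with \code{r}, \code{rho}, logical \code{degenerate} (single
#'   endpoint degree; correlations undefined).
#' @export
degree_correlation_measures <- function(jt) {
  stopifnot(inherits(jt, "fsfn_joint_table") ||
              all(c("k", "kp", "p") %in% names(jt)))
  q <- rowsum(jt$p, jt$k)
  qk <- as.numeric(rownames(q)); qv <- as.vector(q)
  o <- order(qk); qk <- qk[o]; qv <- qv[o]
  if (length(qk) < 2)
    return(list(r = NA_real_, rho = NA_real_, degenerate = TRUE))
  keyf <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rk <- cumsum(c(0, qv))[seq_along(qv)] + qv / 2   # mid-ranks as mass fractions
  rmap <- stats::setNames(rk, keyf(qk))
  mu <- sum(qk * qv); s2 <- sum(qk^2 * qv) - mu^2
  r <- (sum(jt$k * jt$kp * jt$p) - mu^2) / s2
  mur <- sum(rk * qv); s2r <- sum(rk^2 * qv) - mur^2
  rho <- (sum(rmap[keyf(jt$k)] * rmap[keyf(jt$kp)] * jt$p) - mur^2) / s2r
  list(r = unname(r), rho = unname(rho), degenerate = FALSE)
}

#' Infinite-generation degree correlation limits
#'
#' Evaluates \code{r} and \code{rho} at increasing generations until two
#' successive values differ by less than \code{tol}. When \eqn{\gamma \le 4}
#' the third degree moment diverges and the assortativity limit is 0
#' regardless of the finite-generation trend; \code{rho} always converges.
#'
#' @param d an [generator_descriptors()] bundle.
#' @param tol convergence threshold (default 1e-4).
#' @param t_max largest generation tried.
#' @return list with \code{r}, \code{rho}, \code{t_converged}.
#' @export
degree_correlation_limit <- function(d, tol = 1e-4, t_max = 24) {
  stopifnot(inherits(d, "fsfn_descriptors"))
  ex <- degree_exponents(d)
  prev <- degree_correlation_measures(joint_degree_distribution(d, 2))
  tt <- 3
  repeat {
    cur <- degree_correlation_measures(joint_degree_distribution(d, tt))
    rho_ok <- abs(cur$rho - prev$rho) < tol
    r_ok <- abs(cur$r - prev$r) < tol ||
      (!is.na(ex$gamma) && ex$gamma <= 4)  # r limit forced to 0 below
    if (rho_ok && r_ok) break
    prev <- cur
    tt <- tt + 1
    if (tt > t_max) break
  }
  r_inf <- if (!is.na(ex$gamma) && ex$gamma <= 4) 0 else cur$r
  list(r = r_inf, rho = cur$rho, t_converged = tt)
}

#' Scale-free and fractal exponents of a multi-generator mixture
#'
#' When each edge is replaced by generator \eqn{G_i} with probability
#' \eqn{p_i}, the exponents follow the single-generator formulas with the
#' mixture means \eqn{\langle m_{gen}\rangle}, \eqn{\langle\kappa\rangle}
#' (mean root degree, averaging the two roots of asymmetric generators) and
#' \eqn{\langle\lambda\rangle}.
#'
#' @param descriptors list of [generator_descriptors()] bundles.
#' @param prob selection probabilities, summing to 1.
#' @return list with \code{gamma}, \code{D_f}, \code{m_mean},
#'   \code{kappa_mean}, \code{lambda_mean}, divergence flags.
#' @export
mixed_generator_exponents <- function(descriptors, prob) {
  stopifnot(length(descriptors) == length(prob),
            all(vapply(descriptors, inherits, TRUE, "fsfn_descriptors")))
  if (abs(sum(prob) - 1) > 1e-12) stop("probabilities must sum to 1")
  m_mean <- sum(prob * vapply(descriptors, `[[`, 0, "m_gen"))
  k_mean <- sum(prob * vapply(descriptors, `[[`, 0, "kappa_bar"))
  l_mean <- sum(prob * vapply(descriptors, `[[`, 0, "lambda"))
  gamma <- if (k_mean > 1) 1 + log(m_mean) / log(k_mean) else NA_real_
  D_f <- if (l_mean > 1) log(m_mean) / log(l_mean) else Inf
  list(gamma = gamma, D_f = D_f, m_mean = m_mean, kappa_mean = k_mean,
       lambda_mean = l_mean, scale_free = k_mean > 1, small_world = l_mean <= 1)
}

#' Full structural report of the network grown from a generator
#'
#' Assembles sizes, degree moments (finite and infinite generation), the
#' power-law and fractal exponents, average and global clustering, and the
#' degree-correlation measures into one flat record.
#'
#' @param g an [fsfn_generator()].
#' @param t finite generation at which to evaluate the finite-\code{t}
#'   quantities (default 3).
#' @return list of class \code{fsfn_structure_report}.
#' @export
structure_report <- function(g, t = 3) {
  stopifnot(inherits(g, "fsfn_generator"))
  d <- generator_descriptors(g)
  cond <- validate_conditions(g)
  sz <- closed_form_sizes(d, t)
  mom_t <- degree_moments(d, t)
  mom_inf <- degree_moments(d, Inf)
  ex <- degree_exponents(d)
  fd <- fractal_dimension(d)
  applicable <- cond$cond1 && cond$cond2
  corr <- degree_correlation_limit(d)
  corr_t <- degree_correlation_measures(joint_degree_distribution(d, t))
  structure(list(
    generator = g$name, t = t,
    N_t = sz$N, M_t = sz$M,
    k_mean_t = mom_t$k_mean, k_mean_inf = mom_inf$k_mean,
    k2_mean_t = mom_t$k2_mean, k2_mean_inf = mom_inf$k2_mean,
    k2_divergent = mom_inf$k2_divergent,
    gamma = if (applicable) ex$gamma else NA_real_,
    gamma_prime = if (applicable) ex$gamma_prime else NA_real_,
    scale_free = applicable && isTRUE(ex$scale_free),
    D_f = if (applicable) fd$D_f else NA_real_,
    small_world = fd$small_world,
    C_t = clustering_average(d, t), C_inf = clustering_average(d, Inf),
    C_tri_t = clustering_global(d, t), C_tri_inf = clustering_global(d, Inf),
    r_t = corr_t$r, rho_t = corr_t$rho,
    r_inf = if (applicable) corr$r else NA_real_,
    rho_inf = if (applicable) corr$rho else NA_real_,
    conditions = cond
  ), class = "fsfn_structure_report")
}

#' @export
print.fsfn_structure_report <- function(x, ...) {
  cat("<fsfn_structure_report>", x$generator, " (t =", x$t, ")\n")
  cat(sprintf("  N_t=%s M_t=%s\n", format(x$N_t), format(x$M_t)))
  cat(sprintf("  <k>_t=%s  <k>_inf=%s\n",
              format_fraction(x$k_mean_t), format_fraction(x$k_mean_inf)))
  cat(sprintf("  <k2>_t=%s  <k2>_inf=%s%s\n",
              format_fraction(x$k2_mean_t), format_fraction(x$k2_mean_inf),
              if (x$k2_divergent) " (divergent)" else ""))
  cat(sprintf("  gamma=%s gamma'=%s D_f=%s\n", format(x$gamma),
              format(x$gamma_prime), format(x$D_f)))
  cat(sprintf("  C_t=%s C_inf=%s Ctri_t=%s Ctri_inf=%s\n",
              signif(x$C_t, 6), signif(x$C_inf, 6),
              format_fraction(x$C_tri_t), format_fraction(x$C_tri_inf)))
  cat(sprintf("  r_t=%s rho_t=%s r_inf=%s rho_inf=%s\n",
              signif(x$r_t, 5), signif(x$rho_t, 5),
              format(x$r_inf), format_fraction(x$rho_inf)))
  invisible(x)
}
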