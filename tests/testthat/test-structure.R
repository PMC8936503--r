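test_that("closed-form sizes reproduce the reference counts exactly", {
  dA <- generator_descriptors(builtin_generator("A"))
  dC <- generator_descriptors(builtin_generator("C"))
  expect_equal(closed_form_sizes(dA, 3), list(N = 294, M = 512))
  expect_equal(closed_form_sizes(dA, 0), list(N = 2, M = 1))
  expect_equal(closed_form_sizes(dC, 6), list(N = 58826, M = 117649))
})

test_that("degree-count tables satisfy the recurrences and conserve mass", {
  fs <- fixture_set()
  dA <- generator_descriptors(fs$A)
  t2 <- degree_count_table(dA, 2)
  expect_equal(t2$k, c(3, 4, 6))
  expect_equal(t2$count, c(32, 2, 4))
  t1c <- degree_count_table(generator_descriptors(fs$C), 1)
  expect_equal(t1c$k, c(2, 3))
  expect_equal(t1c$count, c(1, 4))

  for (nm in names(fs)) {
    d <- generator_descriptors(fs[[nm]])
    for (tt in 0:5) {
      tab <- degree_count_table(d, tt)
      sz <- closed_form_sizes(d, tt)
      expect_equal(sum(tab$count), sz$N, info = paste(nm, tt))
      expect_equal(sum(tab$k * tab$count), 2 * sz$M, info = paste(nm, tt))
    }
  }
  expect_error(degree_count_table(generator_descriptors(fs$C), 2,
                                  mode = "symmetric"), "asymmetric")
})

test_that("degree moments take their exact infinite-generation values", {
  dA <- generator_descriptors(builtin_generator("A"))
  dB <- generator_descriptors(builtin_generator("B"))
  dC <- generator_descriptors(builtin_generator("C"))
  mA <- degree_moments(dA, Inf)
  expect_equal(mA$k_mean, 7 / 2)
  expect_equal(mA$k2_mean, 63 / 4)
  mB <- degree_moments(dB, Inf)
  expect_equal(mB$k_mean, 7 / 2); expect_equal(mB$k2_mean, 63 / 4)
  mC <- degree_moments(dC, Inf)
  expect_equal(mC$k_mean, 4)
  expect_equal(mC$k2_mean, 220 / 3)
  # m_gen = kappa^2 sits on the divergence boundary
  mf <- degree_moments(generator_descriptors(builtin_generator("flower", u = 2, v = 2)), Inf)
  expect_true(mf$k2_divergent)
  expect_equal(mf$k2_mean, Inf)
})

test_that("finite-generation moments agree with the tables to 1e-12", {
  for (nm in c("A", "B", "C", "shm2")) {
    d <- generator_descriptors(fixture_set()[[nm]])
    for (tt in c(2, 4)) {
      tab <- degree_count_table(d, tt)
      N <- closed_form_sizes(d, tt)$N
      mom <- degree_moments(d, tt)
      expect_equal(mom$k_mean, sum(tab$k * tab$count) / N,
                   tolerance = 1e-12, info = paste(nm, tt))
      expect_equal(mom$k2_mean, sum(tab$k^2 * tab$count) / N,
                   tolerance = 1e-12, info = paste(nm, tt))
    }
  }
  # the m_gen = kappa^2 closed-form branch
  d <- generator_descriptors(builtin_generator("flower", u = 2, v = 2))
  tab <- degree_count_table(d, 3)
  expect_equal(degree_moments(d, 3)$k2_mean,
               sum(tab$k^2 * tab$count) / closed_form_sizes(d, 3)$N,
               tolerance = 1e-12)
})

test_that("power-law exponents follow from the root degree and edge count", {
  dA <- generator_descriptors(builtin_generator("A"))
  dC <- generator_descriptors(builtin_generator("C"))
  exA <- degree_exponents(dA)
  expect_equal(exA$gamma, 4)
  expect_equal(exA$gamma_prime, 3)  # equal root degrees: discretized degrees
  exC <- degree_exponents(dC)
  expect_equal(round(exC$gamma, 4), 3.1237)
  expect_equal(exC$gamma_prime, exC$gamma)  # distinct root degrees
  expect_equal(degree_exponents(generator_descriptors(
    builtin_generator("flower", u = 2, v = 2)))$gamma, 3)
  # gamma >= 2 for every admissible generator
  for (nm in names(fixture_set())) {
    ex <- degree_exponents(generator_descriptors(fixture_set()[[nm]]))
    expect_gte(ex$gamma, 2)
  }
  # degree-1 root: not scale-free
  path <- fsfn_generator(c("r1", "x", "y", "r2"),
                         rbind(c("r1", "x"), c("x", "y"), c("y", "r2")),
                         c("r1", "r2"))
  expect_false(degree_exponents(generator_descriptors(path))$scale_free)
})

test_that("fractal dimension is log m over log lambda, diverging at lambda 1", {
  expect_equal(fractal_dimension(generator_descriptors(builtin_generator("A")))$D_f,
               log(8) / log(3))
  expect_equal(fractal_dimension(generator_descriptors(builtin_generator("C")))$D_f,
               log(7) / log(2))
  tri <- fsfn_generator(c("r1", "r2", "x"),
                        rbind(c("r1", "r2"), c("r1", "x"), c("r2", "x")),
                        c("r1", "r2"))
  fd <- fractal_dimension(generator_descriptors(tri))
  expect_true(fd$small_world)
  expect_equal(fd$D_f, Inf)
  # known-model recovery through the same formulas
  fl <- generator_descriptors(builtin_generator("flower", u = 3, v = 2))
  expect_equal(fractal_dimension(fl)$D_f, log(5) / log(2))
  expect_equal(degree_exponents(fl)$gamma, 1 + log(5) / log(2))
  sh <- generator_descriptors(builtin_generator("shm", z = 2))
  expect_equal(fractal_dimension(sh)$D_f, log(5) / log(3))
  expect_equal(degree_exponents(sh)$gamma, 1 + log(5) / log(2))
})

test_that("average clustering matches its closed forms and direct counts", {
  dA <- generator_descriptors(builtin_generator("A"))
  dB <- generator_descriptors(builtin_generator("B"))
  dC <- generator_descriptors(builtin_generator("C"))
  expect_equal(round(clustering_average(dA, Inf), 5), 0.31486)
  for (tt in 0:4) expect_equal(clustering_average(dB, tt), 0)
  expect_equal(clustering_average(dB, Inf), 0)
  expect_lt(abs(clustering_average(dC, Inf) - 0.3952), 1e-4)
  expect_equal(clustering_average(dA, 1), 5 / 9)

  # closed form vs direct count on the built network
  for (tt in 2:3) {
    net <- build_network(builtin_generator("A"), tt)
    emp <- igraph::transitivity(as_igraph(net), type = "localaverage",
                                isolates = "zero")
    expect_equal(clustering_average(dA, tt), emp, tolerance = 1e-12,
                 info = paste("t =", tt))
  }
  netC <- build_network(builtin_generator("C"), 3, seed = 2)
  empC <- igraph::transitivity(as_igraph(netC), type = "localaverage",
                               isolates = "zero")
  expect_lt(abs(clustering_average(dC, 3) - empC), 0.02)
})

test_that("global clustering matches its closed forms and direct counts", {
  dA <- generator_descriptors(builtin_generator("A"))
  dC <- generator_descriptors(builtin_generator("C"))
  expect_equal(clustering_global(dA, Inf), 3 / 14)
  expect_equal(clustering_global(dC, Inf), 9 / 182)
  expect_equal(clustering_global(generator_descriptors(builtin_generator("B")), Inf), 0)
  # a triangle-bearing generator with gamma <= 3: coefficient vanishes
  k4 <- fsfn_generator(c("r1", "r2", "x", "y"),
                       rbind(c("r1", "r2"), c("r1", "x"), c("r1", "y"),
                             c("r2", "x"), c("r2", "y"), c("x", "y")),
                       c("r1", "r2"))
  dtf <- generator_descriptors(k4)
  expect_gt(dtf$Delta_gen, 0)
  expect_lte(dtf$m_gen, dtf$kappa_bar^2)
  expect_equal(clustering_global(dtf, Inf), 0)
  for (tt in 2:3) {
    net <- build_network(builtin_generator("A"), tt)
    emp <- igraph::transitivity(as_igraph(net), type = "global")
    expect_equal(clustering_global(dA, tt), emp, tolerance = 1e-12,
                 info = paste("t =", tt))
  }
})

test_that("joint degree tables are normalized, symmetric and exact at t = 1", {
  dA <- generator_descriptors(builtin_generator("A"))
  j1 <- joint_degree_distribution(dA, 1)
  get <- function(jt, k, kp) jt$p[jt$k == k & jt$kp == kp]
  expect_equal(get(j1, 3, 3), 1 / 2)
  expect_equal(get(j1, 2, 3), 1 / 4)
  expect_equal(get(j1, 3, 2), 1 / 4)
  for (nm in c("A", "C", "flower32", "shm2")) {
    d <- generator_descriptors(fixture_set()[[nm]])
    for (tt in c(1, 3)) {
      jt <- joint_degree_distribution(d, tt)
      expect_equal(sum(jt$p), 1, tolerance = 1e-10, info = paste(nm, tt))
      flipped <- jt[order(jt$kp, jt$k), ]
      expect_equal(flipped$p, jt$p, info = paste(nm, tt))  # symmetry in (k, k')
    }
  }
  # same nearest-neighbour structure: A and B share every joint table
  dB <- generator_descriptors(builtin_generator("B"))
  for (tt in 1:4) {
    ja <- joint_degree_distribution(dA, tt)
    jb <- joint_degree_distribution(dB, tt)
    expect_equal(ja$k, jb$k); expect_equal(ja$kp, jb$kp)
    expect_equal(ja$p, jb$p, tolerance = 1e-12)
  }
})

test_that("degree-correlation measures behave and converge to known limits", {
  # product-form table: no correlation
  f <- c(0.25, 0.5, 0.25); ks <- c(2, 3, 5)
  prod_tab <- expand.grid(k = ks, kp = ks)
  prod_tab$p <- f[match(prod_tab$k, ks)] * f[match(prod_tab$kp, ks)]
  cm <- degree_correlation_measures(prod_tab)
  expect_equal(cm$r, 0, tolerance = 1e-12)
  expect_equal(cm$rho, 0, tolerance = 1e-12)

  degen <- data.frame(k = 3, kp = 3, p = 1)
  expect_true(degree_correlation_measures(degen)$degenerate)

  dA <- generator_descriptors(builtin_generator("A"))
  dB <- generator_descriptors(builtin_generator("B"))
  dC <- generator_descriptors(builtin_generator("C"))
  limA <- degree_correlation_limit(dA)
  expect_equal(limA$rho, -21 / 64, tolerance = 1e-4)
  expect_equal(degree_correlation_limit(dB)$rho, -21 / 64, tolerance = 1e-4)
  limC <- degree_correlation_limit(dC)
  expect_equal(limC$rho, -0.5221, tolerance = 1e-4)
  expect_equal(limC$r, 0)  # third moment diverges for gamma < 4
})

test_that("mixture exponents interpolate the single-generator formulas", {
  dA <- generator_descriptors(builtin_generator("A"))
  dB <- generator_descriptors(builtin_generator("B"))
  single <- mixed_generator_exponents(list(dA), 1)
  expect_equal(single$gamma, degree_exponents(dA)$gamma)
  expect_equal(single$D_f, fractal_dimension(dA)$D_f)
  mixAB <- mixed_generator_exponents(list(dA, dB), c(0.5, 0.5))
  expect_equal(mixAB$gamma, 4)
  expect_equal(mixAB$D_f, log(8) / log(3))
  # continuity and monotonicity in the mixing probability
  d22 <- generator_descriptors(builtin_generator("flower", u = 2, v = 2))
  d33 <- generator_descriptors(builtin_generator("flower", u = 3, v = 3))
  gs <- vapply(seq(0, 1, by = 0.1), function(p)
    mixed_generator_exponents(list(d22, d33), c(p, 1 - p))$gamma, 0)
  expect_equal(gs[1], degree_exponents(d33)$gamma)
  expect_equal(gs[11], degree_exponents(d22)$gamma)
  expect_true(all(diff(gs) > 0) || all(diff(gs) < 0))
  expect_error(mixed_generator_exponents(list(dA, dB), c(0.7, 0.7)), "sum to 1")
})

test_that("the structure report flags inapplicable sections for degenerate generators", {
  rep_ok <- structure_report(builtin_generator("A"), t = 2)
  expect_equal(rep_ok$gamma, 4)
  expect_equal(rep_ok$N_t, 38)
  tri <- fsfn_generator(c("r1", "r2", "x"),
                        rbind(c("r1", "r2"), c("r1", "x"), c("r2", "x")),
                        c("r1", "r2"))
  rep_bad <- structure_report(tri, t = 2)
  expect_true(is.na(rep_bad$gamma))
  expect_true(rep_bad$small_world)
  expect_gt(rep_bad$C_t, 0)  # clustering theory still applies
})
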