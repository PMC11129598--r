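models_each_scenario <- list(
  GHOST = msci_from_grid("GHOST", 0.3, 0.5, 0.3),
  INFLOW = msci_from_grid("INFLOW", 0.3, 0.5, 0.3),
  OUTFLOW = msci_from_grid("OUTFLOW", 0.3, 0.5, 0.3))

test_that("pairwise mixtures are proper densities", {
  for (m in models_each_scenario) {
    for (p in c("ab", "bc", "ac")) {
      d <- pairwise_density(m, p)
      w <- vapply(d$components, `[[`, 0, "weight")
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1)
      expect_equal(quad_mixture_mass(d), 1, tolerance = 1e-8)
      expect_equal(mixture_cdf(d, Inf), 1)
      expect_equal(mixture_cdf(d, support_min(d)), 0)
      expect_equal(mixture_pdf(d, support_min(d) / 2), 0)
    }
  }
})

test_that("a single within-population component is a shifted exponential", {
  # pure MSC, pair ab: weight-1 component starting at tau_T with rate 2/theta
  m <- msci_model("INFLOW", tau_T = 0.01, tau_R = 10, tau_H = 0.005,
                  tau_O = 11, theta = 0.036, gamma = 0)
  d <- pairwise_density(m, "ab")
  expect_length(d$components, 1L)
  tt <- seq(0.01, 0.2, length.out = 50)
  lam <- 2 / 0.036
  expect_equal(mixture_pdf(d, tt), lam * exp(-lam * (tt - 0.01)))
  # mean theta/2 above the support start
  mean_t <- stats::integrate(function(t) t * mixture_pdf(d, t), 0.01, Inf,
                             rel.tol = 1e-10)$value
  expect_equal(mean_t - 0.01, 0.036 / 2, tolerance = 1e-6)
})

test_that("minimum coalescent times order as the scenarios dictate", {
  sup <- function(m) vapply(c("ab", "bc", "ac"), function(p)
    support_min(pairwise_density(m, p)), 0)
  g <- sup(models_each_scenario$GHOST)
  expect_true(g[["ab"]] < g[["ac"]])
  expect_equal(g[["ac"]], g[["bc"]])           # both at tau_R
  expect_equal(g[["ab"]], models_each_scenario$GHOST$tau_T)
  i <- sup(models_each_scenario$INFLOW)
  expect_true(i[["bc"]] < i[["ab"]] && i[["ab"]] < i[["ac"]])
  expect_equal(i[["bc"]], models_each_scenario$INFLOW$tau_H)
  o <- sup(models_each_scenario$OUTFLOW)
  expect_true(o[["bc"]] < o[["ab"]])
  expect_equal(o[["ab"]], o[["ac"]])           # both at tau_T
  expect_equal(o[["bc"]], models_each_scenario$OUTFLOW$tau_H)
})

test_that("the pair not involving the recipient is a smooth single component", {
  smooth_pair <- c(GHOST = "bc", INFLOW = "ac", OUTFLOW = "ab")
  for (s in names(smooth_pair)) {
    d <- pairwise_density(models_each_scenario[[s]], smooth_pair[[s]])
    expect_length(d$components, 1L)
    # the recipient pairs carry a genuine two-component gamma mixture
    other <- setdiff(c("ab", "bc", "ac"), smooth_pair[[s]])
    for (p in other)
      expect_length(pairwise_density(models_each_scenario[[s]], p)$components, 2L)
  }
})

test_that("the joint density nests the 3-taxon MSC at gamma 0", {
  m <- msci_model("INFLOW", tau_T = 0.012, tau_R = 0.03, tau_H = 0.006,
                  tau_O = 0.15, theta = 0.04, gamma = 0)
  jd <- joint_density(m)
  pts <- list(list("ab|c", 0.02, 0.04), list("ab|c", 0.015, 0.032),
              list("a|bc", 0.035, 0.05), list("ac|b", 0.031, 0.06),
              list("ab|c", 0.05, 0.08))
  for (pt in pts)
    expect_equal(jd$logpdf(pt[[1]], pt[[2]], pt[[3]]),
                 msc_logpdf(pt[[1]], pt[[2]], pt[[3]], 0.012, 0.03, 0.04),
                 tolerance = 1e-10)
  # out-of-support ages give zero density, reported as -Inf
  expect_identical(jd$logpdf("ab|c", 0.005, 0.04), -Inf)
  expect_error(jd$logpdf("ab|c", 0.05, 0.04), "t2")
})

test_that("marginalizing the joint density reproduces the topology law and the pair laws", {
  for (s in names(models_each_scenario)) {
    m <- models_each_scenario[[s]]
    cu <- coalescent_units(m)
    p_theory <- topology_probs(m$gamma, cu[["C_T"]], cu[["C_S"]])
    p_quad <- vapply(1:3, function(k) quad_topology_prob(m, k), 0)
    expect_equal(unname(p_quad), unname(p_theory), tolerance = 1e-6)
    expect_equal(sum(p_quad), 1, tolerance = 1e-6)
  }
  # marginal density of one pair's coalescent age from the joint density
  m <- models_each_scenario$INFLOW
  jd <- joint_density(m)
  d_bc <- pairwise_density(m, "bc")
  hi <- m$tau_O + 60 * max(m$theta)
  for (t in c(0.009, 0.02, 0.05)) {
    # t_bc = t1 when bc coalesces first, t2 otherwise
    marg <- stats::integrate(function(v) exp(jd$logpdf(2L, t, v)), t, hi,
                             rel.tol = 1e-9)$value +
      sum(vapply(c(1L, 3L), function(k)
        stats::integrate(function(u) exp(jd$logpdf(k, u, t)),
                         0, t, rel.tol = 1e-9)$value, 0))
    expect_equal(marg, mixture_pdf(d_bc, t), tolerance = 1e-5)
  }
})

test_that("matched scenarios share topology laws but not time densities", {
  # match (gamma, C_T, C_S) across the three scenarios
  g <- 0.3; C_T <- 0.5; C_S <- 1.2; th <- 0.036
  mg <- msci_from_grid("GHOST", 0.3, C_T, g, ghost_stem_cu = C_S)
  mi <- msci_from_grid("INFLOW", 1.5 - (C_S - C_T), C_T, g)
  mo <- msci_from_grid("OUTFLOW", 1.5 - C_S, C_T, g)
  for (m in list(mg, mi, mo))
    expect_equal(coalescent_units(m), c(C_T = C_T, C_S = C_S))
  tt <- seq(0, 0.2, length.out = 400)
  sup_diff <- function(m1, m2, p)
    max(abs(mixture_pdf(pairwise_density(m1, p), tt) -
            mixture_pdf(pairwise_density(m2, p), tt)))
  # identical topology probabilities ...
  expect_equal(topology_probs(g, C_T, C_S), topology_probs(g, C_T, C_S))
  # ... but visibly different coalescent-time densities
  expect_gt(sup_diff(mg, mi, "bc"), 1)
  expect_gt(sup_diff(mg, mo, "bc"), 1)
  expect_gt(sup_diff(mi, mo, "ab"), 1)
})
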